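#' Bundle spectra with class labels
#'
#' @param items list of [raman_spectrum()] objects (representation `"full"`)
#'   or [discrete_spectrum()] objects (representation `"discrete"`), all of
#'   one kind.
#' @param labels character vector of class labels, one per item.
#' @param representation `"full"` or `"discrete"`.
#' @return A list of class `labeled_dataset`.
#' @export
labeled_dataset <- function(items, labels,
                            representation = c("full", "discrete")) {
  representation <- match.arg(representation)
  labels <- as.character(labels)
  if (length(items) != length(labels))
    stop_data("items and labels must have equal length")
  check <- if (representation == "full") is_raman_spectrum
           else is_discrete_spectrum
  if (!all(vapply(items, check, logical(1))))
    stop_data(sprintf("all items must be %s spectra", representation))
  structure(list(items = items, labels = labels,
                 representation = representation),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d %s spectra, %d classes\n",
              length(x$items), x$representation,
              length(unique(x$labels))))
  print(table(x$labels))
  invisible(x)
}

#' Build a reference peak vocabulary from training spectra
#'
#' All peak positions of the training discrete spectra are pooled, sorted,
#' and merged by single linkage: runs of positions in which consecutive
#' gaps are at most `delta` collapse to their mean. The resulting reference
#' positions are therefore pairwise more than `delta` apart, giving the
#' fixed feature dimension needed by LDA.
#'
#' @param training a `labeled_dataset` of discrete spectra (or a plain list
#'   of [discrete_spectrum()] objects).
#' @param delta merge/matching tolerance in cm^-1.
#' @return A list of class `peak_vocabulary` with `positions` and `delta`.
#' @export
build_vocabulary <- function(training, delta = 10) {
  items <- if (inherits(training, "labeled_dataset")) training$items
           else training
  if (!length(items)) stop_data("empty training set")
  if (!all(vapply(items, is_discrete_spectrum, logical(1))))
    stop_data("vocabulary requires discrete spectra")
  pos <- sort(unlist(lapply(items, function(d) d$peaks$position)))
  merged <- if (length(pos)) {
    cluster <- cumsum(c(1, diff(pos) > delta))
    as.numeric(tapply(pos, cluster, mean))
  } else numeric(0)
  structure(list(positions = merged, delta = delta),
            class = "peak_vocabulary")
}

#' Project a discrete spectrum onto a peak vocabulary
#'
#' Feature `j` is the intensity of the spectrum's peak matched to vocabulary
#' position `j` (nearest peak within `delta`, each position considered
#' independently), or 0 when no peak falls within the tolerance. Peaks
#' outside the vocabulary are ignored.
#'
#' @param d a [discrete_spectrum()].
#' @param vocab a [build_vocabulary()] result.
#' @return Numeric feature vector of length `length(vocab$positions)`.
#' @export
vectorize_peaks <- function(d, vocab) {
  assert_discrete(d)
  if (!inherits(vocab, "peak_vocabulary"))
    stop_data("vocab must be a peak_vocabulary")
  out <- numeric(length(vocab$positions))
  if (!nrow(d$peaks) || !length(out)) return(out)
  for (j in seq_along(vocab$positions)) {
    dist <- abs(d$peaks$position - vocab$positions[j])
    w <- which.min(dist)
    if (dist[w] <= vocab$delta) out[j] <- d$peaks$intensity[w]
  }
  out
}

# Feature matrix (samples in rows) of a list of discrete spectra.
vectorize_all <- function(items, vocab) {
  m <- matrix(0, length(items), length(vocab$positions))
  for (i in seq_along(items)) m[i, ] <- vectorize_peaks(items[[i]], vocab)
  m
}

# Intensities of all spectra interpolated onto one common grid (the first
# spectrum's grid unless given), spectra in rows.
dataset_matrix <- function(items, grid = NULL) {
  if (is.null(grid)) grid <- items[[1]]$shifts
  t(vapply(items, function(s) {
    if (length(s$shifts) == length(grid) && all(s$shifts == grid))
      s$intensities
    else
      stats::approx(s$shifts, s$intensities, xout = grid, rule = 2)$y
  }, numeric(length(grid))))
}

# Pearson-correlation similarity between rows of two spectrum matrices.
pearson_similarity <- function(A, B) {
  stats::cor(t(A), t(B))
}

# Pairwise combined similarity between two lists of discrete spectra.
combined_similarity_matrix <- function(xs, ys, delta = 10) {
  S <- matrix(0, length(xs), length(ys))
  for (i in seq_along(xs))
    for (j in seq_along(ys))
      S[i, j] <- combined_similarity(xs[[i]], ys[[j]], delta)
  S
}

# Majority vote over the k most similar references; similarity ties are
# broken by earlier reference order (stable sort), vote ties by the label
# of the single nearest neighbour.
.vote <- function(sims, ref_labels, k) {
  ord <- order(-sims)  # stable: equal similarities keep reference order
  top <- ref_labels[ord[seq_len(k)]]
  counts <- table(top)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1) winners else top[1]
}

#' k-nearest-neighbour prediction for one spectrum
#'
#' Similarity to every reference is computed with the measure that matches
#' the representation: Pearson correlation of intensity vectors over the
#' common shift grid for full spectra, or the combined discrete similarity
#' `sqrt(s1) * s2` for discrete spectra. The majority label among the `k`
#' most similar references is returned; similarity ties are broken by
#' earlier dataset order and vote ties by the nearest neighbour's label.
#'
#' @param query a [raman_spectrum()] or [discrete_spectrum()] matching the
#'   reference representation.
#' @param references a [labeled_dataset()].
#' @param k number of neighbours (default 1).
#' @param delta matching tolerance for the discrete measure.
#' @return The predicted class label (character scalar).
#' @export
knn_predict <- function(query, references, k = 1L, delta = 10) {
  if (!inherits(references, "labeled_dataset"))
    stop_data("references must be a labeled_dataset")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop_config("k must be >= 1")
  if (k > length(references$items))
    stop_config(sprintf("k=%d exceeds the number of references (%d)",
                        k, length(references$items)))
  sims <- if (references$representation == "full") {
    assert_spectrum(query)
    drop(pearson_similarity(dataset_matrix(list(query)),
                            dataset_matrix(references$items,
                                           grid = query$shifts)))
  } else {
    assert_discrete(query)
    vapply(references$items,
           function(r) combined_similarity(query, r, delta), numeric(1))
  }
  .vote(sims, references$labels, k)
}

#' Fit a regularized linear discriminant classifier
#'
#' Multi-class Fisher discriminant: per-class mean vectors and the pooled
#' within-class covariance, regularized as `Sigma + ridge * I` so the fit
#' remains defined when the feature dimension exceeds the sample count
#' (as it does for full spectra with > 1,000 channels). Classification uses
#' the standard linear discriminant score
#' `x' W mu_k - mu_k' W mu_k / 2 + log pi_k` with `W` the inverse
#' regularized covariance.
#'
#' @param x numeric feature matrix, samples in rows.
#' @param labels class label per row; >= 2 classes, >= 2 samples per class.
#' @param ridge non-negative ridge added to the diagonal of the pooled
#'   covariance (default 1e-3).
#' @param priors `"equal"` (default) or `"frequency"` for class-frequency
#'   priors.
#' @return A list of class `rdisc_lda`.
#' @export
lda_fit <- function(x, labels, ridge = 1e-3, priors = c("equal", "frequency")) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels))
    stop_data("x and labels must have matching lengths")
  if (!is.finite(ridge) || ridge < 0) stop_config("ridge must be >= 0")
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop_data("LDA needs at least 2 classes")
  counts <- table(factor(labels, classes))
  if (any(counts < 2))
    stop_data("LDA needs at least 2 samples per class")
  p <- ncol(x)
  means <- matrix(0, length(classes), p)
  for (ci in seq_along(classes))
    means[ci, ] <- colMeans(x[labels == classes[ci], , drop = FALSE])
  centered <- x - means[match(labels, classes), , drop = FALSE]
  sw <- crossprod(centered) / (nrow(x) - length(classes))
  sw_r <- sw + diag(ridge, p)
  winv <- tryCatch(solve(sw_r, t(means)),
                   error = function(e)
                     stop_rdisc(paste0("singular within-class scatter; ",
                                       "refit with ridge > 0"),
                                "rdisc_numerical_error"))
  prior <- if (priors == "equal") rep(1 / length(classes), length(classes))
           else as.numeric(counts) / nrow(x)
  structure(list(classes = classes, means = means, w = winv,
                 const = -0.5 * colSums(t(means) * winv) + log(prior),
                 ridge = ridge, priors = priors),
            class = "rdisc_lda")
}

#' Predict class labels with a fitted LDA model
#'
#' @param model an [lda_fit()] result.
#' @param x feature matrix (or single vector) with the training dimension.
#' @return Character vector of predicted labels, one per row; ties go to the
#'   first class in sorted order (deterministic).
#' @export
lda_predict <- function(model, x) {
  if (!inherits(model, "rdisc_lda")) stop_data("model must be an rdisc_lda")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$w))
    stop_data(sprintf("feature dimension %d does not match the model (%d)",
                      ncol(x), nrow(model$w)))
  scores <- x %*% model$w + rep(model$const, each = nrow(x))
  model$classes[apply(scores, 1, which.max)]
}

#' Evaluate a classifier under repeated stratified splits
#'
#' The protocol used throughout: the labeled dataset is split at random
#' into training and test groups at the given ratio (stratified per class
#' so small classes never vanish from training), the classifier is fitted
#' on the training side only -- including the peak vocabulary for discrete
#' LDA -- and test accuracy is recorded; this is repeated `repeats` times
#' and the per-repeat accuracies and their mean reported.
#'
#' @param dataset a [labeled_dataset()].
#' @param method `"knn"` or `"lda"`.
#' @param split training fraction in (0, 1), default 0.6.
#' @param repeats number of random splits, default 10.
#' @param seed integer master seed; fixed seed gives an identical report.
#' @param k neighbours for k-NN (default 1).
#' @param ridge LDA regularization (default 1e-3).
#' @param delta peak matching tolerance in cm^-1 (default 10).
#' @return A list of class `rdisc_eval`: `per_repeat_accuracy`,
#'   `mean_accuracy`, `method`, `representation`, `seed`.
#' @examples
#' \donttest{
#' tpls <- default_templates(3, seed = 1)
#' ds <- simulate_dataset(tpls, per_class = 6, n_shifts = 512, seed = 1)
#' disc <- discretize_dataset(ds)
#' evaluate_classification(disc, "knn", repeats = 2, seed = 1)
#' }
#' @export
evaluate_classification <- function(dataset, method = c("knn", "lda"),
                                    split = 0.6, repeats = 10L, seed = 1L,
                                    k = 1L, ridge = 1e-3, delta = 10) {
  method <- match.arg(method)
  if (!inherits(dataset, "labeled_dataset"))
    stop_data("dataset must be a labeled_dataset")
  if (!is.finite(split) || split <= 0 || split >= 1)
    stop_config("split must be in (0, 1)")
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1) stop_config("repeats must be >= 1")
  labels <- dataset$labels
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < 2))
    stop_data(sprintf("stratified splitting needs >= 2 members per class; '%s' has %d",
                      names(counts)[which.min(counts)], min(counts)))
  representation <- dataset$representation

  # classifier-independent pairwise similarities can be precomputed once
  S <- NULL
  full_mat <- NULL
  if (method == "knn") {
    S <- if (representation == "full") {
      full_mat <- dataset_matrix(dataset$items)
      pearson_similarity(full_mat, full_mat)
    } else {
      combined_similarity_matrix(dataset$items, dataset$items, delta)
    }
  } else if (representation == "full") {
    full_mat <- dataset_matrix(dataset$items)
  }

  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    train_idx <- integer(0)
    for (cl in names(counts)) {
      members <- which(labels == cl)
      n_tr <- max(1L, min(length(members) - 1L,
                          round(split * length(members))))
      train_idx <- c(train_idx, sample(members, n_tr))
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(n), train_idx)
    pred <- if (method == "knn") {
      if (k > length(train_idx))
        stop_config(sprintf("k=%d exceeds the training size (%d)",
                            k, length(train_idx)))
      vapply(test_idx, function(i)
        .vote(S[i, train_idx], labels[train_idx], k), character(1))
    } else if (representation == "discrete") {
      vocab <- build_vocabulary(dataset$items[train_idx], delta)
      xtr <- vectorize_all(dataset$items[train_idx], vocab)
      xte <- vectorize_all(dataset$items[test_idx], vocab)
      model <- lda_fit(xtr, labels[train_idx], ridge = ridge)
      lda_predict(model, xte)
    } else {
      model <- lda_fit(full_mat[train_idx, , drop = FALSE],
                       labels[train_idx], ridge = ridge)
      lda_predict(model, full_mat[test_idx, , drop = FALSE])
    }
    acc[r] <- mean(pred == labels[test_idx])
  }
  structure(list(per_repeat_accuracy = acc, mean_accuracy = mean(acc),
                 method = method, representation = representation,
                 seed = as.integer(seed)),
            class = "rdisc_eval")
}

#' @export
print.rdisc_eval <- function(x, ...) {
  cat(sprintf("<rdisc_eval> %s / %s representation, %d repeats (seed %d)\n",
              x$method, x$representation, length(x$per_repeat_accuracy),
              x$seed))
  cat("  per-repeat accuracy:",
      paste(sprintf("%.3f", x$per_repeat_accuracy), collapse = " "), "\n")
  cat(sprintf("  mean accuracy: %.4f\n", x$mean_accuracy))
  invisible(x)
}

#' Quality-control every spectrum of a full-representation dataset
#'
#' Runs [qc_pipeline()] on each spectrum, keeping the full representation.
#' Classification of full spectra is meant to operate on quality-controlled
#' intensities, so run this before [evaluate_classification()] on raw data.
#'
#' @param dataset a full-representation [labeled_dataset()].
#' @param cfg a [qc_config()].
#' @return A full-representation [labeled_dataset()] of QC'd spectra.
#' @export
qc_dataset <- function(dataset, cfg = qc_config()) {
  if (!inherits(dataset, "labeled_dataset") ||
      dataset$representation != "full")
    stop_data("dataset must be a full-representation labeled_dataset")
  labeled_dataset(lapply(dataset$items, qc_pipeline, cfg = cfg),
                  dataset$labels, "full")
}

#' Discretize every spectrum of a full-representation dataset
#'
#' Convenience wrapper: runs [qc_pipeline()] (optionally) and [discretize()]
#' on each spectrum and returns the discrete-representation dataset.
#'
#' @param dataset a full-representation [labeled_dataset()].
#' @param qc run [qc_pipeline()] first (default `TRUE`; set to `FALSE` for
#'   spectra that are already quality-controlled).
#' @param qc_cfg a [qc_config()].
#' @param cfg a [disc_config()].
#' @return A discrete-representation [labeled_dataset()].
#' @export
discretize_dataset <- function(dataset, qc = TRUE, qc_cfg = qc_config(),
                               cfg = disc_config()) {
  if (!inherits(dataset, "labeled_dataset") ||
      dataset$representation != "full")
    stop_data("dataset must be a full-representation labeled_dataset")
  items <- lapply(dataset$items, function(s) {
    if (qc) s <- qc_pipeline(s, qc_cfg)
    discretize(s, cfg)
  })
  labeled_dataset(items, dataset$labels, "discrete")
}
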