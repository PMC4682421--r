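# Similarity of discrete spectra: peaks from the two spectra are put in
# one-to-one correspondence (positions within delta cm^-1 of each other),
# then scored by position overlap (Jaccard), matched-intensity Pearson
# correlation, and their combination sqrt(s1) * s2.

#' Match peaks of two discrete spectra
#'
#' Finds a one-to-one matching between the peak lists of `a` and `b` such
#' that matched positions differ by at most `delta` cm^-1, the number of
#' matched pairs is maximal, and among maximal matchings the total position
#' distance is minimal. Because peak lists are sorted, an optimal matching
#' is always non-crossing, so it is computed by dynamic programming over the
#' two sorted lists. The result is invariant to argument order.
#'
#' @param a,b [discrete_spectrum()] objects.
#' @param delta matching tolerance in cm^-1 (> 0), default 10.
#' @return A list of class `peak_matching`: `pairs` (two-column integer
#'   matrix of matched indices into `a` and `b`), `n_a`, `n_b`, `delta`.
#' @examples
#' a <- discrete_spectrum(data.frame(position = c(1000, 1200, 1400),
#'   intensity = c(.5, .7, .9), curvature = c(1, 1, 1)), 2048)
#' b <- discrete_spectrum(data.frame(position = c(1005, 1200, 1600),
#'   intensity = c(.4, .8, .2), curvature = c(1, 1, 1)), 2048)
#' match_peaks(a, b, 10)$pairs
#' @export
match_peaks <- function(a, b, delta = 10) {
  assert_discrete(a); assert_discrete(b)
  if (!is.finite(delta) || delta <= 0) stop_config("delta must be > 0")
  # canonical argument order makes tie-breaking symmetric in (a, b)
  key <- function(d) c(nrow(d$peaks), if (nrow(d$peaks)) d$peaks$position[1] else -Inf,
                       sum(d$peaks$position))
  swap <- {
    ka <- key(a); kb <- key(b)
    cmp <- kb - ka
    nz <- which(cmp != 0)
    length(nz) > 0 && cmp[nz[1]] < 0
  }
  if (swap) { tmp <- a; a <- b; b <- tmp }
  pa <- a$peaks$position
  pb <- b$peaks$position
  na <- length(pa); nb <- length(pb)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  if (na > 0 && nb > 0) {
    cnt <- matrix(0L, na + 1, nb + 1)
    tot <- matrix(0, na + 1, nb + 1)
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        best_c <- cnt[i, j + 1]; best_t <- tot[i, j + 1]   # skip a_i
        if (cnt[i + 1, j] > best_c ||
            (cnt[i + 1, j] == best_c && tot[i + 1, j] < best_t)) {
          best_c <- cnt[i + 1, j]; best_t <- tot[i + 1, j] # skip b_j
        }
        d <- abs(pa[i] - pb[j])
        if (d <= delta) {
          mc <- cnt[i, j] + 1L; mt <- tot[i, j] + d
          if (mc > best_c || (mc == best_c && mt < best_t)) {
            best_c <- mc; best_t <- mt
          }
        }
        cnt[i + 1, j + 1] <- best_c
        tot[i + 1, j + 1] <- best_t
      }
    }
    i <- na; j <- nb
    acc <- vector("list", min(na, nb)); np <- 0L
    while (i > 0 && j > 0) {
      d <- abs(pa[i] - pb[j])
      if (d <= delta &&
          cnt[i + 1, j + 1] == cnt[i, j] + 1L &&
          tot[i + 1, j + 1] == tot[i, j] + d) {
        np <- np + 1L
        acc[[np]] <- c(i, j)
        i <- i - 1L; j <- j - 1L
      } else if (cnt[i + 1, j + 1] == cnt[i, j + 1] &&
                 tot[i + 1, j + 1] == tot[i, j + 1]) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    }
    if (np > 0)
      pairs <- matrix(unlist(rev(acc[seq_len(np)])), ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("a", "b")))
  }
  if (swap) {
    pairs <- pairs[, 2:1, drop = FALSE]
    colnames(pairs) <- c("a", "b")
    tmp <- na; na <- nb; nb <- tmp
    tmp <- a; a <- b; b <- tmp
  }
  structure(list(pairs = pairs, n_a = na, n_b = nb, delta = delta),
            class = "peak_matching")
}

#' Peak-position similarity (Jaccard over matched peaks)
#'
#' `s1 = |matched| / |union|` with the union counted by inclusion-exclusion,
#' `n_a + n_b - |matched|`. Two spectra with no peaks at all score 0.
#'
#' @inheritParams match_peaks
#' @return A score in \[0, 1\].
#' @export
s1_position <- function(a, b, delta = 10) {
  m <- match_peaks(a, b, delta)
  denom <- m$n_a + m$n_b - nrow(m$pairs)
  if (denom == 0) return(0)
  nrow(m$pairs) / denom
}

#' Matched-peak intensity similarity (Pearson correlation)
#'
#' Pearson correlation of the intensities of matched peak pairs. Defined as
#' 0 when there are no common peaks; the same convention extends to a single
#' common peak or constant matched intensities, where the correlation is
#' undefined.
#'
#' @inheritParams match_peaks
#' @return A score in \[-1, 1\].
#' @export
s2_intensity <- function(a, b, delta = 10) {
  m <- match_peaks(a, b, delta)
  if (nrow(m$pairs) < 2) return(0)
  va <- a$peaks$intensity[m$pairs[, "a"]]
  vb <- b$peaks$intensity[m$pairs[, "b"]]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(0)
  stats::cor(va, vb)
}

#' Combined discrete-spectrum similarity
#'
#' `s = sqrt(s1) * s2`: the square root of the position Jaccard score
#' weighted by the matched-intensity correlation. This is the similarity
#' used for k-NN over discrete spectra.
#'
#' @inheritParams match_peaks
#' @return A score in \[-1, 1\].
#' @examples
#' # identical spectra with >= 2 non-constant peaks score exactly 1
#' a <- discrete_spectrum(data.frame(position = c(800, 1200),
#'   intensity = c(.4, .9), curvature = c(1, 1)), 1024)
#' combined_similarity(a, a)
#' @export
combined_similarity <- function(a, b, delta = 10) {
  sqrt(s1_position(a, b, delta)) * s2_intensity(a, b, delta)
}
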