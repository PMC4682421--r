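#' Discretization configuration
#'
#' @param M sliding half-window in channels for candidate peak detection;
#'   also the width of the noise-estimation windows (default 20).
#' @param lambda_min curvature threshold: a candidate peak is kept only when
#'   its curvature (on the unit channel grid) exceeds this value. Default
#'   3e-3, calibrated so peaks originating from autofluorescence-background
#'   residuals and broad flat bumps (width >= 200 cm^-1) are rejected while
#'   marker peaks of FWHM 10-30 cm^-1 pass: on a ~1.4 cm^-1 channel grid
#'   the weakest marker of interest (relative height 0.3, FWHM 30 cm^-1)
#'   has apex curvature about 5e-3, while smooth background bumps stay
#'   below about 2e-3.
#' @param var_rule rule selecting the quiescent ("below-threshold variant")
#'   windows for noise estimation; currently `"median"`: windows whose
#'   variance is at most the median of all window variances.
#' @param delta_match peak-position matching tolerance in cm^-1 (default 10).
#' @return A list of class `disc_config`.
#' @export
disc_config <- function(M = 20L, lambda_min = 3e-3, var_rule = "median",
                        delta_match = 10) {
  M <- as.integer(M)
  if (is.na(M) || M < 2) stop_config("M must be >= 2")
  if (!is.finite(lambda_min) || lambda_min < 0)
    stop_config("lambda_min must be >= 0")
  if (!identical(var_rule, "median"))
    stop_config("var_rule must be 'median'")
  if (!is.finite(delta_match) || delta_match <= 0)
    stop_config("delta_match must be > 0")
  structure(list(M = M, lambda_min = lambda_min, var_rule = var_rule,
                 delta_match = delta_match),
            class = "disc_config")
}

#' Curvature of the spectrum at interior channels
#'
#' The geometric curvature `|f''| / (1 + f'^2)^(3/2)`, with first and second
#' derivatives estimated by central finite differences on the channel grid
#' (unit spacing, so the default curvature threshold has a grid-independent
#' meaning; rescale `lambda_min` if physical cm^-1 spacing is wanted).
#'
#' @param s a [raman_spectrum()].
#' @param i vector of 1-based channel indices, each in `2:(n-1)`.
#' @return Non-negative curvature values, one per index.
#' @examples
#' # apex of a sampled parabola -x^2 has curvature exactly 2
#' s <- raman_spectrum(1:5, -(-2:2)^2)
#' curvature_at(s, 3)
#' @export
curvature_at <- function(s, i) {
  assert_spectrum(s)
  n <- length(s$intensities)
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 2) || any(i > n - 1))
    stop_rdisc("curvature needs interior channel indices (2..n-1)",
               "rdisc_index_error")
  y <- s$intensities
  d1 <- (y[i + 1] - y[i - 1]) / 2
  d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
  abs(d2) / (1 + d1^2)^1.5
}

#' Estimate the noise level of a spectrum
#'
#' All `n - M + 1` contiguous windows of width `M` are enumerated; among the
#' quiescent windows (variance at most the median window variance) the one
#' with minimum mean intensity is selected, and its mean is the noise level.
#'
#' @param s a [raman_spectrum()] with at least `M` channels.
#' @param cfg a [disc_config()].
#' @return The noise level, in the spectrum's intensity units.
#' @export
estimate_noise_level <- function(s, cfg = disc_config()) {
  assert_spectrum(s)
  y <- s$intensities
  n <- length(y)
  M <- cfg$M
  if (n < M)
    stop_config(sprintf("spectrum length %d shorter than noise window M=%d",
                        n, M))
  cs <- cumsum(c(0, y))
  cs2 <- cumsum(c(0, y^2))
  idx <- seq_len(n - M + 1)
  sums <- cs[idx + M] - cs[idx]
  sums2 <- cs2[idx + M] - cs2[idx]
  means <- sums / M
  vars <- pmax((sums2 - sums^2 / M) / (M - 1), 0)  # guard tiny negatives
  eligible <- vars <= stats::median(vars)
  min(means[eligible])
}

#' Candidate peak channels by sliding strict-maximum window
#'
#' A channel is a candidate peak when its intensity is strictly greater than
#' every other intensity in the window `[i - M, i + M]` (truncated at the
#' spectrum boundaries). Smaller peaks closer than `M` channels to a taller
#' one are thereby suppressed.
#'
#' @param s a [raman_spectrum()] with at least `2M + 1` channels.
#' @param M window half-width in channels.
#' @return Strictly increasing 1-based channel indices.
#' @export
candidate_peaks <- function(s, M = 20L) {
  assert_spectrum(s)
  y <- s$intensities
  n <- length(y)
  M <- as.integer(M)
  if (is.na(M) || M < 2) stop_config("M must be >= 2")
  if (n < 2L * M + 1L)
    stop_config(sprintf("spectrum length %d shorter than window 2M+1=%d",
                        n, 2L * M + 1L))
  is_max <- rep(TRUE, n)
  for (d in c(-(M:1), 1:M)) {
    cmp <- rep(-Inf, n)
    src <- seq_len(n) + d
    ok <- src >= 1 & src <= n
    cmp[ok] <- y[src[ok]]
    is_max <- is_max & (y > cmp)
  }
  which(is_max)
}

#' Discretize a quality-controlled spectrum into representative peaks
#'
#' A channel becomes a representative peak when all three gates hold:
#' it is the strict maximum of the sliding `[-M, +M]` window
#' ([candidate_peaks()]), its curvature exceeds `lambda_min`
#' ([curvature_at()]; boundary channels have no curvature and are
#' rejected), and its intensity exceeds the spectrum's noise level
#' ([estimate_noise_level()]). Each retained peak is recorded with its
#' shift position, intensity and curvature.
#'
#' @param s a quality-controlled (normalized) [raman_spectrum()].
#' @param cfg a [disc_config()].
#' @return A [discrete_spectrum()]; `n_source_shifts` is the channel count
#'   of `s` and metadata is carried over.
#' @examples
#' tpl <- default_templates(1, seed = 1)[[1]]
#' raw <- simulate_spectrum(tpl, n_shifts = 1024, seed = 2)$spectrum
#' d <- discretize(qc_pipeline(raw))
#' nrow(d$peaks)
#' @export
discretize <- function(s, cfg = disc_config()) {
  assert_spectrum(s)
  n <- length(s$intensities)
  cand <- candidate_peaks(s, cfg$M)
  cand <- cand[cand >= 2 & cand <= n - 1]  # curvature undefined at boundary
  noise <- estimate_noise_level(s, cfg)
  if (length(cand)) {
    kappa <- curvature_at(s, cand)
    keep <- kappa > cfg$lambda_min & s$intensities[cand] > noise
    cand <- cand[keep]
    kappa <- kappa[keep]
  } else {
    kappa <- numeric(0)
  }
  peaks <- data.frame(position = s$shifts[cand],
                      intensity = s$intensities[cand],
                      curvature = kappa)
  discrete_spectrum(peaks, n, s$meta)
}
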