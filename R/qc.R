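#' Quality-control configuration
#'
#' Parameters for the three-stage QC chain: wavelet denoising, piecewise
#' trough-based baseline correction, and min-max normalization.
#'
#' @param wavelet_levels decomposition depth of the discrete wavelet
#'   transform (default 3).
#' @param wavelet_family orthogonal compactly supported wavelet; one of
#'   `"db1"`, `"db2"`, `"db4"` (default `"db4"`, the order-4 Daubechies).
#' @param shrink_levels detail levels to soft-threshold, 1 = finest. Default
#'   all levels `1:wavelet_levels`: the universal threshold is conservative,
#'   and noise that survives in the mid bands would otherwise seed spurious
#'   peaks downstream.
#' @param trough_window half-width in channels of the strict-minimum window
#'   used for trough detection (default 25).
#' @param baseline_order polynomial order of each baseline segment, 1
#'   (linear, exact through the troughs) or 2 (default 1).
#' @param clip_negative floor baseline-corrected intensities at 0
#'   (default `TRUE`; physical intensities are non-negative).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(wavelet_levels = 3L, wavelet_family = "db4",
                      shrink_levels = seq_len(wavelet_levels),
                      trough_window = 25L, baseline_order = 1L,
                      clip_negative = TRUE) {
  wavelet_levels <- as.integer(wavelet_levels)
  trough_window <- as.integer(trough_window)
  baseline_order <- as.integer(baseline_order)
  if (is.na(wavelet_levels) || wavelet_levels < 1)
    stop_config("wavelet_levels must be >= 1")
  if (is.na(trough_window) || trough_window < 2)
    stop_config("trough_window must be >= 2")
  if (!baseline_order %in% c(1L, 2L))
    stop_config("baseline_order must be 1 or 2")
  structure(list(wavelet_levels = wavelet_levels,
                 wavelet_family = wavelet_family,
                 shrink_levels = as.integer(shrink_levels),
                 trough_window = trough_window,
                 baseline_order = baseline_order,
                 clip_negative = isTRUE(clip_negative)),
            class = "qc_config")
}

#' Denoise a spectrum by wavelet shrinkage
#'
#' Decomposes the intensity trace with an orthogonal discrete wavelet
#' transform, soft-thresholds the detail coefficients of the configured
#' levels at the universal threshold `sigma * sqrt(2 * log(n))` (with
#' `sigma` the median-absolute-deviation estimate from the finest detail
#' band divided by 0.6745), and reconstructs. Boundaries are handled by
#' symmetric extension; the output is truncated to the input length and
#' stays on the same shift grid.
#'
#' @param s a [raman_spectrum()] with at least `2^wavelet_levels` channels.
#' @param cfg a [qc_config()].
#' @return The denoised [raman_spectrum()].
#' @export
denoise_wavelet <- function(s, cfg = qc_config()) {
  assert_spectrum(s)
  den <- wavelet_shrink(s$intensities, levels = cfg$wavelet_levels,
                        family = cfg$wavelet_family,
                        shrink_levels = cfg$shrink_levels)
  raman_spectrum(s$shifts, den, s$meta)
}

#' Detect baseline anchor troughs
#'
#' A channel is a trough when its intensity is the strict minimum of the
#' window `[i - trough_window, i + trough_window]` (truncated at the
#' boundaries). The first and last channels are always included as anchors
#' so the piecewise baseline covers the whole grid.
#'
#' @param s a [raman_spectrum()].
#' @param trough_window window half-width in channels.
#' @return Strictly increasing integer channel indices (1-based).
#' @export
detect_troughs <- function(s, trough_window = 25L) {
  assert_spectrum(s)
  y <- s$intensities
  n <- length(y)
  w <- as.integer(trough_window)
  if (is.na(w) || w < 2) stop_config("trough_window must be >= 2")
  is_min <- rep(TRUE, n)
  for (d in c(-(w:1), 1:w)) {
    cmp <- rep(Inf, n)
    src <- seq_len(n) + d
    ok <- src >= 1 & src <= n
    cmp[ok] <- y[src[ok]]
    is_min <- is_min & (y < cmp)
  }
  sort(unique(c(1L, which(is_min), n)))
}

# Recursively add anchor channels wherever the signal dips below the chord
# between two adjacent anchors by more than `tol`. On a smooth denoised
# trace the strict-window troughs can be hundreds of channels apart, and a
# straight chord across an intense curved fluorescence background would cut
# through the signal; splitting at the deepest below-chord channel pins the
# baseline to the signal's lower envelope there. Peaks are always above the
# local baseline, so anchors never land on a peak, and the supplied troughs
# stay exact interpolation points.
.refine_anchors <- function(y, anchors, tol) {
  queue <- cbind(anchors[-length(anchors)], anchors[-1])
  out <- anchors
  while (nrow(queue)) {
    i0 <- queue[1, 1]; i1 <- queue[1, 2]
    queue <- queue[-1, , drop = FALSE]
    if (i1 - i0 < 4) next
    span <- (i0 + 1):(i1 - 1)
    chord <- y[i0] + (y[i1] - y[i0]) * (span - i0) / (i1 - i0)
    depth <- y[span] - chord
    w <- which.min(depth)
    if (depth[w] < -tol) {
      mid <- span[w]
      out <- c(out, mid)
      queue <- rbind(queue, c(i0, mid), c(mid, i1))
    }
  }
  sort(out)
}

#' Estimate a piecewise baseline through the troughs
#'
#' Between each pair of adjacent anchor points a low-order curve is fitted
#' and the segments are concatenated into one baseline covering the whole
#' grid. The anchors are the supplied troughs, refined by recursively
#' splitting any segment at the channel falling furthest below its chord
#' (when the dip exceeds a small tolerance), so the baseline tracks the
#' lower envelope of the signal even across long trough-free stretches of
#' a curved fluorescence background. With `baseline_order = 1` each segment
#' is the straight line through its two anchor points, so the baseline
#' interpolates every trough exactly. With `baseline_order = 2` a quadratic
#' through three consecutive anchors is evaluated over the middle segment
#' (nearest triple at the ends).
#'
#' @param s a [raman_spectrum()].
#' @param troughs integer channel indices from [detect_troughs()]; >= 2.
#' @param cfg a [qc_config()].
#' @param anchor_tol below-chord depth, as a fraction of the intensity
#'   range, that triggers an anchor split (default 1e-3).
#' @return A list of class `rdisc_baseline` with elements `values` (same
#'   length as the spectrum) and `trough_positions` (the supplied troughs).
#' @export
estimate_baseline <- function(s, troughs, cfg = qc_config(),
                              anchor_tol = 1e-3) {
  assert_spectrum(s)
  troughs <- as.integer(troughs)
  n <- length(s$intensities)
  if (length(troughs) < 2)
    stop_rdisc("baseline estimation needs at least 2 troughs",
               "rdisc_estimation_error")
  if (any(troughs < 1 | troughs > n) || any(diff(troughs) <= 0))
    stop_data("troughs must be strictly increasing indices into the spectrum")
  x <- s$shifts
  y <- s$intensities
  values <- numeric(n)
  anchors <- .refine_anchors(y, troughs, anchor_tol * diff(range(y)))
  nt <- length(anchors)
  for (seg in seq_len(nt - 1)) {
    i0 <- anchors[seg]; i1 <- anchors[seg + 1]
    span <- i0:i1
    if (cfg$baseline_order == 1L) {
      values[span] <- y[i0] + (y[i1] - y[i0]) *
        (x[span] - x[i0]) / (x[i1] - x[i0])
    } else {
      trip <- if (seg == 1) anchors[1:min(3, nt)]
              else if (seg == nt - 1) anchors[max(1, nt - 2):nt]
              else anchors[(seg - 1):(seg + 1)]
      if (length(trip) < 3) {  # only two troughs in total: fall back to line
        values[span] <- y[i0] + (y[i1] - y[i0]) *
          (x[span] - x[i0]) / (x[i1] - x[i0])
      } else {
        fit <- stats::lm.fit(cbind(1, x[trip], x[trip]^2), y[trip])
        values[span] <- cbind(1, x[span], x[span]^2) %*% fit$coefficients
      }
    }
  }
  structure(list(values = values, trough_positions = troughs),
            class = "rdisc_baseline")
}

#' Subtract a baseline from a spectrum
#'
#' @param s a [raman_spectrum()].
#' @param b an `rdisc_baseline` on the same grid.
#' @param cfg a [qc_config()]; when `clip_negative` is set, corrected
#'   intensities are floored at 0.
#' @return The corrected [raman_spectrum()].
#' @export
correct_baseline <- function(s, b, cfg = qc_config()) {
  assert_spectrum(s)
  if (!inherits(b, "rdisc_baseline") ||
      length(b$values) != length(s$intensities))
    stop_data("baseline must be an rdisc_baseline on the same grid as the spectrum")
  corrected <- s$intensities - b$values
  if (cfg$clip_negative) corrected <- pmax(corrected, 0)
  raman_spectrum(s$shifts, corrected, s$meta)
}

#' Min-max normalize a spectrum
#'
#' Each intensity is mapped to `(y - min(Y)) / (max(Y) - min(Y))`, so the
#' output lies in \[0, 1\] with minimum exactly 0 and maximum exactly 1.
#' Normalization removes instrument scale (voltage, offset) while leaving
#' the spectral shape untouched.
#'
#' @param s a non-constant [raman_spectrum()].
#' @return The normalized [raman_spectrum()].
#' @export
normalize_spectrum <- function(s) {
  assert_spectrum(s)
  rng <- range(s$intensities)
  # degenerate also when constant up to floating-point noise, e.g. a flat
  # trace that picked up reconstruction rounding during denoising
  if (rng[2] - rng[1] <= 1e-12 * max(abs(rng), 1))
    stop_rdisc("cannot normalize a constant spectrum (max == min)",
               "rdisc_degenerate_error")
  raman_spectrum(s$shifts, (s$intensities - rng[1]) / (rng[2] - rng[1]),
                 s$meta)
}

#' Run the full quality-control chain
#'
#' Wavelet denoising, trough detection, baseline estimation and subtraction,
#' then min-max normalization, in that order. The result carries
#' `meta$stage = "qc"`.
#'
#' @param s a raw [raman_spectrum()].
#' @param cfg a [qc_config()].
#' @return The quality-controlled [raman_spectrum()], intensities in
#'   \[0, 1\].
#' @examples
#' tpl <- default_templates(1, seed = 1)[[1]]
#' raw <- simulate_spectrum(tpl, n_shifts = 512, seed = 1)$spectrum
#' qc <- qc_pipeline(raw)
#' range(qc$intensities)
#' @export
qc_pipeline <- function(s, cfg = qc_config()) {
  assert_spectrum(s)
  with_stage <- function(stage, expr) {
    tryCatch(expr, rdisc_error = function(e) {
      stop_rdisc(sprintf("qc stage '%s': %s", stage, conditionMessage(e)),
                 class(e)[1])
    })
  }
  s <- with_stage("denoise", denoise_wavelet(s, cfg))
  troughs <- with_stage("baseline", detect_troughs(s, cfg$trough_window))
  bl <- with_stage("baseline", estimate_baseline(s, troughs, cfg))
  s <- with_stage("baseline", correct_baseline(s, bl, cfg))
  s <- with_stage("normalize", normalize_spectrum(s))
  s$meta$stage <- "qc"
  s
}
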