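# Synthetic single-cell-like Raman spectra with ground truth. Each class is
# a template of Lorentzian marker bands; realized spectra add per-cell
# position jitter and height variation, a broad smooth autofluorescence-like
# baseline, and additive Gaussian noise. Everything is reproducible from
# (template, n_shifts, seed).

#' Class template for the spectrum simulator
#'
#' @param label class name.
#' @param marker_positions Lorentzian band centers in cm^-1, inside
#'   `grid_range`.
#' @param marker_heights relative band heights (> 0; unit scale).
#' @param marker_widths band FWHM values in cm^-1 (> 0).
#' @param baseline_amp baseline amplitude relative to the tallest realized
#'   marker (default 2: the fluorescence background dominates the Raman
#'   bands, as it does in real single-cell spectra).
#' @param noise_sigma additive Gaussian noise standard deviation on the
#'   unit height scale (default 0.02; with the default minimum marker
#'   height 0.3 this is an SNR of 15).
#' @param jitter_sigma per-spectrum Gaussian jitter of band positions in
#'   cm^-1 (default 1.5).
#' @param height_cv per-spectrum multiplicative height variation,
#'   coefficient of variation (default 0.15).
#' @param grid_range wavenumber range of the shift axis (default 400-3200).
#' @return A list of class `class_template`.
#' @export
class_template <- function(label, marker_positions, marker_heights,
                           marker_widths, baseline_amp = 2,
                           noise_sigma = 0.02, jitter_sigma = 1.5,
                           height_cv = 0.15, grid_range = c(400, 3200)) {
  marker_positions <- as.numeric(marker_positions)
  marker_heights <- as.numeric(marker_heights)
  marker_widths <- as.numeric(marker_widths)
  np <- length(marker_positions)
  if (np < 1 || length(marker_heights) != np || length(marker_widths) != np)
    stop_data("marker positions, heights and widths must have equal length >= 1")
  if (any(marker_positions < grid_range[1] | marker_positions > grid_range[2]))
    stop_data("marker positions must lie within grid_range")
  if (any(marker_heights <= 0) || any(marker_widths <= 0))
    stop_data("marker heights and widths must be > 0")
  if (noise_sigma < 0 || jitter_sigma < 0 || height_cv < 0 ||
      baseline_amp < 0)
    stop_data("noise, jitter, height_cv and baseline_amp must be >= 0")
  structure(list(label = as.character(label),
                 marker_positions = marker_positions,
                 marker_heights = marker_heights,
                 marker_widths = marker_widths,
                 baseline_amp = baseline_amp, noise_sigma = noise_sigma,
                 jitter_sigma = jitter_sigma, height_cv = height_cv,
                 grid_range = as.numeric(grid_range)),
            class = "class_template")
}

# rejection-sample a position respecting minimum distances to two sets
.draw_position <- function(lo, hi, own, others, own_gap, other_gap) {
  for (try in 1:20000) {
    cand <- stats::runif(1, lo, hi)
    if ((!length(own) || min(abs(own - cand)) >= own_gap) &&
        (!length(others) || min(abs(others - cand)) >= other_gap))
      return(cand)
  }
  stop_rdisc("could not place a marker peak; too many classes for the grid",
             "rdisc_simulation_error")
}

#' Generate reproducible class templates
#'
#' Builds `n_classes` templates on the 400-3200 cm^-1 grid. Six marker bands
#' are shared by every class (common biomolecule bands); each class
#' additionally gets 3-8 class-unique bands at least 25 cm^-1 from any other
#' class's unique bands, for 9-14 markers per class in total. Within a class
#' all markers are at least 65 cm^-1 apart so neighbouring bands never fall
#' inside one +/-M detection window. Heights are drawn in \[0.3, 1\] and
#' FWHM in \[10, 30\] cm^-1 (Lorentzian bands).
#'
#' @param n_classes number of classes (>= 1).
#' @param seed integer seed; the same seed yields identical templates.
#' @param n_shared number of markers shared across all classes (default 6).
#' @param ... passed to [class_template()] (noise, baseline, jitter
#'   settings).
#' @return A list of [class_template()] objects.
#' @export
default_templates <- function(n_classes, seed = 42L, n_shared = 6L, ...) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 1)
    stop_config("n_classes must be >= 1")
  set.seed(as.integer(seed))
  lo <- 500; hi <- 3100
  shared <- numeric(0)
  for (i in seq_len(n_shared))
    shared <- c(shared, .draw_position(lo, hi, shared, numeric(0), 65, 0))
  shared <- sort(shared)
  all_unique <- numeric(0)
  templates <- vector("list", n_classes)
  for (cl in seq_len(n_classes)) {
    n_uni <- sample(3:8, 1)
    uni <- numeric(0)
    for (i in seq_len(n_uni))
      uni <- c(uni, .draw_position(lo, hi, c(shared, uni), all_unique,
                                   65, 25))
    all_unique <- c(all_unique, uni)
    pos <- sort(c(shared, uni))
    templates[[cl]] <- class_template(
      label = sprintf("class_%02d", cl),
      marker_positions = pos,
      marker_heights = stats::runif(length(pos), 0.3, 1),
      marker_widths = stats::runif(length(pos), 10, 30),
      ...)
  }
  templates
}

#' Simulate one spectrum from a class template
#'
#' Intensity is the sum of Lorentzian marker bands (positions jittered,
#' heights varied per spectrum), a smooth intense baseline (sum of 2-3
#' Gaussians of FWHM >= 500 cm^-1 scaled to `baseline_amp` times the
#' tallest realized marker), and additive Gaussian noise; the result is
#' floored at 0. The returned ground truth records the realized band
#' positions and heights, the baseline values and the seed, so recovery of
#' planted peaks can be scored exactly.
#'
#' @param template a [class_template()].
#' @param n_shifts number of channels (>= 256; default 2048, matching a
#'   full single-cell spectrum of more than 1,000 Raman shifts).
#' @param seed integer seed.
#' @return A list with elements `spectrum` ([raman_spectrum()]) and `truth`
#'   (list: `positions`, `heights`, `widths`, `baseline`, `seed`).
#' @export
simulate_spectrum <- function(template, n_shifts = 2048L, seed = 1L) {
  if (!inherits(template, "class_template"))
    stop_data("template must be a class_template")
  n_shifts <- as.integer(n_shifts)
  if (is.na(n_shifts) || n_shifts < 256)
    stop_config("n_shifts must be >= 256")
  set.seed(as.integer(seed))
  grid <- seq(template$grid_range[1], template$grid_range[2],
              length.out = n_shifts)
  np <- length(template$marker_positions)
  pos <- template$marker_positions +
    stats::rnorm(np, 0, template$jitter_sigma)
  # lognormal height factors with mean 1 and the requested CV
  slog <- sqrt(log(1 + template$height_cv^2))
  heights <- template$marker_heights * exp(stats::rnorm(np, -slog^2 / 2, slog))
  signal <- numeric(n_shifts)
  for (i in seq_len(np)) {
    gam <- template$marker_widths[i] / 2  # HWHM
    signal <- signal + heights[i] * gam^2 / ((grid - pos[i])^2 + gam^2)
  }
  n_bl <- sample(2:3, 1)
  bl_centers <- stats::runif(n_bl, template$grid_range[1],
                             template$grid_range[2])
  bl_sigmas <- stats::runif(n_bl, 300, 800)  # FWHM 700-1900 cm^-1
  bl_amps <- stats::runif(n_bl, 0.3, 1)
  baseline <- numeric(n_shifts)
  for (i in seq_len(n_bl))
    baseline <- baseline +
      bl_amps[i] * exp(-(grid - bl_centers[i])^2 / (2 * bl_sigmas[i]^2))
  if (max(baseline) > 0)
    baseline <- baseline / max(baseline) *
      (template$baseline_amp * max(heights))
  noise <- stats::rnorm(n_shifts, 0, template$noise_sigma)
  intensities <- pmax(signal + baseline + noise, 0)
  s <- raman_spectrum(grid, intensities,
                      list(label = template$label,
                           seed = as.character(seed), stage = "raw"))
  list(spectrum = s,
       truth = list(positions = pos, heights = heights,
                    widths = template$marker_widths,
                    baseline = baseline, seed = as.integer(seed)))
}

#' Simulate a labeled dataset of spectra
#'
#' Generates `per_class` spectra per template; each spectrum's seed is
#' derived deterministically from the master seed, so the whole dataset is
#' reproducible from `(templates, per_class, n_shifts, seed)`.
#'
#' @param templates list of [class_template()] objects.
#' @param per_class spectra per class (>= 2).
#' @param n_shifts channels per spectrum.
#' @param seed integer master seed.
#' @return A list with elements `dataset` (a full-representation
#'   [labeled_dataset()]) and `truths` (ground-truth list, one per
#'   spectrum, in dataset order).
#' @export
simulate_dataset <- function(templates, per_class, n_shifts = 2048L,
                             seed = 42L) {
  if (!length(templates) ||
      !all(vapply(templates, inherits, logical(1), "class_template")))
    stop_data("templates must be a list of class_template objects")
  per_class <- as.integer(per_class)
  if (is.na(per_class) || per_class < 2)
    stop_config("per_class must be >= 2")
  n_total <- length(templates) * per_class
  set.seed(as.integer(seed))
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  items <- vector("list", n_total)
  truths <- vector("list", n_total)
  labels <- character(n_total)
  idx <- 0L
  for (tpl in templates) {
    for (j in seq_len(per_class)) {
      idx <- idx + 1L
      sim <- simulate_spectrum(tpl, n_shifts, child_seeds[idx])
      sim$spectrum$meta$cell_id <- sprintf("%s_%03d", tpl$label, j)
      items[[idx]] <- sim$spectrum
      truths[[idx]] <- sim$truth
      labels[idx] <- tpl$label
    }
  }
  list(dataset = labeled_dataset(items, labels, "full"), truths = truths)
}

#' Score recovery of planted peaks
#'
#' Compares a discretized spectrum against the simulator's ground truth:
#' recall is the fraction of planted band positions with a representative
#' peak within `delta` cm^-1, and every representative peak further than
#' `delta` from all planted bands counts as spurious.
#'
#' @param d a [discrete_spectrum()].
#' @param planted_positions numeric vector of planted band centers (cm^-1).
#' @param delta matching tolerance in cm^-1 (default 10).
#' @return A list with `recall` (fraction) and `n_spurious` (count).
#' @export
peak_recovery <- function(d, planted_positions, delta = 10) {
  assert_discrete(d)
  planted_positions <- as.numeric(planted_positions)
  found <- d$peaks$position
  if (!length(planted_positions))
    return(list(recall = NA_real_, n_spurious = length(found)))
  hit <- vapply(planted_positions, function(p)
    length(found) > 0 && min(abs(found - p)) <= delta, logical(1))
  spur <- if (length(found))
    sum(vapply(found, function(p)
      min(abs(planted_positions - p)) > delta, logical(1)))
  else 0L
  list(recall = mean(hit), n_spurious = as.integer(spur))
}
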