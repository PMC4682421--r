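#' Construct a Raman spectrum object
#'
#' The package's container for one continuous single-cell Raman spectrum:
#' a strictly increasing wavenumber axis (`shifts`, cm^-1), one intensity per
#' channel (arbitrary units), and free-form character metadata (cell id,
#' species label, processing stage, ...).
#'
#' @param shifts numeric vector of Raman shifts in cm^-1, strictly increasing,
#'   length >= 3, all finite.
#' @param intensities numeric vector of intensities, same length as `shifts`,
#'   all finite.
#' @param meta named list of character scalars (coerced with `as.character`).
#' @return An object of class `raman_spectrum`.
#' @examples
#' s <- raman_spectrum(400:410, sin(400:410))
#' length(s$shifts)
#' @export
raman_spectrum <- function(shifts, intensities, meta = list()) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities))
    stop_data("shifts and intensities must have equal length")
  if (length(shifts) < 3)
    stop_data(sprintf("a spectrum needs at least 3 channels, got %d",
                      length(shifts)))
  if (!all(is.finite(shifts)) || !all(is.finite(intensities)))
    stop_data("shifts and intensities must all be finite")
  if (any(diff(shifts) == 0))
    stop_data("duplicate shift values are not allowed")
  if (any(diff(shifts) < 0))
    stop_data("shifts must be strictly increasing")
  if (length(meta) && (is.null(names(meta)) || any(names(meta) == "")))
    stop_data("meta entries must be named")
  meta <- lapply(meta, as.character)
  structure(list(shifts = shifts, intensities = intensities, meta = meta),
            class = "raman_spectrum")
}

is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

assert_spectrum <- function(s) {
  if (!is_raman_spectrum(s))
    stop_data("expected a raman_spectrum object")
  invisible(s)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.1f-%.1f cm^-1\n",
              length(x$shifts), min(x$shifts), max(x$shifts)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, peaks = NULL, ...) {
  graphics::plot(x$shifts, x$intensities, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)", ...)
  if (!is.null(peaks)) {
    pk <- peaks$peaks
    graphics::points(pk$position, pk$intensity, pch = 4, col = "red")
  }
  invisible(x)
}

#' Construct a discrete (rDisc) spectrum object
#'
#' The condensed representation of a spectrum: an ordered table of
#' representative peaks, each with its shift position (cm^-1), normalized
#' intensity and curvature (sharpness) value, plus the channel count of the
#' originating full spectrum so compression ratios stay computable from the
#' discrete record alone.
#'
#' @param peaks data.frame with numeric columns `position`, `intensity`,
#'   `curvature`; positions strictly increasing, curvatures >= 0. May have
#'   zero rows.
#' @param n_source_shifts integer, number of channels of the source spectrum.
#' @param meta named list of character scalars.
#' @return An object of class `discrete_spectrum`.
#' @export
discrete_spectrum <- function(peaks, n_source_shifts, meta = list()) {
  if (!is.data.frame(peaks) ||
      !all(c("position", "intensity", "curvature") %in% names(peaks)))
    stop_data("peaks must be a data.frame with position, intensity, curvature")
  peaks <- data.frame(position = as.numeric(peaks$position),
                      intensity = as.numeric(peaks$intensity),
                      curvature = as.numeric(peaks$curvature))
  n_source_shifts <- as.integer(n_source_shifts)
  if (is.na(n_source_shifts) || n_source_shifts < 0)
    stop_data("n_source_shifts must be a non-negative integer")
  if (nrow(peaks) > n_source_shifts)
    stop_data("cannot have more peaks than source channels")
  if (nrow(peaks)) {
    if (!all(is.finite(as.matrix(peaks))))
      stop_data("peak fields must all be finite")
    if (any(diff(peaks$position) <= 0))
      stop_data("peak positions must be strictly increasing")
    if (any(peaks$curvature < 0))
      stop_data("curvature must be non-negative")
  }
  meta <- lapply(meta, as.character)
  structure(list(peaks = peaks, n_source_shifts = n_source_shifts,
                 meta = meta),
            class = "discrete_spectrum")
}

is_discrete_spectrum <- function(x) inherits(x, "discrete_spectrum")

assert_discrete <- function(d) {
  if (!is_discrete_spectrum(d))
    stop_data("expected a discrete_spectrum object")
  invisible(d)
}

#' @export
print.discrete_spectrum <- function(x, ...) {
  cat(sprintf("<discrete_spectrum> %d peaks from %d source channels\n",
              nrow(x$peaks), x$n_source_shifts))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10))
  invisible(x)
}
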