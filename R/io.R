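# Plain-text readers/writers. Full spectra are two whitespace-separated
# numeric columns (shift, intensity) with '#' comment lines; discrete spectra
# use the rDisc v1 grammar documented in read_rdisc().

# %.17g round-trips an IEEE double exactly through as.numeric()
fmt_num <- function(x) sprintf("%.17g", x)

parse_meta_line <- function(line) {
  m <- regmatches(line, regexec("^#\\s*([^:]+):\\s*(.*)$", line))[[1]]
  if (length(m) == 3) list(key = trimws(m[2]), value = trimws(m[3])) else NULL
}

write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  ok <- tryCatch({
    writeLines(lines, tmp)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    if (file.exists(tmp)) unlink(tmp)
    stop_rdisc(sprintf("cannot write to '%s'", path), "rdisc_io_error")
  }
  invisible(path)
}

#' Read a full Raman spectrum from a two-column text file
#'
#' Accepts the common spectrometer export dialect: whitespace- or
#' tab-separated columns (Raman shift in cm^-1, intensity), '.' decimal
#' separator, `#` comment lines. Comment lines of the form `# key: value`
#' are collected into the spectrum's metadata. Rows are sorted by shift if
#' the file is out of order.
#'
#' @param path path to the file; must contain at least 3 data rows.
#' @param dialect column separator regex; the default splits on any
#'   whitespace run.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, dialect = "[ \t]+") {
  if (!file.exists(path))
    stop_rdisc(sprintf("file not found: '%s'", path), "rdisc_io_error")
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  shifts <- numeric(0)
  intens <- numeric(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      kv <- parse_meta_line(line)
      if (!is.null(kv)) meta[[kv$key]] <- kv$value
      next
    }
    fields <- strsplit(line, dialect)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2)
      stop_format(sprintf("line %d of '%s': expected 2 columns, got %d",
                          i, path, length(fields)))
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(vals)))
      stop_format(sprintf("line %d of '%s': non-numeric value '%s'",
                          i, path, fields[which(is.na(vals))[1]]))
    shifts <- c(shifts, vals[1])
    intens <- c(intens, vals[2])
  }
  if (length(shifts) < 3)
    stop_format(sprintf("'%s': a spectrum needs at least 3 data rows, got %d",
                        path, length(shifts)))
  if (anyDuplicated(shifts))
    stop_data(sprintf("'%s': duplicate shift value %s", path,
                      format(shifts[duplicated(shifts)][1])))
  ord <- order(shifts)
  meta$source <- path
  raman_spectrum(shifts[ord], intens[ord], meta)
}

#' Write a full Raman spectrum to a two-column text file
#'
#' Metadata is emitted as leading `# key: value` comment lines; data rows are
#' tab-separated with full round-trip decimal precision, so
#' `read_spectrum(write_spectrum(s, p))` reproduces the arrays exactly.
#'
#' @param s a [raman_spectrum()].
#' @param path output path (written atomically: temp file then rename).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  assert_spectrum(s)
  meta <- s$meta[setdiff(names(s$meta), "source")]
  header <- if (length(meta))
    sprintf("# %s: %s", names(meta), unlist(meta)) else character(0)
  rows <- paste(fmt_num(s$shifts), fmt_num(s$intensities), sep = "\t")
  write_atomic(c(header, rows), path)
}

#' Read a discrete spectrum from an rDisc v1 file
#'
#' The rDisc v1 grammar (tab-separated, UTF-8):
#' \preformatted{
#' # rDisc v1
#' # n_shifts: <int>
#' # <key>: <value>        (optional metadata lines)
#' shift_cm1	intensity	curvature
#' <pos>	<int>	<curv>   (zero or more rows, positions strictly ascending)
#' }
#'
#' @param path path to an rDisc v1 file.
#' @return A [discrete_spectrum()].
#' @export
read_rdisc <- function(path) {
  if (!file.exists(path))
    stop_rdisc(sprintf("file not found: '%s'", path), "rdisc_io_error")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "# rDisc v1")
    stop_format(sprintf("'%s' is not an rDisc v1 file (missing '# rDisc v1' on line 1)",
                        path))
  meta <- list()
  n_shifts <- NA_integer_
  i <- 2
  while (i <= length(lines) && startsWith(trimws(lines[i]), "#")) {
    kv <- parse_meta_line(lines[i])
    if (!is.null(kv)) {
      if (kv$key == "n_shifts") {
        n_shifts <- suppressWarnings(as.integer(kv$value))
        if (is.na(n_shifts))
          stop_format(sprintf("'%s' line %d: n_shifts is not an integer", path, i))
      } else {
        meta[[kv$key]] <- kv$value
      }
    }
    i <- i + 1
  }
  if (is.na(n_shifts))
    stop_format(sprintf("'%s': missing '# n_shifts: <int>' header", path))
  if (i > length(lines) ||
      !identical(strsplit(trimws(lines[i]), "\t")[[1]],
                 c("shift_cm1", "intensity", "curvature")))
    stop_format(sprintf("'%s': missing column header 'shift_cm1\\tintensity\\tcurvature'",
                        path))
  data_lines <- lines[seq_len(length(lines) - i) + i]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines)) {
    fields <- strsplit(data_lines, "\t")
    bad <- which(lengths(fields) != 3)
    if (length(bad))
      stop_format(sprintf("'%s' data row %d: expected 3 tab-separated fields",
                          path, bad[1]))
    m <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                 ncol = 3, byrow = TRUE))
    if (any(is.na(m)))
      stop_format(sprintf("'%s': non-numeric peak field", path))
    if (any(diff(m[, 1]) <= 0))
      stop_data(sprintf("'%s': peak positions must be strictly increasing", path))
    peaks <- data.frame(position = m[, 1], intensity = m[, 2],
                        curvature = m[, 3])
  } else {
    peaks <- data.frame(position = numeric(0), intensity = numeric(0),
                        curvature = numeric(0))
  }
  discrete_spectrum(peaks, n_shifts, meta)
}

#' Write a discrete spectrum to an rDisc v1 file
#'
#' Lossless round trip: positions, intensities, curvatures, metadata and
#' `n_source_shifts` are all preserved to full decimal precision.
#'
#' @param d a [discrete_spectrum()].
#' @param path output path (written atomically).
#' @return `path`, invisibly.
#' @export
write_rdisc <- function(d, path) {
  assert_discrete(d)
  meta <- d$meta
  lines <- c("# rDisc v1",
             sprintf("# n_shifts: %d", d$n_source_shifts),
             if (length(meta)) sprintf("# %s: %s", names(meta), unlist(meta)),
             "shift_cm1\tintensity\tcurvature")
  if (nrow(d$peaks))
    lines <- c(lines, paste(fmt_num(d$peaks$position),
                            fmt_num(d$peaks$intensity),
                            fmt_num(d$peaks$curvature), sep = "\t"))
  write_atomic(lines, path)
}
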