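# Independent brute-force oracles, deliberately written as direct
# transcriptions of the definitions (exhaustive scans, no shared code with
# the package implementations).

spec_of <- function(y, shifts = seq_along(y)) raman_spectrum(shifts, y)

# strict local maxima over the truncated window [i-M, i+M]
bf_candidates <- function(y, M) {
  n <- length(y)
  which(vapply(seq_len(n), function(i) {
    win <- max(1, i - M):min(n, i + M)
    win <- setdiff(win, i)
    all(y[i] > y[win])
  }, logical(1)))
}

# strict window minima plus forced endpoints
bf_troughs <- function(y, w) {
  n <- length(y)
  interior <- which(vapply(seq_len(n), function(i) {
    win <- setdiff(max(1, i - w):min(n, i + w), i)
    all(y[i] < y[win])
  }, logical(1)))
  sort(unique(c(1L, interior, n)))
}

# enumerate every width-M window; among those with variance <= median
# variance, return the minimum mean
bf_noise <- function(y, M) {
  n <- length(y)
  means <- vapply(seq_len(n - M + 1), function(i) mean(y[i:(i + M - 1)]),
                  numeric(1))
  vars <- vapply(seq_len(n - M + 1), function(i) var(y[i:(i + M - 1)]),
                 numeric(1))
  min(means[vars <= median(vars)])
}

# exhaustive one-to-one matching: maximize pair count, then minimize total
# position distance; returns c(count, total_distance)
bf_match <- function(pa, pb, delta) {
  best <- c(0, 0)
  recurse <- function(i, used_b, count, dist) {
    if (i > length(pa)) {
      if (count > best[1] || (count == best[1] && dist < best[2]))
        best <<- c(count, dist)
      return(invisible())
    }
    # upper bound prune
    if (count + (length(pa) - i + 1) < best[1]) return(invisible())
    recurse(i + 1, used_b, count, dist)  # leave pa[i] unmatched
    for (j in seq_along(pb)) {
      if (!used_b[j] && abs(pa[i] - pb[j]) <= delta) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, count + 1, dist + abs(pa[i] - pb[j]))
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, length(pb)), 0, 0)
  best
}

# quick constructor for discrete spectra in tests
disc_of <- function(positions, intensities = NULL, n_shifts = 2048) {
  k <- length(positions)
  if (is.null(intensities)) intensities <- rep(0.5, k)
  discrete_spectrum(data.frame(position = positions,
                               intensity = intensities,
                               curvature = rep(1, k)), n_shifts)
}

# sum of Lorentzian bands on a grid
lorentz_sum <- function(grid, pos, height, fwhm) {
  out <- numeric(length(grid))
  for (i in seq_along(pos)) {
    g <- fwhm[i] / 2
    out <- out + height[i] * g^2 / ((grid - pos[i])^2 + g^2)
  }
  out
}
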