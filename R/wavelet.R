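# Orthogonal discrete wavelet transform (periodized pyramid algorithm) and
# universal-threshold soft shrinkage. Signals are mirror-extended to an even
# power-of-two length before the periodized transform so both wrap-around
# junctions are continuous; the denoised result is truncated back to the
# input length.

# Daubechies scaling (lowpass decomposition) filters, unit l2 norm.
.db_lowpass <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314469025, 0.836516303737469,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

.wavelet_filter <- function(family) {
  h <- .db_lowpass[[family]]
  if (is.null(h))
    stop_config(sprintf("unknown wavelet family '%s' (available: %s)",
                        family, paste(names(.db_lowpass), collapse = ", ")))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror highpass
  list(h = h, g = g, L = L)
}

# One analysis step of the periodized transform; length(x) even, >= L.
.dwt_step <- function(x, flt) {
  N <- length(x)
  half <- N / 2L
  ca <- numeric(half)
  cd <- numeric(half)
  k2 <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(flt$L)) {
    idx <- (k2 + m - 1L) %% N + 1L
    ca <- ca + flt$h[m] * x[idx]
    cd <- cd + flt$g[m] * x[idx]
  }
  list(ca = ca, cd = cd)
}

# Adjoint (= inverse, the operator is orthogonal) of .dwt_step.
.idwt_step <- function(ca, cd, flt) {
  half <- length(ca)
  N <- 2L * half
  y <- numeric(N)
  k2 <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(flt$L)) {
    idx <- (k2 + m - 1L) %% N + 1L
    y[idx] <- y[idx] + flt$h[m] * ca + flt$g[m] * cd
  }
  y
}

# Full decomposition: returns approximation at the deepest level plus detail
# bands, details[[1]] being the finest. length(x) must be divisible by
# 2^levels and the deepest stage must still be at least one filter long.
.dwt <- function(x, flt, levels) {
  if (length(x) %% 2^levels != 0)
    stop_config("signal length must be divisible by 2^levels")
  if (length(x) / 2^(levels - 1) < flt$L)
    stop_config("signal too short for the requested decomposition depth")
  details <- vector("list", levels)
  approx <- x
  for (j in seq_len(levels)) {
    st <- .dwt_step(approx, flt)
    approx <- st$ca
    details[[j]] <- st$cd
  }
  list(approx = approx, details = details)
}

.idwt <- function(dec, flt) {
  approx <- dec$approx
  for (j in rev(seq_along(dec$details)))
    approx <- .idwt_step(approx, dec$details[[j]], flt)
  approx
}

.soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Mirror-extend to an even power-of-two length: right-reflect to the next
# power of two, then append the full reversal so the periodic extension is
# continuous at both ends.
.mirror_pad <- function(x) {
  n <- length(x)
  P <- 2^ceiling(log2(n))
  if (P > n) {
    refl <- rev(x)[-1]
    while (length(refl) < P - n) refl <- c(refl, rev(refl)[-1])
    x <- c(x, refl[seq_len(P - n)])
  }
  c(x, rev(x))
}

# Wavelet shrinkage denoiser: decompose, soft-threshold the detail bands in
# shrink_levels at the universal threshold sigma*sqrt(2*log(n)) with sigma
# estimated as MAD(finest detail)/0.6745, reconstruct, truncate.
wavelet_shrink <- function(x, levels = 3L, family = "db4",
                           shrink_levels = seq_len(levels)) {
  n <- length(x)
  if (n < 2^levels)
    stop_config(sprintf(
      "spectrum length %d too short for %d-level wavelet decomposition", n, levels))
  flt <- .wavelet_filter(family)
  xe <- .mirror_pad(x)
  dec <- .dwt(xe, flt, levels)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n))
  for (j in intersect(shrink_levels, seq_len(levels)))
    dec$details[[j]] <- .soft_threshold(dec$details[[j]], thr)
  .idwt(dec, flt)[seq_len(n)]
}
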