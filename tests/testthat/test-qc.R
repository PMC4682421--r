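smooth_signal <- function(n = 1024) {
  x <- seq(0, 1, length.out = n)
  0.8 * exp(-(x - 0.3)^2 / 0.01) + exp(-(x - 0.5)^2 / 0.005) +
    0.5 * exp(-(x - 0.8)^2 / 0.02)
}

test_that("wavelet denoising preserves smooth signal and removes noise", {
  truth <- smooth_signal()
  s <- spec_of(truth)
  den <- denoise_wavelet(s)
  expect_lt(sqrt(mean((den$intensities - truth)^2)) / diff(range(truth)),
            0.01)

  set.seed(7)
  noisy <- truth + rnorm(length(truth), 0, 0.05)
  den <- denoise_wavelet(spec_of(noisy))
  v_in <- var(noisy - truth)
  v_out <- var(den$intensities - truth)
  expect_lt(v_out, 0.5 * v_in)

  # constant spectra pass through unchanged (all detail coefficients zero)
  cst <- denoise_wavelet(spec_of(rep(2, 512)))
  expect_equal(cst$intensities, rep(2, 512), tolerance = 1e-12)

  expect_error(denoise_wavelet(spec_of(rnorm(4)), qc_config(wavelet_levels = 5)),
               class = "rdisc_config_error")
})

test_that("denoising is approximately idempotent", {
  set.seed(13)
  noisy <- smooth_signal() + rnorm(1024, 0, 0.05)
  d1 <- denoise_wavelet(spec_of(noisy))
  d2 <- denoise_wavelet(d1)
  change1 <- sqrt(mean((d1$intensities - noisy)^2))
  change2 <- sqrt(mean((d2$intensities - d1$intensities)^2))
  expect_lt(change2, 0.1 * change1)
})

test_that("trough detection matches its definition", {
  # V shape: vertex plus the two forced endpoints
  v <- spec_of(c(10:1, 2:10))
  expect_equal(detect_troughs(v, 5), c(1L, 10L, 19L))
  # monotone: endpoints only
  expect_equal(detect_troughs(spec_of(1:50), 5), c(1L, 50L))
  # two planted valleys recovered exactly
  y <- 5 + sin(seq(0, 4 * pi, length.out = 200))
  s <- spec_of(y)
  expect_equal(setdiff(detect_troughs(s, 20), c(1L, 200L)),
               setdiff(bf_troughs(y, 20), c(1L, 200L)))
  expect_length(setdiff(detect_troughs(s, 20), c(1L, 200L)), 2)
})

test_that("trough detection agrees with the exhaustive window scan", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(50:512, 1)
    w <- sample(2:30, 1)
    y <- cumsum(rnorm(n)) + rnorm(n, 0, 0.2)
    expect_identical(detect_troughs(spec_of(y), w), bf_troughs(y, w))
  }
})

test_that("baseline estimation reproduces lines and planted ramps", {
  # a straight line with endpoint troughs is reproduced exactly
  x <- seq(400, 1000, length.out = 301)
  line <- 0.003 * x + 1
  s <- raman_spectrum(x, line)
  bl <- estimate_baseline(s, c(1L, 301L))
  expect_lt(max(abs(bl$values - line)), 1e-9)

  # flat zero spectrum gives a zero baseline
  z <- spec_of(rep(0, 100))
  expect_equal(estimate_baseline(z, c(1L, 100L))$values, rep(0, 100))

  # narrow peaks on a linear ramp: baseline within 2% of the ramp off-peak
  grid <- seq(400, 3200, length.out = 1024)
  ramp <- 0.5 + (grid - 400) / 2800
  peaks <- lorentz_sum(grid, c(900, 1600, 2400), c(1, 0.8, 0.6),
                       c(14, 14, 14))
  s <- raman_spectrum(grid, ramp + peaks)
  tr <- detect_troughs(s, 25)
  bl <- estimate_baseline(s, tr)
  off <- vapply(grid, function(g) min(abs(c(900, 1600, 2400) - g)) > 80,
                logical(1))
  expect_lt(max(abs(bl$values - ramp)[off]) / max(ramp), 0.02)

  expect_error(estimate_baseline(s, 5L), "2 troughs",
               class = "rdisc_estimation_error")
})

test_that("baseline subtraction obeys the clipping contract", {
  set.seed(3)
  y <- abs(rnorm(64)) + 1
  s <- spec_of(y)
  self <- structure(list(values = y, trough_positions = c(1L, 64L)),
                    class = "rdisc_baseline")
  expect_equal(correct_baseline(s, self)$intensities, rep(0, 64))

  noisy_bl <- structure(list(values = y + rnorm(64, 0, 0.5),
                             trough_positions = c(1L, 64L)),
                        class = "rdisc_baseline")
  kept <- correct_baseline(s, noisy_bl, qc_config(clip_negative = FALSE))
  expect_true(any(kept$intensities < 0))
  clipped <- correct_baseline(s, noisy_bl)
  expect_true(all(clipped$intensities >= 0))
  # with a non-negative baseline, correction never increases any intensity
  nonneg <- structure(list(values = pmax(noisy_bl$values, 0),
                           trough_positions = c(1L, 64L)),
                      class = "rdisc_baseline")
  expect_true(all(correct_baseline(s, nonneg)$intensities <= s$intensities))

  short <- structure(list(values = y[1:10], trough_positions = c(1L, 10L)),
                     class = "rdisc_baseline")
  expect_error(correct_baseline(s, short), class = "rdisc_data_error")
})

test_that("min-max normalization maps onto [0, 1] exactly", {
  s <- normalize_spectrum(spec_of(c(2, 4, 6)))
  expect_identical(s$intensities, c(0, 0.5, 1))
  # already-normalized input is a fixed point
  expect_identical(normalize_spectrum(s)$intensities, s$intensities)
  expect_error(normalize_spectrum(spec_of(rep(1, 10))),
               class = "rdisc_degenerate_error")
})

test_that("the full QC chain lands in [0,1] and suppresses the background", {
  tpls <- default_templates(2, seed = 5)
  for (i in 1:2) {
    sim <- simulate_spectrum(tpls[[i]], n_shifts = 2048, seed = 100 + i)
    q <- qc_pipeline(sim$spectrum)
    expect_identical(range(q$intensities), c(0, 1))
    off <- vapply(q$shifts, function(g)
      min(abs(sim$truth$positions - g)) > 50, logical(1))
    expect_lt(median(q$intensities[off]), 0.1)
    expect_equal(q$meta$stage, "qc")
  }
})

test_that("QC preserves the height ordering of clean, baseline-free peaks", {
  grid <- seq(400, 3200, length.out = 1024)
  pos <- c(700, 1200, 1800, 2400, 2900)
  hts <- c(0.9, 0.5, 1.0, 0.3, 0.7)
  s <- raman_spectrum(grid, lorentz_sum(grid, pos, hts, rep(16, 5)))
  q <- qc_pipeline(s)
  apex <- vapply(pos, function(p) which.min(abs(grid - p)), integer(1))
  expect_identical(order(q$intensities[apex]), order(hts))
})

test_that("a degenerate constant input fails naming the normalize stage", {
  expect_error(qc_pipeline(spec_of(rep(1, 512))), "normalize",
               class = "rdisc_degenerate_error")
})
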