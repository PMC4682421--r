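test_that("curvature matches closed forms at simple shapes", {
  # parabola -x^2 sampled at unit spacing: f' = 0, f'' = -2, kappa = 2
  par <- spec_of(-(-5:5)^2)
  expect_equal(curvature_at(par, 6), 2)
  # straight lines have zero curvature at every interior channel
  line <- spec_of(3 * (1:20) + 1)
  expect_equal(curvature_at(line, 2:19), rep(0, 18))
  # hand-evaluated central differences on (0, 1, 0)
  expect_equal(curvature_at(spec_of(c(0, 1, 0)), 2), 2)
  expect_error(curvature_at(par, 1), class = "rdisc_index_error")
  expect_error(curvature_at(par, 11), class = "rdisc_index_error")
})

test_that("noise level is the mean of the quietest low-variance window", {
  expect_equal(estimate_noise_level(spec_of(rep(0.1, 100))), 0.1)

  # one flat region at 0.05, everything else at or above 0.5
  y <- rep(0.5, 200)
  y[80:120] <- 0.05
  y[150:170] <- 0.7
  expect_equal(estimate_noise_level(spec_of(y)), 0.05)

  # peaks on an exact zero floor: noise level ~ 0
  grid <- seq(400, 3200, length.out = 512)
  s <- raman_spectrum(grid, lorentz_sum(grid, c(1000, 2000), c(1, 1),
                                        c(20, 20)))
  expect_lt(estimate_noise_level(s), 0.01)

  expect_error(estimate_noise_level(spec_of(1:10), disc_config(M = 20)),
               class = "rdisc_config_error")
})

test_that("noise window selection agrees with exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(60:512, 1)
    M <- sample(5:30, 1)
    y <- abs(cumsum(rnorm(n, 0, 0.05))) + runif(n, 0, 0.2)
    expect_equal(estimate_noise_level(spec_of(y), disc_config(M = M)),
                 bf_noise(y, M))
  }
})

test_that("candidate peaks are the strict window maxima", {
  grid <- seq(400, 3200, length.out = 512)
  one <- raman_spectrum(grid, lorentz_sum(grid, 1500, 1, 30))
  apex <- which.min(abs(grid - 1500))
  expect_equal(candidate_peaks(one, 20), apex)

  # two peaks 5 channels apart with M = 20: only the taller survives
  y <- rep(0, 200)
  y[100] <- 1; y[105] <- 0.6
  expect_equal(candidate_peaks(spec_of(y), 20), 100L)

  # flat spectra have no strict maxima
  expect_length(candidate_peaks(spec_of(rep(1, 100)), 10), 0)

  expect_error(candidate_peaks(spec_of(rep(1, 30)), 20),
               class = "rdisc_config_error")
})

test_that("candidate detection agrees with the exhaustive window scan", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(50:512, 1)
    M <- sample(2:25, 1)
    y <- rnorm(n)
    expect_identical(candidate_peaks(spec_of(y), M), bf_candidates(y, M))
  }
})

test_that("discretization recovers planted peaks and rejects flat bumps", {
  tpls <- default_templates(3, seed = 9)
  recalls <- vapply(1:6, function(i) {
    tpl <- tpls[[(i - 1) %% 3 + 1]]
    sim <- simulate_spectrum(tpl, n_shifts = 2048, seed = 300 + i)
    d <- discretize(qc_pipeline(sim$spectrum))
    peak_recovery(d, sim$truth$positions)$recall
  }, numeric(1))
  expect_true(all(recalls >= 0.9))

  # a broad flat bump (width >= 200 cm^-1) is below the curvature gate
  grid <- seq(400, 3200, length.out = 1024)
  bump <- 0.1 * exp(-(grid - 1500)^2 / (2 * 120^2)) +
    lorentz_sum(grid, 2500, 1, 20)
  d <- discretize(normalize_spectrum(raman_spectrum(grid, bump)))
  expect_true(all(abs(d$peaks$position - 2500) < 10))

  # a spectrum that is almost all noise (one real band) stays nearly
  # spurious-free after the full chain
  tpl <- class_template("solo", 1600, 1, 20)
  for (seed in 1:5) {
    sim <- simulate_spectrum(tpl, n_shifts = 1024, seed = seed)
    dn <- discretize(qc_pipeline(sim$spectrum))
    r <- peak_recovery(dn, sim$truth$positions)
    expect_equal(r$recall, 1)
    expect_lte(r$n_spurious, 2)
  }
})

test_that("every reported peak satisfies all three gates post hoc", {
  tpl <- default_templates(1, seed = 15)[[1]]
  sim <- simulate_spectrum(tpl, n_shifts = 2048, seed = 8)
  q <- qc_pipeline(sim$spectrum)
  cfg <- disc_config()
  d <- discretize(q, cfg)
  expect_gt(nrow(d$peaks), 0)
  idx <- match(d$peaks$position, q$shifts)
  expect_false(anyNA(idx))
  noise <- estimate_noise_level(q, cfg)
  expect_true(all(idx %in% candidate_peaks(q, cfg$M)))
  expect_true(all(curvature_at(q, idx) > cfg$lambda_min))
  expect_true(all(q$intensities[idx] > noise))
})

test_that("peak count is monotone in the curvature threshold and window", {
  tpl <- default_templates(1, seed = 23)[[1]]
  q <- qc_pipeline(simulate_spectrum(tpl, 2048, seed = 4)$spectrum)
  counts_lambda <- vapply(c(0, 1e-4, 3e-3, 1e-2, 0.1), function(l)
    nrow(discretize(q, disc_config(lambda_min = l))$peaks), numeric(1))
  expect_true(all(diff(counts_lambda) <= 0))
  counts_M <- vapply(c(5, 10, 20, 40, 80), function(m)
    nrow(discretize(q, disc_config(M = m))$peaks), numeric(1))
  expect_true(all(diff(counts_M) <= 0))
})
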