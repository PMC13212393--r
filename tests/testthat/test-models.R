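test_that("all models are normalized and attenuating", {
  for (s in scheme13$sequences) {
    for (fn in list(impulsed_signal, joint_signal)) {
      S <- fn(params_mid, s)
      expect_equal(S[1], 1)             # b = 0
      expect_true(all(S > 0))
      expect_true(all(diff(S) <= 1e-12))  # non-increasing in b
    }
  }
  S <- exchange_signal(params_mid, scheme13$sequences$PGSE, dt = 0.02)
  expect_equal(S[1], 1)
  expect_true(all(diff(S) <= 1e-12))
})

test_that("IMPULSED reduces to single compartments at the edges", {
  s <- scheme13$sequences$PGSE
  p0 <- microstructure_params(0, 14, 1.8)
  expect_equal(impulsed_signal(p0, s), exp(-b_to_internal(s$b_values) * 1.8))
  # fully restricted tiny-attenuation limit
  p1 <- microstructure_params(1, 0.5, 1.8)
  expect_true(all(impulsed_signal(p1, s) > 0.999))
})

test_that("the Kaerger solution nests IMPULSED at k_in = 0", {
  for (adc_r in c(0.05, 0.3, 0.8)) {
    p0 <- microstructure_params(0.5, 14, 1.8, k_in = 0)
    s <- scheme13$sequences$PGSE
    expect_lt(max(abs(karger_signal(p0, s, adc_r = adc_r) -
                      impulsed_signal(p0, s, adc_r = adc_r))), 1e-12)
  }
})

test_that("fast exchange collapses to the volume-weighted monoexponential", {
  s <- scheme13$sequences$PGSE
  adc_r <- sphere_adc(14, 1.56, s)
  S_mono <- exp(-b_to_internal(s$b_values) * (0.5 * adc_r + 0.5 * 1.8))
  dev_at <- function(k) {
    p <- microstructure_params(0.5, 14, 1.8, k_in = k)
    max(abs(karger_signal(p, s, adc_r = adc_r) / S_mono - 1))
  }
  devs <- vapply(c(0.2, 1, 3, 8), dev_at, numeric(1))
  # the residual of the fast-exchange limit is O(1/(k t_diff)): at k = 1/ms
  # it is ~5e-3 for these tissue values, and it shrinks monotonically
  expect_lt(devs[2], 8e-3)
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[4], 1e-3)
})

test_that("the eigen closed form equals a matrix-exponential oracle", {
  s <- scheme13$sequences$PGSE
  t_diff <- effective_diffusion_time(s)
  for (pars in list(c(0.3, 0.02), c(0.55, 0.007), c(0.8, 0.05))) {
    v <- pars[1]; k <- pars[2]
    p <- microstructure_params(v, 12, 1.9, k_in = k)
    adc_r <- 0.2
    for (b in c(0.25, 0.5, 1)) {
      q2 <- b / t_diff
      kex <- k * v / (1 - v)
      A <- matrix(c(-q2 * adc_r - k, k, kex, -q2 * 1.9 - kex), 2, 2)
      S_oracle <- sum(as.matrix(Matrix::expm(A * t_diff)) %*% c(v, 1 - v))
      S_pkg <- karger_signal(p, s, b = b * 1000, adc_r = adc_r)
      expect_lt(abs(S_pkg - S_oracle), 1e-10)
    }
  }
})

test_that("the Kaerger decomposition respects its ordering convention", {
  dec <- karger_decomposition(params_mid, scheme13$sequences$PGSE,
                              b = c(250, 500, 1000))
  expect_true(all(dec$D1_star <= dec$D2_star))
  expect_true(all(dec$V1 >= 0 & dec$V1 <= 1))
  expect_true(all(dec$D1_star >= 0))
})

test_that("JOINT dispatches by sequence kind", {
  p <- params_mid
  for (nm in c("OGSE_25Hz", "OGSE_50Hz")) {
    s <- scheme13$sequences[[nm]]
    expect_identical(joint_signal(p, s, adc_r = 0.4),
                     impulsed_signal(p, s, adc_r = 0.4))
  }
  s <- scheme13$sequences$PGSE
  p0 <- microstructure_params(0.5, 14, 1.8, k_in = 0)
  expect_lt(max(abs(joint_signal(p0, s, adc_r = 0.1) -
                    impulsed_signal(p0, s, adc_r = 0.1))), 1e-12)
  # with restricted D_a < D_ex, exchange monotonically deepens attenuation
  adc_r <- 0.1
  S_at_b1000 <- vapply(seq(0, 0.05, length.out = 6), function(k) {
    joint_signal(microstructure_params(0.5, 14, 1.8, k_in = k), s,
                 b = 1000, adc_r = adc_r)
  }, numeric(1))
  expect_true(all(diff(S_at_b1000) < 0))
})

test_that("degenerate exchange balance is rejected", {
  p_bad <- microstructure_params(1, 14, 1.8, k_in = 0.01)
  expect_error(karger_signal(p_bad, scheme13$sequences$PGSE, adc_r = 0.1),
               "degenerate balance")
  expect_error(exchange_signal(p_bad, scheme13$sequences$PGSE),
               "degenerate balance")
})

test_that("EXCHANGE conserves magnetization without gradients", {
  s <- scheme13$sequences$PGSE
  S0 <- exchange_signal(params_mid, s, b = 0, dt = 0.02)
  expect_equal(S0, 1)
})

test_that("EXCHANGE matches the Kaerger closed form in the narrow-pulse limit", {
  np <- pgse_sequence(0.5, 70, c(0, 250, 500, 750, 1000), ramp_time = 0.05)
  p <- microstructure_params(0.5, 12, 1.8, k_in = 0.02)
  adc_r <- sphere_adc(12, 1.56, np)
  S_ex <- exchange_signal(p, np, dt = 0.005, d_in_app = adc_r)
  S_ka <- karger_signal(p, np, adc_r = adc_r)
  expect_lt(max(abs(S_ex[-1] / S_ka[-1] - 1)), 0.01)
})

test_that("EXCHANGE is converged in the waveform step", {
  s <- scheme13$sequences$OGSE_25Hz
  S1 <- exchange_signal(params_mid, s, b = c(500, 1000), dt = 0.02)
  S2 <- exchange_signal(params_mid, s, b = c(500, 1000), dt = 0.01)
  expect_lt(max(abs(S1 - S2)), 1e-6)
})

test_that("cellularity is the volume-fraction-per-diameter proxy", {
  expect_equal(cellularity(0.5, 10), 5)
  expect_equal(cellularity(0, 12), 0)
  expect_true(all(diff(cellularity(seq(0.1, 0.9, 0.1), 10)) > 0))
  expect_true(all(diff(cellularity(0.5, seq(8, 20, 2))) < 0))
  expect_error(cellularity(0.5, 0), "positive")
})

test_that("vectorized simulation agrees with the per-voxel models", {
  pars <- dplyr::bind_rows(
    microstructure_params(0.4, 12, 1.9, 0.012),
    microstructure_params(0.6, 16, 1.5, 0.006))
  sig <- simulate_signals(pars, scheme13, model = "JOINT")
  expect_equal(nrow(sig), 2 * 13)
  for (i in 1:2) {
    for (nm in names(scheme13$sequences)) {
      s <- scheme13$sequences[[nm]]
      got <- sig$signal[sig$voxel == i & sig$sequence == nm]
      want <- joint_signal(pars[i, ], s,
                           adc_r = sphere_adc(pars$d[i], 1.56, s, dt = 0.02))
      expect_equal(got, want, tolerance = 1e-4)
    }
  }
})
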