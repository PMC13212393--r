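test_that("MP-PCA passes noiseless low-rank data through unchanged", {
  dm <- c(8, 8, 3, 13)
  base <- exp(-outer(rep(1, prod(dm[1:3])), seq(0, 1, length.out = 13)))
  amp <- matrix(runif(prod(dm[1:3]), 0.5, 1.5), ncol = 1)
  stack <- array(as.vector(amp %*% base[1, , drop = FALSE]), dm)
  out <- mppca_denoise(stack, patch = c(5, 5, 3))
  expect_lt(max(abs(out$stack - stack)) / max(stack), 1e-6)
})

test_that("MP-PCA recovers sigma and strips pure noise", {
  set.seed(42)
  dm <- c(10, 10, 3, 13)
  stack <- array(rnorm(prod(dm), 0, 1), dm)
  out <- mppca_denoise(stack, patch = c(5, 5, 3))
  expect_lt(abs(mean(out$sigma) - 1), 0.1)
  expect_gt(1 - var(as.vector(out$stack)) / var(as.vector(stack)), 0.95)
})

test_that("MP-PCA reduces the error of a signal-plus-noise phantom", {
  set.seed(7)
  specs <- tiny_specs(n_voxels = 60)
  subj <- generate_subject(specs$poor, scheme13, model = "IMPULSED", seed = 3)
  clean_subj <- generate_subject(specs$poor, scheme13, model = "IMPULSED",
                                 seed = 3)
  sigc <- simulate_signals(clean_subj$truth[, c("v_in", "d", "D_ex", "k_in")],
                           scheme13, model = "IMPULSED")
  clean <- matrix(sigc$signal, nrow = 60, byrow = TRUE)
  vox <- which(subj$roi_mask)
  noisy <- matrix(subj$stack, ncol = 13)[vox, ]
  den <- matrix(mppca_denoise(subj$stack, patch = c(5, 5, 3))$stack,
                ncol = 13)[vox, ]
  rmse <- function(x) sqrt(mean((x - clean)^2))
  expect_lt(rmse(den), rmse(noisy))
})

test_that("MP-PCA patch preconditions are enforced", {
  stack <- array(1, c(4, 4, 2, 13))
  expect_error(mppca_denoise(stack, patch = c(5, 5, 3)), "larger than image")
  expect_error(mppca_denoise(stack, patch = c(3, 4, 1)), "exceed")
})

test_that("IVIM removal is exact on monoexponential decays and idempotent", {
  b <- c(0, 250, 500, 750, 1000)
  S <- exp(-0.0012 * b)
  out <- remove_ivim(b, S)
  expect_equal(out, S / S[1], tolerance = 1e-10)
  expect_equal(remove_ivim(b, out), out, tolerance = 1e-10)
})

test_that("IVIM removal deflates a perfusion-contaminated baseline", {
  b <- c(0, 250, 500, 750, 1000)
  # 10% pseudo-perfusion pool with fast decay D* = 20 um2/ms
  S <- 0.9 * exp(-0.001 * b) + 0.1 * exp(-0.02 * b)
  out <- remove_ivim(b, S)
  s0_rev <- S[2] / out[2]     # the baseline the signals were divided by
  expect_lt(s0_rev, S[1])     # perfusion inflates only the measured b = 0
  # the revised decay follows the tissue compartment, not the perfusion pool
  expect_equal(out[5] / out[2], exp(-0.001 * 750), tolerance = 0.01)
})

test_that("the IVIM fit window follows the protocol b-grids", {
  # OGSE-50Hz grid keeps exactly {250, 500}: a two-point window is valid
  expect_silent(remove_ivim(c(0, 250, 500), exp(-0.001 * c(0, 250, 500))))
  # only one point inside the window is not
  expect_error(remove_ivim(c(0, 250), exp(-0.001 * c(0, 250))),
               ">= 2 b-values")
  # the inclusive upper bound keeps b = 1000 in the PGSE fit: perturbing
  # that point moves the revised baseline only when it is inside the window
  b <- c(0, 250, 500, 750, 1000)
  S <- exp(-0.001 * b); S[5] <- S[5] * 1.1
  incl <- remove_ivim(b, S, include_upper = TRUE)
  excl <- remove_ivim(b, S, include_upper = FALSE)
  expect_false(isTRUE(all.equal(incl[2], excl[2])))
  expect_equal(excl[2] * exp(-0.001 * 250)^-1, 1, tolerance = 1e-10)
  expect_error(remove_ivim(c(0, 250, 500), c(1, -0.1, 0.5)), "non-positive")
})

test_that("ADC fitting matches exact slopes", {
  b <- c(0, 250, 500, 750, 1000)
  expect_equal(fit_adc(b, exp(-b_to_internal(b))), 1)
  # two points: exact two-point slope
  expect_equal(fit_adc(c(250, 750), exp(-b_to_internal(c(250, 750)) * 0.7)),
               0.7)
  expect_error(fit_adc(c(500, 500), c(1, 1)), "degenerate")
  expect_error(fit_adc(b, -exp(-b / 1000)), "positive")
})

test_that("time-dependent ADCs from a restricted voxel are ordered", {
  p <- microstructure_params(0.6, 12, 1.8)
  adcs <- vapply(scheme13$sequences, function(s) {
    fit_adc(s$b_values, impulsed_signal(p, s))
  }, numeric(1))
  expect_lt(adcs[["PGSE"]], adcs[["OGSE_25Hz"]])
  expect_lt(adcs[["OGSE_25Hz"]], adcs[["OGSE_50Hz"]])
})

test_that("SNR gating implements the ROI/background ratio rule", {
  img <- array(2, c(6, 6, 1))
  roi <- array(FALSE, dim(img)); roi[3:4, 3:4, 1] <- TRUE
  bg <- array(FALSE, dim(img)); bg[1, , 1] <- TRUE
  img[roi] <- 30; img[bg] <- 2
  out <- compute_snr(img, roi, bg)
  expect_equal(out$snr, 15)
  expect_true(out$pass)
  img[bg] <- 0
  expect_error(compute_snr(img, roi, bg), "background")
  expect_error(compute_snr(img, roi & FALSE, bg), "empty mask")
  expect_error(compute_snr(img, roi, roi), "overlap")
})

test_that("measured SNR on a Rician phantom tracks the configured level", {
  specs <- tiny_specs(n_voxels = 60, snr = 25)
  subj <- generate_subject(specs$poor, scheme13, seed = 8)
  st <- scheme_table(scheme13)
  b0 <- st$volume[st$b_s_mm2 == 0][1]
  out <- compute_snr(subj$stack[, , , b0], subj$roi_mask,
                     subj$background_mask)
  # the background mean is the Rayleigh floor sigma*sqrt(pi/2), so the
  # plain ratio sits near SNR / 1.2533
  expect_lt(abs(out$snr / (25 / sqrt(pi / 2)) - 1), 0.2)
  expect_true(out$pass)
})

test_that("preprocess_stack normalizes every sequence baseline to one", {
  specs <- tiny_specs(n_voxels = 36)
  subj <- generate_subject(specs$poor, scheme13, seed = 4)
  pre <- preprocess_stack(subj$stack, scheme13, mask = subj$roi_mask,
                          denoise = FALSE)
  st <- scheme_table(scheme13)
  flat <- matrix(pre$stack, ncol = 13)[which(subj$roi_mask), ]
  for (b0 in st$volume[st$b_s_mm2 == 0]) {
    expect_equal(unname(flat[, b0]), rep(1, 36))
  }
  expect_true(any(grepl("ivim", pre$log)))
})
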