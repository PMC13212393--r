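# Shared fixtures built in code: the default three-sequence scheme, a quick
# parameter set, and the van Gelderen rectangular-PGSE closed form used as an
# independent oracle for the GPD machinery.

scheme13 <- default_scheme()

params_mid <- microstructure_params(v_in = 0.5, d = 14, D_ex = 1.8,
                                    k_in = 0.01)

# van Gelderen finite-pulse PGSE attenuation for an impermeable sphere,
# expressed as an effective ADC (per unit b); independent of the package's
# waveform-based evaluation path.
vangelderen_pgse_adc <- function(d, D, delta, Delta, n_modes = 25) {
  mu <- sphere_bessel_roots(n_modes)
  R <- d / 2
  a <- mu / R
  lam <- a^2 * D
  num <- 2 * lam * delta - 2 + 2 * exp(-lam * delta) + 2 * exp(-lam * Delta) -
    exp(-lam * (Delta - delta)) - exp(-lam * (Delta + delta))
  minus_lnS_per_g2 <- 2 * sum(num / (D^2 * a^6 * (R^2 * a^2 - 2)))
  b_per_g2 <- delta^2 * (Delta - delta / 3)
  minus_lnS_per_g2 / b_per_g2
}

# small two-group specs for fast cohort tests
tiny_specs <- function(n1 = 4, n2 = 5, n_voxels = 36, snr = 25) {
  list(
    poor = group_spec("poor", n1, v_in = c(0.55, 0.07), d = c(14, 2),
                      D_ex = c(1.6, 0.25), k_in = c(0.007, 0.003),
                      n_voxels = n_voxels, snr = snr),
    well_moderate = group_spec("well_moderate", n2, v_in = c(0.40, 0.07),
                               d = c(14, 2), D_ex = c(1.9, 0.25),
                               k_in = c(0.012, 0.004),
                               n_voxels = n_voxels, snr = snr)
  )
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
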