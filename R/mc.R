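# Random-walk Monte-Carlo oracle: the brute-force truth source used to
# validate the analytic GPD / exchange forward models.

#' Describe a Monte-Carlo geometry
#'
#' @param mode `"free"` (no barriers), `"single_sphere"` (walkers start
#'   inside a sphere of diameter `d`), or `"periodic_packing"` (a sphere per
#'   periodic cubic cell, cell size set by the target packing fraction).
#' @param d sphere diameter, um.
#' @param v_in_target packing fraction for `periodic_packing`; must be below
#'   the close-packing bound 0.74.
#' @param P membrane permeability, um/ms (0 = impermeable).
#' @return an object of class `mrc_geometry`.
#' @export
mc_geometry <- function(mode = c("single_sphere", "periodic_packing", "free"),
                        d = 12, v_in_target = 0.4, P = 0) {
  mode <- match.arg(mode)
  stopifnot(d > 0, P >= 0)
  box <- NA_real_
  if (mode == "periodic_packing") {
    stopifnot(v_in_target > 0, v_in_target < 0.74)
    # one sphere per cubic cell: v = (pi/6) d^3 / box^3
    box <- d * (pi / 6 / v_in_target)^(1 / 3)
  }
  structure(list(mode = mode, d = d, v_in_target = v_in_target, P = P,
                 box = box),
            class = "mrc_geometry")
}

#' Monte-Carlo diffusion signal under a sequence
#'
#' Simulates `n_walkers` random walkers through the sequence's discretized
#' waveform, accumulating per-walker phase `phi = gamma sum g(t) x(t) dt`.
#' Because the phase is linear in the gradient amplitude, a single walk
#' yields the signal at every requested b-value:
#' `S(b) = |mean(exp(i * scale_b * phi_hat))|`.
#'
#' @param geom an `mrc_geometry`.
#' @param seq an `mrc_sequence`.
#' @param b b-values, s/mm2; defaults to the sequence's own.
#' @param D_in,D_ex intra/extracellular diffusivities, um2/ms.
#' @param n_walkers number of walkers.
#' @param dt time step, ms; must satisfy `sqrt(6 D dt) < d/10` for bounded
#'   geometries.
#' @param seed integer RNG seed (bitwise-reproducible walks).
#' @param record_times optional times (ms) at which to record the
#'   intracellular occupancy fraction.
#' @return a tibble with columns `sequence`, `b_s_mm2`, `S`, `stderr`, plus
#'   an `occupancy` attribute (tibble `time`, `inside_frac`) when
#'   `record_times` is given.
#' @export
mc_signal <- function(geom, seq, b = seq$b_values, D_in = 1.56, D_ex = 2.0,
                      n_walkers = 1e5, dt = 0.005, seed = 1,
                      record_times = numeric(0)) {
  stopifnot(inherits(geom, "mrc_geometry"), inherits(seq, "mrc_sequence"))
  Dmax <- if (geom$mode == "single_sphere" && geom$P == 0) D_in
          else max(D_in, D_ex)
  if (geom$mode != "free" && sqrt(6 * Dmax * dt) >= geom$d / 10) {
    stop(sprintf(
      "step length sqrt(6 D dt) = %.3f um exceeds d/10 = %.3f um; reduce dt",
      sqrt(6 * Dmax * dt), geom$d / 10))
  }
  w <- build_waveform(seq, g_amp = 1, dt = min(dt, 0.05))
  # resample the unit waveform onto the simulation grid
  nt <- as.integer(round(max(w$times + w$dt / 2) / dt))
  tm <- (seq_len(nt) - 0.5) * dt
  g <- stats::approx(w$times, w$g, xout = tm, rule = 2)$y
  mode_i <- match(geom$mode, c("free", "single_sphere", "periodic_packing")) - 1L
  rec_steps <- if (length(record_times)) pmax(1, round(record_times / dt)) else numeric(0)
  res <- mc_walk(g, dt, mode_i, geom$d / 2,
                 ifelse(is.na(geom$box), 0, geom$box),
                 D_in, D_ex, geom$P, as.integer(n_walkers),
                 as.integer(seed), rec_steps)
  g_req <- required_gradient(seq, b, max_gradient = Inf, dt = min(dt, 0.05))$g_amp
  out <- purrr::map_dfr(seq_along(b), function(j) {
    phi <- GAMMA_H * g_req[j] * res$phase
    cr <- mean(cos(phi)); ci <- mean(sin(phi))
    S <- sqrt(cr^2 + ci^2)
    se <- stats::sd(cos(phi)) / sqrt(length(phi))
    tibble::tibble(sequence = seq$name, b_s_mm2 = b[j], S = S, stderr = se)
  })
  if (length(record_times)) {
    attr(out, "occupancy") <- tibble::tibble(time = rec_steps * dt,
                                             inside_frac = res$inside_frac)
  }
  out
}

#' Monte-Carlo apparent diffusion coefficient
#'
#' Log-linear fit of the simulated signal decay over the given b-values,
#' mirroring how ADCs are extracted from measured data.
#'
#' @inheritParams mc_signal
#' @return list with `adc` (um2/ms), its standard error, and the signal table.
#' @export
mc_adc <- function(geom, seq, b = c(250, 500, 750, 1000), D_in = 1.56,
                   D_ex = 2.0, n_walkers = 1e5, dt = 0.005, seed = 1) {
  sig <- mc_signal(geom, seq, b = b, D_in = D_in, D_ex = D_ex,
                   n_walkers = n_walkers, dt = dt, seed = seed)
  fit <- stats::lm(log(S) ~ I(b_to_internal(b_s_mm2)), data = sig)
  list(adc = -unname(stats::coef(fit)[2]),
       se = unname(summary(fit)$coefficients[2, 2]),
       signals = sig)
}
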