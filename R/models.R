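# Tissue microstructure forward models: IMPULSED (impermeable two-compartment),
# JOINT (Kaerger transcytolemmal exchange on PGSE, IMPULSED on OGSE) and
# EXCHANGE (discretized two-compartment exchange integrator over the actual
# gradient waveform).

MODEL_NAMES <- c("IMPULSED", "JOINT", "EXCHANGE")

#' Microstructural tissue parameters of one voxel
#'
#' @param v_in intracellular water volume fraction, in `[0, 1]`.
#' @param d mean cell diameter, um.
#' @param D_ex extracellular diffusivity, um2/ms.
#' @param k_in intracellular water exchange rate constant (inverse
#'   intracellular residence time), 1/ms; 0 under IMPULSED.
#' @param D_in intracellular intrinsic diffusivity, um2/ms; conventionally
#'   fixed at 1.56 to stabilize fitting.
#' @return a one-row tibble of class `mrc_params`.
#' @examples
#' microstructure_params(v_in = 0.5, d = 14, D_ex = 1.8)
#' @export
microstructure_params <- function(v_in, d, D_ex, k_in = 0, D_in = 1.56) {
  stopifnot(v_in >= 0, v_in <= 1, d > 0, D_ex >= 0, k_in >= 0, D_in > 0)
  out <- tibble::tibble(v_in = v_in, d = d, D_ex = D_ex, k_in = k_in,
                        D_in = D_in)
  class(out) <- c("mrc_params", class(out))
  out
}

as_params_row <- function(p) {
  if (inherits(p, "data.frame")) {
    stopifnot(nrow(p) == 1)
    p <- as.list(p)
  }
  if (is.null(p$k_in)) p$k_in <- 0
  if (is.null(p$D_in)) p$D_in <- 1.56
  stopifnot(p$v_in >= 0, p$v_in <= 1, p$d > 0, p$D_ex >= 0, p$k_in >= 0)
  p
}

#' Image-derived cellularity
#'
#' The density proxy `rho = v_in / d * 100` (units of 100/um): volume
#' fraction per unit cell diameter.
#'
#' @param v_in intracellular volume fraction.
#' @param d cell diameter, um.
#' @return cellularity, vectorized.
#' @examples
#' cellularity(0.5, 10) # 5
#' @export
cellularity <- function(v_in, d) {
  if (any(d <= 0)) stop("`d` must be positive")
  v_in / d * 100
}

#' IMPULSED two-compartment signal
#'
#' `S = v_in exp(-b ADC_r) + (1 - v_in) exp(-b D_ex)` with ADC_r the
#' GPD restricted-sphere diffusivity of the sequence; transcytolemmal
#' exchange is ignored.
#'
#' @param p microstructure parameters (`microstructure_params()` or a
#'   one-row data frame / named list).
#' @param seq an `mrc_sequence`.
#' @param b b-values in s/mm2; defaults to the sequence's own.
#' @param adc_r optional precomputed ADC_r (um2/ms) to skip the GPD series.
#' @return normalized signal, one value per b.
#' @examples
#' p <- microstructure_params(0.5, 12, 1.8)
#' impulsed_signal(p, default_scheme()$sequences$PGSE)
#' @export
impulsed_signal <- function(p, seq, b = seq$b_values, adc_r = NULL) {
  p <- as_params_row(p)
  if (is.null(adc_r)) adc_r <- sphere_adc(p$d, p$D_in, seq)
  bi <- b_to_internal(b)
  p$v_in * exp(-bi * adc_r) + (1 - p$v_in) * exp(-bi * p$D_ex)
}

# Vectorized Kaerger biexponential over voxels/b. All rates in 1/ms,
# diffusivities um2/ms, b in ms/um2. Returns list(S, V1, D1_star, D2_star).
karger_core <- function(v_in, D_a, D_ex, k_in, b_int, t_diff) {
  if (any(v_in >= 1 & k_in > 0)) {
    stop("degenerate balance: v_in = 1 with k_in > 0 leaves no extracellular pool")
  }
  k_ex <- ifelse(v_in < 1, k_in * v_in / (1 - v_in), 0)
  q2 <- b_int / t_diff
  a11 <- -q2 * D_a - k_in
  a22 <- -q2 * D_ex - k_ex
  a12 <- k_ex
  a21 <- k_in
  m <- (a11 + a22) / 2
  s <- sqrt(pmax(((a11 - a22) / 2)^2 + a12 * a21, 0))
  th1 <- m + s                      # slower-decaying eigenvalue -> D1* <= D2*
  th2 <- m - s
  # spectral weight of th1 on the summed magnetization, initial (v, 1-v)
  num <- (a11 - th2) * v_in + a12 * (1 - v_in) +
    a21 * v_in + (a22 - th2) * (1 - v_in)
  V1 <- ifelse(s > 1e-14, num / (2 * s), v_in)
  h <- s * t_diff
  # th1, th2 <= 0 for this (mass-decaying) generator, so both exponentials
  # are bounded; the series branch covers coalescing eigenvalues (s ~ 0)
  S <- ifelse(h > 1e-8,
              V1 * exp(th1 * t_diff) + (1 - V1) * exp(th2 * t_diff),
              exp(m * t_diff) * (1 + h^2 / 2 + (num - s) * t_diff))
  D1s <- ifelse(q2 > 0, -th1 / q2, D_a * v_in + D_ex * (1 - v_in))
  D2s <- ifelse(q2 > 0, -th2 / q2, D_a * v_in + D_ex * (1 - v_in))
  S[b_int == 0] <- 1
  list(S = S, V1 = V1, D1_star = D1s, D2_star = D2s)
}

#' Kaerger exchange signal for PGSE
#'
#' Two-site exchange between the restricted intracellular pool (apparent
#' diffusivity ADC_r) and the extracellular pool, over the effective
#' diffusion time: `S = V1 exp(-b D1*) + (1 - V1) exp(-b D2*)`, computed as
#' the eigen-solution of the 2x2 exchange-diffusion generator
#' `A = -q^2 diag(ADC_r, D_ex) + K`, `q^2 = b / t_diff`, with the
#' mass-conserving exchange matrix `K = [[-k_in, k_ex], [k_in, -k_ex]]`,
#' `k_ex = k_in v_in / (1 - v_in)` (detailed balance). The ordering
#' convention is `D1* <= D2*` with `V1` the weight on `D1*`.
#'
#' @inheritParams impulsed_signal
#' @return normalized signal per b (`karger_signal`) or a tibble with
#'   columns `b_s_mm2`, `V1`, `D1_star`, `D2_star` (`karger_decomposition`).
#' @export
karger_signal <- function(p, seq, b = seq$b_values, adc_r = NULL) {
  stopifnot(inherits(seq, "mrc_sequence"))
  if (seq$kind != "PGSE") stop("karger_signal() is defined for PGSE sequences")
  p <- as_params_row(p)
  if (is.null(adc_r)) adc_r <- sphere_adc(p$d, p$D_in, seq)
  karger_core(p$v_in, adc_r, p$D_ex, p$k_in, b_to_internal(b),
              effective_diffusion_time(seq))$S
}

#' @rdname karger_signal
#' @export
karger_decomposition <- function(p, seq, b = seq$b_values, adc_r = NULL) {
  stopifnot(inherits(seq, "mrc_sequence"), seq$kind == "PGSE")
  p <- as_params_row(p)
  if (is.null(adc_r)) adc_r <- sphere_adc(p$d, p$D_in, seq)
  k <- karger_core(p$v_in, adc_r, p$D_ex, p$k_in, b_to_internal(b),
                   effective_diffusion_time(seq))
  tibble::tibble(b_s_mm2 = b, V1 = k$V1, D1_star = k$D1_star,
                 D2_star = k$D2_star, S = k$S)
}

#' JOINT signal
#'
#' Exchange is modelled where it matters: PGSE volumes (long diffusion time)
#' use the Kaerger solution; OGSE volumes (short diffusion time) assume the
#' impact of exchange is limited and reduce to IMPULSED.
#'
#' @inheritParams impulsed_signal
#' @return normalized signal per b.
#' @export
joint_signal <- function(p, seq, b = seq$b_values, adc_r = NULL) {
  if (seq$kind == "PGSE") karger_signal(p, seq, b, adc_r)
  else impulsed_signal(p, seq, b, adc_r)
}

#' EXCHANGE signal: discretized waveform exchange integrator
#'
#' Integrates the two-compartment magnetization system
#' `dM/dt = [-q(t)^2 diag(D_in_app, D_ex) + K] M` over the sequence's
#' sampled gradient waveform, `q(t) = gamma int g dt'`, with an exact 2x2
#' matrix exponential per piecewise-constant step (unconditionally stable);
#' `S` is the total magnetization at the echo. The default intracellular
#' apparent diffusivity is the sphere's GPD ADC_r matched to the sequence's
#' diffusion time; `d_in_app` substitutes any other expression.
#'
#' @inheritParams impulsed_signal
#' @param dt waveform sampling step, ms.
#' @param d_in_app optional override for the intracellular apparent
#'   diffusivity (um2/ms): a number, or a function of `(p, seq)`.
#' @return normalized signal per b.
#' @export
exchange_signal <- function(p, seq, b = seq$b_values, dt = 0.01,
                            d_in_app = NULL) {
  stopifnot(inherits(seq, "mrc_sequence"))
  p <- as_params_row(p)
  if (p$v_in >= 1 && p$k_in > 0) {
    stop("degenerate balance: v_in = 1 with k_in > 0 leaves no extracellular pool")
  }
  D1 <- if (is.null(d_in_app)) {
    sphere_adc(p$d, p$D_in, seq, dt = max(dt, 0.01))
  } else if (is.function(d_in_app)) d_in_app(p, seq) else d_in_app
  k_ex <- if (p$v_in < 1) p$k_in * p$v_in / (1 - p$v_in) else 0

  w <- build_waveform(seq, g_amp = 1, dt = dt)
  g_req <- required_gradient(seq, b, max_gradient = Inf, dt = dt)$g_amp
  qhat <- cumsum(w$g) * w$dt
  q0 <- c(0, qhat[-length(qhat)])
  qbar2 <- (q0^2 + q0 * qhat + qhat^2) / 3      # step-mean q^2, unit amplitude
  scale2 <- (GAMMA_H * g_req)^2                  # per-b amplitude factor
  S <- exchange_propagate(qbar2, w$dt, scale2, D1, p$D_ex, p$k_in, k_ex,
                          p$v_in)
  S[b == 0] <- 1
  S
}

#' Forward-simulate a table of voxels through a scheme
#'
#' Vectorized forward model over many voxels: one row of `params` per voxel,
#' one output row per (voxel, volume).
#'
#' @param params a data frame with columns `v_in`, `d`, `D_ex` and optionally
#'   `k_in`, `D_in`.
#' @param scheme an `mrc_scheme`.
#' @param model one of `"IMPULSED"`, `"JOINT"`, `"EXCHANGE"`.
#' @param adc function from `adc_interpolator()`; built on the fly if NULL.
#' @return a tibble with columns `voxel`, `volume`, `sequence`, `b_s_mm2`,
#'   `signal`.
#' @export
simulate_signals <- function(params, scheme, model = "JOINT", adc = NULL) {
  model <- match.arg(model, MODEL_NAMES)
  stopifnot(inherits(scheme, "mrc_scheme"))
  params <- tibble::as_tibble(params)
  if (!"k_in" %in% names(params)) params$k_in <- 0
  if (!"D_in" %in% names(params)) params$D_in <- 1.56
  if (is.null(adc)) adc <- adc_interpolator(scheme, D_in = params$D_in[1])
  nvox <- nrow(params)
  purrr::map_dfr(scheme$sequences, function(s) {
    if (model == "EXCHANGE") {
      # waveform integration voxel by voxel (the reference exchange path)
      sig <- vapply(seq_len(nvox), function(i) {
        exchange_signal(params[i, ], s, dt = 0.02)
      }, numeric(length(s$b_values)))
      return(tibble::tibble(
        voxel = rep(seq_len(nvox), each = length(s$b_values)),
        sequence = s$name, b_s_mm2 = rep(s$b_values, nvox),
        signal = as.vector(sig)))
    }
    D_a <- adc(params$d, s$name)
    use_karger <- model == "JOINT" && s$kind == "PGSE"
    purrr::map_dfr(seq_along(s$b_values), function(j) {
      bi <- s$b[j]
      Sv <- if (use_karger) {
        karger_core(params$v_in, D_a, params$D_ex, params$k_in, bi,
                    effective_diffusion_time(s))$S
      } else {
        params$v_in * exp(-bi * D_a) + (1 - params$v_in) * exp(-bi * params$D_ex)
      }
      tibble::tibble(voxel = seq_len(nvox), sequence = s$name,
                     b_s_mm2 = s$b_values[j], signal = Sv)
    })
  }) |>
    dplyr::left_join(scheme_table(scheme)[, c("volume", "sequence", "b_s_mm2")],
                     by = c("sequence", "b_s_mm2")) |>
    dplyr::arrange(.data$voxel, .data$volume) |>
    dplyr::relocate("volume", .after = "voxel")
}
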