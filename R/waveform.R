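# Discretized effective gradient waveforms. The refocusing 180-degree pulse
# is absorbed as a sign flip of the second lobe, so a waveform is a single
# signed g(t) trace whose zeroth moment vanishes at the echo.

#' Build the discretized gradient waveform of a sequence
#'
#' PGSE lobes are plain trapezoids; OGSE lobes are trapezoid-cosine
#' oscillations: plateaus following the sign of `cos(2*pi*n_cycles*t/delta)`
#' with linear slewing of duration `ramp_time` at the start, end and every
#' polarity reversal (quarter-period leading/trailing plateaus, so each lobe
#' carries exactly `n_cycles` full oscillation periods). The second lobe is
#' sign-flipped. Samples are bin midpoints, so the trace is interpreted as
#' piecewise-constant over steps of `dt`.
#'
#' @param seq an `mrc_sequence`.
#' @param g_amp gradient amplitude, mT/m.
#' @param dt sampling step, ms; must be <= 0.05 and resolve any OGSE period
#'   with at least 20 samples.
#' @return an object of class `mrc_waveform` with fields `times`, `g`, `dt`.
#' @examples
#' w <- build_waveform(pgse_sequence(13.52, 74, c(0, 1000)), g_amp = 40)
#' sum(w$g) * w$dt  # refocused: ~0
#' @export
build_waveform <- function(seq, g_amp, dt = 0.01) {
  stopifnot(inherits(seq, "mrc_sequence"), g_amp >= 0)
  if (dt > 0.05) stop("`dt` must be <= 0.05 ms")
  if (seq$kind == "OGSE") {
    period <- seq$delta / seq$n_cycles
    if (period / dt < 20) {
      stop(sprintf(
        "resolution error: dt = %g ms gives %.1f samples per OGSE period (need >= 20)",
        dt, period / dt))
    }
  }
  total <- seq$Delta + seq$delta
  n <- max(2L, as.integer(round(total / dt)))
  tm <- (seq_len(n) - 0.5) * dt
  lobe <- if (seq$kind == "PGSE") pgse_lobe else ogse_lobe
  g <- lobe(tm, seq) - lobe(tm - seq$Delta, seq)
  structure(list(times = tm, g = g_amp * g, dt = dt, g_amp = g_amp),
            class = "mrc_waveform")
}

# unit-amplitude trapezoid on [0, delta], zero elsewhere
pgse_lobe <- function(t, seq) {
  r <- max(seq$ramp_time, 1e-9)
  pmax(0, pmin(t / r, 1, (seq$delta - t) / r))
}

# unit-amplitude trapezoid-cosine lobe on [0, delta], zero elsewhere
ogse_lobe <- function(t, seq) {
  d <- seq$delta
  Tp <- d / seq$n_cycles
  r <- max(seq$ramp_time, 1e-9)
  # plateau polarity follows cos phase
  s <- sign(cos(2 * pi * t / Tp))
  s[s == 0] <- 1
  out <- s
  # linear transitions of width 2r centred on each interior zero crossing
  crossings <- ((2 * seq_len(2 * seq$n_cycles) - 1) / 4) * Tp
  crossings <- crossings[crossings < d - 1e-12]
  for (tau in crossings) {
    idx <- which(abs(t - tau) < r)
    s_before <- sign(cos(2 * pi * (tau - r) / Tp))
    out[idx] <- s_before * (tau - t[idx]) / r
  }
  # start/end ramps from and to zero
  i0 <- which(t >= 0 & t < r)
  out[i0] <- out[i0] * t[i0] / r
  i1 <- which(t > d - r & t <= d)
  out[i1] <- out[i1] * (d - t[i1]) / r
  out[t < 0 | t > d] <- 0
  out
}

#' Numerical b-value of a waveform
#'
#' Computes `b = integral(q(t)^2 dt)` with `q(t) = gamma * integral(g dt')`,
#' treating the sampled trace as piecewise-constant in g (hence piecewise
#' linear in q, integrated exactly per step). Errors if the waveform is not
#' refocused.
#'
#' @param w an `mrc_waveform`.
#' @return b-value in s/mm2.
#' @examples
#' w <- build_waveform(pgse_sequence(13.52, 74, c(0, 1000)), g_amp = 40)
#' waveform_bvalue(w)
#' @export
waveform_bvalue <- function(w) {
  stopifnot(inherits(w, "mrc_waveform"))
  m0 <- abs(sum(w$g) * w$dt)
  peak <- max(abs(w$g), 1e-12)
  if (m0 > 1e-9 * peak * (max(w$times) + w$dt / 2)) {
    stop("waveform is not refocused (non-zero zeroth moment at echo)")
  }
  q <- GAMMA_H * cumsum(w$g) * w$dt          # q at step ends, rad/um
  q0 <- c(0, q[-length(q)])
  b_int <- sum(w$dt * (q0^2 + q0 * q + q^2) / 3)  # ms/um^2
  b_to_scanner(b_int)
}

#' Gradient amplitude required for a target b-value
#'
#' Solves `waveform_bvalue(build_waveform(seq, g)) = b` using the exact
#' `b proportional to g^2` scaling of a fixed waveform shape, and flags
#' feasibility against the scanner's maximum amplitude.
#'
#' @param seq an `mrc_sequence`.
#' @param b target b-value(s), s/mm2.
#' @param max_gradient amplitude limit, mT/m.
#' @param dt waveform sampling step, ms.
#' @return a tibble with columns `b_s_mm2`, `g_amp` (mT/m) and `feasible`.
#' @export
required_gradient <- function(seq, b, max_gradient = 80, dt = 0.01) {
  stopifnot(all(b >= 0))
  b_unit <- waveform_bvalue(build_waveform(seq, g_amp = 1, dt = dt))
  g <- sqrt(b / b_unit)
  tibble::tibble(b_s_mm2 = b, g_amp = g, feasible = g <= max_gradient)
}
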