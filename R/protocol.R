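#' @useDynLib mrcytometry, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# Proton gyromagnetic ratio in internal units: rad / (ms * mT/m * um).
# With g in mT/m, t in ms and x in um, gamma*g*t has units rad/um and
# b = integral(q^2 dt) comes out in ms/um^2 (1 ms/um^2 == 1000 s/mm^2).
GAMMA_H <- 2.6752218744e-4

#' Convert b-values between scanner and internal units
#'
#' Scanner protocols quote b in s/mm2; all model code works in ms/um2 so that
#' `b * D` is dimensionless when diffusivities are in um2/ms. The bridge is
#' exact: 1000 s/mm2 == 1 ms/um2.
#'
#' @param b_s_mm2,b_ms_um2 numeric b-values.
#' @return numeric vector in the other unit.
#' @examples
#' b_to_internal(1000) # 1.0
#' @export
b_to_internal <- function(b_s_mm2) b_s_mm2 / 1000

#' @rdname b_to_internal
#' @export
b_to_scanner <- function(b_ms_um2) b_ms_um2 * 1000

#' Diffusion sequence descriptions
#'
#' Constructors for pulsed (PGSE) and trapezoid-cosine oscillating (OGSE)
#' gradient spin-echo diffusion sequences. Times are in ms, frequencies are
#' stored in kHz so that all timing stays in ms, and b-values are given in
#' scanner units (s/mm2).
#'
#' @param delta gradient lobe duration (ms).
#' @param Delta separation between lobe onsets (ms); must satisfy
#'   `Delta >= delta`.
#' @param b_values b-values in s/mm2; non-negative, sorted, starting at 0.
#' @param freq oscillation frequency in Hz (OGSE only); converted to kHz
#'   internally.
#' @param n_cycles integer oscillation cycles per gradient lobe (OGSE only).
#' @param ramp_time trapezoid ramp time (ms).
#' @param name sequence label; defaults to a descriptive name.
#' @return an object of class `mrc_sequence`.
#' @examples
#' pgse_sequence(delta = 13.52, Delta = 74, b_values = c(0, 250, 500, 750, 1000))
#' ogse_sequence(delta = 41.52, Delta = 60, freq = 25, n_cycles = 1,
#'               b_values = c(0, 250, 500, 750, 1000))
#' @export
pgse_sequence <- function(delta, Delta, b_values, ramp_time = 1, name = "PGSE") {
  new_sequence(kind = "PGSE", name = name, delta = delta, Delta = Delta,
               freq = NA_real_, n_cycles = NA_integer_,
               b_values = b_values, ramp_time = ramp_time)
}

#' @rdname pgse_sequence
#' @export
ogse_sequence <- function(delta, Delta, freq, n_cycles, b_values, ramp_time = 1,
                          name = sprintf("OGSE_%gHz", freq)) {
  new_sequence(kind = "OGSE", name = name, delta = delta, Delta = Delta,
               freq = freq / 1000, n_cycles = as.integer(n_cycles),
               b_values = b_values, ramp_time = ramp_time)
}

new_sequence <- function(kind, name, delta, Delta, freq, n_cycles, b_values,
                         ramp_time) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0)
  stopifnot(is.numeric(Delta), length(Delta) == 1)
  if (Delta < delta) {
    stop("`Delta` (lobe separation) must be >= `delta` (lobe duration)")
  }
  if (kind == "OGSE") {
    if (!is.finite(freq) || freq <= 0) {
      stop("invalid protocol: OGSE requires a positive oscillation frequency")
    }
    if (!is.finite(n_cycles) || n_cycles < 1) {
      stop("invalid protocol: OGSE requires n_cycles >= 1")
    }
  }
  if (length(b_values) < 1 || any(b_values < 0) || is.unsorted(b_values) ||
      b_values[1] != 0) {
    stop("`b_values` must be non-negative, sorted, and start at 0")
  }
  stopifnot(ramp_time >= 0, ramp_time < delta / 2)
  structure(
    list(kind = kind, name = name, delta = delta, Delta = Delta,
         freq = freq, n_cycles = n_cycles,
         b_values = b_values, b = b_to_internal(b_values),
         ramp_time = ramp_time),
    class = "mrc_sequence"
  )
}

#' @export
print.mrc_sequence <- function(x, ...) {
  cat(sprintf("<mrc_sequence> %s (%s)\n", x$name, x$kind))
  cat(sprintf("  delta/Delta: %.2f/%.2f ms", x$delta, x$Delta))
  if (x$kind == "OGSE") {
    cat(sprintf("  f = %g Hz, %d cycle(s)", x$freq * 1000, x$n_cycles))
  }
  cat(sprintf("\n  t_diff: %.3g ms\n", effective_diffusion_time(x)))
  cat("  b (s/mm2):", paste(x$b_values, collapse = ", "), "\n")
  invisible(x)
}

#' Effective diffusion time of a sequence
#'
#' For PGSE the diffusion time is `Delta - delta/3`; for cosine-modulated
#' OGSE the empirical convention `1/(4f)` is used.
#'
#' @param seq an `mrc_sequence`.
#' @return diffusion time in ms.
#' @examples
#' effective_diffusion_time(pgse_sequence(13.52, 74, c(0, 1000))) # 69.49
#' @export
effective_diffusion_time <- function(seq) {
  stopifnot(inherits(seq, "mrc_sequence"))
  if (seq$kind == "PGSE") {
    seq$Delta - seq$delta / 3
  } else {
    if (!is.finite(seq$freq) || seq$freq <= 0) {
      stop("invalid protocol: OGSE sequence without oscillation frequency")
    }
    1 / (4 * seq$freq)
  }
}

#' Multi-sequence acquisition scheme
#'
#' Bundles an ordered list of sequences with scanner constraints. The default
#' is the three-sequence rectal protocol: OGSE at 25 Hz (1 cycle) and 50 Hz
#' (2 cycles) with delta = 41.52 ms, plus a conventional PGSE with
#' delta/Delta = 13.52/74 ms, at b = 0-1000 s/mm2 (0-500 for OGSE-50Hz).
#'
#' @param sequences list of `mrc_sequence` objects with unique names.
#' @param max_gradient maximum gradient amplitude, mT/m.
#' @param waveform_dt default waveform sampling step, ms.
#' @return an object of class `mrc_scheme`.
#' @examples
#' sch <- default_scheme()
#' scheme_table(sch)
#' @export
acquisition_scheme <- function(sequences, max_gradient = 80, waveform_dt = 0.01) {
  stopifnot(length(sequences) >= 1,
            all(vapply(sequences, inherits, TRUE, "mrc_sequence")))
  nm <- vapply(sequences, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("sequence names must be unique")
  names(sequences) <- nm
  structure(list(sequences = sequences, max_gradient = max_gradient,
                 waveform_dt = waveform_dt),
            class = "mrc_scheme")
}

#' @rdname acquisition_scheme
#' @export
default_scheme <- function(max_gradient = 80, waveform_dt = 0.01) {
  acquisition_scheme(
    list(
      ogse_sequence(delta = 41.52, Delta = 60, freq = 25, n_cycles = 1,
                    b_values = c(0, 250, 500, 750, 1000), name = "OGSE_25Hz"),
      ogse_sequence(delta = 41.52, Delta = 50, freq = 50, n_cycles = 2,
                    b_values = c(0, 250, 500), name = "OGSE_50Hz"),
      pgse_sequence(delta = 13.52, Delta = 74,
                    b_values = c(0, 250, 500, 750, 1000), name = "PGSE")
    ),
    max_gradient = max_gradient, waveform_dt = waveform_dt
  )
}

#' @export
print.mrc_scheme <- function(x, ...) {
  cat(sprintf("<mrc_scheme> %d sequences, %d volumes, G_max = %g mT/m\n",
              length(x$sequences), nrow(scheme_table(x)), x$max_gradient))
  for (s in x$sequences) print(s)
  invisible(x)
}

#' Tabulate the (sequence, b) index of a scheme
#'
#' One row per acquired volume, in acquisition order (sequences in scheme
#' order, b-values ascending within each). This ordering defines the volume
#' axis of every 4-D stack in the package.
#'
#' @param scheme an `mrc_scheme`.
#' @return a tibble with columns `volume`, `sequence`, `kind`, `b_s_mm2`,
#'   `b` (ms/um2) and `t_diff` (ms).
#' @export
scheme_table <- function(scheme) {
  stopifnot(inherits(scheme, "mrc_scheme"))
  purrr::map_dfr(scheme$sequences, function(s) {
    tibble::tibble(sequence = s$name, kind = s$kind,
                   b_s_mm2 = s$b_values, b = s$b,
                   t_diff = effective_diffusion_time(s))
  }) |>
    dplyr::mutate(volume = dplyr::row_number(), .before = 1)
}

#' Read or write a protocol JSON file
#'
#' One record per sequence with fields `kind`, `name`, `delta_ms`, `Delta_ms`,
#' `freq_hz`, `n_cycles`, `b_s_mm2` and `ramp_ms`; scheme-level fields
#' `max_gradient_mT_m` and `waveform_dt_ms`. A fixture with the default
#' three-sequence protocol ships in `inst/extdata/protocol_default.json`.
#'
#' @param path file path.
#' @param scheme an `mrc_scheme` (for writing).
#' @return `read_protocol()` returns an `mrc_scheme`; `write_protocol()`
#'   returns `path` invisibly.
#' @examples
#' sch <- read_protocol(system.file("extdata", "protocol_default.json",
#'                                  package = "mrcytometry"))
#' @export
read_protocol <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  seqs <- lapply(spec$sequences, function(r) {
    if (identical(r$kind, "PGSE")) {
      pgse_sequence(r$delta_ms, r$Delta_ms, unlist(r$b_s_mm2),
                    ramp_time = r$ramp_ms, name = r$name)
    } else {
      ogse_sequence(r$delta_ms, r$Delta_ms, r$freq_hz, r$n_cycles,
                    unlist(r$b_s_mm2), ramp_time = r$ramp_ms, name = r$name)
    }
  })
  acquisition_scheme(seqs, max_gradient = spec$max_gradient_mT_m,
                     waveform_dt = spec$waveform_dt_ms)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(scheme, path) {
  stopifnot(inherits(scheme, "mrc_scheme"))
  spec <- list(
    max_gradient_mT_m = scheme$max_gradient,
    waveform_dt_ms = scheme$waveform_dt,
    sequences = lapply(unname(scheme$sequences), function(s) {
      list(kind = s$kind, name = s$name, delta_ms = s$delta,
           Delta_ms = s$Delta,
           freq_hz = if (is.na(s$freq)) NULL else s$freq * 1000,
           n_cycles = if (is.na(s$n_cycles)) NULL else s$n_cycles,
           b_s_mm2 = s$b_values, ramp_ms = s$ramp_time)
    })
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
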