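# Voxelwise nonlinear least-squares estimation of microstructural
# parameters under IMPULSED / JOINT / EXCHANGE, with seeded multi-start.

#' Fitting options
#'
#' @param model `"IMPULSED"` (free: v_in, d, D_ex), `"JOINT"` or
#'   `"EXCHANGE"` (additionally k_in).
#' @param bounds named list of `c(lower, upper)` per free parameter.
#'   Defaults: v_in in `[0, 1]`, d in `[5, 25]` um, D_ex in `[0.1, 3]`
#'   um2/ms, k_in in `[0, 0.1]` /ms — physiologic tumour-cell scales wide
#'   enough not to bind typical values.
#' @param n_starts number of multi-start points (seeded Latin grid over the
#'   bounds); the objective in (v_in, d) is multimodal, so > 1 is advised.
#' @param n_polish how many of the best-scoring start points receive a full
#'   optimizer run; the remaining starts are screened by their initial
#'   objective only. The best start is always polished, so the returned
#'   objective never exceeds the objective at any tried start.
#' @param seed integer seed controlling the start grid.
#' @param D_in_fixed intracellular diffusivity held fixed (um2/ms).
#' @param tolerance convergence tolerance passed to the optimizer.
#' @param exchange_dt waveform step (ms) for the EXCHANGE integrator during
#'   fitting (the per-step matrix exponential is exact, so a coarser grid
#'   than the b-value computation is adequate).
#' @return an object of class `mrc_fit_options`.
#' @export
fit_options <- function(model = c("IMPULSED", "JOINT", "EXCHANGE"),
                        bounds = NULL, n_starts = 8, n_polish = 3, seed = 1,
                        D_in_fixed = 1.56, tolerance = 1e-8,
                        exchange_dt = 0.05) {
  model <- match.arg(model)
  def <- list(v_in = c(0, 1), d = c(5, 25), D_ex = c(0.1, 3),
              k_in = c(0, 0.1))
  if (!is.null(bounds)) def[names(bounds)] <- bounds
  if (model == "IMPULSED") def$k_in <- NULL
  stopifnot(all(vapply(def, function(x) x[1] < x[2], TRUE)), n_starts >= 1)
  structure(list(model = model, bounds = def, n_starts = n_starts,
                 n_polish = max(1L, min(n_polish, n_starts)),
                 seed = seed, D_in_fixed = D_in_fixed, tolerance = tolerance,
                 exchange_dt = exchange_dt),
            class = "mrc_fit_options")
}

# run code under a temporary RNG state so package internals never disturb
# the caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# seeded Latin-grid start points: one stratum per start and dimension,
# independently permuted
latin_starts <- function(bounds, n, seed) {
  with_local_seed(seed, {
    pts <- vapply(bounds, function(bd) {
      u <- (sample.int(n) - stats::runif(n)) / n
      bd[1] + u * (bd[2] - bd[1])
    }, numeric(n))
    matrix(pts, nrow = n, dimnames = list(NULL, names(bounds)))
  })
}

# Precompute everything the residual function needs for a scheme + model.
fit_context <- function(scheme, opts, adc = NULL) {
  if (is.null(adc)) adc <- adc_interpolator(scheme, D_in = opts$D_in_fixed)
  seqs <- lapply(scheme$sequences, function(s) {
    ctx <- list(name = s$name, kind = s$kind, b = s$b,
                t_diff = effective_diffusion_time(s))
    if (opts$model == "EXCHANGE") {
      w <- build_waveform(s, g_amp = 1, dt = opts$exchange_dt)
      qhat <- cumsum(w$g) * w$dt
      q0 <- c(0, qhat[-length(qhat)])
      ctx$qbar2 <- (q0^2 + q0 * qhat + qhat^2) / 3
      ctx$dt <- w$dt
      ctx$scale2 <- (GAMMA_H *
        required_gradient(s, s$b_values, max_gradient = Inf,
                          dt = opts$exchange_dt)$g_amp)^2
    }
    ctx
  })
  list(adc = adc, seqs = seqs, model = opts$model)
}

predict_signals <- function(par, ctx) {
  # keep a sliver of extracellular pool so the exchange balance stays
  # defined when the optimizer sits on the v_in = 1 bound
  v <- min(par[["v_in"]], 1 - 1e-6); d <- par[["d"]]; Dex <- par[["D_ex"]]
  k <- if (!is.null(par[["k_in"]]) && !is.na(par[["k_in"]])) par[["k_in"]] else 0
  unlist(lapply(ctx$seqs, function(s) {
    Da <- ctx$adc(d, s$name)
    if (ctx$model == "EXCHANGE") {
      kex <- if (v < 1) k * v / (1 - v) else 0
      out <- exchange_propagate(s$qbar2, s$dt, s$scale2, Da, Dex, k, kex, v)
      out[s$b == 0] <- 1
      out
    } else if (ctx$model == "JOINT" && s$kind == "PGSE") {
      karger_core(v, Da, Dex, k, s$b, s$t_diff)$S
    } else {
      v * exp(-s$b * Da) + (1 - v) * exp(-s$b * Dex)
    }
  }), use.names = FALSE)
}

#' Fit one voxel's signals
#'
#' Bounded Levenberg-Marquardt least squares over all (sequence, b) signals,
#' taking the best of `n_starts` seeded Latin-grid starting points;
#' `D_in` is held fixed. Non-convergence across all starts yields a flagged
#' row, not an error.
#'
#' @param signals numeric vector of normalized signals in
#'   `scheme_table(scheme)` volume order, or a data frame with columns
#'   `sequence`, `b_s_mm2`, `signal`.
#' @param scheme an `mrc_scheme`.
#' @param opts an `mrc_fit_options`.
#' @param ctx precomputed context from the internal `fit_context()`
#'   (supplied by `fit_maps()` to amortize setup).
#' @return a one-row tibble: estimates, `rho`, `objective` (residual sum of
#'   squares), `converged`, `at_bound`.
#' @export
fit_voxel <- function(signals, scheme, opts = fit_options(), ctx = NULL) {
  st <- scheme_table(scheme)
  if (is.data.frame(signals)) {
    key <- paste(st$sequence, st$b_s_mm2)
    m <- match(key, paste(signals$sequence, signals$b_s_mm2))
    stopifnot(!anyNA(m))
    signals <- signals$signal[m]
  }
  stopifnot(length(signals) == nrow(st))
  if (is.null(ctx)) ctx <- fit_context(scheme, opts)
  bounds <- opts$bounds
  lower <- vapply(bounds, `[`, 0, 1)
  upper <- vapply(bounds, `[`, 0, 2)
  starts <- latin_starts(bounds, opts$n_starts, opts$seed)
  resid_fn <- function(par) {
    p <- as.list(par)
    predict_signals(p, ctx) - signals
  }
  start_obj <- vapply(seq_len(nrow(starts)),
                      function(i) sum(resid_fn(starts[i, ])^2), 0)
  polish <- order(start_obj)[seq_len(opts$n_polish)]
  best <- NULL
  for (i in polish) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 60, ftol = opts$tolerance,
                           ptol = opts$tolerance)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$obj) {
      best <- list(par = fit$par, obj = obj, info = fit$info)
    }
  }
  if (is.null(best)) {
    est <- stats::setNames(rep(NA_real_, length(lower)), names(bounds))
    return(finish_fit(est, NA_real_, FALSE, FALSE, opts))
  }
  span <- upper - lower
  at_bound <- any(best$par - lower < 1e-6 * span | upper - best$par < 1e-6 * span)
  finish_fit(best$par, best$obj, best$info %in% 1:3, at_bound, opts)
}

finish_fit <- function(par, obj, converged, at_bound, opts) {
  tibble::tibble(
    v_in = par[["v_in"]], d = par[["d"]], D_ex = par[["D_ex"]],
    k_in = if (opts$model == "IMPULSED") 0 else par[["k_in"]],
    rho = if (is.na(par[["v_in"]])) NA_real_
          else cellularity(par[["v_in"]], par[["d"]]),
    objective = obj, converged = converged, at_bound = at_bound)
}

#' Fit parameter maps over a masked stack
#'
#' Runs `fit_voxel()` for every voxel inside the mask and fits the
#' time-dependent ADC of each sequence (log-linear over all its b-values,
#' including the revised b = 0). Voxels outside the mask are absent from the
#' result. Negative ADCs are retained and flagged, not clipped.
#'
#' @param stack preprocessed (normalized) 4-D array.
#' @param mask 3-D logical/0-1 array; an empty mask yields an empty table.
#' @param scheme an `mrc_scheme`.
#' @param opts an `mrc_fit_options`.
#' @return an `mrc_maps` tibble: one row per masked voxel with coordinates,
#'   microstructural estimates, per-sequence `ADC_*` columns and fit
#'   diagnostics; attributes `dim`, `model`.
#' @export
fit_maps <- function(stack, mask, scheme, opts = fit_options()) {
  dm <- dim(stack)
  stopifnot(length(dm) == 4)
  if (!all(dim(mask) == dm[1:3])) stop("mask shape does not match stack")
  st <- scheme_table(scheme)
  stopifnot(dm[4] == nrow(st))
  vox <- which(as.logical(mask))
  coords <- arrayInd(vox, dm[1:3])
  flat <- matrix(stack, ncol = dm[4])[vox, , drop = FALSE]
  ctx <- fit_context(scheme, opts)
  rows <- vector("list", length(vox))
  for (i in seq_along(vox)) {
    rows[[i]] <- fit_voxel(flat[i, ], scheme, opts, ctx = ctx)
  }
  res <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    v_in = numeric(0), d = numeric(0), D_ex = numeric(0), k_in = numeric(0),
    rho = numeric(0), objective = numeric(0), converged = logical(0),
    at_bound = logical(0))
  adcs <- lapply(unique(st$sequence), function(sq) {
    idx <- st$volume[st$sequence == sq]
    if (length(vox) == 0) return(numeric(0))
    fit_adc(st$b_s_mm2[idx], flat[, idx, drop = FALSE])
  })
  names(adcs) <- paste0("ADC_", sub("^OGSE_", "", unique(st$sequence)))
  out <- tibble::tibble(voxel = vox,
                        x = coords[, 1], y = coords[, 2], z = coords[, 3])
  out <- dplyr::bind_cols(out, res, tibble::as_tibble(adcs))
  attr(out, "dim3") <- dm[1:3]
  attr(out, "model") <- opts$model
  class(out) <- c("mrc_maps", class(out))
  out
}

#' Summarize a parameter map over an ROI
#'
#' Arithmetic mean of every fitted metric across converged voxels, plus the
#' convergence fraction — one subject row for the cohort table.
#'
#' @param maps an `mrc_maps` tibble from `fit_maps()`.
#' @param roi optional 3-D mask restricting the summary; defaults to every
#'   fitted voxel.
#' @return a one-row tibble of ROI-mean metrics and `convergence_fraction`.
#' @export
roi_summary <- function(maps, roi = NULL) {
  tb <- tibble::as_tibble(maps)
  if (!is.null(roi)) tb <- tb[tb$voxel %in% which(as.logical(roi)), ]
  if (nrow(tb) == 0) stop("ROI does not overlap the fitted maps")
  conv <- tb[tb$converged %in% TRUE, ]
  if (nrow(conv) == 0) stop("zero converged voxels in ROI")
  metric_cols <- setdiff(names(tb), c("voxel", "x", "y", "z", "objective",
                                      "converged", "at_bound"))
  out <- dplyr::summarise(conv, dplyr::across(dplyr::all_of(metric_cols), mean))
  out$convergence_fraction <- nrow(conv) / nrow(tb)
  out
}
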