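# Data-processing chain applied before model fitting, in fixed order:
# (registration happens upstream) -> MP-PCA denoising -> IVIM removal by
# log-linear re-baselining of b = 0 -> per-sequence normalization -> fitting.

#' MP-PCA denoising of a 4-D diffusion stack
#'
#' Patchwise principal-component denoising: in each sliding patch the
#' voxel-by-volume matrix is eigendecomposed and components whose
#' eigenvalues are consistent with the Marchenko-Pastur bulk of a pure-noise
#' covariance spectrum are removed; the bulk average estimates the noise
#' variance. Overlapping patch reconstructions are averaged.
#'
#' @param stack 4-D numeric array `(x, y, z, volume)`.
#' @param patch patch size in voxels, length 3; its voxel count must exceed
#'   the number of volumes.
#' @param stride patch stride, length 3.
#' @return list with `stack` (denoised array), `sigma` (3-D noise s.d. map)
#'   and `n_components` (3-D map of retained signal components).
#' @export
mppca_denoise <- function(stack, patch = c(5, 5, 3), stride = c(2, 2, 1)) {
  dm <- dim(stack)
  stopifnot(length(dm) == 4)
  M <- dm[4]
  if (any(patch > dm[1:3])) stop("patch larger than image")
  if (prod(patch) <= M) {
    stop(sprintf("patch voxel count (%d) must exceed volume count (%d)",
                 prod(patch), M))
  }
  acc <- array(0, dm)
  cnt <- array(0, dm[1:3])
  sig_acc <- array(0, dm[1:3])
  ncomp_acc <- array(0, dm[1:3])
  starts <- function(n, p, s) {
    last <- max(n - p + 1, 1)
    unique(c(seq(1, last, by = s), last))   # always cover the far edge
  }
  for (ix in starts(dm[1], patch[1], stride[1])) {
    for (iy in starts(dm[2], patch[2], stride[2])) {
      for (iz in starts(dm[3], patch[3], stride[3])) {
        xs <- ix:(ix + patch[1] - 1)
        ys <- iy:(iy + patch[2] - 1)
        zs <- iz:(iz + patch[3] - 1)
        X <- matrix(stack[xs, ys, zs, , drop = FALSE], ncol = M)
        res <- mp_denoise_matrix(X)
        acc[xs, ys, zs, ] <- acc[xs, ys, zs, ] +
          array(res$X, c(patch, M))
        cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
        sig_acc[xs, ys, zs] <- sig_acc[xs, ys, zs] + res$sigma
        ncomp_acc[xs, ys, zs] <- ncomp_acc[xs, ys, zs] + res$p
      }
    }
  }
  out <- acc / as.vector(cnt)  # volume dim recycles over voxel counts
  list(stack = out, sigma = sig_acc / cnt, n_components = ncomp_acc / cnt)
}

# Marchenko-Pastur truncation of one patch matrix (N voxels x M volumes).
# Signal rank p is the smallest p whose trailing eigenvalues fit inside an
# MP bulk: mean of the trailing eigenvalues >= their spread / (4 sqrt(gamma)).
mp_denoise_matrix <- function(X) {
  N <- nrow(X); M <- ncol(X)
  sv <- svd(X)
  lam <- sv$d^2 / N                    # descending eigenvalues of X'X / N
  p_sel <- M - 1
  sigma2 <- 0
  for (p in 0:(M - 1)) {
    tail_lam <- lam[(p + 1):M]
    sig1 <- mean(tail_lam)
    gam <- (M - p) / N
    sig2 <- (lam[p + 1] - lam[M]) / (4 * sqrt(gam))
    if (sig2 <= sig1) { p_sel <- p; sigma2 <- sig1; break }
  }
  if (p_sel == 0) {
    Xd <- matrix(0, N, M)
  } else {
    keep <- seq_len(p_sel)
    Xd <- sv$u[, keep, drop = FALSE] %*%
      (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  }
  list(X = Xd, sigma = sqrt(max(sigma2, 0)), p = p_sel)
}

#' Remove IVIM contamination by re-baselining b = 0
#'
#' Perfusion (IVIM) inflates the measured b = 0 signal. Following the
#' standard remedy, a straight line is fitted to `log(S)` over the diffusion
#' window (b in `(window[1], window[2]]` by default, i.e. 250-1000 s/mm2 for
#' the PGSE/OGSE-25Hz grids and 250-500 for OGSE-50Hz) and the b = 0 signal
#' is replaced by `exp(intercept)`; all signals are then renormalized by the
#' revised baseline. Idempotent on its own output.
#'
#' @param b b-values, s/mm2.
#' @param S signals at those b (same length), or a matrix with one row per
#'   voxel.
#' @param window IVIM exclusion window `(lower, upper)`, s/mm2.
#' @param include_upper is the upper bound part of the fit window?
#' @return revised signals, same shape as `S`, normalized so the revised
#'   baseline is 1.
#' @examples
#' b <- c(0, 250, 500, 750, 1000)
#' S <- 1.1 * c(1, rep(NA, 4)); S[-1] <- exp(-0.001 * b[-1])
#' remove_ivim(b, S)
#' @export
remove_ivim <- function(b, S, window = c(200, 1000), include_upper = TRUE) {
  vec <- is.null(dim(S))
  Sm <- if (vec) matrix(S, nrow = 1) else as.matrix(S)
  stopifnot(ncol(Sm) == length(b))
  in_win <- b > window[1] & (if (include_upper) b <= window[2] else b < window[2])
  if (sum(in_win) < 2) stop("need >= 2 b-values inside the IVIM fit window")
  if (any(Sm[, in_win] <= 0)) {
    bad <- which(rowSums(Sm[, in_win, drop = FALSE] <= 0) > 0)
    stop("non-positive signals in IVIM window for voxel(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bw <- b[in_win]
  L <- log(Sm[, in_win, drop = FALSE])
  bc <- bw - mean(bw)
  slope <- (L %*% bc) / sum(bc^2)
  intercept <- rowMeans(L) - slope * mean(bw)
  s0_rev <- exp(intercept)
  out <- Sm / as.vector(s0_rev)
  out[, b == 0] <- 1
  if (vec) drop(out) else out
}

#' Fit an apparent diffusion coefficient
#'
#' Least-squares slope of `log(S)` against b (internal units), negated:
#' the monoexponential `S = exp(-b ADC)` rate. Negative fits are returned
#' as-is (flag downstream, never clip).
#'
#' @param b b-values, s/mm2 (>= 2 distinct values).
#' @param S signals, vector or voxel-by-b matrix; must be positive.
#' @return ADC in um2/ms (vector if `S` is a matrix).
#' @examples
#' fit_adc(c(0, 500, 1000), exp(-c(0, 0.5, 1))) # 1.0
#' @export
fit_adc <- function(b, S) {
  vec <- is.null(dim(S))
  Sm <- if (vec) matrix(S, nrow = 1) else as.matrix(S)
  stopifnot(ncol(Sm) == length(b), length(b) >= 2)
  bi <- b_to_internal(b)
  if (stats::sd(bi) == 0) stop("degenerate b spread: all b-values identical")
  if (any(Sm <= 0)) stop("signals must be positive for the log-linear ADC fit")
  bc <- bi - mean(bi)
  slope <- (log(Sm) %*% bc) / sum(bc^2)
  adc <- -drop(slope)
  if (vec) adc[1] else adc
}

#' Measured signal-to-noise ratio of an ROI
#'
#' The acquisition QC rule: mean intensity inside the ROI divided by mean
#' background intensity, with subjects failing `SNR >= 15` excluded. Note
#' that on magnitude images the background mean is the Rayleigh noise floor
#' `sigma sqrt(pi/2)`, so this ratio is about `0.8 x` the amplitude SNR.
#'
#' @param image 2-D/3-D numeric array (one volume).
#' @param roi_mask,background_mask logical/0-1 arrays of the same shape;
#'   non-empty and disjoint.
#' @param threshold pass threshold.
#' @return list with `snr` and `pass`.
#' @export
compute_snr <- function(image, roi_mask, background_mask, threshold = 15) {
  roi_mask <- as.logical(roi_mask); background_mask <- as.logical(background_mask)
  if (!any(roi_mask) || !any(background_mask)) stop("empty mask")
  if (any(roi_mask & background_mask)) stop("ROI and background masks overlap")
  bg <- mean(image[background_mask])
  if (bg <= 0) stop("degenerate background: mean intensity is not positive")
  snr <- mean(image[roi_mask]) / bg
  list(snr = snr, pass = snr >= threshold)
}

#' Preprocess a 4-D stack for fitting
#'
#' Applies the fixed chain MP-PCA denoising (optional) -> per-voxel,
#' per-sequence IVIM re-baselining and normalization. Returns normalized
#' signals ready for `fit_maps()` plus QC maps and a provenance log.
#'
#' @param stack 4-D array ordered as `scheme_table(scheme)`.
#' @param scheme the `mrc_scheme` describing the volume axis.
#' @param mask optional 3-D mask restricting the IVIM step (default: voxels
#'   positive at every b = 0 volume).
#' @param denoise run MP-PCA first?
#' @param ivim run the IVIM re-baseline? When `FALSE`, signals are simply
#'   normalized by the measured b = 0 of each sequence (appropriate for
#'   perfusion-free phantoms, where re-estimating the baseline from 2-4
#'   noisy points only adds extrapolation variance).
#' @param patch,stride MP-PCA patch geometry.
#' @return list with `stack` (normalized), `sigma` (or NULL), `log`
#'   (character provenance), `mask`.
#' @export
preprocess_stack <- function(stack, scheme, mask = NULL, denoise = TRUE,
                             ivim = TRUE,
                             patch = c(5, 5, 3), stride = c(1, 1, 1)) {
  st <- scheme_table(scheme)
  dm <- dim(stack)
  stopifnot(length(dm) == 4, dm[4] == nrow(st))
  logline <- character(0)
  sigma <- NULL
  if (denoise) {
    patch <- pmin(patch, dm[1:3])
    dn <- mppca_denoise(stack, patch = patch, stride = stride)
    stack <- dn$stack
    sigma <- dn$sigma
    logline <- c(logline, sprintf("mppca: patch %s stride %s",
                                  paste(patch, collapse = "x"),
                                  paste(stride, collapse = "x")))
  }
  b0_idx <- st$volume[st$b_s_mm2 == 0]
  if (is.null(mask)) {
    mask <- apply(array(stack[, , , b0_idx], c(dm[1:3], length(b0_idx))) > 0,
                  1:3, all)
  }
  vox <- which(mask)
  flat <- matrix(stack, ncol = dm[4])
  for (sq in unique(st$sequence)) {
    idx <- st$volume[st$sequence == sq]
    b <- st$b_s_mm2[st$sequence == sq]
    if (ivim) {
      flat[vox, idx] <- remove_ivim(b, flat[vox, idx, drop = FALSE])
    } else {
      flat[vox, idx] <- flat[vox, idx, drop = FALSE] /
        flat[vox, idx[b == 0]]
    }
  }
  logline <- c(logline,
               if (ivim) "ivim: log-linear re-baseline, window (200, 1000]"
               else "ivim: skipped (normalized by measured b=0)",
               "normalize: per-sequence baseline")
  list(stack = array(flat, dm), sigma = sigma, log = logline, mask = mask)
}
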