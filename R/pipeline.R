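# NIfTI I/O and the end-to-end pipeline spine:
# simulate|load -> SNR gate -> preprocess -> fit -> ROI summary -> statistics.

#' Save / load a 4-D stack as NIfTI with a volume-order sidecar
#'
#' The sidecar JSON records the (sequence, b) identity of every volume;
#' loading validates it against the image shape (and against a scheme when
#' given). Values round-trip at float32 precision; the affine is preserved.
#'
#' @param stack 4-D array.
#' @param path NIfTI path (`.nii` / `.nii.gz`); the sidecar is written next
#'   to it as `<path>.volumes.json`.
#' @param scheme optional `mrc_scheme` used to write/validate the sidecar.
#' @param pixdim voxel size, mm.
#' @return `save_stack()` returns `path`; `load_stack()` returns a list
#'   with `stack`, `volumes` (tibble), `image` (the RNifti object).
#' @export
save_stack <- function(stack, path, scheme = NULL, pixdim = c(1.6, 1.6, 4)) {
  stopifnot(length(dim(stack)) == 4)
  attr(stack, "pixdim") <- c(pixdim, 1)
  img <- RNifti::asNifti(stack, datatype = "float")
  RNifti::writeNifti(img, path)
  vols <- if (!is.null(scheme)) {
    st <- scheme_table(scheme)
    stopifnot(nrow(st) == dim(stack)[4])
    st[, c("volume", "sequence", "b_s_mm2")]
  } else {
    tibble::tibble(volume = seq_len(dim(stack)[4]),
                   sequence = NA_character_, b_s_mm2 = NA_real_)
  }
  jsonlite::write_json(vols, sidecar_path(path), digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".volumes.json")

#' @rdname save_stack
#' @export
load_stack <- function(path, scheme = NULL) {
  img <- RNifti::readNifti(path)
  stack <- array(as.numeric(img), dim(img))
  if (!file.exists(sidecar_path(path))) {
    stop("volume-order sidecar missing: ", sidecar_path(path))
  }
  vols <- tibble::as_tibble(jsonlite::read_json(sidecar_path(path),
                                                simplifyVector = TRUE))
  if (nrow(vols) != dim(stack)[4]) {
    stop(sprintf("sidecar lists %d volumes but image has %d",
                 nrow(vols), dim(stack)[4]))
  }
  if (!is.null(scheme)) {
    st <- scheme_table(scheme)
    if (!identical(paste(st$sequence, st$b_s_mm2),
                   paste(vols$sequence, vols$b_s_mm2))) {
      stop("sidecar volume order does not match the scheme")
    }
  }
  list(stack = stack, volumes = vols, image = img)
}

#' Save parameter maps as one NIfTI per metric
#'
#' @param maps an `mrc_maps` tibble.
#' @param dir output directory (created if needed).
#' @param pixdim voxel size, mm.
#' @return invisibly, the written file paths.
#' @export
save_maps <- function(maps, dir, pixdim = c(1.6, 1.6, 4)) {
  stopifnot(inherits(maps, "mrc_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- attr(maps, "dim3")
  metric_cols <- setdiff(names(maps), c("voxel", "x", "y", "z"))
  paths <- vapply(metric_cols, function(mc) {
    arr <- array(NA_real_, dm)
    arr[maps$voxel] <- as.numeric(maps[[mc]])
    attr(arr, "pixdim") <- pixdim
    img <- RNifti::asNifti(arr, datatype = "float")
    fp <- file.path(dir, paste0(mc, ".nii.gz"))
    RNifti::writeNifti(img, fp)
    fp
  }, character(1))
  invisible(paths)
}

#' Run the full synthetic-cohort pipeline
#'
#' Composes the whole analysis: generate (or accept) a two-group cohort,
#' gate each subject on measured SNR, preprocess (IVIM re-baseline,
#' optional MP-PCA), fit voxelwise parameter maps, summarize ROI means into
#' the cohort table, and compute the classification report. Deterministic
#' under fixed seeds; every stage logs its QC counts.
#'
#' @param specs two `mrc_group_spec`s (see [default_group_specs()]).
#' @param scheme an `mrc_scheme`.
#' @param sim_model forward model used to simulate the phantoms.
#' @param fit_opts an `mrc_fit_options` for the voxelwise fits.
#' @param master_seed integer seed for cohort generation.
#' @param cohort optionally, a pre-generated cohort from
#'   [generate_cohort()] (then `specs`/`master_seed` are ignored).
#' @param snr_threshold QC gate on measured SNR.
#' @param denoise run MP-PCA during preprocessing?
#' @param ivim run the IVIM re-baseline stage?
#' @param models named list of metric panels for [cohort_report()];
#'   defaults to single-metric models for each fitted metric.
#' @param out_dir optional directory: writes `cohort.csv`, `report.csv`,
#'   `qc_log.csv`.
#' @return list with `cohort` (fitted ROI-mean table), `truth`, `report`,
#'   `qc` (per-subject gate log), `excluded`.
#' @export
run_pipeline <- function(specs = default_group_specs(),
                         scheme = default_scheme(),
                         sim_model = "JOINT",
                         fit_opts = fit_options("JOINT"),
                         master_seed = 1,
                         cohort = NULL,
                         snr_threshold = 15,
                         denoise = TRUE,
                         ivim = TRUE,
                         models = NULL,
                         out_dir = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(specs, scheme, model = sim_model,
                              master_seed = master_seed)
  }
  st <- scheme_table(scheme)
  b0_first <- st$volume[st$b_s_mm2 == 0][1]
  qc <- list(); rows <- list()
  for (subj in cohort$subjects) {
    gate <- compute_snr(subj$stack[, , , b0_first], subj$roi_mask,
                        subj$background_mask, threshold = snr_threshold)
    qc[[subj$id]] <- tibble::tibble(subject = subj$id, group = subj$group,
                                    snr = gate$snr, pass = gate$pass,
                                    reason = if (gate$pass) "" else "low_snr")
    if (!gate$pass) next
    pre <- preprocess_stack(subj$stack, scheme, mask = subj$roi_mask,
                            denoise = denoise, ivim = ivim)
    maps <- fit_maps(pre$stack, subj$roi_mask, scheme, fit_opts)
    rows[[subj$id]] <- dplyr::bind_cols(
      tibble::tibble(subject = subj$id, group = subj$group),
      roi_summary(maps))
  }
  qc <- dplyr::bind_rows(qc)
  tab <- dplyr::bind_rows(rows)
  if (is.null(models)) {
    metric_cols <- setdiff(names(tab),
                           c("subject", "group", "convergence_fraction",
                             "objective", "k_in"[fit_opts$model == "IMPULSED"]))
    models <- stats::setNames(as.list(metric_cols), metric_cols)
  }
  report <- cohort_report(tab, models)
  out <- list(cohort = tab, truth = cohort$truth, report = report, qc = qc,
              excluded = qc$subject[!qc$pass])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(tibble::as_tibble(report), file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(out_dir, "qc_log.csv"), row.names = FALSE)
  }
  out
}
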