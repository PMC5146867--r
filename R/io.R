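#' Write a multi-echo image as 4D NIfTI with a JSON sidecar
#'
#' Echoes go along the 4th axis; echo times (ms) and TR land in a
#' sidecar JSON next to the image.
#'
#' @param img A [multi_echo_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, the image and sidecar paths.
#' @export
write_multi_echo_nifti <- function(img, path) {
  stopifnot(inherits(img, "multi_echo_image"))
  nif <- RNifti::asNifti(img$data,
                         pixdim = c(img$voxel_size, 1))
  RNifti::writeNifti(nif, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(echo_times_ms = img$echo_times,
                            tr_ms = img$tr,
                            voxel_size_mm = img$voxel_size),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(image = path, sidecar = sidecar))
}

#' Read a 4D multi-echo NIfTI with its JSON sidecar
#'
#' @param path NIfTI path; the sidecar is looked up by swapping the
#'   extension for `.json` unless given explicitly.
#' @param sidecar Optional sidecar path.
#' @return A [multi_echo_image()].
#' @export
read_multi_echo_nifti <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  arr <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  multi_echo_image(arr, echo_times = meta$echo_times_ms,
                   tr = meta$tr_ms, voxel_size = meta$voxel_size_mm)
}

#' Write an R2* (or delta) map as NIfTI
#'
#' @param map An `r2star_map`, `delta_r2star_map`, or bare 3D array.
#' @param path Output path.
#' @param what For fitted maps, which array to write ("r2star",
#'   "s0", "fit_ok", "residual"; delta maps use "delta"/"percent").
#' @return Invisibly, `path`.
#' @export
write_map_nifti <- function(map, path, what = NULL) {
  arr <- if (is.array(map)) {
    map
  } else if (inherits(map, "delta_r2star_map")) {
    map[[if (is.null(what)) "delta" else what]]
  } else {
    map[[if (is.null(what)) "r2star" else what]]
  }
  RNifti::writeNifti(RNifti::asNifti(arr * 1), path)
  invisible(path)
}

#' Write an ROI label map as NIfTI
#'
#' @param config A [phantom_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_roi_labels_nifti <- function(config, path) {
  lab <- roi_label_map(config)
  RNifti::writeNifti(RNifti::asNifti(lab * 1L), path)
  invisible(path)
}

#' Write a Ct table CSV
#'
#' @param ct_table data.frame (`sample,gene,replicate,ct`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' ROI-wise bound iron by time, copy numbers, and per-ROI baseline
#' means (the voxel maps stay in memory; JSON carries the scalars a
#' reader needs to audit the forward model).
#'
#' @param truth A `phantom_truth`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(true_bound_fe_mM = as.data.frame.table(truth$true_bound_fe,
                                                responseName = "fe_mM"),
         copy_numbers = truth$copy_numbers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' NIfTI maps (baseline/post R2*, delta and percent maps, ROI labels),
#' TSV tables (uptake curve, CNR, quantification, copies, behavior
#' bins), the Ct CSV, the truth JSON, and the run manifest JSON.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  cfg <- result$session$config
  write_multi_echo_nifti(result$session$baseline, p("baseline_multiecho.nii.gz"))
  write_map_nifti(result$baseline_fit, p("baseline_r2star.nii.gz"))
  for (tn in names(result$post_fits)) {
    write_map_nifti(result$post_fits[[tn]],
                    p(sprintf("post_%sh_r2star.nii.gz", tn)))
    write_map_nifti(result$delta_maps[[tn]],
                    p(sprintf("post_%sh_delta.nii.gz", tn)))
    write_map_nifti(result$delta_maps[[tn]],
                    p(sprintf("post_%sh_percent.nii.gz", tn)),
                    what = "percent")
  }
  write_roi_labels_nifti(cfg, p("roi_labels.nii.gz"))
  write_tsv_file(result$uptake_curve, p("uptake_curve.tsv"))
  write_tsv_file(result$cnr, p("cnr.tsv"))
  write_tsv_file(result$quant, p("qpcr_quant.tsv"))
  write_tsv_file(result$copies_measured, p("copies_measured.tsv"))
  write_tsv_file(result$behavior$summary$bins, p("behavior_bins.tsv"))
  write_ct_table(result$ct_table, p("ct_table.csv"))
  write_beambreak_csv(result$behavior$stream, p("beam_events.csv"))
  write_truth_json(result$session$truth, p("truth.json"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a phantom configuration from YAML or JSON
#'
#' The file holds named [phantom_config()] arguments; `roi_geometry`
#' may be omitted (the default geometry for `grid_shape` is used) or
#' given as a named list of linear voxel indices.
#'
#' @param path `.yaml`/`.yml` (needs the yaml package) or `.json` file.
#' @return A [phantom_config()].
#' @export
read_phantom_config <- function(path) {
  args <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (df_field in c("baseline_r2star", "gene_panel")) {
    if (!is.null(args[[df_field]])) {
      args[[df_field]] <- as.data.frame(args[[df_field]])
    }
  }
  do.call(phantom_config, args)
}
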