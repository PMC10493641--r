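#' Read and write volumetric images as NIfTI-1
#'
#' Thin wrappers around RNifti preserving data and affine;
#' `write_image` then `read_image` reproduce the data exactly and the
#' affine to within 1e-6.
#'
#' @param img an [image3d].
#' @param path file path (`.nii` or `.nii.gz`).
#' @export
write_image <- function(img, path) {
  data <- img$data
  storage.mode(data) <- "double"
  nif <- RNifti::asNifti(data)
  nif <- RNifti::`sform<-`(nif, structure(img$affine, code = 2L))
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  nif <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI at ", path,
                                           ": ", conditionMessage(e)))
  aff <- RNifti::xform(nif, useQuaternionFirst = FALSE)
  image3d(array(as.numeric(nif), dim = dim(nif)), unclass(aff))
}

#' Write a cohort table to CSV
#'
#' One row per patient; the column dictionary is documented in
#' [read_cohort()].
#'
#' @param cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expected columns: `id`; covariates `sex`, `disease_duration`,
#' `pre_moca`, `pre_hama`, `pre_hamd`, `ledd_reduction`,
#' `updrs3_percent_change`; questionnaire totals `pre_fogq`, `post_fogq`
#' (0-24); and per hemisphere (`_left`/`_right` suffix) `tip_x/y/z`,
#' `active_contact` (0-3), `amplitude` (V), `pulse_width` (us),
#' `frequency` (Hz). Percent change and group are recomputed on load.
#' Rows violating the inclusion rules (non-positive baseline score,
#' frequency below `min_frequency`) are reported by row number. Missing
#' covariate cells are allowed; such patients are flagged and excluded
#' from covariate-adjusted analyses only.
#'
#' @param path CSV file.
#' @param min_frequency inclusion threshold, Hz.
#' @return validated cohort data.frame with `percent_change`, `group` and
#'   `covariates_complete` columns.
#' @export
read_cohort <- function(path, min_frequency = 90) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "pre_fogq", "post_fogq",
                paste0(rep(c("tip_x_", "tip_y_", "tip_z_", "active_contact_",
                             "amplitude_", "pulse_width_", "frequency_"), 2),
                       rep(c("left", "right"), each = 7)))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$pre_fogq) | df$pre_fogq < 1)
  bad <- union(bad, which(df$frequency_left < min_frequency |
                          df$frequency_right < min_frequency))
  if (length(bad))
    stop("invalid cohort rows (baseline score < 1 or frequency < ",
         min_frequency, " Hz): ", paste(sort(bad), collapse = ", "))
  df$percent_change <- percent_fogq_change(df$pre_fogq, df$post_fogq)
  df$group <- assign_group(df$percent_change)
  cov_cols <- intersect(c("sex", "disease_duration", "pre_moca", "pre_hama",
                          "pre_hamd", "ledd_reduction",
                          "updrs3_percent_change"), names(df))
  df$covariates_complete <- if (length(cov_cols))
    complete.cases(df[, cov_cols, drop = FALSE]) else TRUE
  df
}

#' Analysis run configuration
#'
#' All tunable parameters of the pipeline with their default values:
#' activation threshold 0.2 V/mm, 20% coverage rule, alpha 0.05, 20% fibre
#' filter, top 30% display fraction.
#'
#' @param n_patients cohort size.
#' @param atlas_shape,atlas_voxel_mm atlas grid.
#' @param vta_resolution,vta_margin lead-local solve grid (mm).
#' @param vta_threshold activation threshold, V/mm.
#' @param boundary solver boundary condition.
#' @param coverage_fraction minimum VTA coverage fraction for mapping.
#' @param alpha voxel significance level.
#' @param fibre_min_fraction fibre connectivity filter.
#' @param top_fraction displayed fibre fraction.
#' @param n_streamlines total synthetic streamlines.
#' @param connectome_voxel_mm,connectome_subjects,connectome_t connectome
#'   scale.
#' @param placement_sd_mm lead placement jitter.
#' @param seed master seed; all stage seeds derive from it.
#' @export
run_config <- function(n_patients = 76L, atlas_shape = c(48L, 48L, 48L),
                       atlas_voxel_mm = 1, vta_resolution = 0.5,
                       vta_margin = 6, vta_threshold = 0.2,
                       boundary = "grounded", coverage_fraction = 0.20,
                       alpha = 0.05, fibre_min_fraction = 0.20,
                       top_fraction = 0.30, n_streamlines = 20000L,
                       connectome_voxel_mm = 2, connectome_subjects = 20L,
                       connectome_t = 200L, placement_sd_mm = 1.5,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              atlas_shape = as.integer(atlas_shape),
              atlas_voxel_mm = atlas_voxel_mm,
              vta_resolution = vta_resolution, vta_margin = vta_margin,
              vta_threshold = vta_threshold, boundary = boundary,
              coverage_fraction = coverage_fraction, alpha = alpha,
              fibre_min_fraction = fibre_min_fraction,
              top_fraction = top_fraction,
              n_streamlines = as.integer(n_streamlines),
              connectome_voxel_mm = connectome_voxel_mm,
              connectome_subjects = as.integer(connectome_subjects),
              connectome_t = as.integer(connectome_t),
              placement_sd_mm = placement_sd_mm, seed = as.integer(seed))
  stopifnot(cfg$vta_threshold > 0, cfg$alpha > 0, cfg$alpha <= 1,
            cfg$coverage_fraction >= 0, cfg$coverage_fraction <= 1,
            cfg$fibre_min_fraction >= 0, cfg$fibre_min_fraction <= 1,
            cfg$top_fraction >= 0, cfg$top_fraction <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (YAML)
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a JSON provenance record next to pipeline outputs
#'
#' Records the configuration, seed, package version and the MD5 hashes of
#' the listed artifact files, so that any output can be traced to a
#' config + seed and re-runs can be compared bit for bit.
#'
#' @param config a [run_config()].
#' @param files character vector of artifact paths.
#' @param path output JSON path.
#' @export
write_provenance <- function(config, files, path) {
  files <- files[file.exists(files)]
  rec <- list(package = "stimmap",
              version = as.character(packageVersion("stimmap")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = config$seed,
              config = unclass(config),
              artifacts = as.list(setNames(unname(tools::md5sum(files)),
                                           basename(files))))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
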