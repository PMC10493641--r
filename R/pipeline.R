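#' Simulate a complete synthetic study
#'
#' Generates, from one master seed, every input of the analysis: the toy
#' atlas, the planted ground truth, the cohort with leads and settings, all
#' bilateral VTAs, the synthetic streamline set and its VTA connectivity,
#' and the planted outcomes. The functional connectome is generated
#' separately by [simulate_connectome()] because of its size. Stage seeds
#' are derived deterministically from the master seed so the whole study is
#' reproducible bit for bit.
#'
#' @param config a [run_config()].
#' @param truth optional `ground_truth`; defaults to
#'   [default_ground_truth()] on the generated atlas.
#' @param verbose print stage progress.
#' @return list: `config`, `atlas`, `truth`, `cohort`, `vtas`,
#'   `streamlines`, `connectivity`, `outcomes` (= cohort with outcomes).
#' @export
simulate_study <- function(config = run_config(), truth = NULL,
                           verbose = FALSE) {
  seed <- config$seed
  say <- function(...) if (verbose) message(...)
  say("atlas")
  atlas <- make_toy_atlas(config$atlas_shape, config$atlas_voxel_mm)
  if (is.null(truth)) truth <- default_ground_truth(atlas)
  say("cohort")
  cohort <- sample_cohort(config$n_patients, atlas, seed = seed,
                          placement_sd_mm = config$placement_sd_mm)
  say("vtas")
  vtas <- cohort_vtas(cohort, atlas, resolution = config$vta_resolution,
                      margin = config$vta_margin,
                      threshold = config$vta_threshold,
                      boundary = config$boundary)
  say("streamlines")
  streamlines <- make_synthetic_streamlines(atlas, truth,
                                            n_total = config$n_streamlines,
                                            seed = seed + 1000L)
  say("connectivity")
  connectivity <- fibre_vta_connectivity(streamlines, vtas)
  say("outcomes")
  cohort <- generate_outcomes(cohort, vtas, truth,
                              streamline_connectivity = connectivity,
                              seed = seed + 2000L)
  list(config = config, atlas = atlas, truth = truth, cohort = cohort,
       vtas = vtas, streamlines = streamlines, connectivity = connectivity)
}

#' Simulate the normative functional connectome of a study
#'
#' @param study list from [simulate_study()].
#' @return an `fc_connectome` on a grid of `connectome_voxel_mm` spacing
#'   covering the atlas extent.
#' @export
simulate_connectome <- function(study) {
  cfg <- study$config
  extent <- cfg$atlas_shape * cfg$atlas_voxel_mm
  shape <- as.integer(round(extent / cfg$connectome_voxel_mm))
  centre <- voxel_to_world(study$atlas$labels,
                           matrix((cfg$atlas_shape - 1) / 2, 1))
  grid <- make_grid(shape, cfg$connectome_voxel_mm, centre = as.numeric(centre))
  make_synthetic_functional_connectome(grid, study$atlas,
                                       k_subjects = cfg$connectome_subjects,
                                       t_points = cfg$connectome_t,
                                       seed = cfg$seed + 3000L)
}

#' Patient Fisher-z fingerprints for a whole study
#'
#' @param study list from [simulate_study()].
#' @param connectome an `fc_connectome`.
#' @return patients x voxels matrix of Fisher-z values.
#' @export
study_zmaps <- function(study, connectome) {
  t(vapply(study$vtas, function(vp)
    as.vector(patient_connectivity_map(vp, connectome)$data),
    numeric(prod(img_dim(connectome$grid)))))
}

#' Run the full stimulation-site and network analysis on a study
#'
#' Executes the three levels of the stimulation-site analysis
#' (coordinates, VTA-subregion overlaps, probabilistic stimulation map),
#' the fibre-filtering model, the functional R-map model, and leave-one-out
#' cross-validation with covariate adjustment for all three predictive
#' models.
#'
#' @param study list from [simulate_study()].
#' @param connectome optional `fc_connectome`; if NULL the functional
#'   analysis is skipped.
#' @param verbose print stage progress.
#' @return list of analysis products; see the README walk-through.
#' @export
analyse_study <- function(study, connectome = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  cfg <- study$config
  cohort <- study$cohort
  outcomes <- cohort$percent_change
  covars <- cohort_covariates(cohort)

  say("coordinate level")
  contacts <- cohort_contacts(cohort)
  coord_cor <- coordinate_correlation(contacts, outcomes)
  subgroup <- tryCatch(subgroup_coordinate_compare(contacts, cohort$group),
                       error = function(e) NULL)

  say("vta level")
  regions <- stn_region_names(study$atlas)
  overlaps <- t(vapply(study$vtas, function(vp) {
    o <- overlap_volumes(vp$left, study$atlas, regions)$overlap_mm3 +
      overlap_volumes(vp$right, study$atlas, regions)$overlap_mm3
    o
  }, numeric(length(regions))))
  colnames(overlaps) <- regions
  overlap_cor <- overlap_correlation(overlaps, outcomes)

  say("mapping level")
  coverage <- coverage_matrix(study$vtas, study$atlas$labels)
  psm <- build_psm(coverage, outcomes,
                   coverage_fraction = cfg$coverage_fraction,
                   alpha = cfg$alpha)
  psm_cv <- psm_loocv(coverage, outcomes,
                      coverage_fraction = cfg$coverage_fraction,
                      alpha = cfg$alpha, covariates = covars)
  spots <- list(
    sweet = list(left = centroid_and_peak(psm, "positive", "left"),
                 right = centroid_and_peak(psm, "positive", "right")),
    sour = list(left = centroid_and_peak(psm, "negative", "left"),
                right = centroid_and_peak(psm, "negative", "right")))

  say("fibre filtering")
  fibre_scores <- fibre_t_scores(study$connectivity, outcomes,
                                 min_fraction = cfg$fibre_min_fraction)
  fibre_top <- top_fraction(fibre_scores, cfg$top_fraction)
  fibre_cv <- fibre_loocv(study$connectivity, outcomes,
                          min_fraction = cfg$fibre_min_fraction,
                          covariates = covars)

  rmap <- rmap_cv <- zmaps <- NULL
  if (!is.null(connectome)) {
    say("functional r-map")
    zmaps <- study_zmaps(study, connectome)
    rmap <- build_rmap(zmaps, outcomes, connectome$grid)
    rmap_cv <- rmap_loocv(zmaps, outcomes, connectome$grid,
                          covariates = covars)
  }
  list(coordinate_correlation = coord_cor, subgroup_comparison = subgroup,
       overlaps = overlaps, overlap_correlation = overlap_cor,
       coverage = coverage, psm = psm, psm_cv = psm_cv, spots = spots,
       fibre_scores = fibre_scores, fibre_top = fibre_top,
       fibre_cv = fibre_cv, zmaps = zmaps, rmap = rmap, rmap_cv = rmap_cv)
}

#' Write the principal artifacts of a study and its analysis to disk
#'
#' Writes the cohort CSV, atlas and map volumes (NIfTI), streamlines (TRK),
#' ground truth and config sidecars, CV tables, and a JSON provenance
#' record with the MD5 hash of every artifact.
#'
#' @param study list from [simulate_study()].
#' @param results list from [analyse_study()] (optional).
#' @param dir output directory (created if needed).
#' @return invisibly, the provenance file path.
#' @export
write_study <- function(study, results = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(dir, f)
  write_cohort(study$cohort, p("cohort.csv")); paths <- c(paths, p("cohort.csv"))
  write_image(study$atlas$labels, p("atlas_labels.nii.gz"))
  paths <- c(paths, p("atlas_labels.nii.gz"))
  write_ground_truth(study$truth, p("ground_truth.yaml"))
  paths <- c(paths, p("ground_truth.yaml"))
  write_config(study$config, p("config.yaml")); paths <- c(paths, p("config.yaml"))
  write_streamlines(study$streamlines, p("streamlines.trk"),
                    reference = study$atlas$labels)
  paths <- c(paths, p("streamlines.trk"))
  if (!is.null(results)) {
    me <- results$psm$mean_effect
    me$data[is.na(me$data)] <- 0
    write_image(me, p("psm_mean_effect.nii.gz"))
    write_image(img_like(results$psm$significant_mask,
                         results$psm$significant_mask$data * 1),
                p("psm_significant_mask.nii.gz"))
    pim <- results$psm$p_image
    pim$data[is.na(pim$data)] <- 1
    write_image(pim, p("psm_p.nii.gz"))
    cv <- data.frame(id = study$cohort$id,
                     observed = results$psm_cv$observed,
                     psm_score = results$psm_cv$predicted,
                     fibre_score = results$fibre_cv$predicted)
    if (!is.null(results$rmap_cv)) cv$rmap_similarity <- results$rmap_cv$predicted
    write.csv(cv, p("loocv_predictions.csv"), row.names = FALSE)
    write.csv(results$fibre_scores, p("fibre_t_scores.csv"), row.names = FALSE)
    summ <- list(
      psm = list(r = results$psm_cv$spearman_r, p = results$psm_cv$p_value,
                 r_adj = results$psm_cv$adjusted_spearman_r,
                 p_adj = results$psm_cv$adjusted_p),
      fibre = list(r = results$fibre_cv$spearman_r, p = results$fibre_cv$p_value,
                   r_adj = results$fibre_cv$adjusted_spearman_r,
                   p_adj = results$fibre_cv$adjusted_p))
    if (!is.null(results$rmap_cv))
      summ$rmap <- list(r = results$rmap_cv$spearman_r,
                        p = results$rmap_cv$p_value,
                        r_adj = results$rmap_cv$adjusted_spearman_r,
                        p_adj = results$rmap_cv$adjusted_p)
    jsonlite::write_json(summ, p("cv_summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    paths <- c(paths, p("psm_mean_effect.nii.gz"),
               p("psm_significant_mask.nii.gz"), p("psm_p.nii.gz"),
               p("loocv_predictions.csv"), p("fibre_t_scores.csv"),
               p("cv_summary.json"))
  }
  prov <- p("provenance.json")
  write_provenance(study$config, paths, prov)
  invisible(prov)
}
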