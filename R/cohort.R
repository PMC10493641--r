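#' Ground truth for the synthetic cohort
#'
#' The planted effects that downstream analyses must recover: a beneficial
#' ("sweet") sphere in the dorsolateral STN and a detrimental ("sour")
#' sphere in the ventral STN on each side, per-mm^3 outcome gains for VTA
#' overlap with each sphere, outcome offsets scaling with the fraction of
#' each planted fibre bundle a patient stimulates, and the outcome noise.
#' Sphere centres default to points 3.0 mm along the STN long axis either
#' side of the ellipsoid centre, mirrored across hemispheres.
#'
#' Default gains and noise were calibrated once so that the realised cohort
#' reproduces the clinical outcome scale (mean percent change around
#' +35-40, SD around 40, with alleviation/minor/deterioration structure)
#' while the planted spatial effect remains recoverable.
#'
#' @param atlas a `dbs_atlas`.
#' @param sweet_radius,sour_radius sphere radii, mm.
#' @param sweet_gain,sour_gain percent change per mm^3 of VTA overlap.
#' @param positive_bundle_effect,negative_bundle_effect percent-change
#'   offsets at full bundle stimulation.
#' @param noise_sd outcome noise SD in percent-change units.
#' @param axis_offset distance of sphere centres from the STN centre along
#'   the long axis, mm.
#' @return a `ground_truth` list; sphere centres are 2 x 3 matrices with
#'   rows `left`, `right`.
#' @export
default_ground_truth <- function(atlas, sweet_radius = 2.5, sour_radius = 2.5,
                                 sweet_gain = 1.2, sour_gain = -0.8,
                                 positive_bundle_effect = 15,
                                 negative_bundle_effect = -15,
                                 noise_sd = 40, axis_offset = 3.0) {
  stopifnot(sweet_radius > 0, sour_radius > 0, noise_sd >= 0)
  sweet <- sour <- matrix(NA_real_, 2, 3,
                          dimnames = list(c("left", "right"), NULL))
  for (s in c("left", "right")) {
    g <- atlas$geometry[[s]]
    sweet[s, ] <- g$centre - axis_offset * g$axis  # dorsolateral
    sour[s, ]  <- g$centre + axis_offset * g$axis  # ventromedial
  }
  structure(list(sweet_centre = sweet, sweet_radius = sweet_radius,
                 sweet_gain = sweet_gain,
                 sour_centre = sour, sour_radius = sour_radius,
                 sour_gain = sour_gain,
                 positive_bundle_effect = positive_bundle_effect,
                 negative_bundle_effect = negative_bundle_effect,
                 noise_sd = noise_sd), class = "ground_truth")
}

#' Write / read ground truth as a YAML sidecar
#' @param truth a `ground_truth`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  y <- truth
  y$sweet_centre <- apply(truth$sweet_centre, 1, as.numeric, simplify = FALSE)
  y$sour_centre <- apply(truth$sour_centre, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(unclass(y), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  y <- yaml::read_yaml(path)
  y$sweet_centre <- do.call(rbind, y$sweet_centre[c("left", "right")])
  y$sour_centre <- do.call(rbind, y$sour_centre[c("left", "right")])
  class(y) <- "ground_truth"
  y
}

# Truncated-normal draw by rejection (vectorised over n).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Sample a synthetic bilateral DBS cohort
#'
#' One row per patient: demographics and covariates, per-hemisphere lead
#' tip positions (jittered around a target just below each STN centre so
#' the four contacts straddle the nucleus dorsoventrally), a uniformly
#' drawn active contact, and stimulation settings drawn from truncated
#' normals matching the cohort summary statistics (amplitude about
#' 2.4 +/- 0.55 V per side, pulse width about 68-70 +/- 11 us, frequency
#' about 131 +/- 21 Hz resampled to the >= 90 Hz high-frequency inclusion
#' criterion). Outcome columns are filled later by [generate_outcomes()].
#'
#' @param n cohort size (>= 10; the reference cohort is 76).
#' @param atlas a `dbs_atlas`.
#' @param seed RNG seed.
#' @param placement_sd_mm SD of the lead-tip jitter around the target, mm.
#' @return data.frame, one row per patient.
#' @export
sample_cohort <- function(n = 76L, atlas, seed = 1L, placement_sd_mm = 1.5) {
  if (n < 10L) stop("cohort size must be at least 10")
  set.seed(seed)
  df <- data.frame(id = sprintf("P%03d", seq_len(n)))
  df$sex <- rbinom(n, 1L, 37 / 76)
  df$disease_duration <- rtnorm(n, 10, 4, lower = 1)
  df$pre_moca <- round(rtnorm(n, 24, 3, lower = 10, upper = 30))
  df$pre_hama <- round(rtnorm(n, 12, 6, lower = 0))
  df$pre_hamd <- round(rtnorm(n, 12, 6, lower = 0))
  df$ledd_reduction <- rtnorm(n, 33, 15, lower = -20, upper = 90)
  df$updrs3_percent_change <- rtnorm(n, 55, 18, lower = 0, upper = 95)
  side_par <- list(left = list(amp = c(2.41, 0.52), pw = c(70.00, 11.43),
                               fr = c(130.88, 19.86)),
                   right = list(amp = c(2.36, 0.56), pw = c(67.63, 11.30),
                                fr = c(131.34, 21.24)))
  for (s in c("left", "right")) {
    p <- side_par[[s]]
    target <- atlas$geometry[[s]]$centre + c(0, 0, -3.75)
    tips <- matrix(target, n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, 0, placement_sd_mm), n, 3)
    df[[paste0("tip_x_", s)]] <- tips[, 1]
    df[[paste0("tip_y_", s)]] <- tips[, 2]
    df[[paste0("tip_z_", s)]] <- tips[, 3]
    # programming favours the dorsal contacts, as clinical titration does
    df[[paste0("active_contact_", s)]] <- sample(0:3, n, replace = TRUE,
                                                 prob = c(0.10, 0.20, 0.35, 0.35))
    df[[paste0("amplitude_", s)]] <- rtnorm(n, p$amp[1], p$amp[2], lower = 0.5)
    df[[paste0("pulse_width_", s)]] <- rtnorm(n, p$pw[1], p$pw[2], lower = 30)
    df[[paste0("frequency_", s)]] <- rtnorm(n, p$fr[1], p$fr[2], lower = 90)
  }
  df$pre_fogq <- NA_integer_
  df$post_fogq <- NA_integer_
  df
}

#' Reconstruct the lead model of one cohort row
#'
#' @param row one-row data.frame from [sample_cohort()] / [read_cohort()].
#' @param side `"left"` or `"right"`.
#' @param lead_spec geometry, see [default_lead_spec()].
#' @export
cohort_lead <- function(row, side, lead_spec = default_lead_spec()) {
  build_lead(c(row[[paste0("tip_x_", side)]], row[[paste0("tip_y_", side)]],
               row[[paste0("tip_z_", side)]]),
             direction = c(0, 0, 1), lead_spec = lead_spec,
             hemisphere = side,
             active_contact_index = row[[paste0("active_contact_", side)]])
}

#' Stimulation setting of one cohort row
#' @param row one-row data.frame.
#' @param side `"left"` or `"right"`.
#' @export
cohort_setting <- function(row, side) {
  stimulation_setting(amplitude = row[[paste0("amplitude_", side)]],
                      pulse_width = row[[paste0("pulse_width_", side)]],
                      frequency = row[[paste0("frequency_", side)]])
}

#' Compute all cohort VTAs
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param atlas a `dbs_atlas`.
#' @param ... passed to [compute_vta()].
#' @return list (one per patient) of `left`/`right` `vta_result`s.
#' @export
cohort_vtas <- function(cohort, atlas, ...) {
  lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    out <- list()
    for (s in c("left", "right")) {
      out[[s]] <- compute_vta(cohort_lead(row, s), cohort_setting(row, s),
                              atlas = atlas, patient_id = row$id, ...)
    }
    out
  })
}

# mm^3 of VTA mask inside a sphere.
vta_sphere_overlap <- function(vta, centre, radius) {
  xyz <- voxel_centres(vta$mask)[as.vector(vta$mask$data), , drop = FALSE]
  if (!nrow(xyz)) return(0)
  sum(rowSums(sweep(xyz, 2, centre)^2) <= radius^2) * voxel_volume(vta$mask)
}

#' Plant outcomes into a sampled cohort
#'
#' The latent percent change of patient i is
#' `sum over sides [ sweet_gain * overlap(VTA, sweet sphere) +
#' sour_gain * overlap(VTA, sour sphere) ] +
#' positive_bundle_effect * (fraction of the positive bundle stimulated) +
#' negative_bundle_effect * (fraction of the negative bundle stimulated) +
#' Normal(0, noise_sd)`, clipped to [-100, 100]. The pre-operative score is
#' drawn uniformly from 10-24 and the post-operative score is
#' `round(pre * (1 - change/100))` clipped to the 0-24 questionnaire range,
#' so the realised percent change inherits the questionnaire's
#' discreteness.
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param vtas per-patient VTA list from [cohort_vtas()].
#' @param truth a `ground_truth`.
#' @param streamline_connectivity optional fibres x patients logical matrix
#'   carrying a `labels` attribute (from [fibre_vta_connectivity()] on a
#'   labelled synthetic set); enables the bundle effects.
#' @param seed RNG seed for noise and baseline scores.
#' @return the cohort with `pre_fogq`, `post_fogq`, `percent_change`,
#'   `group` and diagnostic columns (`latent_change`, sphere overlaps)
#'   filled in.
#' @export
generate_outcomes <- function(cohort, vtas, truth,
                              streamline_connectivity = NULL, seed = 1L) {
  n <- nrow(cohort)
  if (length(vtas) != n) stop("one VTA pair per patient required")
  set.seed(seed)
  sweet_ov <- sour_ov <- numeric(n)
  for (i in seq_len(n)) {
    for (s in c("left", "right")) {
      vt <- vtas[[i]][[s]]
      if (is.null(vt)) stop("missing VTA for patient ", i, " (", s, ")")
      sweet_ov[i] <- sweet_ov[i] +
        vta_sphere_overlap(vt, truth$sweet_centre[s, ], truth$sweet_radius)
      sour_ov[i] <- sour_ov[i] +
        vta_sphere_overlap(vt, truth$sour_centre[s, ], truth$sour_radius)
    }
  }
  pos_frac <- neg_frac <- numeric(n)
  if (!is.null(streamline_connectivity)) {
    lab <- attr(streamline_connectivity, "labels")
    if (is.null(lab)) stop("streamline_connectivity must carry bundle labels")
    pos <- lab == "sma_bundle"; neg <- lab == "pfc_bundle"
    if (any(pos))
      pos_frac <- colMeans(streamline_connectivity[pos, , drop = FALSE])
    if (any(neg))
      neg_frac <- colMeans(streamline_connectivity[neg, , drop = FALSE])
  }
  latent <- truth$sweet_gain * sweet_ov + truth$sour_gain * sour_ov +
    truth$positive_bundle_effect * pos_frac +
    truth$negative_bundle_effect * neg_frac +
    rnorm(n, 0, truth$noise_sd)
  latent <- pmin(pmax(latent, -100), 100)
  pre <- if (any(is.na(cohort$pre_fogq))) sample(10:24, n, replace = TRUE)
         else cohort$pre_fogq
  post <- pmin(pmax(round(pre * (1 - latent / 100)), 0L), 24L)
  cohort$pre_fogq <- as.integer(pre)
  cohort$post_fogq <- as.integer(post)
  cohort$percent_change <- percent_fogq_change(cohort$pre_fogq, cohort$post_fogq)
  cohort$group <- assign_group(cohort$percent_change)
  cohort$latent_change <- latent
  cohort$sweet_overlap_mm3 <- sweet_ov
  cohort$sour_overlap_mm3 <- sour_ov
  cohort$positive_bundle_fraction <- pos_frac
  cohort$negative_bundle_fraction <- neg_frac
  cohort
}

#' Active-contact coordinates of a cohort
#'
#' @param cohort data.frame.
#' @param lead_spec geometry.
#' @return list with `left` and `right` n x 3 matrices (mm).
#' @export
cohort_contacts <- function(cohort, lead_spec = default_lead_spec()) {
  out <- list()
  for (s in c("left", "right")) {
    m <- t(vapply(seq_len(nrow(cohort)), function(i)
      active_contact_centre(cohort_lead(cohort[i, ], s, lead_spec)),
      numeric(3)))
    out[[s]] <- m
  }
  out
}

#' Covariate table used for adjusted validation
#'
#' @param cohort data.frame with outcome columns filled.
#' @return data.frame of the covariate columns.
#' @export
cohort_covariates <- function(cohort) {
  cohort[, c("sex", "disease_duration", "pre_moca", "pre_hama", "pre_hamd",
             "ledd_reduction", "updrs3_percent_change")]
}
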