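#' Percent change of the Freezing of Gait Questionnaire score
#'
#' `%change = (pre - post) / pre * 100`; positive values mean alleviation.
#'
#' @param pre,post questionnaire totals; `pre` must be positive (cohort
#'   inclusion guarantees a nonzero baseline).
#' @export
percent_fogq_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop("pre-operative score must be positive")
  (pre - post) / pre * 100
}

#' Assign outcome group from percent change
#'
#' Changes above 30% are `alleviation`, below 0% `deterioration`, and
#' everything in between (boundaries included) `minor`.
#'
#' @param percent_change numeric vector.
#' @param cutoffs lower/upper cutoffs, default `c(0, 30)`.
#' @return factor with levels alleviation/minor/deterioration.
#' @export
assign_group <- function(percent_change, cutoffs = c(0, 30)) {
  if (any(!is.finite(percent_change))) stop("percent change must be finite")
  out <- ifelse(percent_change > cutoffs[2], "alleviation",
                ifelse(percent_change < cutoffs[1], "deterioration", "minor"))
  factor(out, levels = c("alleviation", "minor", "deterioration"))
}

#' Correlate active-contact coordinates with outcome
#'
#' Spearman correlation of each coordinate axis of the active contact with
#' the percent outcome change, per hemisphere, Bonferroni-adjusted over the
#' six tests (3 axes x 2 hemispheres). Axes with zero variance are reported
#' as missing with a warning.
#'
#' @param contacts named list with elements `left` and `right`, each an
#'   n x 3 matrix of active-contact mm coordinates.
#' @param outcomes percent-change vector (length n).
#' @return data.frame: hemisphere, axis, rho, p, p_adj, n.
#' @export
coordinate_correlation <- function(contacts, outcomes) {
  stopifnot(all(c("left", "right") %in% names(contacts)))
  res <- list()
  for (h in c("left", "right")) {
    m <- as.matrix(contacts[[h]])
    if (nrow(m) != length(outcomes)) stop("coordinate/outcome length mismatch")
    if (nrow(m) < 5L) stop("at least 5 patients per hemisphere required")
    for (ax in 1:3) {
      v <- m[, ax]
      if (sd(v) == 0) {
        warning("constant ", c("x", "y", "z")[ax], " coordinate in ", h,
                " hemisphere; correlation undefined")
        sp <- list(rho = NA_real_, p = NA_real_, n = nrow(m))
      } else sp <- spearman(v, outcomes)
      res[[length(res) + 1L]] <- data.frame(
        hemisphere = h, axis = c("x", "y", "z")[ax],
        rho = sp$rho, p = sp$p, n = sp$n)
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni(out$p, m = 6L)
  out
}

#' Compare active-contact coordinates between outcome groups
#'
#' Two-sample comparison (pooled-variance t-test by default, Welch or
#' rank-sum switchable) of each coordinate axis between the alleviation and
#' deterioration groups, per hemisphere, Bonferroni-adjusted over the three
#' axes within each hemisphere.
#'
#' @param contacts as in [coordinate_correlation()].
#' @param groups factor from [assign_group()] (length n).
#' @param method `"t"` (pooled), `"welch"` or `"ranksum"`.
#' @param groups_compared the two levels contrasted, first minus second.
#' @return data.frame: hemisphere, axis, statistic, p, p_adj, group means.
#' @export
subgroup_coordinate_compare <- function(contacts, groups, method = c("t", "welch", "ranksum"),
                                        groups_compared = c("alleviation", "deterioration")) {
  method <- match.arg(method)
  a <- groups == groups_compared[1]
  b <- groups == groups_compared[2]
  if (sum(a) < 2L || sum(b) < 2L)
    stop("both compared groups need at least 2 patients")
  res <- list()
  for (h in c("left", "right")) {
    m <- as.matrix(contacts[[h]])
    for (ax in 1:3) {
      xa <- m[a, ax]; xb <- m[b, ax]
      if (method == "ranksum") {
        stat <- NA_real_; p <- rank_sum_p(xa, xb)
      } else if (method == "t") {
        member <- matrix(c(rep(TRUE, length(xa)), rep(FALSE, length(xb))),
                         1L)
        stat <- pooled_t_matrix(member, c(xa, xb))$t
        p <- 2 * pt(-abs(stat), df = length(xa) + length(xb) - 2)
      } else {
        tt <- t.test(xa, xb)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      res[[length(res) + 1L]] <- data.frame(
        hemisphere = h, axis = c("x", "y", "z")[ax], statistic = stat,
        p = p, mean_a = mean(xa), mean_b = mean(xb))
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  for (h in c("left", "right"))
    out$p_adj[out$hemisphere == h] <- bonferroni(out$p[out$hemisphere == h], m = 3L)
  out
}

#' Overlap volumes between a VTA and atlas regions
#'
#' Overlap is counted on the VTA's own (fine) grid: the number of active
#' VTA voxels whose centres carry the region label, times the voxel volume.
#'
#' @param vta a `vta_result`.
#' @param atlas a `dbs_atlas`.
#' @param regions region names; defaults to all STN regions.
#' @return data.frame: region, overlap_mm3.
#' @export
overlap_volumes <- function(vta, atlas, regions = stn_region_names(atlas)) {
  xyz <- voxel_centres(vta$mask)[as.vector(vta$mask$data), , drop = FALSE]
  lab <- sample_at(atlas$labels, xyz, outside = 0)
  vv <- voxel_volume(vta$mask)
  ov <- vapply(regions, function(rn) {
    row <- atlas$table[atlas$table$name == rn, ]
    codes <- if (row$code == 1L) c(11L, 12L, 13L)
             else if (row$code == 2L) c(21L, 22L, 23L)
             else row$code
    sum(lab %in% codes) * vv
  }, numeric(1))
  data.frame(region = regions, overlap_mm3 = unname(ov), row.names = NULL)
}

#' Correlate per-region VTA overlap volumes with outcome
#'
#' @param overlaps n_patients x n_regions numeric matrix (or data.frame)
#'   of overlap volumes in mm^3.
#' @param outcomes percent-change vector.
#' @return data.frame: region, rho, p, p_adj (Bonferroni over regions).
#' @export
overlap_correlation <- function(overlaps, outcomes) {
  overlaps <- as.matrix(overlaps)
  if (nrow(overlaps) < 5L) stop("at least 5 patients required")
  res <- lapply(colnames(overlaps), function(rn) {
    v <- overlaps[, rn]
    if (sd(v) == 0 || sd(outcomes) == 0) {
      warning("zero variance for region ", rn, "; correlation undefined")
      sp <- list(rho = NA_real_, p = NA_real_)
    } else sp <- spearman(v, outcomes)
    data.frame(region = rn, rho = sp$rho, p = sp$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni(out$p, m = ncol(overlaps))
  out
}

#' Patient-by-voxel coverage matrix on an analysis grid
#'
#' Resamples each patient's bilateral VTA union onto the shared analysis
#' grid. The result is the workhorse of the mapping-level analysis.
#'
#' @param vtas list (one element per patient) of lists with `left` and
#'   `right` `vta_result`s (either may be NULL).
#' @param grid [image3d] analysis grid.
#' @return logical matrix, patients x voxels, with the grid as attribute.
#' @export
coverage_matrix <- function(vtas, grid) {
  n <- length(vtas)
  nv <- prod(img_dim(grid))
  v <- matrix(FALSE, n, nv)
  for (i in seq_len(n)) {
    m <- array(FALSE, dim = img_dim(grid))
    for (side in c("left", "right")) {
      vt <- vtas[[i]][[side]]
      if (!is.null(vt)) m <- m | mask_on_grid(vt$mask, grid)
    }
    v[i, ] <- as.vector(m)
  }
  attr(v, "grid") <- grid
  v
}

#' Per-voxel patient coverage counts
#'
#' @param coverage patients x voxels logical matrix from
#'   [coverage_matrix()].
#' @return [image3d] of counts on the analysis grid.
#' @export
build_coverage <- function(coverage) {
  grid <- attr(coverage, "grid")
  img_like(grid, array(colSums(coverage), dim = img_dim(grid)))
}

#' Minimum patient count implied by a coverage fraction
#' @param n number of patients.
#' @param coverage_fraction minimum fraction of patients (default 0.20).
#' @export
coverage_min_count <- function(n, coverage_fraction = 0.20) {
  as.integer(ceiling(coverage_fraction * n))
}

#' Outcome-weighted mean-effect image
#'
#' For every voxel covered by at least `ceiling(coverage_fraction * n)`
#' patients' VTAs, the mean percent change of the covering patients;
#' elsewhere NA.
#'
#' @param coverage patients x voxels logical matrix.
#' @param outcomes percent-change vector.
#' @param coverage_fraction minimum coverage fraction.
#' @return [image3d]; attribute `eligible` holds the eligibility vector.
#' @export
psm_mean_effect <- function(coverage, outcomes, coverage_fraction = 0.20) {
  grid <- attr(coverage, "grid")
  cnt <- colSums(coverage)
  need <- coverage_min_count(length(outcomes), coverage_fraction)
  eligible <- cnt >= need
  if (!any(eligible)) warning("no voxel reaches the coverage threshold")
  me <- rep(NA_real_, length(cnt))
  me[eligible] <- as.numeric(crossprod(coverage[, eligible, drop = FALSE],
                                       outcomes)) / cnt[eligible]
  out <- img_like(grid, array(me, dim = img_dim(grid)))
  attr(out, "eligible") <- eligible
  out
}

#' Voxel-wise nonparametric test of covered vs non-covered outcomes
#'
#' At each eligible voxel, a two-tailed rank test comparing the outcomes of
#' patients whose VTA covers the voxel against those whose VTA does not.
#' The default contrast is the unpaired Mann-Whitney rank-sum test (exact
#' for combined n <= 20 and tie-free, normal approximation with tie and
#' continuity corrections otherwise); a one-sample signed-rank variant
#' testing the covering patients' outcomes against the grand median is
#' available as a configuration switch.
#'
#' @param coverage patients x voxels logical matrix.
#' @param outcomes percent-change vector.
#' @param eligible logical voxel eligibility (from [psm_mean_effect()]);
#'   default: all voxels covered by at least one patient.
#' @param method `"ranksum"` (default) or `"signedrank"`.
#' @return [image3d] of p-values (NA outside eligible voxels).
#' @export
psm_voxel_test <- function(coverage, outcomes, eligible = NULL,
                           method = c("ranksum", "signedrank")) {
  method <- match.arg(method)
  grid <- attr(coverage, "grid")
  n <- length(outcomes)
  if (is.null(eligible)) eligible <- colSums(coverage) > 0L
  p <- rep(NA_real_, ncol(coverage))
  sub <- coverage[, eligible, drop = FALSE]
  if (method == "ranksum") {
    if (n <= 20L && anyDuplicated(outcomes) == 0L) {
      p[eligible] <- apply(sub, 2, function(v)
        rank_sum_p(outcomes[v], outcomes[!v]))
    } else {
      p[eligible] <- ranksum_p_matrix(sub, outcomes)
    }
  } else {
    centre <- median(outcomes)
    p[eligible] <- apply(sub, 2, function(v) {
      x <- outcomes[v] - centre
      x <- x[x != 0]
      if (length(x) < 2L) return(1)
      suppressWarnings(wilcox.test(x)$p.value)
    })
  }
  img_like(grid, array(p, dim = img_dim(grid)))
}

#' Assemble the probabilistic stimulation map
#'
#' Masks the mean-effect image to voxels with p below `alpha` (uncorrected,
#' matching the mapping convention of retaining only voxel-wise significant
#' mean effects). Positive surviving voxels form the sweet spot, negative
#' the sour spot.
#'
#' @param mean_effect [image3d] from [psm_mean_effect()].
#' @param p_image [image3d] from [psm_voxel_test()].
#' @param alpha significance level (default 0.05).
#' @param coverage_image optional [image3d] of counts for the record.
#' @param n number of patients.
#' @param coverage_fraction recorded coverage rule.
#' @return a `psm_result`.
#' @export
psm_mask <- function(mean_effect, p_image, alpha = 0.05,
                     coverage_image = NULL, n = NA_integer_,
                     coverage_fraction = 0.20) {
  sig <- !is.na(p_image$data) & p_image$data < alpha &
    !is.na(mean_effect$data)
  masked <- mean_effect$data
  masked[!sig] <- NA_real_
  structure(list(
    mean_effect = img_like(mean_effect, masked),
    p_image = p_image,
    significant_mask = img_like(mean_effect, sig),
    coverage_image = coverage_image,
    alpha = alpha, coverage_fraction = coverage_fraction, n = n
  ), class = "psm_result")
}

#' @export
print.psm_result <- function(x, ...) {
  v <- x$mean_effect$data[x$significant_mask$data]
  cat("<psm_result> ", sum(x$significant_mask$data), " significant voxels (",
      sum(v > 0), " sweet, ", sum(v < 0), " sour) at alpha = ", x$alpha,
      "\n", sep = "")
  invisible(x)
}

#' One-call probabilistic stimulation map
#'
#' Runs coverage, mean effect, voxel test and masking in sequence.
#'
#' @param coverage patients x voxels logical matrix ([coverage_matrix()]).
#' @param outcomes percent-change vector.
#' @param coverage_fraction,alpha,method see the stage functions.
#' @return a `psm_result`.
#' @export
build_psm <- function(coverage, outcomes, coverage_fraction = 0.20,
                      alpha = 0.05, method = "ranksum") {
  me <- psm_mean_effect(coverage, outcomes, coverage_fraction)
  p <- psm_voxel_test(coverage, outcomes, eligible = attr(me, "eligible"),
                      method = method)
  psm_mask(me, p, alpha = alpha, coverage_image = build_coverage(coverage),
           n = length(outcomes), coverage_fraction = coverage_fraction)
}

#' Probabilistic mapping score of one patient
#'
#' Sum of the significant mean-effect values over the voxels shared by the
#' patient's (bilateral) VTA coverage and the significant mask.
#'
#' @param patient_coverage logical voxel vector for the patient (a row of
#'   [coverage_matrix()]).
#' @param psm a `psm_result`.
#' @export
psm_score_patient <- function(patient_coverage, psm) {
  sel <- patient_coverage & as.vector(psm$significant_mask$data)
  if (!any(sel)) return(0)
  sum(psm$mean_effect$data[sel])
}

#' Centroid and peak of a signed PSM cluster
#'
#' The centroid weights voxel world coordinates by the absolute
#' mean-effect value; the peak is the most extreme voxel, ties broken by
#' the first voxel in linear (column-major) order.
#'
#' @param psm a `psm_result`.
#' @param sign `"positive"` (sweet) or `"negative"` (sour).
#' @param side `"left"` (x < 0), `"right"` (x > 0) or `"both"`.
#' @return list with `centroid`, `peak` (mm), `n_voxels`, `volume_mm3`;
#'   all NA if the cluster is empty.
#' @export
centroid_and_peak <- function(psm, sign = c("positive", "negative"),
                              side = c("both", "left", "right")) {
  sign <- match.arg(sign); side <- match.arg(side)
  vals <- psm$mean_effect$data
  sel <- as.vector(psm$significant_mask$data) &
    (if (sign == "positive") !is.na(vals) & vals > 0 else !is.na(vals) & vals < 0)
  xyz <- voxel_centres(psm$mean_effect)
  if (side == "left") sel <- sel & xyz[, 1] < 0
  if (side == "right") sel <- sel & xyz[, 1] > 0
  if (!any(sel))
    return(list(centroid = rep(NA_real_, 3), peak = rep(NA_real_, 3),
                n_voxels = 0L, volume_mm3 = 0))
  w <- abs(vals[sel])
  centroid <- colSums(xyz[sel, , drop = FALSE] * w) / sum(w)
  v <- vals[sel]
  ext <- if (sign == "positive") which.max(v) else which.min(v)
  list(centroid = centroid, peak = xyz[sel, , drop = FALSE][ext, ],
       n_voxels = sum(sel), volume_mm3 = sum(sel) * voxel_volume(psm$mean_effect))
}

#' Leave-one-out cross-validation of the PSM model
#'
#' Each fold rebuilds the PSM from the training patients only and scores
#' the held-out patient by [psm_score_patient()].
#'
#' @param coverage patients x voxels logical matrix.
#' @param outcomes percent-change vector.
#' @param coverage_fraction,alpha,method PSM settings.
#' @param covariates optional covariate data.frame for adjusted validation.
#' @return a `cv_result`.
#' @export
psm_loocv <- function(coverage, outcomes, coverage_fraction = 0.20,
                      alpha = 0.05, method = "ranksum", covariates = NULL) {
  grid <- attr(coverage, "grid")
  loocv(outcomes,
        fit = function(train) {
          sub <- coverage[train, , drop = FALSE]
          attr(sub, "grid") <- grid
          build_psm(sub, outcomes[train],
                    coverage_fraction = coverage_fraction, alpha = alpha,
                    method = method)
        },
        predict = function(psm, i) psm_score_patient(coverage[i, ], psm),
        covariates = covariates, model_tag = "psm")
}
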