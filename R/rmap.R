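#' Synthetic normative functional connectome
#'
#' Per-subject voxel time series built from shared low-rank spatial
#' networks plus white noise: one network loads on the SMA-like parcels and
#' the dorsolateral (sensorimotor) STN, the other on the PFC-like parcels
#' and the ventral (limbic) STN. Each subject draws independent network
#' time courses, so within-network voxels correlate strongly and
#' between-network voxels do not.
#'
#' @param grid [image3d] template for the connectome (typically coarser
#'   than the atlas grid).
#' @param atlas a `dbs_atlas`; defines the network regions.
#' @param k_subjects number of normative subjects (default 20).
#' @param t_points time points per subject (default 200).
#' @param seed RNG seed.
#' @param noise_sd white-noise standard deviation.
#' @param standardize centre and scale each voxel series to mean 0, sd 1.
#' @return an `fc_connectome`: `grid`, `subjects` (list of voxels x t
#'   matrices) and the network loading vectors.
#' @export
make_synthetic_functional_connectome <- function(grid, atlas,
                                                 k_subjects = 20L,
                                                 t_points = 200L, seed = 1L,
                                                 noise_sd = 1,
                                                 standardize = FALSE) {
  set.seed(seed)
  lab <- sample_at(atlas$labels, voxel_centres(grid), outside = 0)
  lab[is.na(lab)] <- 0
  w1 <- as.numeric(lab %in% c(31L, 32L, 11L, 21L))   # SMA-like network
  w2 <- as.numeric(lab %in% c(41L, 42L, 13L, 23L))   # PFC-like network
  nv <- length(lab)
  subjects <- vector("list", k_subjects)
  for (s in seq_len(k_subjects)) {
    f1 <- rnorm(t_points); f2 <- rnorm(t_points)
    ts <- outer(w1, f1) + outer(w2, f2) +
      matrix(rnorm(nv * t_points, 0, noise_sd), nv, t_points)
    if (standardize) {
      mu <- rowMeans(ts)
      sdv <- sqrt(rowSums((ts - mu)^2) / (t_points - 1))
      ts <- (ts - mu) / ifelse(sdv > 0, sdv, 1)
    }
    subjects[[s]] <- ts
  }
  structure(list(grid = grid, subjects = subjects, w_sma = w1, w_pfc = w2),
            class = "fc_connectome")
}

#' @export
print.fc_connectome <- function(x, ...) {
  cat("<fc_connectome> ", length(x$subjects), " subjects, ",
      nrow(x$subjects[[1]]), " voxels x ", ncol(x$subjects[[1]]),
      " time points\n", sep = "")
  invisible(x)
}

#' Mean time course of a seed region
#'
#' Unweighted mean over the seed voxels at every time point.
#'
#' @param seed_mask logical vector over connectome voxels.
#' @param subject_ts voxels x t matrix for one subject.
#' @export
seed_timecourse <- function(seed_mask, subject_ts) {
  if (!any(seed_mask)) stop("empty seed: no VTA voxels in the connectome grid")
  colMeans(subject_ts[seed_mask, , drop = FALSE])
}

#' Patient functional-connectivity fingerprint
#'
#' Seeds the bilateral VTA union in the connectome grid; per normative
#' subject, the Pearson correlation of the seed time course with every
#' voxel's time course, clipped to +/-(1 - 1e-6), Fisher z-transformed, and
#' averaged over subjects. Voxels whose series has zero variance in any
#' subject are marked invalid (NA).
#'
#' @param vta_pair list with `left`/`right` `vta_result`s.
#' @param connectome an `fc_connectome`.
#' @return [image3d] of mean Fisher-z values on the connectome grid.
#' @export
patient_connectivity_map <- function(vta_pair, connectome) {
  grid <- connectome$grid
  m <- array(FALSE, dim = img_dim(grid))
  for (side in c("left", "right")) {
    vt <- vta_pair[[side]]
    if (!is.null(vt)) m <- m | mask_on_grid(vt$mask, grid)
  }
  seed <- as.vector(m)
  zsum <- 0
  for (ts in connectome$subjects) {
    sc <- seed_timecourse(seed, ts)
    r <- suppressWarnings(as.numeric(cor(sc, t(ts))))
    r <- pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6)
    zsum <- zsum + atanh(r)
  }
  z <- zsum / length(connectome$subjects)
  img_like(grid, array(z, dim = img_dim(grid)))
}

#' Build the outcome R-map from patient connectivity fingerprints
#'
#' Per voxel, the correlation across patients between the Fisher-z
#' connectivity value and the percent outcome change. Rank (Spearman)
#' correlation by default, Pearson switchable. Voxels with missing or
#' constant values across patients are invalid.
#'
#' @param zmaps patients x voxels matrix of Fisher-z values.
#' @param outcomes percent-change vector.
#' @param grid [image3d] connectome grid.
#' @param method `"rank"` or `"linear"`.
#' @return an `rmap_result`: `r_image`, `valid_mask`, `method`.
#' @export
build_rmap <- function(zmaps, outcomes, grid, method = c("rank", "linear")) {
  method <- match.arg(method)
  if (nrow(zmaps) < 5L) stop("at least 5 patients required")
  if (sd(outcomes) == 0) {
    r <- rep(NA_real_, ncol(zmaps))
  } else {
    y <- if (method == "rank") rank(outcomes) else outcomes
    x <- zmaps
    if (method == "rank") x <- apply(zmaps, 2, rank)
    sds <- apply(x, 2, sd)
    nval <- colSums(is.finite(zmaps))
    r <- suppressWarnings(as.numeric(cor(y, x)))
    r[!is.finite(r) | sds == 0 | nval < 3L] <- NA_real_
  }
  structure(list(
    r_image = img_like(grid, array(r, dim = img_dim(grid))),
    valid_mask = img_like(grid, array(is.finite(r), dim = img_dim(grid))),
    method = method
  ), class = "rmap_result")
}

#' @export
print.rmap_result <- function(x, ...) {
  cat("<rmap_result> (", x$method, ") ", sum(x$valid_mask$data),
      " valid voxels, r in [", signif(min(x$r_image$data, na.rm = TRUE), 3),
      ", ", signif(max(x$r_image$data, na.rm = TRUE), 3), "]\n", sep = "")
  invisible(x)
}

#' Spatial similarity of a patient map to the R-map
#'
#' Pearson correlation between the patient's Fisher-z map and the R-map
#' over valid voxels; the prediction rule of the functional model.
#'
#' @param zmap patient Fisher-z vector over connectome voxels.
#' @param rmap an `rmap_result`.
#' @export
rmap_predict_patient <- function(zmap, rmap) {
  valid <- as.vector(rmap$valid_mask$data) & is.finite(zmap)
  if (sum(valid) < 3L) return(NA_real_)
  rv <- rmap$r_image$data[valid]
  zv <- zmap[valid]
  if (sd(rv) == 0 || sd(zv) == 0) return(NA_real_)
  cor(zv, rv)
}

#' Leave-one-out cross-validation of the R-map model
#'
#' @param zmaps patients x voxels Fisher-z matrix.
#' @param outcomes percent-change vector.
#' @param grid connectome grid.
#' @param method correlation method for the R-map.
#' @param covariates optional covariate data.frame.
#' @return a `cv_result`.
#' @export
rmap_loocv <- function(zmaps, outcomes, grid, method = "rank",
                       covariates = NULL) {
  loocv(outcomes,
        fit = function(train)
          build_rmap(zmaps[train, , drop = FALSE], outcomes[train], grid,
                     method = method),
        predict = function(rmap, i) rmap_predict_patient(zmaps[i, ], rmap),
        covariates = covariates, model_tag = "rmap")
}
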