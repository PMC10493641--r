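test_that("percent change follows the questionnaire formula", {
  expect_equal(percent_fogq_change(16, 8), 50)
  expect_equal(percent_fogq_change(10, 13), -30)
  expect_equal(percent_fogq_change(20, 20), 0)
  expect_error(percent_fogq_change(0, 5), "positive")
})

test_that("grouping cutoffs put the boundaries in the minor class", {
  expect_equal(as.character(assign_group(c(50, -5, 30, 0, 15))),
               c("alleviation", "deterioration", "minor", "minor", "minor"))
  expect_error(assign_group(c(1, NA)), "finite")
})

test_that("coordinate correlations report six Bonferroni-adjusted tests", {
  set.seed(21)
  n <- 30
  right <- cbind(rnorm(n, 12), rnorm(n, -13), rnorm(n, -6))
  left <- cbind(rnorm(n, -12), rnorm(n, -13), rnorm(n, -6))
  out <- sort(right[, 1])[rank(right[, 1])] * 2    # strictly increasing in x
  res <- coordinate_correlation(list(left = left, right = right), out)
  expect_equal(nrow(res), 6L)
  expect_equal(res$rho[res$hemisphere == "right" & res$axis == "x"], 1)
  expect_equal(res$p_adj, pmin(1, 6 * res$p))
  # constant axis: missing with a warning
  right2 <- right; right2[, 2] <- -13
  expect_warning(res2 <- coordinate_correlation(list(left = left, right = right2),
                                                out), "constant")
  expect_true(is.na(res2$rho[res2$hemisphere == "right" & res2$axis == "y"]))
})

test_that("subgroup contrasts reproduce the pooled-t closed form", {
  contacts <- list(left = cbind(c(1, 2, 3, 4, 5, 6), 0, 0),
                   right = cbind(c(1, 2, 3, 4, 5, 6), 0, 0))
  groups <- factor(c(rep("alleviation", 3), rep("deterioration", 3)),
                   levels = c("alleviation", "minor", "deterioration"))
  res <- subgroup_coordinate_compare(contacts, groups)
  tx <- res$statistic[res$hemisphere == "right" & res$axis == "x"]
  expect_equal(tx, -3.674235, tolerance = 1e-6)
  # swapping the compared groups flips the sign, p unchanged
  res_sw <- subgroup_coordinate_compare(contacts, groups,
                                        groups_compared = c("deterioration",
                                                            "alleviation"))
  expect_equal(res_sw$statistic, -res$statistic)
  expect_equal(res_sw$p, res$p)
  # identical groups: t = 0, p = 1
  contacts0 <- list(left = cbind(rep(c(1, 2, 3), 2), 0, 0),
                    right = cbind(rep(c(1, 2, 3), 2), 0, 0))
  res0 <- subgroup_coordinate_compare(contacts0, groups)
  expect_true(all(res0$statistic == 0))
  expect_true(all(res0$p == 1))
})

test_that("overlap volumes count labelled voxels times voxel volume", {
  atlas <- small_atlas()
  # fabricated VTA wholly inside the right STN
  ctr <- atlas$geometry$right$centre
  vta <- fake_vta(ctr, radius = 2, resolution = 0.5)
  ov <- overlap_volumes(vta, atlas)
  stn_r <- ov$overlap_mm3[ov$region == "STN_R"]
  expect_gt(stn_r, 0)
  # subregion overlaps partition the whole-STN overlap
  subs <- ov$overlap_mm3[ov$region %in% c("STN_R_sensorimotor",
                                          "STN_R_associative",
                                          "STN_R_limbic")]
  expect_equal(sum(subs), stn_r)
  # disjoint VTA: zero overlap everywhere
  far <- fake_vta(c(0, 10, 10), radius = 2)
  expect_true(all(overlap_volumes(far, atlas)$overlap_mm3 == 0))
  # the mask voxel count times voxel volume bounds any overlap
  expect_lte(stn_r, vta_volume(vta))
})

test_that("overlap correlations flag degenerate regions and rank-perfect ones", {
  set.seed(2)
  ov <- cbind(a = runif(20), b = runif(20), zero = rep(0, 20))
  out <- rank(ov[, "a"]) * 3 - 5   # rank-identical to region a
  expect_warning(res <- overlap_correlation(ov, out), "zero variance")
  expect_equal(res$rho[res$region == "a"], 1)
  expect_true(is.na(res$rho[res$region == "zero"]))
  expect_equal(res$p_adj, pmin(1, 3 * res$p))
})

test_that("coverage counting identities hold", {
  grid <- make_grid(c(10, 10, 10), 1)
  vtas <- list(
    list(left = fake_vta(c(-2, 0, 0), radius = 2, margin = 4,
                         hemisphere = "left"),
         right = fake_vta(c(2, 0, 0), radius = 2, margin = 4)),
    list(left = NULL,
         right = fake_vta(c(2, 0, 1), radius = 2, margin = 4)))
  cov <- coverage_matrix(vtas, grid)
  cnt <- build_coverage(cov)
  # coverage counts sum to the patients' per-union voxel counts
  expect_equal(sum(cnt$data), sum(rowSums(cov)))
  # one patient: counts are 0/1
  cov1 <- coverage_matrix(vtas[2], grid)
  expect_true(all(build_coverage(cov1)$data %in% 0:1))
  expect_equal(coverage_min_count(76, 0.20), 16L)
  expect_equal(coverage_min_count(10, 0.20), 2L)
})

test_that("mean effect averages covering patients and respects the coverage rule", {
  grid <- make_grid(c(4, 4, 4), 1)
  n <- 4
  cov <- matrix(FALSE, n, 64)
  cov[1, 1:10] <- TRUE
  cov[2, 1:5] <- TRUE
  cov[3, 3] <- TRUE
  attr(cov, "grid") <- grid
  y <- c(10, 30, 50, 0)
  me <- psm_mean_effect(cov, y, coverage_fraction = 0.5)  # need >= 2 of 4
  expect_equal(as.vector(me$data)[1], 20)        # patients 1, 2
  expect_equal(as.vector(me$data)[3], 30)        # patients 1, 2, 3
  expect_true(is.na(as.vector(me$data)[11]))     # covered by nobody
  expect_true(is.na(as.vector(me$data)[6]))      # covered once: below rule
  # all outcomes equal: every eligible voxel equals that constant
  me2 <- psm_mean_effect(cov, rep(7, 4), coverage_fraction = 0.25)
  expect_true(all(me2$data[!is.na(me2$data)] == 7))
  expect_warning(psm_mean_effect(cov, y, coverage_fraction = 0.99),
                 "no voxel")
})

test_that("voxel tests give p = 1 for identical group multisets and exact small-n p", {
  grid <- make_grid(c(2, 2, 2), 1)
  cov <- matrix(FALSE, 6, 8)
  cov[1:3, 1] <- TRUE          # exact extreme 3-vs-3 split at voxel 1
  cov[c(1, 2, 4), 2] <- TRUE   # mixed split at voxel 2
  attr(cov, "grid") <- grid
  y <- c(3, 4, 5, 0, 1, 2)
  p <- psm_voxel_test(cov, y, eligible = c(TRUE, TRUE, rep(FALSE, 6)))
  expect_equal(as.vector(p$data)[1], 0.1)
  expect_true(is.na(as.vector(p$data)[3]))
  # identical multisets in both groups
  y2 <- c(1, 2, 3, 1, 2, 3)
  cov2 <- matrix(FALSE, 6, 8)
  cov2[1:3, 1] <- TRUE
  attr(cov2, "grid") <- grid
  p2 <- psm_voxel_test(cov2, y2, eligible = c(TRUE, rep(FALSE, 7)))
  expect_equal(as.vector(p2$data)[1], 1)
})

test_that("PSM masking keeps only significant voxels and degenerates sensibly", {
  grid <- make_grid(c(3, 3, 3), 1)
  n <- 27
  me <- img_like(grid, array(rnorm(n), dim = c(3, 3, 3)))
  p_all1 <- img_like(grid, array(1, dim = c(3, 3, 3)))
  psm1 <- psm_mask(me, p_all1)
  expect_false(any(psm1$significant_mask$data))
  p_mix <- img_like(grid, array(runif(n), dim = c(3, 3, 3)))
  psm2 <- psm_mask(me, p_mix, alpha = 1)   # alpha = 1 keeps every tested voxel
  expect_equal(sum(psm2$significant_mask$data), n)
  expect_equal(psm_score_patient(rep(FALSE, n), psm2), 0)
  # scoring sums the retained mean effects over the patient's coverage
  sel <- rep(FALSE, n); sel[1:2] <- TRUE
  psm3 <- psm_mask(img_like(grid, array(c(1.5, -0.5, rep(NA, 25)),
                                        dim = c(3, 3, 3))),
                   img_like(grid, array(c(0.01, 0.01, rep(NA, 25)),
                                        dim = c(3, 3, 3))))
  expect_equal(psm_score_patient(sel, psm3), 1.0)
})

test_that("centroids and peaks are value-weighted and tie-broken first", {
  grid <- make_grid(c(5, 5, 5), 1, centre = c(13, -11, -5))
  vals <- array(NA_real_, dim = c(5, 5, 5))
  vals[3, 3, 3] <- 2          # world (13, -11, -5)
  me <- img_like(grid, vals)
  p <- img_like(grid, array(ifelse(is.na(vals), NA, 0.01), dim = c(5, 5, 5)))
  psm <- psm_mask(me, p)
  cp <- centroid_and_peak(psm, "positive")
  expect_equal(cp$centroid, c(13, -11, -5))
  expect_equal(cp$peak, c(13, -11, -5))
  expect_equal(cp$n_voxels, 1L)
  # two equal-valued voxels: centroid at the midpoint, peak at the first
  vals2 <- array(NA_real_, dim = c(5, 5, 5))
  vals2[2, 3, 3] <- 1; vals2[4, 3, 3] <- 1
  psm2 <- psm_mask(img_like(grid, vals2),
                   img_like(grid, array(0.01, dim = c(5, 5, 5))))
  cp2 <- centroid_and_peak(psm2, "positive")
  expect_equal(cp2$centroid, c(13, -11, -5))
  expect_equal(cp2$peak, c(12, -11, -5))
  # empty cluster: missing
  expect_true(all(is.na(centroid_and_peak(psm2, "negative")$centroid)))
})

test_that("negating outcomes negates the mean effect and swaps sweet and sour", {
  set.seed(13)
  grid <- make_grid(c(6, 6, 6), 1)
  n <- 24
  cov <- matrix(runif(n * 216) < 0.35, n, 216)
  attr(cov, "grid") <- grid
  y <- rnorm(n, 10, 20)
  a <- build_psm(cov, y, coverage_fraction = 0.2)
  b <- build_psm(cov, -y, coverage_fraction = 0.2)
  expect_equal(b$p_image$data, a$p_image$data)
  expect_equal(b$significant_mask$data, a$significant_mask$data)
  sig <- a$significant_mask$data
  expect_equal(b$mean_effect$data[sig], -a$mean_effect$data[sig])
})

test_that("raising the coverage fraction never adds eligible voxels", {
  set.seed(14)
  grid <- make_grid(c(5, 5, 5), 1)
  cov <- matrix(runif(20 * 125) < 0.3, 20, 125)
  attr(cov, "grid") <- grid
  y <- rnorm(20)
  e1 <- attr(psm_mean_effect(cov, y, 0.10), "eligible")
  e2 <- attr(psm_mean_effect(cov, y, 0.25), "eligible")
  e3 <- suppressWarnings(attr(psm_mean_effect(cov, y, 0.60), "eligible"))
  expect_true(all(e2 <= e1))
  expect_true(all(e3 <= e2))
})
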