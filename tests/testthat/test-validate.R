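test_that("rank correlation handles perfect, reversed and exact cases", {
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:10, 10:1)$rho, -1)
  sp <- spearman(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(sp$rho, 0.8)
  expect_identical(sp$method, "exact")
  # frozen by full enumeration of the 120 permutations: 16/120
  expect_equal(sp$p, 16 / 120)
  expect_equal(spearman(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4),
                        alternative = "greater")$p, 8 / 120)
})

test_that("exact rank-correlation p agrees with direct enumeration", {
  set.seed(11)
  x <- rnorm(6); y <- rnorm(6)
  sp <- spearman(x, y)
  perms <- stimmap:::permutations_of(6L)
  rhos <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  expect_equal(sp$p, mean(abs(rhos) >= abs(sp$rho) - 1e-9))
})

test_that("rank correlation is invariant under monotone transforms", {
  set.seed(3)
  x <- rnorm(30); y <- x + rnorm(30)
  a <- spearman(x, y)
  b <- spearman(exp(x), y^3 + 5 * y)   # strictly monotone maps
  expect_equal(a$rho, b$rho)
  expect_equal(a$p, b$p)
})

test_that("degenerate correlation inputs are reported missing", {
  expect_true(is.na(spearman(rep(1, 8), rnorm(8))$rho))
  expect_true(is.na(spearman(1:2, 2:1)$rho))
})

test_that("Bonferroni adjustment caps, scales and preserves order", {
  expect_equal(bonferroni(0.01, m = 6), 0.06)
  expect_equal(bonferroni(0.5, m = 6), 1)
  expect_equal(bonferroni(c(0.2, 0.04), m = 1), c(0.2, 0.04))
  p <- runif(20)
  adj <- bonferroni(p, m = 7)
  expect_true(all(adj >= p))
  expect_identical(order(adj), order(pmin(1, 7 * p)))
})

test_that("rank-sum p matches the exact enumeration and wilcox.test", {
  # most extreme 3-vs-3 split: 2 of the 20 equally likely splits
  expect_equal(rank_sum_p(c(3, 4, 5), c(0, 1, 2)), 0.1)
  expect_equal(rank_sum_p(c(3, 4, 5), c(0, 1, 2)),
               wilcox.test(c(3, 4, 5), c(0, 1, 2))$p.value)
  expect_equal(rank_sum_p(numeric(0), c(1, 2)), 1)
  # identical multisets: no evidence
  expect_equal(rank_sum_p(c(1, 2, 3), c(1, 2, 3)), 1)
  # large-sample path with ties agrees with wilcox.test's normal approx
  set.seed(5)
  x <- sample(1:10, 18, replace = TRUE)
  y <- sample(3:12, 15, replace = TRUE)
  expect_equal(rank_sum_p(x, y),
               suppressWarnings(wilcox.test(x, y)$p.value),
               tolerance = 1e-10)
})

test_that("vectorised rank-sum p equals the scalar test column by column", {
  set.seed(9)
  n <- 40
  y <- rnorm(n)
  member <- matrix(runif(n * 12) < 0.4, n, 12)
  member[, 12] <- FALSE                      # empty group column
  p <- ranksum_p_matrix(member, y)
  for (j in 1:11)
    expect_equal(p[j],
                 suppressWarnings(wilcox.test(y[member[, j]], y[!member[, j]],
                                              exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-10)
  expect_equal(p[12], 1)
})

test_that("pooled t over matrix rows matches t.test and the closed form", {
  y <- c(50, 60, 0, 10)
  member <- matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4)
  expect_equal(pooled_t_matrix(member, y)$t, 7.071068, tolerance = 1e-6)
  y2 <- c(1, 2, 3, 4, 5, 6)
  m2 <- matrix(c(rep(TRUE, 3), rep(FALSE, 3)), 1, 6)
  expect_equal(pooled_t_matrix(m2, y2)$t,
               unname(t.test(1:3, 4:6, var.equal = TRUE)$statistic),
               tolerance = 1e-9)
  set.seed(2)
  yy <- rnorm(25)
  mm <- matrix(runif(75) < 0.5, 3, 25)
  tt <- pooled_t_matrix(mm, yy)$t
  for (k in 1:3)
    expect_equal(tt[k], unname(t.test(yy[mm[k, ]], yy[!mm[k, ]],
                                      var.equal = TRUE)$statistic),
                 tolerance = 1e-9)
  # degenerate variance, equal means -> 0; unequal -> capped with warning
  expect_equal(pooled_t_matrix(matrix(c(TRUE, TRUE, FALSE, FALSE), 1),
                               c(1, 1, 1, 1))$t, 0)
  expect_warning(
    tcap <- pooled_t_matrix(matrix(c(TRUE, TRUE, FALSE, FALSE), 1),
                            c(2, 2, 1, 1))$t, "capped")
  expect_equal(tcap, 1e6)
})

test_that("LOOCV isolates folds and scores held-out predictions", {
  set.seed(4)
  x <- rnorm(20)
  y <- 2 * x + 1          # noiseless monotone: perfect rank recovery
  fit <- function(train) lm(y ~ x, data = data.frame(x = x[train], y = y[train]))
  predict_one <- function(mod, i) unname(predict(mod, data.frame(x = x[i])))
  cv <- loocv(y, fit, predict_one)
  expect_equal(cv$spearman_r, 1)
  expect_equal(length(cv$predicted), 20L)

  # constant predictor: correlation undefined, reported missing
  cvc <- loocv(y, function(train) NULL, function(mod, i) 0)
  expect_true(is.na(cvc$spearman_r))

  # fold isolation: corrupting the held-out outcome cannot change its
  # prediction, only its evaluation
  y2 <- y; y2[7] <- 1e6
  fit2 <- function(train) lm(y ~ x, data = data.frame(x = x[train], y = y2[train]))
  cv2 <- loocv(y2, fit2, predict_one)
  expect_equal(cv2$predicted[7], cv$predicted[7], tolerance = 1e-9)

  expect_error(loocv(y[1:3], fit, predict_one), "at least 5")
  expect_error(loocv(y, function(train) stop("boom"), predict_one),
               "fold 1")
})

test_that("covariate adjustment removes covariate-borne signal only", {
  set.seed(8)
  n <- 60
  covars <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  # signal independent of the covariates: adjustment changes little
  pred <- rnorm(n); obs <- pred + rnorm(n)
  raw <- spearman(pred, obs)$rho
  adj <- covariate_adjusted_correlation(pred, obs, covars)$rho
  expect_lt(abs(adj - raw), 0.1)
  # outcome identical to a covariate: adjusted correlation collapses
  obs2 <- covars$a
  pred2 <- covars$a + rnorm(n, 0, 0.1)
  adj2 <- covariate_adjusted_correlation(pred2, obs2, covars)$rho
  expect_lt(abs(adj2), 0.05)
  # rank-deficient designs are refused with the offending column named
  covars$dup <- covars$a
  expect_error(covariate_adjusted_correlation(pred, obs, covars), "dup")
  expect_error(covariate_adjusted_correlation(pred, obs,
                                              data.frame(z = rep(0, n))),
               "rank deficient|collinear")
})
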