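#' Spearman rank correlation with exact small-sample p-value
#'
#' Tie-corrected rank correlation (Pearson correlation of mid-ranks). The
#' p-value uses full enumeration of all `n!` rank permutations when
#' `n <= exact_max` and there are no ties, and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` (positive association) or
#'   `"less"`.
#' @param exact_max largest n for which the permutation distribution is
#'   fully enumerated.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman <- function(x, y, alternative = c("two.sided", "greater", "less"),
                     exact_max = 8L) {
  alternative <- match.arg(alternative)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n, method = "none"))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  rho <- cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= exact_max && !ties) {
    rx <- rank(x); ry <- rank(y)
    perms <- permutations_of(n)
    # rho is monotone in the sum of rank products for untied data
    s_obs <- sum(rx * ry)
    s_all <- as.vector(perms %*% ry[order(rx)])
    mu <- mean(s_all)
    p <- switch(alternative,
      two.sided = mean(abs(s_all - mu) >= abs(s_obs - mu) - 1e-9),
      greater   = mean(s_all >= s_obs - 1e-9),
      less      = mean(s_all <= s_obs + 1e-9))
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- switch(alternative,
    two.sided = 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE),
    greater   = pt(tstat, df = n - 2, lower.tail = FALSE),
    less      = pt(tstat, df = n - 2))
  list(rho = rho, p = min(p, 1), n = n, method = "t-approximation")
}

# All permutations of 1..n as a matrix (n! rows). Used only for small n.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- sub + (sub >= k)
    r <- r + nrow(sub)
  }
  out
}

#' Bonferroni adjustment
#'
#' @param p vector of raw p-values.
#' @param m family size; defaults to `length(p)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

#' Two-sample rank-sum test (Wilcoxon/Mann-Whitney)
#'
#' Exact two-tailed p when the combined sample is small (`n1 + n2 <= 20`)
#' and tie-free; otherwise the normal approximation with tie correction and
#' continuity correction. Mirrors `stats::wilcox.test` but is also
#' available in a vectorised form for voxel-wise maps
#' ([ranksum_p_matrix()]).
#'
#' @param x,y the two groups.
#' @param exact_max largest combined n for the exact distribution.
#' @return two-tailed p-value; 1 if either group is empty.
#' @export
rank_sum_p <- function(x, y, exact_max = 20L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) return(1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (n1 + n2 <= exact_max && !ties) {
    # exact two-tailed p, symmetric distribution of U
    p <- if (u > n1 * n2 / 2) {
      pwilcox(u - 1, n1, n2, lower.tail = FALSE) * 2
    } else if (u < n1 * n2 / 2) {
      pwilcox(u, n1, n2) * 2
    } else 1
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Vectorised rank-sum p-values over the columns of a membership matrix
#'
#' For each column `v` of the logical matrix `member` (observations x
#' tests), computes the two-tailed rank-sum p comparing `y[member[, v]]`
#' against `y[!member[, v]]` with the normal approximation (tie-corrected,
#' continuity-corrected). Columns where either group is empty get p = 1.
#'
#' @param member logical matrix, observations in rows.
#' @param y outcome vector, one value per observation.
#' @return numeric vector of p-values, one per column.
#' @export
ranksum_p_matrix <- function(member, y) {
  n <- length(y)
  stopifnot(nrow(member) == n)
  r <- rank(y)
  n1 <- colSums(member)
  rsum <- as.numeric(crossprod(member, r))
  u <- rsum - n1 * (n1 + 1) / 2
  n2 <- n - n1
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(pmax(sig2, .Machine$double.eps))
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  p[n1 == 0L | n2 == 0L | sig2 <= 0] <- 1
  pmin(p, 1)
}

#' Pooled-variance two-sample t statistics over matrix rows
#'
#' For each row of the logical matrix `member` (tests x observations), the
#' pooled two-sample t contrasting `y` between members and non-members,
#' signed positive when members have the larger mean. Degenerate rows
#' (pooled variance 0) give t = 0 for equal means, otherwise +/-`cap` with
#' a warning.
#'
#' @param member logical matrix, tests in rows, observations in columns.
#' @param y outcome vector.
#' @param cap magnitude used for infinite t.
#' @return list with `t`, `n1`, `n2` per row.
#' @export
pooled_t_matrix <- function(member, y, cap = 1e6) {
  n <- length(y)
  stopifnot(ncol(member) == n)
  storage.mode(member) <- "double"
  n1 <- as.numeric(member %*% rep(1, n))
  n0 <- n - n1
  s1 <- as.numeric(member %*% y)
  sq1 <- as.numeric(member %*% y^2)
  s0 <- sum(y) - s1
  sq0 <- sum(y^2) - sq1
  m1 <- s1 / n1; m0 <- s0 / n0
  ss1 <- sq1 - n1 * m1^2
  ss0 <- sq0 - n0 * m0^2
  s2p <- (ss1 + ss0) / (n1 + n0 - 2)
  se <- sqrt(s2p * (1 / n1 + 1 / n0))
  tval <- (m1 - m0) / se
  deg <- is.finite(m1) & is.finite(m0) & (!is.finite(tval) | se == 0)
  if (any(deg)) {
    eq <- deg & abs(m1 - m0) < 1e-12
    tval[eq] <- 0
    bad <- deg & !eq
    if (any(bad)) {
      warning(sum(bad), " degenerate-variance contrasts capped at +/-", cap)
      tval[bad] <- sign(m1[bad] - m0[bad]) * cap
    }
  }
  list(t = tval, n1 = n1, n2 = n0)
}

#' Leave-one-out cross-validation
#'
#' Fits the supplied model n times, each time excluding one observation,
#' predicts the held-out observation, and correlates held-out predictions
#' with observed outcomes by Spearman rank correlation. A map that
#' predicts outcome should do so in the positive direction, so the
#' default p is one-sided positive; two-sided is available.
#'
#' @param outcomes observed outcome vector (length n).
#' @param fit `function(train_idx)` returning a fitted model object.
#' @param predict `function(model, test_idx)` returning one numeric
#'   prediction.
#' @param covariates optional data.frame of per-observation covariates; if
#'   supplied, a covariate-adjusted correlation is also reported (see
#'   [covariate_adjusted_correlation()]).
#' @param alternative direction of the validation test.
#' @param model_tag label stored on the result.
#' @return a `cv_result`: predictions, `spearman_r`, `p_value`, optional
#'   adjusted values, and the observations.
#' @export
loocv <- function(outcomes, fit, predict, covariates = NULL,
                  alternative = c("greater", "two.sided"),
                  model_tag = "model") {
  alternative <- match.arg(alternative)
  n <- length(outcomes)
  if (n < 5L) stop("LOOCV requires at least 5 observations")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    mod <- tryCatch(fit(train),
                    error = function(e) stop("fit failed on fold ", i, ": ",
                                             conditionMessage(e)))
    preds[i] <- predict(mod, i)
  }
  if (sd(preds) == 0) {
    sp <- list(rho = NA_real_, p = NA_real_)
  } else {
    sp <- spearman(preds, outcomes, alternative = alternative)
  }
  adj <- list(rho = NA_real_, p = NA_real_)
  if (!is.null(covariates) && !is.na(sp$rho))
    adj <- covariate_adjusted_correlation(preds, outcomes, covariates,
                                          alternative = alternative)
  structure(list(observed = outcomes, predicted = preds,
                 spearman_r = sp$rho, p_value = sp$p,
                 adjusted_spearman_r = adj$rho, adjusted_p = adj$p,
                 alternative = alternative, model_tag = model_tag, n = n),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$model_tag, ": LOOCV Spearman R = ",
      signif(x$spearman_r, 3), ", P = ", signif(x$p_value, 3),
      " (n = ", x$n, ", ", x$alternative, ")\n", sep = "")
  if (!is.na(x$adjusted_spearman_r))
    cat("  covariate-adjusted R = ", signif(x$adjusted_spearman_r, 3),
        ", P = ", signif(x$adjusted_p, 3), "\n", sep = "")
  invisible(x)
}

#' Covariate-adjusted rank correlation
#'
#' Residualises both variables on the covariate design by least squares
#' (intercept included) and rank-correlates the residuals. The design must
#' be full rank; collinear columns are reported by name.
#'
#' @param pred,obs numeric vectors.
#' @param covariates data.frame or matrix of covariates.
#' @param alternative passed to [spearman()].
#' @return list with `rho`, `p`, `n`.
#' @export
covariate_adjusted_correlation <- function(pred, obs, covariates,
                                           alternative = "two.sided") {
  covariates <- as.data.frame(covariates)
  ok <- complete.cases(covariates) & is.finite(pred) & is.finite(obs)
  x <- cbind(1, as.matrix(covariates[ok, , drop = FALSE]))
  colnames(x)[1] <- "(intercept)"
  if (nrow(x) <= ncol(x) + 2L)
    stop("too few complete observations for covariate adjustment")
  q <- qr(x)
  if (q$rank < ncol(x)) {
    dropped <- colnames(x)[q$pivot[(q$rank + 1L):ncol(x)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  res_p <- lm.fit(x, pred[ok])$residuals
  res_o <- lm.fit(x, obs[ok])$residuals
  # a variable fully explained by the covariates leaves only numerical
  # noise; its adjusted association is zero by convention
  tiny <- function(r, v) sd(r) <= 1e-10 * max(sd(v), 1)
  if (tiny(res_p, pred[ok]) || tiny(res_o, obs[ok]))
    return(list(rho = 0, p = 1, n = sum(ok)))
  sp <- spearman(res_p, res_o, alternative = alternative)
  list(rho = sp$rho, p = sp$p, n = sum(ok))
}
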