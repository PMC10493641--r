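#' Filter fibres by VTA connectivity
#'
#' Keeps fibres connected to at least `ceiling(min_fraction * n)` patients'
#' VTAs.
#'
#' @param connectivity fibres x patients logical matrix from
#'   [fibre_vta_connectivity()].
#' @param min_fraction minimum fraction of patients (default 0.20).
#' @return integer vector of retained fibre indices.
#' @export
filter_fibres <- function(connectivity, min_fraction = 0.20) {
  need <- ceiling(min_fraction * ncol(connectivity))
  which(rowSums(connectivity) >= need)
}

#' Discriminative fibre T-scores
#'
#' For each retained fibre, the pooled-variance two-sample t statistic
#' contrasting outcomes of patients whose VTAs touch the fibre against
#' those whose VTAs do not. Positive scores mark fibres preferentially
#' stimulated in well-responding patients. Welch's statistic is available
#' behind a switch. Fibres where either group has fewer than 2 patients
#' are assigned NA.
#'
#' @param connectivity fibres x patients logical matrix.
#' @param outcomes percent-change vector.
#' @param min_fraction connectivity filter passed to [filter_fibres()].
#' @param welch use Welch's unequal-variance t instead of the pooled form.
#' @return data.frame: fibre (index), t, connected_count, retained flag for
#'   every fibre in the input set.
#' @export
fibre_t_scores <- function(connectivity, outcomes, min_fraction = 0.20,
                           welch = FALSE) {
  nf <- nrow(connectivity)
  keep <- filter_fibres(connectivity, min_fraction)
  out <- data.frame(fibre = seq_len(nf), t = NA_real_,
                    connected_count = rowSums(connectivity),
                    retained = logical(nf))
  out$retained[keep] <- TRUE
  if (!length(keep)) return(out)
  sub <- connectivity[keep, , drop = FALSE]
  n <- length(outcomes)
  n1 <- rowSums(sub); n0 <- n - n1
  valid <- n1 >= 2L & n0 >= 2L
  if (!welch) {
    tt <- pooled_t_matrix(sub, outcomes)
    tv <- tt$t
  } else {
    storage.mode(sub) <- "double"
    s1 <- as.numeric(sub %*% outcomes); sq1 <- as.numeric(sub %*% outcomes^2)
    m1 <- s1 / n1; m0 <- (sum(outcomes) - s1) / n0
    v1 <- (sq1 - n1 * m1^2) / (n1 - 1)
    v0 <- ((sum(outcomes^2) - sq1) - n0 * m0^2) / (n0 - 1)
    tv <- (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
  }
  tv[!valid] <- NA_real_
  out$t[keep] <- tv
  out
}

#' Top fraction of fibres by absolute T-score
#'
#' Fibres ranked by `|t|`; the top `ceiling(fraction * m)` are returned and
#' ties with the score at the cut are included.
#'
#' @param scores data.frame from [fibre_t_scores()].
#' @param fraction fraction to keep (default 0.30, the display convention).
#' @return integer fibre indices.
#' @export
top_fraction <- function(scores, fraction = 0.30) {
  sc <- scores[scores$retained & !is.na(scores$t), ]
  if (!nrow(sc)) return(integer(0))
  k <- ceiling(fraction * nrow(sc))
  if (k < 1L) return(integer(0))
  a <- abs(sc$t)
  cut <- sort(a, decreasing = TRUE)[k]
  sc$fibre[a >= cut - 1e-12]
}

#' Predicted outcome of one patient from fibre scores
#'
#' Mean T over the retained fibres connected to the patient's VTAs
#' (0 when none are connected); `"sum"` and connectivity-weighted variants
#' are available.
#'
#' @param connectivity_column logical vector over fibres for one patient.
#' @param scores data.frame from [fibre_t_scores()].
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @export
fibre_predict_patient <- function(connectivity_column, scores,
                                  aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  sel <- scores$retained & !is.na(scores$t) & connectivity_column
  if (!any(sel)) return(0)
  if (aggregate == "mean") mean(scores$t[sel]) else sum(scores$t[sel])
}

#' Contrast connectivity patterns between two patient groups
#'
#' Per fibre, an independent-samples t statistic comparing the binary
#' connection indicators of group A patients against group B patients.
#'
#' @param connectivity fibres x patients logical matrix.
#' @param groups factor over patients.
#' @param groups_compared the two levels contrasted (A minus B).
#' @param fibres fibre subset to test (default: all).
#' @return data.frame: fibre, t.
#' @export
group_pattern_compare <- function(connectivity, groups,
                                  groups_compared = c("alleviation", "deterioration"),
                                  fibres = seq_len(nrow(connectivity))) {
  a <- which(groups == groups_compared[1])
  b <- which(groups == groups_compared[2])
  if (length(a) < 2L || length(b) < 2L)
    stop("both compared groups need at least 2 patients")
  sub <- connectivity[fibres, c(a, b), drop = FALSE]
  member <- matrix(FALSE, 1, length(a) + length(b))
  member[1, seq_along(a)] <- TRUE
  ind <- matrix(as.numeric(sub), nrow(sub), ncol(sub))
  # contrast each fibre's indicator between the two groups
  ya <- ind[, seq_along(a), drop = FALSE]
  yb <- ind[, length(a) + seq_along(b), drop = FALSE]
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  ssa <- rowSums((ya - ma)^2); ssb <- rowSums((yb - mb)^2)
  s2p <- (ssa + ssb) / (length(a) + length(b) - 2)
  se <- sqrt(s2p * (1 / length(a) + 1 / length(b)))
  tv <- (ma - mb) / se
  tv[se == 0 & abs(ma - mb) < 1e-12] <- 0
  data.frame(fibre = fibres, t = tv)
}

#' Leave-one-out cross-validation of the fibre-filtering model
#'
#' Each fold recomputes the connectivity filter and fibre T-scores from the
#' training patients only, then predicts the held-out patient as the mean T
#' of their connected retained fibres.
#'
#' @param connectivity fibres x patients logical matrix.
#' @param outcomes percent-change vector.
#' @param min_fraction connectivity filter fraction.
#' @param covariates optional covariate data.frame.
#' @param aggregate prediction rule, see [fibre_predict_patient()].
#' @return a `cv_result`.
#' @export
fibre_loocv <- function(connectivity, outcomes, min_fraction = 0.20,
                        covariates = NULL, aggregate = "mean") {
  loocv(outcomes,
        fit = function(train)
          fibre_t_scores(connectivity[, train, drop = FALSE],
                         outcomes[train], min_fraction = min_fraction),
        predict = function(scores, i)
          fibre_predict_patient(connectivity[, i], scores,
                                aggregate = aggregate),
        covariates = covariates, model_tag = "fibre")
}
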