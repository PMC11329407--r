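#' ROC, DeLong inference and the nonparametric battery
#'
#' The classification layer: Mann-Whitney AUC with midrank tie handling,
#' DeLong's placement-value variance estimator for AUC inference (single
#' AUC against a null value, and paired comparison of two markers on the
#' same subjects), the nonparametric test battery (Kruskal-Wallis across
#' KL groups, Wilcoxon signed rank for paired compartments, Friedman
#' across model variants) with Bonferroni-adjusted significance, and the
#' JSN-versus-degeneration verification (adjusted R-squared and
#' cross-tabulation).
#'
#' A single-predictor logistic model yields the same ROC as the scalar
#' score itself (the fitted probability is monotone in the score), so ROC
#' analyses operate directly on scalar scores such as degenerated-volume
#' fractions.
#'
#' @name stats_classify
NULL

# placement values: for each positive, the fraction of negatives it beats
# (ties half-credit), and vice versa
.placements <- function(scores_pos, scores_neg) {
  m <- length(scores_pos)
  n <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(scores_pos, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(scores_neg, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Mann-Whitney AUC
#'
#' `AUC = (#[pos > neg] + 0.5 #[ties]) / (n_pos * n_neg)`, identical to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores_pos,scores_neg Scores of the positive and negative group
#'   (higher = more positive).
#' @return List with `auc`, `n_pos`, `n_neg`.
#' @examples
#' auc_mann_whitney(c(2, 3), c(1, 2))$auc # 0.875
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score groups must be non-empty")
  }
  pl <- .placements(scores_pos, scores_neg)
  list(auc = pl$auc, n_pos = length(scores_pos), n_neg = length(scores_neg))
}

#' DeLong test for a single AUC
#'
#' Placement-value (structural component) variance estimator with a
#' two-sided normal-approximation p-value against `null_auc`.
#'
#' @inheritParams auc_mann_whitney
#' @param null_auc Null hypothesis AUC (default 0.5).
#' @param comparison_label Optional label carried through to the result.
#' @return A `roc_result`: `auc`, `variance`, `p_value`, `n_pos`, `n_neg`,
#'   `comparison_label`.
#' @export
delong_test <- function(scores_pos, scores_neg, null_auc = 0.5,
                        comparison_label = NULL) {
  m <- length(scores_pos)
  n <- length(scores_neg)
  if (m < 2 || n < 2) stop("DeLong inference needs >= 2 scores per group")
  pl <- .placements(scores_pos, scores_neg)
  v <- var(pl$v10) / m + var(pl$v01) / n
  if (v <= 0) {
    warning("zero DeLong variance (complete separation); p-value is a limit")
    p <- if (abs(pl$auc - null_auc) < .Machine$double.eps^0.5) 1 else 0
  } else {
    p <- 2 * pnorm(-abs(pl$auc - null_auc) / sqrt(v))
  }
  structure(list(auc = pl$auc, variance = v, p_value = p,
                 null_auc = null_auc, n_pos = m, n_neg = n,
                 comparison_label = comparison_label),
            class = "roc_result")
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two markers measured on the same positive and negative
#' subjects using the covariance of their placement values.
#'
#' @param scores1_pos,scores1_neg Marker 1 scores.
#' @param scores2_pos,scores2_neg Marker 2 scores (same subjects, same
#'   order).
#' @return List with both AUCs, the difference, its variance, and the
#'   two-sided p-value.
#' @export
delong_paired_test <- function(scores1_pos, scores1_neg,
                               scores2_pos, scores2_neg) {
  m <- length(scores1_pos)
  n <- length(scores1_neg)
  if (length(scores2_pos) != m || length(scores2_neg) != n) {
    stop("paired DeLong requires identical subjects for both markers")
  }
  if (m < 2 || n < 2) stop("DeLong inference needs >= 2 scores per group")
  p1 <- .placements(scores1_pos, scores1_neg)
  p2 <- .placements(scores2_pos, scores2_neg)
  s10 <- var(cbind(p1$v10, p2$v10))
  s01 <- var(cbind(p1$v01, p2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- p1$auc - p2$auc
  p <- if (v <= 0) {
    warning("zero variance of the AUC difference; p-value is a limit")
    if (abs(d) < .Machine$double.eps^0.5) 1 else 0
  } else 2 * pnorm(-abs(d) / sqrt(v))
  list(auc1 = p1$auc, auc2 = p2$auc, difference = d, variance = v,
       p_value = p)
}

#' Nonparametric comparison battery
#'
#' Runs a declared family of comparisons on a long-format table and
#' attaches the Bonferroni-adjusted significance level (`alpha / m` with
#' `m` the family size). Supported designs:
#' \describe{
#'   \item{kruskal_wallis}{independent groups: `value` by `group`.}
#'   \item{wilcoxon}{paired two-level comparison: `value` across the two
#'     `levels` of column `within`, paired by `id`.}
#'   \item{friedman}{repeated measures: `value` across all levels of
#'     `within`, blocked by `id`.}
#' }
#'
#' @param data Long-format `data.frame`.
#' @param design List of comparison specifications, each a list with
#'   `test` and the column names described above (plus an optional
#'   `label`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return `data.frame` with one row per comparison: test, label,
#'   statistic, p-value, the Bonferroni-adjusted alpha and a significance
#'   flag.
#' @export
nonparametric_battery <- function(data, design, alpha = 0.05) {
  m <- length(design)
  stopifnot(m >= 1)
  adj <- alpha / m
  rows <- lapply(seq_len(m), function(i) {
    d <- design[[i]]
    label <- if (!is.null(d$label)) d$label else d$test
    if (d$test == "kruskal_wallis") {
      kt <- kruskal.test(data[[d$value]], factor(data[[d$group]]))
      stat <- unname(kt$statistic)
      p <- kt$p.value
    } else if (d$test == "wilcoxon") {
      wide <- .pair_values(data, d$value, d$within, d$id, d$levels)
      wt <- suppressWarnings(
        wilcox.test(wide[, 1], wide[, 2], paired = TRUE, exact = FALSE))
      stat <- unname(wt$statistic)
      p <- wt$p.value
    } else if (d$test == "friedman") {
      lev <- unique(data[[d$within]])
      wide <- .pair_values(data, d$value, d$within, d$id, lev)
      ft <- friedman.test(as.matrix(wide))
      stat <- unname(ft$statistic)
      p <- ft$p.value
    } else {
      stop("unknown test: ", d$test)
    }
    data.frame(test = d$test, label = label, statistic = stat,
               p_value = p, bonferroni_adjusted_alpha = adj,
               significant = p < adj, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# reshape a long table to an id x level matrix, failing on incomplete or
# duplicated pairings
.pair_values <- function(data, value, within, id, levels) {
  sub <- data[data[[within]] %in% levels, c(id, within, value)]
  ids <- unique(sub[[id]])
  out <- matrix(NA_real_, length(ids), length(levels),
                dimnames = list(ids, levels))
  for (l in levels) {
    rows <- sub[sub[[within]] == l, ]
    if (any(duplicated(rows[[id]]))) {
      stop("duplicated id within level '", l, "'")
    }
    out[match(rows[[id]], ids), l] <- rows[[value]]
  }
  if (any(is.na(out))) stop("pairing mismatch: incomplete blocks")
  out
}

#' Verify simulated degeneration against joint space narrowing
#'
#' Fits an ordinary least squares model of each knee's maximum
#' compartmental JSN on its overall degenerated fraction (adjusted
#' R-squared with the F-test p-value) and cross-tabulates the compartment
#' with the larger simulated degeneration against the compartment with
#' the larger JSN.
#'
#' @param jsn_table `data.frame` with columns `id`, `jsn_medial`,
#'   `jsn_lateral` (percent).
#' @param degeneration_table `data.frame` with columns `id`,
#'   `fraction_medial`, `fraction_lateral`, `fraction_overall`.
#' @return List with `adjusted_r2`, `p_value`, the 2x2 `crosstab`, and
#'   the fitted `model`.
#' @export
verify_jsn_vs_degeneration <- function(jsn_table, degeneration_table) {
  merged <- merge(jsn_table, degeneration_table, by = "id")
  if (nrow(merged) < 3) stop("need at least 3 matched knees")
  merged$max_jsn <- pmax(merged$jsn_medial, merged$jsn_lateral)
  fit <- lm(max_jsn ~ fraction_overall, data = merged)
  s <- summary(fit)
  fstat <- s$fstatistic
  p <- if (is.null(fstat)) NA_real_ else {
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  lv <- c("medial", "lateral")
  crosstab <- table(
    sim_larger = factor(ifelse(merged$fraction_medial >=
                                 merged$fraction_lateral,
                               "medial", "lateral"), levels = lv),
    jsn_larger = factor(ifelse(merged$jsn_medial >= merged$jsn_lateral,
                               "medial", "lateral"), levels = lv))
  list(adjusted_r2 = s$adj.r.squared, p_value = p, crosstab = crosstab,
       model = fit)
}
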