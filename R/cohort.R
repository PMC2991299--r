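#' Percentage of overlap between two segmentations
#'
#' Inter-operator reproducibility of a segmentation is summarized per cardiac
#' phase as the percentage of overlap between the two masks. The default is
#' the Dice coefficient, `200 |A n B| / (|A| + |B|)`; two empty masks are
#' identical and score 100. Intersection-over-union (Jaccard) is available
#' as an option.
#'
#' @param maskA,maskB logical matrices (or arrays) of identical shape.
#' @param method `"dice"` or `"jaccard"`.
#' @return overlap percentage in `[0, 100]`.
#' @export
overlap_percentage <- function(maskA, maskB, method = c("dice", "jaccard")) {
  method <- match.arg(method)
  if (!identical(dim(maskA), dim(maskB)))
    stop("mask shapes differ")
  a <- sum(maskA); b <- sum(maskB); i <- sum(maskA & maskB)
  if (a + b == 0) return(100)
  if (method == "dice") 200 * i / (a + b) else 100 * i / (a + b - i)
}

#' Inter-operator variability of a repeated measurement
#'
#' The absolute difference of the two measurements expressed as a percentage
#' of their mean. Two zeros have zero variability by convention.
#'
#' @param x1,x2 the two repeated measurements.
#' @return percentage.
#' @export
variability_pct <- function(x1, x2) {
  stopifnot(is.numeric(x1), is.numeric(x2), length(x1) == length(x2))
  m <- (x1 + x2) / 2
  d <- abs(x1 - x2)
  out <- ifelse(d == 0, 0, 100 * d / m)
  if (any(m == 0 & d != 0))
    stop("variability undefined: mean of the pair is 0 with nonzero difference")
  out
}

#' Mann-Whitney U test
#'
#' Non-parametric two-sample comparison. The U statistic uses midranks for
#' ties; the two-sided p-value is exact (distribution of U) when the pooled
#' sample is small (`nA + nB <= 12`) and tie-free, and otherwise uses the
#' normal approximation with tie and continuity corrections.
#'
#' @param groupA,groupB numeric vectors (each non-empty).
#' @return list with `U` (for `groupA` vs `groupB`), `p` (two-sided) and
#'   `method`.
#' @export
mann_whitney <- function(groupA, groupB) {
  groupA <- groupA[!is.na(groupA)]; groupB <- groupB[!is.na(groupB)]
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  nA <- length(groupA); nB <- length(groupB)
  r <- rank(c(groupA, groupB))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- any(duplicated(c(groupA, groupB)))
  exact <- (nA + nB) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, exact = exact, correct = TRUE))
  list(U = unname(U), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Pearson correlation with least-squares line
#'
#' @param x,y numeric vectors of equal length (n >= 3), e.g. a CMR parameter
#'   against its echocardiographic counterpart.
#' @return list with `r`, `slope`, `intercept`, `p` (two-sided test of
#'   `r = 0`) and `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y)
  slope <- stats::cov(x, y) / stats::var(x)
  list(r = unname(ct$estimate), slope = slope,
       intercept = mean(y) - slope * mean(x),
       p = ct$p.value, n = n)
}

#' ROC analysis with Youden-optimal operating point
#'
#' Sweeps all decision thresholds (midpoints between consecutive sorted
#' unique values, plus one beyond each extreme), in both orientations; the
#' orientation with AUC >= 0.5 is reported. AUC is the pairwise concordance
#' probability (trapezoidal area). The optimal threshold maximizes Youden's
#' J = sensitivity + specificity - 1, ties broken by higher accuracy, then
#' lower threshold; sensitivity, specificity, NPV, PPV and accuracy are
#' reported at that point.
#'
#' @param values numeric marker values, one per subject.
#' @param labels group labels, same length.
#' @param positive_group the label counted as positive (diseased).
#' @return object of class `roc_result`: `auc`, `direction` (`">="` when
#'   positives have the higher values), `optimal_threshold`, `sensitivity`,
#'   `specificity`, `npv`, `ppv`, `accuracy`, and the full `sweep` data frame.
#' @export
roc <- function(values, labels, positive_group) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  pos <- labels == positive_group
  if (!any(pos) || all(pos)) stop("both classes must be present")
  np <- sum(pos); nn <- sum(!pos)
  # concordance AUC via midranks (positive class higher)
  r <- rank(values)
  auc_hi <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  direction <- if (auc_hi >= 0.5) ">=" else "<="
  auc <- max(auc_hi, 1 - auc_hi)
  sv <- sort(unique(values))
  thr <- c(sv[1] - 1, (utils::head(sv, -1) + utils::tail(sv, -1)) / 2,
           sv[length(sv)] + 1)
  call_pos <- if (direction == ">=") {
    function(th) values >= th
  } else {
    function(th) values <= th
  }
  sweep <- do.call(rbind, lapply(thr, function(th) {
    cp <- call_pos(th)
    tp <- sum(cp & pos); fp <- sum(cp & !pos)
    fn <- np - tp; tn <- nn - fp
    data.frame(threshold = th,
               sensitivity = tp / np, specificity = tn / nn,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               accuracy = (tp + tn) / (np + nn))
  }))
  sweep$youden <- sweep$sensitivity + sweep$specificity - 1
  o <- order(-sweep$youden, -sweep$accuracy, sweep$threshold)
  best <- sweep[o[1], ]
  structure(list(auc = auc, direction = direction,
                 optimal_threshold = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 npv = best$npv, ppv = best$ppv, accuracy = best$accuracy,
                 sweep = sweep),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (positives %s threshold)\n", x$auc, x$direction))
  cat(sprintf("  optimal threshold %.4g: sens %.2f, spec %.2f, NPV %.2f, PPV %.2f, acc %.2f\n",
              x$optimal_threshold, x$sensitivity, x$specificity, x$npv,
              x$ppv, x$accuracy))
  invisible(x)
}

#' Cohort statistics table
#'
#' For each parameter column of a per-subject table, computes group means and
#' standard deviations, the Mann-Whitney p-value between the two groups, and
#' the full ROC characterization of the parameter's ability to separate them.
#'
#' @param table data frame with one row per subject.
#' @param group_col name of the binary group column.
#' @param positive_group label of the positive (patient) group; defaults to
#'   the rarer level.
#' @param params parameter column names; defaults to all numeric columns
#'   except `group_col`.
#' @return data frame with one row per parameter: `mean_neg`, `sd_neg`,
#'   `mean_pos`, `sd_pos`, `p_value`, `Sensitivity`, `Specificity`, `NPV`,
#'   `PPV`, `Accuracy`, `ROC_threshold`, `AUC`.
#' @export
cohort_stats <- function(table, group_col = "group", positive_group = NULL,
                         params = NULL) {
  stopifnot(is.data.frame(table), group_col %in% names(table))
  g <- table[[group_col]]
  lev <- unique(stats::na.omit(g))
  if (length(lev) != 2L) stop("group column must have exactly two levels")
  if (is.null(positive_group))
    positive_group <- lev[which.min(tabulate(match(g, lev)))]
  neg_group <- setdiff(lev, positive_group)
  if (is.null(params))
    params <- names(table)[vapply(table, is.numeric, logical(1)) &
                             names(table) != group_col]
  rows <- lapply(params, function(pm) {
    v <- table[[pm]]
    vp <- v[g == positive_group & is.finite(v)]
    vn <- v[g == neg_group & is.finite(v)]
    mw <- mann_whitney(vn, vp)
    rr <- roc(v[is.finite(v)], g[is.finite(v)], positive_group)
    data.frame(parameter = pm,
               mean_neg = mean(vn), sd_neg = stats::sd(vn),
               mean_pos = mean(vp), sd_pos = stats::sd(vp),
               p_value = mw$p,
               Sensitivity = rr$sensitivity, Specificity = rr$specificity,
               NPV = rr$npv, PPV = rr$ppv, Accuracy = rr$accuracy,
               ROC_threshold = rr$optimal_threshold, AUC = rr$auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
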