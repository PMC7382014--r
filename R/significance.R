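# Two-group significance screening of the feature table.
#
# For each of the 848 features, a two-sided two-group test of PD vs control
# record values; the report counts, per feature family, how many of the 106
# key points pass each significance level (conventionally .05 and .005).
# Counts are of *raw* significance -- no multiple-testing correction, by
# design: the screen characterizes which families carry signal, it does not
# certify individual points.

#' Two-group test of one feature
#'
#' Welch's unequal-variance t-test by default (the robust default when group
#' variances differ, as tremor features do); `"wilcoxon"` gives a
#' Mann-Whitney U alternative.  Degenerate policy: when both groups have
#' zero variance, p = 1 if the means are equal, else p = 0 in the limit.
#'
#' @param values_pd,values_ctrl Per-record feature values (>= 2 each).
#' @param method `"welch"` or `"wilcoxon"`.
#' @return Two-sided p-value in \[0, 1\].
#' @export
feature_test <- function(values_pd, values_ctrl,
                         method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  n1 <- length(values_pd); n2 <- length(values_ctrl)
  if (n1 < 2 || n2 < 2) stop("need >= 2 records per group")
  if (method == "wilcoxon") {
    if (stats::var(values_pd) == 0 && stats::var(values_ctrl) == 0 &&
        values_pd[1] == values_ctrl[1]) {
      return(1)
    }
    return(stats::wilcox.test(values_pd, values_ctrl, exact = FALSE)$p.value)
  }
  .welch_p(mean(values_pd), mean(values_ctrl),
           stats::var(values_pd), stats::var(values_ctrl), n1, n2)
}

.welch_p <- function(m1, m2, v1, v2, n1, n2) {
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(if (m1 == m2) 1 else 0)
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

#' Significance screen of a feature table
#'
#' @param table A [feature_table()].
#' @param alphas Significance levels (default `c(0.05, 0.005)`).
#' @param method Test, see [feature_test()].
#' @param aggregate_subjects If `TRUE`, records of one subject are averaged
#'   before testing, making subjects (independent units) the test units;
#'   default `FALSE` treats records as units.
#' @return Object of class `significance_report`: list with `pvalues`
#'   (data.frame: point, feature, p -- 848 rows) and `counts` (data.frame:
#'   feature family x one column per alpha, values = number of the 106 key
#'   points with p < alpha, plus a Total row).
#' @export
count_significant <- function(table, alphas = c(0.05, 0.005),
                              method = c("welch", "wilcoxon"),
                              aggregate_subjects = FALSE) {
  method <- match.arg(method)
  parts <- split_feature_table(table)
  x <- parts$x
  if (aggregate_subjects) {
    agg <- stats::aggregate(x, by = list(subject = parts$groups), FUN = mean)
    lab <- vapply(split(as.character(parts$labels), parts$groups),
                  function(l) l[1], "")
    x <- as.matrix(agg[, -1, drop = FALSE])
    is_pd <- lab[agg$subject] == "PD"
  } else {
    is_pd <- parts$labels == "PD"
  }
  if (sum(is_pd) < 2 || sum(!is_pd) < 2) stop("need >= 2 units per group")

  p <- if (method == "welch") {
    x1 <- x[is_pd, , drop = FALSE]; x2 <- x[!is_pd, , drop = FALSE]
    n1 <- nrow(x1); n2 <- nrow(x2)
    mapply(.welch_p, colMeans(x1), colMeans(x2),
           apply(x1, 2, stats::var), apply(x2, 2, stats::var),
           MoreArgs = list(n1 = n1, n2 = n2))
  } else {
    apply(x, 2, function(v) feature_test(v[is_pd], v[!is_pd], "wilcoxon"))
  }

  nm <- colnames(x)
  sp <- strsplit(nm, "__", fixed = TRUE)
  point <- vapply(sp, `[`, "", 1)
  feat <- vapply(sp, `[`, "", 2)
  pvals <- data.frame(point = point, feature = feat, p = unname(p),
                      stringsAsFactors = FALSE)
  counts <- data.frame(feature = FEATURE_NAMES, stringsAsFactors = FALSE)
  for (a in alphas) {
    counts[[sprintf("alpha_%g", a)]] <- vapply(FEATURE_NAMES, function(f) {
      sum(pvals$p[pvals$feature == f] < a)
    }, numeric(1))
  }
  if (length(alphas)) {
    counts <- rbind(counts, data.frame(
      feature = "Total",
      as.list(stats::setNames(colSums(counts[, -1, drop = FALSE]),
                              names(counts)[-1])),
      stringsAsFactors = FALSE))
  }
  structure(list(pvalues = pvals, counts = counts, alphas = alphas,
                 method = method),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat("<significance_report> (", x$method, " test)\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}
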