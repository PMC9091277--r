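# Ranking-performance evaluation of SELV and competitor scores on labeled
# variants. Orientation is explicit everywhere: a score declares whether
# high or low values mark pathogenicity, and curves are computed after
# orienting so that AUC is always the probability that a pathogenic variant
# out-ranks a neutral one (ties counting 1/2).

#' ROC curve and area
#'
#' Enumerates one operating point per distinct score value (tied scores move
#' together) and computes the area by the trapezoidal rule, which with
#' grouped ties equals the Mann-Whitney pair-ordering probability with ties
#' counted 1/2. For `lower_is_pathogenic` scores (such as SELV) the scores
#' are negated internally, so the stored curve and AUC always read in the
#' pathogenic direction; the reported thresholds stay on the original scale.
#'
#' @param scores numeric scores; pairs with a missing score or label are
#'   excluded (count reported in the result).
#' @param labels 0 (neutral) / 1 (pathogenic); both classes required.
#' @param orientation `"higher_is_pathogenic"` or `"lower_is_pathogenic"`.
#' @return object of class `selv_roc`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   `orientation`, class sizes and the missing-pair count. The curve starts
#'   at (0, 0) and ends at (1, 1).
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("higher_is_pathogenic",
                                      "lower_is_pathogenic")) {
  orientation <- match.arg(orientation)
  d <- prep_scores_labels(scores, labels)
  s <- if (orientation == "lower_is_pathogenic") -d$scores else d$scores
  y <- d$labels
  P <- sum(y == 1)
  N <- sum(y == 0)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  y <- y[ord]
  last <- cumsum(rle(s)$lengths)          # last index of each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  thr <- s[last]
  thresholds <- if (orientation == "lower_is_pathogenic") c(-Inf, -thr) else c(Inf, thr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc,
                 orientation = orientation, n_pathogenic = P, n_neutral = N,
                 n_missing = d$n_missing),
            class = "selv_roc")
}

#' @exportS3Method base::print
print.selv_roc <- function(x, ...) {
  cat(sprintf("<selv_roc> AUC = %.4f (%s; %d pathogenic, %d neutral, %d pair(s) dropped)\n",
              x$auc, x$orientation, x$n_pathogenic, x$n_neutral, x$n_missing))
  invisible(x)
}

#' Precision-recall curve and area
#'
#' Precision and recall are evaluated at every distinct score cut (ties
#' grouped); the area is the step-wise sum of precision over each recall
#' increment, i.e. average precision. Linear interpolation in PR space is
#' deliberately not used, as it over-estimates the area.
#'
#' @inheritParams roc_curve
#' @return object of class `selv_pr`: `recall`, `precision`, `pr_auc`,
#'   `orientation`, class sizes. With a constant score the area equals the
#'   prevalence of the pathogenic class.
#' @export
pr_curve <- function(scores, labels,
                     orientation = c("higher_is_pathogenic",
                                     "lower_is_pathogenic")) {
  orientation <- match.arg(orientation)
  d <- prep_scores_labels(scores, labels)
  s <- if (orientation == "lower_is_pathogenic") -d$scores else d$scores
  y <- d$labels
  P <- sum(y == 1)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  y <- y[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  recall <- tp / P
  precision <- tp / (tp + fp)
  pr_auc <- sum(diff(c(0, recall)) * precision)
  structure(list(recall = c(0, recall),
                 precision = c(precision[1L], precision),
                 pr_auc = pr_auc, orientation = orientation,
                 n_pathogenic = P, n_neutral = sum(y == 0),
                 n_missing = d$n_missing,
                 interpolation = "step (average precision)"),
            class = "selv_pr")
}

#' @exportS3Method base::print
print.selv_pr <- function(x, ...) {
  cat(sprintf("<selv_pr> PR-AUC = %.4f (%s; %d pathogenic, %d neutral)\n",
              x$pr_auc, x$orientation, x$n_pathogenic, x$n_neutral))
  invisible(x)
}

# DeLong placement values for one score: auc plus the per-positive (V10)
# and per-negative (V01) components whose empirical covariances estimate
# the sampling variance of the AUC.
delong_placements <- function(scores, labels) {
  xp <- scores[labels == 1]
  xn <- scores[labels == 0]
  M <- outer(xp, xn, function(p, q) (p > q) + 0.5 * (p == q))
  list(auc = mean(M), v10 = rowMeans(M), v01 = colMeans(M))
}

#' Paired DeLong test of two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same variants. Placement
#' values are computed per observation for each score, the variance of the
#' AUC difference is estimated from their paired covariances, and the
#' D-statistic `D = (auc_a - auc_b) / sqrt(var(diff))` is referred to a
#' standard normal for a two-sided p-value. Only observations with both
#' scores present are used (pairwise-complete); identical or strictly
#' monotone-related score vectors give exactly D = 0, p = 1.
#'
#' @param scores_a,scores_b the two score vectors, aligned to `labels`.
#' @param labels 0/1 labels.
#' @param orientation_a,orientation_b pathogenic direction of each score.
#' @return object of class `selv_auc_cmp`: `auc_a`, `auc_b`, `d_statistic`,
#'   `p_value`, `var_diff`, `n_paired`.
#' @export
compare_auc <- function(scores_a, scores_b, labels,
                        orientation_a = "higher_is_pathogenic",
                        orientation_b = "higher_is_pathogenic") {
  orientation_a <- check_orientation(orientation_a)
  orientation_b <- check_orientation(orientation_b)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("`scores_a`, `scores_b` and `labels` must have the same length",
         call. = FALSE)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  a <- as.numeric(scores_a[keep])
  b <- as.numeric(scores_b[keep])
  y <- as.numeric(labels[keep])
  if (!all(y %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  m <- sum(y == 1)
  n0 <- sum(y == 0)
  if (m < 2L || n0 < 2L)
    stop("at least 2 observations per class are required", call. = FALSE)
  if (orientation_a == "lower_is_pathogenic") a <- -a
  if (orientation_b == "lower_is_pathogenic") b <- -b

  pa <- delong_placements(a, y)
  pb <- delong_placements(b, y)
  diff <- pa$auc - pb$auc
  var_diff <- stats::var(pa$v10 - pb$v10) / m + stats::var(pa$v01 - pb$v01) / n0
  if (var_diff == 0) {
    if (diff == 0) {
      d_stat <- 0
      p <- 1
    } else {
      stop("degenerate comparison: zero variance of the AUC difference with unequal AUCs",
           call. = FALSE)
    }
  } else {
    d_stat <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(d_stat))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, d_statistic = d_stat,
                 p_value = p, var_diff = var_diff, n_paired = length(y)),
            class = "selv_auc_cmp")
}

#' @exportS3Method base::print
print.selv_auc_cmp <- function(x, ...) {
  cat(sprintf("<selv_auc_cmp> AUC %.4f vs %.4f, D = %.3f, p = %.4g (n = %d paired)\n",
              x$auc_a, x$auc_b, x$d_statistic, x$p_value, x$n_paired))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' the asymptotic two-sided Kolmogorov approximation (appropriate for the
#' large samples this package targets). Missing values are dropped.
#'
#' @param sample_a,sample_b numeric samples, both non-empty.
#' @return object of class `selv_ks`: `d`, `p_value`, sample sizes.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = FALSE))
  structure(list(d = unname(kt$statistic), p_value = kt$p.value,
                 n_a = length(a), n_b = length(b)),
            class = "selv_ks")
}

#' @exportS3Method base::print
print.selv_ks <- function(x, ...) {
  cat(sprintf("<selv_ks> D = %.4f, p = %.4g (n = %d vs %d)\n",
              x$d, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value (sum of hypergeometric probabilities no larger
#' than that of the observed table) and the conditional maximum-likelihood
#' odds ratio; complete separation reports an infinite odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return object of class `selv_fisher`: `table`, `odds_ratio`, `p_value`.
#' @export
fisher_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("`table` must be a 2x2 matrix", call. = FALSE)
  if (anyNA(m) || any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("cells must be non-negative integers", call. = FALSE)
  if (sum(m) == 0)
    stop("at least one non-zero margin is required", call. = FALSE)
  m <- round(m)
  ft <- stats::fisher.test(m)
  structure(list(table = m, odds_ratio = unname(ft$estimate),
                 p_value = min(1, ft$p.value)),
            class = "selv_fisher")
}

#' @exportS3Method base::print
print.selv_fisher <- function(x, ...) {
  cat(sprintf("<selv_fisher> OR = %.4g, p = %.4g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' Benchmark SELV against competitor scores
#'
#' For each competitor column the evaluation is restricted to the variants
#' where that competitor is available (pairwise-complete with SELV, which is
#' defined everywhere); on that subset the report holds ROC and PR results
#' for both the competitor and SELV, plus the paired DeLong comparison. The
#' number of variants dropped for missing competitor values is always
#' reported. SELV is evaluated on the full labeled set as well.
#'
#' @param scored a scored variant table (from [score_variants()]) with a
#'   `label` column and competitor-score columns.
#' @param score_columns competitor columns; default the table's
#'   `score_columns` attribute.
#' @param context optional genomic-context filter (character vector matched
#'   against the `context` column).
#' @param orientations named list/vector giving each competitor's pathogenic
#'   direction; unlisted competitors default to `"higher_is_pathogenic"`.
#'   SELV itself is always evaluated as `"lower_is_pathogenic"` (low
#'   observed variability marks suspicious positions).
#' @return object of class `selv_benchmark`; see [benchmark_summary()] and
#'   [write_benchmark_json()].
#' @export
benchmark_report <- function(scored, score_columns = NULL, context = NULL,
                             orientations = NULL) {
  x <- as.data.frame(scored, stringsAsFactors = FALSE)
  if (!all(c("label", "selv") %in% names(x)))
    stop("`scored` must have `label` and `selv` columns (run score_variants first)",
         call. = FALSE)
  if (!is.null(context) && "context" %in% names(x))
    x <- x[x$context %in% context, , drop = FALSE]
  x <- x[!is.na(x$label), , drop = FALSE]
  if (is.null(score_columns))
    score_columns <- attr(scored, "score_columns", exact = TRUE) %||% character(0)
  score_columns <- intersect(score_columns, names(x))
  selv_or <- "lower_is_pathogenic"

  overall <- list(n = nrow(x),
                  roc = roc_curve(x$selv, x$label, selv_or),
                  pr = pr_curve(x$selv, x$label, selv_or))

  competitors <- lapply(score_columns, function(sc) {
    or <- as.character(orientations[[sc]] %||% "higher_is_pathogenic")
    keep <- !is.na(x[[sc]])
    sub <- x[keep, , drop = FALSE]
    list(score = sc, orientation = or,
         n_used = nrow(sub), n_dropped = sum(!keep),
         roc = roc_curve(sub[[sc]], sub$label, or),
         pr = pr_curve(sub[[sc]], sub$label, or),
         selv_roc = roc_curve(sub$selv, sub$label, selv_or),
         selv_pr = pr_curve(sub$selv, sub$label, selv_or),
         comparison = compare_auc(sub$selv, sub[[sc]], sub$label,
                                  orientation_a = selv_or,
                                  orientation_b = or))
  })
  names(competitors) <- score_columns

  structure(list(selv = overall, competitors = competitors,
                 metadata = list(selv_orientation = selv_or,
                                 pr_interpolation = "step (average precision)",
                                 context = context)),
            class = "selv_benchmark")
}

#' Flatten a benchmark report to a data frame
#'
#' One row per evaluated score: the SELV row on the full labeled set, then
#' one row per competitor on its pairwise-complete subset with the SELV AUC
#' on that same subset and the DeLong D and p of the comparison.
#'
#' @param report a `selv_benchmark` object.
#' @return data frame with columns `score`, `orientation`, `n_used`,
#'   `n_dropped`, `auc`, `pr_auc`, `selv_auc_same_subset`, `d_statistic`,
#'   `p_value`.
#' @export
benchmark_summary <- function(report) {
  stopifnot(inherits(report, "selv_benchmark"))
  rows <- list(data.frame(score = "selv",
                          orientation = report$metadata$selv_orientation,
                          n_used = report$selv$n, n_dropped = 0L,
                          auc = report$selv$roc$auc,
                          pr_auc = report$selv$pr$pr_auc,
                          selv_auc_same_subset = report$selv$roc$auc,
                          d_statistic = NA_real_, p_value = NA_real_,
                          stringsAsFactors = FALSE))
  for (comp in report$competitors) {
    rows[[length(rows) + 1L]] <-
      data.frame(score = comp$score, orientation = comp$orientation,
                 n_used = comp$n_used, n_dropped = comp$n_dropped,
                 auc = comp$roc$auc, pr_auc = comp$pr$pr_auc,
                 selv_auc_same_subset = comp$selv_roc$auc,
                 d_statistic = comp$comparison$d_statistic,
                 p_value = comp$comparison$p_value,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @exportS3Method base::print
print.selv_benchmark <- function(x, ...) {
  cat("<selv_benchmark>\n")
  print(benchmark_summary(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a benchmark report as JSON
#'
#' Machine-readable dump of the per-score AUC / PR-AUC / n values and the
#' pairwise DeLong comparisons against SELV, plus the report metadata
#' (orientations, PR interpolation rule).
#'
#' @param report a `selv_benchmark` object.
#' @param path output file.
#' @export
write_benchmark_json <- function(report, path) {
  stopifnot(inherits(report, "selv_benchmark"))
  comp_list <- lapply(report$competitors, function(comp) {
    list(orientation = comp$orientation, n_used = comp$n_used,
         n_dropped = comp$n_dropped, auc = comp$roc$auc,
         pr_auc = comp$pr$pr_auc, selv_auc_same_subset = comp$selv_roc$auc,
         d_statistic = comp$comparison$d_statistic,
         p_value = comp$comparison$p_value)
  })
  out <- list(selv = list(n = report$selv$n, auc = report$selv$roc$auc,
                          pr_auc = report$selv$pr$pr_auc),
              competitors = comp_list,
              metadata = report$metadata)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Dump ROC or PR curve points as TSV
#'
#' @param curve a `selv_roc` or `selv_pr` object.
#' @param path output file.
#' @export
write_curve_tsv <- function(curve, path) {
  if (inherits(curve, "selv_roc")) {
    df <- data.frame(threshold = curve$thresholds, fpr = curve$fpr,
                     tpr = curve$tpr)
  } else if (inherits(curve, "selv_pr")) {
    df <- data.frame(recall = curve$recall, precision = curve$precision)
  } else stop("`curve` must be a selv_roc or selv_pr object", call. = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
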