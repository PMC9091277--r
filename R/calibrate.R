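# Youden-index threshold calibration and pathogenic/neutral classification.
# Decisions use the inclusive rule: with a lower_is_pathogenic score a
# variant is called pathogenic when its score is <= the threshold, so
# SELV = 0 variants (positions with no reported variability) are called
# pathogenic at any positive threshold.

#' Sensitivity and specificity at a fixed threshold
#'
#' Applies the inclusive decision rule at `threshold` and reports the
#' confusion-matrix rates: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).
#'
#' @param scores numeric scores (missing pairs dropped).
#' @param labels 0/1 labels, both classes required.
#' @param threshold the cut-off.
#' @param orientation pathogenic direction of the score.
#' @return object of class `selv_confusion`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `threshold`, `orientation`.
#' @export
evaluate_at_threshold <- function(scores, labels, threshold,
                                  orientation = c("higher_is_pathogenic",
                                                  "lower_is_pathogenic")) {
  orientation <- match.arg(orientation)
  d <- prep_scores_labels(scores, labels)
  call_patho <- decide_pathogenic(d$scores, threshold, orientation)
  y <- d$labels
  tp <- sum(call_patho & y == 1)
  fp <- sum(call_patho & y == 0)
  fn <- sum(!call_patho & y == 1)
  tn <- sum(!call_patho & y == 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 threshold = threshold, orientation = orientation),
            class = "selv_confusion")
}

#' @exportS3Method base::print
print.selv_confusion <- function(x, ...) {
  cat(sprintf("<selv_confusion> threshold %.6g (%s): sensitivity %.4f, specificity %.4f\n",
              x$threshold, x$orientation, x$sensitivity, x$specificity))
  invisible(x)
}

#' Youden-index threshold calibration
#'
#' Evaluates J = sensitivity + specificity - 1 at every candidate cut-off —
#' the midpoints between consecutive distinct scores, plus -Inf and +Inf
#' sentinels — under the inclusive decision rule, and returns the
#' maximizing cut. Ties on J are broken toward higher sensitivity (in a
#' prioritization setting a missed pathogenic variant costs more than a
#' false alarm), then toward the lower threshold. The reported sensitivity
#' and specificity are resubstitution values on the calibration data.
#'
#' @inheritParams evaluate_at_threshold
#' @param context genomic-context tag recorded in the calibration (used by
#'   [classify_variants()] to match variants to calibrations).
#' @return object of class `selv_calibration`: `context`, `threshold`,
#'   `sensitivity`, `specificity`, `youden_j`, `orientation`, class sizes
#'   and a provenance checksum of the calibration set.
#' @export
youden_threshold <- function(scores, labels,
                             orientation = c("higher_is_pathogenic",
                                             "lower_is_pathogenic"),
                             context = "unspecified") {
  orientation <- match.arg(orientation)
  d <- prep_scores_labels(scores, labels)
  s <- d$scores
  y <- d$labels
  u <- sort(unique(s))
  cand <- if (length(u) > 1L) {
    c(-Inf, (u[-length(u)] + u[-1L]) / 2, Inf)
  } else c(-Inf, Inf)
  P <- sum(y == 1)
  N <- sum(y == 0)
  stats_at <- vapply(cand, function(t) {
    p <- decide_pathogenic(s, t, orientation)
    c(sens = sum(p & y == 1) / P, spec = sum(!p & y == 0) / N)
  }, numeric(2))
  sens <- stats_at["sens", ]
  spec <- stats_at["spec", ]
  J <- sens + spec - 1
  pick <- order(-J, -sens, cand)[1L]
  structure(list(context = context, threshold = cand[pick],
                 sensitivity = sens[pick], specificity = spec[pick],
                 youden_j = J[pick], orientation = orientation,
                 n_pathogenic = P, n_neutral = N,
                 calibration_hash = sprintf("%d:%d:%.10g", P, N, sum(s))),
            class = "selv_calibration")
}

#' @exportS3Method base::print
print.selv_calibration <- function(x, ...) {
  cat(sprintf("<selv_calibration> context '%s': threshold %.6g (%s)\n",
              x$context, x$threshold, x$orientation))
  cat(sprintf("  J = %.4f (sensitivity %.4f, specificity %.4f; resubstitution, %d/%d)\n",
              x$youden_j, x$sensitivity, x$specificity,
              x$n_pathogenic, x$n_neutral))
  invisible(x)
}

# normalize a single calibration or a list into a named-by-context list
calibration_set <- function(calibrations) {
  if (inherits(calibrations, "selv_calibration"))
    calibrations <- list(calibrations)
  if (!length(calibrations) ||
      !all(vapply(calibrations, inherits, logical(1), "selv_calibration")))
    stop("`calibrations` must be one or more selv_calibration objects",
         call. = FALSE)
  stats::setNames(calibrations,
                  vapply(calibrations, `[[`, character(1), "context"))
}

#' Classify scored variants with context-specific calibrations
#'
#' Applies to each variant the calibration matching its `context` tag and
#' predicts `"pathogenic"` or `"neutral"` under the inclusive decision rule.
#' The prediction is a deterministic function of (selv, threshold,
#' orientation), so classification is idempotent and order-independent.
#'
#' @param scored a scored variant table with `selv` and (optionally)
#'   `context` columns; variants without a context use `"unspecified"`.
#' @param calibrations a `selv_calibration` or list of them (one per
#'   context). A variant context with no calibration is an error listing
#'   the missing contexts.
#' @return the input table with `predicted_class` and `threshold_used`
#'   columns appended; per-context prediction counts are attached as the
#'   `"counts"` attribute.
#' @export
classify_variants <- function(scored, calibrations) {
  cals <- calibration_set(calibrations)
  x <- as.data.frame(scored, stringsAsFactors = FALSE)
  if (!"selv" %in% names(x))
    stop("`scored` must have a `selv` column (run score_variants first)",
         call. = FALSE)
  ctx <- if ("context" %in% names(x)) {
    ifelse(is.na(x$context), "unspecified", as.character(x$context))
  } else rep("unspecified", nrow(x))
  missing_ctx <- setdiff(unique(ctx), names(cals))
  if (length(missing_ctx))
    stop("no calibration for context(s): ",
         paste(missing_ctx, collapse = ", "), call. = FALSE)

  thr <- vapply(ctx, function(cc) cals[[cc]]$threshold, numeric(1),
                USE.NAMES = FALSE)
  or <- vapply(ctx, function(cc) cals[[cc]]$orientation, character(1),
               USE.NAMES = FALSE)
  patho <- ifelse(or == "lower_is_pathogenic", x$selv <= thr, x$selv >= thr)
  x$predicted_class <- ifelse(patho, "pathogenic", "neutral")
  x$threshold_used <- thr

  attr(x, "counts") <- table(context = ctx, predicted = x$predicted_class)
  attr(x, "build") <- attr(scored, "build", exact = TRUE)
  attr(x, "score_columns") <- attr(scored, "score_columns", exact = TRUE)
  class(x) <- c("selv_scored", "data.frame")
  x
}

#' Write calibrations to a JSON file
#'
#' Serializes one or more context calibrations (threshold, orientation,
#' resubstitution metrics, class sizes, provenance checksum) so that
#' classification runs are reproducible and auditable.
#'
#' @param calibrations a `selv_calibration` or list of them.
#' @param path output file.
#' @export
write_calibration <- function(calibrations, path) {
  cals <- calibration_set(calibrations)
  jsonlite::write_json(lapply(cals, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read calibrations from a JSON file
#'
#' @param path file written by [write_calibration()].
#' @return named list of `selv_calibration` objects keyed by context.
#' @export
read_calibration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(cal) {
    cal$threshold <- as.numeric(cal$threshold)  # "Inf"/"-Inf" round-trip
    structure(cal, class = "selv_calibration")
  })
}
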