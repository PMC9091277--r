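# internal helpers shared across modules

.BASES <- c("A", "C", "G", "T")

# label used for the pooled (all-ancestries) stratum; empty/NA population
# tags map here because R named lists cannot be indexed by "".
.COMBINED <- "combined"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonicalize contig names
#'
#' Maps the common mitochondrial contig aliases (`chrM`, `MT`, `chrMT`, `M`)
#' onto one canonical name so that frequency resources and query variants
#' using different conventions still land on the same locus. The canonical
#' name defaults to `"chrM"` and can be changed globally via
#' `options(selv.mito_contig = ...)`.
#'
#' @param contig character vector of contig names.
#' @param mito canonical name for the mitochondrial contig.
#' @return character vector with mitochondrial aliases replaced.
#' @export
canonical_contig <- function(contig, mito = getOption("selv.mito_contig", "chrM")) {
  x <- as.character(contig)
  x[x %in% c("chrM", "MT", "chrMT", "M")] <- mito
  x
}

is_snv <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  !is.na(ref) & !is.na(alt) & ref %in% .BASES & alt %in% .BASES & ref != alt
}

locus_key <- function(contig, position) {
  paste0(canonical_contig(contig), ":", as.integer(position))
}

# validate scores/labels pairs shared by roc/pr/youden; drops pairs with a
# missing score, errors on single-class labels.
prep_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  labels <- as.numeric(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- as.numeric(scores[keep])
  labels <- labels[keep]
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 (neutral) or 1 (pathogenic)", call. = FALSE)
  if (!any(labels == 1) || !any(labels == 0))
    stop("both pathogenic (1) and neutral (0) labels are required", call. = FALSE)
  list(scores = scores, labels = labels, n_missing = sum(!keep))
}

.ORIENTATIONS <- c("higher_is_pathogenic", "lower_is_pathogenic")

check_orientation <- function(orientation) {
  match.arg(orientation, .ORIENTATIONS)
}

# inclusive decision rule: pathogenic iff score is at or beyond the cut-off
# in the pathogenic direction.
decide_pathogenic <- function(scores, threshold, orientation) {
  if (orientation == "lower_is_pathogenic") scores <= threshold else scores >= threshold
}
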