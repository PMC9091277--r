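#' Shannon entropy of locus variability (SELV)
#'
#' Computes the SELV statistic for one locus from the vector of population
#' allele frequencies reported there:
#' \deqn{SELV = -\sum_{i=1}^{n} F_i \log(F_i)}
#' where \eqn{F_i} is the reported frequency of the i-th variant at the
#' position. Frequencies are used exactly as reported: no renormalization is
#' performed and the reference allele contributes no term. The usual entropy
#' conventions \eqn{0 \log 0 = 0} and \eqn{1 \log 1 = 0} apply, so the value
#' is always finite and non-negative; an empty vector (no reported variants)
#' gives 0. Higher values mean more observed variability at the position.
#'
#' @param frequencies numeric vector of allele frequencies, each in
#'   \[0, 1\]. May be empty.
#' @param base logarithm base; natural log by default. The choice of base is
#'   a monotone rescaling and does not affect ranking, ROC curves or
#'   threshold-based classification (only the raw reported values).
#' @return a single non-negative number.
#' @examples
#' compute_selv(numeric(0))     # 0: no reported variability
#' compute_selv(c(0.5))         # 0.5 * ln 2
#' compute_selv(c(0.5, 0.5))    # ln 2
#' compute_selv(c(0.25, 0.25), base = 2)
#' @export
compute_selv <- function(frequencies, base = exp(1)) {
  if (length(frequencies) == 0L) return(0)
  if (!is.numeric(frequencies))
    stop("`frequencies` must be a numeric vector", call. = FALSE)
  if (anyNA(frequencies))
    stop("`frequencies` must not contain missing values", call. = FALSE)
  if (!is.numeric(base) || length(base) != 1L || is.na(base) || base <= 0 || base == 1)
    stop("`base` must be a single positive number different from 1", call. = FALSE)
  bad <- which(frequencies < 0 | frequencies > 1)
  if (length(bad))
    stop(sprintf("frequency outside [0, 1]: %g (element %d)",
                 frequencies[bad[1L]], bad[1L]), call. = FALSE)
  f <- frequencies[frequencies > 0 & frequencies < 1]
  if (length(f) == 0L) return(0)
  -sum(f * log(f)) / log(base)
}

# coerce and validate a frequency-record data frame; returns the normalized
# frame with canonical contigs, integer positions, uppercase alleles and a
# population column (empty/NA -> "combined").
normalize_frequency_records <- function(records) {
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("contig", "position", "ref", "alt", "frequency")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols))
    stop("frequency records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rec$contig <- canonical_contig(rec$contig)
  rec$position <- as.integer(rec$position)
  if (anyNA(rec$position) || any(rec$position < 1L))
    stop("`position` must be a 1-based integer coordinate", call. = FALSE)
  rec$ref <- toupper(as.character(rec$ref))
  rec$alt <- toupper(as.character(rec$alt))
  rec$frequency <- as.numeric(rec$frequency)
  if (!"population" %in% names(rec)) rec$population <- .COMBINED
  rec$population <- as.character(rec$population)
  rec$population[is.na(rec$population) | rec$population == ""] <- .COMBINED
  rec[c("contig", "position", "ref", "alt", "frequency", "population")]
}

#' Build a locus table from population frequency records
#'
#' Pools all alternate alleles reported at the same (contig, position,
#' population stratum) into one per-locus frequency vector, the input to
#' [compute_selv()]. Multi-allelic sites must arrive already split into one
#' record per alternate allele (the readers in this package do so).
#'
#' Non-SNV records (ref or alt not a single A/C/G/T) are rejected and
#' counted; records with frequency exactly 0 contribute nothing and are
#' dropped with a reported count; a duplicated
#' (contig, position, ref, alt, population) record is an error, since a
#' frequency resource should be deduplicated upstream and silently merging
#' would corrupt the vectors.
#'
#' @param records data frame of frequency records with columns `contig`,
#'   `position`, `ref`, `alt`, `frequency` and optionally `population`
#'   (empty or `NA` meaning the combined, all-ancestries stratum).
#' @param build genome-build tag (e.g. `"GRCh38"`, `"rCRS"`). Builds are
#'   opaque labels: tables and query variants with different tags never mix.
#' @return an object of class `selv_locus_table`: per-stratum lists of
#'   per-locus frequency vectors plus bookkeeping counts (`kept`,
#'   `zero_dropped`, `non_snv_rejected`).
#' @seealso [score_variants()], [stratified_selv()]
#' @export
build_locus_table <- function(records, build) {
  if (missing(build) || length(build) != 1L)
    stop("`build` must be a single genome-build tag", call. = FALSE)
  rec <- normalize_frequency_records(records)

  snv <- is_snv(rec$ref, rec$alt)
  n_non_snv <- sum(!snv)
  if (n_non_snv > 0L) {
    message(sprintf("build_locus_table: rejected %d non-SNV record(s)", n_non_snv))
    rec <- rec[snv, , drop = FALSE]
  }
  if (anyNA(rec$frequency) || any(rec$frequency < 0 | rec$frequency > 1)) {
    off <- rec$frequency[which(is.na(rec$frequency) | rec$frequency < 0 | rec$frequency > 1)[1L]]
    stop(sprintf("frequency outside [0, 1]: %s", format(off)), call. = FALSE)
  }

  key <- paste(rec$contig, rec$position, rec$ref, rec$alt, rec$population, sep = "\t")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate frequency record(s), e.g. ",
         gsub("\t", " ", key[which(dup)[1L]]),
         "; deduplicate the resource upstream", call. = FALSE)

  zero <- rec$frequency == 0
  n_zero <- sum(zero)
  if (n_zero > 0L) {
    message(sprintf("build_locus_table: dropped %d zero-frequency record(s)", n_zero))
    rec <- rec[!zero, , drop = FALSE]
  }

  vectors <- lapply(
    split(rec, rec$population),
    function(d) split(d$frequency, factor(locus_key(d$contig, d$position)))
  )
  if (!.COMBINED %in% names(vectors)) {
    vectors[[.COMBINED]] <- structure(list(), names = character(0))
  }

  structure(
    list(build = as.character(build),
         vectors = vectors,
         counts = c(kept = nrow(rec), zero_dropped = n_zero,
                    non_snv_rejected = n_non_snv)),
    class = "selv_locus_table"
  )
}

#' @exportS3Method base::print
print.selv_locus_table <- function(x, ...) {
  strata <- names(x$vectors)
  cat(sprintf("<selv_locus_table> build %s\n", x$build))
  for (s in strata)
    cat(sprintf("  stratum %-12s %d loci\n", s, length(x$vectors[[s]])))
  cat(sprintf("  records kept %d, zero-frequency dropped %d, non-SNV rejected %d\n",
              x$counts[["kept"]], x$counts[["zero_dropped"]],
              x$counts[["non_snv_rejected"]]))
  invisible(x)
}

# frequency vector stored for a locus (numeric(0) when the position is
# absent from the stratum).
locus_frequencies <- function(table, contig, position, population = .COMBINED) {
  vl <- table$vectors[[population]]
  if (is.null(vl)) return(numeric(0))
  v <- vl[[locus_key(contig, position)]]
  if (is.null(v)) numeric(0) else v
}

#' Score query variants with the SELV of their locus
#'
#' Each variant receives the SELV computed from the frequency vector stored
#' at its (contig, position) in the combined stratum of the locus table. A
#' variant at a position absent from the table receives SELV = 0 with
#' `n_variants = 0`: a position with no reported variants shows minimal
#' observed variability, which under the selective-pressure interpretation
#' makes novel-position variants maximally suspicious. The query variant's
#' own alternate allele is never added to the vector — only
#' database-reported frequencies count, so a novel query cannot inflate its
#' own score.
#'
#' @param variants data frame of query variants with columns `contig` and
#'   `position` (plus any label/context/score columns, which are carried
#'   through). If the data frame carries a `"build"` attribute (as set by
#'   [read_variant_table()]) it must match the table's build tag.
#' @param table a `selv_locus_table` from [build_locus_table()].
#' @param base logarithm base passed to [compute_selv()].
#' @return the input data frame with `selv` and `n_variants` columns
#'   appended, row order preserved (class `selv_scored`).
#' @export
score_variants <- function(variants, table, base = exp(1)) {
  if (!inherits(table, "selv_locus_table"))
    stop("`table` must be a selv_locus_table (see build_locus_table)", call. = FALSE)
  vb <- attr(variants, "build", exact = TRUE)
  if (!is.null(vb) && !is.na(vb) && !is.na(table$build) &&
      !identical(as.character(vb), table$build))
    stop(sprintf("genome build mismatch: variants are tagged '%s' but the locus table is '%s'",
                 vb, table$build), call. = FALSE)
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!all(c("contig", "position") %in% names(v)))
    stop("`variants` must have columns `contig` and `position`", call. = FALSE)

  vl <- table$vectors[[.COMBINED]]
  idx <- match(locus_key(v$contig, v$position), names(vl))
  v$selv <- vapply(idx, function(i) {
    if (is.na(i)) 0 else compute_selv(vl[[i]], base = base)
  }, numeric(1))
  v$n_variants <- vapply(idx, function(i) {
    if (is.na(i)) 0L else length(vl[[i]])
  }, integer(1))

  attr(v, "build") <- if (is.null(vb)) table$build else vb
  attr(v, "score_columns") <- attr(variants, "score_columns", exact = TRUE)
  class(v) <- c("selv_scored", "data.frame")
  v
}

#' Per-ancestry SELV at one locus
#'
#' Computes one SELV per population stratum of the table, each from that
#' stratum's own frequency vector only; the combined stratum is always
#' reported alongside. Useful for asking whether the score at a position is
#' driven by a single ancestry.
#'
#' @param table a `selv_locus_table` built from records carrying population
#'   tags.
#' @param contig,position the locus.
#' @param populations strata to report; default all available (combined
#'   included). Requesting an unknown stratum is an error that lists the
#'   available ones.
#' @param base logarithm base.
#' @return data frame with columns `population`, `n_variants`, `selv`.
#' @export
stratified_selv <- function(table, contig, position, populations = NULL,
                            base = exp(1)) {
  if (!inherits(table, "selv_locus_table"))
    stop("`table` must be a selv_locus_table", call. = FALSE)
  avail <- names(table$vectors)
  if (is.null(populations)) populations <- avail
  unknown <- setdiff(populations, avail)
  if (length(unknown))
    stop("unknown population stratum: ", paste(unknown, collapse = ", "),
         " (available: ", paste(avail, collapse = ", "), ")", call. = FALSE)
  res <- lapply(populations, function(p) {
    f <- locus_frequencies(table, contig, position, population = p)
    data.frame(population = p, n_variants = length(f),
               selv = compute_selv(f, base = base),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
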