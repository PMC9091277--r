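# Readers and writers for population frequency resources (VCF / TSV),
# query variant tables and scored output. All coordinates are 1-based (VCF
# convention); all readers accept gzip-compressed input.

text_connection <- function(path) gzfile(path)  # reads plain files too

#' Read a gnomAD-style frequency VCF
#'
#' Yields one frequency record per (site, alternate allele), with the
#' frequency taken from the allele-matched entry of an INFO key
#' (`Number=A`-style comma lists are split alongside the ALT list).
#' Multi-allelic lines therefore become several records at the same
#' position, which [build_locus_table()] pools back into one locus vector.
#'
#' Sites lacking the AF key are skipped and counted; non-SNV alternate
#' alleles (symbolic, multi-base, or multi-base REF) are rejected and
#' counted. Per-population INFO keys yield additional records tagged with
#' the stratum name.
#'
#' @param path VCF file (plain or gzip).
#' @param af_key INFO key holding the allele frequency (default `"AF"`).
#'   Which field to use (overall AF, popmax, ...) is a caller choice.
#' @param population_keys optional named character vector mapping stratum
#'   labels to INFO keys, e.g. `c(afr = "AF_afr", nfe = "AF_nfe")`; unnamed
#'   entries use the key itself as the label.
#' @param build genome-build tag attached to the records.
#' @return data frame of frequency records (`contig`, `position`, `ref`,
#'   `alt`, `frequency`, `population`) with attributes `build`,
#'   `n_skipped_no_af` and `n_rejected_non_snv`.
#' @export
read_frequency_vcf <- function(path, af_key = "AF", population_keys = NULL,
                               build = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  has_info <- function(key)
    any(grepl(paste0("^##INFO=<ID=", key, "[,>]"), vcf@meta))
  if (!has_info(af_key))
    stop(sprintf("INFO key '%s' is not declared in the VCF header", af_key),
         call. = FALSE)
  if (!is.null(population_keys)) {
    labels <- names(population_keys) %||% as.character(population_keys)
    labels[labels == ""] <- as.character(population_keys)[labels == ""]
    for (k in population_keys)
      if (!has_info(k))
        stop(sprintf("INFO key '%s' is not declared in the VCF header", k),
             call. = FALSE)
  }

  fix <- vcf@fix
  n <- nrow(fix)
  empty <- data.frame(contig = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      frequency = numeric(0), population = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "build") <- build
    attr(empty, "n_skipped_no_af") <- 0L
    attr(empty, "n_rejected_non_snv") <- 0L
    return(empty)
  }

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos))
    stop(sprintf("malformed VCF record %d: non-integer POS '%s'",
                 which(is.na(pos))[1L], fix[which(is.na(pos))[1L], "POS"]),
         call. = FALSE)
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  extract_key <- function(key, pop_label) {
    raw <- vcfR::extract.info(vcf, element = key)
    skipped <- 0L
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (is.na(raw[i]) || raw[i] == "" || raw[i] == ".") {
        skipped <- skipped + 1L
        next
      }
      afs <- suppressWarnings(as.numeric(strsplit(raw[i], ",", fixed = TRUE)[[1L]]))
      alts <- alt_list[[i]]
      if (length(afs) != length(alts))
        stop(sprintf("malformed VCF record %d (%s:%s): %d ALT allele(s) but %d '%s' value(s)",
                     i, fix[i, "CHROM"], fix[i, "POS"], length(alts),
                     length(afs), key), call. = FALSE)
      rows[[i]] <- data.frame(contig = unname(fix[i, "CHROM"]),
                              position = pos[i],
                              ref = unname(fix[i, "REF"]), alt = alts,
                              frequency = afs, population = pop_label,
                              stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, rows) %||% empty, skipped = skipped)
  }

  combined <- extract_key(af_key, .COMBINED)
  records <- combined$records
  n_skipped <- combined$skipped
  if (!is.null(population_keys)) {
    for (j in seq_along(population_keys)) {
      strat <- extract_key(population_keys[[j]], labels[j])
      records <- rbind(records, strat$records)
    }
  }

  snv <- is_snv(records$ref, records$alt)
  n_non_snv <- sum(!snv)
  records <- records[snv, , drop = FALSE]
  rownames(records) <- NULL

  attr(records, "build") <- build
  attr(records, "n_skipped_no_af") <- n_skipped
  attr(records, "n_rejected_non_snv") <- n_non_snv
  records
}

#' Read a tab-separated frequency table
#'
#' Generic reader for helixMTdb-style exports: one row per reported allele,
#' with a header. Column names are mapped through `columns`, so arbitrarily
#' named exports can be ingested. Rows failing validation (non-SNV alleles,
#' frequency outside \[0, 1\] or missing, bad position) are rejected and
#' counted by reason; frequency exactly 0 is accepted here and dropped later
#' by [build_locus_table()].
#'
#' @param path TSV file (plain or gzip), header row required.
#' @param columns named character vector mapping the required record fields
#'   (`contig`, `position`, `ref`, `alt`, `frequency`) to column names in
#'   the file.
#' @param population_column column holding ancestry-stratum tags; by
#'   default a column literally named `population` is used when present.
#' @param build genome-build tag.
#' @return data frame of frequency records with attributes `build`, `n_in`
#'   and `rejections` (named integer vector of per-reason counts).
#' @export
read_frequency_tsv <- function(path,
                               columns = c(contig = "contig",
                                           position = "position",
                                           ref = "ref", alt = "alt",
                                           frequency = "frequency"),
                               population_column = NULL,
                               build = NA_character_) {
  required <- c("contig", "position", "ref", "alt", "frequency")
  full <- stats::setNames(required, required)
  full[names(columns)] <- columns
  df <- utils::read.delim(text_connection(path), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  absent <- full[!full %in% names(df)]
  if (length(absent))
    stop("cannot map required column(s): ",
         paste(sprintf("%s -> '%s'", names(absent), absent), collapse = ", "),
         call. = FALSE)

  rec <- data.frame(contig = as.character(df[[full["contig"]]]),
                    position = suppressWarnings(as.integer(df[[full["position"]]])),
                    ref = toupper(as.character(df[[full["ref"]]])),
                    alt = toupper(as.character(df[[full["alt"]]])),
                    frequency = suppressWarnings(as.numeric(df[[full["frequency"]]])),
                    stringsAsFactors = FALSE)
  if (is.null(population_column) && "population" %in% names(df))
    population_column <- "population"
  rec$population <- if (!is.null(population_column)) {
    if (!population_column %in% names(df))
      stop(sprintf("population column '%s' not present", population_column),
           call. = FALSE)
    as.character(df[[population_column]])
  } else .COMBINED

  bad_pos <- is.na(rec$position) | rec$position < 1L
  bad_freq <- is.na(rec$frequency) | rec$frequency < 0 | rec$frequency > 1
  bad_snv <- !is_snv(rec$ref, rec$alt)
  keep <- !(bad_pos | bad_freq | bad_snv)
  rejections <- c(bad_position = sum(bad_pos),
                  bad_frequency = sum(bad_freq & !bad_pos),
                  non_snv = sum(bad_snv & !bad_pos & !bad_freq))
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "build") <- build
  attr(out, "n_in") <- nrow(rec)
  attr(out, "rejections") <- rejections
  out
}

#' Write frequency records as a TSV resource
#'
#' Inverse of [read_frequency_tsv()]; one row per record, stratified records
#' keep their `population` tag. Frequencies are written with enough digits
#' to round-trip exactly.
#'
#' @param records frequency-record data frame.
#' @param path output file.
#' @export
write_frequency_tsv <- function(records, path) {
  rec <- normalize_frequency_records(records)
  rec$frequency <- formatC(rec$frequency, digits = 17, format = "g")
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write frequency records as a minimal sites-only VCF
#'
#' Writes one line per position with alternate alleles comma-joined and the
#' allele-frequency INFO key aligned to the ALT order. Only combined-stratum
#' records can be represented this way; stratified resources should use
#' [write_frequency_tsv()], since a per-population `Number=A` field would
#' need zero-filling for alleles absent from a stratum and zero is not the
#' same statement as "not reported".
#'
#' @param records combined-stratum frequency records.
#' @param path output file.
#' @param af_key INFO key to declare and write (default `"AF"`).
#' @param build genome-build tag written as a header comment.
#' @export
write_frequency_vcf <- function(records, path, af_key = "AF",
                                build = NA_character_) {
  rec <- normalize_frequency_records(records)
  if (any(rec$population != .COMBINED))
    stop("write_frequency_vcf handles combined-stratum records only; ",
         "use write_frequency_tsv for stratified resources", call. = FALSE)
  key <- paste(rec$contig, rec$position, rec$ref, sep = "\t")
  ord <- order(rec$contig, rec$position)
  rec <- rec[ord, , drop = FALSE]
  key <- key[ord]
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.na(build)) sprintf("##reference=%s", build),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Population allele frequency\">", af_key),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- vapply(split(seq_len(nrow(rec)), factor(key, levels = unique(key))),
                 function(ii) {
                   d <- rec[ii, , drop = FALSE]
                   sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s=%s",
                           d$contig[1L], d$position[1L], d$ref[1L],
                           paste(d$alt, collapse = ","), af_key,
                           paste(sprintf("%.6f", d$frequency), collapse = ","))
                 }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a query variant table
#'
#' Tab-separated, header required; `contig`, `position`, `ref`, `alt` are
#' mandatory, `label` (0 = neutral, 1 = pathogenic, empty = unlabeled) and
#' `context` (genomic-context tag such as `splice_site`,
#' `nuclear_noncoding`, `mito_noncoding`, `protein_coding`) are optional.
#' Every remaining column — or the explicit `score_columns` list — is read
#' as a numeric competitor score; empty cells become `NA`, never 0, so a
#' missing score can be excluded pairwise downstream.
#'
#' @param path TSV file (plain or gzip).
#' @param score_columns explicit competitor-score column names; default all
#'   non-reserved columns.
#' @param build genome-build tag attached to the table.
#' @return data frame of variants with attributes `build`, `score_columns`
#'   and `n_rejected_non_snv`; duplicated (contig, position, ref, alt) keys
#'   are an error.
#' @export
read_variant_table <- function(path, score_columns = NULL,
                               build = NA_character_) {
  df <- utils::read.delim(text_connection(path), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  required <- c("contig", "position", "ref", "alt")
  absent <- setdiff(required, names(df))
  if (length(absent))
    stop("variant table is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  df$contig <- as.character(df$contig)
  df$position <- as.integer(df$position)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))

  if ("label" %in% names(df)) {
    df$label <- suppressWarnings(as.numeric(df$label))
    if (!all(df$label %in% c(0, 1) | is.na(df$label)))
      stop("`label` must be 0, 1 or missing", call. = FALSE)
  } else df$label <- NA_real_
  if ("context" %in% names(df)) {
    df$context <- as.character(df$context)
    df$context[is.na(df$context)] <- "unspecified"
  } else df$context <- "unspecified"

  reserved <- c("contig", "position", "ref", "alt", "label", "context")
  if (is.null(score_columns)) score_columns <- setdiff(names(df), reserved)
  for (sc in score_columns) {
    if (!sc %in% names(df))
      stop(sprintf("score column '%s' not present", sc), call. = FALSE)
    df[[sc]] <- suppressWarnings(as.numeric(df[[sc]]))
  }

  snv <- is_snv(df$ref, df$alt)
  n_non_snv <- sum(!snv)
  df <- df[snv, , drop = FALSE]
  key <- paste(canonical_contig(df$contig), df$position, df$ref, df$alt)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicated variant key(s), e.g. ", key[which(dup)[1L]], call. = FALSE)
  rownames(df) <- NULL
  attr(df, "build") <- build
  attr(df, "score_columns") <- score_columns
  attr(df, "n_rejected_non_snv") <- n_non_snv
  df
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]; missing labels and scores are written
#' as `"NA"`.
#'
#' @param variants variant data frame.
#' @param path output file.
#' @export
write_variant_table <- function(variants, path) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  lead <- intersect(c("contig", "position", "ref", "alt", "label", "context"),
                    names(v))
  v <- v[c(lead, setdiff(names(v), lead))]
  utils::write.table(v, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a scored (and optionally classified) variant table
#'
#' Tab-separated output with a stable column order: variant key, label and
#' context, `selv` and `n_variants`, competitor scores, then
#' `predicted_class`/`threshold_used` when present.
#'
#' @param scored a `selv_scored` data frame from [score_variants()] or
#'   [classify_variants()].
#' @param path output file.
#' @export
write_scored_table <- function(scored, path) {
  x <- as.data.frame(scored, stringsAsFactors = FALSE)
  lead <- intersect(c("contig", "position", "ref", "alt", "label", "context",
                      "selv", "n_variants"), names(x))
  tail_cols <- intersect(c("predicted_class", "threshold_used"), names(x))
  mid <- setdiff(names(x), c(lead, tail_cols))
  x <- x[c(lead, mid, tail_cols)]
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Annotate a VCF with SELV values
#'
#' Adds a header-declared `Number=1,Type=Float` INFO field carrying the SELV
#' of each record's position, looked up in a scored table. The file is
#' edited at line level: records whose position is absent from the scores,
#' and every other byte of the file, are left exactly as they were — no
#' reordering, dropping or reformatting.
#'
#' @param path_in input VCF (plain or gzip).
#' @param scored data frame with `contig`, `position` and `selv` columns
#'   (e.g. from [score_variants()]).
#' @param path_out output path (written uncompressed).
#' @param info_key INFO key to declare and write (default `"SELV"`).
#' @param digits significant digits for the written values.
#' @export
annotate_vcf <- function(path_in, scored, path_out, info_key = "SELV",
                         digits = 6) {
  con <- text_connection(path_in)
  lines <- readLines(con, warn = FALSE)
  close(con)
  chrom_idx <- which(startsWith(lines, "#CHROM"))[1L]
  if (is.na(chrom_idx))
    stop("not a VCF: no #CHROM header line found", call. = FALSE)

  hdr <- sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Shannon entropy of locus variability">',
                 info_key)
  lookup_keys <- locus_key(scored$contig, scored$position)
  first <- !duplicated(lookup_keys)
  lookup <- stats::setNames(scored$selv[first], lookup_keys[first])

  data_idx <- setdiff(seq_along(lines), seq_len(chrom_idx))
  data_idx <- data_idx[!startsWith(lines[data_idx], "#") & nzchar(lines[data_idx])]
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stop(sprintf("malformed VCF line %d: fewer than 8 fields", i), call. = FALSE)
    key <- locus_key(f[1L], f[2L])
    if (!key %in% names(lookup)) next
    entry <- sprintf("%s=%s", info_key,
                     sprintf("%.*g", digits, lookup[[key]]))
    f[8L] <- if (f[8L] == "." || f[8L] == "") entry else paste(f[8L], entry, sep = ";")
    lines[i] <- paste(f, collapse = "\t")
  }
  out <- append(lines, hdr, after = chrom_idx - 1L)
  writeLines(out, path_out)
  invisible(path_out)
}
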