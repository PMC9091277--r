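# Synthetic population frequency resources and labeled variant cohorts.
# The generator emulates the statistical premise behind SELV: pathogenic
# variants sit at low frequencies and preferentially at loci under strong
# selective pressure, i.e. loci with low observed variability. Pathogenic
# positions are sampled with probability proportional to exp(-beta * SELV)
# of the true locus score, so the synthetic signal travels through the full
# pipeline (resource -> vectors -> scores -> benchmark) rather than being
# painted onto the scores directly.

#' Configuration for a synthetic frequency resource and cohort
#'
#' @param n_loci number of genomic positions in the resource.
#' @param n_pathogenic,n_neutral cohort sizes per class.
#' @param seed mandatory integer seed; identical seed + config reproduce
#'   the outputs exactly (no silent global randomness).
#' @param alt_count_probs probabilities over 0..3 alternate alleles per
#'   locus; must sum to 1. The default mimics the fact that most genomic
#'   positions carry no or one reported variant.
#' @param frequency per-allele frequency model: `list(family = "beta",
#'   shape1, shape2)` for a heavy-tailed spectrum on (0, 1\] (the default
#'   `shape1 = 0.25, shape2 = 8` concentrates mass at rare alleles, as
#'   population AF spectra do), or `list(family = "fixed", value = f)` for
#'   degenerate designs with known SELV strata. Drawn frequencies are
#'   rounded to 6 decimals (floor 1e-6), matching the printed precision of
#'   public resources and making text round-trips exact.
#' @param beta placement-bias strength: pathogenic positions are sampled
#'   with probability proportional to `exp(-beta * selv)`; `beta = 0` means
#'   no signal, large `beta` concentrates pathogenic variants at
#'   low-variability loci.
#' @param contig,first_position where the synthetic loci live.
#' @param context genomic-context tag stamped on the cohort.
#' @param populations optional character vector of ancestry-stratum labels;
#'   each stratum resamples every allele count binomially at
#'   `population_depth` haploid samples (subsampling noise), dropping
#'   alleles unobserved in the stratum.
#' @param population_depth haploid sample size per stratum.
#' @param build genome-build tag stamped on resource and cohort.
#' @return object of class `selv_cohort_config`.
#' @export
cohort_config <- function(n_loci, n_pathogenic, n_neutral, seed,
                          alt_count_probs = c(`0` = 0.15, `1` = 0.55,
                                              `2` = 0.22, `3` = 0.08),
                          frequency = list(family = "beta",
                                           shape1 = 0.25, shape2 = 8),
                          beta = 4,
                          contig = "chr1", first_position = 10001L,
                          context = "unspecified",
                          populations = NULL, population_depth = 5000L,
                          build = "synthetic-1") {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(n_loci) && length(n_loci) == 1L && n_loci >= 0,
      "`n_loci` must be a non-negative integer")
  chk(is.numeric(n_pathogenic) && n_pathogenic >= 0,
      "`n_pathogenic` must be a non-negative integer")
  chk(is.numeric(n_neutral) && n_neutral >= 0,
      "`n_neutral` must be a non-negative integer")
  chk(!missing(seed) && is.numeric(seed) && length(seed) == 1L && !is.na(seed),
      "`seed` is mandatory and must be a single integer")
  chk(length(alt_count_probs) == 4L && all(alt_count_probs >= 0) &&
        abs(sum(alt_count_probs) - 1) < 1e-8,
      "`alt_count_probs` must be 4 probabilities over 0..3 alts summing to 1")
  chk(is.list(frequency) && frequency$family %in% c("beta", "fixed"),
      "`frequency$family` must be 'beta' or 'fixed'")
  if (is.list(frequency) && identical(frequency$family, "beta"))
    chk(isTRUE(frequency$shape1 > 0) && isTRUE(frequency$shape2 > 0),
        "beta frequency family needs positive `shape1` and `shape2`")
  if (is.list(frequency) && identical(frequency$family, "fixed"))
    chk(isTRUE(frequency$value > 0) && isTRUE(frequency$value <= 1),
        "fixed frequency family needs `value` in (0, 1]")
  chk(is.numeric(beta) && length(beta) == 1L && !is.na(beta),
      "`beta` must be a single number")
  chk(is.numeric(population_depth) && population_depth >= 1,
      "`population_depth` must be a positive integer")
  if (length(problems))
    stop("invalid cohort config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  structure(list(n_loci = as.integer(n_loci),
                 n_pathogenic = as.integer(n_pathogenic),
                 n_neutral = as.integer(n_neutral),
                 seed = as.integer(seed),
                 alt_count_probs = as.numeric(alt_count_probs),
                 frequency = frequency, beta = as.numeric(beta),
                 contig = contig,
                 first_position = as.integer(first_position),
                 context = context, populations = populations,
                 population_depth = as.integer(population_depth),
                 build = build),
            class = "selv_cohort_config")
}

draw_frequencies <- function(n, model) {
  f <- switch(model$family,
              beta = stats::rbeta(n, model$shape1, model$shape2),
              fixed = rep(model$value, n))
  pmax(round(f, 6), 1e-6)
}

#' Generate a synthetic population frequency resource
#'
#' Draws, per locus, an alternate-allele count from the configured
#' distribution and that many allele frequencies from the configured
#' family; records the true per-locus frequency vector and SELV (natural
#' log) as bookkeeping, so oracle tests can diff pipeline output against
#' ground truth. Optional ancestry strata binomially subsample each allele
#' frequency at the configured depth.
#'
#' @param config a [cohort_config()] object.
#' @return object of class `selv_resource`: `records` (a frequency-record
#'   data frame writable by [write_frequency_vcf()] /
#'   [write_frequency_tsv()]), `truth` (per-locus `contig`, `position`,
#'   `ref`, `n_alts`, `selv`) and the `config`.
#' @export
generate_frequency_resource <- function(config) {
  stopifnot(inherits(config, "selv_cohort_config"))
  set.seed(config$seed)
  L <- config$n_loci
  positions <- config$first_position + seq_len(L) - 1L
  refs <- sample(.BASES, L, replace = TRUE)
  k <- sample(0:3, L, replace = TRUE, prob = config$alt_count_probs)

  total <- sum(k)
  freqs <- draw_frequencies(total, config$frequency)
  locus_of <- rep.int(seq_len(L), k)
  alts <- unlist(lapply(seq_len(L), function(i) {
    if (k[i] == 0L) character(0)
    else sample(setdiff(.BASES, refs[i]), k[i])
  }), use.names = FALSE)

  records <- data.frame(contig = rep(config$contig, total),
                        position = positions[locus_of],
                        ref = refs[locus_of], alt = alts,
                        frequency = freqs,
                        population = rep(.COMBINED, total),
                        stringsAsFactors = FALSE)

  if (!is.null(config$populations)) {
    depth <- config$population_depth
    combined <- records
    for (pop in config$populations) {
      ac <- stats::rbinom(nrow(combined), depth, combined$frequency)
      keep <- ac > 0L
      if (any(keep)) {
        strat <- combined[keep, , drop = FALSE]
        strat$frequency <- ac[keep] / depth
        strat$population <- pop
        records <- rbind(records, strat)
      }
    }
    rownames(records) <- NULL
  }

  selv_true <- vapply(split(freqs, factor(locus_of, levels = seq_len(L))),
                      compute_selv, numeric(1))
  truth <- data.frame(contig = rep(config$contig, L), position = positions,
                      ref = refs, n_alts = k, selv = unname(selv_true),
                      stringsAsFactors = FALSE)

  structure(list(records = records, truth = truth, config = config),
            class = "selv_resource")
}

#' @exportS3Method base::print
print.selv_resource <- function(x, ...) {
  cat(sprintf("<selv_resource> %d loci, %d records (build %s)\n",
              nrow(x$truth), nrow(x$records), x$config$build))
  invisible(x)
}

# sample `n` loci with replacement under weights `w`, honoring a per-locus
# capacity (3 distinct alternate alleles per position); draws exceeding a
# locus's remaining capacity are redrawn, which perturbs the target
# distribution only when a locus is hit more than 3 times.
sample_with_capacity <- function(n, w, cap_left) {
  if (n == 0L) return(list(chosen = integer(0), cap_left = cap_left))
  if (sum(cap_left[w > 0]) < n)
    stop("requested more variants than loci available under the placement rule",
         call. = FALSE)
  chosen <- integer(n)
  got <- 0L
  while (got < n) {
    idx <- sample.int(length(w), size = (n - got) * 2L + 10L,
                      replace = TRUE, prob = w)
    for (i in idx) {
      if (cap_left[i] > 0L) {
        cap_left[i] <- cap_left[i] - 1L
        got <- got + 1L
        chosen[got] <- i
        if (got == n) break
      }
    }
  }
  list(chosen = chosen, cap_left = cap_left)
}

#' Generate a labeled variant cohort over a synthetic resource
#'
#' Pathogenic variants are placed at loci sampled with probability
#' proportional to `exp(-beta * selv)` of the true locus SELV; neutral
#' variants are placed uniformly over loci. Each placed variant receives a
#' random alternate allele distinct from the locus reference and from any
#' allele already used at that locus by this cohort (at most 3 variants per
#' locus), so cohort variant keys are unique.
#'
#' @param config the [cohort_config()] used for the resource.
#' @param resource the matching [generate_frequency_resource()] output.
#' @return data frame of labeled variants (`contig`, `position`, `ref`,
#'   `alt`, `label`, `context`) with attributes `build`, `true_selv` (the
#'   bookkeeping SELV of each variant's locus) and `selv_gap` (mean true
#'   SELV of neutral minus pathogenic variants, the realized class
#'   separation).
#' @export
generate_labeled_cohort <- function(config, resource) {
  stopifnot(inherits(config, "selv_cohort_config"),
            inherits(resource, "selv_resource"))
  truth <- resource$truth
  L <- nrow(truth)
  if (L == 0L)
    stop("resource has no loci to place variants on", call. = FALSE)
  set.seed(config$seed + 1L)

  w_path <- exp(-config$beta * truth$selv)
  w_neut <- rep(1, L)
  cap <- rep(3L, L)

  placed_p <- sample_with_capacity(config$n_pathogenic, w_path, cap)
  placed_n <- sample_with_capacity(config$n_neutral, w_neut, placed_p$cap_left)
  loci <- c(placed_p$chosen, placed_n$chosen)
  label <- rep(c(1, 0), c(config$n_pathogenic, config$n_neutral))

  # assign distinct alternate alleles per locus across the whole cohort
  alt <- character(length(loci))
  used <- vector("list", L)
  ord <- sample.int(length(loci))   # interleave classes for allele draws
  for (j in ord) {
    i <- loci[j]
    avail <- setdiff(setdiff(.BASES, truth$ref[i]), used[[i]])
    pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
    used[[i]] <- c(used[[i]], pick)
    alt[j] <- pick
  }

  cohort <- data.frame(contig = truth$contig[loci],
                       position = truth$position[loci],
                       ref = truth$ref[loci], alt = alt,
                       label = label, context = config$context,
                       stringsAsFactors = FALSE)
  attr(cohort, "build") <- config$build
  attr(cohort, "true_selv") <- truth$selv[loci]
  attr(cohort, "selv_gap") <-
    mean(truth$selv[placed_n$chosen]) - mean(truth$selv[placed_p$chosen])
  attr(cohort, "score_columns") <- character(0)
  cohort
}

#' Analytic AUC implied by the placement rule
#'
#' Closed-form probability that a pathogenic variant out-ranks a neutral one
#' under the `lower_is_pathogenic` orientation, given the realized locus
#' SELV values: pathogenic positions follow `p_i` proportional to
#' `exp(-beta * selv_i)`, neutral positions are uniform, and
#' `AUC = P(S_path < S_neut) + P(S_path = S_neut) / 2`. This is the
#' expectation the empirical pipeline AUC converges to (up to the
#' finite-capacity correction of at most 3 variants per locus), and serves
#' as the generator's ground-truth check on end-to-end signal recovery.
#'
#' @param resource a `selv_resource`.
#' @param beta placement-bias strength (default the resource config's).
#' @return a single number in \[0, 1\].
#' @export
expected_placement_auc <- function(resource, beta = resource$config$beta) {
  s <- resource$truth$selv
  w <- exp(-beta * s)
  p <- w / sum(w)              # pathogenic placement distribution
  q <- rep(1 / length(s), length(s))
  u <- sort(unique(s))
  pu <- vapply(u, function(v) sum(p[s == v]), numeric(1))
  qu <- vapply(u, function(v) sum(q[s == v]), numeric(1))
  q_above <- rev(cumsum(rev(qu))) - qu   # neutral mass strictly above each value
  sum(pu * (q_above + qu / 2))
}
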