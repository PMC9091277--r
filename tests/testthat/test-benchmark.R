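test_that("roc_curve handles perfect separation, ties and orientation", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1), "lower_is_pathogenic")
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(utils::tail(r$fpr, 1), 1)
  expect_equal(utils::tail(r$tpr, 1), 1)

  # all scores equal: every pair is a tie, AUC = 1/2
  expect_equal(roc_curve(rep(3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  expect_error(roc_curve(1:3, c(1, 1, 1)), "both")
  expect_error(roc_curve(1:3, c(1, 0)), "length")
})

test_that("roc_curve AUC equals Mann-Whitney pair counting on random instances", {
  set.seed(202)
  for (i in 1:60) {
    inst <- random_instance(sample(2:40, 1), sample(2:40, 1),
                            signal = runif(1, 0, 2), ties = i %% 2 == 0)
    for (or in c("higher_is_pathogenic", "lower_is_pathogenic")) {
      r <- roc_curve(inst$scores, inst$labels, or)
      expect_equal(r$auc, brute_auc(inst$scores, inst$labels, or),
                   tolerance = 1e-12)
      # curve invariants
      expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
      expect_true(all(r$fpr >= 0 & r$fpr <= 1 & r$tpr >= 0 & r$tpr <= 1))
    }
    # flipping the orientation complements the AUC
    expect_equal(roc_curve(inst$scores, inst$labels, "higher_is_pathogenic")$auc +
                   roc_curve(inst$scores, inst$labels, "lower_is_pathogenic")$auc,
                 1, tolerance = 1e-12)
    # AUC invariant under strictly increasing transforms
    expect_equal(roc_curve(inst$scores, inst$labels)$auc,
                 roc_curve(exp(inst$scores) + 2, inst$labels)$auc,
                 tolerance = 1e-12)
  }
})

test_that("roc_curve agrees with pROC as an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(17)
  inst <- random_instance(30, 40, signal = 0.8, ties = TRUE)
  r <- roc_curve(inst$scores, inst$labels)
  ref <- pROC::roc(inst$labels, inst$scores, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("pr_curve matches exhaustive cut enumeration and known edge cases", {
  # perfect separation
  expect_equal(pr_curve(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1),
                        "lower_is_pathogenic")$pr_auc, 1)
  # constant score: area equals prevalence
  expect_equal(pr_curve(rep(1, 10), rep(c(1, 0), c(3, 7)))$pr_auc, 0.3)

  set.seed(303)
  for (i in 1:40) {
    inst <- random_instance(sample(2:30, 1), sample(2:30, 1),
                            signal = runif(1, 0, 2), ties = i %% 2 == 0)
    for (or in c("higher_is_pathogenic", "lower_is_pathogenic")) {
      p <- pr_curve(inst$scores, inst$labels, or)
      expect_equal(p$pr_auc, brute_pr_auc(inst$scores, inst$labels, or),
                   tolerance = 1e-12)
      expect_true(p$pr_auc >= 0 && p$pr_auc <= 1)
      expect_equal(utils::tail(p$recall, 1), 1)  # recall reaches 1
    }
  }
})

test_that("compare_auc gives D = 0, p = 1 for identical or monotone-related scores", {
  set.seed(404)
  inst <- random_instance(15, 15, signal = 1)
  same <- compare_auc(inst$scores, inst$scores, inst$labels)
  expect_identical(same$d_statistic, 0)
  expect_identical(same$p_value, 1)
  mono <- compare_auc(inst$scores, exp(inst$scores) - 5, inst$labels)
  expect_identical(mono$d_statistic, 0)
  # opposite-orientation encoding of the same ranking also collapses to D = 0
  flip <- compare_auc(inst$scores, -inst$scores, inst$labels,
                      orientation_b = "lower_is_pathogenic")
  expect_identical(flip$d_statistic, 0)
})

test_that("compare_auc is antisymmetric and matches pROC's paired DeLong test", {
  skip_if_not_installed("pROC")
  set.seed(505)
  for (i in 1:10) {
    n_pos <- sample(10:30, 1)
    n_neg <- sample(10:30, 1)
    labels <- rep(c(1, 0), c(n_pos, n_neg))
    a <- rnorm(n_pos + n_neg, mean = labels)
    b <- 0.6 * a + rnorm(n_pos + n_neg, mean = 0.5 * labels)
    ab <- compare_auc(a, b, labels)
    ba <- compare_auc(b, a, labels)
    expect_equal(ab$d_statistic, -ba$d_statistic, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

    ref <- pROC::roc.test(pROC::roc(labels, a, direction = "<", quiet = TRUE),
                          pROC::roc(labels, b, direction = "<", quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(ab$d_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ab$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("compare_auc drops pairs with a missing score and validates input", {
  labels <- c(1, 1, 1, 0, 0, 0)
  a <- c(3, 2.5, 2, 1, 0.5, 0)
  b <- c(3, NA, 2, 1, 0.5, 0)
  out <- compare_auc(a, b, labels)
  expect_equal(out$n_paired, 5L)
  expect_error(compare_auc(a[1:4], b[1:4], labels[1:4]), "2 observations")
})

test_that("ks_two_sample computes the ECDF supremum distance", {
  x <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, x)$d, 0)
  expect_equal(ks_two_sample(0, 1)$d, 1)   # disjoint singletons
  set.seed(606)
  for (i in 1:25) {
    a <- rnorm(sample(5:100, 1))
    b <- rnorm(sample(5:100, 1), mean = runif(1, 0, 1))
    k <- ks_two_sample(a, b)
    expect_equal(k$d, brute_ks_d(a, b), tolerance = 1e-12)
    expect_true(k$p_value >= 0 && k$p_value <= 1)
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("fisher_2x2 matches fixed-margin enumeration and is transpose-invariant", {
  hom <- fisher_2x2(matrix(5, 2, 2))
  expect_equal(hom$p_value, 1)
  expect_equal(hom$odds_ratio, 1)

  sep <- fisher_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_true(is.infinite(sep$odds_ratio))
  expect_equal(sep$p_value, brute_fisher_p(matrix(c(10, 0, 0, 10), 2)),
               tolerance = 1e-10)

  set.seed(707)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    f <- fisher_2x2(tab)
    expect_equal(f$p_value, brute_fisher_p(tab), tolerance = 1e-10)
    expect_equal(fisher_2x2(t(tab))$p_value, f$p_value, tolerance = 1e-12)
  }
  expect_error(fisher_2x2(matrix(c(1, 2, 3, -1), 2)), "non-negative")
  expect_error(fisher_2x2(matrix(c(1, 2, 3, 1.5), 2)), "integer")
})

test_that("benchmark_report restricts each comparison to its pairwise-complete subset", {
  set.seed(808)
  n <- 120
  labels <- rep(c(1, 0), each = n / 2)
  selv <- ifelse(labels == 1, rbeta(n, 1, 6), rbeta(n, 2, 3))
  comp <- ifelse(labels == 1, rnorm(n, 1.2), rnorm(n, 0))
  comp[sample(n, 30)] <- NA
  x <- data.frame(contig = "chr1", position = seq_len(n), ref = "A", alt = "C",
                  label = labels, context = "splice_site",
                  selv = selv, n_variants = 1L, ada = comp)
  rep_ <- benchmark_report(x, score_columns = "ada")

  expect_equal(rep_$selv$n, n)
  ada <- rep_$competitors$ada
  expect_equal(ada$n_used, n - 30L)
  expect_equal(ada$n_dropped, 30L)
  # report AUCs equal direct roc_curve calls on the same subsets
  sub <- x[!is.na(x$ada), ]
  expect_equal(ada$roc$auc, roc_curve(sub$ada, sub$label)$auc)
  expect_equal(ada$selv_roc$auc,
               roc_curve(sub$selv, sub$label, "lower_is_pathogenic")$auc)
  expect_equal(rep_$selv$roc$auc,
               roc_curve(x$selv, x$label, "lower_is_pathogenic")$auc)

  # a competitor that is a monotone transform of -SELV ties SELV exactly
  x$mirror <- -x$selv
  rep2 <- benchmark_report(x, score_columns = "mirror")
  expect_equal(rep2$competitors$mirror$roc$auc, rep2$competitors$mirror$selv_roc$auc)
  expect_identical(rep2$competitors$mirror$comparison$d_statistic, 0)

  # structure survives JSON serialization
  path <- withr::local_tempfile(fileext = ".json")
  write_benchmark_json(rep_, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$selv$auc, rep_$selv$roc$auc, tolerance = 1e-12)
  expect_equal(parsed$competitors$ada$d_statistic,
               rep_$competitors$ada$comparison$d_statistic, tolerance = 1e-12)

  s <- benchmark_summary(rep_)
  expect_equal(nrow(s), 2L)
  expect_equal(s$auc[s$score == "ada"], ada$roc$auc)
})
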