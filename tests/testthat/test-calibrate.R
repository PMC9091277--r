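test_that("youden_threshold separates cleanly separable scores with J = 1", {
  cal <- youden_threshold(c(0.001, 0.002, 0.5, 0.8), c(1, 1, 0, 0),
                          "lower_is_pathogenic", context = "splice_site")
  expect_equal(cal$youden_j, 1)
  expect_equal(cal$sensitivity, 1)
  expect_equal(cal$specificity, 1)
  expect_true(cal$threshold > 0.002 && cal$threshold < 0.5)
  expect_equal(cal$context, "splice_site")
})

test_that("youden_threshold gives J = 0 when scores carry no information", {
  cal <- youden_threshold(rep(0.5, 8), rep(c(1, 0), 4), "lower_is_pathogenic")
  expect_equal(cal$youden_j, 0)
  # tie on J broken toward higher sensitivity: call everything pathogenic
  expect_equal(cal$sensitivity, 1)
})

test_that("youden_threshold matches exhaustive search over all candidate cuts", {
  set.seed(909)
  for (i in 1:60) {
    inst <- random_instance(sample(2:50, 1), sample(2:50, 1),
                            signal = runif(1, 0, 2), ties = i %% 3 == 0)
    for (or in c("higher_is_pathogenic", "lower_is_pathogenic")) {
      cal <- youden_threshold(inst$scores, inst$labels, or)
      expect_equal(cal$youden_j, brute_youden(inst$scores, inst$labels, or),
                   tolerance = 1e-12)
      expect_equal(cal$youden_j, cal$sensitivity + cal$specificity - 1,
                   tolerance = 1e-15)
      expect_lte(cal$youden_j, 1)
      # returned metrics are reproducible at the returned cut
      ev <- evaluate_at_threshold(inst$scores, inst$labels, cal$threshold, or)
      expect_equal(ev$sensitivity, cal$sensitivity)
      expect_equal(ev$specificity, cal$specificity)
    }
  }
})

test_that("J equals 2*AUC - 1 for a binary-valued score", {
  set.seed(123)
  scores <- sample(c(0, 1), 60, replace = TRUE)
  labels <- rbinom(60, 1, ifelse(scores == 1, 0.8, 0.3))
  if (length(unique(labels)) == 2) {
    cal <- youden_threshold(scores, labels, "higher_is_pathogenic")
    auc <- roc_curve(scores, labels, "higher_is_pathogenic")$auc
    expect_equal(cal$youden_j, abs(2 * auc - 1), tolerance = 1e-12)
  }
})

test_that("evaluate_at_threshold matches brute confusion counting and extremes", {
  # lower_is_pathogenic with the cut below every score: nothing called
  ev <- evaluate_at_threshold(c(1, 2, 3, 4), c(1, 0, 1, 0), 0.5,
                              "lower_is_pathogenic")
  expect_equal(ev$sensitivity, 0)
  expect_equal(ev$specificity, 1)
  ev2 <- evaluate_at_threshold(c(1, 2, 3, 4), c(1, 0, 1, 0), 10,
                               "lower_is_pathogenic")
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 0)

  set.seed(321)
  for (i in 1:30) {
    inst <- random_instance(sample(2:30, 1), sample(2:30, 1), ties = TRUE)
    thr <- sample(inst$scores, 1)
    ev <- evaluate_at_threshold(inst$scores, inst$labels, thr,
                                "lower_is_pathogenic")
    called <- inst$scores <= thr    # inclusive rule
    expect_equal(ev$tp, sum(called & inst$labels == 1))
    expect_equal(ev$tn, sum(!called & inst$labels == 0))
    expect_equal(ev$sensitivity, ev$tp / (ev$tp + ev$fn))
  }
})

test_that("sensitivity and specificity trade off monotonically in the threshold", {
  set.seed(555)
  inst <- random_instance(40, 40, signal = 1)
  cuts <- sort(unique(inst$scores))
  evs <- lapply(cuts, function(t)
    evaluate_at_threshold(inst$scores, inst$labels, t, "lower_is_pathogenic"))
  sens <- vapply(evs, `[[`, numeric(1), "sensitivity")
  spec <- vapply(evs, `[[`, numeric(1), "specificity")
  expect_true(all(diff(sens) >= 0))   # raising the cut can only call more
  expect_true(all(diff(spec) <= 0))
})

test_that("classify_variants applies the inclusive per-context rule", {
  x <- data.frame(contig = "chr1", position = 1:6, ref = "A", alt = "C",
                  context = rep(c("splice_site", "mito_noncoding"), 3),
                  selv = c(0, 0.0005, 0.5, 0.009, 0.2, 0.001))
  cals <- list(
    structure(list(context = "splice_site", threshold = 0.001,
                   orientation = "lower_is_pathogenic"),
              class = "selv_calibration"),
    structure(list(context = "mito_noncoding", threshold = 0.009,
                   orientation = "lower_is_pathogenic"),
              class = "selv_calibration"))
  out <- classify_variants(x, cals)
  # selv = 0 (novel/invariant locus) is pathogenic at any positive threshold
  expect_equal(out$predicted_class,
               c("pathogenic", "pathogenic", "neutral",
                 "pathogenic", "neutral", "pathogenic"))
  expect_equal(out$threshold_used, rep(c(0.001, 0.009), 3))
  # idempotent and order-independent
  out2 <- classify_variants(out[sample(nrow(out)), ], cals)
  expect_equal(sort(rownames(out2)[out2$predicted_class == "pathogenic"]),
               sort(rownames(out)[out$predicted_class == "pathogenic"]))
  # counts attribute sums per-variant decisions
  expect_equal(sum(attr(out, "counts")), nrow(out))
  expect_error(classify_variants(transform(x, context = "nuclear_noncoding"),
                                 cals), "nuclear_noncoding")
})

test_that("classification reproduces the calibration confusion matrix exactly", {
  set.seed(777)
  inst <- random_instance(80, 80, signal = 1.2, ties = TRUE)
  cal <- youden_threshold(inst$scores, inst$labels, "lower_is_pathogenic",
                          context = "splice_site")
  x <- data.frame(contig = "chr1", position = seq_along(inst$scores),
                  ref = "A", alt = "C", label = inst$labels,
                  context = "splice_site", selv = inst$scores)
  out <- classify_variants(x, cal)
  ev <- evaluate_at_threshold(inst$scores, inst$labels, cal$threshold,
                              "lower_is_pathogenic")
  expect_equal(sum(out$predicted_class == "pathogenic" & out$label == 1), ev$tp)
  expect_equal(sum(out$predicted_class == "pathogenic" & out$label == 0), ev$fp)
  expect_equal(sum(out$predicted_class == "neutral" & out$label == 0), ev$tn)
  expect_equal(sum(out$predicted_class == "neutral" & out$label == 1), ev$fn)
})

test_that("calibrations survive a JSON round-trip, including infinite cuts", {
  set.seed(42)
  inst <- random_instance(20, 20, signal = 1)
  cal1 <- youden_threshold(inst$scores, inst$labels, "lower_is_pathogenic",
                           context = "splice_site")
  cal2 <- structure(list(context = "mito_noncoding", threshold = Inf,
                         orientation = "lower_is_pathogenic",
                         sensitivity = 1, specificity = 0, youden_j = 0),
                    class = "selv_calibration")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(list(cal1, cal2), path)
  back <- read_calibration(path)
  expect_setequal(names(back), c("splice_site", "mito_noncoding"))
  expect_equal(back$splice_site$threshold, cal1$threshold, tolerance = 1e-12)
  expect_identical(back$mito_noncoding$threshold, Inf)
  expect_equal(back$splice_site$youden_j, cal1$youden_j, tolerance = 1e-12)
  # a classification run with re-read calibrations is unchanged
  x <- data.frame(contig = "chr1", position = seq_along(inst$scores),
                  ref = "A", alt = "C", context = "splice_site",
                  selv = inst$scores)
  expect_equal(classify_variants(x, back)$predicted_class,
               classify_variants(x, cal1)$predicted_class)
})
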