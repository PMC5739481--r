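# 4-record reference cohort: scores (0.9 M, 0.7 B, 0.6 M, 0.3 B).
four_record <- function() {
  scored_cohort(paste0("L", 1:4), c(0.9, 0.7, 0.6, 0.3), c(1, 0, 1, 0))
}

test_that("confusion counts follow the score >= threshold rule", {
  co <- scored_cohort(paste0("L", 1:4), c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  cm <- confusion_at_threshold(co, 0.5)
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  cm0 <- confusion_at_threshold(co, 0)
  expect_equal(unlist(cm0[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 2L, TN = 0L, FN = 0L))
  cm65 <- confusion_at_threshold(four_record(), 0.65)
  expect_equal(unlist(cm65[c("TP", "FP", "TN", "FN")]),
               c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  # counts partition the cohort at any threshold
  for (t in c(-1, 0.3, 0.6, 0.9, 2)) {
    cm <- confusion_at_threshold(four_record(), t)
    expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, 4L)
  }
})

test_that("roc_curve enumerates tie-grouped operating points with endpoints", {
  curve <- roc_curve(four_record())
  expect_equal(curve$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(curve$tpr, c(0, 0.5, 0.5, 1, 1))

  # perfectly separated cohort passes through (0, 1)
  cp <- roc_curve(perfect_cohort())
  expect_true(any(cp$fpr == 0 & cp$tpr == 1))

  # total tie: endpoints plus the single point (1,1)
  ct <- roc_curve(scored_cohort(paste0("L", 1:4), rep(0.5, 4), c(1, 0, 1, 0)))
  expect_equal(ct$fpr, c(0, 1))
  expect_equal(ct$tpr, c(0, 1))
  expect_equal(auc_roc(ct), 0.5)

  expect_error(roc_curve(scored_cohort("a", 0.5, 1)), "at least one")
})

test_that("auc_roc equals the pairwise oracle and honours label-swap duality", {
  expect_equal(auc_roc(four_record()), 0.75)
  expect_equal(auc_roc(perfect_cohort()), 1)
  for (seed in 1:25) {
    co <- random_cohort(sample(4:60, 1L), seed)
    expect_equal(auc_roc(co), oracle_auc(co))
    swapped <- scored_cohort(co$lesion_id, co$score,
                             ifelse(co$label == "malignant", 0L, 1L))
    expect_equal(auc_roc(swapped), 1 - auc_roc(co))
  }
})

test_that("auc_roc agrees with pROC on a tie-heavy cohort", {
  co <- random_cohort(150, seed = 42, tie_heavy = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = co$label, predictor = co$score,
    levels = c("benign", "malignant"), direction = "<", quiet = TRUE)))
  expect_equal(auc_roc(co), ref)
})

test_that("average precision is the uninterpolated step-sum", {
  # descending labels M,B,M,B -> (1 + 2/3) / 2
  co <- scored_cohort(paste0("L", 1:4), c(0.9, 0.7, 0.6, 0.3), c(1, 0, 1, 0))
  expect_equal(average_precision(co), (1 + 2 / 3) / 2)
  expect_equal(average_precision(perfect_cohort()), 1)
  # single malignant ranked last of n -> 1/n
  n <- 7L
  last <- scored_cohort(paste0("L", 1:n), seq(0.9, 0.3, length.out = n),
                        c(rep(0L, n - 1L), 1L))
  expect_equal(average_precision(last), 1 / n)
  for (seed in 26:50) {
    co <- random_cohort(sample(4:60, 1L), seed)
    expect_equal(average_precision(co), oracle_ap(co))
  }
})

test_that("specificity at sensitivity picks the best qualifying operating point", {
  co <- scored_cohort(paste0("L", 1:5), c(0.9, 0.8, 0.7, 0.4, 0.2),
                      c(1, 1, 0, 1, 0))
  s <- specificity_at_sensitivity(co, 0.95)
  expect_equal(s$specificity, 0.5)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$threshold, 0.4)

  # perfect separation: any target gives 1
  for (t in c(0.5, 0.95, 0.99, 1)) {
    expect_equal(specificity_at_sensitivity(perfect_cohort(), t)$specificity, 1)
  }

  # target 1 is the operating point at the lowest malignant score
  co2 <- random_cohort(40, 7)
  s1 <- specificity_at_sensitivity(co2, 1)
  tmin <- min(co2$score[co2$label == "malignant"])
  expect_equal(s1$specificity,
               confusion_at_threshold(co2, tmin)$specificity)
})

test_that("specificity at sensitivity is non-increasing in the target", {
  targets <- c(0.5, 0.8, 0.9, 0.95, 0.98, 0.99, 1)
  for (seed in 51:80) {
    co <- random_cohort(sample(5:80, 1L), seed)
    spec <- vapply(targets,
                   function(t) specificity_at_sensitivity(co, t)$specificity,
                   numeric(1L))
    expect_true(all(diff(spec) <= 1e-12))
  }
})

test_that("linear-interpolation variant brackets the empirical rule", {
  co <- scored_cohort(paste0("L", 1:5), c(0.9, 0.8, 0.7, 0.4, 0.2),
                      c(1, 1, 0, 1, 0))
  emp <- specificity_at_sensitivity(co, 0.95)$specificity
  lin <- specificity_at_sensitivity(co, 0.95, interpolate = "linear")$specificity
  expect_gte(lin, emp)
  expect_equal(specificity_at_sensitivity(co, 1, interpolate = "linear")$specificity,
               specificity_at_sensitivity(co, 1)$specificity)
})

test_that("partial AUC integrates specificity over the sensitivity band", {
  expect_equal(partial_auc_roc(perfect_cohort(), 0.95),
               list(raw = 0.05, normalized = 1))
  # normalised partial AUC of a perfect classifier is 1 for every band
  for (lo in c(0.2, 0.5, 0.9, 0.99)) {
    expect_equal(partial_auc_roc(perfect_cohort(), lo)$normalized, 1)
  }
  # fpr = 1 everywhere above the cut: scores anti-separated
  anti <- scored_cohort(paste0("L", 1:4), c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))
  expect_equal(partial_auc_roc(anti, 0.95)$raw, 0)
  # 4-record cohort, band [0.5, 1]
  co <- scored_cohort(paste0("L", 1:4), c(0.9, 0.7, 0.6, 0.3), c(1, 0, 1, 0))
  pa <- partial_auc_roc(co, 0.5)
  expect_equal(pa$raw, 0.25)
  expect_equal(pa$normalized, 0.5)
})

test_that("measure panel is internally consistent and complete", {
  p <- measure_panel(perfect_cohort())
  expect_equal(unlist(p),
               c(average_precision = 1, auc_roc = 1, spec_at_se95 = 1,
                 spec_at_se98 = 1, spec_at_se99 = 1,
                 pauc_se95_100_raw = 0.05, pauc_se95_100_norm = 1))

  # anti-perfect classifier floors every measure
  anti <- scored_cohort(paste0("L", 1:8), seq(0.9, 0.2, length.out = 8),
                        c(0, 0, 0, 0, 0, 1, 1, 1))
  pa <- measure_panel(anti)
  expect_equal(pa$auc_roc, 0)
  expect_equal(pa$spec_at_se95, 0)
  expect_equal(pa$pauc_se95_100_raw, 0)

  # monotone ordering of the high-sensitivity measures
  for (seed in 81:100) {
    co <- random_cohort(sample(10:100, 1L), seed)
    p <- measure_panel(co)
    expect_gte(p$spec_at_se95, p$spec_at_se98)
    expect_gte(p$spec_at_se98, p$spec_at_se99)
    expect_equal(p$pauc_se95_100_norm, p$pauc_se95_100_raw / 0.05)
  }
})

test_that("random scores give chance-level AUC on a large cohort", {
  set.seed(99)
  co <- scored_cohort(paste0("L", 1:2000), runif(2000),
                      sample(c(0, 1), 2000, replace = TRUE, prob = c(0.8, 0.2)))
  expect_lt(abs(auc_roc(co) - 0.5), 0.05)
})

test_that("every panel measure is invariant to strictly increasing score maps", {
  for (seed in 101:115) {
    co <- random_cohort(sample(10:80, 1L), seed)
    tr <- scored_cohort(co$lesion_id, co$score^3, co$label)
    expect_equal(unlist(measure_panel(tr)), unlist(measure_panel(co)))
  }
})
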