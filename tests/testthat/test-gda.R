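test_that("1-D LDA fit recovers hand-computed means and pooled variance", {
  ft <- feature_table(data.frame(f1 = c(-1, 1, 1, 3)), label = c(0, 0, 1, 1))
  m <- fit_gda(ft, "lda", ridge = 0)
  expect_equal(unname(m$means[, 1]), c(0, 2))
  expect_equal(m$cov$benign[1, 1], 2)       # (2 + 2) / (4 - 2)
  expect_identical(m$cov$benign, m$cov$malignant)
})

test_that("diagonal variants equal full variants with zeroed off-diagonals", {
  ft <- small_features(60, seed = 5, d = 3L)
  for (pair in list(c("qda", "dqda"), c("lda", "dlda"))) {
    full <- fit_gda(ft, pair[1], ridge = 1e-8)
    diag_ <- fit_gda(ft, pair[2], ridge = 1e-8)
    for (cl in c("benign", "malignant")) {
      expect_equal(unname(diag_$cov[[cl]]), diag(diag(full$cov[[cl]])))
    }
    expect_equal(diag_$means, full$means)
  }
})

test_that("singular covariance without ridge errors naming the variant", {
  # d = 3 with 2 rows per class: full covariance is rank deficient
  x <- data.frame(f1 = c(0, 1, 2, 3), f2 = c(0, 1, 2, 3), f3 = c(1, 1, 2, 2))
  ft <- feature_table(x, label = c(0, 0, 1, 1))
  expect_error(fit_gda(ft, "qda", ridge = 0), "qda")
  # default ridge rescues it
  expect_s3_class(fit_gda(ft, "qda"), "gda_model")
  expect_error(fit_gda(feature_table(data.frame(f1 = c(1, 2, 3)), c(0, 1, 1)),
                       "lda"), "at least 2 rows")
})

test_that("large-sample fit recovers the generating parameters", {
  ft <- simulate_feature_table(n = 20000, n_pos = 10000,
                               mu0 = c(0, -1), mu1 = c(1.5, 0.5),
                               sigma0 = diag(2), sigma1 = diag(2) * 2,
                               seed = 11)
  m <- fit_gda(ft, "qda")
  expect_lt(max(abs(m$means["benign", ] - c(0, -1))), 0.05)
  expect_lt(max(abs(m$means["malignant", ] - c(1.5, 0.5))), 0.05)
  expect_lt(max(abs(m$cov$malignant - diag(2) * 2)), 0.15)
  expect_equal(m$prior1, 0.5)
})

test_that("posterior matches the closed-form 1-D log-odds", {
  # mu0 = -1, mu1 = 1, shared variance 1, equal priors
  ft <- feature_table(data.frame(f1 = c(-2, -1, 0, 0, 1, 2)),
                      label = c(0, 0, 0, 1, 1, 1))
  m <- fit_gda(ft, "lda", ridge = 0)   # pooled var (2 + 2) / 4 = 1
  expect_equal(as.numeric(posterior(m, 0)), 0.5)
  expect_equal(as.numeric(posterior(m, 1)), stats::plogis(2))
  # closed form: logit p = (mu1 - mu0) x / s2 - (mu1^2 - mu0^2) / (2 s2)
  for (x in c(-1.5, 0.3, 2.5)) {
    expect_equal(as.numeric(posterior(m, x)), stats::plogis(2 * x))
  }
  expect_error(posterior(m, NaN), "non-finite")
})

test_that("posterior agrees with MASS lda/qda", {
  ft <- small_features(80, seed = 21, d = 2L)
  x <- cbind(f1 = as.data.frame(ft)$f1, f2 = as.data.frame(ft)$f2)
  y <- factor(as.data.frame(ft)$label)
  for (v in c("lda", "qda")) {
    ref_fit <- if (v == "lda") MASS::lda(x, y) else MASS::qda(x, y)
    ref <- predict(ref_fit, x)$posterior[, "malignant"]
    mine <- as.numeric(posterior(fit_gda(ft, v, ridge = 0), x))
    expect_equal(mine, unname(ref), tolerance = 1e-10)
  }
})

test_that("a prior override pushes the posterior monotonically to its limit", {
  ft <- small_features(50, seed = 31)
  m <- fit_gda(ft, "lda")
  x <- as.matrix(as.data.frame(ft)[, c("f1", "f2")])[1, , drop = FALSE]
  priors <- c(0.001, 0.1, 0.5, 0.9, 0.999)
  p <- vapply(priors, function(pi) as.numeric(posterior(m, x, prior = pi)),
              numeric(1L))
  expect_true(all(diff(p) > 0))
  expect_gt(as.numeric(posterior(m, x, prior = 1 - 1e-12)), 0.999)
})

test_that("saturation is flagged at working precision and relaxes toward prior 1/2", {
  # degenerate single-point classes force saturated posteriors
  ft <- feature_table(data.frame(f1 = c(0, 0, 100, 100)), label = c(0, 0, 1, 1))
  m <- fit_gda(ft, "lda", ridge = 1e-3)
  p <- posterior(m, c(0, 100))
  expect_true(all(attr(p, "saturated")))

  ftw <- small_features(60, seed = 41, sep = 3)
  mw <- fit_gda(ftw, "lda")
  xw <- as.matrix(as.data.frame(ftw)[, c("f1", "f2")])
  sat_count <- vapply(c(1e-14, 1e-8, 1e-3, 0.5),
                      function(pi) sum(attr(posterior(mw, xw, prior = pi),
                                            "saturated")),
                      numeric(1L))
  expect_true(all(diff(sat_count) <= 0))
})

test_that("QDA with forced-equal class covariances reproduces LDA posteriors", {
  set.seed(13)
  z <- matrix(rnorm(40), 20, 2)
  x <- rbind(z, sweep(z, 2L, c(2, 1), "+"))   # identical within-class residuals
  ft <- feature_table(as.data.frame(`colnames<-`(x, c("f1", "f2"))),
                      label = rep(c(0, 1), each = 20))
  grid <- as.matrix(expand.grid(f1 = seq(-2, 4, 1), f2 = seq(-2, 3, 1)))
  p_lda <- as.numeric(posterior(fit_gda(ft, "lda", ridge = 0), grid))
  p_qda <- as.numeric(posterior(fit_gda(ft, "qda", ridge = 0), grid))
  expect_equal(p_qda, p_lda, tolerance = 1e-10)
})

test_that("dLDA converges to LDA on diagonal-covariance populations", {
  ft <- simulate_feature_table(n = 20000, n_pos = 10000,
                               mu0 = c(0, 0), mu1 = c(1, 0.5),
                               sigma0 = diag(c(1, 2)), sigma1 = diag(c(1, 2)),
                               seed = 17)
  grid <- as.matrix(expand.grid(f1 = seq(-2, 3, 0.5), f2 = seq(-3, 4, 0.5)))
  colnames(grid) <- c("f1", "f2")
  p_lda <- as.numeric(posterior(fit_gda(ft, "lda"), grid))
  p_dlda <- as.numeric(posterior(fit_gda(ft, "dlda"), grid))
  expect_lt(max(abs(p_lda - p_dlda)), 0.02)
})

test_that("posterior is invariant to affine feature rescaling after refit", {
  ft <- small_features(70, seed = 51)
  x <- as.matrix(as.data.frame(ft)[, c("f1", "f2")])
  a <- c(3, 0.2); b <- c(-5, 40)
  xs <- sweep(sweep(x, 2L, a, "*"), 2L, b, "+")
  fts <- feature_table(as.data.frame(xs), feature_labels(ft))
  for (v in c("lda", "qda", "dlda", "dqda")) {
    p1 <- as.numeric(posterior(fit_gda(ft, v, ridge = 0), x))
    p2 <- as.numeric(posterior(fit_gda(fts, v, ridge = 0), xs))
    expect_equal(p1, p2, tolerance = 1e-8)
  }
})

test_that("threshold sweep yields at most n + 1 operating points and sane AUC", {
  ft <- simulate_feature_table(n = 300, n_pos = 80, mu0 = c(0, 0),
                               mu1 = c(2.5, 2.5), sigma0 = diag(2),
                               sigma1 = diag(2), seed = 61)
  m <- fit_gda(ft, "qda")
  sw <- threshold_sweep(m, ft)
  expect_lte(nrow(sw$curve), nrow(ft) + 1L)
  expect_gt(auc_roc(sw$curve), 0.95)
})

test_that("prior sweep hits (0,0), (1,1) and validates its grid", {
  ft <- small_features(40, seed = 71)
  m <- fit_gda(ft, "lda")
  ps <- prior_sweep(m, ft)
  expect_equal(ps$curve$fpr[1], 0)
  expect_equal(ps$curve$tpr[1], 0)
  expect_equal(ps$curve$fpr[nrow(ps$curve)], 1)
  expect_equal(ps$curve$tpr[nrow(ps$curve)], 1)
  expect_error(prior_sweep(m, ft, grid = c(0, 0.5)), "inside \\(0, 1\\)")
  expect_error(prior_sweep(m, ft, grid = c(0.5, 0.2)), "increasing")
})

test_that("prior sweep and threshold sweep produce identical operating points", {
  for (seed in 1:12) {
    ft <- small_features(sample(15:40, 1L), seed = 100 + seed)
    for (v in c("lda", "qda", "dlda", "dqda")) {
      m <- fit_gda(ft, v)
      expect_identical(point_set(threshold_sweep(m, ft)$curve),
                       point_set(prior_sweep(m, ft)$curve))
    }
  }
})
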