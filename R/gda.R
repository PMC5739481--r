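#' Fit a Gaussian discriminant classifier
#'
#' Fits one of four Gaussian class-conditional models to a two-class feature
#' table, with `malignant` as the positive class:
#'
#' * `lda` — shared (pooled) full covariance; linear decision boundary.
#' * `qda` — per-class full covariances; quadratic boundary.
#' * `dlda` / `dqda` — the diagonal-covariance counterparts, i.e. Gaussian
#'   naive-Bayes classifiers.
#'
#' Means are maximum-likelihood class means. The pooled covariance is the
#' within-class estimator with denominator \eqn{n - 2}; per-class covariances
#' use \eqn{n_k - 1}. A ridge is added to the diagonal to guarantee a positive
#' definite matrix when \eqn{d} approaches the class sizes; the default is
#' \eqn{10^{-6}} times the mean diagonal variance. With `ridge = 0` a
#' singular covariance is an error naming the variant.
#'
#' @param features A [feature_table()] with both classes present and at least
#'   two rows per class.
#' @param variant One of `"lda"`, `"qda"`, `"dlda"`, `"dqda"`.
#' @param ridge Non-negative ridge added to the covariance diagonal; `NULL`
#'   (default) uses `1e-6 * mean(diag(cov))`.
#' @param prior Training prior \eqn{\pi_1} for the malignant class:
#'   `"empirical"` (class fraction in `features`) or a fixed number in (0,1).
#' @return Object of class `"gda_model"`: list with `variant`, `means`
#'   (2 x d matrix, rows `benign`/`malignant`), `cov` (list of two d x d
#'   matrices, equal for the pooled variants), `prior1`, `ridge`,
#'   `feature_names`, class counts.
#' @examples
#' ft <- feature_table(data.frame(f1 = c(-1, 1, 1, 3)),
#'                     label = c(0, 0, 1, 1))
#' m <- fit_gda(ft, "lda")
#' posterior(m, data.frame(f1 = 0))
#' @export
fit_gda <- function(features, variant = c("lda", "qda", "dlda", "dqda"),
                    ridge = NULL, prior = "empirical") {
  variant <- match.arg(variant)
  stopifnot(inherits(features, "feature_table"))
  x <- feature_matrix(features)
  y <- feature_labels(features)
  classes <- c("benign", "malignant")
  nk <- table(factor(y, levels = classes))
  if (any(nk < 2L)) {
    stop("each class needs at least 2 rows to fit a Gaussian model", call. = FALSE)
  }
  d <- ncol(x)
  n <- nrow(x)
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(x[y == cl, , drop = FALSE])
  }))
  rownames(means) <- classes
  ss <- lapply(classes, function(cl) {
    xc <- sweep(x[y == cl, , drop = FALSE], 2L, means[cl, ])
    crossprod(xc)
  })
  names(ss) <- classes
  pooled <- variant %in% c("lda", "dlda")
  covs <- if (pooled) {
    S <- (ss$benign + ss$malignant) / (n - 2)
    list(benign = S, malignant = S)
  } else {
    list(benign = ss$benign / (nk[["benign"]] - 1L),
         malignant = ss$malignant / (nk[["malignant"]] - 1L))
  }
  if (variant %in% c("dlda", "dqda")) {
    covs <- lapply(covs, function(S) diag(diag(S), nrow = d))
  }
  if (is.null(ridge)) {
    ridge <- 1e-6 * mean(vapply(covs, function(S) mean(diag(S)), numeric(1L)))
  }
  stopifnot(ridge >= 0)
  covs <- lapply(covs, function(S) S + diag(ridge, d))
  chols <- lapply(covs, function(S) {
    tryCatch(chol(S), error = function(e) {
      stop(sprintf("singular covariance in %s fit (ridge = %g); increase ridge",
                   variant, ridge), call. = FALSE)
    })
  })
  prior1 <- if (identical(prior, "empirical")) {
    nk[["malignant"]] / n
  } else {
    stopifnot(is.numeric(prior), length(prior) == 1L, prior > 0, prior < 1)
    prior
  }
  structure(list(variant = variant, means = means, cov = covs,
                 chol = chols, prior1 = as.numeric(prior1), ridge = ridge,
                 feature_names = colnames(x), n = as.vector(nk)),
            class = "gda_model")
}

#' @export
print.gda_model <- function(x, ...) {
  cat(sprintf("Gaussian discriminant model (%s), d = %d, prior pi1 = %.4f\n",
              toupper(x$variant), ncol(x$means), x$prior1))
  invisible(x)
}

# log N(x; mu, Sigma) per row, using a precomputed Cholesky factor
mvn_logdens <- function(x, mu, R) {
  d <- length(mu)
  xc <- sweep(x, 2L, mu)
  z <- backsolve(R, t(xc), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

# class-conditional log-density difference log f1(x) - log f0(x); the
# prior-free part of the posterior log-odds
log_density_diff <- function(model, x) {
  x <- coerce_features(model, x)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  mvn_logdens(x, model$means["malignant", ], model$chol$malignant) -
    mvn_logdens(x, model$means["benign", ], model$chol$benign)
}

#' Posterior probability of malignancy
#'
#' Bayes posterior from the fitted class-conditional Gaussian densities and
#' the class prior, evaluated in the log domain and mapped through the
#' logistic function for numerical stability:
#' \deqn{\mathrm{logit}\, P(malignant \mid x) =
#'   \log f_1(x) - \log f_0(x) + \mathrm{logit}\, \pi_1.}
#'
#' Posteriors outside \eqn{(10^{-15}, 1 - 10^{-15})} are flagged as
#' *saturated* (attribute `"saturated"`): at working precision they are
#' indistinguishable from 0 or 1, so thresholding them cannot separate the
#' affected lesions — the motivation for the class-prior sweep
#' ([prior_sweep()]).
#'
#' @param model A fitted [fit_gda()] model.
#' @param x Feature matrix / data frame / vector (one row per lesion).
#' @param prior Optional override of the training prior \eqn{\pi_1}.
#' @return Numeric vector of posteriors in \eqn{[0,1]} with attributes
#'   `saturated` (logical) and `log_odds`.
#' @export
posterior <- function(model, x, prior = NULL) {
  stopifnot(inherits(model, "gda_model"))
  p1 <- if (is.null(prior)) model$prior1 else {
    stopifnot(is.numeric(prior), length(prior) == 1L, prior > 0, prior < 1)
    prior
  }
  lo <- log_density_diff(model, x) + stats::qlogis(p1)
  p <- stats::plogis(lo)
  structure(p, saturated = p <= 1e-15 | p >= 1 - 1e-15, log_odds = lo)
}

#' Operating curve by posterior-threshold sweep
#'
#' Scores every lesion once with the model's training prior and builds the
#' empirical ROC by adjusting the posterior threshold from 0 to 1 (every
#' distinct posterior value is an operating point; at most n + 1 points).
#'
#' @param model A fitted [fit_gda()] model.
#' @param features A labelled [feature_table()] to score.
#' @return List of class `"gda_sweep"`: `curve` (an `"operating_curve"`),
#'   `cohort` (the [scored_cohort()] of posteriors), `n_saturated`.
#' @export
threshold_sweep <- function(model, features) {
  stopifnot(inherits(features, "feature_table"))
  p <- posterior(model, feature_matrix(features))
  cohort <- scored_cohort(as.data.frame(features)$lesion_id, as.numeric(p),
                          feature_labels(features))
  structure(list(curve = roc_curve(cohort), cohort = cohort,
                 n_saturated = sum(attr(p, "saturated")),
                 mode = "threshold"),
            class = "gda_sweep")
}

#' Operating curve by class-prior sweep
#'
#' Instead of thresholding the posterior, the malignant-class prior is swept
#' from 0 to 1 and each lesion is classified by posterior \eqn{\ge 0.5} at
#' every prior. Varying the prior adds a constant to every lesion's posterior
#' log-odds, so the induced operating points coincide with those of
#' [threshold_sweep()] — but the sweep works directly on log-odds and is
#' therefore immune to posterior saturation at working precision, which is
#' the point of the construction.
#'
#' The default grid is 201 points uniform in prior log-odds over
#' \eqn{[-12, 12]}, augmented with the exact breakpoints implied by each
#' lesion's class-conditional log-density difference, so every achievable
#' operating point is hit.
#'
#' @param model A fitted [fit_gda()] model.
#' @param features A labelled [feature_table()].
#' @param grid Optional vector of priors, strictly increasing within (0,1);
#'   breakpoints are always added.
#' @return List of class `"gda_sweep"`: `curve` (distinct operating points as
#'   an `"operating_curve"`; the `threshold` column holds the prior that
#'   first realises each point), `grid`, `mode = "prior"`.
#' @export
prior_sweep <- function(model, features, grid = NULL) {
  stopifnot(inherits(features, "feature_table"))
  if (is.null(grid)) {
    eta <- seq(-12, 12, length.out = 201L)
  } else {
    if (any(grid <= 0 | grid >= 1)) {
      stop("prior grid values must lie strictly inside (0, 1)", call. = FALSE)
    }
    if (is.unsorted(grid, strictly = TRUE)) {
      stop("prior grid must be strictly increasing", call. = FALSE)
    }
    eta <- stats::qlogis(grid)
  }
  delta <- log_density_diff(model, feature_matrix(features))
  # the sweep runs on the prior log-odds scale, where lesion i flips exactly
  # at eta = -delta_i; working there keeps the breakpoints exact
  eta <- sort(unique(c(eta, -delta[is.finite(delta)])))
  y <- as.integer(feature_labels(features) == "malignant")
  np <- sum(y)
  nn <- sum(1L - y)
  pts <- vapply(eta, function(e) {
    pred <- delta + e >= 0
    c(sum(pred & y == 0L) / nn, sum(pred & y == 1L) / np)
  }, numeric(2L))
  df <- data.frame(threshold = stats::plogis(eta), fpr = pts[1L, ], tpr = pts[2L, ])
  # increasing the prior can only add malignant calls: sort accordingly and
  # keep the first prior realising each distinct point
  df <- df[order(df$fpr, df$tpr, df$threshold), ]
  dup <- duplicated(df[, c("fpr", "tpr")])
  df <- df[!dup, ]
  if (df$fpr[1L] != 0 || df$tpr[1L] != 0) {
    df <- rbind(data.frame(threshold = NA_real_, fpr = 0, tpr = 0), df)
  }
  n <- nrow(df)
  if (df$fpr[n] != 1 || df$tpr[n] != 1) {
    df <- rbind(df, data.frame(threshold = NA_real_, fpr = 1, tpr = 1))
  }
  rownames(df) <- NULL
  curve <- structure(df, n_pos = np, n_neg = nn,
                     class = c("operating_curve", "data.frame"))
  structure(list(curve = curve, grid = stats::plogis(eta), mode = "prior"),
            class = "gda_sweep")
}

#' @export
print.gda_sweep <- function(x, ...) {
  cat(sprintf("GDA %s sweep: %d operating points, AUC %.4f\n",
              x$mode, nrow(x$curve), auc_roc(x$curve)))
  invisible(x)
}

coerce_features <- function(model, x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = ncol(model$means))
  if (ncol(x) != ncol(model$means)) {
    stop(sprintf("expected %d features, got %d", ncol(model$means), ncol(x)),
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}
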