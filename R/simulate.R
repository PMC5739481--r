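#' Challenge-scale cohort specification
#'
#' Defaults mirror an open melanoma-classification challenge cohort: an
#' independent test set of 379 lesion images of which 75 are melanomas, and a
#' training set of 900 images. Class counts are fixed, not sampled: a
#' challenge test set is a fixed collection, so prevalence carries no
#' binomial noise.
#'
#' @param n_test Test-set size (default 379).
#' @param n_melanoma Number of melanomas in the test set (default 75).
#' @param n_train Training-set size (default 900).
#' @param seed Integer seed for everything derived from this cohort.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_test = 379L, n_melanoma = 75L, n_train = 900L,
                        seed = 2016L) {
  stopifnot(n_melanoma > 0L, n_melanoma < n_test, n_train > 0L)
  structure(list(n_test = as.integer(n_test),
                 n_melanoma = as.integer(n_melanoma),
                 n_train = as.integer(n_train),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Beta-mixture score distributions
#'
#' Class-conditional score distributions are mixtures of Beta components:
#' supported on \eqn{[0,1]} like posterior probabilities, with the bulk and
#' the tails independently tunable — which is exactly what engineering
#' rank-reversal behaviour requires (a small high-score benign component, or
#' melanoma scores bounded away from the benign bulk).
#'
#' @param shape1,shape2 Positive shape vectors, one entry per component.
#' @param weights Mixture weights (normalised internally); default uniform.
#' @return List of class `"beta_mix"`.
#' @export
beta_mix <- function(shape1, shape2, weights = NULL) {
  stopifnot(length(shape1) == length(shape2), all(shape1 > 0), all(shape2 > 0))
  if (is.null(weights)) weights <- rep(1, length(shape1))
  stopifnot(length(weights) == length(shape1), all(weights > 0))
  structure(list(shape1 = as.numeric(shape1), shape2 = as.numeric(shape2),
                 weights = as.numeric(weights / sum(weights))),
            class = "beta_mix")
}

as_beta_mix <- function(x) {
  if (inherits(x, "beta_mix")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(beta_mix(x[1L], x[2L]))
  stop("expected a beta_mix or a length-2 numeric c(shape1, shape2)",
       call. = FALSE)
}

#' @rdname beta_mix
#' @param n Number of draws.
#' @param mix A `"beta_mix"`.
#' @export
rbeta_mix <- function(n, mix) {
  mix <- as_beta_mix(mix)
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  stats::rbeta(n, mix$shape1[comp], mix$shape2[comp])
}

beta_mix_mean <- function(mix) {
  sum(mix$weights * mix$shape1 / (mix$shape1 + mix$shape2))
}

#' Score distribution of one synthetic system
#'
#' @param system_id System identifier.
#' @param benign,melanoma Class-conditional score distributions: a
#'   [beta_mix()] or a length-2 `c(shape1, shape2)`. A warning is issued if
#'   the melanoma mean does not exceed the benign mean (a "system" worse than
#'   chance).
#' @return List of class `"system_score_spec"`.
#' @export
system_score_spec <- function(system_id, benign, melanoma) {
  benign <- as_beta_mix(benign)
  melanoma <- as_beta_mix(melanoma)
  if (beta_mix_mean(melanoma) <= beta_mix_mean(benign)) {
    warning(sprintf("system '%s': melanoma score distribution is not above the benign one",
                    system_id))
  }
  structure(list(system_id = as.character(system_id), benign = benign,
                 melanoma = melanoma),
            class = "system_score_spec")
}

#' Simulate one system's challenge submission
#'
#' Draws per-lesion malignancy scores class-conditionally from the system's
#' Beta mixtures over a shared synthetic test cohort. Exactly
#' `cohort$n_melanoma` lesions are malignant; which ones is decided once per
#' cohort (by `cohort$seed`), so every system scored on the same cohort sees
#' the same ground truth. Scores are rounded to 10 decimals, matching the
#' on-disk precision, so results are identical whether or not they round-trip
#' through a file.
#'
#' @param spec A [system_score_spec()].
#' @param cohort A [cohort_spec()].
#' @param seed Seed for the score draws; default derives deterministically
#'   from the cohort seed and the system id so systems on one cohort get
#'   distinct streams.
#' @return List with `submission` (lesion_id, score) and `truth`
#'   (lesion_id, label) data frames, and `cohort`.
#' @export
simulate_cohort_scores <- function(spec, cohort = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "system_score_spec"), inherits(cohort, "cohort_spec"))
  n <- cohort$n_test
  ids <- sprintf("SYN_%06d", seq_len(n))
  set.seed(cohort$seed)
  pos <- sample.int(n, cohort$n_melanoma)
  label <- rep("benign", n)
  label[pos] <- "malignant"
  if (is.null(seed)) {
    seed <- (cohort$seed + 131 * sum(utf8ToInt(spec$system_id))) %% (2^31 - 1)
  }
  set.seed(as.integer(seed))
  score <- numeric(n)
  score[pos] <- rbeta_mix(length(pos), spec$melanoma)
  score[-pos] <- rbeta_mix(n - length(pos), spec$benign)
  score <- round(score, 10)
  list(submission = data.frame(lesion_id = ids, score = score,
                               stringsAsFactors = FALSE),
       truth = data.frame(lesion_id = ids, label = label,
                          stringsAsFactors = FALSE),
       cohort = cohort)
}

#' Simulate a Gaussian feature table
#'
#' Class-conditional multivariate Gaussian features for the classifier
#' experiments: `n_pos` malignant rows from \eqn{N(\mu_1, \Sigma_1)} and
#' `n - n_pos` benign rows from \eqn{N(\mu_0, \Sigma_0)}.
#'
#' @param n Total rows; defaults mirror the test cohort (379, 75 malignant).
#' @param n_pos Number of malignant rows.
#' @param mu0,mu1 Class mean vectors (length d).
#' @param sigma0,sigma1 Class covariance matrices (d x d, symmetric positive
#'   definite; scalars allowed for d = 1).
#' @param seed Integer seed.
#' @return A [feature_table()] with features `f1..fd`.
#' @export
simulate_feature_table <- function(n = 379L, n_pos = 75L, mu0, mu1,
                                   sigma0, sigma1, seed = 1L) {
  stopifnot(n_pos > 0L, n_pos < n)
  mu0 <- as.numeric(mu0); mu1 <- as.numeric(mu1)
  d <- length(mu0)
  stopifnot(length(mu1) == d)
  sigma0 <- as_pd_matrix(sigma0, d, "sigma0")
  sigma1 <- as_pd_matrix(sigma1, d, "sigma1")
  set.seed(as.integer(seed))
  x <- matrix(NA_real_, n, d)
  lab <- rep("benign", n)
  pos <- sample.int(n, n_pos)
  lab[pos] <- "malignant"
  x[pos, ] <- MASS::mvrnorm(n_pos, mu1, sigma1)
  x[-pos, ] <- MASS::mvrnorm(n - n_pos, mu0, sigma0)
  colnames(x) <- paste0("f", seq_len(d))
  feature_table(x, lab, lesion_id = sprintf("SYN_%06d", seq_len(n)))
}

as_pd_matrix <- function(s, d, what) {
  if (is.null(dim(s))) {
    if (length(s) == 1L) s <- diag(as.numeric(s), d) else
      if (length(s) == d) s <- diag(as.numeric(s), d) else
        stop(sprintf("%s has wrong length", what), call. = FALSE)
  }
  s <- as.matrix(s)
  if (!isSymmetric(s, tol = 1e-10)) {
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
  }
  ev <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop(sprintf("%s is not positive definite", what), call. = FALSE)
  s
}

#' The shipped rank-reversal system archetypes
#'
#' Frozen Beta-mixture parameters for the 25-system suite. Three archetypes
#' bracket the behaviour the leaderboard analysis is about:
#'
#' * `global-optimiser` (`SYS_A`) — excellent bulk separation (top average
#'   precision) but a small fraction of melanomas scoring down among the
#'   benign lesions, plus a thin high-scoring benign tail: reaching 98%
#'   sensitivity forces the threshold under the stragglers and specificity
#'   collapses.
#' * `high-sensitivity-optimiser` (`SYS_C`) — melanoma scores bounded away
#'   from the benign bulk (excellent specificity at 98-99% sensitivity) but
#'   more benign mass among the melanoma bulk, so its global measures are
#'   unremarkable.
#' * `mediocre` (`SYS_B`, `SYS_D`...`SYS_Y`) — a graded family of ordinary
#'   single-component systems spanning weak to good.
#'
#' The constants were chosen once and are shipped frozen so the engineered
#' leaderboard behaviour is a stable, testable property of the package.
#'
#' @return Named list of [system_score_spec()], length 25.
#' @export
rank_reversal_archetypes <- function() {
  ids <- paste0("SYS_", LETTERS[1:25])
  specs <- vector("list", 25L)
  names(specs) <- ids
  specs[["SYS_A"]] <- system_score_spec(
    "SYS_A",
    benign = beta_mix(c(1.5, 12), c(9, 3), weights = c(0.97, 0.03)),
    melanoma = beta_mix(c(30, 1.5), c(1.5, 6), weights = c(0.9, 0.1)))
  specs[["SYS_C"]] <- system_score_spec(
    "SYS_C",
    benign = beta_mix(c(2.2, 6), c(6, 6), weights = c(0.7, 0.3)),
    melanoma = beta_mix(30, 10))
  # graded mediocre family: melanoma Beta(a1, 2.5) vs benign Beta(2, b0)
  a1 <- seq(2.4, 4.8, length.out = 23L)
  b0 <- seq(5, 7, length.out = 23L)
  med_ids <- setdiff(ids, c("SYS_A", "SYS_C"))
  for (i in seq_along(med_ids)) {
    specs[[med_ids[i]]] <- system_score_spec(
      med_ids[i],
      benign = beta_mix(2, b0[i]),
      melanoma = beta_mix(a1[i], 2.5))
  }
  specs
}

#' Generate the 25-system rank-reversal suite
#'
#' One shared synthetic test cohort (defaults: 379 lesions, 75 melanomas) and
#' 25 systems — the participation count of the challenge part the suite
#' emulates — drawn from the frozen [rank_reversal_archetypes()]. With the
#' default seed the suite exhibits the leaderboard phenomenon the package
#' exists to study: the `global-optimiser` tops the average-precision ranking
#' yet drops at least five rank positions under specificity-at-98%-
#' sensitivity.
#'
#' @param seed Suite seed (default 2016).
#' @param cohort Optional [cohort_spec()]; defaults to `cohort_spec(seed = seed)`.
#' @return List of class `"reversal_suite"`: `truth` data frame, `submissions`
#'   (named list of submission data frames), `specs`, `cohort`, `archetypes`
#'   (named id map).
#' @export
make_rank_reversal_suite <- function(seed = 2016L, cohort = NULL) {
  if (is.null(cohort)) cohort <- cohort_spec(seed = seed)
  specs <- rank_reversal_archetypes()
  sims <- lapply(specs, simulate_cohort_scores, cohort = cohort)
  structure(list(
    truth = sims[[1L]]$truth,
    submissions = lapply(sims, `[[`, "submission"),
    specs = specs,
    cohort = cohort,
    archetypes = c(`global-optimiser` = "SYS_A",
                   `high-sensitivity-optimiser` = "SYS_C",
                   mediocre = "SYS_B")),
    class = "reversal_suite")
}

#' @export
print.reversal_suite <- function(x, ...) {
  cat(sprintf("Rank-reversal suite: %d systems on a %d-lesion cohort (%d melanomas), seed %d\n",
              length(x$submissions), x$cohort$n_test, x$cohort$n_melanoma,
              x$cohort$seed))
  invisible(x)
}

#' Measure panels for every system of a suite
#'
#' @param suite A `"reversal_suite"`.
#' @param ... Passed to [measure_panel()].
#' @return Named list of `"measure_panel"`, one per system.
#' @export
suite_panels <- function(suite, ...) {
  stopifnot(inherits(suite, "reversal_suite"))
  lapply(suite$submissions, function(sub) {
    measure_panel(join_cohort(sub, suite$truth), ...)
  })
}
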