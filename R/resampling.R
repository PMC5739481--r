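#' Cross-validated measure panel for a GDA classifier
#'
#' Stratified k-fold cross-validation of a Gaussian discriminant classifier:
#' the model is fitted on k-1 folds and the held-out lesions are scored with
#' their posterior probability of malignancy. Two aggregations are available:
#'
#' * `"pooled"` (default) — all out-of-fold posteriors are pooled into one
#'   cohort and the measure panel is computed once. With only tens of
#'   melanomas per fold the high-sensitivity measures are dominated by one or
#'   two lesions per fold, so pooling is the stabilising choice.
#' * `"per_fold"` — the panel is computed per fold and averaged.
#'
#' Per-fold panels are reported in either case (a fold that ends up
#' single-class, e.g. under leave-one-out, gets `NA`s); their spread yields
#' the standard errors.
#'
#' @param features A [feature_table()].
#' @param variant GDA variant, see [fit_gda()].
#' @param k Number of folds, `>= 2`; each class must have at least `k` rows.
#' @param seed Integer seed controlling the fold assignment.
#' @param ridge Passed to [fit_gda()].
#' @param aggregate `"pooled"` or `"per_fold"`.
#' @param se_targets,pauc_lo Passed to [measure_panel()].
#' @return Object of class `"resampled_panel"`: list with `estimate` (named
#'   numeric), `se`, `ci` (2.5/97.5 percentile over resamples), `resamples`
#'   (data frame of per-fold panels), `pooled_cohort` and `scheme`.
#' @export
cv_panel <- function(features, variant = "lda", k = 5L, seed = 1L,
                     ridge = NULL, aggregate = c("pooled", "per_fold"),
                     se_targets = c(0.95, 0.98, 0.99), pauc_lo = 0.95) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(features, "feature_table"), k >= 2L)
  y <- feature_labels(features)
  n <- nrow(features)
  nk <- table(factor(y, levels = c("benign", "malignant")))
  if (k != n && any(nk < k)) {
    # k = n is leave-one-out: singleton folds cannot be stratified and their
    # per-fold panels are undefined; only the pooled panel is meaningful
    stop(sprintf("each class needs at least k = %d rows (got %d benign, %d malignant)",
                 k, nk[["benign"]], nk[["malignant"]]), call. = FALSE)
  }
  fold <- integer(n)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (k == n) {
    fold <- seq_len(n)
  } else {
    for (cl in c("benign", "malignant")) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  x <- feature_matrix(features)
  ids <- as.data.frame(features)$lesion_id
  scores <- numeric(n)
  fold_panels <- vector("list", k)
  for (i in seq_len(k)) {
    test <- fold == i
    train_ft <- feature_table(x[!test, , drop = FALSE], y[!test],
                              lesion_id = ids[!test])
    model <- fit_gda(train_ft, variant, ridge = ridge)
    scores[test] <- as.numeric(posterior(model, x[test, , drop = FALSE]))
    fold_panels[i] <- list(if (length(unique(y[test])) == 2L) {
      unlist(measure_panel(scored_cohort(ids[test], scores[test], y[test]),
                           se_targets = se_targets, pauc_lo = pauc_lo))
    } else NULL)
  }
  pooled <- scored_cohort(ids, scores, y)
  pooled_panel <- unlist(measure_panel(pooled, se_targets = se_targets,
                                       pauc_lo = pauc_lo))
  res <- do.call(rbind, lapply(fold_panels, function(p) {
    if (is.null(p)) rep(NA_real_, length(pooled_panel)) else p
  }))
  colnames(res) <- names(pooled_panel)
  res <- as.data.frame(res)
  estimate <- if (aggregate == "pooled") pooled_panel else {
    colMeans(res, na.rm = TRUE)
  }
  new_resampled_panel(estimate, res,
                      scheme = list(method = "cv", k = k, seed = seed,
                                    variant = variant, aggregate = aggregate),
                      pooled_cohort = pooled)
}

#' Bootstrap measure panel for a scored cohort
#'
#' Resamples the cohort B times with replacement and recomputes the measure
#' panel on each resample; reports the mean, standard error and the 2.5/97.5
#' percentile interval per measure. The stratified bootstrap (default)
#' resamples melanomas and benign lesions separately so every resample keeps
#' the original class counts — on a cohort with few melanomas this is what
#' keeps the high-sensitivity measures defined in every resample. An
#' unstratified resample that ends up single-class is dropped (and counted in
#' the scheme descriptor); it is an error if all B are dropped.
#'
#' @param cohort A [scored_cohort()].
#' @param B Number of bootstrap resamples, `>= 1`.
#' @param seed Integer master seed; resample b uses the derived seed
#'   `(seed + 7919 * b) mod (2^31 - 1)`, so panels are reproducible and
#'   independent of evaluation order.
#' @param stratified Resample within class (default `TRUE`).
#' @param se_targets,pauc_lo Passed to [measure_panel()].
#' @return A `"resampled_panel"` (see [cv_panel()]).
#' @export
bootstrap_panel <- function(cohort, B = 1000L, seed = 1L, stratified = TRUE,
                            se_targets = c(0.95, 0.98, 0.99), pauc_lo = 0.95) {
  stopifnot(inherits(cohort, "scored_cohort"), B >= 1L)
  assert_two_class(cohort)
  y <- label01(cohort)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  n <- nrow(cohort)
  panels <- vector("list", B)
  dropped <- 0L
  base_seed <- as.numeric(seed)
  for (b in seq_len(B)) {
    set.seed(as.integer((base_seed + 7919 * b) %% (2^31 - 1)))
    idx <- if (stratified) {
      c(sample(pos, length(pos), replace = TRUE),
        sample(neg, length(neg), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    yb <- y[idx]
    if (sum(yb) == 0L || sum(yb) == length(yb)) {
      dropped <- dropped + 1L
      next
    }
    co <- scored_cohort(paste0("B", seq_along(idx)), cohort$score[idx],
                        yb)
    panels[[b]] <- unlist(measure_panel(co, se_targets = se_targets,
                                        pauc_lo = pauc_lo))
  }
  panels <- panels[!vapply(panels, is.null, logical(1L))]
  if (!length(panels)) {
    stop("all bootstrap resamples were single-class; use stratified = TRUE",
         call. = FALSE)
  }
  if (dropped > 0L) {
    message(sprintf("bootstrap_panel: dropped %d single-class resample(s)", dropped))
  }
  res <- as.data.frame(do.call(rbind, panels))
  new_resampled_panel(colMeans(res), res,
                      scheme = list(method = "bootstrap", B = B, seed = seed,
                                    stratified = stratified, dropped = dropped))
}

new_resampled_panel <- function(estimate, resamples, scheme,
                                pooled_cohort = NULL) {
  m <- as.matrix(resamples)
  # bootstrap SE is the sd of the replicates; for CV the replicates are folds
  # and the SE of their mean divides by sqrt(#folds)
  se <- apply(m, 2L, stats::sd, na.rm = TRUE)
  if (identical(scheme$method, "cv")) {
    se <- se / sqrt(pmax(colSums(!is.na(m)), 1L))
  }
  ci <- apply(m, 2L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(estimate = estimate, se = se, ci = ci,
                 resamples = resamples, scheme = scheme,
                 pooled_cohort = pooled_cohort),
            class = "resampled_panel")
}

#' @export
print.resampled_panel <- function(x, digits = 4, ...) {
  s <- x$scheme
  hdr <- if (s$method == "cv") {
    sprintf("%d-fold CV (%s, %s, seed %s)", s$k, s$variant, s$aggregate, s$seed)
  } else {
    sprintf("bootstrap B=%d (%s, seed %s)", s$B,
            if (s$stratified) "stratified" else "unstratified", s$seed)
  }
  cat("Resampled measure panel —", hdr, "\n")
  for (nm in names(x$estimate)) {
    cat(sprintf("  %-20s %.*f  (se %.4f, 95%% CI [%.4f, %.4f])\n",
                nm, digits, x$estimate[[nm]], x$se[[nm]],
                x$ci[1L, nm], x$ci[2L, nm]))
  }
  invisible(x)
}
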