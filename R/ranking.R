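#' Rank systems by multiple accuracy measures
#'
#' Builds the leaderboard view: one integer rank per system and measure, where
#' a larger measure value is always better (all seven panel measures are
#' oriented that way) and ties are resolved by *competition ranking* — tied
#' systems share the smallest applicable rank and the next rank is skipped
#' ("1224"). Column order is by system id for display determinism only; it
#' never affects the ranks.
#'
#' @param entries Named list of [measure_panel()] objects (names are the
#'   system ids), or a data frame / matrix with systems as rows, measures as
#'   columns and system ids as row names.
#' @param measures Optional character subset of measures to rank on; default
#'   all measures present in every panel.
#' @return Object of class `"rank_table"`: list with `ranks` (measures x
#'   systems integer matrix), `scores` (same shape, the underlying values),
#'   `systems`, `measures`.
#' @examples
#' s <- rbind(A = c(auc_roc = 0.9), B = c(auc_roc = 0.8), C = c(auc_roc = 0.8))
#' rank_systems(s)$ranks
#' @export
rank_systems <- function(entries, measures = NULL) {
  if (is.list(entries) && !is.data.frame(entries) &&
      all(vapply(entries, inherits, logical(1L), "measure_panel"))) {
    ids <- names(entries)
    if (is.null(ids) || any(!nzchar(ids))) {
      stop("panels must be named by system id", call. = FALSE)
    }
    scores <- do.call(rbind, lapply(entries, unlist))
    rownames(scores) <- ids
  } else {
    scores <- as.matrix(entries)
  }
  if (is.null(rownames(scores))) stop("system ids missing", call. = FALSE)
  if (anyDuplicated(rownames(scores))) {
    stop(sprintf("duplicate system id(s): %s",
                 paste(unique(rownames(scores)[duplicated(rownames(scores))]),
                       collapse = ", ")), call. = FALSE)
  }
  if (nrow(scores) < 2L) stop("need at least 2 systems to rank", call. = FALSE)
  if (is.null(measures)) measures <- colnames(scores)
  missing <- setdiff(measures, colnames(scores))
  if (length(missing)) {
    stop(sprintf("measure(s) not present in every panel: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  scores <- scores[order(rownames(scores)), measures, drop = FALSE]
  ranks <- apply(scores, 2L, competition_rank)
  structure(list(ranks = t(ranks), scores = t(scores),
                 systems = rownames(scores), measures = measures),
            class = "rank_table")
}

# competition ("1224") ranking, higher value = better (rank 1)
competition_rank <- function(v) {
  vapply(v, function(x) 1L + sum(v > x), integer(1L))
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("Rank table: %d systems x %d measures (competition ranking)\n",
              length(x$systems), length(x$measures)))
  print(x$ranks)
  invisible(x)
}

#' Write / read a rank table
#'
#' Plain CSV, one row per measure and one column per system, integer ranks;
#' round-trips exactly through [read_rank_table()] (the underlying scores are
#' not serialised).
#'
#' @param table A `"rank_table"`.
#' @param path Output path.
#' @return `path` invisibly; the reader returns a `"rank_table"` whose
#'   `scores` are `NA`.
#' @export
write_rank_table <- function(table, path) {
  stopifnot(inherits(table, "rank_table"))
  df <- data.frame(measure = table$measures, table$ranks,
                   check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write rank table to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_rank_table
#' @export
read_rank_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "measure" || ncol(df) < 3L) {
    stop(sprintf("'%s' is not a rank-table CSV", path), call. = FALSE)
  }
  ranks <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(ranks == round(ranks))) {
    stop("rank table contains non-integer ranks", call. = FALSE)
  }
  storage.mode(ranks) <- "integer"
  rownames(ranks) <- df$measure
  structure(list(ranks = ranks,
                 scores = matrix(NA_real_, nrow(ranks), ncol(ranks),
                                 dimnames = dimnames(ranks)),
                 systems = colnames(ranks), measures = df$measure),
            class = "rank_table")
}

#' Kendall's tau-b rank correlation
#'
#' Exhaustive pair-count implementation with the tie correction:
#' \eqn{\tau_b = (C - D)/\sqrt{(n_0 - n_1)(n_0 - n_2)}} where C/D are the
#' concordant/discordant pair counts, \eqn{n_0 = \binom{n}{2}} and
#' \eqn{n_1, n_2} are the within-tie pair counts of each vector. Quadratic in
#' the number of systems, which is the regime leaderboards live in.
#'
#' @param x,y Numeric vectors of equal length (typically rank vectors).
#' @return tau-b in \eqn{[-1, 1]} (`NaN` if either vector is constant).
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  C <- sum(s > 0)
  D <- sum(s < 0)
  n0 <- sum(up)
  n1 <- sum(dx[up] == 0)
  n2 <- sum(dy[up] == 0)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

#' Rank-instability report
#'
#' Quantifies how much the leaderboard depends on the choice of accuracy
#' measure: per system, the maximum rank shift across any pair of measures;
#' per measure pair, Kendall's tau-b between the two rank vectors; globally,
#' the mean and maximum per-system shift. A table where every measure induces
#' the same ordering gives shifts of 0 and tau-b of 1 throughout.
#'
#' @param table A `"rank_table"` with at least two measures.
#' @return List of class `"rank_instability"`: `max_shift` (named per-system),
#'   `tau` (measures x measures tau-b matrix), `mean_shift`, `global_max_shift`.
#' @export
rank_instability <- function(table) {
  stopifnot(inherits(table, "rank_table"))
  r <- table$ranks
  if (nrow(r) < 2L) stop("need at least two measures", call. = FALSE)
  max_shift <- apply(r, 2L, function(v) max(v) - min(v))
  m <- nrow(r)
  tau <- matrix(1, m, m, dimnames = list(rownames(r), rownames(r)))
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      tau[i, j] <- tau[j, i] <- kendall_tau_b(r[i, ], r[j, ])
    }
  }
  structure(list(max_shift = max_shift, tau = tau,
                 mean_shift = mean(max_shift),
                 global_max_shift = max(max_shift)),
            class = "rank_instability")
}

#' @export
print.rank_instability <- function(x, ...) {
  cat(sprintf("Rank instability: mean max-shift %.2f, largest shift %d\n",
              x$mean_shift, x$global_max_shift))
  cat(sprintf("  min pairwise tau-b: %.3f\n", min(x$tau)))
  invisible(x)
}
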