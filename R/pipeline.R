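#' Evaluate one submission against a ground truth
#'
#' Convenience wrapper joining a submission with its truth file and computing
#' the measure panel; the file-level analogue of [measure_panel()].
#'
#' @param submission Path to a submission CSV, or a data frame from
#'   [read_submission()].
#' @param truth Path to a ground-truth CSV, or a data frame from
#'   [read_truth()].
#' @param se_targets,pauc_lo,interpolate Passed to [measure_panel()].
#' @return A `"measure_panel"` with the joined [scored_cohort()] attached as
#'   attribute `"cohort"`.
#' @export
evaluate_submission <- function(submission, truth,
                                se_targets = c(0.95, 0.98, 0.99),
                                pauc_lo = 0.95,
                                interpolate = c("none", "linear")) {
  if (is.character(submission)) submission <- read_submission(submission)
  if (is.character(truth)) truth <- read_truth(truth)
  cohort <- join_cohort(submission, truth)
  panel <- measure_panel(cohort, se_targets = se_targets, pauc_lo = pauc_lo,
                         interpolate = interpolate)
  attr(panel, "cohort") <- cohort
  panel
}

#' Run the end-to-end challenge re-enactment pipeline
#'
#' Chains simulate -> evaluate -> rank -> report on a synthetic suite and
#' writes a self-contained report bundle to `out_dir`:
#'
#' * `truth.csv`, `submissions/<id>.csv` — the synthetic challenge data;
#' * `panels.csv` — one row per system, the seven-measure panel;
#' * `rank_table.csv` — measures x systems integer ranks;
#' * `instability.json` — per-system max rank shift, pairwise Kendall tau-b,
#'   global shift statistics;
#' * `curves/<id>_roc.csv`, `curves/<id>_pr.csv` — operating-curve points for
#'   each system that tops at least one measure;
#' * `summary.txt` — per measure, the top-ranked system and its score;
#' * `manifest.json` — the fully resolved configuration plus package version;
#'   re-running from a manifest reproduces the bundle.
#' * `log.txt` — timestamped stage log (the only file allowed to differ
#'   between reruns with identical configuration).
#'
#' Any stage failure moves the partial outputs into `out_dir/failed/` and
#' aborts with an error naming the stage.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset `"rank-reversal-suite"` (25 engineered systems) or
#'   `"challenge-cohort"` (a single mid-quality system).
#' @param seed Integer seed for the simulation stage.
#' @param se_targets,pauc_lo Passed to [measure_panel()].
#' @param quiet Suppress console messages (the log file is always written).
#' @return Invisibly, a list with the panels, rank table, instability report
#'   and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         preset = c("rank-reversal-suite", "challenge-cohort"),
                         seed = 2016L,
                         se_targets = c(0.95, 0.98, 0.99),
                         pauc_lo = 0.95,
                         quiet = FALSE) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("[%s] pipeline start (preset=%s, seed=%d)\n",
              format(Sys.time()), preset, seed),
      file = log_path)
  stage <- function(name, expr) {
    if (!quiet) message("stage: ", name)
    cat(sprintf("[%s] stage %s\n", format(Sys.time()), name),
        file = log_path, append = TRUE)
    tryCatch(expr, error = function(e) {
      failed <- file.path(out_dir, "failed")
      dir.create(failed, showWarnings = FALSE)
      keep <- setdiff(list.files(out_dir), c("failed", "log.txt"))
      file.rename(file.path(out_dir, keep), file.path(failed, keep))
      cat(sprintf("[%s] stage %s FAILED: %s\n", format(Sys.time()), name,
                  conditionMessage(e)), file = log_path, append = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  suite <- stage("simulate", {
    if (preset == "rank-reversal-suite") {
      make_rank_reversal_suite(seed = seed)
    } else {
      spec <- system_score_spec("SYS_A", benign = c(2, 6), melanoma = c(5, 2.5))
      sim <- simulate_cohort_scores(spec, cohort_spec(seed = seed))
      structure(list(truth = sim$truth,
                     submissions = list(SYS_A = sim$submission),
                     specs = list(SYS_A = spec),
                     cohort = sim$cohort,
                     archetypes = c(single = "SYS_A")),
                class = "reversal_suite")
    }
  })
  stage("write-data", {
    write_truth(suite$truth, file.path(out_dir, "truth.csv"))
    sub_dir <- file.path(out_dir, "submissions")
    dir.create(sub_dir, showWarnings = FALSE)
    for (id in names(suite$submissions)) {
      write_submission(suite$submissions[[id]],
                       file.path(sub_dir, paste0(id, ".csv")))
    }
  })
  panels <- stage("evaluate", {
    suppressMessages(suite_panels(suite, se_targets = se_targets,
                                  pauc_lo = pauc_lo))
  })
  stage("write-panels", {
    df <- data.frame(system_id = names(panels),
                     do.call(rbind, lapply(panels, unlist)))
    utils::write.csv(df, file.path(out_dir, "panels.csv"),
                     row.names = FALSE, quote = FALSE)
  })

  if (length(panels) >= 2L) {
    table <- stage("rank", rank_systems(panels))
    instab <- stage("instability", rank_instability(table))
    stage("write-rank", {
      write_rank_table(table, file.path(out_dir, "rank_table.csv"))
      jsonlite::write_json(
        list(max_shift = as.list(instab$max_shift),
             tau = as.data.frame(instab$tau),
             mean_shift = instab$mean_shift,
             global_max_shift = instab$global_max_shift),
        file.path(out_dir, "instability.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  } else {
    table <- NULL
    instab <- NULL
  }

  stage("curves", {
    curve_dir <- file.path(out_dir, "curves")
    dir.create(curve_dir, showWarnings = FALSE)
    top <- if (is.null(table)) names(panels) else {
      unique(table$systems[apply(table$ranks, 1L, which.min)])
    }
    for (id in top) {
      cohort <- join_cohort(suite$submissions[[id]], suite$truth)
      utils::write.csv(roc_curve(cohort),
                       file.path(curve_dir, paste0(id, "_roc.csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(pr_curve(cohort),
                       file.path(curve_dir, paste0(id, "_pr.csv")),
                       row.names = FALSE, quote = FALSE)
    }
  })

  stage("summary", {
    lines <- c(sprintf("Challenge re-enactment (%s, seed %d)", preset, seed),
               sprintf("%d systems on %d lesions (%d melanomas)",
                       length(panels), suite$cohort$n_test,
                       suite$cohort$n_melanoma),
               "", "Top system per measure:")
    if (!is.null(table)) {
      for (m in table$measures) {
        i <- which.min(table$ranks[m, ])
        lines <- c(lines, sprintf("  %-20s %s (score %.4f)",
                                  m, table$systems[i], table$scores[m, i]))
      }
    } else {
      lines <- c(lines, sprintf("  single system: %s",
                                names(panels)[1L]))
    }
    writeLines(lines, file.path(out_dir, "summary.txt"))
  })

  manifest <- list(package = "melrank",
                   version = as.character(utils::packageVersion("melrank")),
                   preset = preset, seed = seed,
                   se_targets = se_targets, pauc_lo = pauc_lo,
                   cohort = unclass(suite$cohort))
  stage("manifest", {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  cat(sprintf("[%s] pipeline done\n", format(Sys.time())),
      file = log_path, append = TRUE)
  invisible(list(panels = panels, rank_table = table, instability = instab,
                 manifest = manifest))
}

#' Re-run a pipeline from a written manifest
#'
#' @param manifest_path Path to a `manifest.json` written by [run_pipeline()].
#' @param out_dir Output directory for the reproduced bundle.
#' @param quiet Passed to [run_pipeline()].
#' @return See [run_pipeline()].
#' @export
run_from_manifest <- function(manifest_path, out_dir, quiet = FALSE) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  run_pipeline(out_dir, preset = m$preset, seed = as.integer(m$seed),
               se_targets = as.numeric(m$se_targets),
               pauc_lo = as.numeric(m$pauc_lo), quiet = quiet)
}
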