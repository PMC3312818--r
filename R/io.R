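# Trial-log I/O, the analysis battery over a scored table, and the
# simulate -> score -> analyze pipeline.

.log_columns <- c("subject_id", "group", "strain", "dose", "series",
                  "stage", "trial", "chosen_side", "chosen_odor",
                  "chosen_medium", "correct", "latency_s", "exploratory",
                  "stage_completed")

# deterministic short hash of a config for output manifests (simple
# polynomial rolling hash over the canonical JSON; no digest dependency)
.config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write session logs to a trial-level CSV
#'
#' One row per trial; the first line is a `#`-prefixed comment recording the
#' seed and config hash so two runs with equal hashes can be compared
#' byte-for-byte. Columns: `subject_id`, `group`, `strain`, `dose`,
#' `series`, `stage`, `trial`, `chosen_side`, `chosen_odor`,
#' `chosen_medium`, `correct`, `latency_s`, `exploratory`,
#' `stage_completed`.
#'
#' @param cohort an `asst_cohort` (or list of `asst_session`s).
#' @param path output CSV path.
#' @param seed,config_hash recorded in the header comment; the cohort's own
#'   seed attribute is used when `seed` is missing.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(cohort, path, seed = attr(cohort, "seed"),
                            config_hash = NULL) {
  df <- as.data.frame.asst_cohort(cohort)
  header <- sprintf("# setshiftr trial log; seed=%s; config_hash=%s",
                    seed %||% "NA", config_hash %||% "NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df[, .log_columns], con, row.names = FALSE)
  invisible(path)
}

#' Read session logs from a trial-level CSV
#'
#' Re-assembles `asst_session` objects from a CSV written by
#' [write_trial_log()] (or produced by real testing apparatus software with
#' the same column dictionary). Unknown extra columns are preserved in each
#' session's trial table. Malformed files are rejected with the offending
#' column or row identified.
#'
#' @param path CSV path; `#`-prefixed lines are ignored.
#' @return A list of `asst_session`s (class `asst_cohort`); empty list for
#'   a header-only file.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- setdiff(.log_columns, c("group"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trial log is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L)
    return(structure(list(), class = "asst_cohort"))
  if (!("group" %in% names(df))) df$group <- df$strain

  sessions <- lapply(split(df, df$subject_id), function(sd) {
    sd <- sd[order(match(sd$stage, asst_stages()), sd$trial), ]
    for (stg in unique(sd$stage)) {
      tr <- sd$trial[sd$stage == stg]
      if (!identical(as.integer(tr), seq_along(tr))) {
        rows <- which(df$subject_id == sd$subject_id[1] & df$stage == stg)
        stop("non-contiguous trial indices for subject ",
             sd$subject_id[1], ", stage ", stg,
             " (rows ", paste(utils::head(rows, 5), collapse = ", "), ")")
      }
    }
    completed <- vapply(split(sd$stage_completed, sd$stage),
                        function(v) as.logical(v[1]), logical(1))
    extra <- setdiff(names(sd), c("subject_id", "group", "strain", "dose",
                                  "series", "stage_completed"))
    structure(list(
      subject_id = sd$subject_id[1], strain = sd$strain[1],
      dose = sd$dose[1], series = as.integer(sd$series[1]),
      group = sd$group[1],
      trials = sd[, extra, drop = FALSE],
      completed = completed
    ), class = "asst_session")
  })
  structure(unname(sessions), class = "asst_cohort")
}

#' Run the full statistical battery on a scored table
#'
#' Mirrors the analysis applied to the animal experiments: a two-way mixed
#' RM-ANOVA (group x stage) on trials to criterion and on mean latency; a
#' group x error-subtype RM-ANOVA on per-subject subtype totals; per-stage
#' one-way ANOVAs with Fisher LSD post-hocs; paired t-tests for the CD-vs-ID
#' and ID-vs-ED set-formation contrasts within each group; and the
#' SD-vs-ED trials correlation within each group.
#'
#' @param scores an `asst_scores` data frame from [score_cohort()].
#' @param adjust multiplicity handling for the LSD tables (`"none"`, the
#'   LSD default, or `"holm"`).
#' @return A list of class `asst_analysis` with elements `anova_trials`,
#'   `anova_latency`, `anova_errors`, `posthoc` (per-stage LSD tables),
#'   `contrasts` (paired-t table) and `correlations`.
#' @export
analyze_scores <- function(scores, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  an_tr <- mixed_rm_anova(scores, "trials", "group", "stage", "subject_id")
  an_lat <- mixed_rm_anova(scores, "mean_latency_s", "group", "stage",
                           "subject_id")

  subj <- unique(scores[, c("subject_id", "group")])
  etot <- do.call(rbind, lapply(c("perseverative", "regressive",
                                  "never_reinforced"), function(tp) {
    data.frame(subject_id = subj$subject_id, group = subj$group,
               subtype = tp,
               count = tapply(scores[[tp]], scores$subject_id,
                              sum)[subj$subject_id],
               stringsAsFactors = FALSE)
  }))
  an_err <- mixed_rm_anova(etot, "count", "group", "subtype", "subject_id")

  posthoc <- lapply(stats::setNames(nm = asst_stages()), function(stg) {
    sel <- scores$stage == stg
    oneway_anova_lsd(scores$trials[sel], scores$group[sel], adjust = adjust)
  })

  tr_w <- tapply(scores$trials, list(scores$subject_id,
                                     as.character(scores$stage)), mean)
  grp_of <- tapply(scores$group, scores$subject_id, function(v) v[1])
  contrasts <- do.call(rbind, lapply(unique(scores$group), function(gname) {
    ids <- names(grp_of)[grp_of == gname]
    rbind(
      data.frame(group = gname, contrast = "CD_vs_ID",
                 as.data.frame(paired_t(tr_w[ids, "CD"], tr_w[ids, "ID"]))),
      data.frame(group = gname, contrast = "ID_vs_ED",
                 as.data.frame(paired_t(tr_w[ids, "ID"], tr_w[ids, "ED"])))
    )
  }))
  correlations <- do.call(rbind, lapply(unique(scores$group),
                                        function(gname) {
    ids <- names(grp_of)[grp_of == gname]
    ct <- pearson_correlation(tr_w[ids, "SD"], tr_w[ids, "ED"])
    data.frame(group = gname, pair = "SD_vs_ED_trials",
               r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
  }))
  structure(list(anova_trials = an_tr, anova_latency = an_lat,
                 anova_errors = an_err, posthoc = posthoc,
                 contrasts = contrasts, correlations = correlations),
            class = "asst_analysis")
}

#' @export
print.asst_analysis <- function(x, ...) {
  cat("== Trials to criterion: group x stage RM-ANOVA ==\n")
  print(x$anova_trials)
  cat("\n== Mean latency: group x stage RM-ANOVA ==\n")
  print(x$anova_latency)
  cat("\n== Error subtypes: group x subtype RM-ANOVA ==\n")
  print(x$anova_errors)
  cat("\n== Set-formation paired contrasts (trials) ==\n")
  print(x$contrasts, row.names = FALSE)
  cat("\n== SD-vs-ED correlations (trials) ==\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Run the simulate -> score -> analyze pipeline
#'
#' Simulates a cohort, scores it, runs the statistical battery, and writes
#' all intermediate tables under `out_dir`: `logs.csv` (trial level),
#' `stage_metrics.csv`, `anova_*.csv`, `posthoc.csv`, `contrasts.csv`,
#' `correlations.csv`, a human-readable `report.txt` and a `manifest.json`
#' recording the seed, config hash and row counts.
#'
#' @param config list (or path to a YAML/JSON file) with optional fields
#'   `experiment` (1 or 2, or a full `design` data frame), `seed`,
#'   `max_trials_per_stage`, `adjust` ("none"/"holm").
#' @param out_dir output directory, created if needed; `NULL` skips file
#'   output.
#' @return List with `cohort`, `scores`, `analysis`, `manifest`
#'   (invisibly when writing files).
#' @export
run_full_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  mts <- config$max_trials_per_stage %||% 150L
  design <- if (!is.null(config$design)) as.data.frame(config$design)
            else if ((config$experiment %||% 1) == 2) experiment2_design()
            else experiment1_design()

  cohort <- simulate_cohort(design, seed = seed,
                            max_trials_per_stage = mts)
  scores <- score_cohort(cohort)
  analysis <- analyze_scores(scores, adjust = config$adjust %||% "none")

  hash <- .config_hash(list(design = design, seed = seed,
                            max_trials_per_stage = mts))
  manifest <- list(seed = seed, config_hash = hash,
                   n_sessions = length(cohort),
                   n_trial_rows = nrow(as.data.frame.asst_cohort(cohort)),
                   n_metric_rows = nrow(scores))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      con <- file(file.path(out_dir, name), "w")
      writeLines(sprintf("# seed=%s; config_hash=%s", seed, hash), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    write_trial_log(cohort, file.path(out_dir, "logs.csv"),
                    seed = seed, config_hash = hash)
    wcsv(scores, "stage_metrics.csv")
    wcsv(as.data.frame(analysis$anova_trials), "anova_trials.csv")
    wcsv(as.data.frame(analysis$anova_latency), "anova_latency.csv")
    wcsv(as.data.frame(analysis$anova_errors), "anova_errors.csv")
    ph <- do.call(rbind, lapply(names(analysis$posthoc), function(stg) {
      cbind(stage = stg, analysis$posthoc[[stg]]$pairwise,
            F = analysis$posthoc[[stg]]$F, p_anova = analysis$posthoc[[stg]]$p)
    }))
    wcsv(ph, "posthoc.csv")
    wcsv(analysis$contrasts, "contrasts.csv")
    wcsv(analysis$correlations, "correlations.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    sink(file.path(out_dir, "report.txt"))
    on.exit(sink(), add = TRUE)
    print(analysis)
  }
  invisible(list(cohort = cohort, scores = scores, analysis = analysis,
                 manifest = manifest))
}
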