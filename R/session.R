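# Running simulated agents through a schedule and assembling cohorts.

#' Run one agent through a full seven-stage session
#'
#' Each stage runs until the criterion of six consecutive correct trials or
#' until `max_trials_per_stage` is reached; a capped stage is flagged
#' incomplete but subsequent stages still run. The belief state carries over
#' between stages — this carry-over is what makes reversals and the
#' extradimensional shift costly. Trial configurations are consumed from the
#' schedule (or drawn on demand when the schedule holds fewer than the cap).
#'
#' @param params an `asst_agent_params`.
#' @param schedule an `asst_schedule` from [build_schedule()].
#' @param seed optional integer seed for the agent's choices and latencies.
#' @param max_trials_per_stage stage cap (>= 6); default 150.
#' @param pretrained when `TRUE`, at each stage onset the belief is set to
#'   the stage's solution (correct exemplar value 1, its foil 0, attention
#'   on the relevant dimension), emulating an overtrained error-free animal.
#'   Useful for validating the scoring arithmetic: every stage then
#'   completes in exactly the six criterion trials.
#' @return An object of class `asst_session`: list with `subject_id`,
#'   `strain`, `dose`, `series`, `trials` (one row per trial: `stage`,
#'   `trial`, `chosen_side`, `chosen_odor`, `chosen_medium`, `correct`,
#'   `latency_s`, `exploratory`) and `completed` (named logical per stage;
#'   `NA` for stages not reached after a dig refusal).
#' @export
run_session <- function(params, schedule, seed = NULL,
                        max_trials_per_stage = 150L, pretrained = FALSE) {
  stopifnot(inherits(params, "asst_agent_params"),
            inherits(schedule, "asst_schedule"))
  max_trials_per_stage <- as.integer(max_trials_per_stage)
  if (max_trials_per_stage < 6L) stop("`max_trials_per_stage` must be >= 6")
  if (!is.null(seed)) set.seed(seed)

  all_ex <- unique(unlist(lapply(schedule$stages, function(s)
    c(s$pair_relevant, s$pair_irrelevant))))
  belief <- init_belief(params, all_ex)
  seen <- character(0)

  rec <- list()
  completed <- stats::setNames(rep(NA, length(schedule$stages)),
                               vapply(schedule$stages, `[[`, "", "name"))
  refused <- FALSE

  for (si in seq_along(schedule$stages)) {
    sp <- schedule$stages[[si]]
    if (refused) break
    belief <- .stage_transition(params, belief, sp, seen)
    if (pretrained) {
      belief$values[sp$pair_relevant] <- c(0, 0)
      belief$values[sp$correct_exemplar] <- 1
      if (!is.null(sp$pair_irrelevant))
        belief$values[sp$pair_irrelevant] <- 0.5
      belief$attn[] <- 0
      belief$attn[sp$relevant_dimension] <- 1
    }
    seen <- union(seen, c(sp$pair_relevant, sp$pair_irrelevant))

    cfg <- schedule$trials[schedule$trials$stage == sp$name, , drop = FALSE]
    if (nrow(cfg) < max_trials_per_stage) {
      extra <- generate_trial_configs(sp, max_trials_per_stage - nrow(cfg))
      extra$trial <- extra$trial + nrow(cfg)
      extra$exploratory <- extra$trial <= 4L
      cfg <- rbind(cfg, extra)
    }

    shift <- -params$stage_decay * (si - 1) +
      if (sp$name %in% .novel_stages) log(params$novelty_latency_gain) else 0

    lo <- cfg$left_odor; lm <- cfg$left_medium
    ro <- cfg$right_odor; rm_ <- cfg$right_medium
    bs <- cfg$baited_side
    has_odor <- !is.na(lo[1L]); has_medium <- !is.na(lm[1L])

    streak <- 0L
    n_done <- 0L
    chosen_side <- character(max_trials_per_stage)
    chosen_odor <- chosen_medium <- rep(NA_character_, max_trials_per_stage)
    corr <- logical(max_trials_per_stage)
    lat <- numeric(max_trials_per_stage)
    for (ti in seq_len(max_trials_per_stage)) {
      if (params$refuse_prob > 0 && stats::runif(1) < params$refuse_prob) {
        refused <- TRUE
        break
      }
      if (has_odor && has_medium) {
        lft <- c(lo[ti], lm[ti]); rgt <- c(ro[ti], rm_[ti])
      } else if (has_odor) {
        lft <- lo[ti]; rgt <- ro[ti]
      } else {
        lft <- lm[ti]; rgt <- rm_[ti]
      }
      ch <- agent_choose(params, belief, lft, rgt, latency_shift = shift)
      if (ch$side == "L") {
        cup <- lft; other <- rgt
      } else {
        cup <- rgt; other <- lft
      }
      # the baited cup always holds the correct exemplar, so first-dig
      # correctness is side equality
      ok <- ch$side == bs[ti]
      belief <- agent_update(params, belief, cup, as.numeric(ok), other)
      n_done <- ti
      chosen_side[ti] <- ch$side
      if (has_odor) chosen_odor[ti] <- cup[1L]
      if (has_medium) chosen_medium[ti] <- cup[length(cup)]
      corr[ti] <- ok
      lat[ti] <- ch$latency_s
      streak <- if (ok) streak + 1L else 0L
      if (streak >= 6L) break
    }
    if (n_done > 0L) {
      rec[[sp$name]] <- data.frame(
        stage = sp$name, trial = seq_len(n_done),
        chosen_side = chosen_side[seq_len(n_done)],
        chosen_odor = chosen_odor[seq_len(n_done)],
        chosen_medium = chosen_medium[seq_len(n_done)],
        correct = corr[seq_len(n_done)],
        latency_s = lat[seq_len(n_done)],
        exploratory = seq_len(n_done) <= 4L,
        stringsAsFactors = FALSE)
    }
    completed[sp$name] <- if (refused) FALSE else streak >= 6L
  }

  structure(list(
    subject_id = schedule$subject_id,
    strain = attr(params, "strain") %||% NA_character_,
    dose = attr(params, "dose") %||% 0,
    series = schedule$series,
    trials = if (length(rec)) do.call(rbind, c(rec, make.row.names = FALSE))
             else data.frame(),
    completed = completed
  ), class = "asst_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.asst_session <- function(x, ...) {
  cat("ASST session:", x$subject_id,
      if (!is.na(x$strain)) paste0("(", x$strain,
        if (x$dose > 0) paste0(", MPH ", x$dose, " mg/kg"), ")"), "\n")
  tb <- stage_metrics_table(x)
  print(tb[, c("stage", "trials", "errors", "mean_latency_s", "completed")],
        row.names = FALSE)
  invisible(x)
}

#' Cohort design for the strain-comparison experiment
#'
#' Three strains (SHR, WKY, SD), 8 subjects each, no treatment.
#' @return A design data frame for [simulate_cohort()].
#' @export
experiment1_design <- function() {
  data.frame(group = c("SHR", "WKY", "SD"),
             strain = c("SHR", "WKY", "SD"),
             dose = 0, n = 8L, stringsAsFactors = FALSE)
}

#' Cohort design for the methylphenidate dose experiment
#'
#' Three groups of 8 SHR subjects: vehicle, 2.5 mg/kg (MPH-L) and 5 mg/kg
#' (MPH-H).
#' @return A design data frame for [simulate_cohort()].
#' @export
experiment2_design <- function() {
  data.frame(group = c("SHR-vehicle", "MPH-L", "MPH-H"),
             strain = "SHR", dose = c(0, 2.5, 5.0), n = 8L,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of agents through the task
#'
#' One session per subject. Within each group, exemplar-pair assignments
#' cycle through the latin square and the shift direction alternates between
#' series 1 and series 2 (half of the subjects shift odor-to-medium, half
#' medium-to-odor). Subject-level seeds are derived deterministically from
#' the master seed, so a cohort is fully reproducible.
#'
#' @param design data frame with columns `group`, `strain`
#'   (SHR/WKY/SD), `dose` (0, 2.5 or 5.0 mg/kg) and `n` (subjects per
#'   group); see [experiment1_design()] and [experiment2_design()].
#' @param seed master integer seed.
#' @param max_trials_per_stage stage cap passed to [run_session()].
#' @param presets optional named list of `asst_agent_params` overriding
#'   [strain_preset()] per strain.
#' @return An object of class `asst_cohort`: list of `asst_session`s with
#'   attributes `design` and `seed`.
#' @export
simulate_cohort <- function(design = experiment1_design(), seed = 1L,
                            max_trials_per_stage = 150L, presets = NULL) {
  stopifnot(is.data.frame(design),
            all(c("group", "strain", "dose", "n") %in% names(design)))
  bad <- setdiff(design$strain, c("SHR", "WKY", "SD"))
  if (length(bad)) stop("unknown strain preset: ", paste(bad, collapse = ", "))
  set.seed(seed)
  total <- sum(design$n)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, max(total, 1L))

  sessions <- list()
  k <- 0L
  for (g in seq_len(nrow(design))) {
    n <- design$n[g]
    if (n == 0L) next
    base <- if (!is.null(presets) && design$strain[g] %in% names(presets))
      presets[[design$strain[g]]] else strain_preset(design$strain[g])
    par <- apply_treatment(base, design$dose[g])
    attr(par, "strain") <- design$strain[g]
    attr(par, "dose") <- design$dose[g]
    assigns <- latin_square_assignment(n)
    for (j in seq_len(n)) {
      k <- k + 1L
      sid <- sprintf("%s_%02d", design$group[g], j)
      series <- if (j %% 2L == 1L) 1L else 2L
      ses_seed <- subj_seeds[k]
      sched <- build_schedule(sid, series, assigns[[j]],
                              n_trials_per_stage = max_trials_per_stage,
                              seed = ses_seed)
      ses <- run_session(par, sched, seed = ses_seed + 1L,
                         max_trials_per_stage = max_trials_per_stage)
      ses$group <- design$group[g]
      sessions[[length(sessions) + 1L]] <- ses
    }
  }
  structure(sessions, class = "asst_cohort", design = design, seed = seed)
}

#' @export
print.asst_cohort <- function(x, ...) {
  d <- attr(x, "design")
  cat("ASST cohort:", length(x), "sessions;",
      nrow(d), "groups (", paste(d$group, collapse = ", "), ")\n")
  invisible(x)
}

#' Flatten a cohort to one row per trial
#'
#' @param x an `asst_cohort`.
#' @param ... unused.
#' @return A data frame: `subject_id`, `group`, `strain`, `dose`, `series`,
#'   trial columns as in [run_session()], plus `stage_completed`.
#' @export
as.data.frame.asst_cohort <- function(x, ...) {
  do.call(rbind, lapply(x, function(s) {
    tr <- s$trials
    if (nrow(tr) == 0L) return(NULL)
    cbind(data.frame(subject_id = s$subject_id,
                     group = s$group %||% s$strain,
                     strain = s$strain, dose = s$dose, series = s$series,
                     stringsAsFactors = FALSE),
          tr,
          stage_completed = unname(s$completed[tr$stage]))
  }))
}
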