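# Scoring of session logs: trials/errors to criterion, latency, and the
# perseverative / regressive / never-reinforced error taxonomy.

#' Trials and errors to criterion for one stage
#'
#' The criterion is six consecutive correct trials; the returned trial count
#' is the index of the trial completing the first such run (so a perfect
#' stage scores exactly 6). Errors and mean latency are computed over trials
#' 1..trials_to_criterion. Correctness is defined by the first dig
#' throughout, exploratory trials included. When the criterion is never
#' reached the stage is flagged incomplete and totals cover all trials.
#'
#' @param stage_trials data frame of one stage's trials, ordered by
#'   `trial`, with at least `correct` (logical) and `latency_s`.
#' @return A list (class `asst_stage_metrics`): `trials_to_criterion`,
#'   `errors_to_criterion`, `mean_latency_s`, `completed`.
#' @examples
#' tr <- data.frame(correct = c(TRUE, TRUE, FALSE, rep(TRUE, 6)),
#'                  latency_s = 10)
#' trials_to_criterion(tr)$trials_to_criterion  # 9
#' @export
trials_to_criterion <- function(stage_trials) {
  if (is.null(stage_trials) || nrow(stage_trials) == 0L)
    stop("empty stage trial list")
  corr <- as.logical(stage_trials$correct)
  streak <- 0L
  ttc <- NA_integer_
  for (i in seq_along(corr)) {
    streak <- if (corr[i]) streak + 1L else 0L
    if (streak >= 6L) { ttc <- i; break }
  }
  completed <- !is.na(ttc)
  upto <- if (completed) ttc else length(corr)
  structure(list(
    trials_to_criterion = upto,
    errors_to_criterion = sum(!corr[seq_len(upto)]),
    mean_latency_s = mean(stage_trials$latency_s[seq_len(upto)]),
    completed = completed
  ), class = "asst_stage_metrics")
}

# Old-rule consistency of each error, by stage role:
#  - reversal stages: every error chooses the previously correct exemplar,
#    so all errors are old-rule-consistent (never-reinforced is structurally
#    zero there);
#  - acquisition stages (SD/CD/ID): no previously rewarded competing rule
#    exists, so no error is old-rule-consistent;
#  - ED: exemplars are new, so the old rule is anchored to the
#    previous-dimension exemplar in the cup chosen on the first error;
#    later errors are old-rule-consistent iff their cup contains the anchor.
.old_rule_consistent <- function(stage_trials, stage_spec) {
  err <- !as.logical(stage_trials$correct)
  orc <- rep(FALSE, nrow(stage_trials))
  nm <- stage_spec$name
  if (nm %in% c("CDR", "IDR", "EDR")) {
    if (is.null(stage_spec$previous_correct_exemplar))
      stop("reversal stage spec lacks `previous_correct_exemplar`")
    orc[err] <- TRUE
  } else if (nm == "ED") {
    if (is.null(stage_spec$previous_relevant_dimension))
      stop("ED stage spec lacks `previous_relevant_dimension`")
    col <- if (stage_spec$previous_relevant_dimension == "odor")
      "chosen_odor" else "chosen_medium"
    idx <- which(err)
    if (length(idx)) {
      anchor <- stage_trials[[col]][idx[1L]]
      orc[idx] <- !is.na(anchor) & stage_trials[[col]][idx] == anchor
    }
  }
  orc
}

#' Classify a stage's errors into the three subtypes
#'
#' Implements the block-of-four taxonomy. Each error is first tagged as
#' old-rule-consistent or not (consistent with the previously rewarded rule;
#' see Details). Trials are then partitioned into consecutive blocks of four
#' from trial 1 (the final block may be short). Scanning blocks in order,
#' while the subject is still in the perseveration phase a block with three
#' or more errors of any type marks its old-rule-consistent errors
#' perseverative; the first block with two or fewer errors switches the
#' phase, and that block's and all subsequent old-rule-consistent errors are
#' regressive. Errors that are not old-rule-consistent are never-reinforced
#' regardless of phase.
#'
#' @details Old-rule consistency by stage role: at reversals (CDR/IDR/EDR)
#' every error chooses the previously correct exemplar, so all errors are
#' old-rule-consistent; at acquisition stages (SD/CD/ID) no previously
#' rewarded competing rule exists and every error is never-reinforced; at
#' the extradimensional shift the previous-dimension exemplar contained in
#' the cup chosen on the first error anchors the old rule, and subsequent
#' errors are old-rule-consistent iff their chosen cup contains that anchor.
#'
#' Typically called on trials 1..trials_to_criterion (what
#' [stage_metrics_table()] does), but any ordered prefix may be passed.
#'
#' @param stage_trials ordered data frame of one stage's trials with
#'   `correct` and, for ED, `chosen_odor`/`chosen_medium`.
#' @param stage_spec the stage's specification (carries the previous-rule
#'   fields).
#' @return A list (class `asst_error_breakdown`): `perseverative`,
#'   `regressive`, `never_reinforced`; the three sum to the total error
#'   count.
#' @export
classify_errors <- function(stage_trials, stage_spec) {
  stopifnot(inherits(stage_spec, "asst_stage_spec"))
  n <- nrow(stage_trials)
  err <- !as.logical(stage_trials$correct)
  orc <- .old_rule_consistent(stage_trials, stage_spec)

  pers <- regr <- 0L
  in_persev_phase <- TRUE
  if (n > 0L) {
    block <- ceiling(seq_len(n) / 4)
    for (b in unique(block)) {
      sel <- block == b
      n_err <- sum(err[sel])
      n_orc <- sum(orc[sel] & err[sel])
      if (in_persev_phase) {
        if (n_err >= 3L) {
          pers <- pers + n_orc
        } else {
          in_persev_phase <- FALSE
          regr <- regr + n_orc
        }
      } else {
        regr <- regr + n_orc
      }
    }
  }
  structure(list(
    perseverative = pers,
    regressive = regr,
    never_reinforced = sum(err & !orc)
  ), class = "asst_error_breakdown")
}

#' Per-stage metrics and error breakdown for a session
#'
#' One row per stage in task order: trials/errors to criterion, mean
#' latency, completion flag and the three error subtype counts (classified
#' over the same trial range as the error count).
#'
#' @param session an `asst_session` (from [run_session()] or
#'   [read_trial_log()]). Its `stages` specifications are rebuilt from the
#'   session's series and pair assignment when absent.
#' @param stages optional list of stage specifications; defaults to
#'   `build_stage_sequence(session$series, session$pair_assignment)` when
#'   the session carries a pair assignment, else the natural-order sequence.
#' @return A data frame with columns `subject_id`, `group`, `strain`,
#'   `dose`, `stage`, `trials`, `errors`, `mean_latency_s`,
#'   `perseverative`, `regressive`, `never_reinforced`, `completed`.
#' @export
stage_metrics_table <- function(session, stages = NULL) {
  stopifnot(inherits(session, "asst_session"))
  if (is.null(stages)) {
    pa <- session$pair_assignment %||% 1:3
    stages <- build_stage_sequence(session$series %||% 1L, pa)
  }
  rows <- lapply(stages, function(sp) {
    tt <- session$trials[session$trials$stage == sp$name, , drop = FALSE]
    if (nrow(tt) == 0L) {
      stop("session for subject ", session$subject_id,
           " is missing stage ", sp$name)
    }
    m <- trials_to_criterion(tt)
    eb <- classify_errors(tt[seq_len(m$trials_to_criterion), , drop = FALSE],
                          sp)
    data.frame(
      subject_id = session$subject_id,
      group = session$group %||% session$strain,
      strain = session$strain, dose = session$dose,
      stage = sp$name,
      trials = m$trials_to_criterion, errors = m$errors_to_criterion,
      mean_latency_s = m$mean_latency_s,
      perseverative = eb$perseverative, regressive = eb$regressive,
      never_reinforced = eb$never_reinforced,
      completed = m$completed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stage <- factor(out$stage, levels = asst_stages())
  out
}

#' Score every session of a cohort
#'
#' @param cohort an `asst_cohort` or list of `asst_session`s.
#' @return Row-bound [stage_metrics_table()] output, one row per subject and
#'   stage, of class `asst_scores`.
#' @export
score_cohort <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(s) {
    stages <- if (!is.null(s$pair_assignment))
      build_stage_sequence(s$series, s$pair_assignment) else NULL
    stage_metrics_table(s, stages)
  }))
  rownames(out) <- NULL
  class(out) <- c("asst_scores", class(out))
  out
}

#' Set-formation contrasts for one subject
#'
#' A subject that has formed an attentional set masters the
#' intradimensional shift faster than both the original compound
#' discrimination and the extradimensional shift, so positive CD-ID and
#' ED-ID trial differences indicate set formation.
#'
#' @param metrics_table one subject's [stage_metrics_table()].
#' @return List with `cd_minus_id` and `ed_minus_id`.
#' @export
set_formation_contrasts <- function(metrics_table) {
  need <- c("CD", "ID", "ED")
  rows <- metrics_table[match(need, as.character(metrics_table$stage)), ]
  if (anyNA(rows$trials)) stop("CD, ID and ED rows are all required")
  if (!all(rows$completed))
    stop("set-formation contrasts are undefined unless CD, ID and ED ",
         "all reached criterion")
  list(cd_minus_id = rows$trials[1L] - rows$trials[2L],
       ed_minus_id = rows$trials[3L] - rows$trials[2L])
}

#' Summary plot of a scored cohort
#'
#' Three base-graphics panels mirroring the conventional presentation:
#' group-mean latency per stage, trials to criterion per stage, and total
#' error subtype counts per group.
#'
#' @param x an `asst_scores` data frame from [score_cohort()].
#' @param ... unused.
#' @export
plot.asst_scores <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  groups <- unique(x$group)
  stages <- asst_stages()
  agg <- function(col) {
    sapply(groups, function(g) sapply(stages, function(s)
      mean(x[[col]][x$group == g & x$stage == s])))
  }
  lat <- agg("mean_latency_s"); tri <- agg("trials")
  graphics::matplot(lat, type = "b", pch = 19, lty = 1, xaxt = "n",
                    xlab = "stage", ylab = "mean latency (s)",
                    main = "Latency")
  graphics::axis(1, at = seq_along(stages), labels = stages)
  graphics::legend("topright", legend = groups, col = seq_along(groups),
                   pch = 19, bty = "n", cex = 0.8)
  graphics::matplot(tri, type = "b", pch = 19, lty = 1, xaxt = "n",
                    xlab = "stage", ylab = "trials to criterion",
                    main = "Trials to criterion")
  graphics::axis(1, at = seq_along(stages), labels = stages)
  errs <- t(sapply(groups, function(g) c(
    perseverative = sum(x$perseverative[x$group == g]),
    regressive = sum(x$regressive[x$group == g]),
    never_reinforced = sum(x$never_reinforced[x$group == g])) /
      sum(x$group == g) * length(stages)))
  graphics::barplot(t(errs / length(stages)), beside = TRUE,
                    legend.text = colnames(errs),
                    ylab = "errors per subject", main = "Error subtypes")
  invisible(x)
}
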