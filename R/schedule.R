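# Task-schedule construction for the seven-stage attentional set-shifting
# task (ASST): SD, CD, CDR, ID, IDR, ED, EDR.

#' Stage names of the attentional set-shifting task, in task order
#'
#' Simple discrimination (SD), compound discrimination (CD) and its reversal
#' (CDR), intradimensional shift (ID) and its reversal (IDR),
#' extradimensional shift (ED) and its reversal (EDR). The order is fixed and
#' identical for every subject.
#'
#' @export
asst_stages <- function() c("SD", "CD", "CDR", "ID", "IDR", "ED", "EDR")

# Stage blocks sharing an exemplar pair: 1 = SD/CD/CDR, 2 = ID/IDR, 3 = ED/EDR
.stage_block <- c(SD = 1L, CD = 1L, CDR = 1L, ID = 2L, IDR = 2L,
                  ED = 3L, EDR = 3L)

# Stages that introduce exemplars unseen in earlier stages (latency is
# elevated there relative to the following reversal stages).
.novel_stages <- c("SD", "CD", "ID", "ED")

.other_dim <- function(dim) if (dim == "odor") "medium" else "odor"

# Exemplar labels for pair index p: odors O(2p-1)/O(2p), media M(2p-1)/M(2p)
.exemplar_pair <- function(dimension, pair_index) {
  prefix <- if (dimension == "odor") "O" else "M"
  paste0(prefix, c(2L * pair_index - 1L, 2L * pair_index))
}

.exemplar_dim <- function(label) {
  c("odor", "medium")[(substr(label, 1L, 1L) != "O") + 1L]
}

#' Build the ordered stage sequence for one subject
#'
#' Constructs the seven stage specifications from a series and an exemplar
#' pair assignment. In series 1 the relevant dimension is odor from SD
#' through IDR and flips to digging medium at the extradimensional shift;
#' series 2 is the mirror image (medium first, odor at ED). Reversal stages
#' reuse the preceding stage's exemplars with the correct exemplar swapped;
#' ID/IDR and ED/EDR introduce fresh exemplar pairs never used earlier.
#'
#' @param series 1 or 2: direction of the extradimensional shift
#'   (odor-to-medium or medium-to-odor).
#' @param pair_assignment integer permutation of `1:3`; element `b` is the
#'   exemplar pair used by stage block `b` (block 1 = SD/CD/CDR,
#'   block 2 = ID/IDR, block 3 = ED/EDR). See [latin_square_assignment()].
#' @return A list of 7 stage specifications (class `asst_stage_spec`), each
#'   with fields `name`, `relevant_dimension`, `correct_exemplar`,
#'   `pair_relevant`, `pair_irrelevant` (`NULL` for SD),
#'   `previous_correct_exemplar` (reversal stages only) and
#'   `previous_relevant_dimension` (ED only).
#' @examples
#' seq1 <- build_stage_sequence(1, 1:3)
#' seq1[[6]]$relevant_dimension  # "medium": series 1 shifts odor -> medium
#' @export
build_stage_sequence <- function(series, pair_assignment) {
  series <- as.integer(series)
  if (!series %in% c(1L, 2L)) stop("`series` must be 1 or 2")
  pair_assignment <- as.integer(pair_assignment)
  if (length(pair_assignment) != 3L ||
      !identical(sort(pair_assignment), 1:3)) {
    stop("`pair_assignment` must be a permutation of 1:3 ",
         "(a bijection from stage blocks to exemplar pairs); got: ",
         paste(pair_assignment, collapse = ", "))
  }

  dim1 <- if (series == 1L) "odor" else "medium"   # relevant SD..IDR
  dim2 <- .other_dim(dim1)                         # relevant ED/EDR

  spec <- function(name, rel_dim, pair_idx, correct_pos,
                   compound = TRUE, prev_correct = NULL, prev_dim = NULL) {
    rel <- .exemplar_pair(rel_dim, pair_idx)
    irr <- if (compound) .exemplar_pair(.other_dim(rel_dim), pair_idx)
           else NULL
    structure(list(
      name = name,
      relevant_dimension = rel_dim,
      correct_exemplar = rel[correct_pos],
      pair_relevant = rel,
      pair_irrelevant = irr,
      previous_correct_exemplar = prev_correct,
      previous_relevant_dimension = prev_dim
    ), class = "asst_stage_spec")
  }

  p1 <- pair_assignment[1L]; p2 <- pair_assignment[2L]
  p3 <- pair_assignment[3L]
  rel1 <- .exemplar_pair(dim1, p1)
  rel2 <- .exemplar_pair(dim1, p2)
  rel3 <- .exemplar_pair(dim2, p3)

  list(
    spec("SD",  dim1, p1, 1L, compound = FALSE),
    spec("CD",  dim1, p1, 1L),
    spec("CDR", dim1, p1, 2L, prev_correct = rel1[1L]),
    spec("ID",  dim1, p2, 1L),
    spec("IDR", dim1, p2, 2L, prev_correct = rel2[1L]),
    spec("ED",  dim2, p3, 1L, prev_dim = dim1),
    spec("EDR", dim2, p3, 2L, prev_correct = rel3[1L])
  )
}

#' Latin-square assignment of exemplar pairs to stage blocks
#'
#' Cycles through the three rotations of a 3x3 cyclic latin square, so that
#' over any 3 consecutive subjects each exemplar pair serves each stage block
#' (SD/CD/CDR, ID/IDR, ED/EDR) exactly once. Subject 1 receives the identity
#' assignment (pair 1 to the SD block).
#'
#' @param n_subjects number of subjects (>= 1).
#' @return A list of length `n_subjects` of integer permutations of `1:3`,
#'   each usable as the `pair_assignment` of [build_stage_sequence()].
#' @export
latin_square_assignment <- function(n_subjects) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) stop("`n_subjects` must be >= 1")
  lapply(seq_len(n_subjects), function(i) {
    r <- (i - 1L) %% 3L
    ((0:2 + r) %% 3L) + 1L
  })
}

# Extend a binary sequence under the run-length <= 2 constraint: a per-trial
# feasibility check (run-length-2 state machine) — when the last two symbols
# are equal the next is forced to the alternative, otherwise it is sampled
# uniformly. A feasible extension always exists with two symbols, but the
# guard is kept for safety.
.constrained_seq <- function(n, symbols) {
  if (length(symbols) < 2L)
    stop("no feasible extension of constrained sequence")
  u <- stats::runif(n) < 0.5
  out <- integer(n)
  out[1L] <- 1L + u[1L]
  if (n >= 2L) out[2L] <- 1L + u[2L]
  for (i in seq_len(n)[-(1:2)]) {
    out[i] <- if (out[i - 1L] == out[i - 2L]) 3L - out[i - 1L]
              else 1L + u[i]
  }
  symbols[out]
}

#' Generate trial configurations for one stage
#'
#' Draws `n_trials` cup configurations for a stage under the two
#' counterbalancing constraints: no more than 2 consecutive trials with the
#' same exemplar combination, and no more than 2 consecutive trials with the
#' bait on the same side. Compound stages alternate pseudorandomly between
#' the two cross-pairings of the relevant and irrelevant exemplar pairs; the
#' cup containing the stage's correct exemplar is always the baited one.
#' Trials 1-4 are flagged exploratory (the animal may dig in both cups; the
#' first dig still defines the choice).
#'
#' @param stage_spec a stage specification from [build_stage_sequence()].
#' @param n_trials number of trials to generate (>= 1).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the configuration sequence is reproducible. When `NULL` the current RNG
#'   stream is used (this is how sessions consume configurations).
#' @return A data frame with one row per trial: `stage`, `trial`,
#'   `left_odor`, `left_medium`, `right_odor`, `right_medium` (NA for the
#'   dimension absent at SD), `baited_side` ("L"/"R") and `exploratory`.
#' @export
generate_trial_configs <- function(stage_spec, n_trials, seed = NULL) {
  stopifnot(inherits(stage_spec, "asst_stage_spec"))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("`n_trials` must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  rel <- stage_spec$pair_relevant
  irr <- stage_spec$pair_irrelevant
  compound <- !is.null(irr)

  comb <- if (compound) .constrained_seq(n_trials, c(1L, 2L))
          else rep(1L, n_trials)
  side <- .constrained_seq(n_trials, c("L", "R"))

  correct <- stage_spec$correct_exemplar
  n <- n_trials
  # combination 1 pairs rel[j] with irr[j]; combination 2 crosses them
  if (compound) {
    irr_with_rel1 <- irr[comb]        # irrelevant exemplar in rel[1]'s cup
    irr_with_rel2 <- irr[3L - comb]
    if (correct == rel[1L]) {
      b_rel <- rel[1L]; b_irr <- irr_with_rel1
      f_rel <- rel[2L]; f_irr <- irr_with_rel2
    } else {
      b_rel <- rel[2L]; b_irr <- irr_with_rel2
      f_rel <- rel[1L]; f_irr <- irr_with_rel1
    }
    is_l <- side == "L"
    l_rel <- ifelse(is_l, b_rel, f_rel); l_irr <- ifelse(is_l, b_irr, f_irr)
    r_rel <- ifelse(is_l, f_rel, b_rel); r_irr <- ifelse(is_l, f_irr, b_irr)
    if (stage_spec$relevant_dimension == "odor") {
      left_odor <- l_rel; left_medium <- l_irr
      right_odor <- r_rel; right_medium <- r_irr
    } else {
      left_odor <- l_irr; left_medium <- l_rel
      right_odor <- r_irr; right_medium <- r_rel
    }
  } else {
    foil <- setdiff(rel, correct)
    l_rel <- ifelse(side == "L", correct, foil)
    r_rel <- ifelse(side == "L", foil, correct)
    if (stage_spec$relevant_dimension == "odor") {
      left_odor <- l_rel; left_medium <- rep(NA_character_, n)
      right_odor <- r_rel; right_medium <- rep(NA_character_, n)
    } else {
      left_odor <- rep(NA_character_, n); left_medium <- l_rel
      right_odor <- rep(NA_character_, n); right_medium <- r_rel
    }
  }

  data.frame(
    stage = stage_spec$name,
    trial = seq_len(n),
    left_odor = left_odor, left_medium = left_medium,
    right_odor = right_odor, right_medium = right_medium,
    baited_side = side,
    exploratory = seq_len(n) <= 4L,
    stringsAsFactors = FALSE
  )
}

#' Build a complete per-subject schedule
#'
#' Combines [build_stage_sequence()] and [generate_trial_configs()] into one
#' schedule object holding, for every stage, up to `n_trials_per_stage`
#' pre-drawn trial configurations (sessions consume a prefix of each stage's
#' list, stopping at criterion).
#'
#' @param subject_id subject identifier.
#' @param series 1 or 2.
#' @param pair_assignment integer permutation of 1:3 (see
#'   [build_stage_sequence()]).
#' @param n_trials_per_stage configurations drawn per stage.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `asst_schedule`: list with `subject_id`,
#'   `series`, `pair_assignment`, `stages` (list of stage specs) and
#'   `trials` (row-bound trial configuration data frame).
#' @export
build_schedule <- function(subject_id, series, pair_assignment,
                           n_trials_per_stage = 150L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stages <- build_stage_sequence(series, pair_assignment)
  trials <- do.call(rbind, lapply(stages, generate_trial_configs,
                                  n_trials = n_trials_per_stage))
  structure(list(subject_id = subject_id, series = as.integer(series),
                 pair_assignment = as.integer(pair_assignment),
                 stages = stages, trials = trials),
            class = "asst_schedule")
}

#' @export
print.asst_schedule <- function(x, ...) {
  cat("ASST schedule for subject", x$subject_id,
      "(series", x$series, ")\n")
  cat("Pair assignment (SD/CD/CDR, ID/IDR, ED/EDR):",
      paste(x$pair_assignment, collapse = ", "), "\n")
  for (s in x$stages) {
    cat(sprintf("  %-3s relevant=%s correct=%s\n", s$name,
                s$relevant_dimension, s$correct_exemplar))
  }
  invisible(x)
}

#' Validate a schedule against the counterbalancing contracts
#'
#' Scans trial configurations for violations of the structural rules: the
#' two cups of a trial must not share an exemplar; exactly one cup holds the
#' stage's correct exemplar and that cup is the baited one; no 3 consecutive
#' trials share the same exemplar combination; no 3 consecutive trials share
#' the same baited side; the exploratory flag marks exactly trials 1-4.
#'
#' @param schedule an `asst_schedule`, or a trial-configuration data frame
#'   (as from [generate_trial_configs()]) if `stages` is supplied.
#' @param stages list of stage specifications; taken from the schedule when
#'   omitted.
#' @return A data frame of violations (`stage`, `trial`, `rule`, `message`),
#'   empty when the schedule is valid.
#' @export
validate_schedule <- function(schedule, stages = NULL) {
  if (inherits(schedule, "asst_schedule")) {
    trials <- schedule$trials
    stages <- schedule$stages
  } else {
    trials <- schedule
    if (is.null(stages)) stop("`stages` required when validating a raw trial table")
  }
  if (nrow(trials) == 0L) stop("empty trial configuration list")
  spec_by_name <- stats::setNames(stages,
                                  vapply(stages, `[[`, "", "name"))
  viol <- list()
  add <- function(stage, trial, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      stage = stage, trial = trial, rule = rule, message = message,
      stringsAsFactors = FALSE)
  }

  for (stg in unique(trials$stage)) {
    tt <- trials[trials$stage == stg, , drop = FALSE]
    sp <- spec_by_name[[stg]]
    combo_key <- character(nrow(tt))
    for (i in seq_len(nrow(tt))) {
      lft <- stats::na.omit(c(tt$left_odor[i], tt$left_medium[i]))
      rgt <- stats::na.omit(c(tt$right_odor[i], tt$right_medium[i]))
      if (length(intersect(lft, rgt)) > 0L) {
        add(stg, tt$trial[i], "shared_exemplar",
            "the two cups share an exemplar")
      }
      if (!is.null(sp)) {
        in_l <- sp$correct_exemplar %in% lft
        in_r <- sp$correct_exemplar %in% rgt
        if (in_l == in_r) {
          add(stg, tt$trial[i], "bait_mismatch",
              "correct exemplar must appear in exactly one cup")
        } else {
          baited <- if (in_l) "L" else "R"
          if (!identical(baited, tt$baited_side[i])) {
            add(stg, tt$trial[i], "bait_mismatch",
                "baited cup does not contain the correct exemplar")
          }
        }
      }
      if (!identical(tt$exploratory[i], tt$trial[i] <= 4L)) {
        add(stg, tt$trial[i], "exploratory_flag",
            "exploratory must flag exactly trials 1-4")
      }
      combo_key[i] <- paste(sort(c(paste(sort(lft), collapse = "+"),
                                   paste(sort(rgt), collapse = "+"))),
                            collapse = " vs ")
    }
    # single-dimension (SD) trials admit only one combination, so the
    # combination run-length rule applies to compound trials only
    compound_stage <- any(!is.na(tt$left_odor) & !is.na(tt$left_medium))
    for (i in seq_len(nrow(tt))) {
      if (compound_stage && i >= 3L && combo_key[i] == combo_key[i - 1L] &&
          combo_key[i] == combo_key[i - 2L]) {
        add(stg, tt$trial[i], "combination_run",
            "3 consecutive trials with the same exemplar combination")
      }
      if (i >= 3L && tt$baited_side[i] == tt$baited_side[i - 1L] &&
          tt$baited_side[i] == tt$baited_side[i - 2L]) {
        add(stg, tt$trial[i], "side_run",
            "3 consecutive trials baited on the same side")
      }
    }
  }
  if (length(viol) == 0L) {
    data.frame(stage = character(), trial = integer(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, viol)
  }
}
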