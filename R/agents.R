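# Synthetic rat agents: attention-weighted exemplar-value learners with
# softmax choice, lapses, attentional inertia and a lognormal latency model.

# Base rate of attentional re-allocation; the effective per-trial step is
# .attn_rate * (1 - perseveration).
.attn_rate <- 0.4

#' Behavioural parameters of a simulated rat
#'
#' The agent maintains a value in \[0,1\] for every exemplar and an attention
#' weight per stimulus dimension (odor, digging medium) summing to 1. On
#' each trial the agent lapses into a uniformly random choice with
#' probability `lapse`; otherwise it attends one of the dimensions present
#' (with probability equal to that dimension's attention weight) and
#' chooses between the cups by a softmax over the attended dimension's
#' exemplar values. Attending the irrelevant dimension is therefore close
#' to a coin flip — dimensional attention, not exemplar knowledge, is what
#' distinguishes the shift stages. After feedback, the chosen cup's
#' exemplar values move toward the outcome by `learning_rate`, and
#' attention drifts toward the dimension whose exemplar value better
#' predicted the outcome, at a rate damped by `perseveration` (the inertia
#' that produces perseverative responding after a rule change). First-dig
#' latency is lognormal, declining multiplicatively across stages and
#' elevated in stages that introduce new exemplars.
#'
#' @param attn_odor,attn_medium nonnegative initial attention weights; they
#'   are renormalised to sum to 1.
#' @param learning_rate value-learning step in (0, 1].
#' @param perseveration attentional inertia in \[0, 1); higher values slow
#'   re-allocation of attention after a rule change.
#' @param lapse probability in \[0, 0.5) of a uniformly random choice.
#' @param inverse_temperature softmax inverse temperature (> 0); higher is
#'   more deterministic.
#' @param latency_mu,latency_sigma location and scale of the lognormal
#'   first-dig latency, in log-seconds.
#' @param novelty_latency_gain multiplicative latency elevation (>= 0,
#'   typically >= 1) applied in stages introducing new exemplars
#'   (SD, CD, ID, ED).
#' @param stage_decay per-stage multiplicative latency decline (>= 0, in log
#'   units per stage; stage i is scaled by `exp(-stage_decay * (i - 1))`).
#' @param novelty_attention stage-onset attentional capture in \[0, 1): when
#'   a stage introduces a stimulus dimension never encountered before (the
#'   irrelevant dimension appearing at the compound discrimination), that
#'   dimension's attention weight is raised to at least this value and the
#'   weights renormalised. New exemplars within familiar dimensions (ID,
#'   ED) do not capture attention, so a formed dimensional set survives
#'   them. This capture is what makes the compound discrimination harder
#'   than the intradimensional shift.
#' @param stage_forgetting inter-stage memory decay in \[0, 1\]: at each
#'   stage transition every learned exemplar value relaxes toward the
#'   uninformative 0.5 by this fraction. Dimensional attention does not
#'   decay — that asymmetry (values fade, the attentional set persists) is
#'   what lets the intradimensional shift outpace the compound
#'   discrimination.
#' @param refuse_prob per-trial probability in \[0, 1) that the animal
#'   refuses to dig, terminating the session (0 by default).
#' @return An object of class `asst_agent_params`.
#' @export
agent_params <- function(attn_odor = 0.5, attn_medium = 0.5,
                         learning_rate = 0.5, perseveration = 0.25,
                         lapse = 0.02, inverse_temperature = 6,
                         latency_mu = log(20), latency_sigma = 0.35,
                         novelty_latency_gain = 1.35, stage_decay = 0.08,
                         novelty_attention = 0.75, stage_forgetting = 0.5,
                         refuse_prob = 0) {
  if (attn_odor < 0 || attn_medium < 0 || attn_odor + attn_medium <= 0)
    stop("attention weights must be nonnegative and not both zero")
  if (learning_rate <= 0 || learning_rate > 1)
    stop("`learning_rate` must be in (0, 1]")
  if (perseveration < 0 || perseveration >= 1)
    stop("`perseveration` must be in [0, 1)")
  if (lapse < 0 || lapse >= 0.5) stop("`lapse` must be in [0, 0.5)")
  if (inverse_temperature <= 0) stop("`inverse_temperature` must be > 0")
  if (latency_sigma < 0) stop("`latency_sigma` must be >= 0")
  if (novelty_latency_gain < 0) stop("`novelty_latency_gain` must be >= 0")
  if (stage_decay < 0) stop("`stage_decay` must be >= 0")
  if (novelty_attention < 0 || novelty_attention >= 1)
    stop("`novelty_attention` must be in [0, 1)")
  if (stage_forgetting < 0 || stage_forgetting > 1)
    stop("`stage_forgetting` must be in [0, 1]")
  if (refuse_prob < 0 || refuse_prob >= 1)
    stop("`refuse_prob` must be in [0, 1)")
  s <- attn_odor + attn_medium
  structure(list(
    attn_odor = attn_odor / s, attn_medium = attn_medium / s,
    learning_rate = learning_rate, perseveration = perseveration,
    lapse = lapse, inverse_temperature = inverse_temperature,
    latency_mu = latency_mu, latency_sigma = latency_sigma,
    novelty_latency_gain = novelty_latency_gain, stage_decay = stage_decay,
    novelty_attention = novelty_attention,
    stage_forgetting = stage_forgetting, refuse_prob = refuse_prob
  ), class = "asst_agent_params")
}

#' @export
print.asst_agent_params <- function(x, ...) {
  cat("ASST agent parameters\n")
  cat(sprintf("  attention (odor/medium): %.2f / %.2f\n",
              x$attn_odor, x$attn_medium))
  cat(sprintf("  learning_rate=%.2f perseveration=%.2f lapse=%.3f beta=%.1f\n",
              x$learning_rate, x$perseveration, x$lapse,
              x$inverse_temperature))
  cat(sprintf("  latency: mu=%.2f sigma=%.2f novelty_gain=%.2f decay=%.3f\n",
              x$latency_mu, x$latency_sigma, x$novelty_latency_gain,
              x$stage_decay))
  invisible(x)
}

#' Strain presets for the simulated cohorts
#'
#' Default agent parameters emulating the three strains' behavioural
#' profiles: the spontaneously hypertensive rat (SHR, the ADHD model) is
#' impulsive (short latencies), lapse-prone and attentionally rigid (high
#' perseveration, so it fails to form an attentional set and perseverates at
#' rule changes); Wistar-Kyoto (WKY) and Sprague-Dawley (SD) share the
#' control learning profile and differ only in response speed, WKY being the
#' slowest of the three. Latency locations are calibrated so that the
#' grand-mean first-dig latency of an 8-subject cohort over the full task
#' falls near 14.7 s (SHR), 46.4 s (WKY) and 26.9 s (SD).
#'
#' @param strain one of `"SHR"`, `"WKY"`, `"SD"`.
#' @return An `asst_agent_params` object.
#' @export
strain_preset <- function(strain = c("SHR", "WKY", "SD")) {
  strain <- match.arg(strain)
  switch(strain,
    SHR = agent_params(learning_rate = 0.18, perseveration = 0.99,
                       lapse = 0.16, inverse_temperature = 3.5,
                       novelty_attention = 0.55,
                       latency_mu = 2.71, latency_sigma = 0.35),
    WKY = agent_params(learning_rate = 0.55, perseveration = 0.73,
                       lapse = 0.008, inverse_temperature = 12,
                       novelty_attention = 0.97,
                       latency_mu = 3.82, latency_sigma = 0.35),
    SD  = agent_params(learning_rate = 0.55, perseveration = 0.73,
                       lapse = 0.008, inverse_temperature = 12,
                       novelty_attention = 0.97,
                       latency_mu = 3.26, latency_sigma = 0.35)
  )
}

#' Apply a methylphenidate dose transform to an agent preset
#'
#' Models chronic methylphenidate (MPH) purely as a static transform of the
#' behavioural parameters: both doses lengthen latency and reduce lapses,
#' and the effect on perseveration follows an inverted-U — the 2.5 mg/kg
#' dose releases attentional inertia much more than the 5 mg/kg dose, which
#' barely changes it. No pharmacokinetics are modelled.
#'
#' @param preset an `asst_agent_params` object (typically
#'   `strain_preset("SHR")`).
#' @param dose_mg_per_kg 0 (vehicle; identity), 2.5 or 5.0.
#' @return The transformed `asst_agent_params`.
#' @export
apply_treatment <- function(preset, dose_mg_per_kg = 0) {
  stopifnot(inherits(preset, "asst_agent_params"))
  if (!dose_mg_per_kg %in% c(0, 2.5, 5.0))
    stop("unsupported dose: ", dose_mg_per_kg,
         " (supported: 0, 2.5, 5.0 mg/kg)")
  if (dose_mg_per_kg == 0) return(preset)
  d <- if (dose_mg_per_kg == 2.5) {
    list(lapse = -0.10, perseveration = -0.55, latency_mu = 0.45)
  } else {
    list(lapse = -0.07, perseveration = -0.08, latency_mu = 0.60)
  }
  p <- preset
  p$lapse <- max(0.005, p$lapse + d$lapse)
  p$perseveration <- max(0.05, p$perseveration + d$perseveration)
  p$latency_mu <- p$latency_mu + d$latency_mu
  p
}

#' Initialise an agent's belief state over a schedule's exemplars
#'
#' Exemplar values start at 0.5 (no information) and attention weights at
#' the preset's initial weights.
#'
#' @param params an `asst_agent_params`.
#' @param exemplars character vector of exemplar labels the agent will
#'   encounter.
#' @return A list with `values` (named numeric in \[0,1\]) and `attn`
#'   (named numeric, `odor` and `medium`, summing to 1).
#' @export
init_belief <- function(params, exemplars) {
  list(values = stats::setNames(rep(0.5, length(exemplars)), exemplars),
       attn = c(odor = params$attn_odor, medium = params$attn_medium))
}

#' One choice of the simulated agent
#'
#' With probability `lapse` the choice is uniformly random; otherwise the
#' agent attends a single dimension drawn with probability proportional to
#' the attention weights of the dimensions on offer, and chooses between
#' the cups by a softmax (with the preset's inverse temperature) over the
#' attended dimension's exemplar values. The marginal probability of
#' choosing the left cup is thus
#' `lapse/2 + (1-lapse) * sum_d w_d * plogis(beta * (V_dL - V_dR))`.
#' Latency is drawn lognormal with location `latency_mu + latency_shift`.
#'
#' @param params an `asst_agent_params`.
#' @param belief belief state from [init_belief()] / [agent_update()].
#' @param left,right character vectors of the exemplars in each cup.
#' @param latency_shift additive shift of the lognormal location (log-s),
#'   encoding stage decay and novelty elevation; 0 by default.
#' @return A list with `side` ("L" or "R"), `latency_s` and `lapsed`.
#' @export
agent_choose <- function(params, belief, left, right, latency_shift = 0) {
  if (stats::runif(1) < params$lapse) {
    side <- if (stats::runif(1) < 0.5) "L" else "R"
    lapsed <- TRUE
  } else {
    dims <- .exemplar_dim(left)
    if (length(dims) == 1L) {
      k <- 1L
    } else {
      w <- belief$attn[dims]
      k <- if (stats::runif(1) < w[1L] / sum(w)) 1L else 2L
    }
    dim_right <- .exemplar_dim(right)
    vl <- belief$values[[left[k]]]
    vr <- belief$values[[right[which(dim_right == dims[k])]]]
    p_left <- 1 / (1 + exp(-params$inverse_temperature * (vl - vr)))
    side <- if (stats::runif(1) < p_left) "L" else "R"
    lapsed <- FALSE
  }
  lat <- exp(stats::rnorm(1, params$latency_mu + latency_shift,
                          params$latency_sigma))
  list(side = side, latency_s = lat, lapsed = lapsed)
}

#' Update the belief state after feedback
#'
#' The chosen cup's exemplar values move toward the reward outcome by
#' `learning_rate`. On compound trials attention drifts toward the
#' dimension better able to predict reward — the one whose two on-offer
#' exemplars have the more strongly differentiated values
#' (`|V(chosen) - V(unchosen)|`) — with per-trial step
#' `0.4 * (1 - perseveration)` scaled by the differentiation margin
#' between the dimensions, so weak or conflicting evidence moves attention
#' little; ties leave attention unchanged. Weights
#' are renormalised to sum to 1 after every update. Both of an irrelevant
#' dimension's exemplars track the same overall reward rate, so its
#' within-pair differentiation stays near zero and attention reliably
#' consolidates on the relevant dimension; confidently wrong values — as
#' right after a reversal — keep attention on the old dimension until
#' relearning catches up.
#'
#' @param params an `asst_agent_params`.
#' @param belief current belief state.
#' @param chosen character vector of exemplars in the chosen cup.
#' @param reward 1 if the choice was rewarded, 0 otherwise.
#' @param unchosen exemplars of the cup not chosen (used only for the
#'   attention drift; when `NULL` attention is left unchanged).
#' @return The updated belief state.
#' @export
agent_update <- function(params, belief, chosen, reward, unchosen = NULL) {
  dims <- .exemplar_dim(chosen)
  v_old <- belief$values[chosen]
  belief$values[chosen] <- v_old + params$learning_rate * (reward - v_old)
  if (length(chosen) >= 2L && length(unchosen) >= 2L) {
    v_un <- belief$values[unchosen][match(dims, .exemplar_dim(unchosen))]
    know <- abs(v_old - v_un)  # within-pair value differentiation
    names(know) <- dims
    if (abs(know["odor"] - know["medium"]) > 1e-12) {
      best <- names(know)[which.max(know)]
      margin <- abs(know["odor"] - know["medium"])
      step <- .attn_rate * (1 - params$perseveration) * margin
      belief$attn[best] <- belief$attn[best] +
        step * (1 - belief$attn[best])
      belief$attn[setdiff(names(belief$attn), best)] <-
        1 - belief$attn[best]
    }
  }
  belief
}

# Stage transition: learned values relax toward 0.5 by stage_forgetting;
# a dimension appearing for the first time (no exemplar of it seen in any
# earlier stage) captures attention by novelty_attention before
# renormalisation. Attention itself does not decay between stages.
.stage_transition <- function(params, belief, stage_spec, seen) {
  belief$values <- 0.5 + (belief$values - 0.5) * (1 - params$stage_forgetting)
  ex <- c(stage_spec$pair_relevant, stage_spec$pair_irrelevant)
  seen_dims <- unique(.exemplar_dim(seen))
  new_dims <- setdiff(unique(.exemplar_dim(ex)), seen_dims)
  if (length(new_dims) == 1L) {
    belief$attn[new_dims] <- max(belief$attn[new_dims],
                                 params$novelty_attention)
    belief$attn[setdiff(names(belief$attn), new_dims)] <-
      1 - belief$attn[new_dims]
  }
  belief
}
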