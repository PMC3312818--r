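# Independent oracles used across the suite. These deliberately re-derive
# the contracts by different means than the package implementation.

# Literal block/phase error classifier: materialise the 4-trial blocks,
# locate the first block with <= 2 errors (of any type), and tag each
# old-rule-consistent error perseverative before that block and regressive
# from it onward; errors that are not old-rule-consistent are
# never-reinforced regardless of phase.
oracle_classify <- function(err, orc) {
  stopifnot(length(err) == length(orc))
  n <- length(err)
  if (n == 0L) return(c(perseverative = 0, regressive = 0,
                        never_reinforced = 0))
  block_of <- (seq_len(n) - 1L) %/% 4L + 1L
  err_per_block <- tapply(err, block_of, sum)
  calm <- which(err_per_block <= 2L)
  switch_block <- if (length(calm)) min(calm) else Inf
  pers <- regr <- nr <- 0L
  for (i in seq_len(n)) {
    if (!err[i]) next
    if (!orc[i]) {
      nr <- nr + 1L
    } else if (block_of[i] < switch_block) {
      pers <- pers + 1L
    } else {
      regr <- regr + 1L
    }
  }
  c(perseverative = pers, regressive = regr, never_reinforced = nr)
}

# Old-rule consistency tags re-derived independently from a trial table
# and stage role (mirrors the anchoring convention for the ED stage).
oracle_orc <- function(trials, stage_spec) {
  err <- !trials$correct
  nm <- stage_spec$name
  if (nm %in% c("CDR", "IDR", "EDR")) return(err)
  if (nm == "ED") {
    col <- if (stage_spec$previous_relevant_dimension == "odor")
      "chosen_odor" else "chosen_medium"
    orc <- rep(FALSE, nrow(trials))
    first_err <- which(err)[1]
    if (!is.na(first_err)) {
      anchor <- trials[[col]][first_err]
      orc <- err & trials[[col]] == anchor
    }
    return(orc)
  }
  rep(FALSE, nrow(trials))
}

# All binary sequences of length n with no run longer than 2, by exhaustive
# enumeration of the 2^n candidates.
enumerate_constrained <- function(n, symbols = c("L", "R")) {
  grid <- expand.grid(rep(list(symbols), n), stringsAsFactors = FALSE)
  keep <- apply(grid, 1, function(s) max(rle(s)$lengths) <= 2)
  grid[keep, , drop = FALSE]
}

# One-way ANOVA by brute-force sum-of-squares decomposition.
oracle_oneway <- function(values, groups) {
  g <- factor(groups)
  grand <- mean(values)
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  ss_b <- sum(ns * (means - grand)^2)
  ss_t <- sum((values - grand)^2)
  ss_w <- ss_t - ss_b
  df1 <- nlevels(g) - 1
  df2 <- length(values) - nlevels(g)
  F <- (ss_b / df1) / (ss_w / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# A small simulated control cohort used by several scoring/stats tests.
make_test_cohort <- function(seed = 420, n = 4, strain = "WKY") {
  simulate_cohort(data.frame(group = strain, strain = strain,
                             dose = 0, n = n),
                  seed = seed)
}

# A random ED-like trial table (random correctness, random chosen cups)
# over the series-1 ED stage exemplars.
random_ed_trials <- function(n, seed_stage = NULL) {
  odors <- sample(c("O5", "O6"), n, replace = TRUE)
  media <- sample(c("M5", "M6"), n, replace = TRUE)
  data.frame(
    stage = "ED", trial = seq_len(n),
    chosen_odor = odors, chosen_medium = media,
    correct = media == "M5",        # M5 is correct at series-1 ED
    latency_s = 1, exploratory = seq_len(n) <= 4,
    stringsAsFactors = FALSE)
}
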