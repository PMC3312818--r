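make_belief <- function(params, values, attn_odor = 0.5) {
  b <- init_belief(params, names(values))
  b$values[names(values)] <- values
  b$attn <- c(odor = attn_odor, medium = 1 - attn_odor)
  b
}

test_that("greedy limit: known values and no lapse give the baited cup", {
  p <- agent_params(lapse = 0, inverse_temperature = 1000)
  # single-dimension cups: value 1 vs 0 decides deterministically
  b <- make_belief(p, c(O1 = 1, O2 = 0))
  set.seed(1)
  sides <- replicate(200, agent_choose(p, b, "O1", "O2")$side)
  expect_true(all(sides == "L"))
  # compound cups with attention settled on the knowing dimension
  b2 <- make_belief(p, c(O1 = 1, O2 = 0, M1 = 0.5, M2 = 0.5),
                    attn_odor = 1)
  sides2 <- replicate(200, agent_choose(p, b2, c("O1", "M1"),
                                        c("O2", "M2"))$side)
  expect_true(all(sides2 == "L"))
})

test_that("full lapse with equal values is an unbiased coin", {
  p <- agent_params(lapse = 0.49, inverse_temperature = 5)
  b <- make_belief(p, c(O1 = 0.5, O2 = 0.5))
  set.seed(2)
  n <- 4000
  left <- mean(replicate(n, agent_choose(p, b, "O1", "O2")$side) == "L")
  se <- sqrt(0.25 / n)
  expect_lt(abs(left - 0.5), 3 * se)
})

test_that("choice frequencies match the mixture closed form", {
  p <- agent_params(lapse = 0.1, inverse_temperature = 3)
  vals <- c(O1 = 0.8, O2 = 0.3, M1 = 0.6, M2 = 0.45)
  b <- make_belief(p, vals, attn_odor = 0.7)
  # closed form: lapse/2 + (1-lapse) * sum_d w_d * plogis(beta * dV_d)
  p_theory <- 0.05 + 0.9 *
    (0.7 * plogis(3 * (0.8 - 0.3)) + 0.3 * plogis(3 * (0.6 - 0.45)))
  set.seed(3)
  n <- 10000
  p_hat <- mean(replicate(n, agent_choose(p, b, c("O1", "M1"),
                                          c("O2", "M2"))$side) == "L")
  se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(p_hat - p_theory), 3 * se)
})

test_that("value update moves chosen exemplars toward the outcome", {
  p <- agent_params(learning_rate = 1)
  b <- make_belief(p, c(O1 = 0.2, O2 = 0.9, M1 = 0.4, M2 = 0.6))
  b2 <- agent_update(p, b, c("O1", "M1"), 1, c("O2", "M2"))
  expect_equal(unname(b2$values[c("O1", "M1")]), c(1, 1))
  expect_equal(b2$values[c("O2", "M2")], b$values[c("O2", "M2")])
  b3 <- agent_update(p, b, c("O1", "M1"), 0, c("O2", "M2"))
  expect_equal(unname(b3$values[c("O1", "M1")]), c(0, 0))

  # partial learning
  p2 <- agent_params(learning_rate = 0.5)
  b4 <- agent_update(p2, b, c("O1", "M1"), 1, c("O2", "M2"))
  expect_equal(unname(b4$values["O1"]), 0.2 + 0.5 * 0.8)
})

test_that("near-total perseveration freezes attention", {
  p <- agent_params(perseveration = 0.999)
  b <- make_belief(p, c(O1 = 1, O2 = 0, M1 = 0.5, M2 = 0.5),
                   attn_odor = 0.4)
  for (r in c(0, 1)) {
    b2 <- agent_update(p, b, c("O1", "M1"), r, c("O2", "M2"))
    expect_lt(max(abs(b2$attn - b$attn)), 0.01)
  }
})

test_that("without perseveration attention converges on the relevant dimension", {
  # deterministic feedback on a compound discrimination: reward follows O1
  p <- agent_params(perseveration = 0, lapse = 0, inverse_temperature = 8)
  stage <- build_stage_sequence(1, 1:3)[[2]]
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    cfg <- generate_trial_configs(stage, 50)
    b <- make_belief(p, c(O1 = 0.5, O2 = 0.5, M1 = 0.5, M2 = 0.5))
    for (i in 1:50) {
      lft <- c(cfg$left_odor[i], cfg$left_medium[i])
      rgt <- c(cfg$right_odor[i], cfg$right_medium[i])
      ch <- agent_choose(p, b, lft, rgt)
      cup <- if (ch$side == "L") lft else rgt
      oth <- if (ch$side == "L") rgt else lft
      b <- agent_update(p, b, cup, as.numeric("O1" %in% cup), oth)
    }
    if (b$attn["odor"] > 0.9) ok <- ok + 1
  }
  expect_gte(ok, 99)
})

test_that("latency follows the shifted lognormal location", {
  p <- agent_params(latency_mu = log(20), latency_sigma = 0.3)
  b <- make_belief(p, c(O1 = 1, O2 = 0))
  set.seed(4)
  lats <- replicate(3000, agent_choose(p, b, "O1", "O2",
                                       latency_shift = log(2))$latency_s)
  # E[lognormal] = exp(mu + shift + sigma^2/2)
  expected <- exp(log(20) + log(2) + 0.09 / 2)
  expect_lt(abs(mean(lats) / expected - 1), 0.05)
  expect_true(all(lats > 0))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(agent_params(lapse = 0.5), "lapse")
  expect_error(agent_params(perseveration = 1), "perseveration")
  expect_error(agent_params(learning_rate = 0), "learning_rate")
  expect_error(agent_params(inverse_temperature = 0), "inverse_temperature")
  expect_error(agent_params(attn_odor = -1), "attention")
})

test_that("strain presets encode the intended behavioural ordering", {
  shr <- strain_preset("SHR"); wky <- strain_preset("WKY")
  sd <- strain_preset("SD")
  expect_lt(shr$latency_mu, sd$latency_mu)
  expect_lt(sd$latency_mu, wky$latency_mu)   # WKY slowest
  expect_gt(shr$lapse, wky$lapse)
  expect_gt(shr$lapse, sd$lapse)
  expect_gt(shr$perseveration, wky$perseveration)
  expect_gt(shr$perseveration, sd$perseveration)
})

test_that("methylphenidate transforms follow the inverted-U profile", {
  shr <- strain_preset("SHR")
  expect_identical(apply_treatment(shr, 0), shr)
  low <- apply_treatment(shr, 2.5)
  high <- apply_treatment(shr, 5.0)
  # both doses slow responding and reduce lapses
  expect_gt(low$latency_mu, shr$latency_mu)
  expect_gt(high$latency_mu, shr$latency_mu)
  expect_lt(low$lapse, shr$lapse)
  expect_lt(high$lapse, shr$lapse)
  # the low dose releases perseveration far more than the high dose
  expect_lt(low$perseveration, high$perseveration)
  expect_lt(high$perseveration, shr$perseveration)
  expect_error(apply_treatment(shr, 1.0), "unsupported dose")
})

test_that("sessions stop at criterion, carry belief, and respect the cap", {
  # error-free overtrained agent: exactly 6 trials per stage
  p <- agent_params(lapse = 0, inverse_temperature = 500)
  sch <- build_schedule("perfect", 1, 1:3, 10, seed = 21)
  ses <- run_session(p, sch, seed = 22, pretrained = TRUE)
  tab <- stage_metrics_table(ses)
  expect_equal(tab$trials, rep(6L, 7))
  expect_equal(tab$errors, rep(0L, 7))
  expect_true(all(tab$completed))
  expect_equal(nrow(ses$trials), 42)

  # tight cap with heavy lapsing: incomplete stages, but all stages run
  p2 <- agent_params(lapse = 0.49)
  ses2 <- run_session(p2, build_schedule("lapser", 1, 1:3, 6, seed = 30),
                      seed = 31, max_trials_per_stage = 6)
  expect_named(ses2$completed, asst_stages())
  expect_gt(sum(!ses2$completed), 3)
  expect_setequal(unique(ses2$trials$stage), asst_stages())
  expect_error(run_session(p2, build_schedule("x", 1, 1:3, 6, seed = 1),
                           max_trials_per_stage = 5), ">= 6")
})

test_that("sessions and cohorts are reproducible from their seeds", {
  p <- strain_preset("SD")
  s1 <- run_session(p, build_schedule("a", 1, 1:3, 150, seed = 5), seed = 6)
  s2 <- run_session(p, build_schedule("a", 1, 1:3, 150, seed = 5), seed = 6)
  expect_identical(s1$trials, s2$trials)

  c1 <- simulate_cohort(experiment1_design(), seed = 99)
  c2 <- simulate_cohort(experiment1_design(), seed = 99)
  expect_identical(as.data.frame.asst_cohort(c1),
                   as.data.frame.asst_cohort(c2))
})

test_that("cohort designs produce the requested group structure", {
  co <- simulate_cohort(experiment1_design(), seed = 12,
                        max_trials_per_stage = 80)
  expect_length(co, 24)
  strains <- vapply(co, `[[`, "", "strain")
  expect_equal(unname(table(strains)[c("SHR", "WKY", "SD")]),
               rep(8L, 3), ignore_attr = TRUE)
  # series alternate within each group
  series <- vapply(co, `[[`, 0L, "series")
  expect_equal(sum(series == 1), 12)

  # empty group is allowed
  d <- experiment1_design(); d$n[2] <- 0L
  co2 <- simulate_cohort(d, seed = 12, max_trials_per_stage = 60)
  expect_length(co2, 16)
  expect_false("WKY" %in% vapply(co2, `[[`, "", "strain"))

  expect_error(simulate_cohort(data.frame(group = "x", strain = "RAT",
                                          dose = 0, n = 2), seed = 1),
               "unknown strain")
})
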