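rm_long <- function(Y, groups) {
  # Y: subjects x within-levels matrix
  k <- ncol(Y)
  data.frame(
    subject = rep(sprintf("s%02d", seq_len(nrow(Y))), each = k),
    group = rep(groups, each = k),
    level = rep(sprintf("w%d", seq_len(k)), nrow(Y)),
    y = as.vector(t(Y)))
}

test_that("sphericity epsilons respect their analytic ranges", {
  set.seed(10)
  for (i in 1:200) {
    k <- sample(3:6, 1)
    n <- sample(8:20, 1)
    Y <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k), k, k)
    eps <- sphericity_epsilons(Y)
    expect_gte(eps$epsilon_gg, 1 / (k - 1) - 1e-10)
    expect_lte(eps$epsilon_gg, 1 + 1e-10)
    expect_gte(eps$epsilon_hf, eps$epsilon_gg - 1e-10)
  }
  # 2 within levels: sphericity trivially holds
  eps2 <- sphericity_epsilons(matrix(rnorm(20), 10, 2))
  expect_equal(eps2$epsilon_gg, 1)
  expect_equal(eps2$epsilon_hf, 1)
  expect_true(eps2$trivial)
  expect_error(sphericity_epsilons(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)),
               "missing")
})

test_that("compound-symmetric data give epsilons near one", {
  set.seed(11)
  n <- 200; k <- 5
  subj <- rnorm(n, sd = 2)
  Y <- subj + matrix(rnorm(n * k), n, k)
  eps <- sphericity_epsilons(Y)
  expect_gt(eps$epsilon_gg, 0.95)
})

test_that("epsilons and corrections agree with the car reference", {
  skip_if_not_installed("car")
  set.seed(12)
  n <- 8; k <- 5
  Y <- matrix(rnorm(3 * n * k), 3 * n, k) %*%
    (diag(k) + 0.5 * matrix(runif(k * k), k, k))
  groups <- rep(c("a", "b", "c"), each = n)
  mlm <- lm(Y ~ groups)
  idata <- data.frame(level = factor(sprintf("w%d", 1:k)))
  av <- suppressWarnings(
    summary(car::Anova(mlm, idata = idata, idesign = ~level),
            multivariate = FALSE))  # car warns when capping HF at 1
  gg_car <- av$pval.adjustments["groups:level", "GG eps"]
  hf_car <- av$pval.adjustments["groups:level", "HF eps"]

  fit <- mixed_rm_anova(rm_long(Y, groups), "y", "group", "level", "subject")
  expect_equal(fit$epsilon_gg[2], unname(gg_car), tolerance = 1e-6)
  expect_equal(fit$epsilon_hf[2], unname(hf_car), tolerance = 1e-6)

  # univariate F tests match as well
  uni <- av$univariate.tests
  expect_equal(fit$F[1],
               unname(uni["groups", "Sum Sq"] / uni["groups", "num Df"] /
                      (uni["groups", "Error SS"] / uni["groups", "den Df"])),
               tolerance = 1e-8)
  expect_equal(fit$F[2],
               unname(uni["level", "Sum Sq"] / uni["level", "num Df"] /
                      (uni["level", "Error SS"] / uni["level", "den Df"])),
               tolerance = 1e-8)
  # Mauchly p agrees
  expect_equal(attr(fit, "mauchly")$p,
               unname(av$sphericity.tests["level", "p-value"]),
               tolerance = 1e-6)
})

test_that("a 2-level within factor reduces to the paired t-test", {
  set.seed(13)
  Y <- matrix(rnorm(24), 12, 2)
  fit <- mixed_rm_anova(rm_long(Y, rep("g", 12)), "y", "group", "level",
                        "subject")
  tt <- paired_t(Y[, 1], Y[, 2])
  expect_equal(fit$F[2], tt$t^2, tolerance = 1e-10)
  expect_equal(fit$p_uncorrected[2], tt$p, tolerance = 1e-10)
  expect_equal(fit$correction_used[2], "none")
})

test_that("mixed ANOVA partitions the total sum of squares", {
  set.seed(14)
  for (i in 1:20) {
    a <- sample(2:4, 1); s <- sample(4:10, 1); k <- sample(3:7, 1)
    Y <- matrix(rnorm(a * s * k, sd = sample(1:3, 1)), a * s, k)
    groups <- rep(letters[1:a], each = s)
    fit <- mixed_rm_anova(rm_long(Y, groups), "y", "group", "level",
                          "subject")
    ss <- attr(fit, "ss")
    expect_equal(ss[["total"]],
                 sum(ss[c("between", "subjects", "within",
                          "interaction", "error")]),
                 tolerance = 1e-8 * ss[["total"]])
  }
})

test_that("location shifts leave all F statistics unchanged", {
  set.seed(15)
  Y <- matrix(rnorm(3 * 8 * 7), 24, 7)
  groups <- rep(c("a", "b", "c"), each = 8)
  f1 <- mixed_rm_anova(rm_long(Y, groups), "y", "group", "level", "subject")
  f2 <- mixed_rm_anova(rm_long(Y + 100, groups), "y", "group", "level",
                       "subject")
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
})

test_that("epsilon correction inflates the p of a real within effect", {
  set.seed(16)
  k <- 6
  Y <- matrix(rnorm(16 * k), 16, k)
  Y[, 1] <- Y[, 1] * 4          # induce a sphericity violation
  Y <- Y + rep(seq_len(k), each = 16) * 1.2  # and a real within effect
  fit <- mixed_rm_anova(rm_long(Y, rep(c("a", "b"), each = 8)),
                        "y", "group", "level", "subject")
  expect_true(fit$correction_used[2] %in% c("GG", "HF"))
  expect_gt(fit$F[2], 1)
  expect_gte(fit$p_corrected[2], fit$p_uncorrected[2])
})

test_that("unbalanced designs are rejected", {
  set.seed(17)
  d <- rm_long(matrix(rnorm(30), 10, 3), rep(c("a", "b"), c(4, 6)))
  expect_error(mixed_rm_anova(d, "y", "group", "level", "subject"),
               "unbalanced")
  d2 <- rm_long(matrix(rnorm(30), 10, 3), rep(c("a", "b"), each = 5))
  d2 <- d2[-1, ]  # drop one cell
  expect_error(mixed_rm_anova(d2, "y", "group", "level", "subject"),
               "unbalanced")
})

test_that("one-way ANOVA with LSD matches the reference computations", {
  set.seed(18)
  # two groups: LSD p equals the pooled two-sample t-test p
  x <- rnorm(8); y <- rnorm(8, 1)
  res <- oneway_anova_lsd(c(x, y), rep(c("a", "b"), each = 8))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$pairwise$p_lsd[1], tt$p.value, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # brute-force SS agreement on a random 3 x 8 table
  v <- rnorm(24); g <- rep(c("a", "b", "c"), each = 8)
  res3 <- oneway_anova_lsd(v, g)
  orc <- oracle_oneway(v, g)
  expect_equal(res3$F, orc$F, tolerance = 1e-10)
  expect_equal(res3$p, orc$p, tolerance = 1e-10)
  expect_equal(nrow(res3$pairwise), 3)
  # and against the built-in linear-model ANOVA
  expect_equal(res3$F, unname(anova(lm(v ~ g))[1, "F value"]),
               tolerance = 1e-10)

  # identical groups: F = 0, zero mean differences
  v0 <- rep(rnorm(8), 3)
  res0 <- oneway_anova_lsd(v0, g)
  expect_equal(res0$F, 0)
  expect_equal(res0$pairwise$mean_diff, rep(0, 3))

  # degenerate input
  expect_error(oneway_anova_lsd(rep(1, 6), rep(c("a", "b"), 3)),
               "zero within-group variance")
  # Holm adjustment is monotone over LSD
  resh <- oneway_anova_lsd(v, g, adjust = "holm")
  expect_true(all(resh$pairwise$p_lsd >= res3$pairwise$p_lsd - 1e-12))
})

test_that("paired t matches its closed form and rejects degenerate input", {
  set.seed(19)
  x <- rnorm(10); y <- rnorm(10)
  res <- paired_t(x, y)
  d <- x - y
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-10)
  expect_equal(res$p, t.test(x, y, paired = TRUE)$p.value, tolerance = 1e-10)
  expect_equal(res$df, 9)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, x - 3), "zero variance")
  expect_error(paired_t(x, rnorm(5)), "equal length")
})

test_that("pearson correlation handles the exact and degenerate cases", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(20)
  a <- rnorm(12); b <- rnorm(12)
  res <- pearson_correlation(a, b)
  # closed form: r via standardised cross-products, p via the t transform
  r_manual <- sum(scale(a) * scale(b)) / 11
  t_manual <- r_manual * sqrt(10 / (1 - r_manual^2))
  expect_equal(res$r, r_manual, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 10), tolerance = 1e-10)
  expect_error(pearson_correlation(a, rep(1, 12)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("null correlations at n = 8 reject at the nominal rate", {
  set.seed(21)
  nsim <- 5000
  hits <- 0
  for (i in seq_len(nsim)) {
    if (pearson_correlation(rnorm(8), rnorm(8))$p < 0.05) hits <- hits + 1
  }
  ci <- qbinom(c(0.005, 0.995), nsim, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})
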