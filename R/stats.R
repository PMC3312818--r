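# Statistical battery: mixed repeated-measures ANOVA with sphericity
# handling, one-way ANOVAs with Fisher LSD post-hocs, paired t-tests and
# Pearson correlations.

# k x (k-1) orthonormal basis of contrasts (helmert-style, normalised)
.ortho_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Greenhouse-Geisser and Huynh-Feldt sphericity epsilons
#'
#' Computes both epsilons from the sample covariance of the within-subject
#' scores. With fewer than 3 within levels sphericity holds trivially and
#' `(1, 1)` is returned with the `trivial` flag set. The Huynh-Feldt value
#' is the standard small-sample correction of the Greenhouse-Geisser value
#' and may exceed 1; it is returned uncapped (cap at 1 when adjusting
#' degrees of freedom).
#'
#' @param within_matrix numeric matrix, subjects in rows, within levels in
#'   columns, no missing cells.
#' @param n_groups number of between-subject groups the covariance is
#'   pooled over (1 for a single-sample design); affects only the
#'   Huynh-Feldt small-sample term.
#' @return List with `epsilon_gg`, `epsilon_hf`, `trivial`.
#' @export
sphericity_epsilons <- function(within_matrix, n_groups = 1L) {
  within_matrix <- as.matrix(within_matrix)
  if (anyNA(within_matrix)) stop("missing cells are not supported")
  k <- ncol(within_matrix)
  n <- nrow(within_matrix)
  if (k < 3L) {
    return(list(epsilon_gg = 1, epsilon_hf = 1, trivial = TRUE))
  }
  if (n < 2L) stop("at least 2 subjects required")
  S <- stats::cov(within_matrix)
  M <- .ortho_contrasts(k)
  E <- t(M) %*% S %*% M
  gg <- (sum(diag(E)))^2 / ((k - 1) * sum(E * E))
  df <- n - n_groups   # degrees of freedom of the covariance estimate
  hf <- ((df + 1) * (k - 1) * gg - 2) /
    ((k - 1) * (df - (k - 1) * gg))
  list(epsilon_gg = gg, epsilon_hf = hf, trivial = FALSE)
}

# Mauchly's sphericity test on a pooled within-group covariance with
# `df_cov` degrees of freedom.
.mauchly <- function(S, k, df_cov) {
  M <- .ortho_contrasts(k)
  E <- t(M) %*% S %*% M
  p <- k - 1
  W <- det(E) / (sum(diag(E)) / p)^p
  if (!is.finite(W) || W <= 0) return(list(W = W, p = 0))
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * df_cov)
  z <- -df_cov * rho * log(W)
  df <- p * (p + 1) / 2 - 1
  # chi-square approximation with the standard second-order term
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * k + 2) /
    (288 * (df_cov * p * rho)^2)
  pr1 <- stats::pchisq(z, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(z, df + 4, lower.tail = FALSE)
  list(W = W, p = pr1 + w2 * (pr2 - pr1))
}

#' Two-way mixed repeated-measures ANOVA with sphericity handling
#'
#' One between-subjects factor (e.g. strain or treatment) crossed with one
#' within-subjects factor (e.g. stage or error subtype), balanced design.
#' Sums of squares are computed directly from the cell means. Sphericity of
#' the within factor is examined with Mauchly's test on the pooled
#' within-group covariance; when violated (p < 0.05) the within and
#' interaction degrees of freedom are scaled by the Greenhouse-Geisser
#' epsilon for large violations (epsilon_GG < 0.75) and by the Huynh-Feldt
#' epsilon (capped at 1) for small ones.
#'
#' @param data long-format data frame.
#' @param dv,between,within,subject column names of the response, the
#'   between factor, the within factor and the subject identifier.
#' @return Object of class `asst_rm_anova`: an effects data frame
#'   (`effect`, `F`, `df_num`, `df_den`, `p_uncorrected`, `epsilon_gg`,
#'   `epsilon_hf`, `correction_used`, `p_corrected`) with the Mauchly test
#'   and the sum-of-squares partition as attributes.
#' @export
mixed_rm_anova <- function(data, dv, between, within, subject) {
  y <- data[[dv]]
  g <- factor(data[[between]])
  w <- factor(data[[within]], levels = unique(data[[within]]))
  id <- factor(data[[subject]])
  if (anyNA(y)) stop("missing responses are not supported")

  a <- nlevels(g); k <- nlevels(w)
  tab <- table(id, w)
  if (any(tab != 1L))
    stop("unbalanced design: every subject must contribute exactly one ",
         "observation per within level")
  subj_group <- tapply(as.character(g), id, function(v) unique(v)[1])
  n_per <- table(factor(subj_group, levels = levels(g)))
  if (length(unique(n_per)) != 1L)
    stop("unbalanced design: groups must have equal numbers of subjects")
  s <- as.integer(n_per[1L])
  N <- a * s

  grand <- mean(y)
  gm <- tapply(y, g, mean)              # group means
  wm <- tapply(y, w, mean)              # within-level means
  cm <- tapply(y, list(g, w), mean)     # cell means
  sm <- tapply(y, id, mean)             # subject means

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- k * sum((sm - grand)^2)
  ss_a <- s * k * sum((gm - grand)^2)
  ss_subj <- ss_between_subj - ss_a
  ss_w <- N * sum((wm - grand)^2)
  ss_aw <- s * sum((cm - outer(gm - grand, wm - grand, "+") - grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_w - ss_aw

  df_a <- a - 1; df_subj <- a * (s - 1)
  df_w <- k - 1; df_aw <- (a - 1) * (k - 1)
  df_err <- a * (s - 1) * (k - 1)

  # with a single group the between and interaction effects are undefined
  F_a <- if (a > 1) (ss_a / df_a) / (ss_subj / df_subj) else NA_real_
  F_w <- (ss_w / df_w) / (ss_err / df_err)
  F_aw <- if (a > 1) (ss_aw / df_aw) / (ss_err / df_err) else NA_real_

  # pooled within-group covariance of the within-level scores
  scores <- tapply(y, list(id, w), mean)
  Spooled <- matrix(0, k, k)
  for (lv in levels(g)) {
    rows <- scores[names(subj_group)[subj_group == lv], , drop = FALSE]
    Spooled <- Spooled + stats::cov(rows) * (nrow(rows) - 1)
  }
  Spooled <- Spooled / (N - a)

  if (k >= 3L) {
    # epsilons from the pooled covariance (group means removed)
    M <- .ortho_contrasts(k)
    E <- t(M) %*% Spooled %*% M
    gg <- (sum(diag(E)))^2 / ((k - 1) * sum(E * E))
    hf <- ((N - a + 1) * (k - 1) * gg - 2) /
      ((k - 1) * (N - a - (k - 1) * gg))
    mau <- .mauchly(Spooled, k, N - a)
  } else {
    gg <- 1; hf <- 1
    mau <- list(W = 1, p = 1)
  }

  correction <- if (k < 3L || mau$p >= 0.05) "none"
                else if (gg < 0.75) "GG" else "HF"
  eps_used <- switch(correction, none = 1, GG = gg, HF = min(hf, 1))

  p_of <- function(F, d1, d2, e = 1) {
    if (!is.finite(F) || d1 < 1) return(NA_real_)
    stats::pf(F, d1 * e, d2 * e, lower.tail = FALSE)
  }

  effects <- data.frame(
    effect = c("between", "within", "interaction"),
    F = c(F_a, F_w, F_aw),
    df_num = c(df_a, df_w, df_aw),
    df_den = c(df_subj, df_err, df_err),
    p_uncorrected = c(p_of(F_a, df_a, df_subj),
                      p_of(F_w, df_w, df_err),
                      p_of(F_aw, df_aw, df_err)),
    epsilon_gg = c(NA, gg, gg),
    epsilon_hf = c(NA, hf, hf),
    correction_used = c("none", correction, correction),
    p_corrected = c(p_of(F_a, df_a, df_subj),
                    p_of(F_w, df_w, df_err, eps_used),
                    p_of(F_aw, df_aw, df_err, eps_used)),
    stringsAsFactors = FALSE
  )
  structure(effects, class = c("asst_rm_anova", "data.frame"),
            mauchly = mau,
            ss = c(total = ss_total, between = ss_a, subjects = ss_subj,
                   within = ss_w, interaction = ss_aw, error = ss_err),
            design = c(groups = a, subjects_per_group = s,
                       within_levels = k))
}

#' @export
print.asst_rm_anova <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("Mixed RM-ANOVA: %d groups x %d within levels, n=%d/group\n",
              d["groups"], d["within_levels"], d["subjects_per_group"]))
  mau <- attr(x, "mauchly")
  cat(sprintf("Mauchly W = %.4f, p = %.4g\n", mau$W, mau$p))
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$p_uncorrected <- signif(df$p_uncorrected, 4)
  df$p_corrected <- signif(df$p_corrected, 4)
  df$epsilon_gg <- round(df$epsilon_gg, 3)
  df$epsilon_hf <- round(df$epsilon_hf, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Fisher LSD pairwise comparisons
#'
#' Per-stage group comparison followed by Fisher's least-significant-
#' difference test: pairwise t statistics on the pooled error term with the
#' ANOVA error degrees of freedom, unadjusted for multiplicity (optionally
#' Holm-adjusted).
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @param adjust `"none"` (Fisher LSD proper, the default) or `"holm"`.
#' @return List with `F`, `df` (numerator, denominator), `p` and `pairwise`
#'   (data frame: `group_a`, `group_b`, `mean_diff`, `t`, `p_lsd`).
#' @export
oneway_anova_lsd <- function(values, groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least 2 groups required")
  ns <- tapply(values, g, length)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  means <- tapply(values, g, mean)
  grand <- mean(values)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((values - means[g])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  if (ss_w == 0) stop("zero within-group variance in all groups")
  mse <- ss_w / df2
  Fv <- (ss_b / df1) / mse
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)

  cmb <- utils::combn(levels(g), 2L)
  pw <- data.frame(
    group_a = cmb[1L, ], group_b = cmb[2L, ],
    mean_diff = means[cmb[1L, ]] - means[cmb[2L, ]],
    stringsAsFactors = FALSE)
  pw$t <- pw$mean_diff / sqrt(mse * (1 / ns[pw$group_a] + 1 / ns[pw$group_b]))
  pw$p_lsd <- 2 * stats::pt(-abs(pw$t), df2)
  if (adjust == "holm") pw$p_lsd <- stats::p.adjust(pw$p_lsd, "holm")
  rownames(pw) <- NULL
  list(F = Fv, df = c(df1, df2), p = p, pairwise = pw)
}

#' Paired t-test
#'
#' Two-sided paired t on the within-subject differences, used for the
#' CD-vs-ID and ID-vs-ED set-formation comparisons.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("at least 2 pairs required")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero variance of the paired differences")
  n <- length(d)
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, df = n - 1L,
       p = 2 * stats::pt(-abs(t), n - 1L), mean_diff = mean(d))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("at least 3 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in `x` or `y`")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
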