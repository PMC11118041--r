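# Statistical analysis: Kolmogorov-Smirnov normality screening, balanced
# two-way ANOVA with replicates (speed x load with subjects as
# replicates), and post-hoc all-pairwise comparisons of marginal means.
#
# The ANOVA is computed from the textbook balanced sum-of-squares
# decomposition directly rather than delegated to a model-fitting routine,
# so that brute-force arithmetic oracles can check it term by term.

#' Kolmogorov-Smirnov normality screen
#'
#' Tests a sample against a normal distribution with the sample's own mean
#' and standard deviation. Because the parameters are estimated from the
#' data, the asymptotic p-value is conservative (a Lilliefors correction
#' would reject more often); a caveat to that effect is attached.
#'
#' @param sample Numeric vector, n >= 5, nonzero variance.
#' @return A list with `statistic`, `p_value`, and a `caveat` string.
#' @export
ks_normality <- function(sample) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 5L) stop("need n >= 5", call. = FALSE)
  s <- stats::sd(sample)
  if (s == 0) stop("degenerate sample: zero variance", call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean(sample), s)
  )
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       caveat = "parameters estimated from the sample; asymptotic p-value is conservative (no Lilliefors correction)")
}

# Coerce a long data.frame (factor_a, factor_b, response) to a balanced
# 3-d array [a, b, replicate]; errors if unbalanced or replicates < 2.
balanced_array <- function(df, response, factor_a, factor_b) {
  a <- factor(df[[factor_a]])
  b <- factor(df[[factor_b]])
  y <- df[[response]]
  counts <- table(a, b)
  reps <- unique(as.vector(counts))
  if (length(reps) != 1L) {
    stop("unbalanced design: unequal replicates per cell; rebalance or subset before the two-way ANOVA",
         call. = FALSE)
  }
  if (reps < 2L) {
    stop("need >= 2 replicates per cell", call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(nlevels(a), nlevels(b), reps),
               dimnames = list(levels(a), levels(b), NULL))
  ord <- order(as.integer(a), as.integer(b))
  arr[] <- aperm(array(y[ord], dim = c(reps, nlevels(b), nlevels(a))),
                 c(3, 2, 1))
  arr
}

# SS decomposition on a balanced [a, b, r] array.
anova_from_array <- function(arr) {
  na <- dim(arr)[1]; nb <- dim(arr)[2]; r <- dim(arr)[3]
  grand <- mean(arr)
  mean_a <- apply(arr, 1, mean)
  mean_b <- apply(arr, 2, mean)
  mean_ab <- apply(arr, c(1, 2), mean)
  ss_a <- nb * r * sum((mean_a - grand)^2)
  ss_b <- na * r * sum((mean_b - grand)^2)
  ss_ab <- r * sum((sweep(sweep(mean_ab, 1, mean_a), 2, mean_b) + grand)^2)
  ss_e <- sum(sweep(arr, c(1, 2), mean_ab)^2)
  ss_t <- sum((arr - grand)^2)
  df <- c(a = na - 1L, b = nb - 1L, ab = (na - 1L) * (nb - 1L),
          e = na * nb * (r - 1L))
  ms <- c(ss_a, ss_b, ss_ab, ss_e) / df
  f <- ms[1:3] / ms[4]
  p <- stats::pf(f, df[1:3], df[4], lower.tail = FALSE)
  list(ss = c(a = ss_a, b = ss_b, ab = ss_ab, e = ss_e, total = ss_t),
       df = df, ms = ms, f = f, p = p,
       mean_a = mean_a, mean_b = mean_b, grand = grand, r = r,
       na = na, nb = nb)
}

#' Balanced two-way ANOVA with replicates
#'
#' Decomposes the outcome variance into the two factor main effects, their
#' interaction, and the residual, for a balanced design with equal
#' replicates per cell (subjects serve as replicates). F statistics use
#' the residual mean square; if all cells are identical the tests are
#' reported as undefined (`NA` F and p).
#'
#' @param df Long data.frame holding one outcome slice.
#' @param response Name of the response column.
#' @param factor_a,factor_b Names of the two factor columns. Defaults
#'   `"speed"` and `"load"`.
#' @param alpha Significance level recorded in the table. Default 0.05.
#' @return A data.frame of class `anova_table` with rows `factor_a`,
#'   `factor_b`, `interaction`, `residual`, `total` and columns `source`,
#'   `ss`, `df`, `ms`, `f`, `p`, `significant`.
#' @export
two_way_anova <- function(df, response, factor_a = "speed",
                          factor_b = "load", alpha = 0.05) {
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found", col), call. = FALSE)
    }
  }
  arr <- balanced_array(df, response, factor_a, factor_b)
  dec <- anova_from_array(arr)
  degenerate <- dec$ss[["e"]] == 0 && dec$ss[["total"]] == 0
  f <- if (degenerate) rep(NA_real_, 3) else unname(dec$f)
  p <- if (degenerate) rep(NA_real_, 3) else unname(dec$p)
  out <- data.frame(
    source = c(factor_a, factor_b, "interaction", "residual", "total"),
    ss = unname(dec$ss),
    df = c(unname(dec$df), sum(dec$df)),
    ms = c(unname(dec$ms), NA_real_),
    f = c(f, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "alpha") <- alpha
  attr(out, "decomposition") <- dec
  class(out) <- c("anova_table", class(out))
  out
}

#' Post-hoc all-pairwise comparisons of marginal means
#'
#' Compares every pair of levels of one factor using the two-way ANOVA's
#' residual mean square and degrees of freedom. `method = "tukey"`
#' (default) uses the studentized-range distribution (Tukey HSD);
#' `"bonferroni"` multiplies pairwise t-test p-values by the number of
#' pairs.
#'
#' @param df Long data.frame holding one outcome slice.
#' @param response Response column name.
#' @param factor Factor to compare (`"speed"` or `"load"`, or any column).
#' @param other The second factor completing the two-way design.
#' @param method `"tukey"` or `"bonferroni"`.
#' @param alpha Significance level. Default 0.05.
#' @return A data.frame of class `comparison_set`: one row per level pair
#'   with `level_1`, `level_2`, `diff` (marginal mean difference),
#'   `p_raw` (unadjusted pairwise t), `p_adj`, `significant`.
#' @export
multiple_comparisons <- function(df, response, factor,
                                 other = setdiff(c("speed", "load"), factor)[1],
                                 method = c("tukey", "bonferroni"),
                                 alpha = 0.05) {
  method <- match.arg(method)
  lv <- unique(df[[factor]])
  if (length(lv) < 2L) {
    stop("`factor` must have >= 2 levels", call. = FALSE)
  }
  an <- two_way_anova(df, response, factor_a = factor, factor_b = other,
                      alpha = alpha)
  dec <- attr(an, "decomposition")
  ms_e <- dec$ms[4]
  df_e <- dec$df[["e"]]
  k <- dec$na
  n_marg <- dec$nb * dec$r          # observations per marginal level
  means <- dec$mean_a
  levels_sorted <- names(means)
  pairs <- utils::combn(seq_along(levels_sorted), 2)
  out <- data.frame(
    level_1 = levels_sorted[pairs[1, ]],
    level_2 = levels_sorted[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    stringsAsFactors = FALSE
  )
  se_t <- sqrt(2 * ms_e / n_marg)
  tstat <- abs(out$diff) / se_t
  out$p_raw <- 2 * stats::pt(tstat, df_e, lower.tail = FALSE)
  if (method == "tukey") {
    q <- abs(out$diff) / sqrt(ms_e / n_marg)
    out$p_adj <- stats::ptukey(q, nmeans = k, df = df_e,
                               lower.tail = FALSE)
  } else {
    out$p_adj <- pmin(1, out$p_raw * nrow(out))
  }
  out$p_adj <- pmax(out$p_adj, out$p_raw)   # adjusted never below raw
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_set", class(out))
  out
}

#' Monte-Carlo type-I error calibration of the two-way ANOVA
#'
#' Simulates balanced null outcome grids (i.i.d. normal cell values with
#' no speed or load effect) and reports the empirical rejection rate of
#' each source at the given level. Under a correct implementation each
#' rate lies in the binomial band around `alpha`.
#'
#' @param n_sims Number of simulated grids. Default 500.
#' @param n_subjects Replicates per cell. Default 15.
#' @param n_a,n_b Factor level counts. Default 7 and 7.
#' @param alpha Significance level. Default 0.05.
#' @param seed Integer seed.
#' @return Named numeric vector of rejection rates for `a`, `b`, `ab`.
#' @export
calibrate_anova_type1 <- function(n_sims = 500, n_subjects = 15,
                                  n_a = 7, n_b = 7, alpha = 0.05,
                                  seed = 1) {
  rej <- with_seed(seed, {
    counts <- c(a = 0L, b = 0L, ab = 0L)
    for (i in seq_len(n_sims)) {
      arr <- array(stats::rnorm(n_a * n_b * n_subjects),
                   dim = c(n_a, n_b, n_subjects))
      dec <- anova_from_array(arr)
      counts <- counts + (dec$p < alpha)
    }
    counts
  })
  rej / n_sims
}
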