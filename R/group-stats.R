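# Group-level inference: 2x2 mixed ANOVA, paired t-tests, Pearson
# correlations and repeated-measures power analysis.

#' Mixed 2x2 ANOVA (group between, time within)
#'
#' Classical sums-of-squares decomposition for one between-subjects factor
#' with two groups crossed with one within-subject factor with two levels,
#' computed through the exact average/difference-score decomposition:
#' the between stratum is a one-way ANOVA on subject averages, the within
#' stratum decomposes the per-subject change scores into time, time-by-group
#' interaction and within-subject error. All effects have df = (1, N - 2).
#' If an error stratum has (numerically) zero variance, an effect with zero
#' sum of squares gets F = 0, p = 1.
#'
#' @param data data.frame with columns \code{participant}, \code{group} (two
#'   levels), \code{time} (identifying the within levels, e.g. "pre"/"post"),
#'   and \code{value}; every participant must appear once per time.
#' @param time_order character of length 2 giving the (reference, second)
#'   time levels; the change score is second minus reference.
#' @return data.frame with rows for effects \code{group}, \code{time},
#'   \code{interaction}: columns effect, ss, F, df1, df2, p.
#' @export
mixed_anova_2x2 <- function(data, time_order = NULL) {
  need <- c("participant", "group", "time", "value")
  assert_that(all(need %in% names(data)),
              "data must have columns %s", paste(need, collapse = ", "))
  groups <- unique(as.character(data$group))
  times <- unique(as.character(data$time))
  assert_that(length(groups) == 2, "need exactly 2 groups, got %d",
              length(groups))
  assert_that(length(times) == 2, "need exactly 2 time points, got %d",
              length(times))
  if (is.null(time_order)) time_order <- sort(times)
  assert_that(all(sort(time_order) == sort(times)), "time_order mismatch")
  wide <- stats::reshape(
    data[, need], direction = "wide", idvar = c("participant", "group"),
    timevar = "time", v.names = "value"
  )
  v1 <- wide[[paste0("value.", time_order[1])]]
  v2 <- wide[[paste0("value.", time_order[2])]]
  assert_that(!anyNA(v1) && !anyNA(v2), "incomplete pre/post cells")
  grp <- as.character(wide$group)
  n_g <- table(grp)
  assert_that(all(n_g >= 2), "need >= 2 participants per group")
  n <- length(v1)

  avg <- (v1 + v2) / 2
  dif <- v2 - v1
  g_mean_a <- tapply(avg, grp, mean)
  g_mean_d <- tapply(dif, grp, mean)
  grand_a <- mean(avg)
  grand_d <- mean(dif)

  # between stratum (factor m = 2 measurements restores the original scale)
  ss_group <- 2 * sum(n_g * (g_mean_a - grand_a)^2)
  ss_berr <- 2 * sum((avg - g_mean_a[grp])^2)
  # within stratum
  ss_time <- n * grand_d^2 / 2
  ss_int <- sum(n_g * (g_mean_d - grand_d)^2) / 2
  ss_werr <- sum((dif - g_mean_d[grp])^2) / 2

  f_and_p <- function(ss_eff, ss_err) {
    ms_err <- ss_err / (n - 2)
    scale <- max(ss_eff, ss_err, 1e-300)
    if (ms_err <= 1e-12 * scale) {
      if (ss_eff <= 1e-12 * scale) return(c(0, 1))
      return(c(Inf, 0))
    }
    f <- ss_eff / ms_err
    c(f, stats::pf(f, 1, n - 2, lower.tail = FALSE))
  }
  rg <- f_and_p(ss_group, ss_berr)
  rt <- f_and_p(ss_time, ss_werr)
  ri <- f_and_p(ss_int, ss_werr)
  data.frame(
    effect = c("group", "time", "interaction"),
    ss = c(ss_group, ss_time, ss_int),
    F = c(rg[1], rt[1], ri[1]),
    df1 = 1L, df2 = n - 2L,
    p = c(rg[2], rt[2], ri[2])
  )
}

#' Paired-samples t-test
#'
#' Classic paired t on post - pre differences, two-sided, df = n - 1.
#'
#' @param pre,post numeric vectors of equal length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_diff}.
#' @export
paired_t <- function(pre, post) {
  assert_that(length(pre) == length(post) && length(pre) >= 2,
              "pre/post must have equal length >= 2")
  d <- post - pre
  assert_that(stats::sd(d) > 0, "zero variance of paired differences")
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with \code{r}, \code{df}, \code{p}, \code{n}.
#' @export
pearson_cor <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x/y must have equal length >= 3")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in x or y")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), df = unname(ht$parameter),
       p = ht$p.value, n = length(x))
}

#' Welch two-sample t-test for baseline group comparisons
#'
#' @param x,y numeric vectors (one per group).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
baseline_welch_t <- function(x, y) {
  ht <- stats::t.test(x, y)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Power of the within-between interaction in a repeated-measures ANOVA
#'
#' Noncentral-F power under the G*Power convention for a design with
#' \code{n_groups} between groups and \code{n_measurements} repeated
#' measurements: noncentrality
#' \deqn{\lambda = f^2 N m \epsilon / (1 - \rho)}
#' with numerator df \eqn{(g-1)(m-1)\epsilon} and denominator df
#' \eqn{(N-g)(m-1)\epsilon}.
#'
#' @param n_total total sample size N (> n_groups).
#' @param f Cohen's f effect size.
#' @param alpha significance level.
#' @param n_groups number of groups g (default 2).
#' @param n_measurements number of repeated measurements m (default 2).
#' @param rho repeated-measures correlation (default 0.5).
#' @param eps nonsphericity correction (default 1).
#' @return achieved power (probability).
#' @export
rm_interaction_power <- function(n_total, f, alpha = 0.05, n_groups = 2,
                                 n_measurements = 2, rho = 0.5, eps = 1) {
  assert_that(f > 0, "effect size f must be positive")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  assert_that(rho >= 0 && rho < 1, "rho must lie in [0, 1)")
  assert_that(n_total > n_groups, "N must exceed the number of groups")
  df1 <- (n_groups - 1) * (n_measurements - 1) * eps
  df2 <- (n_total - n_groups) * (n_measurements - 1) * eps
  lambda <- f^2 * n_total * n_measurements * eps / (1 - rho)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Required sample size for the repeated-measures interaction
#'
#' Smallest total N, balanced across groups, whose interaction power reaches
#' \code{power_target} under \code{\link{rm_interaction_power}}.
#'
#' @param f Cohen's f effect size (0.21 is the conventional medium effect for
#'   this design).
#' @param alpha significance level (default 0.05).
#' @param power_target target power (default 0.80).
#' @param n_groups,n_measurements design size (defaults 2 and 2).
#' @param rho repeated-measures correlation (default 0.5).
#' @param eps nonsphericity correction (default 1).
#' @param n_max search ceiling.
#' @return list with \code{n_total}, \code{n_per_group},
#'   \code{achieved_power}.
#' @export
required_sample_size <- function(f = 0.21, alpha = 0.05, power_target = 0.80,
                                 n_groups = 2, n_measurements = 2, rho = 0.5,
                                 eps = 1, n_max = 100000) {
  assert_that(f > 0, "unattainable power: effect size f must be positive")
  assert_that(power_target > 0 && power_target < 1,
              "power target must lie in (0, 1)")
  n <- 2L * n_groups
  repeat {
    pw <- rm_interaction_power(n, f, alpha, n_groups, n_measurements, rho, eps)
    if (pw >= power_target) {
      return(list(n_total = n, n_per_group = n %/% n_groups,
                  achieved_power = pw))
    }
    n <- n + n_groups
    if (n > n_max) stopf("no N <= %d reaches power %.2f", n_max, power_target)
  }
}
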