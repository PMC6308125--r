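make_panel <- function(pre_a, post_a, pre_b, post_b,
                       groups = c("dance", "active")) {
  na <- length(pre_a); nb <- length(pre_b)
  ids <- sprintf("s%02d", seq_len(na + nb))
  data.frame(
    participant = rep(ids, 2),
    group = rep(rep(groups, c(na, nb)), 2),
    time = rep(c("pre", "post"), each = na + nb),
    value = c(pre_a, pre_b, post_a, post_b)
  )
}

test_that("mixed ANOVA matches a hand-worked sums-of-squares table", {
  # 4 per group, hand-checkable numbers
  panel <- make_panel(pre_a = c(10, 12, 11, 13), post_a = c(14, 15, 13, 16),
                      pre_b = c(11, 10, 12, 12), post_b = c(11, 11, 13, 12))
  out <- mixed_anova_2x2(panel, time_order = c("pre", "post"))

  # independent arithmetic: averages and differences per subject
  avg <- c(12, 13.5, 12, 14.5, 11, 10.5, 12.5, 12)
  dif <- c(4, 3, 2, 3, 0, 1, 1, 0)
  grp <- rep(c("dance", "active"), each = 4)
  ss_group <- 2 * sum(4 * (tapply(avg, grp, mean) - mean(avg))^2)
  ss_berr <- 2 * sum((avg - tapply(avg, grp, mean)[grp])^2)
  ss_time <- 8 * mean(dif)^2 / 2
  ss_int <- sum(4 * (tapply(dif, grp, mean) - mean(dif))^2) / 2
  ss_werr <- sum((dif - tapply(dif, grp, mean)[grp])^2) / 2
  expect_equal(out$F[out$effect == "group"], (ss_group) / (ss_berr / 6))
  expect_equal(out$F[out$effect == "time"], ss_time / (ss_werr / 6))
  expect_equal(out$F[out$effect == "interaction"], ss_int / (ss_werr / 6))
  expect_equal(out$df2, rep(6L, 3))

  # total sum of squares decomposes exactly
  ss_total <- sum((panel$value - mean(panel$value))^2)
  expect_equal(ss_total, ss_group + ss_berr + ss_time + ss_int + ss_werr)
})

test_that("mixed ANOVA agrees with aov() on random balanced designs", {
  set.seed(61)
  for (i in 1:5) {
    n <- sample(c(4, 6, 10), 1)
    panel <- make_panel(rnorm(n), rnorm(n, 0.5), rnorm(n), rnorm(n))
    out <- mixed_anova_2x2(panel, time_order = c("pre", "post"))
    panel$group <- factor(panel$group)
    panel$time <- factor(panel$time, levels = c("pre", "post"))
    fit <- summary(stats::aov(value ~ group * time +
                                Error(participant / time), data = panel))
    btab <- fit[["Error: participant"]][[1]]
    wtab <- fit[["Error: participant:time"]][[1]]
    expect_equal(out$F[out$effect == "group"], btab["group", "F value"],
                 tolerance = 1e-10)
    expect_equal(out$F[out$effect == "time"], wtab["time", "F value"],
                 tolerance = 1e-10)
    expect_equal(out$F[out$effect == "interaction"],
                 wtab["group:time", "F value"], tolerance = 1e-10)
    expect_equal(out$p[out$effect == "interaction"],
                 wtab["group:time", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("mixed ANOVA symmetry and degenerate cases", {
  panel <- make_panel(c(1, 2, 3), c(2, 4, 5), c(0, 1, 2), c(1, 1, 2))
  out <- mixed_anova_2x2(panel, time_order = c("pre", "post"))
  swapped <- panel
  swapped$group <- ifelse(panel$group == "dance", "active", "dance")
  out2 <- mixed_anova_2x2(swapped, time_order = c("pre", "post"))
  expect_equal(out$F[out$effect == "interaction"],
               out2$F[out2$effect == "interaction"])

  flat <- make_panel(rep(5, 3), rep(5, 3), rep(5, 3), rep(5, 3))
  outf <- mixed_anova_2x2(flat)
  expect_equal(outf$F, rep(0, 3))
  expect_equal(outf$p, rep(1, 3))

  expect_error(mixed_anova_2x2(make_panel(1, 2, 3, 4)), ">= 2 participants")
})

test_that("paired t and Pearson match their closed forms", {
  pt <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(pt$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(pt$df, 2)
  pt2 <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(pt2$t, -pt$t)
  expect_equal(pt2$p, pt$p)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")

  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  set.seed(62)
  a <- rnorm(50); b <- a + rnorm(50)
  expect_equal(pearson_cor(a, b)$r, cor(a, b))
  expect_equal(pearson_cor(-a, b)$r, -cor(a, b))
  expect_equal(pearson_cor(-a, b)$p, pearson_cor(a, b)$p)
  set.seed(63)
  expect_lt(abs(pearson_cor(rnorm(1000), rnorm(1000))$r), 0.1)
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("power analysis is monotone and minimal at the returned N", {
  res <- required_sample_size(f = 0.21, alpha = 0.05, power_target = 0.80,
                              n_groups = 2, n_measurements = 2, rho = 0.5,
                              eps = 1)
  expect_equal(res$n_total %% 2, 0)
  expect_gte(res$achieved_power, 0.80)
  expect_lt(rm_interaction_power(res$n_total - 2, 0.21), 0.80)

  # doubling the effect size strictly shrinks the requirement
  res2 <- required_sample_size(f = 0.42)
  expect_lt(res2$n_total, res$n_total)

  # power grows with N and with f
  ns <- seq(8, 80, by = 4)
  pw <- vapply(ns, rm_interaction_power, numeric(1), f = 0.21)
  expect_true(all(diff(pw) > 0))
  fs <- seq(0.1, 0.5, by = 0.05)
  pf_ <- vapply(fs, function(f) rm_interaction_power(40, f), numeric(1))
  expect_true(all(diff(pf_) > 0))

  expect_error(required_sample_size(f = 0), "positive")
})
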