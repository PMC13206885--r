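test_that("mortality rate is dead over n with guarded inputs", {
  expect_equal(mortality_rate(25, 25), 1)
  expect_equal(mortality_rate(0, 25), 0)
  expect_equal(mortality_rate(17, 25), 0.68)
  expect_error(mortality_rate(1, 0), "positive")
  expect_error(mortality_rate(26, 25), "\\[0, n\\]")
})

test_that("Abbott's correction matches the formula, clamps, and is monotone", {
  for (T in c(0, 0.25, 0.68, 1)) {
    expect_equal(abbott_correction(T, 0), T)
  }
  expect_equal(abbott_correction(0.5, 0.2), 0.375)
  expect_equal(abbott_correction(0.1, 0.2), 0)   # floored
  expect_error(abbott_correction(0.5, 1), "degenerate control")

  # monotone in treatment mortality, bounded in [0, 1]
  for (C in c(0, 0.1, 0.3, 0.6)) {
    Ts <- seq(0, 1, by = 0.05)
    out <- abbott_correction(Ts, C)
    expect_true(all(diff(out) >= 0))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("control correction of interval counts preserves structure", {
  tab <- bioassay_table(rbind(
    series_table(c(3, 8, 12), dose = 1e5),
    series_table(c(6, 13, 20), dose = 1e7),
    series_table(c(0, 0, 0), dose = 0)))
  iv <- to_interval_data(tab)

  # zero-deaths control leaves treated counts untouched
  corr <- corrected_interval_counts(iv)
  treated <- iv[iv$dose > 0, ]
  expect_equal(corr$deaths, treated$deaths)
  expect_equal(corr$at_risk, treated$at_risk)

  # single-day worked example: T = 0.5, C = 0.2, n = 25 -> 9.375 deaths
  one <- structure(data.frame(dose = c(0, 1e6), day = 1,
                              at_risk = c(25, 25), deaths = c(5, 12.5),
                              log10_dose = c(-Inf, 6)),
                   class = c("interval_data", "data.frame"))
  corr1 <- corrected_interval_counts(one)
  expect_equal(corr1$deaths, 9.375)

  # corrected cumulative total is conserved exactly on re-accumulation
  ctrl <- bioassay_table(rbind(series_table(c(1, 2, 3), dose = 0),
                               series_table(c(4, 9, 15), dose = 1e6),
                               series_table(c(2, 5, 9), dose = 1e4)))
  ivc <- to_interval_data(ctrl)
  corr2 <- corrected_interval_counts(ivc)
  for (d in unique(corr2$dose)) {
    s <- corr2[corr2$dose == d, ]
    s <- s[order(s$day), ]
    n0 <- s$at_risk[1]
    raw <- ivc[ivc$dose == d, ]
    p_raw <- cumsum(raw$deaths[order(raw$day)]) / n0
    p_ctl <- cumsum(ivc$deaths[ivc$dose == 0]) / 25
    expected_final <- abbott_correction(p_raw[3], p_ctl[3]) * n0
    expect_equal(sum(s$deaths), expected_final, tolerance = 1e-12)
    expect_true(all(s$deaths >= 0))
    expect_true(all(s$at_risk >= s$deaths))
  }
  expect_error(
    corrected_interval_counts(one,
      control = structure(data.frame(dose = 0, day = 1, at_risk = 25,
                                     deaths = 25, log10_dose = -Inf),
                          class = c("interval_data", "data.frame"))),
    "degenerate control")
})

test_that("correction recovers the pathogen-only mortality under a known control hazard", {
  # paired large-n assays with and without natural mortality: after Abbott
  # correction the hazard-contaminated assay should match the clean one
  n <- 20000L
  pars <- larvae_ref
  base <- simulation_config(beta = pars$beta, gamma = pars$gamma,
                            doses = c(1e6, 1e8), n_per_replicate = n,
                            replicates = 1L, control_daily_hazard = 0)
  noisy <- simulation_config(beta = pars$beta, gamma = pars$gamma,
                             doses = c(1e6, 1e8), n_per_replicate = n,
                             replicates = 1L, control_daily_hazard = 0.02)
  clean <- to_interval_data(simulate_assay(base, seed = 5))
  contaminated <- to_interval_data(simulate_assay(noisy, seed = 6))
  corr <- corrected_interval_counts(contaminated)
  for (d in c(1e6, 1e8)) {
    p_clean <- cumsum(clean$deaths[clean$dose == d]) / n
    p_corr <- cumsum(corr$deaths[corr$dose == d]) / n
    # Monte-Carlo tolerance: ~3 binomial SDs at n = 20000
    expect_true(all(abs(p_clean - p_corr) < 3.5 * sqrt(0.25 / n) + 0.004))
  }
})

test_that("stage ANOVA separates distinct groups and matches a direct F computation", {
  groups <- list(larvae = c(0.9, 0.95, 0.94), eggs = c(0.2, 0.21, 0.19))
  res <- stage_anova(groups)
  expect_lt(res$p, 0.01)
  expect_false(res$letters[["larvae"]] == res$letters[["eggs"]])

  # independent oracle: one-way F from its definition
  y <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  F_direct <- (ssb / 1) / (ssw / 4)
  expect_equal(res$F, F_direct, tolerance = 1e-10)

  # equal group means with within-group noise: F near zero
  same <- list(a = c(0.5, 0.6, 0.7), b = c(0.6, 0.5, 0.7),
               c = c(0.7, 0.6, 0.5))
  expect_lt(stage_anova(same)$F, 1e-10)

  expect_error(stage_anova(list(a = 1:3)), "two groups")
  expect_error(stage_anova(list(a = 1, b = 2)), "two replicates")
})

test_that("stage ANOVA holds its nominal type-I error on null data", {
  set.seed(2024)
  rejections <- 0L
  n_sim <- 1000L
  for (i in seq_len(n_sim)) {
    groups <- list(a = rnorm(3, 0.5, 0.05), b = rnorm(3, 0.5, 0.05),
                   c = rnorm(3, 0.5, 0.05))
    if (stage_anova(groups)$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  mc_sd <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), 3 * mc_sd)
})
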