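test_that("conditional and cumulative cloglog probabilities evaluate correctly", {
  # predictor at ln(ln 2) gives the median
  expect_equal(conditional_probability(log(log(2)), 0, 0), 0.5)
  expect_equal(cumulative_probability(log(log(2)), 0, 0), 0.5)

  # vanishing hazard
  expect_lt(conditional_probability(-50, 0.748, 8), 1e-15)

  # direct evaluation at the published larval day-5 effect, top dose
  expect_equal(conditional_probability(-5.908, 0.748, 8), 0.6600,
               tolerance = 1e-4)
  # published larval day-7 cumulative parameters, top dose
  expect_equal(cumulative_probability(-4.781, 0.748, 8), 0.96421,
               tolerance = 5e-5)
})

test_that("cumulative mortality equals the complement of the conditional survival product", {
  set.seed(41)
  for (i in 1:20) {
    gamma <- sort(rnorm(7, -6, 2))[sample(7)]
    beta <- runif(1, 0.2, 1.5)
    x <- runif(1, 3, 8)
    tau <- accumulate_tau(gamma)
    q <- conditional_probability(gamma, beta, x)
    P <- cumulative_probability(tau, beta, x)
    expect_equal(P, 1 - cumprod(1 - q), tolerance = 1e-12)
    # increasing in day and in dose when beta > 0
    expect_true(all(diff(P) >= 0))
    unsaturated <- P < 1 - 1e-12
    expect_true(all(cumulative_probability(tau, beta, x + 0.5)[unsaturated] >
                      P[unsaturated]))
  }
})

test_that("log-sum-exp accumulation reproduces the published cumulative effects", {
  expect_equal(accumulate_tau(larvae_ref$gamma), larvae_ref$tau,
               tolerance = 0.001)
  expect_equal(accumulate_tau(pupae_ref$gamma), pupae_ref$tau,
               tolerance = 0.001)
  # a single interval accumulates to itself
  expect_equal(accumulate_tau(-8.412), -8.412)
  # overflow-safe for large inputs
  expect_equal(accumulate_tau(c(700, 700)), c(700, 700 + log(2)))
  # -Inf (zero hazard) contributes nothing
  expect_equal(accumulate_tau(c(-Inf, -5)), c(-Inf, -5))
  # nondecreasing for arbitrary inputs
  set.seed(7)
  for (i in 1:20) {
    expect_true(all(diff(accumulate_tau(rnorm(10, -5, 3))) >= 0))
  }
  expect_error(accumulate_tau(numeric(0)), "at least one")
})

test_that("the fitter maximises the likelihood (score zero, beats truth and init)", {
  suppressMessages({
    cfg <- simulation_config(beta = 0.748, gamma = larvae_ref$gamma,
                             n_per_replicate = 200L, replicates = 1L,
                             control_daily_hazard = 0)
    data <- to_interval_data(simulate_assay(cfg, seed = 3))
    fit <- fit_tcm(data)
  })
  treated <- data[data$dose > 0, ]
  # log-likelihood at the optimum beats the generating truth
  expect_gte(fit$loglik, loglik_direct(0.748, larvae_ref$gamma, treated))
  # matches a direct evaluation of the likelihood at the fitted values
  expect_equal(fit$loglik, loglik_direct(fit$beta, fit$gamma, treated),
               tolerance = 1e-8)
  # score is numerically zero at the optimum for the active parameters
  active <- setdiff(seq_len(fit$J), fit$degenerate)
  grad <- tcmfit:::tcm_negloglik_grad(
    c(fit$beta, fit$gamma[active]), x = treated$log10_dose,
    day_idx = as.integer(treated$day), s = treated$at_risk,
    d = treated$deaths, gamma_full = fit$gamma, active = active)
  expect_lt(max(abs(grad)), 1e-3)
})

test_that("the fitter recovers generating parameters at large n", {
  cfg <- simulation_config(beta = 0.748, gamma = larvae_ref$gamma,
                           n_per_replicate = 2000L, replicates = 1L,
                           control_daily_hazard = 0)
  fit <- suppressMessages(fit_tcm(to_interval_data(simulate_assay(cfg, seed = 17))))
  expect_lt(abs(fit$beta - 0.748), 0.05)
  # day 6 is generated at the hazard floor, so it should be degenerate
  expect_true(6 %in% fit$degenerate)
  expect_equal(fit$gamma[6], -18.8)
  active <- setdiff(1:7, fit$degenerate)
  expect_lt(max(abs(fit$gamma[active] - larvae_ref$gamma[active])), 0.5)
  # delta-method variances present and positive on active days
  expect_true(all(fit$var_tau[active] > 0))
  expect_true(all(is.finite(fit$cov_tau_beta)))
})

test_that("degenerate designs are rejected with clear errors", {
  one_dose <- to_interval_data(bioassay_table(series_table(c(2, 5, 9))))
  expect_error(fit_tcm(one_dose), "two distinct positive doses")

  all_dead <- to_interval_data(bioassay_table(rbind(
    series_table(c(25, 25), dose = 1e6),
    series_table(c(25, 25), dose = 1e8))))
  expect_error(fit_tcm(all_dead), "complete separation")

  no_deaths <- to_interval_data(bioassay_table(rbind(
    series_table(c(0, 0), dose = 1e6),
    series_table(c(0, 0), dose = 1e8))))
  expect_error(fit_tcm(no_deaths), "no deaths")
})

test_that("t statistics are estimate over SE with degenerate days masked", {
  expect_equal(abs(-8.412 / 0.440), 19.118, tolerance = 1e-3)

  pars <- tcm_parameters(beta = 0.748, se_beta = 0.046,
                         gamma = c(-8.412, -18.8),
                         se_gamma = c(0.440, NA), degenerate = 2L)
  ts <- parameter_t_stats(pars)
  expect_equal(unname(ts["gamma1"]), -8.412 / 0.440)
  expect_true(is.na(ts["gamma2"]))
  expect_equal(unname(ts["beta"]), 0.748 / 0.046)

  zero <- tcm_parameters(beta = 0, se_beta = 1, gamma = -5, se_gamma = 2)
  expect_equal(unname(parameter_t_stats(zero)["beta"]), 0)
})
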