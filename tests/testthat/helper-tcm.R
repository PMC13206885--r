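# shared fixtures: small tables built in code, published parameter sets

larvae_ref <- stage_parameters("larvae")
pupae_ref <- stage_parameters("pupae")

# one dose series as a raw table
series_table <- function(dead_cum, dose = 1e6, n = 25, replicate = 1) {
  data.frame(dose = dose, replicate = replicate,
             day = seq_along(dead_cum), n = n, dead = dead_cum)
}

# two-dose, two-day toy dataset used by the brute-force likelihood oracle
toy_interval_data <- function() {
  tab <- bioassay_table(rbind(
    series_table(c(2, 5), dose = 1e4, n = 10),
    series_table(c(4, 8), dose = 1e6, n = 10)))
  to_interval_data(tab)
}

# conditional cloglog log-likelihood of interval data, written directly
# from the model definition (independent of the fitter's internals)
loglik_direct <- function(beta, gamma, data) {
  eta <- gamma[data$day] + beta * data$log10_dose
  q <- 1 - exp(-exp(eta))
  sum(data$deaths * log(q) + (data$at_risk - data$deaths) * (-exp(eta)))
}
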