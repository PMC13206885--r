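#' Simulation configuration for a synthetic bioassay
#'
#' Describes a replicated cohort bioassay generated from the TCM model: a
#' serial dose range, cohorts of fixed size, and daily observation of
#' deaths, with an independent natural-mortality hazard that acts on
#' treated and control cohorts alike. The defaults mirror a standard
#' entomopathogenic-fungus virulence assay: six serial concentrations
#' (10^3 to 10^8 conidia/mL) plus an untreated control, cohorts of 25
#' insects, three replicates, and seven daily observations.
#'
#' @param beta Dose slope on log10 dose.
#' @param gamma Conditional time effects, one per observation day.
#' @param doses Positive treatment doses in conidia/mL.
#' @param n_per_replicate Cohort size per replicate.
#' @param replicates Number of replicates per dose (and for the control).
#' @param control_daily_hazard Daily probability of natural death, applied
#'   independently of the fungal hazard (default 0.005).
#' @param seed Optional integer seed stored with the configuration.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(beta, gamma, doses = 10^(3:8),
                              n_per_replicate = 25L, replicates = 3L,
                              control_daily_hazard = 0.005, seed = NULL) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(gamma), length(gamma) >= 1L, all(is.finite(gamma)))
  if (any(doses <= 0) || anyDuplicated(doses)) {
    stop("doses must be positive and distinct", call. = FALSE)
  }
  if (n_per_replicate < 1L || n_per_replicate != round(n_per_replicate)) {
    stop("n_per_replicate must be a positive integer", call. = FALSE)
  }
  if (replicates < 1L || replicates != round(replicates)) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  if (control_daily_hazard < 0 || control_daily_hazard >= 1) {
    stop("control_daily_hazard must be in [0, 1)", call. = FALSE)
  }
  structure(list(beta = beta, gamma = gamma, doses = sort(doses),
                 n_per_replicate = as.integer(n_per_replicate),
                 replicates = as.integer(replicates),
                 control_daily_hazard = control_daily_hazard,
                 days = length(gamma), seed = seed),
            class = "simulation_config")
}

#' Simulate a replicated cohort bioassay
#'
#' For each replicate and dose, survivors transition daily: an insect alive
#' at the start of day j dies during that day with probability
#' `1 - (1 - q_j)(1 - h)`, where `q_j` is the conditional TCM probability
#' at that dose and `h` the natural daily hazard. The control cohort
#' (dose 0) is exposed to `h` only. The two risks compose multiplicatively
#' on survival (independent competing risks), which is the regime in which
#' Abbott's correction is the approximately correct de-confounder.
#'
#' Reproducibility: one top-level seed; each (dose, replicate) cohort draws
#' from its own stream seeded deterministically from it.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [bioassay_table()] including the control series.
#' @export
simulate_assay <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  all_doses <- c(0, config$doses)
  n_streams <- length(all_doses) * config$replicates
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stream_seeds <- sample.int(.Machine$integer.max, n_streams)

  h <- config$control_daily_hazard
  rows <- vector("list", n_streams)
  k <- 0L
  for (dose in all_doses) {
    q <- if (dose > 0) {
      conditional_probability(config$gamma, config$beta, log10(dose))
    } else {
      rep(0, config$days)
    }
    p_die <- 1 - (1 - q) * (1 - h)
    for (r in seq_len(config$replicates)) {
      k <- k + 1L
      set.seed(stream_seeds[k])
      alive <- config$n_per_replicate
      dead_cum <- numeric(config$days)
      total <- 0
      for (j in seq_len(config$days)) {
        deaths <- stats::rbinom(1L, alive, p_die[j])
        total <- total + deaths
        alive <- alive - deaths
        dead_cum[j] <- total
      }
      rows[[k]] <- data.frame(dose = dose, replicate = r,
                              day = seq_len(config$days),
                              n = config$n_per_replicate, dead = dead_cum)
    }
  }
  bioassay_table(do.call(rbind, rows))
}

# Published TCM parameter sets for Metarhizium robertsii ML-2 against
# Phthorimaea operculella, transcribed at 3-decimal precision. gamma and
# tau were each rounded independently at the source, so both are stored.
.reference_params <- list(
  larvae = list(
    beta = 0.748, se_beta = 0.046,
    gamma = c(-8.412, -7.084, -5.778, -6.915, -5.908, -18.800, -7.562),
    se_gamma = c(0.440, 0.364, 0.328, 0.389, 0.314, NA, 1.887),
    tau = c(-8.412, -6.849, -5.483, -5.269, -4.845, -4.845, -4.781),
    var_tau = c(0.329, 0.216, 0.181, 0.179, 0.161, 0.161, 0.165),
    cov_tau_beta = c(-0.026, -0.025, -0.024, -0.024, -0.023, -0.023,
                     -0.015),
    degenerate = 6L
  ),
  pupae = list(
    beta = 0.538, se_beta = 0.060,
    gamma = c(-9.236, -5.500, -4.846, -5.133, -4.919, -6.033, -16.290),
    se_gamma = c(1.206, 0.443, 0.432, 0.422, 0.374, 0.481, NA),
    tau = c(-9.236, -5.477, -4.419, -4.020, -3.679, -3.588, -3.588),
    var_tau = c(2.731, 0.367, 0.337, 0.315, 0.279, 0.272, 0.272),
    cov_tau_beta = c(-0.044, -0.046, -0.046, -0.045, -0.042, -0.042,
                     -0.042),
    degenerate = 7L
  )
)

#' Published reference parameters by insect stage
#'
#' Returns the fitted TCM parameter set reported for *Metarhizium
#' robertsii* strain ML-2 against 3-day-old *Phthorimaea operculella*
#' larvae or 1-day-old pupae (values transcribed at their published
#' 3-decimal precision; the gamma of a day with no deaths is the sentinel
#' floor the original software printed). These sets drive the worked
#' examples and serve as generating truth for the synthetic assays.
#'
#' @param stage `"larvae"` or `"pupae"`.
#' @return A [tcm_parameters()] object.
#' @export
stage_parameters <- function(stage = c("larvae", "pupae")) {
  if (!is.character(stage) || !stage[1L] %in% names(.reference_params)) {
    stop("unknown stage '", stage[1L],
         "'; available stages: ", paste(names(.reference_params),
                                        collapse = ", "),
         " (no model was fitted for eggs)", call. = FALSE)
  }
  p <- .reference_params[[stage[1L]]]
  tcm_parameters(beta = p$beta, gamma = p$gamma, se_beta = p$se_beta,
                 se_gamma = p$se_gamma, var_tau = p$var_tau,
                 cov_tau_beta = p$cov_tau_beta, tau = p$tau,
                 degenerate = p$degenerate, label = stage[1L])
}

#' Reference simulation scenario by insect stage
#'
#' A [simulation_config()] pre-loaded with the published stage parameters
#' ([stage_parameters()]) and the reference assay design: doses 10^3 to
#' 10^8 conidia/mL by decades, 25 insects per replicate, 3 replicates,
#' 7 daily observations.
#'
#' @param stage `"larvae"` or `"pupae"`.
#' @param control_daily_hazard Natural daily hazard (default 0.005).
#' @param seed Optional seed stored in the config.
#' @return A `simulation_config`.
#' @export
stage_scenario <- function(stage = c("larvae", "pupae"),
                           control_daily_hazard = 0.005, seed = NULL) {
  p <- stage_parameters(stage)
  simulation_config(beta = p$beta, gamma = p$gamma,
                    doses = 10^(3:8), n_per_replicate = 25L,
                    replicates = 3L,
                    control_daily_hazard = control_daily_hazard,
                    seed = seed)
}
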