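#' Time-concentration-mortality parameter set
#'
#' Container for the parameters of the TCM model. The conditional model says
#' that an insect alive at the start of day j, exposed to dose with log10
#' value x, dies during day j with probability
#' \deqn{q_j(x) = 1 - \exp(-\exp(\gamma_j + \beta x)),}
#' a complementary log-log (cloglog) binomial model with one shared dose
#' slope \eqn{\beta} and per-day intercepts \eqn{\gamma_j}. Because the
#' per-day hazards add on the exp scale, cumulative mortality by day j has
#' the same form with intercept
#' \eqn{\tau_j = \log \sum_{k \le j} \exp(\gamma_k)} (see
#' [accumulate_tau()]).
#'
#' @param beta Dose-effect slope on log10 dose.
#' @param gamma Numeric vector of conditional time effects, one per day.
#' @param se_beta,se_gamma Standard errors (NA for degenerate days).
#' @param var_tau Delta-method variances of the cumulative time effects.
#' @param cov_tau_beta Delta-method covariances Cov(tau_j, beta).
#' @param loglik Maximised log-likelihood (NA for externally supplied sets).
#' @param degenerate Integer indices of days whose gamma was fixed at the
#'   floor because no deaths occurred on that day at any dose.
#' @param tau Cumulative time effects; computed from `gamma` when omitted.
#'   Supplying `tau` directly supports parameter sets transcribed from
#'   published tables, where gamma and tau are each rounded independently.
#' @param label Optional free-text label (e.g. the insect stage).
#' @return An object of class `tcm_parameters`.
#' @export
tcm_parameters <- function(beta, gamma, se_beta = NA_real_,
                           se_gamma = rep(NA_real_, length(gamma)),
                           var_tau = rep(NA_real_, length(gamma)),
                           cov_tau_beta = rep(NA_real_, length(gamma)),
                           loglik = NA_real_, degenerate = integer(0),
                           tau = NULL, label = NA_character_) {
  stopifnot(is.numeric(beta), length(beta) == 1L,
            is.numeric(gamma), length(gamma) >= 1L)
  if (is.null(tau)) tau <- accumulate_tau(gamma)
  if (length(tau) != length(gamma)) {
    stop("gamma and tau must have the same length", call. = FALSE)
  }
  structure(list(beta = beta, gamma = gamma, tau = tau,
                 se_beta = se_beta, se_gamma = se_gamma,
                 var_tau = var_tau, cov_tau_beta = cov_tau_beta,
                 loglik = loglik, degenerate = as.integer(degenerate),
                 J = length(gamma), label = label),
            class = "tcm_parameters")
}

#' @export
print.tcm_parameters <- function(x, ...) {
  cat("Time-concentration-mortality parameters",
      if (!is.na(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  beta (log10-dose slope): %.4f (SE %.4f)\n",
              x$beta, x$se_beta))
  tab <- data.frame(day = seq_len(x$J), gamma = x$gamma,
                    se_gamma = x$se_gamma, tau = x$tau,
                    var_tau = x$var_tau, cov_tau_beta = x$cov_tau_beta)
  if (length(x$degenerate)) {
    tab$se_gamma[x$degenerate] <- NA_real_
    cat("  degenerate days (gamma at floor):",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  print(tab, row.names = FALSE, digits = 4)
  if (!is.na(x$loglik)) cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

# cloglog inverse, accurate for small and large eta
cloglog_inv <- function(eta) -expm1(-exp(eta))

#' Conditional daily mortality probability
#'
#' Probability that an insect alive at the start of day j dies during day j,
#' under the conditional cloglog model `q = 1 - exp(-exp(gamma_j + beta*x))`.
#'
#' @param gamma_j Conditional time effect for the day.
#' @param beta Dose slope.
#' @param log10_dose Base-10 log of the dose in conidia/mL.
#' @return Probability in (0, 1); vectorized over any argument.
#' @export
#' @examples
#' conditional_probability(log(log(2)), 0, 0)  # 0.5 at the cloglog median
conditional_probability <- function(gamma_j, beta, log10_dose) {
  cloglog_inv(gamma_j + beta * log10_dose)
}

#' Cumulative mortality probability
#'
#' Probability of death by the end of day j, using the cumulative intercept
#' tau_j: `P = 1 - exp(-exp(tau_j + beta*x))`. Identical to
#' `1 - prod(1 - q_k)` over the conditional probabilities for days k <= j.
#'
#' @param tau_j Cumulative time effect for the day.
#' @inheritParams conditional_probability
#' @return Probability in (0, 1); vectorized.
#' @export
cumulative_probability <- function(tau_j, beta, log10_dose) {
  cloglog_inv(tau_j + beta * log10_dose)
}

#' Accumulate conditional time effects into cumulative time effects
#'
#' Computes `tau_j = log(sum_{k<=j} exp(gamma_k))` with an overflow-safe
#' log-sum-exp, so cumulative mortality inherits the cloglog form of the
#' conditional model. Degenerate gammas at a very negative floor contribute
#' hazard exp(gamma) ~ 0, as intended. The output is nondecreasing.
#'
#' @param gamma Numeric vector of conditional time effects (finite; `-Inf`
#'   allowed for truly zero-hazard days).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' accumulate_tau(c(-8.412, -7.084))  # c(-8.412, -6.849)
accumulate_tau <- function(gamma) {
  if (length(gamma) == 0L) {
    stop("gamma must have at least one element", call. = FALSE)
  }
  if (anyNA(gamma)) stop("gamma contains missing values", call. = FALSE)
  tau <- numeric(length(gamma))
  running_max <- -Inf
  running_sum <- 0   # sum of exp(gamma - running_max)
  for (j in seq_along(gamma)) {
    g <- gamma[j]
    if (g == -Inf) {
      tau[j] <- if (running_max == -Inf) -Inf
                else running_max + log(running_sum)
      next
    }
    if (g > running_max) {
      running_sum <- running_sum * exp(running_max - g) + 1
      running_max <- g
    } else {
      running_sum <- running_sum + exp(g - running_max)
    }
    tau[j] <- running_max + log(running_sum)
  }
  tau
}

# Negative log-likelihood and gradient of the conditional binomial model.
# theta = c(beta, gamma[active]); cells: x, day, at_risk s, deaths d.
# loglik = sum d*log(q) + (s - d)*log(1 - q),  log(1 - q) = -exp(eta).
tcm_negloglik <- function(theta, x, day_idx, s, d, gamma_full, active) {
  gamma_full[active] <- theta[-1L]
  eta <- gamma_full[day_idx] + theta[1L] * x
  A <- exp(eta)
  q <- -expm1(-A)
  logq <- ifelse(A < 1e-8, eta, log(q))  # q ~ A for tiny hazards
  -sum(d * logq - (s - d) * A)
}

tcm_negloglik_grad <- function(theta, x, day_idx, s, d, gamma_full, active) {
  gamma_full[active] <- theta[-1L]
  eta <- gamma_full[day_idx] + theta[1L] * x
  A <- exp(eta)
  q <- -expm1(-A)
  # d/deta log q = A * exp(-A) / q; -> 1 as A -> 0
  w <- ifelse(A < 1e-8, 1 - A / 2, A * exp(-A) / q)
  deta <- d * w - (s - d) * A
  gbeta <- sum(deta * x)
  ggamma <- vapply(active, function(j) sum(deta[day_idx == j]), numeric(1))
  -c(gbeta, ggamma)
}

#' Fit the time-concentration-mortality model
#'
#' Maximises the conditional binomial log-likelihood
#' \deqn{\ell = \sum_{i,j} d_{ij} \log q_{ij} + (s_{ij} - d_{ij})
#'   \log(1 - q_{ij})}
#' over the dose slope and the per-day conditional time effects, where
#' \eqn{q_{ij}} is the cloglog conditional probability for dose i on day j.
#' Standard errors come from the inverse observed information; variances and
#' covariances of the cumulative effects follow by the delta method with
#' \eqn{\partial\tau_j/\partial\gamma_k = \exp(\gamma_k - \tau_j)}.
#'
#' Fractional (control-corrected) counts are accepted as real-valued
#' quasi-counts. Days on which no deaths occurred at any dose are flagged
#' degenerate: their gamma is fixed at `gamma_floor` and excluded from the
#' information matrix (the boundary estimate has no curvature to report).
#'
#' @param data An `interval_data` data frame from [to_interval_data()] or
#'   [corrected_interval_counts()]. Control (dose 0) rows are ignored with a
#'   message; correct against them first if desired.
#' @param gamma_floor Value at which degenerate conditional effects are
#'   fixed (default -18.8, a hazard of ~7e-9 per day).
#' @param control Optional control `interval_data`; when supplied the
#'   treatment counts are Abbott-corrected via
#'   [corrected_interval_counts()] before fitting.
#' @param label Optional label stored on the result.
#' @param maxit Maximum BFGS iterations.
#' @return A [tcm_parameters()] object with the additional class `tcm_fit`
#'   and fields `data` (the cells used), `fitted_q` (fitted conditional
#'   probabilities), `convergence`, and `iterations`.
#' @export
fit_tcm <- function(data, gamma_floor = -18.8, control = NULL,
                    label = NA_character_, maxit = 500L) {
  stopifnot(is.data.frame(data))
  if (!is.null(control)) data <- corrected_interval_counts(data, control)
  data <- as.data.frame(data)
  treated <- data[data$dose > 0, , drop = FALSE]
  if (nrow(treated) < nrow(data)) {
    message("dropping ", nrow(data) - nrow(treated),
            " control (dose 0) rows from the likelihood")
  }
  if (length(unique(treated$dose)) < 2L) {
    stop("at least two distinct positive doses are required; ",
         "the dose effect is unidentifiable from one dose", call. = FALSE)
  }
  if (sum(treated$deaths) <= 0) {
    stop("no deaths observed at any dose; nothing to fit", call. = FALSE)
  }

  J <- max(treated$day)
  x <- treated$log10_dose
  day_idx <- as.integer(treated$day)
  s <- treated$at_risk
  d <- treated$deaths
  if (any(d < 0) || any(d > s + 1e-9)) {
    stop("interval deaths must lie in [0, at_risk]", call. = FALSE)
  }

  day1 <- day_idx == 1L
  if (sum(d[day1]) >= sum(s[day1]) - 1e-9) {
    stop("complete separation: every insect died by day 1; ",
         "the time structure is degenerate", call. = FALSE)
  }

  deaths_by_day <- vapply(seq_len(J), function(j) sum(d[day_idx == j]),
                          numeric(1))
  degenerate <- which(deaths_by_day <= 1e-9)
  active <- setdiff(seq_len(J), degenerate)
  if (length(active) == 0L) stop("no estimable days", call. = FALSE)

  # init: beta = 0.5, gamma_j = cloglog of pooled conditional mortality
  # minus beta * mean(x), clamped
  beta0 <- 0.5
  gamma_full <- rep(gamma_floor, J)
  for (j in active) {
    sel <- day_idx == j
    qbar <- min(max(sum(d[sel]) / sum(s[sel]), 1e-6), 1 - 1e-6)
    gamma_full[j] <- min(max(log(-log(1 - qbar)) - beta0 * mean(x[sel]),
                             -12), 2)
  }
  theta0 <- c(beta0, gamma_full[active])

  opt <- stats::optim(theta0, tcm_negloglik, gr = tcm_negloglik_grad,
                      x = x, day_idx = day_idx, s = s, d = d,
                      gamma_full = gamma_full, active = active,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0L) {
    # polish with a bounded quasi-Newton pass before giving up
    opt2 <- stats::nlminb(opt$par, tcm_negloglik, tcm_negloglik_grad,
                          x = x, day_idx = day_idx, s = s, d = d,
                          gamma_full = gamma_full, active = active,
                          control = list(iter.max = maxit))
    if (opt2$objective <= opt$value) {
      opt$par <- opt2$par
      opt$value <- opt2$objective
      opt$convergence <- if (opt2$convergence == 0L) 0L else opt$convergence
    }
    if (opt$convergence != 0L) {
      stop("TCM fit did not converge after ", maxit, " iterations ",
           "(final negative log-likelihood ", format(opt$value), ")",
           call. = FALSE)
    }
  }

  theta <- opt$par
  beta <- theta[1L]
  gamma_full[active] <- theta[-1L]

  hess <- stats::optimHess(theta, tcm_negloglik, tcm_negloglik_grad,
                           x = x, day_idx = day_idx, s = s, d = d,
                           gamma_full = gamma_full, active = active)
  vcov <- tryCatch(solve(hess), error = function(e) MASS::ginv(hess))
  vdiag <- pmax(diag(vcov), 0)

  se_beta <- sqrt(vdiag[1L])
  se_gamma <- rep(NA_real_, J)
  se_gamma[active] <- sqrt(vdiag[-1L])

  tau <- accumulate_tau(gamma_full)
  var_tau <- rep(NA_real_, J)
  cov_tau_beta <- rep(NA_real_, J)
  for (j in seq_len(J)) {
    ks <- active[active <= j]
    grad <- numeric(length(theta))           # order: beta, gamma[active]
    grad[1L + match(ks, active)] <- exp(gamma_full[ks] - tau[j])
    var_tau[j] <- max(drop(t(grad) %*% vcov %*% grad), 0)
    cov_tau_beta[j] <- drop(vcov[1L, ] %*% grad)
  }

  params <- tcm_parameters(beta = beta, gamma = gamma_full,
                           se_beta = se_beta, se_gamma = se_gamma,
                           var_tau = var_tau, cov_tau_beta = cov_tau_beta,
                           loglik = -opt$value, degenerate = degenerate,
                           label = label)
  params$fitted_q <- conditional_probability(gamma_full[day_idx], beta, x)
  params$data <- treated
  params$convergence <- opt$convergence
  params$iterations <- opt$counts[["function"]]
  class(params) <- c("tcm_fit", class(params))
  params
}

#' Parameter t statistics
#'
#' Returns estimate/SE for the dose slope and each estimable conditional
#' time effect; degenerate days (gamma fixed at the floor) are reported as
#' `NA` rather than the meaningless boundary ratio.
#'
#' @param params A [tcm_parameters()] object with standard errors.
#' @return Named numeric vector `beta`, `gamma1`..`gammaJ`.
#' @export
parameter_t_stats <- function(params) {
  stopifnot(inherits(params, "tcm_parameters"))
  t_gamma <- params$gamma / params$se_gamma
  if (length(params$degenerate)) t_gamma[params$degenerate] <- NA_real_
  nondeg <- setdiff(seq_len(params$J), params$degenerate)
  bad <- nondeg[!is.na(params$se_gamma[nondeg]) &
                  params$se_gamma[nondeg] == 0]
  if (length(bad) || identical(params$se_beta, 0)) {
    warning("zero standard error on a non-degenerate parameter; ",
            "the information matrix is numerically singular")
  }
  stats::setNames(c(params$beta / params$se_beta, t_gamma),
                  c("beta", paste0("gamma", seq_len(params$J))))
}
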