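#' Lethal concentration LCp at a given day
#'
#' Inverts the cumulative cloglog model at mortality level p:
#' `log10 LCp = (log(-log(1 - p)) - tau_j) / beta`.
#'
#' @param params A [tcm_parameters()] object.
#' @param day Observation day j (1..J).
#' @param p Target mortality proportion in (0, 1); default 0.5.
#' @return A one-row data frame of class `lethal_endpoint` with columns
#'   `kind` ("LC"), `p`, `day`, `dose` (NA), `estimate` (conidia/mL),
#'   `estimable`.
#' @export
#' @examples
#' pars <- stage_parameters("larvae")
#' lc_p(pars, day = 7, p = 0.5)  # ~8e5 conidia/mL
lc_p <- function(params, day, p = 0.5) {
  stopifnot(inherits(params, "tcm_parameters"),
            length(day) == 1L, day >= 1L, day <= params$J,
            p > 0, p < 1)
  if (params$beta <= 0) {
    stop("dose slope is non-positive; the model cannot be inverted ",
         "for a lethal concentration", call. = FALSE)
  }
  log10_lc <- (log(-log(1 - p)) - params$tau[day]) / params$beta
  endpoint_row("LC", p, day = day, dose = NA_real_,
               estimate = 10^log10_lc, estimable = TRUE)
}

#' Lethal time LTp at a given dose
#'
#' Finds the time at which the cumulative model crosses mortality level p
#' at a fixed dose. The cumulative predictor `eta(t) = tau(t) + beta * x`
#' is treated as piecewise linear in t between observation days (with a
#' floor predictor at t = 0 so crossings within day 1 have a root); the
#' crossing is located by linear interpolation. If mortality p is not
#' reached by the last observation day the endpoint is flagged
#' non-estimable rather than extrapolated.
#'
#' @param params A [tcm_parameters()] object.
#' @param dose Dose in conidia/mL (> 0).
#' @param p Target mortality proportion in (0, 1); default 0.5.
#' @param interpolation `"linear"` (default) interpolates the predictor
#'   linearly in t; `"log10"` interpolates linearly in log10 t (days >= 1).
#' @param floor_tau Predictor floor assigned to t = 0 (default -18.8).
#' @return A one-row `lethal_endpoint` data frame with `estimate` in days.
#' @export
#' @examples
#' lt_p(stage_parameters("larvae"), dose = 1e6, p = 0.5)  # ~4.98 days
lt_p <- function(params, dose, p = 0.5,
                 interpolation = c("linear", "log10"), floor_tau = -18.8) {
  stopifnot(inherits(params, "tcm_parameters"),
            length(dose) == 1L, dose > 0, p > 0, p < 1)
  interpolation <- match.arg(interpolation)
  x <- log10(dose)
  target_tau <- log(-log(1 - p)) - params$beta * x

  tau <- params$tau
  J <- params$J
  if (target_tau > tau[J]) {
    return(endpoint_row("LT", p, day = NA_real_, dose = dose,
                        estimate = NA_real_, estimable = FALSE))
  }
  grid_t <- c(0, seq_len(J))
  grid_tau <- c(min(floor_tau, tau[1L]), tau)
  j <- which(grid_tau >= target_tau)[1L]
  if (j == 1L) {
    est <- 0
  } else {
    t0 <- grid_t[j - 1L]; t1 <- grid_t[j]
    f <- (target_tau - grid_tau[j - 1L]) / (grid_tau[j] - grid_tau[j - 1L])
    if (interpolation == "log10" && t0 >= 1) {
      est <- 10^(log10(t0) + f * (log10(t1) - log10(t0)))
    } else {
      est <- t0 + f * (t1 - t0)
    }
  }
  endpoint_row("LT", p, day = NA_real_, dose = dose,
               estimate = est, estimable = TRUE)
}

endpoint_row <- function(kind, p, day, dose, estimate, estimable) {
  structure(data.frame(kind = kind, p = p, day = day, dose = dose,
                       estimate = estimate, estimable = estimable),
            class = c("lethal_endpoint", "data.frame"))
}

#' Table of lethal endpoints
#'
#' Evaluates LC endpoints at the requested days and LT endpoints at the
#' requested doses, for each mortality level, in one long table.
#' Non-estimable lethal times appear with `estimable = FALSE` and render
#' as an em dash in [format_endpoint_table()].
#'
#' @param params A [tcm_parameters()] object.
#' @param doses Doses (conidia/mL) at which to estimate lethal times; may
#'   be empty.
#' @param days Days at which to estimate lethal concentrations; may be
#'   empty.
#' @param p_levels Mortality levels, e.g. `c(0.5, 0.9)`.
#' @param ... Passed on to [lt_p()] (e.g. `interpolation`).
#' @return A `lethal_endpoint` data frame with one row per endpoint.
#' @export
endpoint_table <- function(params, doses = numeric(0), days = integer(0),
                           p_levels = c(0.5, 0.9), ...) {
  rows <- list()
  for (p in p_levels) {
    for (d in days) rows[[length(rows) + 1L]] <- lc_p(params, d, p)
    for (do in doses) rows[[length(rows) + 1L]] <- lt_p(params, do, p, ...)
  }
  if (length(rows) == 0L) {
    return(structure(data.frame(kind = character(0), p = numeric(0),
                                day = numeric(0), dose = numeric(0),
                                estimate = numeric(0),
                                estimable = logical(0)),
                     class = c("lethal_endpoint", "data.frame")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render an endpoint table with dashes for non-estimable cells
#'
#' @param endpoints A `lethal_endpoint` data frame.
#' @param digits Significant digits for estimates.
#' @return Character matrix-style data frame, estimates formatted, with
#'   `"—"` where the endpoint is non-estimable.
#' @export
format_endpoint_table <- function(endpoints, digits = 3L) {
  out <- as.data.frame(endpoints)
  out$estimate <- ifelse(out$estimable,
                         signif(out$estimate, digits), NA)
  out$estimate <- ifelse(is.na(out$estimate), "—",
                         format(out$estimate, trim = TRUE))
  out
}
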