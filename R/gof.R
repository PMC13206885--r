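#' Upper-tail chi-square probability
#'
#' `P(chisq_df > x)`, the regularized upper incomplete gamma function
#' evaluated through [stats::pchisq()].
#'
#' @param x Non-negative statistic value.
#' @param df Degrees of freedom.
#' @return Upper-tail probability.
#' @export
#' @examples
#' chi_square_tail(14.04, 8)  # 0.0807
chi_square_tail <- function(x, df) {
  if (any(x < 0)) stop("statistic must be non-negative", call. = FALSE)
  if (any(df <= 0)) stop("df must be positive", call. = FALSE)
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Grouped chi-square heterogeneity test of a fitted binomial model. The
#' (dose, day) cells are sorted by predicted probability (ties broken by
#' dose, then day, for determinism), partitioned into `n_groups` contiguous
#' groups of near-equal cell count, and compared via
#' \deqn{C = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g / n_g)}}
#' with `df = n_groups - 2` and an upper-tail chi-square p-value. A p-value
#' of at least 0.05 is conventionally read as the model passing the
#' heterogeneity test.
#'
#' @param observed_deaths Observed deaths per cell (may be fractional after
#'   control correction).
#' @param at_risk Number at risk per cell.
#' @param predicted_probs Model probabilities per cell, in (0, 1).
#' @param n_groups Target number of groups (default 10, giving df = 8).
#' @param dose,day Optional cell labels used only to break ties in the sort.
#' @return List of class `gof_result` with `C`, `df`, `p`, `n_groups`.
#' @export
hosmer_lemeshow <- function(observed_deaths, at_risk, predicted_probs,
                            n_groups = 10L, dose = NULL, day = NULL) {
  m <- length(observed_deaths)
  stopifnot(length(at_risk) == m, length(predicted_probs) == m)
  if (any(predicted_probs <= 0 | predicted_probs >= 1)) {
    stop("predicted probabilities must be strictly inside (0, 1)",
         call. = FALSE)
  }
  if (m < n_groups) {
    warning("fewer cells (", m, ") than groups (", n_groups,
            "); reducing group count")
    n_groups <- max(m, 3L)
  }
  ord <- order(predicted_probs,
               if (is.null(dose)) seq_len(m) else dose,
               if (is.null(day)) seq_len(m) else day)
  o <- observed_deaths[ord]
  s <- at_risk[ord]
  p <- predicted_probs[ord]
  grp <- ceiling(seq_len(m) / (m / n_groups))

  O <- tapply(o, grp, sum)
  E <- tapply(s * p, grp, sum)
  N <- tapply(s, grp, sum)
  # merge groups with no at-risk mass (or vanishing expectation) into the
  # previous group
  bad <- which(N <= 0 | E <= 1e-12 | E >= N - 1e-12)
  while (length(bad) > 0L) {
    g <- bad[1L]
    tgt <- if (g > 1L) g - 1L else 2L
    O[tgt] <- O[tgt] + O[g]; E[tgt] <- E[tgt] + E[g]; N[tgt] <- N[tgt] + N[g]
    O <- O[-g]; E <- E[-g]; N <- N[-g]
    bad <- which(N <= 0 | E <= 1e-12 | E >= N - 1e-12)
  }
  C <- sum((O - E)^2 / (E * (1 - E / N)))
  df <- length(O) - 2L
  structure(list(C = C, df = df, p = chi_square_tail(C, df),
                 n_groups = length(O)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: C = %.2f, df = %d, p = %.3f (%s)\n",
              x$C, x$df, x$p,
              if (x$p >= 0.05) "model passes the heterogeneity test"
              else "heterogeneity detected"))
  invisible(x)
}

#' Hosmer-Lemeshow test of a fitted TCM model
#'
#' Convenience wrapper applying [hosmer_lemeshow()] to the conditional
#' (dose, day) cells and fitted probabilities of a [fit_tcm()] result.
#'
#' @param fit A `tcm_fit` object.
#' @param n_groups Number of groups (default 10).
#' @return A `gof_result`.
#' @export
gof_tcm <- function(fit, n_groups = 10L) {
  stopifnot(inherits(fit, "tcm_fit"))
  keep <- fit$fitted_q > 0 & fit$fitted_q < 1
  hosmer_lemeshow(fit$data$deaths[keep], fit$data$at_risk[keep],
                  fit$fitted_q[keep], n_groups = n_groups,
                  dose = fit$data$dose[keep], day = fit$data$day[keep])
}
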