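#' Mortality rate
#'
#' @param dead Number of dead insects.
#' @param n Number of test insects.
#' @return `dead / n`; vectorized.
#' @export
mortality_rate <- function(dead, n) {
  if (any(n <= 0)) stop("cohort size must be positive", call. = FALSE)
  if (any(dead < 0 | dead > n)) {
    stop("dead must lie in [0, n]", call. = FALSE)
  }
  dead / n
}

#' Abbott's control-mortality correction
#'
#' Corrects treatment mortality for natural mortality observed in the
#' untreated control: `(T - C) / (1 - C)`, floored at 0. When control
#' mortality is zero the treatment mortality is returned unchanged.
#'
#' @param treatment_mortality Proportion(s) in \[0, 1\].
#' @param control_mortality Proportion(s) in \[0, 1).
#' @return Corrected proportion(s) in \[0, 1\]; vectorized.
#' @export
#' @examples
#' abbott_correction(0.5, 0.2)  # 0.375
abbott_correction <- function(treatment_mortality, control_mortality) {
  if (any(treatment_mortality < 0 | treatment_mortality > 1)) {
    stop("treatment mortality must be in [0, 1]", call. = FALSE)
  }
  if (any(control_mortality < 0)) {
    stop("control mortality must be non-negative", call. = FALSE)
  }
  if (any(control_mortality >= 1)) {
    stop("degenerate control: control mortality is 1, ",
         "correction is undefined", call. = FALSE)
  }
  pmin(pmax((treatment_mortality - control_mortality) /
              (1 - control_mortality), 0), 1)
}

#' Control-correct interval counts
#'
#' Applies Abbott's correction day by day to the cumulative mortality of
#' each treated dose, against the same-day cumulative control mortality,
#' then re-expands the corrected cumulative series to fractional interval
#' deaths and at-risk counts on the original cohort size. Monotonicity of
#' the corrected cumulative series is enforced by isotonic clipping
#' (running maximum), so the corrected total is conserved exactly when
#' re-accumulated.
#'
#' @param data Pooled `interval_data` for the treated doses (may include
#'   dose-0 rows, which are dropped from the output).
#' @param control Pooled `interval_data` for the control (dose 0), or `NULL`
#'   to take the dose-0 rows of `data`. Must cover the same days.
#' @return `interval_data` for the treated doses with fractional `deaths`
#'   and `at_risk`.
#' @export
corrected_interval_counts <- function(data, control = NULL) {
  data <- as.data.frame(data)
  if (is.null(control)) {
    control <- data[data$dose == 0, , drop = FALSE]
    if (nrow(control) == 0L) {
      stop("no control (dose 0) series available for correction",
           call. = FALSE)
    }
  } else {
    control <- as.data.frame(control)
    control <- control[control$dose == 0 | control$dose ==
                         min(control$dose), , drop = FALSE]
  }
  treated <- data[data$dose > 0, , drop = FALSE]
  days <- sort(unique(treated$day))
  control <- control[order(control$day), , drop = FALSE]
  if (!all(days %in% control$day)) {
    stop("control series does not cover every observation day",
         call. = FALSE)
  }

  n0_control <- control$at_risk[control$day == min(control$day)]
  control_cum <- cumsum(control$deaths) / n0_control
  if (any(control_cum >= 1)) {
    stop("degenerate control: complete control mortality on day ",
         control$day[which(control_cum >= 1)[1L]], call. = FALSE)
  }
  names(control_cum) <- control$day

  series <- split(treated, treated$dose)
  rows <- lapply(series, function(s) {
    s <- s[order(s$day), , drop = FALSE]
    n0 <- s$at_risk[1L]
    p_cum <- cumsum(s$deaths) / n0
    p_corr <- abbott_correction(pmin(p_cum, 1),
                                control_cum[as.character(s$day)])
    p_corr <- cummax(p_corr)        # isotonic clipping
    cum_dead <- n0 * p_corr
    prev <- c(0, cum_dead[-length(cum_dead)])
    data.frame(dose = s$dose, day = s$day,
               at_risk = n0 - prev, deaths = cum_dead - prev,
               log10_dose = s$log10_dose)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dose, out$day),
             c("dose", "day", "at_risk", "deaths", "log10_dose")]
  rownames(out) <- NULL
  structure(out, class = c("interval_data", "data.frame"))
}

#' Per-dose per-day mortality summary
#'
#' Raw and Abbott-corrected cumulative mortality with replicate standard
#' errors, the descriptive companion to the model fit.
#'
#' @param table A [bioassay_table()].
#' @return Data frame with columns `dose`, `day`, `mortality`,
#'   `corrected_mortality`, `se` (SE of raw mortality across replicates).
#'   Corrected values equal raw values when there is no control or the
#'   control had no deaths.
#' @export
mortality_summary <- function(table) {
  stopifnot(inherits(table, "bioassay_table"))
  df <- as.data.frame(table)
  df$mortality <- mortality_rate(df$dead, df$n)
  agg <- stats::aggregate(mortality ~ dose + day, data = df,
                          FUN = function(v) c(mean = mean(v),
                                              se = stats::sd(v) /
                                                sqrt(length(v))))
  out <- data.frame(dose = agg$dose, day = agg$day,
                    mortality = agg$mortality[, "mean"],
                    se = agg$mortality[, "se"])
  ctrl <- out[out$dose == 0, , drop = FALSE]
  if (nrow(ctrl) > 0L) {
    cm <- stats::setNames(ctrl$mortality, ctrl$day)
    out$corrected_mortality <- ifelse(
      out$dose > 0,
      abbott_correction(out$mortality, cm[as.character(out$day)]),
      out$mortality)
  } else {
    out$corrected_mortality <- out$mortality
  }
  out <- out[order(out$dose, out$day),
             c("dose", "day", "mortality", "corrected_mortality", "se")]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD letters for stage comparison
#'
#' Compares final mortality across groups (e.g. insect life stages) by
#' one-way ANOVA on untransformed proportions, followed by Tukey's honestly
#' significant difference test at alpha = 0.05 with a compact letter
#' display: groups sharing a letter are not significantly different.
#'
#' @param groups Named list of numeric vectors of replicate mortality
#'   proportions, one vector per group.
#' @return List of class `stage_anova` with `F`, `p`, `df`, the Tukey
#'   pairwise table (`tukey`), and per-group `letters`. When both mean
#'   squares are zero the F statistic is undefined and returned as `NaN`.
#' @export
stage_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least two replicates", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- stats::aov(y ~ group, data = df)
  an <- summary(fit)[[1L]]
  Fstat <- an[["F value"]][1L]
  pval <- an[["Pr(>F)"]][1L]
  tukey <- stats::TukeyHSD(fit, conf.level = 0.95)$group
  letters <- tryCatch({
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
    multcomp::cld(glht_fit, level = 0.05)$mcletters$Letters
  }, error = function(e) stats::setNames(rep(NA_character_,
                                             length(groups)),
                                         names(groups)))
  structure(list(F = Fstat, p = pval,
                 df = c(between = an$Df[1L], within = an$Df[2L]),
                 means = vapply(groups, mean, numeric(1)),
                 tukey = tukey, letters = letters[names(groups)]),
            class = "stage_anova")
}

#' @export
print.stage_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df["between"], x$df["within"], x$F, x$p))
  tab <- data.frame(group = names(x$means), mean = x$means,
                    letter = x$letters)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
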