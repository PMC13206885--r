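#' Construct and validate a bioassay table
#'
#' A bioassay table holds replicated daily cohort observations from a
#' dose-response mortality experiment: for each conidial concentration
#' (including an optional zero-dose control), each replicate, and each
#' observation day, the initial cohort size and the cumulative number dead
#' by the end of that day.
#'
#' @param data A data frame with columns `dose` (conidia/mL, 0 = control),
#'   `replicate` (identifier), `day` (integer day post-inoculation, starting
#'   at 1), `n` (initial cohort size), and `dead` (cumulative dead by the end
#'   of `day`).
#'
#' @details Validation enforces, per (dose, replicate) series: days are
#'   consecutive integers starting at 1, `0 <= dead <= n`, cumulative deaths
#'   are nondecreasing, and the cohort size is constant. At least one
#'   positive dose must be present. Row order is irrelevant.
#'
#' @return The validated data frame, sorted by dose, replicate, day, with
#'   class `bioassay_table` and attributes `days` (observation horizon J) and
#'   `doses` (sorted distinct dose levels).
#' @export
#' @examples
#' tab <- bioassay_table(data.frame(
#'   dose = 1e6, replicate = 1, day = 1:3, n = 25, dead = c(2, 5, 5)))
#' attr(tab, "days")
bioassay_table <- function(data) {
  required <- c("dose", "replicate", "day", "n", "dead")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("bioassay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[required]
  if (nrow(data) == 0L) stop("bioassay table has no rows", call. = FALSE)

  for (col in c("dose", "day", "n", "dead")) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]])) {
      stop("column '", col, "' must be numeric with no missing values",
           call. = FALSE)
    }
  }
  if (any(data$dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (!any(data$dose > 0)) {
    stop("bioassay table must contain at least one positive dose",
         call. = FALSE)
  }
  if (any(data$n <= 0 | data$n != round(data$n))) {
    stop("cohort size 'n' must be a positive integer", call. = FALSE)
  }
  if (any(data$dead != round(data$dead))) {
    stop("cumulative deaths 'dead' must be integer counts", call. = FALSE)
  }

  data <- data[order(data$dose, data$replicate, data$day), , drop = FALSE]
  rownames(data) <- NULL

  series <- split(data, list(data$dose, data$replicate), drop = TRUE)
  for (s in series) {
    id <- sprintf("(dose %g, replicate %s)", s$dose[1L], s$replicate[1L])
    if (!identical(as.integer(s$day), seq_len(nrow(s)))) {
      stop("days for ", id, " must be consecutive integers starting at 1",
           call. = FALSE)
    }
    if (length(unique(s$n)) != 1L) {
      stop("cohort size changes within ", id, call. = FALSE)
    }
    bad <- which(s$dead < 0 | s$dead > s$n)
    if (length(bad) > 0L) {
      stop("cumulative deaths outside [0, n] at ", id, ", day ",
           s$day[bad[1L]], call. = FALSE)
    }
    drop_ <- which(diff(s$dead) < 0)
    if (length(drop_) > 0L) {
      stop("cumulative deaths decrease at ", id, ", day ",
           s$day[drop_[1L] + 1L], call. = FALSE)
    }
  }

  structure(data,
            class = c("bioassay_table", "data.frame"),
            days = max(data$day),
            doses = sort(unique(data$dose)))
}

#' Read a bioassay table from CSV
#'
#' Expects long format, one row per (dose, replicate, day). Column names can
#' be remapped through `schema` for files using different headers.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping the canonical names
#'   `dose`, `replicate`, `day`, `n`, `dead` to the column names in the file.
#' @return A validated [bioassay_table()].
#' @export
read_assay_table <- function(path,
                             schema = c(dose = "dose", replicate = "replicate",
                                        day = "day", n = "n", dead = "dead")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[unname(schema)]
  names(out) <- names(schema)
  bioassay_table(out)
}

#' Write a bioassay table to CSV
#'
#' @param table A [bioassay_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(table, path) {
  stopifnot(inherits(table, "bioassay_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Reduce cumulative counts to interval (conditional) form
#'
#' Converts per-day cumulative deaths into the sufficient data of the
#' conditional likelihood: per (dose, day) the number at risk at the start of
#' the day and the deaths during the day.
#'
#' @param table A [bioassay_table()].
#' @param pool_replicates Sum counts across replicates at each dose before
#'   returning (default `TRUE`; the fitted model has a single parameter set
#'   per assay, so pooled counts are its natural input).
#' @return A data frame of class `interval_data` with columns `dose`,
#'   `log10_dose` (`-Inf` for the control), `day`, `at_risk`, `deaths`,
#'   and `replicate` when not pooled. Counts are integers here; fractional
#'   values arise only after control correction
#'   (see [corrected_interval_counts()]).
#' @export
#' @examples
#' tab <- bioassay_table(data.frame(
#'   dose = 1e6, replicate = 1, day = 1:3, n = 25, dead = c(2, 5, 5)))
#' to_interval_data(tab)
to_interval_data <- function(table, pool_replicates = TRUE) {
  stopifnot(inherits(table, "bioassay_table"))
  df <- as.data.frame(table)
  series <- split(df, list(df$dose, df$replicate), drop = TRUE)
  rows <- lapply(series, function(s) {
    s <- s[order(s$day), , drop = FALSE]
    prev <- c(0, s$dead[-nrow(s)])
    data.frame(dose = s$dose, replicate = s$replicate, day = s$day,
               at_risk = s$n - prev, deaths = s$dead - prev)
  })
  out <- do.call(rbind, rows)
  if (pool_replicates) {
    agg <- stats::aggregate(cbind(at_risk, deaths) ~ dose + day, data = out,
                            FUN = sum)
    out <- agg[order(agg$dose, agg$day), , drop = FALSE]
  } else {
    out <- out[order(out$dose, out$replicate, out$day), , drop = FALSE]
  }
  out$log10_dose <- ifelse(out$dose > 0, log10(out$dose), -Inf)
  rownames(out) <- NULL
  structure(out, class = c("interval_data", "data.frame"))
}

#' Serialize fitted TCM parameters to JSON
#'
#' Writes every component of a [tcm_parameters()] object (dose slope, the
#' conditional and cumulative time effects with their uncertainties, fit
#' metadata) at full double precision, so `read_parameters()` round-trips
#' losslessly.
#'
#' @param params A [tcm_parameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "tcm_parameters"))
  payload <- unclass(params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read fitted TCM parameters from JSON
#'
#' @param path Path written by [write_parameters()].
#' @return A [tcm_parameters()] object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  tcm_parameters(
    beta = num(payload$beta),
    gamma = num(payload$gamma),
    se_beta = num(payload$se_beta),
    se_gamma = num(payload$se_gamma),
    var_tau = num(payload$var_tau),
    cov_tau_beta = num(payload$cov_tau_beta),
    loglik = num(payload$loglik),
    degenerate = as.integer(payload$degenerate %||% integer(0)),
    tau = num(payload$tau),
    label = payload$label %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
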