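#' Baseline stability screen for predrug control trials
#'
#' Pharmacological testing proceeds only after three consecutive stable
#' control trials: the C-fibre-evoked response may vary by less than 10% and
#' every other tracked measure by less than 20%. Variation is computed over
#' the last three trials; the default rule is the range as a percentage of the
#' mean, with the maximum absolute deviation from the mean available as an
#' alternative. A measure that is zero in all three trials has 0% variation
#' by convention.
#'
#' @param trials Data frame (or matrix) with one row per control trial and one
#'   column per measure, in chronological order; at least 3 rows. Column names
#'   are measure names; the C-fibre total must be named `"c"` (or supplied via
#'   `c_measure`).
#' @param c_threshold Percent threshold for the C-fibre measure (default 10).
#' @param other_threshold Percent threshold for all other measures (default 20).
#' @param rule `"range"` (100 * (max - min) / mean) or `"max_dev"`
#'   (100 * max |x - mean| / mean).
#' @param c_measure Name of the C-fibre column.
#' @return List with `accepted` (logical), `variation` (named percent vector
#'   over the last three trials) and `rule`.
#' @export
check_baseline_stability <- function(trials, c_threshold = 10,
                                     other_threshold = 20,
                                     rule = c("range", "max_dev"),
                                     c_measure = "c") {
  rule <- match.arg(rule)
  trials <- as.matrix(trials)
  if (nrow(trials) < 3L)
    stop("at least 3 consecutive control trials are required", call. = FALSE)
  last3 <- trials[nrow(trials) - 2:0, , drop = FALSE]
  variation <- apply(last3, 2L, function(x) {
    m <- mean(x)
    if (m == 0) return(if (all(x == 0)) 0 else Inf)
    dev <- if (rule == "range") max(x) - min(x) else max(abs(x - m))
    100 * dev / m
  })
  thr <- ifelse(colnames(last3) == c_measure, c_threshold, other_threshold)
  list(accepted = all(variation < thr), variation = variation, rule = rule)
}

#' Average predrug control values
#'
#' Arithmetic mean per measure over the (stable) control trials; these means
#' are the predrug baselines against which every dose is compared.
#'
#' @inheritParams check_baseline_stability
#' @param require_stable If `TRUE` (default), error when the stability screen
#'   rejects the trials.
#' @param ... Passed to [check_baseline_stability()].
#' @return Named numeric vector of baselines.
#' @export
average_predrug <- function(trials, require_stable = TRUE, ...) {
  trials <- as.matrix(trials)
  if (isTRUE(require_stable)) {
    st <- check_baseline_stability(trials, ...)
    if (!st$accepted)
      stop("control trials fail the baseline stability screen (",
           paste(sprintf("%s=%.1f%%", names(st$variation), st$variation),
                 collapse = ", "), ")", call. = FALSE)
  }
  colMeans(trials[nrow(trials) - 2:0, , drop = FALSE])
}

#' Maximum-percentage-change dose effect for one measure
#'
#' The drug effect for a dose is the maximum percentage change from the
#' averaged predrug baseline over the post-dose test minutes, signed
#' (inhibition negative, facilitation positive); the raw response at the
#' maximal-change minute is retained for group summaries. Ties in absolute
#' change are broken by the earliest minute. A zero baseline makes the
#' percentage undefined: the effect is then reported as the raw difference
#' with `pct_defined = FALSE`.
#'
#' @param baseline Averaged predrug value for the measure.
#' @param values_by_minute Named numeric vector, names = post-dose minutes
#'   (e.g. `c("10" = 80, "30" = 60, "50" = 70)`).
#' @param measure,dose Labels carried into the result.
#' @return Object of class `dose_effect`: list with `measure`, `dose`,
#'   `baseline`, `values_by_minute`, `minute_at_max`, `raw_at_max`,
#'   `max_pct_change`, `raw_change`, `pct_defined`.
#' @export
dose_effect <- function(baseline, values_by_minute, measure = NA_character_,
                        dose = NA_real_) {
  stopifnot(length(baseline) == 1L, is.finite(baseline),
            length(values_by_minute) >= 1L, all(is.finite(values_by_minute)))
  minutes <- as.numeric(names(values_by_minute))
  if (any(is.na(minutes)))
    stop("values_by_minute must be named by post-dose minute", call. = FALSE)
  ord <- order(minutes)
  minutes <- minutes[ord]; vals <- unname(values_by_minute[ord])
  dev <- abs(vals - baseline)
  i <- which(dev == max(dev))[1L]           # tie -> earliest minute
  raw <- vals[i]
  pct_defined <- baseline != 0
  structure(list(measure = measure, dose = dose, baseline = baseline,
                 values_by_minute = stats::setNames(vals, minutes),
                 minute_at_max = minutes[i], raw_at_max = raw,
                 max_pct_change = if (pct_defined)
                   100 * (raw - baseline) / baseline else NA_real_,
                 raw_change = raw - baseline, pct_defined = pct_defined),
            class = "dose_effect")
}

#' @export
print.dose_effect <- function(x, ...) {
  eff <- if (x$pct_defined) sprintf("%+.1f%%", x$max_pct_change)
         else sprintf("%+g (raw; baseline 0)", x$raw_change)
  cat(sprintf("dose_effect %s @ dose %s: baseline %.3g -> %s at %g min (raw %.4g)\n",
              x$measure, format(x$dose), x$baseline, eff, x$minute_at_max,
              x$raw_at_max))
  invisible(x)
}

#' Assemble a group dose-response table
#'
#' Aggregates per-neurone dose effects into the group summary: for each
#' measure and dose, the mean and SEM of the raw response at the
#' maximal-change minute, alongside the mean baseline. This is the "mean
#' maximal evoked neuronal response" layout feeding the statistical battery.
#'
#' @param effects Either a list of `dose_effect` objects or a data frame with
#'   columns `neurone_id`, `measure`, `dose`, `baseline`, `raw_at_max` (extra
#'   columns are ignored). Each neurone must carry the same dose ladder for a
#'   given measure.
#' @return Data frame with columns `measure`, `dose` (`"baseline"` or the dose
#'   as character), `n`, `mean`, `sem`.
#' @export
assemble_dose_response <- function(effects) {
  df <- if (is.data.frame(effects)) effects else
    do.call(rbind, lapply(effects, function(e)
      data.frame(neurone_id = NA_character_, measure = e$measure,
                 dose = e$dose, baseline = e$baseline,
                 raw_at_max = e$raw_at_max)))
  need <- c("measure", "dose", "baseline", "raw_at_max")
  if (!all(need %in% names(df)))
    stop("effects must provide columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 1L) stop("no dose effects supplied", call. = FALSE)
  if ("neurone_id" %in% names(df) && !all(is.na(df$neurone_id))) {
    ladders <- tapply(df$dose, df$neurone_id,
                      function(d) paste(sort(unique(d)), collapse = ","))
    if (length(unique(ladders)) > 1L)
      stop("inconsistent dose ladders across neurones", call. = FALSE)
  }
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  base <- unique(df[c("measure", if ("neurone_id" %in% names(df)) "neurone_id",
                      "baseline")])
  rows <- list()
  for (m in unique(df$measure)) {
    b <- base$baseline[base$measure == m]
    rows[[length(rows) + 1L]] <- data.frame(
      measure = m, dose = "baseline", n = length(b),
      mean = mean(b), sem = sem(b))
    sub <- df[df$measure == m, ]
    for (d in sort(unique(sub$dose))) {
      v <- sub$raw_at_max[sub$dose == d]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, dose = as.character(d), n = length(v),
        mean = mean(v), sem = sem(v))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
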