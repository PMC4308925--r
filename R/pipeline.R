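#' Quantify a set of recordings into a long measures table
#'
#' Electrical recordings yield the six excitability measures (Abeta, Adelta,
#' C and postdischarge totals, input, wind-up); each natural-stimulus
#' recording yields its evoked count under a measure label (`brush`,
#' `vf_<g>`, `heat_<degC>`).
#'
#' @param recordings List of `spike_recording`s.
#' @param windows A `latency_windows`.
#' @param include_postdischarge Wind-up convention flag (see
#'   [windup_measure()]).
#' @return Long data frame: `neurone_id`, `group`, `route`, `dose`, `minute`,
#'   `trial`, `measure`, `value`.
#' @export
quantify_recordings <- function(recordings, windows = latency_windows(),
                                include_postdischarge = FALSE) {
  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    meta <- data.frame(neurone_id = rec$neurone_id, group = rec$group,
                       route = rec$route, dose = as.character(rec$dose),
                       minute = rec$minute, trial = rec$trial)
    if (is_electrical(rec)) {
      s <- summarise_electrical(rec, windows, include_postdischarge)
      rows[[i]] <- cbind(meta[rep(1L, 6L), ],
                         measure = c("abeta", "adelta", "c", "pd", "input",
                                     "windup"),
                         value = c(s$abeta_total, s$adelta_total, s$c_total,
                                   s$pd_total, s$input, s$windup))
    } else {
      lbl <- measure_label(rec$stimulus)
      nr <- natural_evoked_count(rec)
      rows[[i]] <- cbind(meta, measure = lbl, value = nr$evoked_count)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

measure_label <- function(stimulus) {
  switch(stimulus$modality,
         brush = "brush",
         von_frey = paste0("vf_", stimulus$magnitude),
         heat = paste0("heat_", stimulus$magnitude))
}

# measures screened for baseline stability; wind-up is a derived difference
# and is excluded from the screen (its range/mean is ill-behaved near zero)
stability_measures <- function(measures) setdiff(measures, "windup")

#' Per-neurone dose effects from a quantified timecourse
#'
#' For each neurone: screens the three predrug trials with
#' [check_baseline_stability()], averages them into per-measure baselines,
#' and computes the maximum-percentage-change [dose_effect()] per measure and
#' dose over the post-dose test minutes.
#'
#' @param quantified Long table from [quantify_recordings()].
#' @param stability_rule `"range"` or `"max_dev"` (see
#'   [check_baseline_stability()]).
#' @param enforce_stability Error on neurones failing the screen (`TRUE`) or
#'   keep them with a warning (`FALSE`).
#' @return Data frame: `neurone_id`, `group`, `measure`, `dose` (numeric),
#'   `baseline`, `minute_at_max`, `raw_at_max`, `max_pct_change`.
#' @export
neurone_dose_effects <- function(quantified, stability_rule = "range",
                                 enforce_stability = TRUE) {
  out <- list()
  for (id in unique(quantified$neurone_id)) {
    q <- quantified[quantified$neurone_id == id, ]
    base <- q[q$dose == "predrug", ]
    if (!nrow(base)) stop("neurone ", id, " has no predrug trials",
                          call. = FALSE)
    bt <- stats::xtabs(value ~ trial + measure, base)
    bt <- as.matrix(unclass(bt))
    st <- check_baseline_stability(
      bt[, stability_measures(colnames(bt)), drop = FALSE],
      rule = stability_rule)
    if (!st$accepted) {
      msg <- paste0("neurone ", id, " fails the baseline stability screen")
      if (enforce_stability) stop(msg, call. = FALSE) else warning(msg)
    }
    baseline <- colMeans(bt)
    post <- q[q$dose != "predrug", ]
    for (m in unique(post$measure)) {
      for (d in unique(post$dose)) {
        sub <- post[post$measure == m & post$dose == d, ]
        vals <- stats::setNames(sub$value, sub$minute)
        de <- dose_effect(baseline[[m]], vals, measure = m,
                          dose = as.numeric(d))
        out[[length(out) + 1L]] <- data.frame(
          neurone_id = id, group = q$group[1L], measure = m,
          dose = as.numeric(d), baseline = baseline[[m]],
          minute_at_max = de$minute_at_max, raw_at_max = de$raw_at_max,
          max_pct_change = de$max_pct_change)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Analyse a full dosing experiment
#'
#' The complete analysis pipeline for one administration route: quantify
#' every recording, screen and baseline each neurone, compute dose effects,
#' assemble per-group mean +/- SEM dose-response tables, and run the
#' statistical battery -- a one-way repeated-measures ANOVA across dose
#' levels (baseline + each dose, on the raw maximal responses) with
#' Bonferroni-corrected paired t-tests per dose versus baseline, for each
#' measure within each group; Mann-Whitney baseline comparisons between MIA
#' and sham per measure; and two-way (dose x intensity) repeated-measures
#' ANOVAs for the von Frey and heat families.
#'
#' @param recordings List of `spike_recording`s covering >= 1 neurone with 3
#'   predrug trials and a full dose ladder each.
#' @param windows Latency bands.
#' @param include_postdischarge Wind-up convention flag.
#' @param stability_rule Baseline variation rule.
#' @param alpha Significance threshold (default 0.05).
#' @return Object of class `dh_analysis`: list with `quantified`, `effects`,
#'   `dose_response` (per group), `anova` (per group x measure one-way
#'   RM-ANOVA), `paired` (per dose Bonferroni paired t), `family_anova`
#'   (two-way dose x intensity), `baseline_comparison` (Mann-Whitney MIA vs
#'   sham), `alpha`.
#' @export
analyse_experiment <- function(recordings, windows = latency_windows(),
                               include_postdischarge = FALSE,
                               stability_rule = "range", alpha = 0.05) {
  q <- quantify_recordings(recordings, windows, include_postdischarge)
  eff <- neurone_dose_effects(q, stability_rule)
  groups <- intersect(c("sham", "MIA"), unique(eff$group))
  dose_response <- lapply(stats::setNames(groups, groups), function(g)
    assemble_dose_response(eff[eff$group == g, ]))

  anova_rows <- list(); paired_rows <- list(); fam_rows <- list()
  for (g in groups) {
    eg <- eff[eff$group == g, ]
    for (m in unique(eg$measure)) {
      long <- effect_long_table(eg[eg$measure == m, ])
      a <- rm_anova(long, "one_way")
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        group = g, measure = m, a[a$effect == "factor1", , drop = FALSE])
      if (!a$degenerate[1L]) {
        pt <- bonferroni_paired_t(long)
        paired_rows[[length(paired_rows) + 1L]] <-
          data.frame(group = g, measure = m, pt)
      }
    }
    for (fam in c("vf", "heat")) {
      ef <- eg[startsWith(eg$measure, paste0(fam, "_")), ]
      if (!nrow(ef)) next
      long <- effect_long_table(ef)
      long$factor2 <- sub("^[a-z]+_", "", long$measure)
      fa <- rm_anova(long, "two_way")
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(group = g, family = fam,
                                                      fa)
    }
  }

  base_rows <- list()
  if (length(groups) == 2L) {
    b <- unique(eff[c("neurone_id", "group", "measure", "baseline")])
    for (m in unique(b$measure)) {
      x <- b$baseline[b$measure == m & b$group == "MIA"]
      y <- b$baseline[b$measure == m & b$group == "sham"]
      mw <- mann_whitney_u(x, y)
      base_rows[[length(base_rows) + 1L]] <- data.frame(
        measure = m, U = mw$statistic, p_value = mw$p_value,
        n_mia = length(x), n_sham = length(y))
    }
  }

  structure(list(quantified = q, effects = eff, dose_response = dose_response,
                 anova = do.call(rbind, anova_rows),
                 paired = if (length(paired_rows))
                   do.call(rbind, paired_rows) else NULL,
                 family_anova = if (length(fam_rows))
                   do.call(rbind, fam_rows) else NULL,
                 baseline_comparison = if (length(base_rows))
                   do.call(rbind, base_rows) else NULL,
                 alpha = alpha),
            class = "dh_analysis")
}

# long RM table for one measure: baseline level + raw_at_max per dose,
# factor1 ordered baseline < dose1 < dose2 < ...
effect_long_table <- function(eff) {
  doses <- sort(unique(eff$dose))
  base <- unique(eff[c("neurone_id", "measure", "baseline")])
  long <- rbind(
    data.frame(subject = base$neurone_id, measure = base$measure,
               factor1 = "baseline", value = base$baseline),
    data.frame(subject = eff$neurone_id, measure = eff$measure,
               factor1 = as.character(eff$dose), value = eff$raw_at_max))
  long$factor1 <- factor(long$factor1,
                         levels = c("baseline", as.character(doses)))
  long
}

#' @export
print.dh_analysis <- function(x, ...) {
  cat("Dose-response analysis:",
      length(unique(x$effects$neurone_id)), "neurones,",
      length(unique(x$effects$measure)), "measures,",
      length(unique(x$effects$dose)), "doses\n")
  sig <- x$anova[!is.na(x$anova$p_value) & x$anova$p_value < x$alpha, ]
  if (nrow(sig)) {
    cat("Significant main effects of dose (one-way RM-ANOVA, P <",
        x$alpha, "):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s / %-8s F(%d,%d) = %.2f, p = %.4f\n", sig$group[i],
                  sig$measure[i], sig$df1[i], sig$df2[i], sig$F[i],
                  sig$p_value[i]))
  } else cat("No significant main effect of dose in any group/measure.\n")
  invisible(x)
}

#' Significant dose effects flagged by the analysis
#'
#' @param analysis A `dh_analysis`.
#' @return Data frame `group`, `measure`, `significant` (one-way RM-ANOVA
#'   main effect of dose at the analysis alpha).
#' @export
significant_measures <- function(analysis) {
  stopifnot(inherits(analysis, "dh_analysis"))
  a <- analysis$anova
  data.frame(group = a$group, measure = a$measure,
             significant = !is.na(a$p_value) & a$p_value < analysis$alpha)
}

#' Analyse a behavioural cohort
#'
#' Day-14 MIA-versus-sham comparisons per endpoint (Mann-Whitney U) and,
#' post-drug, Kruskal-Wallis across the MIA arms with Dunn's posttest against
#' vehicle at each timepoint.
#'
#' @param records Data frame from [simulate_behaviour_cohort()] (or read via
#'   [read_behaviour_records()]).
#' @param alpha Significance threshold.
#' @return List with `group_comparison` (day-14 MW per endpoint) and
#'   `drug_comparison` (KW + Dunn vs vehicle per endpoint x timepoint).
#' @export
analyse_behaviour <- function(records, alpha = 0.05) {
  endpoints <- c("pwt50", "acetone_freq", "weight_bearing_ipsi")
  grp_rows <- list()
  d14 <- records[records$timepoint == "day14", ]
  if (all(c("MIA", "sham") %in% d14$group)) {
    for (ep in endpoints) {
      mw <- mann_whitney_u(d14[[ep]][d14$group == "MIA"],
                           d14[[ep]][d14$group == "sham"])
      grp_rows[[length(grp_rows) + 1L]] <- data.frame(
        endpoint = ep, U = mw$statistic, p_value = mw$p_value)
    }
  }
  drug_rows <- list()
  arms <- setdiff(unique(records$arm), "sham")
  for (tp in intersect(c("post30", "post60"), unique(records$timepoint))) {
    sub <- records[records$timepoint == tp & records$arm %in% arms, ]
    for (ep in endpoints) {
      gl <- split(sub[[ep]], sub$arm)[arms]
      if (length(gl) < 3L) next
      kw <- kruskal_wallis(gl)
      dn <- dunn_posttest(gl, comparisons = lapply(
        setdiff(arms, "vehicle"), function(a) c("vehicle", a)))
      drug_rows[[length(drug_rows) + 1L]] <- data.frame(
        timepoint = tp, endpoint = ep, H = kw$statistic, kw_p = kw$p_value,
        arm = dn$group2, z = dn$z, p_adjusted = dn$p_adjusted)
    }
  }
  list(group_comparison = if (length(grp_rows)) do.call(rbind, grp_rows)
                          else NULL,
       drug_comparison = if (length(drug_rows)) do.call(rbind, drug_rows)
                         else NULL,
       alpha = alpha)
}
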