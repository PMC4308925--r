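#' Generative parameters for a synthetic dorsal horn neurone
#'
#' Mean evoked spike counts per pulse for each latency band, a saturating
#' wind-up recruitment (gain and time constant in units of stimuli), and
#' monotone rate functions for the natural stimuli (brush rate; linear
#' force coding for von Frey; logistic temperature coding for heat). MIA
#' neurones are hyperexcitable: all rates are scaled by `mia_gain`.
#' Magnitudes are free choices emulating typical wide-dynamic-range firing
#' (C totals of a few hundred spikes per 16-pulse train).
#'
#' @param group `"MIA"` or `"sham"`; MIA applies `mia_gain`.
#' @param mu_abeta,mu_adelta,mu_c,mu_pd Mean spikes per pulse per band (sham).
#' @param windup_gain Dimensionless wind-up gain `w >= 0`.
#' @param windup_tau Wind-up recruitment constant (stimuli).
#' @param brush_rate Brush-evoked rate (spikes/s).
#' @param vf_rate0,vf_slope Von Frey rate intercept (spikes/s) and slope
#'   (spikes/s per g); slope must be >= 0 (graded coding).
#' @param heat_rmax,heat_t50,heat_width Logistic heat coding: max rate
#'   (spikes/s), half-activation temperature (degC), width (degC).
#' @param latency_jitter Reserved latency jitter (ms) for spike placement.
#' @param trial_gain_cv Lognormal sigma of the common excitability gain shared
#'   by all measures within a post-dose trial. Evoked responses drift between
#'   trials well beyond Poisson counting noise; the default 0.15 emulates the
#'   10-20% trial-to-trial variability typical of evoked dorsal horn
#'   responses over an hour-long timecourse.
#' @param mia_gain Multiplicative hyperexcitability factor for MIA neurones.
#' @return Object of class `neurone_params`.
#' @export
neurone_params <- function(group = c("sham", "MIA"),
                           mu_abeta = 8, mu_adelta = 6, mu_c = 12, mu_pd = 4,
                           windup_gain = 0.8, windup_tau = 4,
                           brush_rate = 6, vf_rate0 = 1, vf_slope = 0.12,
                           heat_rmax = 10, heat_t50 = 45, heat_width = 1.5,
                           latency_jitter = 2, trial_gain_cv = 0.15,
                           mia_gain = 1.2) {
  group <- match.arg(group)
  p <- list(group = group, mu_abeta = mu_abeta, mu_adelta = mu_adelta,
            mu_c = mu_c, mu_pd = mu_pd, windup_gain = windup_gain,
            windup_tau = windup_tau, brush_rate = brush_rate,
            vf_rate0 = vf_rate0, vf_slope = vf_slope, heat_rmax = heat_rmax,
            heat_t50 = heat_t50, heat_width = heat_width,
            latency_jitter = latency_jitter, trial_gain_cv = trial_gain_cv,
            mia_gain = mia_gain)
  rates <- c("mu_abeta", "mu_adelta", "mu_c", "mu_pd", "brush_rate",
             "vf_rate0", "vf_slope", "heat_rmax")
  if (group == "MIA") for (nm in rates) p[[nm]] <- p[[nm]] * mia_gain
  if (any(unlist(p[rates]) < 0) || p$windup_gain < 0 || p$windup_tau <= 0)
    stop("rates must be >= 0, windup_gain >= 0, windup_tau > 0", call. = FALSE)
  structure(p, class = "neurone_params")
}

#' Natural-stimulus firing rate implied by neurone parameters
#'
#' Monotone nondecreasing in von Frey force and heat temperature.
#'
#' @param params A `neurone_params`.
#' @param stimulus A `natural_stimulus`.
#' @return Firing rate in spikes/s.
#' @export
natural_rate <- function(params, stimulus) {
  switch(stimulus$modality,
         brush = params$brush_rate,
         von_frey = params$vf_rate0 + params$vf_slope * stimulus$magnitude,
         heat = params$heat_rmax *
           stats::plogis((stimulus$magnitude - params$heat_t50) /
                         params$heat_width))
}

# wind-up recruitment factor for pulse i (1-based): 1 + w (1 - exp(-(i-1)/tau))
windup_factor <- function(params, i) {
  1 + params$windup_gain * (1 - exp(-(i - 1) / params$windup_tau))
}

#' State-dependent drug inhibition model
#'
#' Phenomenological Hill-type binomial thinning: the fraction of evoked
#' spikes suppressed at a dose is
#' `f_max * dose^hill / (dose^hill + ed50^hill) * state_factor[group]`.
#' The group-dependent state factor captures state-dependent efficacy:
#' inhibition is conditional on the hyperexcitable (MIA) condition, with the
#' sham factor a small fraction of the MIA factor.
#'
#' @param f_max Maximal inhibited fraction in `[0, 1]`.
#' @param ed50 Half-maximal dose (same units as the schedule's doses).
#' @param hill Hill exponent (> 0).
#' @param s_mia,s_sham State factors in `[0, 1]` for MIA and sham.
#' @return Object of class `drug_model`.
#' @export
drug_model <- function(f_max = 0.7, ed50 = 30, hill = 1.5,
                       s_mia = 1, s_sham = 0.1) {
  stopifnot(f_max >= 0, f_max <= 1, ed50 > 0, hill > 0,
            s_mia >= 0, s_mia <= 1, s_sham >= 0, s_sham <= 1)
  structure(list(f_max = f_max, ed50 = ed50, hill = hill,
                 state_factor = c(MIA = s_mia, sham = s_sham)),
            class = "drug_model")
}

#' Inhibited fraction at a dose for a group
#'
#' @param drug A `drug_model`.
#' @param dose Dose quantity (0 for vehicle/predrug).
#' @param group `"MIA"` or `"sham"`.
#' @return Fraction in `[0, 1)`.
#' @export
inhibition_fraction <- function(drug, dose, group) {
  stopifnot(inherits(drug, "drug_model"), dose >= 0)
  group <- match.arg(group, c("MIA", "sham"))
  if (dose == 0) return(0)
  d <- dose^drug$hill
  unname(drug$f_max * d / (d + drug$ed50^drug$hill) *
           drug$state_factor[[group]])
}

# Draw per-pulse band counts: Poisson around lambda, or, for low-variability
# baseline trials, deterministic rounding of the quantised expectation times
# the common trial factor. Quantising first keeps counts <= 25 constant at a
# +/-2% factor, bounding every measure's trial-to-trial variation below the
# stability thresholds.
draw_counts <- function(lambda, stable_factor = NULL) {
  if (is.null(stable_factor)) stats::rpois(length(lambda), lambda)
  else as.integer(round(round(lambda) * stable_factor))
}

#' Simulate one electrical-train recording
#'
#' Per pulse `i`, the C-band count is Poisson with mean
#' `mu_c (1 - inhibition) (1 + w (1 - exp(-(i-1)/tau)))`; the A-bands are
#' non-potentiating Poisson and the postdischarge count follows the same
#' wind-up factor as the C band. Spike latencies are drawn uniformly within
#' each latency window and added to the pulse onsets.
#'
#' @param params A `neurone_params`.
#' @param inhibition Inhibited fraction in `[0, 1)`.
#' @param protocol An electrical `train_protocol`.
#' @param windows A `latency_windows`.
#' @param stable_factor If non-`NULL`, counts are the deterministic rounding
#'   of `lambda * stable_factor` (used for low-variability baseline trials).
#' @param gain Common excitability gain multiplying every band's mean count
#'   (trial-level drift; drawn by [simulate_timecourse()]).
#' @param neurone_id,route,dose,minute,trial Metadata for the recording.
#' @return A `spike_recording`.
#' @export
simulate_electrical_train <- function(params, inhibition = 0,
                                      protocol = electrical_train_protocol(),
                                      windows = latency_windows(),
                                      stable_factor = NULL, gain = 1,
                                      neurone_id = "n1", route = NA_character_,
                                      dose = "predrug", minute = NA_real_,
                                      trial = 1L) {
  stopifnot(inherits(params, "neurone_params"))
  if (!is.finite(inhibition) || inhibition < 0 || inhibition >= 1)
    stop("inhibition must lie in [0, 1)", call. = FALSE)
  onsets <- stimulus_onsets(protocol)
  n <- protocol$n_pulses
  wu <- windup_factor(params, seq_len(n))
  thin <- (1 - inhibition) * gain
  lam <- cbind(abeta = rep(params$mu_abeta * thin, n),
               adelta = rep(params$mu_adelta * thin, n),
               c = params$mu_c * thin * wu,
               postdischarge = params$mu_pd * thin * wu)
  spikes <- numeric(0)
  w <- unclass(windows)
  for (b in seq_len(4L)) {
    cnt <- draw_counts(lam[, b], stable_factor)
    if (sum(cnt) == 0) next
    lo <- w[[b]][1]; hi <- w[[b]][2]
    lat <- stats::runif(sum(cnt), lo, hi)
    spikes <- c(spikes, rep(onsets, cnt) + lat)
  }
  spike_recording(neurone_id, params$group, onsets, sort(spikes),
                  protocol, route, dose, minute, trial)
}

#' Simulate one natural-stimulus recording
#'
#' The evoked count over the application window is Poisson with mean
#' `rate * duration * (1 - inhibition)`; spike times are uniform within the
#' window.
#'
#' @inheritParams simulate_electrical_train
#' @param stimulus A `natural_stimulus`.
#' @return A `spike_recording`.
#' @export
simulate_natural_recording <- function(params, stimulus, inhibition = 0,
                                       stable_factor = NULL, gain = 1,
                                       neurone_id = "n1",
                                       route = NA_character_,
                                       dose = "predrug", minute = NA_real_,
                                       trial = 1L) {
  stopifnot(inherits(params, "neurone_params"),
            inherits(stimulus, "natural_stimulus"))
  if (!is.finite(inhibition) || inhibition < 0 || inhibition >= 1)
    stop("inhibition must lie in [0, 1)", call. = FALSE)
  lam <- natural_rate(params, stimulus) * stimulus$duration_s *
    (1 - inhibition) * gain
  cnt <- draw_counts(lam, stable_factor)
  spikes <- sort(stats::runif(cnt, 0, stimulus$duration_s * 1000))
  spike_recording(neurone_id, params$group, 0, spikes, stimulus,
                  route, dose, minute, trial)
}

# the standard natural-stimulus battery applied each testing cycle
natural_battery <- function() {
  c(list(natural_stimulus("brush")),
    lapply(c(2, 8, 26, 60), function(g) natural_stimulus("von_frey", g)),
    lapply(c(40, 45, 48), function(t) natural_stimulus("heat", t)))
}

# one full testing cycle: electrical train + the natural battery
simulate_trial <- function(params, inhibition, protocol, windows,
                           stable_factor, gain, neurone_id, route, dose,
                           minute, trial) {
  recs <- list(simulate_electrical_train(params, inhibition, protocol, windows,
                                         stable_factor, gain, neurone_id,
                                         route, dose, minute, trial))
  for (st in natural_battery())
    recs[[length(recs) + 1L]] <-
      simulate_natural_recording(params, st, inhibition, stable_factor, gain,
                                 neurone_id, route, dose, minute, trial)
  recs
}

#' Simulate a neurone's full dosing timecourse
#'
#' Three predrug control trials (no inhibition, trial-to-trial variability
#' held below the stability thresholds by a small common multiplicative
#' factor per trial), then, for each dose of the cumulative ladder, one fully
#' stochastic trial per post-dose test minute at the state-dependent
#' inhibited fraction.
#'
#' @param params A `neurone_params`.
#' @param drug A `drug_model`.
#' @param schedule A `dose_schedule`.
#' @param neurone_id Identifier.
#' @param protocol,windows Stimulation protocol and latency bands.
#' @param baseline_jitter Half-width of the uniform baseline trial factor
#'   (default 0.02, keeping C variation well under the 10% screen).
#' @return List of `spike_recording`s (3 baseline cycles + one cycle per dose
#'   x test minute, each cycle = electrical train + natural battery).
#' @export
simulate_timecourse <- function(params, drug, schedule, neurone_id = "n1",
                                protocol = electrical_train_protocol(),
                                windows = latency_windows(),
                                baseline_jitter = 0.02) {
  stopifnot(inherits(drug, "drug_model"), inherits(schedule, "dose_schedule"))
  recs <- list()
  for (t in 1:3) {
    f <- 1 + stats::runif(1, -baseline_jitter, baseline_jitter)
    recs <- c(recs, simulate_trial(params, 0, protocol, windows, f, 1,
                                   neurone_id, schedule$route, "predrug",
                                   NA_real_, t))
  }
  for (d in schedule$doses) {
    inh <- inhibition_fraction(drug, d, params$group)
    for (m in schedule$test_minutes) {
      g <- exp(stats::rnorm(1, 0, params$trial_gain_cv))
      recs <- c(recs, simulate_trial(params, inh, protocol, windows, NULL, g,
                                     neurone_id, schedule$route,
                                     as.character(d), m, 1L))
    }
  }
  recs
}

#' Configuration of a synthetic MIA/sham cohort
#'
#' Cohort sizes follow the study layout: 6 sham and 7 MIA neurones for the
#' spinal route, 6 and 5 for the systemic route, 5 animals per behavioural
#' arm. Between-neurone heterogeneity is lognormal on the rate parameters.
#' Behavioural arms are parameterised by group log10-threshold means, an
#' acetone withdrawal probability per trial, and the mean ipsilateral
#' weight-bearing fraction.
#'
#' @param seed Master seed (mandatory).
#' @param route `"spinal"` or `"systemic"` (sets default cohort sizes).
#' @param n_mia,n_sham Neurones per group (defaults by route).
#' @param n_animals Animals per behavioural arm.
#' @param neurone_cv Lognormal sigma for between-neurone rate heterogeneity.
#' @param mu_log_pwt_sham,mu_log_pwt_mia Group means of animal log10
#'   thresholds (g); defaults 10^1.08 ~ 12 g and 1.4 g.
#' @param sd_log_pwt Between-animal SD of log10 threshold.
#' @param psycho_slope Spread of the logistic psychometric in log10-force.
#' @param acetone_p_mia,acetone_p_sham Per-trial withdrawal probability.
#' @param wb_mean_mia,wb_mean_sham Mean ipsilateral weight-bearing fraction.
#' @param wb_sd Between-animal SD of the fraction.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(seed, route = c("spinal", "systemic"),
                          n_mia = NULL, n_sham = NULL, n_animals = 5,
                          neurone_cv = 0.15,
                          mu_log_pwt_sham = log10(12),
                          mu_log_pwt_mia = log10(1.4),
                          sd_log_pwt = 0.12, psycho_slope = 0.06,
                          acetone_p_mia = 0.8, acetone_p_sham = 0.04,
                          wb_mean_mia = 0.40, wb_mean_sham = 0.50,
                          wb_sd = 0.02) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a master seed is mandatory", call. = FALSE)
  route <- match.arg(route)
  if (is.null(n_mia)) n_mia <- if (route == "spinal") 7L else 5L
  if (is.null(n_sham)) n_sham <- 6L
  stopifnot(n_mia >= 1, n_sham >= 1, n_animals >= 1)
  structure(list(seed = as.integer(seed), route = route,
                 n_mia = as.integer(n_mia), n_sham = as.integer(n_sham),
                 n_animals = as.integer(n_animals), neurone_cv = neurone_cv,
                 mu_log_pwt_sham = mu_log_pwt_sham,
                 mu_log_pwt_mia = mu_log_pwt_mia, sd_log_pwt = sd_log_pwt,
                 psycho_slope = psycho_slope, acetone_p_mia = acetone_p_mia,
                 acetone_p_sham = acetone_p_sham, wb_mean_mia = wb_mean_mia,
                 wb_mean_sham = wb_mean_sham, wb_sd = wb_sd),
            class = "cohort_config")
}

# lognormal jitter of a neurone's rate parameters around the group defaults
jitter_params <- function(group, cv) {
  base <- neurone_params(group)
  for (nm in c("mu_abeta", "mu_adelta", "mu_c", "mu_pd", "brush_rate",
               "vf_rate0", "vf_slope", "heat_rmax"))
    base[[nm]] <- base[[nm]] * exp(stats::rnorm(1, 0, cv))
  base
}

#' Simulate a full electrophysiology cohort
#'
#' Generates the complete MIA/sham dosing experiment for one administration
#' route: per neurone, between-neurone parameter heterogeneity plus a full
#' [simulate_timecourse()]. Fully deterministic given the config seed.
#'
#' @param config A `cohort_config`.
#' @param drug A `drug_model` (defaults: Hill thinning with ed50 matched to
#'   the route's dose ladder).
#' @param schedule A `dose_schedule` (defaults to the config's route).
#' @return List of `spike_recording`s.
#' @export
simulate_cohort <- function(config, drug = NULL, schedule = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(schedule)) schedule <- dose_schedule(config$route)
  if (is.null(drug))
    drug <- drug_model(ed50 = if (config$route == "spinal") 30 else 8)
  set.seed(config$seed)
  recs <- list()
  for (g in c("sham", "MIA")) {
    n <- if (g == "MIA") config$n_mia else config$n_sham
    for (i in seq_len(n)) {
      p <- jitter_params(g, config$neurone_cv)
      id <- sprintf("%s_%02d", g, i)
      recs <- c(recs, simulate_timecourse(p, drug, schedule, id))
    }
  }
  recs
}

#' Simulate a behavioural pharmacology cohort
#'
#' Day-14 predrug records for sham animals and three MIA arms (vehicle, low
#' and high systemic dose, `n_animals` each), then post-drug records at 30
#' and 60 min for the MIA arms. Each animal has a latent log10 withdrawal
#' threshold; withdrawal at a filament is Bernoulli through a logistic
#' psychometric in log-force, and the 50% threshold is estimated by the
#' up-down staircase exactly as for real data. Acetone withdrawals are
#' Bernoulli per trial; weight-bearing comes from triplicate noisy readings
#' per limb. Drug shifts MIA thresholds toward the sham mean (and the acetone
#' probability toward the sham probability) by the inhibited fraction;
#' weight-bearing asymmetry is left uncorrected.
#'
#' @param config A `cohort_config`.
#' @param drug A `drug_model` for the systemic behavioural doses (default
#'   ed50 8 mg/kg).
#' @param doses Behavioural dose arms in mg/kg (default 3 and 30).
#' @return Data frame of behavioural records: `animal_id`, `group`, `arm`,
#'   `timepoint`, `pwt50`, `acetone_freq`, `weight_bearing_ipsi`.
#' @export
simulate_behaviour_cohort <- function(config, drug = drug_model(ed50 = 8),
                                      doses = c(3, 30)) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  arms <- c("sham", "vehicle", paste0(doses, "mg/kg"))
  arm_dose <- c(0, 0, doses)
  rows <- list()
  hind_load <- 150  # combined hindlimb load (g) on the incapacitance tester
  for (a in seq_along(arms)) {
    arm <- arms[a]
    grp <- if (arm == "sham") "sham" else "MIA"
    mu <- if (grp == "sham") config$mu_log_pwt_sham else config$mu_log_pwt_mia
    p_ac <- if (grp == "sham") config$acetone_p_sham else config$acetone_p_mia
    wb_mu <- if (grp == "sham") config$wb_mean_sham else config$wb_mean_mia
    for (i in seq_len(config$n_animals)) {
      id <- sprintf("%s_%02d", gsub("/", "", arm), i)
      theta <- stats::rnorm(1, mu, config$sd_log_pwt)
      timepoints <- if (grp == "sham") "day14"
                    else c("day14", "post30", "post60")
      for (tp in timepoints) {
        inh <- if (tp == "day14") 0
               else inhibition_fraction(drug, arm_dose[a], "MIA")
        th <- theta + inh * (config$mu_log_pwt_sham - theta)
        responder <- function(force)
          stats::runif(1) < stats::plogis((log10(force) - th) /
                                          config$psycho_slope)
        sess <- run_updown(responder)
        p_now <- p_ac * (1 - inh) + config$acetone_p_sham * inh
        ac <- acetone_frequency(stats::rbinom(1, 5, p_now))
        frac <- min(max(stats::rnorm(1, wb_mu, config$wb_sd), 0.05), 0.95)
        ipsi <- stats::rnorm(3, frac * hind_load, 2)
        contra <- stats::rnorm(3, (1 - frac) * hind_load, 2)
        wb <- weight_bearing_percent(pmax(ipsi, 1), pmax(contra, 1))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = grp, arm = arm, timepoint = tp,
          pwt50 = sess$pwt50, acetone_freq = ac, weight_bearing_ipsi = wb)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
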