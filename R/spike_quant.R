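#' A spike train recorded against a stimulation protocol
#'
#' Container for one trial's extracellular recording from a deep dorsal horn
#' (wide dynamic range) neurone: absolute spike times on the same clock as the
#' stimulus onsets, plus the experimental metadata needed downstream (group,
#' administration route, dose, post-dose minute, trial index).
#'
#' @param neurone_id Identifier (character).
#' @param group `"MIA"` or `"sham"`.
#' @param onsets Stimulus onset times in ms, sorted ascending. Electrical
#'   recordings have one onset per pulse; natural-stimulus recordings have a
#'   single application onset.
#' @param spikes Spike times in ms (absolute, same clock as `onsets`), sorted.
#' @param stimulus A `train_protocol` or `natural_stimulus`.
#' @param route Administration route (or `NA` before dosing studies).
#' @param dose Dose quantity, or `"predrug"`.
#' @param minute Post-dose minute (`NA` for predrug trials).
#' @param trial Trial index within its (dose, minute) context.
#' @return An object of class `spike_recording`.
#' @export
spike_recording <- function(neurone_id, group = c("MIA", "sham"),
                            onsets, spikes, stimulus,
                            route = NA_character_, dose = "predrug",
                            minute = NA_real_, trial = 1L) {
  group <- match.arg(group)
  onsets <- as.numeric(onsets); spikes <- as.numeric(spikes)
  if (!inherits(stimulus, "train_protocol") &&
      !inherits(stimulus, "natural_stimulus"))
    stop("stimulus must be a train_protocol or natural_stimulus", call. = FALSE)
  rec <- structure(list(neurone_id = as.character(neurone_id), group = group,
                        route = route, dose = dose, minute = minute,
                        trial = as.integer(trial),
                        onsets = onsets, spikes = spikes, stimulus = stimulus),
                   class = "spike_recording")
  validate_spike_recording(rec)
}

validate_spike_recording <- function(rec) {
  stopifnot(inherits(rec, "spike_recording"))
  for (fld in c("onsets", "spikes")) {
    x <- rec[[fld]]
    if (any(!is.finite(x)) || any(x < 0))
      stop(fld, " must be finite and >= 0 ms", call. = FALSE)
    if (is.unsorted(x)) stop(fld, " must be sorted ascending", call. = FALSE)
  }
  if (inherits(rec$stimulus, "train_protocol") &&
      length(rec$onsets) != rec$stimulus$n_pulses)
    stop("electrical recording must carry one onset per pulse", call. = FALSE)
  if (inherits(rec$stimulus, "natural_stimulus") && length(rec$onsets) != 1L)
    stop("natural-stimulus recording must carry a single application onset",
         call. = FALSE)
  rec
}

is_electrical <- function(rec) inherits(rec$stimulus, "train_protocol")

#' @export
print.spike_recording <- function(x, ...) {
  kind <- if (is_electrical(x)) "electrical" else x$stimulus$modality
  cat(sprintf("Spike recording %s [%s, %s]: %d spikes, %d onsets (%s), dose %s\n",
              x$neurone_id, x$group,
              if (is.na(x$route)) "no route" else x$route,
              length(x$spikes), length(x$onsets), kind, format(x$dose)))
  invisible(x)
}

# Per-spike latency relative to the nearest preceding onset; spikes before the
# first onset get latency NA (never counted).
spike_latencies <- function(rec) {
  idx <- findInterval(rec$spikes, rec$onsets)
  lat <- rec$spikes - rec$onsets[pmax(idx, 1L)]
  lat[idx == 0L] <- NA_real_
  list(pulse = idx, latency = lat)
}

#' Post-stimulus time histogram
#'
#' Pools spike latencies over all pulses of an electrical train into latency
#' bins covering `[0, 800)` ms.
#'
#' @param recording An electrical `spike_recording`.
#' @param bin_width Bin width in ms; must divide 800 evenly.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
build_psth <- function(recording, bin_width = 10) {
  validate_spike_recording(recording)
  if (!is_electrical(recording))
    stop("build_psth requires an electrical recording", call. = FALSE)
  if (bin_width <= 0 || abs(800 / bin_width - round(800 / bin_width)) > 1e-9)
    stop("bin_width must divide 800 ms evenly", call. = FALSE)
  lat <- spike_latencies(recording)$latency
  lat <- lat[!is.na(lat) & lat >= 0 & lat < 800]
  breaks <- seq(0, 800, by = bin_width)
  nbin <- length(breaks) - 1L
  counts <- tabulate(floor(lat / bin_width) + 1L, nbins = nbin)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = as.integer(counts))
}

#' Latency-band spike counts for an electrical train
#'
#' Classifies every spike by its latency relative to the nearest preceding
#' pulse onset into the Abeta, Adelta, C or postdischarge band (half-open
#' windows). Spikes later than the postdischarge window (or before the first
#' pulse) are not counted.
#'
#' @param recording An electrical `spike_recording`.
#' @param windows A `latency_windows` object.
#' @return An object of class `band_counts`: list with `per_stimulus`
#'   (n_pulses x 4 integer matrix) and `totals` (named band totals).
#' @export
band_counts <- function(recording, windows = latency_windows()) {
  validate_spike_recording(recording)
  validate_latency_windows(windows)
  if (!is_electrical(recording))
    stop("band_counts requires an electrical recording", call. = FALSE)
  n <- recording$stimulus$n_pulses
  bands <- names(unclass(windows))
  m <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, bands))
  sl <- spike_latencies(recording)
  keep <- !is.na(sl$latency)
  if (any(keep)) {
    edges <- window_edges(windows)
    band <- findInterval(sl$latency[keep], edges)   # 1..4 inside, 0/5 outside
    pulse <- sl$pulse[keep]
    inside <- band >= 1L & band <= 4L
    if (any(inside)) {
      tab <- table(factor(pulse[inside], levels = seq_len(n)),
                   factor(band[inside], levels = 1:4))
      m <- matrix(as.integer(tab), nrow = n, dimnames = list(NULL, bands))
    }
  }
  structure(list(per_stimulus = m, totals = colSums(m)), class = "band_counts")
}

#' @export
print.band_counts <- function(x, ...) {
  cat("Band totals over", nrow(x$per_stimulus), "pulses:\n")
  print(x$totals)
  invisible(x)
}

#' The 'input' measure of non-potentiated afferent drive
#'
#' Number of action potentials evoked in the C-fibre latency band by the first
#' pulse of the train, multiplied by the number of pulses (16 under the default
#' protocol). Indexes the baseline C-fibre evoked response before any
#' activity-dependent potentiation.
#'
#' @param bc A `band_counts` object.
#' @param n_pulses Number of pulses in the train (default: rows of
#'   `per_stimulus`).
#' @return Integer count.
#' @export
input_measure <- function(bc, n_pulses = nrow(bc$per_stimulus)) {
  stopifnot(inherits(bc, "band_counts"))
  if (nrow(bc$per_stimulus) < 1L)
    stop("empty per-stimulus matrix", call. = FALSE)
  if (n_pulses < 1L) stop("n_pulses must be >= 1", call. = FALSE)
  as.integer(bc$per_stimulus[1L, "c"] * n_pulses)
}

#' The 'wind-up' measure of activity-dependent potentiation
#'
#' Total C-fibre-evoked action potentials over the train minus the input
#' measure. Positive wind-up is the frequency-dependent incremental increase
#' in firing to repeated constant C-fibre stimulation (a model of temporal
#' summation / central sensitisation); a habituating neurone yields a negative
#' value, which is not clamped.
#'
#' @param bc A `band_counts` object.
#' @param n_pulses Number of pulses in the train.
#' @param include_postdischarge If `TRUE`, the postdischarge total is added to
#'   the C total before subtracting input (alternative laboratory convention).
#' @return Integer count (may be negative).
#' @export
windup_measure <- function(bc, n_pulses = nrow(bc$per_stimulus),
                           include_postdischarge = FALSE) {
  stopifnot(inherits(bc, "band_counts"))
  total <- bc$totals[["c"]] +
    if (isTRUE(include_postdischarge)) bc$totals[["postdischarge"]] else 0L
  as.integer(total - input_measure(bc, n_pulses))
}

#' Evoked count for a natural stimulus
#'
#' Counts spikes within the 10 s application window of a brush, von Frey or
#' heat stimulus. No spontaneous-rate subtraction is applied; the raw window
#' count is the response measure.
#'
#' @param recording A natural-stimulus `spike_recording` (single onset).
#' @return List of class `natural_response` with `stimulus` and `evoked_count`.
#' @export
natural_evoked_count <- function(recording) {
  validate_spike_recording(recording)
  if (is_electrical(recording))
    stop("natural_evoked_count requires a natural-stimulus recording",
         call. = FALSE)
  onset <- recording$onsets[1L]
  win <- recording$stimulus$duration_s * 1000
  n <- sum(recording$spikes >= onset & recording$spikes < onset + win)
  structure(list(stimulus = recording$stimulus, evoked_count = as.integer(n)),
            class = "natural_response")
}

#' @export
print.natural_response <- function(x, ...) {
  cat(sprintf("%s response: %d spikes in %g s\n", x$stimulus$modality,
              x$evoked_count, x$stimulus$duration_s))
  invisible(x)
}

#' Summarise an electrical-train recording
#'
#' Chains [band_counts()], [input_measure()] and [windup_measure()] into the
#' per-neurone electrical response summary (band totals, input, wind-up).
#'
#' @inheritParams band_counts
#' @param include_postdischarge Passed to [windup_measure()].
#' @return Object of class `electrical_summary`: named list with
#'   `abeta_total`, `adelta_total`, `c_total`, `pd_total`, `input`, `windup`.
#' @export
summarise_electrical <- function(recording, windows = latency_windows(),
                                 include_postdischarge = FALSE) {
  bc <- band_counts(recording, windows)
  n <- recording$stimulus$n_pulses
  structure(list(abeta_total = bc$totals[["abeta"]],
                 adelta_total = bc$totals[["adelta"]],
                 c_total = bc$totals[["c"]],
                 pd_total = bc$totals[["postdischarge"]],
                 input = input_measure(bc, n),
                 windup = windup_measure(bc, n, include_postdischarge)),
            class = "electrical_summary")
}

#' @export
print.electrical_summary <- function(x, ...) {
  cat(sprintf("Abeta %d | Adelta %d | C %d | PD %d | input %d | wind-up %d\n",
              x$abeta_total, x$adelta_total, x$c_total, x$pd_total,
              x$input, x$windup))
  invisible(x)
}
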