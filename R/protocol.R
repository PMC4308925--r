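#' Electrical train stimulation protocol
#'
#' Constructs the transcutaneous electrical stimulation protocol used to evoke
#' dorsal horn responses: a train of square pulses delivered at a multiple of
#' the C-fibre activation threshold current. The default is the standard
#' 16-pulse, 2 ms, 0.5 Hz train at three times C-fibre threshold.
#'
#' @param n_pulses Number of pulses in the train (>= 1).
#' @param pulse_width Pulse width in ms (> 0).
#' @param frequency Stimulation frequency in Hz (> 0).
#' @param intensity_multiple Stimulus intensity as a dimensionless multiple of
#'   the C-fibre threshold current.
#' @return An object of class `train_protocol`.
#' @examples
#' p <- electrical_train_protocol()
#' stimulus_onsets(p)
#' @export
electrical_train_protocol <- function(n_pulses = 16, pulse_width = 2,
                                      frequency = 0.5, intensity_multiple = 3) {
  p <- structure(list(n_pulses = as.integer(n_pulses),
                      pulse_width = as.numeric(pulse_width),
                      frequency = as.numeric(frequency),
                      intensity_multiple = as.numeric(intensity_multiple)),
                 class = "train_protocol")
  validate_train_protocol(p)
}

validate_train_protocol <- function(p) {
  stopifnot(inherits(p, "train_protocol"))
  if (length(p$n_pulses) != 1L || is.na(p$n_pulses) || p$n_pulses < 1L)
    stop("n_pulses must be a single integer >= 1", call. = FALSE)
  if (!is.finite(p$pulse_width) || p$pulse_width <= 0)
    stop("pulse_width must be > 0 ms", call. = FALSE)
  if (!is.finite(p$frequency) || p$frequency <= 0)
    stop("frequency must be > 0 Hz", call. = FALSE)
  if (!is.finite(p$intensity_multiple) || p$intensity_multiple <= 0)
    stop("intensity_multiple must be > 0", call. = FALSE)
  p
}

#' @export
print.train_protocol <- function(x, ...) {
  cat(sprintf("Electrical train: %d pulses, %g ms wide, %g Hz, %gx C-fibre threshold\n",
              x$n_pulses, x$pulse_width, x$frequency, x$intensity_multiple))
  invisible(x)
}

#' Pulse onset times of an electrical train
#'
#' @param protocol A `train_protocol`.
#' @return Numeric vector of onset times in ms; the first pulse is at 0 and
#'   consecutive pulses are separated by `1000 / frequency` ms.
#' @export
stimulus_onsets <- function(protocol) {
  validate_train_protocol(protocol)
  (seq_len(protocol$n_pulses) - 1) * (1000 / protocol$frequency)
}

#' Latency windows separating afferent fibre classes
#'
#' Post-stimulus latency bands used to attribute evoked spikes to afferent
#' classes by conduction latency: Abeta (fast myelinated), Adelta, C
#' (unmyelinated) and the postdischarge that outlasts C-fibre latency.
#' All windows are half-open `[lo, hi)` in ms so every spike falls in exactly
#' one band; bands must be contiguous, non-overlapping and ordered.
#'
#' @param abeta,adelta,cband,postdischarge Length-2 numeric `c(lo, hi)` in ms
#'   (the C-fibre band is named `cband` here; it is stored as `c`).
#' @return An object of class `latency_windows`.
#' @export
latency_windows <- function(abeta = c(0, 20), adelta = c(20, 90),
                            cband = c(90, 350), postdischarge = c(350, 800)) {
  w <- structure(list(abeta = as.numeric(abeta), adelta = as.numeric(adelta),
                      c = as.numeric(cband), postdischarge = as.numeric(postdischarge)),
                 class = "latency_windows")
  validate_latency_windows(w)
}

validate_latency_windows <- function(w) {
  stopifnot(inherits(w, "latency_windows"))
  for (b in w) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] >= b[2])
      stop("each latency window must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  edges <- window_edges(w)
  if (any(diff(edges) <= 0))
    stop("latency windows must be ordered and non-degenerate", call. = FALSE)
  # contiguity: each window starts where the previous ends
  hi <- vapply(w, `[`, numeric(1), 2L)
  lo <- vapply(w, `[`, numeric(1), 1L)
  if (any(abs(hi[-length(hi)] - lo[-1]) > sqrt(.Machine$double.eps)))
    stop("latency windows must be contiguous (no gap or overlap)", call. = FALSE)
  w
}

# break points lo1, hi1(=lo2), ..., hi4 for findInterval classification
window_edges <- function(w) {
  c(w$abeta[1], w$abeta[2], w$adelta[2], w$c[2], w$postdischarge[2])
}

#' @export
print.latency_windows <- function(x, ...) {
  cat("Latency bands (ms, half-open):\n")
  for (nm in names(x))
    cat(sprintf("  %-13s [%g, %g)\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Natural (non-electrical) stimulus descriptor
#'
#' Dynamic brush, graded punctate von Frey filaments (2, 8, 26, 60 g) or
#' contact heat (40, 45, 48 degrees C), each applied for 10 s to the
#' peripheral receptive field.
#'
#' @param modality One of `"brush"`, `"von_frey"`, `"heat"`.
#' @param magnitude Force in g (von Frey) or temperature in degrees C (heat);
#'   must be `NA` for brush. Must come from the protocol's graded set unless
#'   `strict = FALSE`.
#' @param duration_s Application duration in seconds (default 10).
#' @param strict Enforce membership of `magnitude` in the protocol set.
#' @return An object of class `natural_stimulus`.
#' @export
natural_stimulus <- function(modality = c("brush", "von_frey", "heat"),
                             magnitude = NA_real_, duration_s = 10,
                             strict = TRUE) {
  modality <- match.arg(modality)
  magnitude <- as.numeric(magnitude)
  if (modality == "brush") {
    if (!is.na(magnitude)) stop("brush has no magnitude", call. = FALSE)
  } else {
    if (is.na(magnitude)) stop("magnitude required for ", modality, call. = FALSE)
    sets <- list(von_frey = c(2, 8, 26, 60), heat = c(40, 45, 48))
    if (strict && !magnitude %in% sets[[modality]])
      stop(sprintf("magnitude %g not in the %s protocol set (%s)", magnitude,
                   modality, paste(sets[[modality]], collapse = ", ")),
           call. = FALSE)
  }
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  structure(list(modality = modality, magnitude = magnitude,
                 duration_s = as.numeric(duration_s)),
            class = "natural_stimulus")
}

#' @export
print.natural_stimulus <- function(x, ...) {
  unit <- switch(x$modality, von_frey = " g", heat = " degC", "")
  mag <- if (is.na(x$magnitude)) "" else paste0(" ", x$magnitude, unit)
  cat(sprintf("Natural stimulus: %s%s, %g s\n", x$modality, mag, x$duration_s))
  invisible(x)
}

#' Cumulative dosing schedule
#'
#' Encodes a cumulative dose ladder with post-dose test times. The standard
#' schedules are topical spinal dosing at 10, 50 and 100 ug and systemic
#' (subcutaneous) 3 and 30 mg/kg, each dose followed for an hour with trials
#' at 10, 30 and 50 min before the next dose; behavioural dosing is a single
#' intraperitoneal injection tested at 30 and 60 min.
#'
#' @param route One of `"spinal"`, `"systemic"`, `"intraperitoneal"`.
#' @param doses Strictly increasing dose ladder; defaults by route
#'   (spinal: 10, 50, 100 ug; otherwise 3, 30 mg/kg).
#' @param test_minutes Post-dose test times in minutes, within `[0, 60]`.
#' @param cycle_minutes Trial cycle length in minutes.
#' @param cumulative Logical; doses applied cumulatively.
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(route = c("spinal", "systemic", "intraperitoneal"),
                          doses = NULL, test_minutes = NULL,
                          cycle_minutes = 20, cumulative = TRUE) {
  route <- match.arg(route)
  if (is.null(doses))
    doses <- if (route == "spinal") c(10, 50, 100) else c(3, 30)
  if (is.null(test_minutes))
    test_minutes <- if (route == "intraperitoneal") c(30, 60) else c(10, 30, 50)
  doses <- as.numeric(doses)
  test_minutes <- as.numeric(test_minutes)
  if (length(doses) < 1L || any(!is.finite(doses)) || any(diff(doses) <= 0) ||
      any(doses <= 0))
    stop("doses must be a strictly increasing positive ladder", call. = FALSE)
  if (any(test_minutes < 0 | test_minutes > 60))
    stop("test_minutes must lie in [0, 60]", call. = FALSE)
  structure(list(route = route, doses = doses,
                 dose_unit = if (route == "spinal") "ug" else "mg/kg",
                 test_minutes = test_minutes,
                 cycle_minutes = as.numeric(cycle_minutes),
                 cumulative = isTRUE(cumulative)),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("Dose schedule (%s): %s %s%s; tests at %s min\n", x$route,
              paste(x$doses, collapse = ", "), x$dose_unit,
              if (x$cumulative) " (cumulative)" else "",
              paste(x$test_minutes, collapse = ", ")))
  invisible(x)
}

#' Serialise a protocol to a flat key=value config file
#'
#' @param protocol A `train_protocol`.
#' @param path File to write.
#' @export
write_protocol_config <- function(protocol, path) {
  validate_train_protocol(protocol)
  lines <- sprintf("%s=%s", names(unclass(protocol)),
                   vapply(unclass(protocol), format, character(1)))
  writeLines(c("# electrical train protocol", lines), path)
  invisible(path)
}

#' Read a protocol from a flat key=value config file
#'
#' @param path File written by [write_protocol_config()].
#' @return A `train_protocol`.
#' @export
read_protocol_config <- function(path) {
  kv <- read_flat_config(path)
  known <- c("n_pulses", "pulse_width", "frequency", "intensity_multiple")
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop("unknown protocol keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- electrical_train_protocol()
  for (k in names(kv)) defaults[[k]] <- as.numeric(kv[[k]])
  defaults$n_pulses <- as.integer(defaults$n_pulses)
  validate_train_protocol(defaults)
}

# shared flat key=value parser; '#' comments and blank lines skipped
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  out <- list()
  for (i in keep) {
    ln <- lines[i]
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("config %s line %d: expected key=value, got '%s'",
                   path, i, ln), call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!nzchar(key))
      stop(sprintf("config %s line %d: empty key", path, i), call. = FALSE)
    out[[key]] <- val
  }
  out
}
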