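#' Write spike recordings as delimited text
#'
#' Serialises recordings to the documented tab-separated event schema: one
#' header line, then one row per event with columns `neurone_id`, `group`,
#' `route`, `dose`, `minute`, `trial`, `stimulus_kind` (`electrical`,
#' `brush`, `von_frey`, `heat`), `stimulus_magnitude`, `event_type` (`onset`
#' or `spike`) and `time_ms` (fixed 6-decimal format, so identical data give
#' byte-identical files). Within a recording, onsets precede spikes and each
#' is sorted by time.
#'
#' @param recordings List of `spike_recording`s.
#' @param path Output file.
#' @export
write_recordings <- function(recordings, path) {
  rows <- lapply(recordings, function(rec) {
    validate_spike_recording(rec)
    kind <- if (is_electrical(rec)) "electrical" else rec$stimulus$modality
    mag <- if (is_electrical(rec)) NA_real_ else rec$stimulus$magnitude
    times <- c(rec$onsets, rec$spikes)
    data.frame(neurone_id = rec$neurone_id, group = rec$group,
               route = rec$route, dose = as.character(rec$dose),
               minute = rec$minute, trial = rec$trial, stimulus_kind = kind,
               stimulus_magnitude = mag,
               event_type = rep(c("onset", "spike"),
                                c(length(rec$onsets), length(rec$spikes))),
               time_ms = sprintf("%.6f", times))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

recording_schema <- c("neurone_id", "group", "route", "dose", "minute",
                      "trial", "stimulus_kind", "stimulus_magnitude",
                      "event_type", "time_ms")

#' Read spike recordings from delimited text
#'
#' Strict parser for the schema written by [write_recordings()]: unknown
#' columns, unknown enum values, non-finite or negative times and unsorted
#' event times are rejected with the offending line number. Electrical
#' protocols are reconstructed from the onset rows (pulse count and spacing;
#' pulse width and intensity take the standard defaults, which the schema
#' does not carry). Spikes preceding the first onset are accepted (they are
#' simply never counted downstream).
#'
#' @param path File written by [write_recordings()].
#' @return List of `spike_recording`s in file order.
#' @export
read_recordings <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(rep("character", 4), "numeric",
                                         "integer", "character", "numeric",
                                         "character", "numeric"),
                          na.strings = "NA", stringsAsFactors = FALSE)
  if (!identical(names(df), recording_schema))
    stop("schema violation: expected columns ",
         paste(recording_schema, collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(df)) + 1L   # file line numbers (header = line 1)
  bad <- which(!df$group %in% c("MIA", "sham"))
  if (length(bad)) stop("line ", bad[1] + 1L, ": unknown group '",
                        df$group[bad[1]], "'", call. = FALSE)
  bad <- which(!df$stimulus_kind %in% c("electrical", "brush", "von_frey",
                                        "heat"))
  if (length(bad)) stop("line ", line[bad[1]], ": unknown stimulus_kind '",
                        df$stimulus_kind[bad[1]], "'", call. = FALSE)
  bad <- which(!df$event_type %in% c("onset", "spike"))
  if (length(bad)) stop("line ", line[bad[1]], ": unknown event_type '",
                        df$event_type[bad[1]], "'", call. = FALSE)
  bad <- which(!is.finite(df$time_ms) | df$time_ms < 0)
  if (length(bad)) stop("line ", line[bad[1]],
                        ": time_ms must be finite and >= 0", call. = FALSE)

  key <- paste(df$neurone_id, df$dose, df$minute, df$trial, df$stimulus_kind,
               df$stimulus_magnitude, sep = "\r")
  recs <- list()
  for (k in unique(key)) {
    sub <- df[key == k, ]
    subline <- line[key == k]
    for (et in c("onset", "spike")) {
      tm <- sub$time_ms[sub$event_type == et]
      if (is.unsorted(tm))
        stop("line ", subline[sub$event_type == et][which(diff(tm) < 0)[1] + 1L],
             ": unsorted ", et, " times within a recording", call. = FALSE)
    }
    onsets <- sub$time_ms[sub$event_type == "onset"]
    spikes <- sub$time_ms[sub$event_type == "spike"]
    if (!length(onsets))
      stop("line ", subline[1], ": recording without onset events",
           call. = FALSE)
    stim <- if (sub$stimulus_kind[1] == "electrical") {
      freq <- if (length(onsets) > 1) 1000 / diff(onsets)[1] else 0.5
      electrical_train_protocol(n_pulses = length(onsets), frequency = freq)
    } else {
      natural_stimulus(sub$stimulus_kind[1], sub$stimulus_magnitude[1],
                       strict = FALSE)
    }
    recs[[length(recs) + 1L]] <- spike_recording(
      sub$neurone_id[1], sub$group[1], onsets, spikes, stim,
      route = sub$route[1], dose = sub$dose[1], minute = sub$minute[1],
      trial = sub$trial[1])
  }
  recs
}

#' Write / read behavioural records
#'
#' Tab-separated table with columns `animal_id`, `group`, `arm`, `timepoint`,
#' `pwt50`, `acetone_freq`, `weight_bearing_ipsi`. The reader validates the
#' endpoint ranges (PWT within the instrument range is not enforced here;
#' percentages must lie in `[0, 100]`).
#'
#' @param records Behavioural data frame.
#' @param path File path.
#' @export
write_behaviour_records <- function(records, path) {
  need <- c("animal_id", "group", "arm", "timepoint", "pwt50", "acetone_freq",
            "weight_bearing_ipsi")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- records[need]
  for (col in c("pwt50", "acetone_freq", "weight_bearing_ipsi"))
    out[[col]] <- sprintf("%.6f", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behaviour_records
#' @export
read_behaviour_records <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "arm", "timepoint", "pwt50", "acetone_freq",
            "weight_bearing_ipsi")
  if (!identical(names(df), need))
    stop("schema violation: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in c("acetone_freq", "weight_bearing_ipsi")) {
    bad <- which(df[[col]] < 0 | df[[col]] > 100)
    if (length(bad)) stop("line ", bad[1] + 1L, ": ", col,
                          " out of [0, 100]", call. = FALSE)
  }
  df
}

#' Read a run configuration from a flat key=value file
#'
#' Strict: unknown keys are rejected. Recognised keys: `seed`, `route`,
#' `n_mia`, `n_sham`, `n_animals`, `include_postdischarge` (true/false),
#' `stability_rule` (range/max_dev), `exact_threshold`, `bin_width`.
#'
#' @param path Config file.
#' @return Object of class `run_config` (named list with typed values).
#' @export
read_run_config <- function(path) {
  kv <- read_flat_config(path)
  defaults <- list(seed = NULL, route = "spinal", n_mia = NULL, n_sham = NULL,
                   n_animals = 5L, include_postdischarge = FALSE,
                   stability_rule = "range", exact_threshold = 14L,
                   bin_width = 10)
  unknown <- setdiff(names(kv), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(kv)) {
    v <- kv[[k]]
    defaults[[k]] <- switch(k,
      route = match.arg(v, c("spinal", "systemic")),
      stability_rule = match.arg(v, c("range", "max_dev")),
      include_postdischarge = as.logical(v),
      seed = , n_mia = , n_sham = , n_animals = , exact_threshold =
        as.integer(v),
      as.numeric(v))
  }
  structure(defaults, class = "run_config")
}

#' Write a reproducibility manifest
#'
#' Every output directory gets a JSON manifest carrying the package version,
#' the seed, the effective configuration and an md5 of the serialised
#' configuration -- sufficient to reproduce the run bit-for-bit.
#'
#' @param dir Output directory.
#' @param config Named list (or `run_config`) echoed into the manifest.
#' @param seed Seed used for the run.
#' @export
write_manifest <- function(dir, config, seed) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, format, character(1)), sep = "="),
             tmp)
  manifest <- list(package = "dorsalhorn",
                   version = as.character(utils::packageVersion("dorsalhorn")),
                   seed = seed, config = cfg,
                   config_md5 = unname(tools::md5sum(tmp)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
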