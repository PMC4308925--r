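#' Von Frey up-down staircase session
#'
#' Runs the Dixon up-down staircase for tactile threshold estimation on the
#' plantar hind paw: starting at 2 g, the filament force is stepped down after
#' a withdrawal and up after no withdrawal; after the first change in response
#' the staircase continues for exactly four further presentations. Sessions
#' that would step above the 15 g cutoff (continuous non-response) or below
#' the weakest filament (continuous response) terminate at the boundary rule.
#'
#' @param responder Function `force_g -> logical` returning `TRUE` for a
#'   withdrawal (may be probabilistic; draws are taken from the R RNG).
#' @param filament_set Ascending filament forces in g (Touch-Test ladder
#'   0.4, 0.6, 1, 2, 4, 6, 8, 15 by default).
#' @param start Starting force in g; must belong to `filament_set`.
#' @param cutoff Upper boundary in g (default 15).
#' @param rng_seed Optional seed set before the first presentation, making a
#'   probabilistic session reproducible.
#' @return Object of class `updown_session`: `forces`, `responses` (logical,
#'   `TRUE` = withdrawal), `boundary` (`"none"`, `"high"`, `"low"`),
#'   `filament_set`, `cutoff`, and `pwt50` (g) computed by
#'   [pwt50_from_sequence()].
#' @export
run_updown <- function(responder, filament_set = c(0.4, 0.6, 1, 2, 4, 6, 8, 15),
                       start = 2, cutoff = 15, rng_seed = NULL) {
  filament_set <- sort(as.numeric(filament_set))
  if (!start %in% filament_set)
    stop("start force must belong to the filament set", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  i <- match(start, filament_set)
  forces <- numeric(0); responses <- logical(0)
  boundary <- "none"; post_change <- NA_integer_
  repeat {
    f <- filament_set[i]
    r <- responder(f)
    if (!is.logical(r) || length(r) != 1L || is.na(r))
      stop("responder must return a single TRUE/FALSE", call. = FALSE)
    forces <- c(forces, f); responses <- c(responses, r)
    if (is.na(post_change)) {
      if (length(responses) > 1L && r != responses[length(responses) - 1L])
        post_change <- 0L
    } else {
      post_change <- post_change + 1L
    }
    if (!is.na(post_change) && post_change >= 4L) break
    i_next <- if (r) i - 1L else i + 1L
    if (i_next > length(filament_set)) { boundary <- "high"; break }
    if (i_next < 1L) { boundary <- "low"; break }
    i <- i_next
  }
  s <- structure(list(forces = forces, responses = responses,
                      boundary = boundary, filament_set = filament_set,
                      cutoff = cutoff, pwt50 = NA_real_),
                 class = "updown_session")
  s$pwt50 <- pwt50_from_sequence(s)
  s
}

#' @export
print.updown_session <- function(x, ...) {
  marks <- ifelse(x$responses, "X", "O")
  cat(sprintf("Up-down session: %s -> 50%% PWT %.3g g%s\n",
              paste0(x$forces, marks, collapse = " "), x$pwt50,
              if (x$boundary != "none") paste0(" (", x$boundary, " boundary)")
              else ""))
  invisible(x)
}

#' 50% paw withdrawal threshold from an up-down sequence
#'
#' Estimates the force with 50% withdrawal probability as
#' `10^(X_f + k * delta)` in log10-gram units, where `X_f` is the final
#' presented force (log), `delta` the mean log-step of the filament ladder,
#' and `k` the pattern-dependent offset. `k` is obtained by probit maximum
#' likelihood with the psychometric spread fixed at `delta` — the normal-model
#' assumption behind the classical small-sample up-down tables — so any
#' sequence containing both response types (including boundary-clamped ones)
#' has a well-defined estimate. Sessions with only non-withdrawals return the
#' cutoff; sessions with only withdrawals return the weakest filament.
#'
#' @param session An `updown_session`.
#' @return Threshold in g, within `[min(filament_set), cutoff]`.
#' @export
pwt50_from_sequence <- function(session) {
  stopifnot(inherits(session, "updown_session"))
  resp <- session$responses
  if (length(resp) == 0L) stop("empty session", call. = FALSE)
  if (!any(resp)) return(session$cutoff)            # never withdrew
  if (all(resp)) return(min(session$filament_set))  # always withdrew
  delta <- mean(diff(log10(session$filament_set)))
  xf <- log10(session$forces[length(session$forces)])
  k <- updown_k(log10(session$forces), resp, delta, xf)
  est <- 10^(xf + k * delta)
  min(max(est, min(session$filament_set)), session$cutoff)
}

# Pattern offset k = (mu_hat - x_f)/delta, with mu_hat the probit MLE of the
# 50% point given responses at log-forces x, sigma fixed at delta.
updown_k <- function(x, withdraw, delta, xf) {
  nll <- function(mu) {
    p <- stats::pnorm((x - mu) / delta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(withdraw, log(p), log(1 - p)))
  }
  lo <- min(x) - 5 * delta; hi <- max(x) + 5 * delta
  mu_hat <- stats::optimise(nll, c(lo, hi), tol = 1e-8)$minimum
  (mu_hat - xf) / delta
}

#' Acetone (cooling) withdrawal frequency
#'
#' Paw withdrawal frequency to acetone application, as a percentage of the
#' maximal response: `(withdrawals / trials) * 100` over the standard 5-trial
#' block.
#'
#' @param withdrawals Number of foot withdrawals (0..`trials`).
#' @param trials Number of acetone applications (default 5).
#' @return Percentage in `[0, 100]`.
#' @export
acetone_frequency <- function(withdrawals, trials = 5) {
  stopifnot(length(withdrawals) == 1L, length(trials) == 1L)
  if (trials < 1 || withdrawals < 0 || withdrawals > trials)
    stop("withdrawals must lie in [0, trials]", call. = FALSE)
  100 * withdrawals / trials
}

#' Ipsilateral hind limb weight-bearing percentage
#'
#' Incapacitance-tester readout: each hind limb's load is the mean of three
#' consecutive readings, and the ipsilateral (injected) limb is expressed as a
#' percentage of the total weight borne by both hind limbs. 50% indicates
#' symmetric weight-bearing; ongoing joint discomfort shifts load off the
#' injected limb.
#'
#' @param ipsi_readings,contra_readings Exactly three positive readings (g)
#'   per limb.
#' @return Percentage in `(0, 100)`.
#' @export
weight_bearing_percent <- function(ipsi_readings, contra_readings) {
  for (r in list(ipsi_readings, contra_readings)) {
    if (length(r) != 3L)
      stop("exactly three readings per limb are required", call. = FALSE)
    if (any(!is.finite(r)) || any(r <= 0))
      stop("readings must be positive", call. = FALSE)
  }
  mi <- mean(ipsi_readings); mc <- mean(contra_readings)
  100 * mi / (mi + mc)
}
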