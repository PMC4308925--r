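# Fixtures built in code; no data files.

default_onsets <- function() stimulus_onsets(electrical_train_protocol())

# Train whose C-band counts ramp 1, 2, ..., 16 across the pulses
# (c_total 136, input 16, wind-up 120); no spikes in other bands.
ramped_train <- function() {
  on <- default_onsets()
  spikes <- sort(unlist(lapply(1:16, function(i)
    on[i] + seq(100, 300, length.out = i))))
  spike_recording("ramp", "MIA", on, spikes, electrical_train_protocol())
}

# Random synthetic train: spikes uniform over the whole sweep, so some fall
# outside every latency window (between 800 ms post-pulse and the next pulse
# would need >2 s gaps; here windows cover [0,800) of each 2000 ms cycle).
random_train <- function(n_spikes = 300, t_max = 32000) {
  on <- default_onsets()
  spikes <- sort(runif(n_spikes, 0, t_max))
  spike_recording("rand", "sham", on, spikes, electrical_train_protocol())
}

# Independent O(n * m) oracle: classify each spike against each onset/window
# by direct scanning, no shared code with band_counts().
brute_force_bands <- function(onsets, spikes, windows = latency_windows()) {
  w <- unclass(windows)
  tot <- setNames(numeric(4), names(w))
  per <- matrix(0L, length(onsets), 4, dimnames = list(NULL, names(w)))
  for (s in spikes) {
    prev <- which(onsets <= s)
    if (!length(prev)) next
    i <- max(prev)
    lat <- s - onsets[i]
    for (b in names(w)) {
      if (lat >= w[[b]][1] && lat < w[[b]][2]) {
        tot[b] <- tot[b] + 1
        per[i, b] <- per[i, b] + 1L
        break
      }
    }
  }
  list(per_stimulus = per, totals = tot)
}

# Deterministic step responder: withdraw iff force >= threshold.
step_responder <- function(threshold) function(force) force >= threshold

# Independent probit-ML 50% point by grid search (hand oracle for pwt50).
grid_pwt50 <- function(forces, withdraw, filament_set) {
  delta <- mean(diff(log10(filament_set)))
  x <- log10(forces)
  mus <- seq(min(x) - 5 * delta, max(x) + 5 * delta, length.out = 20001)
  ll <- vapply(mus, function(mu) {
    p <- pnorm((x - mu) / delta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(ifelse(withdraw, log(p), log(1 - p)))
  }, numeric(1))
  10^mus[which.max(ll)]
}

# Exact Mann-Whitney two-sided p by direct enumeration over value labelings
# (independent of the package's rank-split implementation).
enum_mw_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  vals <- c(x, y)
  mu <- n1 * length(y) / 2
  u_of <- function(idx) {
    xs <- vals[idx]; ys <- vals[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(N, n1), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Direct within-subject sums-of-squares oracle for one-way RM-ANOVA.
direct_rm_anova_1w <- function(mat) {  # subjects x levels
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_lvl <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_lvl - ss_subj
  f <- (ss_lvl / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = f, df1 = k - 1, df2 = (n - 1) * (k - 1),
       p = pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

long_from_matrix <- function(mat) {
  data.frame(subject = rep(rownames(mat) %||% seq_len(nrow(mat)), ncol(mat)),
             factor1 = rep(colnames(mat) %||% paste0("l", seq_len(ncol(mat))),
                           each = nrow(mat)),
             value = as.vector(mat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
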