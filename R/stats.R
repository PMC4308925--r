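#' Statistical battery for group and dose comparisons
#'
#' Two-group comparisons use the Mann-Whitney U test (exact by full
#' enumeration for small samples, tie-corrected normal approximation
#' otherwise); multi-group behavioural comparisons use Kruskal-Wallis with
#' Dunn's posttest; dose timecourses use one- or two-way repeated-measures
#' ANOVA followed by Bonferroni-corrected paired t-tests. All tests are
#' two-sided with significance at P < 0.05.
#'
#' @param statistic Test statistic.
#' @param p_value Two-sided p-value.
#' @param method Method tag.
#' @param n Named or unnamed sample sizes.
#' @param correction Multiplicity correction applied (`"none"` unless stated).
#' @param ... Extra fields stored on the result.
#' @return Object of class `dh_test` (list).
#' @keywords internal
dh_test <- function(statistic, p_value, method, n, correction = "none", ...) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, correction = correction, ...),
            class = "dh_test")
}

#' @export
print.dh_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/"),
              if (x$correction != "none") paste0(", ", x$correction) else ""))
  invisible(x)
}

#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' Exact mode enumerates all `choose(n1 + n2, n1)` group labelings of the
#' pooled sample (ties handled through midranks) and reports the two-sided
#' probability of a U at least as far from its null mean `n1 n2 / 2` as the
#' observed one. Approximate mode uses the normal approximation with tie
#' correction and continuity correction. `"auto"` switches to exact when
#' `n1 + n2 <= 14` (at most 3432 labelings).
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @param exact_threshold Total-n cutoff for `"auto"` (default 14).
#' @return A `dh_test` with fields `statistic` (U of sample `x`), `p_value`,
#'   `mode_used`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approximate"),
                           exact_threshold = 14) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- mode == "exact" || (mode == "auto" && N <= exact_threshold)
  if (use_exact) {
    mu <- n1 * n2 / 2
    idx <- utils::combn(N, n1)
    rsums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rsums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    mode_used <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    mode_used <- "approximate"
  }
  dh_test(statistic = u_obs, p_value = p,
          method = paste0("Mann-Whitney U (", mode_used, ")"),
          n = c(n1 = n1, n2 = n2), mode_used = mode_used)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to a chi-squared distribution with
#' `k - 1` degrees of freedom (via [stats::kruskal.test()]). When every pooled
#' observation is identical the tie correction degenerates; H is then defined
#' as 0 with p = 1.
#'
#' @param groups List of >= 3 non-empty numeric samples.
#' @return A `dh_test` with fields `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("at least 3 groups are required", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("all groups must be non-empty", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(pooled)) == 1L)
    return(dh_test(statistic = 0, p_value = 1, method = "Kruskal-Wallis",
                   n = vapply(groups, length, 1L), df = length(groups) - 1L))
  kt <- stats::kruskal.test(pooled, g)
  dh_test(statistic = unname(kt$statistic), p_value = kt$p.value,
          method = "Kruskal-Wallis", n = vapply(groups, length, 1L),
          df = unname(kt$parameter))
}

#' Dunn's posttest after Kruskal-Wallis
#'
#' Pairwise rank comparisons on the pooled midranks:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t)`; two-sided p-values are Bonferroni
#' multiplied by the number of comparisons and clamped to 1.
#'
#' @param groups Named list of numeric samples.
#' @param comparisons List of length-2 character vectors naming group pairs;
#'   default all pairs.
#' @param adjust Only `"bonferroni"` is provided.
#' @return Data frame: `group1`, `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posttest <- function(groups, comparisons = NULL, adjust = "bonferroni") {
  adjust <- match.arg(adjust, "bonferroni")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (is.null(comparisons))
    comparisons <- utils::combn(names(groups), 2, simplify = FALSE)
  for (cmp in comparisons)
    if (!all(cmp %in% names(groups)))
      stop("unknown group in comparisons: ",
           paste(setdiff(cmp, names(groups)), collapse = ", "), call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  lab <- rep(names(groups), vapply(groups, length, 1L))
  r <- rank(pooled)
  N <- length(pooled)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  meanrank <- tapply(r, lab, mean)
  nn <- tapply(r, lab, length)
  m <- length(comparisons)
  out <- do.call(rbind, lapply(comparisons, function(cmp) {
    v <- (N * (N + 1) / 12 - tie_term) * (1 / nn[[cmp[1]]] + 1 / nn[[cmp[2]]])
    z <- if (v > 0) (meanrank[[cmp[1]]] - meanrank[[cmp[2]]]) / sqrt(v) else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = cmp[1], group2 = cmp[2], z = z, p_raw = p,
               p_adjusted = min(1, p * m))
  }))
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANOVA (one-way, two-way, or mixed)
#'
#' Within-subject sums-of-squares decomposition via [stats::aov()] with
#' `Error()` strata on a complete balanced long table. `"one_way"` tests a
#' single within-subject factor; `"two_way"` crosses two within-subject
#' factors (main effects and interaction, each against its own
#' subject-by-factor error stratum); `"mixed"` treats `factor2` as a
#' between-subject grouping (used for baseline MIA-vs-sham comparisons across
#' stimulus intensities). No sphericity correction is applied (`caveat`
#' field); a table with zero within-cell variability is flagged degenerate
#' with `p = NA`.
#'
#' @param data Long data frame with columns `subject`, `value`, `factor1`
#'   (and `factor2` for two-way/mixed designs).
#' @param design `"one_way"`, `"two_way"` or `"mixed"`.
#' @return Data frame: `effect`, `df1`, `df2`, `F`, `p_value`, `degenerate`,
#'   `caveat`.
#' @export
rm_anova <- function(data, design = c("one_way", "two_way", "mixed")) {
  design <- match.arg(design)
  need <- c("subject", "value", "factor1",
            if (design != "one_way") "factor2")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  data$subject <- factor(data$subject)
  data$factor1 <- factor(data$factor1)
  if (design != "one_way") data$factor2 <- factor(data$factor2)
  cells <- if (design == "one_way") table(data$subject, data$factor1)
           else table(data$subject, data$factor1, data$factor2)
  if (design == "mixed") {
    # each subject appears in exactly one level of the between factor
    per <- table(data$subject, data$factor2) > 0
    if (any(rowSums(per) != 1L))
      stop("mixed design: each subject must belong to one group", call. = FALSE)
    cells <- table(data$subject, data$factor1)
  }
  if (any(cells != 1L) && design != "mixed")
    stop("design must be complete and balanced (one observation per cell)",
         call. = FALSE)
  if (design == "mixed" && any(cells != 1L))
    stop("mixed design: one observation per subject x within-level cell",
         call. = FALSE)
  if (stats::var(data$value) == 0)
    return(data.frame(effect = "factor1", df1 = NA_real_, df2 = NA_real_,
                      F = NA_real_, p_value = NA_real_, degenerate = TRUE,
                      caveat = "all cells equal"))
  fml <- switch(design,
    one_way = value ~ factor1 + Error(subject / factor1),
    two_way = value ~ factor1 * factor2 + Error(subject / (factor1 * factor2)),
    mixed   = value ~ factor1 * factor2 + Error(subject / factor1))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    effs <- trimws(rownames(tab))
    res_i <- which(effs == "Residuals")
    if (!length(res_i)) next
    df2 <- tab$Df[res_i]
    for (i in seq_len(nrow(tab))) {
      if (i == res_i) next
      Fv <- tab[["F value"]][i]
      degen <- !is.finite(Fv)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = effs[i], df1 = tab$Df[i], df2 = df2,
        F = if (degen) NA_real_ else Fv,
        p_value = if (degen) NA_real_ else tab[["Pr(>F)"]][i],
        degenerate = degen, caveat = "no sphericity correction")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected paired t-tests
#'
#' Paired t-test per requested level pair of a within-subject factor, with
#' p-values multiplied by the number of pairs and clamped to 1. Identical
#' paired vectors (zero difference variance) give t = 0, p = 1.
#'
#' @param data Long data frame with columns `subject`, `value`, `factor1`.
#' @param level_pairs List of length-2 vectors of `factor1` levels; default
#'   every later level against the first (baseline-versus-dose layout).
#' @return Data frame: `level1`, `level2`, `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
bonferroni_paired_t <- function(data, level_pairs = NULL) {
  need <- c("subject", "value", "factor1")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  data$factor1 <- factor(data$factor1)
  levs <- levels(data$factor1)
  if (is.null(level_pairs))
    level_pairs <- lapply(levs[-1], function(l) c(levs[1], l))
  m <- length(level_pairs)
  out <- do.call(rbind, lapply(level_pairs, function(pr) {
    if (!all(pr %in% levs))
      stop("unknown factor level in pair: ", paste(pr, collapse = " vs "),
           call. = FALSE)
    a <- data[data$factor1 == pr[1], ]
    b <- data[data$factor1 == pr[2], ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    if (nrow(a) != nrow(b) || !all(as.character(a$subject) ==
                                   as.character(b$subject)))
      stop("pair ", paste(pr, collapse = " vs "),
           ": subjects are not fully paired", call. = FALSE)
    if (nrow(a) < 2L) stop("at least 2 paired observations required",
                           call. = FALSE)
    d <- a$value - b$value
    if (stats::sd(d) == 0) {
      tt <- list(statistic = 0, parameter = nrow(a) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(a$value, b$value, paired = TRUE)
    }
    p <- tt$p.value
    data.frame(level1 = pr[1], level2 = pr[2], t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = p,
               p_adjusted = min(1, p * m))
  }))
  rownames(out) <- NULL
  out
}
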