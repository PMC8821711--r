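# Nonparametric test battery and presence summaries: Shapiro-Wilk
# normality screening, Mann-Whitney / Kruskal-Wallis comparisons with
# Dunn-Bonferroni post-hocs, and effort-normalised presence probability
# for duty-cycled recording protocols.

#' Shapiro-Wilk normality check
#'
#' @param values numeric sample, `n >= 3`, non-constant.
#' @return list `statistic`, `p_value`.
#' @export
normality_check <- function(values) {
  if (length(values) < 3) stop("normality check needs n >= 3")
  if (stats::sd(values) == 0) stop("constant sample has no defined test")
  t <- stats::shapiro.test(values)
  list(statistic = unname(t$statistic), p_value = t$p.value)
}

# Dunn post-hoc z tests on joint ranks with tie correction
dunn_posthoc <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_)
  for (i in seq_len(m)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[a] + 1 / ns[b]))
    z <- (rbar[a] - rbar[b]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out$z[i] <- z
    out$p_value[i] <- p
    out$p_adjusted[i] <- min(1, p * m)   # Bonferroni
  }
  out
}

#' Nonparametric group comparison
#'
#' Two groups: Mann-Whitney (Wilcoxon rank-sum). More than two:
#' Kruskal-Wallis, optionally followed by Dunn pairwise tests with
#' Bonferroni correction when the omnibus test is significant at `alpha`.
#'
#' @param values numeric observations.
#' @param labels group labels, same length; >= 2 groups, each `n >= 3`.
#' @param posthoc run Dunn-Bonferroni post-hocs after a significant
#'   Kruskal-Wallis.
#' @param alpha significance level (default 0.05).
#' @return list with `test` (`"mann-whitney"` or `"kruskal-wallis"`),
#'   `statistic`, `p_value`, `group_medians`, `significant`, and (when
#'   computed) `posthoc` data.frame.
#' @export
compare_groups <- function(values, labels, posthoc = FALSE, alpha = 0.05) {
  stopifnot(length(values) == length(labels))
  g <- factor(labels)
  ns <- table(g)
  if (length(ns) < 2) stop("need at least two groups")
  if (any(ns == 0)) stop("empty group")
  if (any(ns < 3)) stop("each group needs n >= 3")
  meds <- tapply(values, g, stats::median)
  if (length(ns) == 2) {
    t <- stats::wilcox.test(values ~ g, exact = FALSE)
    res <- list(test = "mann-whitney", statistic = unname(t$statistic),
                p_value = t$p.value, group_medians = meds,
                significant = t$p.value <= alpha)
  } else {
    t <- stats::kruskal.test(values, g)
    res <- list(test = "kruskal-wallis", statistic = unname(t$statistic),
                p_value = t$p.value, group_medians = meds,
                significant = t$p.value <= alpha)
    if (posthoc && res$significant) {
      res$posthoc <- dunn_posthoc(values, g)
    }
  }
  res
}

#' Effort-normalised probability of acoustic presence
#'
#' Fraction of recorded time with at least one active passage, per
#' hour-of-day or per day period, normalised by the recording effort in
#' each bin (the duty cycle varies across sessions, so bins differ in
#' effort). Bins with zero effort are `NA` (missing), not zero.
#'
#' @param passages data.frame `start_s`, `end_s` (seconds from the survey
#'   origin, assumed midnight).
#' @param coverage data.frame `start_s`, `end_s` of recorded intervals.
#' @param bin `"hour"` (24 bins) or `"period"`.
#' @param periods named list of `c(start_hour, end_hour)` defining the
#'   day periods (defaults: Night 0-6, Morning 6-12, Afternoon 12-18,
#'   Evening 18-24).
#' @param resolution_s discretisation step (s).
#' @return data.frame `bin`, `effort_s`, `presence_s`, `probability`.
#' @export
presence_probability <- function(passages, coverage, bin = c("hour", "period"),
                                 periods = list(Night = c(0, 6),
                                                Morning = c(6, 12),
                                                Afternoon = c(12, 18),
                                                Evening = c(18, 24)),
                                 resolution_s = 60) {
  bin <- match.arg(bin)
  if (nrow(coverage) == 0) stop("no recording coverage")
  grid <- unlist(lapply(seq_len(nrow(coverage)), function(i) {
    s <- coverage$start_s[i]; e <- coverage$end_s[i]
    if (e <= s) return(numeric(0))
    seq(s, e - resolution_s / 2, by = resolution_s)
  }))
  present <- rep(FALSE, length(grid))
  if (nrow(passages) > 0) {
    for (i in seq_len(nrow(passages))) {
      present <- present | (grid + resolution_s > passages$start_s[i] &
                              grid < passages$end_s[i])
    }
  }
  hod <- (grid %% 86400) / 3600
  key <- if (bin == "hour") floor(hod) else {
    lab <- rep(NA_character_, length(hod))
    for (nm in names(periods)) {
      p <- periods[[nm]]
      lab[hod >= p[1] & hod < p[2]] <- nm
    }
    lab
  }
  bins <- if (bin == "hour") as.character(0:23) else names(periods)
  out <- data.frame(bin = bins, effort_s = 0, presence_s = 0,
                    probability = NA_real_)
  for (i in seq_along(bins)) {
    sel <- !is.na(key) & as.character(key) == bins[i]
    out$effort_s[i] <- sum(sel) * resolution_s
    out$presence_s[i] <- sum(sel & present) * resolution_s
    if (out$effort_s[i] > 0) {
      out$probability[i] <- out$presence_s[i] / out$effort_s[i]
    }
  }
  out
}
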