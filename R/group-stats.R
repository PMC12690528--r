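#' Per-condition summary of overlap scores
#'
#' @param scores numeric vector of per-ROI overlap scores.
#' @return List with `n`, `mean`, `variance` (unbiased, `NA` for n < 2),
#'   `median`, `q1`, `q3`. Quartiles use the linear-interpolation
#'   convention (`stats::quantile` type 7).
#' @export
summarize_scores <- function(scores) {
  if (length(scores) == 0L) stop("empty score group", call. = FALSE)
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(scores), mean = mean(scores),
       variance = if (length(scores) >= 2L) stats::var(scores) else NA_real_,
       median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Brown-Forsythe heteroscedastic one-way ANOVA
#'
#' The mean-based Brown-Forsythe modified F statistic for comparing k
#' group means without assuming equal variances (the "Brown-Forsythe
#' ANOVA test" of common graphing software) — not Levene's
#' median-centered test of variances:
#' \deqn{F^* = \frac{\sum_i n_i(\bar y_i - \bar y)^2}
#'                  {\sum_i (1 - n_i/N) s_i^2}}
#' with the grand mean \eqn{\bar y} over all observations, numerator df
#' `k - 1`, and Satterthwaite-type denominator df from
#' `1/df2 = sum(c_i^2 / (n_i - 1))`, where
#' `c_i = (1 - n_i/N) s_i^2 / sum_j (1 - n_j/N) s_j^2`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations, not all variances zero).
#' @return List with `F_star`, `df1`, `df2`, `p`.
#' @export
brown_forsythe_anova <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- vapply(groups, length, integer(1L))
  if (any(n < 2L)) stop("every group needs >= 2 observations",
                        call. = FALSE)
  s2 <- vapply(groups, stats::var, numeric(1L))
  if (all(s2 == 0))
    stop("degenerate data: all group variances are zero", call. = FALSE)
  N <- sum(n)
  ybar <- vapply(groups, mean, numeric(1L))
  grand <- sum(n * ybar) / N
  num <- sum(n * (ybar - grand)^2)
  w <- (1 - n / N) * s2
  denom <- sum(w)
  F_star <- num / denom
  ci <- w / denom
  df2 <- 1 / sum(ci^2 / (n - 1))
  p <- stats::pf(F_star, k - 1, df2, lower.tail = FALSE)
  list(F_star = F_star, df1 = k - 1L, df2 = df2,
       p = min(max(p, .Machine$double.xmin), 1))
}

welch_pair <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  se2 <- va + vb
  if (se2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = max(na, nb) - 1))
    stop("degenerate pair: zero variances with unequal means",
         call. = FALSE)
  }
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = (mean(a) - mean(b)) / sqrt(se2), df = max(df, 1))
}

#' Dunnett T3 style pairwise comparisons for unequal variances
#'
#' For each requested pair of groups, a Welch-type statistic
#' `t = (mean_i - mean_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with
#' Welch-Satterthwaite degrees of freedom (floored at 1), and an adjusted
#' two-sided p-value from the independence-form studentized maximum
#' modulus law with `m` = the number of requested comparisons:
#' `p_adj = 1 - P(|T_df| <= |t|)^m`, clamped to (0, 1]. Tabulated SMM
#' critical values used by graphing software are approximated by this
#' independence form.
#'
#' @param groups named list of numeric score vectors (each n >= 2).
#' @param pairs list of length-2 character vectors naming the group pairs
#'   to compare; defaults to all unordered pairs.
#' @return data.frame with one row per pair: `group_a`, `group_b`, `t`,
#'   `df`, `p_adj`, `m`.
#' @export
dunnett_t3 <- function(groups, pairs = NULL) {
  if (is.null(pairs)) {
    labs <- names(groups)
    pairs <- utils::combn(labs, 2L, simplify = FALSE)
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(p) {
    if (!all(p %in% names(groups)))
      stop("unknown group label in pair: ", paste(p, collapse = " vs "),
           call. = FALSE)
    if (length(groups[[p[1L]]]) < 2L || length(groups[[p[2L]]]) < 2L)
      stop("pairwise comparison requires n >= 2 per group", call. = FALSE)
    w <- welch_pair(groups[[p[1L]]], groups[[p[2L]]])
    central <- 2 * stats::pt(abs(w$t), w$df) - 1
    p_adj <- 1 - central^m
    data.frame(group_a = p[1L], group_b = p[2L], t = w$t, df = w$df,
               p_adj = min(max(p_adj, .Machine$double.xmin), 1), m = m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Unpaired two-sample Student's t-test (pooled variance)
#'
#' @param a,b numeric samples, each n >= 2.
#' @return List with `t`, `df` (`n_a + n_b - 2`), and the two-sided `p`.
#'   Zero pooled variance with equal means yields `t = 0, p = 1`; with
#'   unequal means it is an error (the statistic is undefined).
#' @export
student_t_unpaired <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need n >= 2 in both samples",
                               call. = FALSE)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    stop("degenerate data: zero pooled variance with unequal means",
         call. = FALSE)
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Group per-ROI overlap results by condition
#'
#' @param results data.frame of per-ROI overlap results (as produced by
#'   [analyze_roi()], row-bound), with at least `condition`, `overlap`
#'   and `roi_id` columns.
#' @return Named list (one entry per condition, in order of first
#'   appearance) of lists with `label`, `scores`, and `roi_ids` for
#'   traceability. Empty input yields an empty list.
#' @export
aggregate_conditions <- function(results) {
  if (is.null(results) || nrow(results) == 0L) return(list())
  labs <- unique(results$condition)
  out <- lapply(labs, function(l) {
    i <- results$condition == l
    list(label = l, scores = results$overlap[i],
         roi_ids = results$roi_id[i])
  })
  stats::setNames(out, labs)
}
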