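#' Organelle center from the reference channel
#'
#' The center of a region's organelle (e.g. a single rod Golgi) is the
#' arithmetic mean position of the reference channel's molecules; the
#' comparison channel plays no part in defining it.
#'
#' @param ref_channel a [localization_table()] holding the reference
#'   channel's molecules; must be non-empty.
#' @return Numeric length-2 vector `c(x_nm, y_nm)`.
#' @export
golgi_center <- function(ref_channel) {
  if (nrow(ref_channel) == 0L)
    stop("cannot compute a center from an empty channel", call. = FALSE)
  c(x_nm = mean(ref_channel$x_nm), y_nm = mean(ref_channel$y_nm))
}

#' Euclidean distances of molecules to a center point
#'
#' @param channel a non-empty [localization_table()].
#' @param center numeric length-2 `c(x, y)` in nm.
#' @return Sorted (ascending) numeric vector of distances in nm, one per
#'   molecule.
#' @export
distances_to_center <- function(channel, center) {
  if (nrow(channel) == 0L)
    stop("cannot compute distances for an empty channel", call. = FALSE)
  sort(sqrt((channel$x_nm - center[[1L]])^2 +
            (channel$y_nm - center[[2L]])^2))
}

#' Empirical CDF as an explicit step function
#'
#' Returns the right-continuous empirical CDF of a sample as its jump
#' points and cumulative fractions; tied values are merged into a single
#' jump of height multiplicity/n. The final cumulative fraction is
#' exactly 1.
#'
#' @param values non-empty numeric vector (need not be pre-sorted).
#' @return data.frame with columns `x` (ascending unique jump points) and
#'   `F` (cumulative fraction at and beyond each jump).
#' @export
distance_ecdf <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  tab <- table(values)
  x <- as.numeric(names(tab))
  data.frame(x = x, F = cumsum(as.numeric(tab)) / length(values))
}

ecdf_at <- function(sorted_sample, x) {
  findInterval(x, sorted_sample) / length(sorted_sample)
}

#' Exact two-sample Kolmogorov-Smirnov statistic
#'
#' The sup-norm distance between the two empirical CDFs, computed exactly
#' over all pooled jump points — no binning or grid approximation. Both
#' one-sided ECDF differences are evaluated at every pooled point
#' (i.e. at the point and just below it), which handles ties between the
#' two samples, the edge case the classical no-ties formula glosses over.
#'
#' @param a,b non-empty numeric samples (distance lists, nm).
#' @return D in \[0, 1\].
#' @export
ks_D <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  sa <- sort(a); sb <- sort(b)
  pooled <- sort(unique(c(sa, sb)))
  d_at <- abs(ecdf_at(sa, pooled) - ecdf_at(sb, pooled))
  # left limits: counts strictly below each pooled point
  fa_l <- findInterval(pooled, sa, left.open = TRUE) / length(sa)
  fb_l <- findInterval(pooled, sb, left.open = TRUE) / length(sb)
  max(d_at, abs(fa_l - fb_l))
}

#' Asymptotic two-sided p-value for the two-sample K-S statistic
#'
#' Uses the Kolmogorov limiting distribution with the standard
#' small-sample correction: with effective size
#' `n_e = n_a * n_b / (n_a + n_b)`, the tail probability is
#' `Q_KS((sqrt(n_e) + 0.12 + 0.11 / sqrt(n_e)) * D)` where
#' `Q_KS(z) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 z^2)`. The value is
#' asymptotic — for very small samples it can deviate from the exact
#' permutation p-value by up to roughly 0.15 — and is clamped to (0, 1].
#' The pipeline's primary statistic is the overlap score, not this p.
#'
#' @param D K-S statistic in \[0, 1\].
#' @param n_a,n_b sample sizes (>= 1).
#' @return Two-sided p-value in (0, 1].
#' @export
ks_pvalue <- function(D, n_a, n_b) {
  if (!is.finite(D) || D < 0 || D > 1)
    stop("D must lie in [0, 1]", call. = FALSE)
  if (n_a < 1L || n_b < 1L) stop("sample sizes must be >= 1", call. = FALSE)
  n_e <- n_a * n_b / (n_a + n_b)
  z <- (sqrt(n_e) + 0.12 + 0.11 / sqrt(n_e)) * D
  if (z == 0) return(1)
  j <- seq_len(101L)
  p <- 2 * sum((-1)^(j - 1L) * exp(-2 * j^2 * z^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' Overlap score between two distance distributions
#'
#' The colocalization score `1 - D`, where D is the exact two-sample K-S
#' statistic between the two channels' distance-to-center distributions:
#' 1 means identical distributions, 0 means fully separated supports.
#'
#' @inheritParams ks_D
#' @return Overlap score in \[0, 1\].
#' @export
overlap_score <- function(a, b) 1 - ks_D(a, b)

#' Score a single region of interest
#'
#' Composes the per-region analysis: center of the reference channel,
#' distance-to-center distributions for both channels, exact K-S D,
#' overlap score `1 - D`, and the (auxiliary, asymptotic) K-S p-value.
#'
#' @param roi_channels named list of per-channel [localization_table()]s,
#'   as returned by [extract_roi()].
#' @param roi the [roi_spec()] (supplies `roi_id`, `condition`,
#'   `ref_channel`).
#' @param comparison label of the comparison channel; required when more
#'   than two channels are present, otherwise inferred.
#' @return List with `result` (one-row data.frame: `roi_id`, `condition`,
#'   `n_ref`, `n_other`, `D`, `overlap`, `ks_p`) and `profile` (list:
#'   `roi_id`, `center`, `distances` — per-channel sorted distances).
#' @export
analyze_roi <- function(roi_channels, roi, comparison = NULL) {
  ref <- roi$ref_channel
  if (is.null(roi_channels[[ref]]) || nrow(roi_channels[[ref]]) == 0L)
    stop("reference channel '", ref, "' missing or empty in ROI ",
         roi$roi_id, call. = FALSE)
  others <- setdiff(names(roi_channels), ref)
  if (is.null(comparison)) {
    if (length(others) != 1L)
      stop("ROI ", roi$roi_id, " has ", length(others),
           " non-reference channels; specify `comparison`", call. = FALSE)
    comparison <- others
  }
  cmp <- roi_channels[[comparison]]
  if (is.null(cmp) || nrow(cmp) == 0L)
    stop("comparison channel '", comparison, "' missing or empty in ROI ",
         roi$roi_id, call. = FALSE)

  center <- golgi_center(roi_channels[[ref]])
  d_ref <- distances_to_center(roi_channels[[ref]], center)
  d_cmp <- distances_to_center(cmp, center)
  D <- ks_D(d_ref, d_cmp)
  list(
    result = data.frame(
      roi_id = roi$roi_id, condition = roi$condition,
      n_ref = length(d_ref), n_other = length(d_cmp),
      D = D, overlap = 1 - D,
      ks_p = ks_pvalue(D, length(d_ref), length(d_cmp)),
      stringsAsFactors = FALSE
    ),
    profile = list(roi_id = roi$roi_id, center = center,
                   distances = stats::setNames(list(d_ref, d_cmp),
                                               c(ref, comparison)))
  )
}

#' Histogram of distances for frequency plots
#'
#' Bins are left-closed, right-open, anchored at 0:
#' `[0, w), [w, 2w), ...`. Counts always sum to the number of input
#' values. Display support only — the K-S statistic never uses binning.
#'
#' @param values numeric distances (nm), all >= 0.
#' @param bin_width_nm positive bin width in nm (default 50).
#' @return data.frame with `bin_start`, `bin_end`, `count`; zero rows for
#'   empty input.
#' @export
distance_histogram <- function(values, bin_width_nm = 50) {
  if (!is.numeric(bin_width_nm) || bin_width_nm <= 0)
    stop("bin width must be positive", call. = FALSE)
  if (length(values) == 0L)
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  idx <- floor(values / bin_width_nm)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  starts <- (seq_along(counts) - 1L) * bin_width_nm
  data.frame(bin_start = starts, bin_end = starts + bin_width_nm,
             count = counts)
}
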