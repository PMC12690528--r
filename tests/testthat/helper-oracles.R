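# Independent oracles the implementation is tested against. These stay
# deliberately naive: direct definitions, enumeration, dense grids.

# Brute-force two-sample K-S: sup |F_a - F_b| over every sample point
# plus a dense grid spanning the pooled range.
brute_force_ks <- function(a, b, grid_n = 2000L) {
  xs <- c(a, b,
          seq(min(a, b) - 1, max(a, b) + 1, length.out = grid_n))
  Fa <- vapply(xs, function(x) mean(a <= x), numeric(1L))
  Fb <- vapply(xs, function(x) mean(b <= x), numeric(1L))
  max(abs(Fa - Fb))
}

# Exact permutation p-value for the two-sample K-S statistic: enumerate
# every split of the pooled sample into groups of the original sizes.
permutation_ks_pvalue <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  obs <- brute_force_ks(a, b)
  idx <- utils::combn(n, length(a))
  Ds <- apply(idx, 2L, function(i)
    brute_force_ks(pooled[i], pooled[-i]))
  mean(Ds >= obs - 1e-12)
}

# Step-by-step Brown-Forsythe F*, df2 and p from the definition.
bf_anova_by_hand <- function(groups) {
  n <- sapply(groups, length); N <- sum(n)
  m <- sapply(groups, mean); s2 <- sapply(groups, var)
  grand <- sum(unlist(groups)) / N
  Fs <- sum(n * (m - grand)^2) / sum((1 - n / N) * s2)
  ci <- (1 - n / N) * s2 / sum((1 - n / N) * s2)
  df2 <- 1 / sum(ci^2 / (n - 1))
  list(F_star = Fs, df2 = df2,
       p = pf(Fs, length(groups) - 1, df2, lower.tail = FALSE))
}

# Small random localization table for property tests.
random_loc_table <- function(n, channels = c("561", "647"),
                             box = c(0, 1000)) {
  localization_table(
    runif(n, box[1L], box[2L]), runif(n, box[1L], box[2L]),
    frame = seq_len(n), uncertainty_nm = runif(n, 0, 30),
    channel = sample(channels, n, replace = TRUE)
  )
}

# Mean per-ROI overlap for a condition config.
mean_condition_overlap <- function(cfg) {
  sc <- vapply(simulate_condition(cfg)$rois, function(r) {
    suppressMessages(
      analyze_roi(extract_roi(r$table, r$roi), r$roi)$result$overlap)
  }, numeric(1L))
  mean(sc)
}
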