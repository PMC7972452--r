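# Group-level statistics: Welch/BH testing, permutation-calibrated FDR
# feature screening, variability analyses, the robustness screen, and
# AB-size bin / correlation analyses.

#' Screening configuration
#'
#' @param effect_threshold minimum absolute relative mean difference
#'   (default 0.15, i.e. a 15\% effect).
#' @param target_fdr false discovery rate the permutation calibration
#'   aims for (default 0.10).
#' @param n_shuffles number of label permutations (default 100).
#' @param min_embryos_per_group coverage rule: a feature must be scored
#'   in at least this many embryos in each group (default 5).
#' @param alpha_grid descending candidate p-value cutoffs.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(effect_threshold = 0.15, target_fdr = 0.10,
                          n_shuffles = 100L, min_embryos_per_group = 5L,
                          alpha_grid = c(0.05, 0.02, 0.01, 0.008, 0.005,
                                         0.002, 0.001)) {
  stopifnot(effect_threshold > 0, effect_threshold < 1,
            target_fdr > 0, target_fdr < 1)
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  structure(list(effect_threshold = effect_threshold,
                 target_fdr = target_fdr,
                 n_shuffles = as.integer(n_shuffles),
                 min_embryos_per_group = as.integer(min_embryos_per_group),
                 alpha_grid = sort(alpha_grid, decreasing = TRUE)),
            class = "screen_config")
}

# numeric feature columns of a feature_table-style data.frame
.feature_matrix <- function(feature_table) {
  num <- vapply(feature_table, is.numeric, logical(1))
  as.matrix(feature_table[, num, drop = FALSE])
}

# vectorized Welch statistics over the columns of two matrices
.welch_columns <- function(A, B, effect = c("relative", "absolute")) {
  effect <- match.arg(effect)
  na <- colSums(!is.na(A)); nb <- colSums(!is.na(B))
  ma <- colMeans(A, na.rm = TRUE); mb <- colMeans(B, na.rm = TRUE)
  va <- apply(A, 2, stats::var, na.rm = TRUE)
  vb <- apply(B, 2, stats::var, na.rm = TRUE)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  zero_var <- is.finite(va) & is.finite(vb) & va == 0 & vb == 0
  if (any(zero_var, na.rm = TRUE)) {
    warning(sum(zero_var), " feature(s) with zero variance in both groups;",
            " p set to 1")
    p[zero_var] <- 1; t_stat[zero_var] <- 0
  }
  eff <- if (effect == "relative") (ma - mb) / mb else ma - mb
  data.frame(feature = colnames(A), n_a = na, n_b = nb, mean_a = ma,
             mean_b = mb, effect = eff, t = t_stat, df = df, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-feature Welch tests with Benjamini-Hochberg correction
#'
#' Welch's unequal-variance t-test for every feature column between two
#' groups, with the relative mean difference `(mean_a - mean_b)/mean_b`
#' as effect size and BH step-up adjustment across all tested features.
#' Features scored in fewer than `min_embryos_per_group` embryos in
#' either group are excluded (recorded in the `excluded` attribute);
#' all-missing features likewise.
#'
#' @param feature_table data.frame with a `group` column and numeric
#'   feature columns (see [feature_table()]), or a numeric matrix plus
#'   `labels`.
#' @param group_a,group_b group labels to compare (effect is relative to
#'   `group_b`, conventionally the control/alive group).
#' @param config a [screen_config()].
#' @param effect `"relative"` (default) or `"absolute"` mean difference.
#' @param labels optional explicit group vector when `feature_table` is a
#'   bare matrix.
#' @return data.frame with per-feature `effect`, `p`, `p_adj` and group
#'   summaries.
#' @export
welch_bh <- function(feature_table, group_a, group_b,
                     config = screen_config(),
                     effect = c("relative", "absolute"), labels = NULL) {
  if (is.null(labels)) labels <- feature_table$group
  X <- .feature_matrix(as.data.frame(feature_table))
  A <- X[labels == group_a, , drop = FALSE]
  B <- X[labels == group_b, , drop = FALSE]
  res <- .welch_columns(A, B, effect = match.arg(effect))
  keep <- res$n_a >= config$min_embryos_per_group &
    res$n_b >= config$min_embryos_per_group
  excluded <- res$feature[!keep]
  res <- res[keep, , drop = FALSE]
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  attr(res, "excluded") <- excluded
  res
}

#' Permutation-calibrated screening threshold
#'
#' Screens features between two groups with the joint rule
#' `|effect| >= effect_threshold AND p < alpha`, choosing `alpha` on a
#' descending grid by a permutation estimate of the false discovery
#' rate: the expected number of passing features is the mean count over
#' `n_shuffles` label shuffles, and `FDR(alpha) = expected /
#' max(observed, 1)`. The chosen cutoff is the largest grid value with
#' estimated FDR at or below the target. The same shuffle set is reused
#' across the grid.
#'
#' @inheritParams welch_bh
#' @param seed RNG seed for the label shuffles.
#' @return list of class `screen_result`: `alpha_star`, `screen` (the
#'   [welch_bh()] table with a `pass` flag at `alpha_star`), and
#'   `fdr_table` (per grid alpha: observed/expected counts and estimated
#'   FDR).
#' @export
permutation_fdr_alpha <- function(feature_table, group_a, group_b,
                                  config = screen_config(), seed = 1L,
                                  labels = NULL) {
  if (is.null(labels)) labels <- feature_table$group
  if (config$n_shuffles < 1)
    stop("n_shuffles must be >= 1", call. = FALSE)
  X <- .feature_matrix(as.data.frame(feature_table))
  in_pair <- labels %in% c(group_a, group_b)
  X <- X[in_pair, , drop = FALSE]
  lab <- labels[in_pair]

  observed <- welch_bh(X, group_a, group_b, config, labels = lab)
  passes_at <- function(res, alpha)
    sum(abs(res$effect) >= config$effect_threshold & res$p < alpha,
        na.rm = TRUE)
  obs_counts <- vapply(config$alpha_grid,
                       function(a) passes_at(observed, a), numeric(1))

  shuffle_counts <- with_seed(derive_seed(seed, "label-shuffles"), {
    vapply(seq_len(config$n_shuffles), function(s) {
      perm <- sample(lab)
      res <- suppressWarnings(
        welch_bh(X, group_a, group_b, config, labels = perm))
      vapply(config$alpha_grid, function(a) passes_at(res, a), numeric(1))
    }, numeric(length(config$alpha_grid)))
  })
  expected <- rowMeans(matrix(shuffle_counts,
                              nrow = length(config$alpha_grid)))
  fdr <- expected / pmax(obs_counts, 1)
  ok <- which(fdr <= config$target_fdr)
  if (length(ok)) {
    alpha_star <- config$alpha_grid[min(ok)]   # grid is descending
  } else {
    alpha_star <- min(config$alpha_grid)
    warning("no alpha on the grid meets the FDR target; ",
            "using the smallest grid value (expect no passing features)")
  }
  screen <- observed
  screen$pass <- abs(screen$effect) >= config$effect_threshold &
    screen$p < alpha_star
  list(alpha_star = alpha_star, screen = screen,
       fdr_table = data.frame(alpha = config$alpha_grid,
                              observed = obs_counts, expected = expected,
                              fdr = fdr))
}

#' Per-group variability of each feature
#'
#' Sample SD and coefficient of variation (CV = SD/mean) per group and
#' feature column. The CV is reported only where the group mean is
#' positive (it is meaningless for signed position features) and is
#' flagged `NA` otherwise.
#'
#' @param feature_table data.frame with `group` plus numeric feature
#'   columns.
#' @param min_n minimum embryos per group to report (default 2).
#' @return data.frame: `group`, `feature`, `n`, `mean`, `sd`, `cv`.
#' @export
variability_stats <- function(feature_table, min_n = 2L) {
  X <- .feature_matrix(as.data.frame(feature_table))
  groups <- unique(feature_table$group)
  rows <- lapply(groups, function(g) {
    sub <- X[feature_table$group == g, , drop = FALSE]
    n <- colSums(!is.na(sub))
    m <- colMeans(sub, na.rm = TRUE)
    s <- apply(sub, 2, stats::sd, na.rm = TRUE)
    cv <- ifelse(m > 0, s / m, NA_real_)
    data.frame(group = g, feature = colnames(X), n = n, mean = m, sd = s,
               cv = cv, row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$n >= min_n, ]
}

#' Compare variability across groups (ANOVA + Tukey HSD)
#'
#' One-way ANOVA of a per-feature variability measure (CV or SD) across
#' groups with Tukey's honest significant difference post-hoc test, and
#' Welch tests between the AB and P1 super-lineages within each group
#' when features are per-cell (named `<cell>.<feature>`).
#'
#' @param vartab output of [variability_stats()].
#' @param measure `"cv"` or `"sd"`.
#' @return list with `anova_p`, `tukey` (matrix from
#'   [stats::TukeyHSD()]), and `within_group` (Welch p of AB vs P1 per
#'   group, where cell names are resolvable).
#' @export
variability_anova <- function(vartab, measure = c("cv", "sd")) {
  measure <- match.arg(measure)
  v <- vartab[is.finite(vartab[[measure]]), ]
  if (length(unique(v$group)) < 2L)
    stop("need at least two groups", call. = FALSE)
  fit <- stats::aov(v[[measure]] ~ factor(v$group))
  tk <- stats::TukeyHSD(fit)[[1]]
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  within <- NULL
  cells <- sub("\\..*$", "", v$feature)
  ok <- is_valid_cell_name(cells)
  if (any(ok)) {
    sl <- rep(NA_character_, nrow(v))
    sl[ok] <- founder_of(cells[ok])$super_lineage
    within <- vapply(unique(v$group), function(g) {
      a <- v[[measure]][v$group == g & sl == "AB"]
      b <- v[[measure]][v$group == g & sl == "P1"]
      if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) return(NA_real_)
      stats::t.test(a, b)$p.value
    }, numeric(1))
  }
  list(anova_p = anova_p, tukey = tk, within_group = within)
}

#' Robustness screen: same mean, increased variability
#'
#' Returns the features whose mean is statistically indistinguishable
#' between the groups (Welch p >= `mean_alpha`) while the variance is
#' significantly larger in `group_b` (one-sided F variance-ratio test,
#' p < `var_alpha`). The test choice is a package decision; a
#' Levene-type alternative on absolute deviations from the median is
#' available via `method`.
#'
#' @inheritParams welch_bh
#' @param mean_alpha threshold for "mean unchanged" (default 0.05).
#' @param var_alpha threshold for "variance increased" (default 0.05).
#' @param method `"f"` (variance-ratio) or `"levene"`.
#' @return data.frame of flagged features with the two p-values.
#' @export
robustness_screen <- function(feature_table, group_a, group_b,
                              config = screen_config(), mean_alpha = 0.05,
                              var_alpha = 0.05, method = c("f", "levene"),
                              labels = NULL) {
  method <- match.arg(method)
  if (is.null(labels)) labels <- feature_table$group
  X <- .feature_matrix(as.data.frame(feature_table))
  A <- X[labels == group_a, , drop = FALSE]
  B <- X[labels == group_b, , drop = FALSE]
  na <- colSums(!is.na(A)); nb <- colSums(!is.na(B))
  keep <- na >= config$min_embryos_per_group &
    nb >= config$min_embryos_per_group
  A <- A[, keep, drop = FALSE]; B <- B[, keep, drop = FALSE]
  welch <- suppressWarnings(.welch_columns(A, B))
  if (method == "f") {
    va <- apply(A, 2, stats::var, na.rm = TRUE)
    vb <- apply(B, 2, stats::var, na.rm = TRUE)
    p_var <- stats::pf(vb / va, colSums(!is.na(B)) - 1,
                       colSums(!is.na(A)) - 1, lower.tail = FALSE)
  } else {
    p_var <- vapply(seq_len(ncol(A)), function(j) {
      a <- abs(A[, j] - stats::median(A[, j], na.rm = TRUE))
      b <- abs(B[, j] - stats::median(B[, j], na.rm = TRUE))
      if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) return(NA_real_)
      stats::t.test(b, a, alternative = "greater")$p.value
    }, numeric(1))
  }
  flag <- !is.na(welch$p) & welch$p >= mean_alpha &
    !is.na(p_var) & p_var < var_alpha
  data.frame(feature = colnames(A), p_mean = welch$p, p_var = p_var,
             row.names = NULL, stringsAsFactors = FALSE)[flag, ]
}

#' AB-size bin and correlation analyses
#'
#' Bins embryos into 2\%-wide half-open relative-AB-size intervals
#' (labelled in descending notation, e.g. `"(56-54]"`), reporting the
#' lethality fraction and count per bin (empty bins are reported, not
#' dropped); and, when a per-embryo quantity is supplied, the Pearson
#' correlation between relative AB size and that quantity with a
#' two-sided p-value from the asymptotic t approximation on n-2 degrees
#' of freedom.
#'
#' @param metadata data.frame with `embryo_id`, `relative_AB_size`,
#'   `outcome`.
#' @param quantity optional named numeric vector (names = embryo ids),
#'   e.g. AB-P1 division asynchrony.
#' @param bin_width bin width in percentage points (default 2).
#' @return list with `bins` (data.frame `bin`, `n`, `n_dead`,
#'   `lethality`) and, if `quantity` given, `correlation` (list `r`,
#'   `t`, `df`, `p`, `n`).
#' @export
ab_size_analyses <- function(metadata, quantity = NULL, bin_width = 2) {
  ab <- metadata$relative_AB_size
  lo <- floor(min(ab) / bin_width) * bin_width
  if (any(ab <= lo)) lo <- lo - bin_width  # intervals are open below
  hi <- ceiling(max(ab) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- cut(ab, breaks = breaks, right = TRUE, include.lowest = FALSE,
             labels = FALSE)
  bins <- data.frame(
    bin = sprintf("(%g-%g]", breaks[-1], breaks[-length(breaks)]),
    n = 0L, n_dead = 0L, lethality = NA_real_, stringsAsFactors = FALSE)
  for (b in seq_len(nrow(bins))) {
    sel <- !is.na(idx) & idx == b
    bins$n[b] <- sum(sel)
    bins$n_dead[b] <- sum(metadata$outcome[sel] == "dead")
    bins$lethality[b] <- if (bins$n[b] > 0) bins$n_dead[b] / bins$n[b]
                         else NA_real_
  }
  bins <- bins[rev(seq_len(nrow(bins))), ]   # largest AB sizes first
  rownames(bins) <- NULL
  out <- list(bins = bins)
  if (!is.null(quantity)) {
    q <- quantity[match(metadata$embryo_id, names(quantity))]
    ok <- is.finite(q) & is.finite(ab)
    n <- sum(ok)
    if (n >= 3) {
      r <- stats::cor(ab[ok], q[ok])
      t_stat <- r * sqrt((n - 2) / (1 - r^2))
      out$correlation <- list(r = r, t = t_stat, df = n - 2,
                              p = 2 * stats::pt(-abs(t_stat), n - 2), n = n)
    }
  }
  out
}
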