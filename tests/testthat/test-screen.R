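test_that("vectorized Welch statistics match stats::t.test", {
  # hand-checkable case: {1..5} vs {3..7} gives t = -2 on 8 df
  ft <- data.frame(group = rep(c("a", "b"), each = 5),
                   f1 = c(1:5, 3:7), f2 = c(rnorm(5, 0, 1), rnorm(5, 2, 3)))
  res <- welch_bh(ft, "a", "b", config = screen_config(
    min_embryos_per_group = 2))
  expect_equal(res$t[res$feature == "f1"], -2)
  expect_equal(res$df[res$feature == "f1"], 8)
  for (f in c("f1", "f2")) {
    ora <- t.test(ft[[f]][ft$group == "a"], ft[[f]][ft$group == "b"])
    expect_equal(res$p[res$feature == f], ora$p.value, tolerance = 1e-12)
    expect_equal(res$t[res$feature == f], unname(ora$statistic),
                 tolerance = 1e-12)
  }
  # relative effect against group b
  expect_equal(res$effect[res$feature == "f1"], (3 - 5) / 5)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  ft <- data.frame(group = rep(c("a", "b"), each = 6))
  # independent brute-force BH: cummin over ranked p * m / rank
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  bh <- pmin(1, cummin(p[o] * m / rank(p)[o]))[order(o)]
  expect_equal(bh, rep(0.04, 4))
  # the screen's adjusted p values follow the same rule
  set.seed(1)
  X <- matrix(rnorm(12 * 6), 12, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  ft <- cbind(ft, X)
  res <- welch_bh(ft, "a", "b",
                  config = screen_config(min_embryos_per_group = 2))
  o2 <- order(res$p, decreasing = TRUE)
  bh2 <- pmin(1, cummin(res$p[o2] * nrow(res) / rank(res$p)[o2]))[order(o2)]
  expect_equal(res$p_adj, bh2)
  expect_true(all(res$p_adj >= res$p))
})

test_that("identical groups give null effects and p near 1", {
  X <- matrix(rep(c(1, 2, 3, 4, 5, 6), 4), 12, 2)
  colnames(X) <- c("f1", "f2")
  ft <- data.frame(group = rep(c("a", "b"), each = 6), X)
  expect_warning(
    res <- welch_bh(ft, "a", "b",
                    config = screen_config(min_embryos_per_group = 2)),
    NA)
  expect_equal(res$effect, c(0, 0))
  expect_true(all(res$p > 0.99))
  # all-constant feature triggers the zero-variance warning
  ft$f3 <- 1
  expect_warning(welch_bh(ft, "a", "b", config = screen_config(
    min_embryos_per_group = 2)), "zero variance")
})

test_that("permutation FDR screen is calibrated on null data", {
  set.seed(11)
  n <- 20; nf <- 200
  ft <- data.frame(group = rep(c("a", "b"), each = n),
                   matrix(rnorm(2 * n * nf, 1, 0.2), 2 * n, nf,
                          dimnames = list(NULL, paste0("f", 1:nf))),
                   check.names = FALSE)
  res <- permutation_fdr_alpha(
    ft, "a", "b", config = screen_config(n_shuffles = 30), seed = 2)
  expect_lte(sum(res$screen$pass), 3)
  expect_error(
    permutation_fdr_alpha(ft, "a", "b",
                          config = screen_config(n_shuffles = 0)),
    "n_shuffles")
})

test_that("coefficient of variation behaves like a scale-free spread", {
  ft <- data.frame(group = "g",
                   d1 = c(10, 10, 10), d2 = c(9, 10, 11))
  vs <- variability_stats(ft)
  expect_equal(vs$cv[vs$feature == "d1"], 0)
  expect_equal(vs$cv[vs$feature == "d2"], 0.1)      # sd 1, mean 10
  expect_equal(vs$sd[vs$feature == "d2"], 1)
  # uniform time dilation leaves every CV unchanged, scales SD
  ft2 <- ft; ft2[, c("d1", "d2")] <- ft[, c("d1", "d2")] * 1.3
  vs2 <- variability_stats(ft2)
  expect_equal(vs2$cv, vs$cv)
  expect_equal(vs2$sd, vs$sd * 1.3)
  # CV undefined for non-positive means
  ft3 <- data.frame(group = "g", d = c(-2, 0, 2))
  expect_true(is.na(variability_stats(ft3)$cv))
})

test_that("variability ANOVA compares groups and lineages", {
  set.seed(3)
  cells <- c("ABa", "ABp", "MSa", "Ea")
  tab <- do.call(rbind, lapply(c("g1", "g2", "g3"), function(g) {
    data.frame(group = g, feature = paste0(cells, ".LifeTime"),
               n = 5, mean = 10,
               sd = abs(rnorm(4, ifelse(g == "g3", 3, 1), 0.2)),
               cv = NA)
  }))
  tab$cv <- tab$sd / tab$mean
  out <- variability_anova(tab, measure = "cv")
  expect_lt(out$anova_p, 0.05)
  expect_true(any(grepl("g3", rownames(out$tukey))))
})

test_that("robustness screen flags equal-mean inflated-variance features", {
  cfg <- screen_config(min_embryos_per_group = 5)
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 20
    ft <- data.frame(group = rep(c("alive", "dead"), each = n),
                     planted = c(rnorm(n, 5, 1), rnorm(n, 5, 3)),
                     null1 = rnorm(2 * n, 5, 1),
                     shrunk = c(rnorm(n, 5, 3), rnorm(n, 5, 1)))
    out <- robustness_screen(ft, "alive", "dead", cfg)
    if ("planted" %in% out$feature) hits <- hits + 1
    expect_false("shrunk" %in% out$feature)  # one-sided: b must inflate
  }
  expect_gte(hits / 20, 0.8)
  # identical groups flag nothing
  same <- data.frame(group = rep(c("alive", "dead"), each = 10),
                     f = rep(rnorm(10, 5, 1), 2))
  expect_equal(nrow(robustness_screen(same, "alive", "dead", cfg)), 0)
})

test_that("AB-size bins and correlation follow the printed conventions", {
  md <- data.frame(embryo_id = paste0("e", 1:10),
                   relative_AB_size = c(59, 58.5, 57, 55, 53, 52, 51,
                                        50, 49, 46),
                   outcome = c(rep("alive", 5), rep("dead", 5)))
  out <- ab_size_analyses(md)
  expect_true(any(grepl("^\\(\\d+-\\d+\\]$", out$bins$bin)))
  expect_equal(sum(out$bins$n), 10)
  # bins are reported even when empty
  expect_true(all(c("n", "lethality") %in% names(out$bins)))
  all_alive <- md; all_alive$outcome <- "alive"
  expect_true(all(ab_size_analyses(all_alive)$bins$lethality %in%
                    c(0, NA)))
  # closed-form t from r on a hand-made table matches cor.test
  q <- setNames(md$relative_AB_size * 0.3 + rnorm(10, 0, 0.5),
                md$embryo_id)
  cr <- ab_size_analyses(md, quantity = q)$correlation
  ora <- cor.test(md$relative_AB_size, q)
  expect_equal(cr$r, unname(ora$estimate), tolerance = 1e-12)
  expect_equal(cr$p, ora$p.value, tolerance = 1e-12)
  expect_equal(cr$t, unname(ora$statistic), tolerance = 1e-12)
  # perfectly linear quantity gives r = 1
  lin <- setNames(md$relative_AB_size * 2 - 3, md$embryo_id)
  expect_equal(ab_size_analyses(md, quantity = lin)$correlation$r, 1)
})
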