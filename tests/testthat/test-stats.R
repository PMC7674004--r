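test_that("Mann-Whitney exact enumeration matches known p-values", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)  # 2/20 assignments as extreme
  # independent oracle: base R exact Wilcoxon
  expect_equal(r$p_value, wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value)
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_equal(mann_whitney(1:4, 1:4)$p_value, 1)
})

test_that("Mann-Whitney asymptotic p agrees with a permutation oracle", {
  set.seed(71)
  for (rep in 1:3) {
    x <- rnorm(20); y <- rnorm(20)
    p_asym <- mann_whitney(x, y, mode = "asymptotic")$p_value
    # Monte-Carlo permutation oracle on the U statistic
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[1:20]) - 20 * 21 / 2
    Us <- replicate(20000, {
      idx <- sample.int(40, 20)
      sum(r[idx]) - 20 * 21 / 2
    })
    p_mc <- 2 * min(mean(Us <= U), mean(Us >= U))
    expect_lt(abs(p_asym - min(p_mc, 1)), 0.02)
  }
})

test_that("Kruskal-Wallis: identity with Mann-Whitney, ties, and base R", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(15) + 0.7
  p_kw <- kruskal_wallis(list(x, y))$p_value
  p_mw <- mann_whitney(x, y, mode = "asymptotic")$p_value
  expect_lt(abs(p_kw - p_mw), 0.01)
  # independent oracle
  g <- list(rnorm(10), rnorm(12) + 1, rnorm(8) - 0.5)
  ours <- kruskal_wallis(g)
  base <- kruskal.test(unlist(g), rep(1:3, lengths(g)))
  expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, base$p.value, tolerance = 1e-10)
  # degenerate
  expect_equal(kruskal_wallis(list(rep(3, 5), rep(3, 4)))$statistic, 0)
  expect_equal(kruskal_wallis(list(rep(3, 5), rep(3, 4)))$p_value, 1)
  expect_error(kruskal_wallis(list(1:5)), ">= 2")
})

test_that("Kruskal-Wallis chi-square p matches a permutation p at n = 30", {
  set.seed(12)
  g <- list(rnorm(10), rnorm(10) + 0.8, rnorm(10))
  p_chi <- kruskal_wallis(g)$p_value
  pooled <- unlist(g)
  idx <- rep(1:3, each = 10)
  H_obs <- kruskal_wallis(g)$statistic
  Hs <- replicate(10000, {
    sh <- sample(pooled)
    kruskal_wallis(split(sh, idx))$statistic
  })
  expect_lt(abs(p_chi - mean(Hs >= H_obs - 1e-12)), 0.02)
})

test_that("permutation ANOVA is calibrated under the null", {
  ps <- vapply(1:200, function(s) {
    g <- with(list(), {
      set.seed(4000 + s)
      split(rnorm(24), rep(1:3, each = 8))
    })
    suppressWarnings(permutation_oneway(g, n_perm = 499, seed = s))$p_value
  }, numeric(1))
  D <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  expect_lt(D, 1.63 / sqrt(length(ps)) + 1 / 500)  # KS at 0.01 + lattice
  expect_true(all(ps >= 1 / 500))
})

test_that("permutation ANOVA detects a 5 SD shift", {
  set.seed(9)
  g <- list(rnorm(10), rnorm(10), rnorm(10) + 5)
  r <- permutation_oneway(g, n_perm = 10000, seed = 2)
  expect_lte(r$p_value, 0.001)
  expect_warning(permutation_oneway(g, n_perm = 200, seed = 1), "unstable")
})

test_that("pairwise permutation post hoc with BH adjustment", {
  set.seed(10)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 4)
  res <- suppressWarnings(pairwise_permutation_fdr(g, n_perm = 999, seed = 3))
  expect_equal(nrow(res), 3L)
  # the shifted group differs from both others
  expect_true(all(res$p_adjusted[res$group2 == "c"] < 0.05))
  # BH adjusted p's are monotone non-decreasing in raw-p order
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("AUROC equals the normalized Mann-Whitney U by enumeration", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(lab) || !any(lab)) next
    s <- sample(1:4, n, replace = TRUE)  # many ties
    # brute-force U with the 1/0.5/0 kernel
    pos <- s[lab]; neg <- s[!lab]
    u <- sum(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auroc(s, lab), u / (sum(lab) * sum(!lab)),
                 tolerance = 1e-12)
  }
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
})

test_that("DeLong test: degenerate cases and symmetry", {
  set.seed(30)
  lab <- rep(c(TRUE, FALSE), each = 20)
  s <- rnorm(40) + lab
  same <- delong_test(s, s, lab)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  s2 <- rnorm(40) + 0.5 * lab
  ab <- delong_test(s, s2, lab)
  ba <- delong_test(s2, s, lab)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$auc_a, auroc(s, lab))
  expect_error(delong_test(s, s2, rep(TRUE, 40)), "both classes")
})

test_that("DeLong variance matches the bootstrap variance within 15%", {
  set.seed(31)
  lab <- rep(c(TRUE, FALSE), each = 50)
  s <- rnorm(100) + 1.0 * lab
  pl <- octamls:::delong_placements(s, lab)
  v_delong <- var(pl$V10) / 50 + var(pl$V01) / 50
  boots <- replicate(5000, {
    ip <- sample(which(lab), replace = TRUE)
    im <- sample(which(!lab), replace = TRUE)
    auroc(c(s[ip], s[im]), c(lab[ip], lab[im]))
  })
  expect_lt(abs(v_delong - var(boots)) / var(boots), 0.15)
})

test_that("McNemar-Bowker statistic follows the symmetry formula", {
  sym <- matrix(c(10, 3, 2, 3, 8, 4, 2, 4, 6), 3, 3)
  r <- mcnemar_bowker(sym)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand-evaluated asymmetric pair: n12 = 5, n21 = 1, others symmetric
  tab <- matrix(c(10, 1, 2, 5, 8, 3, 2, 3, 6), 3, 3, byrow = TRUE)
  r2 <- mcnemar_bowker(tab)
  expect_equal(r2$statistic, 16 / 6, tolerance = 1e-12)
  expect_equal(r2$df, 3L)
  expect_equal(r2$p_value, pchisq(16 / 6, 3, lower.tail = FALSE))
  # K = 2 reduces to McNemar chi-square without continuity correction
  t2 <- matrix(c(20, 7, 2, 15), 2, 2)
  ours <- mcnemar_bowker(t2)
  base <- mcnemar.test(t2, correct = FALSE)
  expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
  expect_error(mcnemar_bowker(matrix(1, 2, 3)), "square")
})

test_that("stratified bootstrap CI: degenerate and containment properties", {
  lab <- factor(rep(c("a", "b"), each = 15))
  s <- c(rep(0, 15), rep(1, 15))  # perfect separation
  ci <- stratified_bootstrap_ci(function(l, x) auroc(x, l == "b"), lab, s,
                                n_boot = 1000, seed = 1)
  expect_equal(as.numeric(ci), c(1, 1))
  set.seed(3)
  s2 <- rnorm(30) + (lab == "b")
  point <- auroc(s2, lab == "b")
  ci2 <- stratified_bootstrap_ci(function(l, x) auroc(x, l == "b"), lab, s2,
                                 n_boot = 1000, seed = 2)
  expect_lte(ci2[1], point)
  expect_gte(ci2[2], point)
  expect_warning(
    stratified_bootstrap_ci(function(l, x) mean(x), lab, s2, n_boot = 200,
                            seed = 1),
    "unstable")
})

test_that("bootstrap AUROC CI coverage is near nominal", {
  true_auc <- pnorm(1 / sqrt(2))  # N(1,1) positives vs N(0,1) negatives
  lab <- factor(rep(c("neg", "pos"), each = 50))
  hits <- vapply(1:200, function(s) {
    scores <- with_seed_local(6000 + s, rnorm(100) + (lab == "pos"))
    ci <- stratified_bootstrap_ci(function(l, x) auroc(x, l == "pos"), lab,
                                  scores, n_boot = 1000, seed = s)
    ci[1] <= true_auc && true_auc <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.91)
  expect_lte(mean(hits), 0.99)
})

test_that("KS normality check calibrates and has power", {
  cal <- vapply(1:100, function(s) {
    ks_normality(with_seed_local(s, rnorm(100)))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(cal), 0.90)
  pow <- vapply(1:100, function(s) {
    ks_normality(with_seed_local(s, rexp(200)))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(pow), 0.90)
  d <- ks_normality(rnorm(50))$statistic
  expect_gte(d, 0)
  expect_lte(d, 1)
  expect_error(ks_normality(rep(2, 10)), "constant")
  expect_error(ks_normality(1:3), "n >= 5")
})

test_that("p-value heat grid marks non-significant cells with an X", {
  tb <- binary_cohort(12, 12, deficit_effect("superficial_IT", -60),
                      seed = 77)
  grid <- univariate_pvalue_grid(tb, "diagnosis")
  expect_equal(nrow(grid), 42L)
  p <- plot_pvalue_grid(grid)
  expect_s3_class(p, "ggplot")
  # the X layer's data contains exactly the p > 0.05 cells
  xdat <- ggplot2::layer_data(p, 2)
  expect_equal(nrow(xdat), sum(grid$p_value > 0.05))
  expect_true(all(xdat$label == "X"))
})
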