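test_result <- function(method, statistic, p_value, df = NA_real_,
                        n_perm = NA_integer_, ...) {
  p_value <- min(max(p_value, 0), 1)
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 df = df, n_perm = n_perm, ...),
            class = "octa_test")
}

#' @export
print.octa_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste(" df =", x$df),
      "\n  p-value =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided comparison of two independent samples. For small samples
#' (`n1 + n2 <= 12` in `"auto"` mode) the null distribution of the U
#' statistic is obtained by full enumeration of all label assignments of the
#' pooled sample (ties handled through midranks), and the two-sided p is
#' `2 * min(P(U <= u), P(U >= u))` capped at 1. Larger samples use the
#' tie-corrected normal approximation without continuity correction, which
#' makes the two-group Kruskal-Wallis identity `H = z^2` exact.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"` (exact when `n1 + n2 <= 12`), `"exact"` (full
#'   enumeration, refused above a combined size of 24) or `"asymptotic"`.
#' @return An `octa_test` with the U statistic and two-sided p-value.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (mode == "auto") mode <- if (N <= 12L) "exact" else "asymptotic"
  if (mode == "exact") {
    if (N > 24L) {
      stop("exact enumeration refused for n1 + n2 > 24; use asymptotic",
           call. = FALSE)
    }
    combos <- combn(N, n1)
    base <- n1 * (n1 + 1) / 2
    Us <- colSums(matrix(r[combos], nrow = n1)) - base
    p <- 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9))
    return(test_result("Mann-Whitney (exact enumeration)", U, p))
  }
  mu <- n1 * n2 / 2
  tie <- table(pooled)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sig2 <= 0) {
    return(test_result("Mann-Whitney (asymptotic)", U, 1))
  }
  z <- (U - mu) / sqrt(sig2)
  test_result("Mann-Whitney (asymptotic)", U, 2 * pnorm(-abs(z)), z = z)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction and chi-square p-value on
#' `length(groups) - 1` degrees of freedom. With two groups it is the square
#' of the Mann-Whitney z, so the two p-values agree.
#'
#' @param groups list of (non-empty) numeric samples, one per group.
#' @return An `octa_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  tie <- table(pooled)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  df <- length(groups) - 1
  if (C <= 0) return(test_result("Kruskal-Wallis", 0, 1, df = df))
  H <- H / C
  test_result("Kruskal-Wallis", H, pchisq(H, df, lower.tail = FALSE),
              df = df)
}

oneway_F <- function(pooled, idx, k, N) {
  gm <- mean(pooled)
  means <- tapply(pooled, idx, mean)
  sizes <- tabulate(idx, k)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((pooled - means[idx])^2)
  if (ssw <= 0) return(if (ssb > 0) Inf else 0)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' One-way permutation ANOVA
#'
#' Permutation test of equality of group locations: the observed one-way F
#' statistic is compared with its distribution under random reassignment of
#' group labels. The p-value uses the add-one estimator
#' `(1 + #(F* >= F)) / (1 + n_perm)`, so it is never below
#' `1 / (1 + n_perm)`.
#'
#' @param groups list of numeric samples.
#' @param n_perm number of label permutations (default 10000; below 999 a
#'   warning is issued but the test proceeds).
#' @param seed integer seed.
#' @return An `octa_test`.
#' @export
permutation_oneway <- function(groups, n_perm = 10000L, seed = 1L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (n_perm < 999L) {
    warning("n_perm < 999 gives unstable p-values", call. = FALSE)
  }
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  k <- length(groups)
  idx <- rep(seq_along(groups), lengths(groups))
  Fobs <- oneway_F(pooled, idx, k, N)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      oneway_F(pooled[sample.int(N)], idx, k, N) >= Fobs - 1e-12
    }, logical(1)))
  })
  test_result("one-way permutation ANOVA", Fobs, (1 + hits) / (1 + n_perm),
              df = k - 1, n_perm = as.integer(n_perm))
}

#' Pairwise post hoc permutation tests with FDR adjustment
#'
#' All pairwise two-sample permutation tests on the absolute mean difference,
#' with Benjamini-Hochberg false-discovery-rate adjustment across the pairs.
#'
#' @inheritParams permutation_oneway
#' @return data.frame with one row per pair: groups, statistic, raw and
#'   BH-adjusted p-values.
#' @export
pairwise_permutation_fdr <- function(groups, n_perm = 10000L, seed = 1L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (n_perm < 999L) {
    warning("n_perm < 999 gives unstable p-values", call. = FALSE)
  }
  nm <- names(groups) %||% as.character(seq_along(groups))
  pairs <- combn(length(groups), 2)
  res <- with_seed(seed, {
    apply(pairs, 2, function(pr) {
      a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
      pooled <- c(a, b)
      n1 <- length(a); N <- length(pooled)
      obs <- abs(mean(a) - mean(b))
      hits <- sum(vapply(seq_len(n_perm), function(bb) {
        sh <- pooled[sample.int(N)]
        abs(mean(sh[seq_len(n1)]) - mean(sh[-seq_len(n1)])) >= obs - 1e-12
      }, logical(1)))
      c(obs, (1 + hits) / (1 + n_perm))
    })
  })
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    statistic = res[1, ], p_value = res[2, ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Area under the ROC curve
#'
#' AUROC computed through the Mann-Whitney U identity on midranks, so tied
#' scores contribute 1/2.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels logical (or coercible) positive-class indicator.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  m <- sum(labels); n <- sum(!labels)
  if (m == 0L || n == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

# Placement values of DeLong: V10 over positives, V01 over negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  V10 <- (r_all[seq_len(m)] - rank(pos)) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
  list(auc = mean(V10), V10 = V10, V01 = V01)
}

#' DeLong test for two correlated ROC curves
#'
#' Nonparametric comparison of the AUROCs of two score vectors evaluated on
#' the same subjects, using the DeLong placement-value covariance estimate
#' and a two-sided z-test. Swapping the two score vectors negates z and
#' leaves p unchanged. Identical score vectors give z = 0, p = 1.
#'
#' @param scores_a,scores_b paired numeric score vectors.
#' @param labels logical (or coercible) positive-class indicator.
#' @return An `octa_test` with fields `auc_a`, `auc_b`, `variance`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  S10 <- stats::cov(cbind(pa$V10, pb$V10))
  S01 <- stats::cov(cbind(pa$V01, pb$V01))
  v <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
       (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  if (!is.finite(v) || v <= 1e-15) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  test_result("DeLong test for correlated ROC curves", z, p,
              auc_a = pa$auc, auc_b = pb$auc, variance = v)
}

#' McNemar-Bowker symmetry test
#'
#' Chi-square test of symmetry of a square contingency table:
#' `sum over i < j with n_ij + n_ji > 0 of (n_ij - n_ji)^2 / (n_ij + n_ji)`,
#' with degrees of freedom equal to the number of included pairs. For a 2x2
#' table this is McNemar's chi-square without continuity correction.
#'
#' @param table square matrix of nonnegative integer counts (e.g. paired
#'   classifications of the same subjects by two models).
#' @return An `octa_test`.
#' @export
mcnemar_bowker <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) {
    stop("contingency table must be square", call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be nonnegative", call. = FALSE)
  K <- nrow(table)
  stat <- 0; df <- 0L
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    s <- table[i, j] + table[j, i]
    if (s > 0) {
      stat <- stat + (table[i, j] - table[j, i])^2 / s
      df <- df + 1L
    }
  }
  p <- if (df == 0L || stat == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  test_result("McNemar-Bowker symmetry test", stat, p, df = df)
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples subjects with replacement within each class stratum (class
#' counts preserved, so metrics needing both classes stay defined) and
#' returns the percentile interval of the metric over the resamples.
#'
#' @param metric_fn function `(labels, x) -> scalar`.
#' @param labels factor (or coercible) of class labels defining the strata.
#' @param x per-subject data passed to `metric_fn`: a vector, or a matrix
#'   resampled by rows.
#' @param n_boot number of resamples (default 1000; fewer triggers a
#'   warning).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return Numeric `c(low, high)` with the bootstrap draws attached as
#'   attribute `values`.
#' @export
stratified_bootstrap_ci <- function(metric_fn, labels, x, n_boot = 1000L,
                                    seed = 1L, conf = 0.95) {
  labels <- as.factor(labels)
  if (n_boot < 1000L) {
    warning("n_boot < 1000 gives unstable intervals", call. = FALSE)
  }
  strata <- split(seq_along(labels), labels)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(strata, function(s) {
        s[sample.int(length(s), length(s), replace = TRUE)]
      }), use.names = FALSE)
      xs <- if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
      metric_fn(labels[idx], xs)
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  structure(c(low = ci[1], high = ci[2]), values = vals)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the sample against a normal distribution with
#' the sample mean and SD, with the asymptotic Kolmogorov p-value. Because
#' the parameters are estimated from the same sample the p-value is
#' conservative (the Lilliefors correction is not applied); this matches
#' common practice and is documented as such.
#'
#' @param sample numeric vector, `n >= 5`, non-constant.
#' @return An `octa_test` with the D statistic in `[0, 1]`.
#' @export
ks_normality <- function(sample) {
  n <- length(sample)
  if (n < 5L) stop("need n >= 5", call. = FALSE)
  if (sd(sample) == 0) stop("constant sample: normality undefined",
                            call. = FALSE)
  Fhat <- pnorm(sort(sample), mean(sample), sd(sample))
  D <- max(seq_len(n) / n - Fhat, Fhat - (seq_len(n) - 1) / n)
  t <- sqrt(n) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  test_result("Kolmogorov-Smirnov normality check", D, min(max(p, 0), 1))
}

#' Univariate p-value grid over the 42 features
#'
#' Tests every (layer, sector) feature against the task labels (Mann-Whitney
#' for binary tasks, Kruskal-Wallis for 3 or more groups) and returns the
#' grid in long form, ready for [plot_pvalue_grid()].
#'
#' @param table cohort feature table.
#' @param task `"diagnosis"`, `"type"` or `"severity"`.
#' @return data.frame `(layer, sector, feature, p_value)`.
#' @export
univariate_pvalue_grid <- function(table,
                                   task = c("diagnosis", "type", "severity")) {
  labels <- task_labels(table, task)
  rk <- rank_features_univariate(table, labels)
  parts <- strsplit(rk$feature, "_", fixed = TRUE)
  out <- data.frame(layer = vapply(parts, `[`, "", 1),
                    sector = vapply(parts, `[`, "", 2),
                    feature = rk$feature, p_value = rk$p_value,
                    stringsAsFactors = FALSE)
  out[order(match(out$layer, octa_layers()),
            match(out$sector, octa_sectors())), , drop = FALSE]
}

#' Heat-grid of -log10 p-values per (layer, sector)
#'
#' Renders the feature-significance grid with cells colored by
#' `-log10(p)`; cells whose p-value exceeds 0.05 are marked with an X
#' (not statistically significant).
#'
#' @param grid output of [univariate_pvalue_grid()].
#' @param alpha significance level for the X marks (default 0.05).
#' @return A ggplot object.
#' @export
plot_pvalue_grid <- function(grid, alpha = 0.05) {
  grid$layer <- factor(grid$layer, levels = octa_layers())
  grid$sector <- factor(grid$sector, levels = octa_sectors())
  grid$neglog10p <- -log10(pmax(grid$p_value, 1e-300))
  ns <- grid[grid$p_value > alpha, , drop = FALSE]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$sector, y = .data$layer,
                                     fill = .data$neglog10p)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(data = ns, label = "X", size = 5) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(x = "Garway-Heath sector", y = "OCTA layer") +
    ggplot2::theme_minimal()
}
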