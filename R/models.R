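#' Reference hyperparameter grids
#'
#' The exhaustive grids searched during inner 5-fold tuning: SVM over kernel
#' (linear / RBF), penalty C and RBF gamma across decades 1e-5..1e3 (gamma
#' ignored for the linear kernel); random forest over number of trees, split
#' quality, bootstrap, minimum leaf / split percentages and maximum depth;
#' gradient boosting over minimum child weight, learning rate, minimum loss
#' reduction, row and column subsampling, minimum leaf percentage and
#' maximum depth. `Inf` encodes unlimited depth. Leaf/split percentages are
#' percentages of training samples, converted to counts by ceiling.
#'
#' @param model `"svm"`, `"rf"` or `"xgb"`.
#' @return A data.frame with one row per configuration.
#' @export
default_grid <- function(model = c("svm", "rf", "xgb")) {
  model <- match.arg(model)
  decades <- 10^(-5:3)
  switch(model,
    svm = rbind(
      data.frame(kernel = "linear", C = decades, gamma = NA_real_),
      expand.grid(kernel = "rbf", C = decades, gamma = decades,
                  stringsAsFactors = FALSE)),
    rf = expand.grid(n_trees = c(10L, 25L, 50L),
                     split_quality = c("gini", "entropy"),
                     bootstrap = c(TRUE, FALSE),
                     min_leaf_pct = c(10, 30, 50),
                     min_split_pct = c(10, 30, 50),
                     max_depth = c(5, 10, 15, Inf),
                     stringsAsFactors = FALSE),
    xgb = expand.grid(min_child_weight = c(1, 5, 10),
                      learning_rate = c(0.01, 0.1, 0.25),
                      min_loss_reduction = c(0.1, 1, 3),
                      subsample = c(0.6, 0.8, 1),
                      colsample = c(0.6, 0.8, 1),
                      min_leaf_pct = c(10, 30, 50),
                      max_depth = c(5, 10, 15, Inf),
                      stringsAsFactors = FALSE))
}

pct_to_count <- function(pct, n) max(1L, as.integer(ceiling(pct / 100 * n)))

depth_to_int <- function(d) if (is.infinite(d)) 0L else as.integer(d)

## ---- support vector machine (dual QP via quadprog) ------------------------

kernel_matrix <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(A %*% t(B))
  # RBF: exp(-gamma * ||a - b||^2)
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

# C-SVM trained by solving the standard dual QP. Features are standardized
# with training-split statistics. y must be a two-level factor; the second
# level is the positive class and receives positive decision values.
svm_fit <- function(X, y, kernel = "linear", C = 1, gamma = NULL) {
  X <- as.matrix(X)
  lev <- levels(y)
  stopifnot(length(lev) == 2L)
  yv <- ifelse(y == lev[2], 1, -1)
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  n <- nrow(Xs)
  K <- kernel_matrix(Xs, Xs, kernel, gamma)
  D <- (yv %o% yv) * K
  D <- D + diag(1e-7 * (mean(diag(D)) + 1), n)
  A <- cbind(yv, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  f0 <- as.vector(K %*% (a * yv))
  eps <- 1e-6 * C
  free <- a > eps & a < C - eps
  if (any(free)) {
    b <- mean(yv[free] - f0[free])
  } else {
    up <- (yv > 0 & a < C - eps) | (yv < 0 & a > eps)
    lo <- (yv > 0 & a > eps) | (yv < 0 & a < C - eps)
    hi_b <- if (any(up)) min(yv[up] - f0[up]) else 0
    lo_b <- if (any(lo)) max(yv[lo] - f0[lo]) else 0
    b <- (hi_b + lo_b) / 2
  }
  sv <- a > eps
  structure(list(kernel = kernel, C = C, gamma = gamma, levels = lev,
                 mu = mu, sigma = sg, X_sv = Xs[sv, , drop = FALSE],
                 coef_sv = (a * yv)[sv], b = b),
            class = "octa_svm")
}

svm_decision <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$mu), 2, fit$sigma, "/")
  if (nrow(fit$X_sv) == 0L) return(rep(fit$b, nrow(Xs)))
  K <- kernel_matrix(Xs, fit$X_sv, fit$kernel, fit$gamma)
  as.vector(K %*% fit$coef_sv) + fit$b
}

## ---- random forest --------------------------------------------------------

# Bagged CART ensemble; per-node feature subsampling of floor(sqrt(p))
# features; class probability = mean of per-tree leaf class frequencies.
rf_fit <- function(X, y, n_trees = 50L, split_quality = "gini",
                   bootstrap = TRUE, min_leaf_pct = 10, min_split_pct = 10,
                   max_depth = Inf) {
  X <- as.matrix(X)
  lev <- levels(y)
  yi <- as.integer(y) - 1L
  n <- nrow(X)
  crit <- if (split_quality == "entropy") 1L else 0L
  mtry <- max(1L, floor(sqrt(ncol(X))))
  min_leaf <- pct_to_count(min_leaf_pct, n)
  min_split <- pct_to_count(min_split_pct, n)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    trees[[t]] <- .build_tree_cpp(X, yi, numeric(0), numeric(0),
                                  as.integer(idx - 1L), length(lev), 0L,
                                  crit, depth_to_int(max_depth),
                                  min_split, min_leaf, mtry, 0, 0, 0)
  }
  structure(list(trees = trees, levels = lev), class = "octa_rf")
}

rf_prob <- function(fit, X) {
  X <- as.matrix(X)
  p <- matrix(0, nrow(X), length(fit$levels))
  for (tr in fit$trees) p <- p + .predict_tree_cpp(tr, X)
  colnames(p) <- fit$levels
  p / length(fit$trees)
}

## ---- gradient boosting ----------------------------------------------------

# Second-order gradient boosting of regression trees on the logistic loss
# (binary). Leaf weights -G/(H + lambda); split gain thresholded by the
# minimum loss reduction; row subsampling without replacement and column
# subsampling per tree.
xgb_fit <- function(X, y, n_rounds = 100L, learning_rate = 0.1,
                    min_child_weight = 1, min_loss_reduction = 0,
                    subsample = 1, colsample = 1, min_leaf_pct = 10,
                    max_depth = 5, lambda = 1) {
  X <- as.matrix(X)
  lev <- levels(y)
  stopifnot(length(lev) == 2L)
  yv <- as.numeric(y == lev[2])
  n <- nrow(X)
  p <- ncol(X)
  min_leaf <- pct_to_count(min_leaf_pct, n)
  f <- rep(0, n)
  trees <- vector("list", n_rounds)
  cols <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    prob <- 1 / (1 + exp(-f))
    g <- prob - yv
    h <- pmax(prob * (1 - prob), 1e-12)
    idx <- if (subsample < 1) {
      sample.int(n, max(2L, floor(subsample * n)))
    } else {
      seq_len(n)
    }
    cl <- if (colsample < 1) {
      sort(sample.int(p, max(1L, floor(colsample * p))))
    } else {
      seq_len(p)
    }
    tr <- .build_tree_cpp(X[, cl, drop = FALSE], integer(0), g, h,
                          as.integer(idx - 1L), 0L, 1L, 0L,
                          depth_to_int(max_depth), 2L, min_leaf, 0L,
                          min_child_weight, lambda, min_loss_reduction)
    trees[[t]] <- tr
    cols[[t]] <- cl
    f <- f + learning_rate *
      as.vector(.predict_tree_cpp(tr, X[, cl, drop = FALSE]))
  }
  structure(list(trees = trees, cols = cols, eta = learning_rate,
                 levels = lev), class = "octa_xgb")
}

xgb_prob <- function(fit, X) {
  X <- as.matrix(X)
  f <- rep(0, nrow(X))
  for (t in seq_along(fit$trees)) {
    f <- f + fit$eta *
      as.vector(.predict_tree_cpp(fit$trees[[t]],
                                  X[, fit$cols[[t]], drop = FALSE]))
  }
  1 / (1 + exp(-f))
}

## ---- unified binary interface --------------------------------------------

# Fit one binary classifier from a grid row. `y` must be a two-level factor;
# scores returned by predict_score are signed decision values for the SVM
# and positive-class probabilities for the tree ensembles (both orderings
# are valid ROC scores; documented choice).
fit_binary <- function(model, X, y, params, seed = 1L) {
  lev <- levels(y)
  if (length(unique(y)) < 2L) {
    # degenerate training split: constant classifier on the observed class
    return(structure(list(levels = lev, constant = as.character(y[1])),
                     class = "octa_constant"))
  }
  with_seed(seed, switch(model,
    svm = svm_fit(X, y, kernel = params$kernel, C = params$C,
                  gamma = params$gamma),
    rf = rf_fit(X, y, n_trees = params$n_trees,
                split_quality = as.character(params$split_quality),
                bootstrap = params$bootstrap,
                min_leaf_pct = params$min_leaf_pct,
                min_split_pct = params$min_split_pct,
                max_depth = params$max_depth),
    xgb = xgb_fit(X, y, min_child_weight = params$min_child_weight,
                  learning_rate = params$learning_rate,
                  min_loss_reduction = params$min_loss_reduction,
                  subsample = params$subsample, colsample = params$colsample,
                  min_leaf_pct = params$min_leaf_pct,
                  max_depth = params$max_depth),
    stop("unknown model: ", model)))
}

predict_score <- function(fit, X) {
  if (inherits(fit, "octa_constant")) {
    s <- if (fit$constant == fit$levels[2]) 1 else -1
    return(rep(s, nrow(as.matrix(X))))
  }
  switch(class(fit),
         octa_svm = svm_decision(fit, X),
         octa_rf = rf_prob(fit, X)[, fit$levels[2]],
         octa_xgb = xgb_prob(fit, X),
         stop("unknown fit class"))
}

predict_label_binary <- function(fit, X) {
  s <- predict_score(fit, X)
  thr <- if (inherits(fit, "octa_svm") || inherits(fit, "octa_constant")) {
    0
  } else {
    0.5
  }
  factor(ifelse(s > thr, fit$levels[2], fit$levels[1]), levels = fit$levels)
}

## ---- one-versus-all wrapper for multiclass --------------------------------

# One classifier per class (that class positive, the rest negative);
# predicted class is the argmax of the per-class scores.
fit_ova <- function(model, X, y, params, seed = 1L) {
  lev <- levels(y)
  fits <- lapply(seq_along(lev), function(i) {
    yb <- factor(ifelse(y == lev[i], "pos", "rest"), levels = c("rest", "pos"))
    fit_binary(model, X, yb, params, seed = derive_seed(seed, lev[i]))
  })
  structure(list(fits = fits, levels = lev), class = "octa_ova")
}

ova_scores <- function(fit, X) {
  nr <- nrow(as.matrix(X))
  s <- vapply(fit$fits, function(f) predict_score(f, X), numeric(nr))
  s <- matrix(s, nrow = nr)
  colnames(s) <- fit$levels
  s
}

ova_predict <- function(fit, X) {
  s <- ova_scores(fit, X)
  factor(fit$levels[max.col(s, ties.method = "first")], levels = fit$levels)
}

# Dispatch on the number of classes.
fit_any <- function(model, X, y, params, seed = 1L) {
  if (nlevels(y) == 2L) fit_binary(model, X, y, params, seed)
  else fit_ova(model, X, y, params, seed)
}

predict_any <- function(fit, X) {
  if (inherits(fit, "octa_ova")) ova_predict(fit, X)
  else predict_label_binary(fit, X)
}
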