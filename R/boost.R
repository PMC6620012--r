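# Second-order gradient-boosted decision trees for weighted binary
# classification, with per-split gradient/Hessian statistics retained so the
# regularised feature-gain formula is computable exactly from the model.

#' Boosting configuration
#'
#' @param n_estimators number of trees (>= 1).
#' @param learning_rate shrinkage eta applied to each tree's output.
#' @param lambda L2 regularization on leaf weights.
#' @param alpha L1 regularization (soft-threshold shrinkage).
#' @param gamma per-split penalty subtracted from every gain.
#' @param max_features features sampled (without replacement) at each node;
#'   default NULL = floor(sqrt(d)), the membrane-classifier convention.
#' @param min_samples_leaf minimum samples in a child.
#' @param max_depth maximum tree depth; NULL (the default) leaves depth
#'   unbounded.
#' @param seed integer seed controlling feature subsampling.
#' @return object of class `boost_config`.
#' @export
boost_config <- function(n_estimators = 100, learning_rate = 0.3,
                         lambda = 1, alpha = 0, gamma = 0,
                         max_features = NULL, min_samples_leaf = 1,
                         max_depth = NULL, seed = 1) {
  stopifnot(n_estimators >= 1, learning_rate > 0,
            lambda >= 0, alpha >= 0, gamma >= 0, min_samples_leaf >= 1,
            is.null(max_depth) || max_depth >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate, lambda = lambda,
                 alpha = alpha, gamma = gamma, max_features = max_features,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_depth = if (is.null(max_depth)) NULL
                             else as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "boost_config")
}

#' Soft-threshold (L1 shrinkage) function
#'
#' `f_alpha(x) = x + alpha` if `x < -alpha`, `x - alpha` if `x > alpha`,
#' and 0 otherwise.
#'
#' @param x numeric vector.
#' @param alpha non-negative shrinkage.
#' @return numeric vector.
#' @export
soft_threshold <- function(x, alpha) {
  stopifnot(alpha >= 0)
  ifelse(x > alpha, x - alpha, ifelse(x < -alpha, x + alpha, 0))
}

#' Regularised second-order split gain
#'
#' `FG = 1/2 (f_a(G_L)^2/(H_L+lambda) + f_a(G_R)^2/(H_R+lambda)
#'       - f_a(G)^2/(H+lambda)) - gamma`, where G and H are the summed
#' gradients and Hessians of the loss on the node and its children.
#'
#' @param stats list (or one-row data.frame) with G, H, G_L, H_L, G_R, H_R.
#' @param config a [boost_config()] supplying lambda, alpha, gamma.
#' @return single numeric gain.
#' @export
split_gain <- function(stats, config = boost_config()) {
  G <- stats$G; H <- stats$H
  GL <- stats$G_L; HL <- stats$H_L
  GR <- stats$G_R; HR <- stats$H_R
  stopifnot(abs(GL + GR - G) < 1e-9, abs(HL + HR - H) < 1e-9)
  la <- config$lambda
  if (H + la == 0 || HL + la == 0 || HR + la == 0) {
    stop("undefined split gain: zero Hessian-plus-lambda denominator")
  }
  sc <- function(g, h) soft_threshold(g, config$alpha)^2 / (h + la)
  0.5 * (sc(GL, HL) + sc(GR, HR) - sc(G, H)) - config$gamma
}

#' Fit a boosted-tree classifier
#'
#' Logistic loss on labels +1/-1 with per-sample weights: gradient
#' `g = w (p - y01)`, Hessian `h = w p (1 - p)` with `y01 = (y+1)/2`. Trees
#' are grown exact-greedy with `max_features` features sampled per node and
#' a split accepted only when its gain is positive; depth is unbounded.
#' Deterministic for a fixed seed; the model with fewer trees is an exact
#' prefix of the model with more (the RNG stream is consumed tree by tree).
#'
#' @param X numeric matrix (n x d), no missing values.
#' @param y labels +1 / -1, both classes present.
#' @param sample_weights optional non-negative per-sample weights.
#' @param config a [boost_config()].
#' @return object of class `boosted_model`.
#' @export
boost_fit <- function(X, y, sample_weights = NULL,
                      config = boost_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= 2, length(y) == n, all(y %in% c(-1, 1)),
            all(is.finite(X)))
  if (length(unique(y)) < 2) {
    stop("degenerate fit: only one class present in y")
  }
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  stopifnot(length(sample_weights) == n, all(sample_weights >= 0))
  mf <- config$max_features
  if (is.null(mf)) mf <- max(1L, floor(sqrt(d)))
  stopifnot(mf >= 1, mf <= d)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  y01 <- (y + 1) / 2
  raw <- rep(0, n)  # base score 0.5 on the probability scale
  trees <- vector("list", config$n_estimators)
  for (m in seq_len(config$n_estimators)) {
    p <- 1 / (1 + exp(-raw))
    g <- sample_weights * (p - y01)
    h <- sample_weights * p * (1 - p)
    tree <- .build_tree_cpp(X, g, h, config$lambda, config$alpha,
                            config$gamma, as.integer(mf),
                            config$min_samples_leaf,
                            if (is.null(config$max_depth)) -1L
                            else config$max_depth)
    trees[[m]] <- tree
    raw <- raw + config$learning_rate * .predict_tree_cpp(tree, X)
  }
  structure(list(trees = trees, config = config, d = d,
                 feature_names = colnames(X),
                 base_raw = 0,
                 layout_version = LAYOUT_VERSION),
            class = "boosted_model")
}

#' @export
print.boosted_model <- function(x, ...) {
  n_splits <- sum(vapply(x$trees, function(t) sum(!is.na(t$feature)),
                         numeric(1)))
  cat("boosted_model:", length(x$trees), "trees,", n_splits, "splits,",
      x$d, "features\n")
  invisible(x)
}

#' @keywords internal
check_predict_input <- function(model, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$d) {
    stop("X has ", ncol(X), " columns; the model was trained on ", model$d)
  }
  X
}

#' Raw (logit-scale) prediction
#' @keywords internal
boost_raw <- function(model, X, n_trees = NULL) {
  X <- check_predict_input(model, X)
  if (is.null(n_trees)) n_trees <- length(model$trees)
  raw <- rep(model$base_raw, nrow(X))
  eta <- model$config$learning_rate
  for (m in seq_len(n_trees)) {
    raw <- raw + eta * .predict_tree_cpp(model$trees[[m]], X)
  }
  raw
}

#' Predict class scores
#'
#' @param model a [boost_fit()] model.
#' @param X feature matrix with the training column count.
#' @param n_trees evaluate only the first `n_trees` trees (default all).
#' @return scores in (0, 1) (probability of the +1 class).
#' @export
predict_score <- function(model, X, n_trees = NULL) {
  1 / (1 + exp(-boost_raw(model, X, n_trees)))
}

#' Predict labels
#'
#' @inheritParams predict_score
#' @param threshold score cutoff; label +1 iff score > threshold.
#' @return labels in {+1, -1}.
#' @export
predict_label <- function(model, X, threshold = 0.5, n_trees = NULL) {
  ifelse(predict_score(model, X, n_trees) > threshold, 1, -1)
}

#' Staged scores after 1..n_estimators trees
#'
#' @inheritParams predict_score
#' @return matrix nrow(X) x n_trees of scores; column m uses the first m
#'   trees.
#' @export
staged_scores <- function(model, X) {
  X <- check_predict_input(model, X)
  n <- nrow(X); M <- length(model$trees)
  eta <- model$config$learning_rate
  raw <- rep(model$base_raw, n)
  out <- matrix(NA_real_, n, M)
  for (m in seq_len(M)) {
    raw <- raw + eta * .predict_tree_cpp(model$trees[[m]], X)
    out[, m] <- 1 / (1 + exp(-raw))
  }
  out
}

#' Per-feature gain
#'
#' The mean of the regularised split gain over every split that uses the
#' feature, across all trees; features never used score 0.
#'
#' @param model a [boost_fit()] model.
#' @return numeric vector of length d (named if the training matrix had
#'   column names).
#' @export
feature_gain <- function(model) {
  sums <- numeric(model$d)
  counts <- numeric(model$d)
  for (tree in model$trees) {
    sp <- !is.na(tree$feature)
    if (!any(sp)) next
    f <- tree$feature[sp]
    g <- tree$gain[sp]
    for (i in seq_along(f)) {
      sums[f[i]] <- sums[f[i]] + g[i]
      counts[f[i]] <- counts[f[i]] + 1
    }
  }
  fg <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  names(fg) <- model$feature_names
  fg
}

#' Gain-based feature selection
#'
#' Keeps feature j iff `fg[j] >= fraction * max(fg)`.
#'
#' @param fg non-negative feature gains.
#' @param fraction retention threshold as a fraction of the maximum gain.
#' @return integer indices of the retained features, in original order.
#' @export
select_features <- function(fg, fraction = 0.01) {
  stopifnot(all(fg >= 0))
  if (max(fg) == 0) stop("all feature gains are zero: empty selection")
  which(fg >= fraction * max(fg))
}

#' Serialize a boosted model to JSON
#'
#' Trees are stored node by node with their split statistics, so a loaded
#' model reproduces predictions and feature gains exactly.
#'
#' @param model a [boost_fit()] model.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    class = "boosted_model",
    layout_version = model$layout_version,
    d = model$d,
    base_raw = model$base_raw,
    feature_names = model$feature_names,
    config = unclass(model$config),
    trees = lapply(model$trees, as.data.frame))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a boosted model saved by [save_model()]
#'
#' @param path JSON path.
#' @return a `boosted_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$class, "boosted_model")) {
    stop("not a serialized boosted_model: ", path)
  }
  cfg <- payload$config
  config <- boost_config(n_estimators = cfg$n_estimators,
                         learning_rate = cfg$learning_rate,
                         lambda = cfg$lambda, alpha = cfg$alpha,
                         gamma = cfg$gamma,
                         max_features = cfg$max_features,
                         min_samples_leaf = cfg$min_samples_leaf,
                         max_depth = cfg$max_depth,
                         seed = cfg$seed)
  trees <- payload$trees
  if (is.data.frame(trees)) trees <- list(trees)
  trees <- lapply(trees, function(t) {
    t$feature <- as.integer(t$feature)
    t$left <- as.integer(t$left)
    t$right <- as.integer(t$right)
    t
  })
  structure(list(trees = trees, config = config, d = payload$d,
                 feature_names = payload$feature_names,
                 base_raw = payload$base_raw,
                 layout_version = payload$layout_version),
            class = "boosted_model")
}
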