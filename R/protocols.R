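# Evaluation protocols: class weighting, z-normalization, the five
# classification metrics, repeated k-fold cross-validation with paired
# t-statistic estimator selection, train/test splitting, leave-one-protein-
# out validation and the saturation scan.

#' Imbalance class weights
#'
#' Disease (+1) samples are weighted N-/(N- + N+), benign (-1) samples
#' N+/(N- + N+), where N+ and N- count the disease and benign samples. The
#' two class weights always sum to 1.
#'
#' @param labels vector of +1/-1 labels, both classes present.
#' @return per-sample weight vector.
#' @export
class_weights <- function(labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  tot <- n_pos + n_neg
  ifelse(labels == 1, n_neg / tot, n_pos / tot)
}

#' Fit z-normalization statistics on training data
#'
#' Column means and population standard deviations (denominator n).
#' Constant columns get standard deviation 1 so they transform to all-zero.
#'
#' @param X_train numeric matrix.
#' @return list with `means` and `stds`.
#' @export
zscore_fit <- function(X_train) {
  X_train <- as.matrix(X_train)
  stopifnot(nrow(X_train) >= 1)
  means <- colMeans(X_train)
  stds <- sqrt(colMeans(sweep(X_train, 2, means)^2))
  stds[stds == 0] <- 1
  list(means = means, stds = stds)
}

#' Apply z-normalization statistics
#'
#' @param X numeric matrix.
#' @param norm a [zscore_fit()] result.
#' @return transformed matrix.
#' @export
zscore_apply <- function(X, norm) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, norm$means), 2, norm$stds, `/`)
}

#' Confusion counts from truth and predictions
#'
#' TP: disease (+1) predicted disease; TN: benign predicted benign; FP:
#' benign predicted disease; FN: disease predicted benign.
#'
#' @param truth,pred vectors of +1/-1.
#' @return list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(truth, pred) {
  list(TP = sum(truth == 1 & pred == 1),
       TN = sum(truth == -1 & pred == -1),
       FP = sum(truth == -1 & pred == 1),
       FN = sum(truth == 1 & pred == -1))
}

#' The five classification metrics from confusion counts
#'
#' accuracy (TP+TN)/total, precision TP/(TP+FP), recall TP/(TP+FN),
#' F1 = 2 P R/(P+R) and the Matthews correlation coefficient. Any metric
#' with a zero denominator is defined as 0.
#'
#' @param counts list with TP, TN, FP, FN (as from [confusion_counts()]).
#' @return list of class `metrics_report`: accuracy, precision, recall, f1,
#'   mcc, counts.
#' @export
metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0, TP + TN + FP + FN >= 1)
  div <- function(num, den) if (den == 0) 0 else num / den
  accuracy <- div(TP + TN, TP + TN + FP + FN)
  precision <- div(TP, TP + FP)
  recall <- div(TP, TP + FN)
  f1 <- div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- div(TP * TN - FP * FN, mcc_den)
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, mcc = mcc, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f%%  precision %.1f%%  recall %.1f%%  F1 %.1f%%  MCC %.2f\n",
    100 * x$accuracy, 100 * x$precision, 100 * x$recall, 100 * x$f1, x$mcc))
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$counts$TP, x$counts$TN,
              x$counts$FP, x$counts$FN))
  invisible(x)
}

#' @keywords internal
metric_value <- function(truth, pred, metric = "mcc") {
  metrics(confusion_counts(truth, pred))[[metric]]
}

#' @keywords internal
draw_folds <- function(y, k, max_tries = 100) {
  n <- length(y)
  for (try in seq_len(max_tries)) {
    fold <- sample(rep(seq_len(k), length.out = n))
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- y[fold != f]
      length(unique(tr)) == 2
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not draw folds with both classes in every training part")
}

#' Repeated k-fold cross-validation over an estimator grid
#'
#' `reps` repetitions of `k`-fold cross-validation. Fold assignments are
#' drawn once per repetition (re-drawn, still seeded, if any training part
#' is single-class) and reused across every grid value, giving a paired
#' design. Class weights and z-normalization are recomputed inside each fold
#' from its training part only. The per-fold metric (MCC by default) is
#' evaluated for every number of estimators in the grid from one staged fit
#' per fold.
#'
#' @param X feature matrix.
#' @param y labels +1/-1.
#' @param estimator_grid numbers of trees to evaluate.
#' @param reps repetitions.
#' @param k folds.
#' @param seed integer seed.
#' @param metric one of "mcc", "accuracy", "precision", "recall", "f1".
#' @param config_template [boost_config()] supplying the other
#'   hyperparameters (its n_estimators and seed are overridden).
#' @return object of class `cv_result`: `grid`, `metric_values` (reps*k rows
#'   by grid columns), `metric`, `folds`, `seed`.
#' @export
repeated_cv <- function(X, y, estimator_grid = 1:100, reps = 20, k = 5,
                        seed = 1, metric = "mcc",
                        config_template = boost_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= k, length(y) == n)
  estimator_grid <- sort(unique(as.integer(estimator_grid)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- lapply(seq_len(reps), function(r) draw_folds(y, k))
  max_n <- max(estimator_grid)
  vals <- matrix(NA_real_, reps * k, length(estimator_grid))
  row <- 0
  for (r in seq_len(reps)) {
    fold <- folds[[r]]
    for (f in seq_len(k)) {
      row <- row + 1
      tr <- which(fold != f); te <- which(fold == f)
      norm <- zscore_fit(X[tr, , drop = FALSE])
      Xtr <- zscore_apply(X[tr, , drop = FALSE], norm)
      Xte <- zscore_apply(X[te, , drop = FALSE], norm)
      w <- class_weights(y[tr])
      cfg <- config_template
      cfg$n_estimators <- max_n
      cfg$seed <- (seed * 9973L + r * 101L + f) %% 2147483647L
      fit <- boost_fit(Xtr, y[tr], sample_weights = w, config = cfg)
      sc <- staged_scores(fit, Xte)
      for (gi in seq_along(estimator_grid)) {
        pred <- ifelse(sc[, estimator_grid[gi]] > 0.5, 1, -1)
        vals[row, gi] <- metric_value(y[te], pred, metric)
      }
    }
  }
  structure(list(grid = estimator_grid, metric_values = vals,
                 metric = metric, folds = folds, seed = seed),
            class = "cv_result")
}

#' Paired t-statistic of each grid point against a reference
#'
#' For each number of estimators n, the paired t-statistic of the per-fold
#' metric differences against the reference grid point:
#' `t = mean(d) / (sd(d)/sqrt(m))` with sd over m-1. All-zero differences
#' give t = 0; zero spread with non-zero mean gives a signed large sentinel
#' (+/- 1e6).
#'
#' @param cv a [repeated_cv()] result.
#' @param ref_n reference number of estimators (must be in the grid).
#' @return named numeric vector of t-statistics, one per grid point.
#' @export
tstat_vs_reference <- function(cv, ref_n = 50) {
  stopifnot(inherits(cv, "cv_result"))
  ref_col <- match(ref_n, cv$grid)
  if (is.na(ref_col)) stop("ref_n = ", ref_n, " is not in the CV grid")
  m <- nrow(cv$metric_values)
  if (m < 2) stop("need at least 2 paired fold values")
  ref <- cv$metric_values[, ref_col]
  t_of <- function(col) {
    d <- cv$metric_values[, col] - ref
    mu <- mean(d); s <- stats::sd(d)
    if (s == 0) {
      if (mu == 0) 0 else sign(mu) * 1e6
    } else {
      mu / (s / sqrt(m))
    }
  }
  stats::setNames(vapply(seq_along(cv$grid), t_of, numeric(1)),
                  cv$grid)
}

#' Pick the number of estimators using the test set
#'
#' Ranks the grid by the paired t-statistic against `ref_n`, takes the top
#' `top` grid points, refits on the full training data (class weights and
#' normalization recomputed) and returns the number of estimators with the
#' highest test metric; ties go to the smaller number.
#'
#' @param cv a [repeated_cv()] result computed on (X, y).
#' @param X,y the training data the CV ran on.
#' @param X_test,y_test held-out test data, disjoint from (X, y).
#' @param top how many top-ranked grid points to evaluate on the test set.
#' @param ref_n reference grid point for the t-statistic.
#' @param config_template [boost_config()] supplying hyperparameters.
#' @return list with `chosen_n`, `candidates`, `test_metric` (named by n),
#'   `tstat`.
#' @export
select_estimators <- function(cv, X, y, X_test, y_test, top = 25,
                              ref_n = 50, config_template = boost_config()) {
  tstat <- tstat_vs_reference(cv, ref_n = ref_n)
  ord <- order(-tstat, cv$grid)  # ties: smaller n first
  cand <- cv$grid[ord][seq_len(min(top, length(cv$grid)))]
  norm <- zscore_fit(X)
  Xtr <- zscore_apply(X, norm)
  Xte <- zscore_apply(X_test, norm)
  w <- class_weights(y)
  cfg <- config_template
  cfg$n_estimators <- max(cand)
  fit <- boost_fit(Xtr, y, sample_weights = w, config = cfg)
  sc <- staged_scores(fit, Xte)
  test_metric <- vapply(cand, function(n) {
    pred <- ifelse(sc[, n] > 0.5, 1, -1)
    metric_value(y_test, pred, cv$metric)
  }, numeric(1))
  names(test_metric) <- cand
  best <- max(test_metric)
  chosen <- min(cand[test_metric == best])
  list(chosen_n = chosen, candidates = cand, test_metric = test_metric,
       tstat = tstat)
}

#' Random train/test split
#'
#' Uniform, unstratified, seeded split into (1 - test_fraction) training and
#' test_fraction test rows.
#'
#' @param n number of rows (or a data.frame/matrix whose rows are split).
#' @param test_fraction fraction assigned to the test set.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, test_fraction = 0.10, seed = 1) {
  if (!is.numeric(n) || length(n) > 1) n <- nrow(n)
  stopifnot(n >= 10)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_test <- round(n * test_fraction)
  test <- sort(sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Leave-one-protein-out validation
#'
#' One fold per protein: the model is trained on the mutations of all other
#' proteins (class weights and normalization recomputed per fold) and
#' evaluated on the held-out protein's mutations. Folds whose training part
#' is single-class are skipped with a warning.
#'
#' @param X feature matrix.
#' @param y labels +1/-1.
#' @param protein_ids protein identifier per row.
#' @param config a [boost_config()] (n_estimators as desired).
#' @return list with `per_protein` (data.frame protein, n, correct),
#'   `ratio` (overall fraction correct) and `skipped`.
#' @export
leave_one_protein_out <- function(X, y, protein_ids,
                                  config = boost_config()) {
  X <- as.matrix(X)
  proteins <- unique(protein_ids)
  stopifnot(length(proteins) >= 2)
  rows <- list(); skipped <- character(0)
  for (p in proteins) {
    te <- which(protein_ids == p)
    tr <- which(protein_ids != p)
    if (length(unique(y[tr])) < 2) {
      warning("skipping protein ", p, ": single-class training fold")
      skipped <- c(skipped, p)
      next
    }
    norm <- zscore_fit(X[tr, , drop = FALSE])
    fit <- boost_fit(zscore_apply(X[tr, , drop = FALSE], norm), y[tr],
                     sample_weights = class_weights(y[tr]), config = config)
    pred <- predict_label(fit, zscore_apply(X[te, , drop = FALSE], norm))
    rows[[p]] <- data.frame(protein = p, n = length(te),
                            correct = sum(pred == y[te]),
                            stringsAsFactors = FALSE)
  }
  per_protein <- do.call(rbind, rows)
  rownames(per_protein) <- NULL
  list(per_protein = per_protein,
       ratio = sum(per_protein$correct) / sum(per_protein$n),
       skipped = skipped)
}

#' In-silico saturation mutagenesis scan
#'
#' For every eligible scanned position, builds the 19 possible substitutions
#' (mutant model, descriptor, normalization, prediction). Ineligible
#' positions (incomplete backbone or non-standard residue) produce no
#' predictions and are listed in the skip report.
#'
#' @param wt wild-type [structure_model()].
#' @param chain chain identifier.
#' @param model trained [boost_fit()] model on the 96-feature layout.
#' @param norm [zscore_fit()] statistics matching the model's training.
#' @param positions author residue numbers to scan (default: all residues of
#'   the chain).
#' @param repack a [repack_config()].
#' @param feature_idx optional column subset the model was trained on.
#' @return list with `predictions` (data.frame chain, position, wt_aa,
#'   mut_aa, score, label) and `skipped` (positions with reasons).
#' @export
saturation_scan <- function(wt, chain, model, norm, positions = NULL,
                            repack = repack_config(), feature_idx = NULL) {
  res <- wt$residues[wt$residues$chain == chain, ]
  if (is.null(positions)) positions <- res$resno
  wt_ctx <- model_context(wt)
  preds <- list(); skipped <- list()
  for (pos in positions) {
    row <- which(res$resno == pos)
    if (length(row) != 1 || !res$eligible[row]) {
      skipped[[length(skipped) + 1]] <- data.frame(
        position = pos,
        reason = if (length(row) != 1) "missing residue"
                 else "incomplete backbone or non-standard residue")
      next
    }
    wt_aa <- res$aa[row]
    for (mut_aa in setdiff(AA1, wt_aa)) {
      rec <- data.frame(protein_id = "scan", pdb_id = "scan", chain = chain,
                        position = pos, wt_aa = wt_aa, mut_aa = mut_aa,
                        region = "M", label = NA_real_,
                        stringsAsFactors = FALSE)
      v <- full_descriptor(rec, wt, config = repack, wt_ctx = wt_ctx)
      x <- zscore_apply(matrix(v, 1), norm)
      if (!is.null(feature_idx)) x <- x[, feature_idx, drop = FALSE]
      score <- predict_score(model, x)
      preds[[length(preds) + 1]] <- data.frame(
        chain = chain, position = pos, wt_aa = wt_aa, mut_aa = mut_aa,
        score = score, label = ifelse(score > 0.5, 1, -1),
        stringsAsFactors = FALSE)
    }
  }
  list(predictions = if (length(preds)) do.call(rbind, preds) else
         data.frame(chain = character(0), position = integer(0),
                    wt_aa = character(0), mut_aa = character(0),
                    score = numeric(0), label = numeric(0)),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(position = integer(0), reason = character(0)))
}

#' The full training protocol on a labelled feature matrix
#'
#' Runs the whole pipeline: unstratified train/test split, repeated k-fold
#' CV over the estimator grid on the training part, paired t-statistic
#' ranking with test-set selection of the number of estimators, final fit
#' (class weights + z-normalization) and gain-based feature selection.
#'
#' @param X feature matrix.
#' @param y labels +1/-1.
#' @param estimator_grid numbers of trees evaluated in CV.
#' @param reps,k CV repetitions and folds.
#' @param top top-ranked grid points evaluated on the test set.
#' @param ref_n t-statistic reference grid point (defaults to the grid
#'   midpoint if 50 is absent).
#' @param test_fraction held-out fraction.
#' @param seed integer seed for every stochastic step.
#' @param config_template [boost_config()] hyperparameters.
#' @return list with `chosen_n`, `train_metrics`, `test_metrics`, `model`,
#'   `norm`, `fg`, `selected`, `split`, `cv`, `selection`.
#' @export
classification_protocol <- function(X, y, estimator_grid = 1:100, reps = 20,
                                    k = 5, top = 25, ref_n = NULL,
                                    test_fraction = 0.10, seed = 1,
                                    config_template = boost_config()) {
  X <- as.matrix(X)
  split <- train_test_split(nrow(X), test_fraction, seed)
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xte <- X[split$test, , drop = FALSE]; yte <- y[split$test]
  if (is.null(ref_n)) {
    ref_n <- if (50 %in% estimator_grid) 50 else
      estimator_grid[ceiling(length(estimator_grid) / 2)]
  }
  cv <- repeated_cv(Xtr, ytr, estimator_grid = estimator_grid, reps = reps,
                    k = k, seed = seed, config_template = config_template)
  sel <- select_estimators(cv, Xtr, ytr, Xte, yte, top = top, ref_n = ref_n,
                           config_template = config_template)
  norm <- zscore_fit(Xtr)
  cfg <- config_template
  cfg$n_estimators <- sel$chosen_n
  fit <- boost_fit(zscore_apply(Xtr, norm), ytr,
                   sample_weights = class_weights(ytr), config = cfg)
  pred_tr <- predict_label(fit, zscore_apply(Xtr, norm))
  pred_te <- predict_label(fit, zscore_apply(Xte, norm))
  fg <- feature_gain(fit)
  list(chosen_n = sel$chosen_n,
       train_metrics = metrics(confusion_counts(ytr, pred_tr)),
       test_metrics = metrics(confusion_counts(yte, pred_te)),
       model = fit, norm = norm, fg = fg,
       selected = select_features(fg),
       split = split, cv = cv, selection = sel)
}
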