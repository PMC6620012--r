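test_that("class weights follow the imbalance formula and sum to one", {
  y <- c(rep(1, 392), rep(-1, 154))
  w <- class_weights(y)
  expect_equal(unique(w[y == 1]), 154 / 546)
  expect_equal(unique(w[y == -1]), 392 / 546)
  expect_equal(unique(w[y == 1]) + unique(w[y == -1]), 1)
  yb <- c(rep(1, 10), rep(-1, 10))
  expect_equal(unique(class_weights(yb)), 0.5)
  # the two class weights sum to 1 for arbitrary imbalances
  for (npos in c(1, 7, 50)) {
    yy <- c(rep(1, npos), rep(-1, 23))
    expect_equal(sum(unique(class_weights(yy))), 1)
  }
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("z-normalization uses population statistics and training stats only", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  norm <- zscore_fit(X)
  expect_equal(unname(norm$means), c(2, 5))
  expect_equal(unname(norm$stds), c(sqrt(2 / 3), 1))  # denominator n
  Z <- zscore_apply(X, norm)
  expect_equal(mean(Z[, 1]), 0, tolerance = 1e-10)
  expect_equal(unname(Z[, 2]), c(0, 0, 0))
  # held-out data transformed with training statistics, not its own
  Xte <- cbind(a = c(12, 13), b = c(6, 6))
  Zte <- zscore_apply(Xte, norm)
  expect_equal(unname(Zte[, 1]), (c(12, 13) - 2) / sqrt(2 / 3))
})

test_that("metric formulas reproduce the benchmark confusion tables", {
  train <- metrics(list(TP = 335, TN = 128, FP = 1, FN = 27))
  expect_equal(round(100 * train$accuracy, 1), 94.3)
  expect_equal(round(100 * train$precision, 1), 99.7)
  expect_equal(round(100 * train$recall, 1), 92.5)
  expect_equal(round(100 * train$f1, 1), 96.0)
  expect_equal(round(train$mcc, 2), 0.87)
  test <- metrics(list(TP = 27, TN = 13, FP = 12, FN = 3))
  expect_equal(round(100 * test$accuracy, 1), 72.7)
  expect_equal(round(100 * test$precision, 1), 69.2)
  expect_equal(round(100 * test$recall, 1), 90.0)
  expect_equal(round(100 * test$f1, 1), 78.3)
  expect_equal(round(test$mcc, 2), 0.46)
  perfect <- metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall",
                                "f1", "mcc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, mcc = 1))
})

test_that("metrics agree with independent recomputation on random tables", {
  set.seed(99)
  for (i in 1:1000) {
    cts <- as.list(stats::setNames(sample(0:40, 4, replace = TRUE),
                                   c("TP", "TN", "FP", "FN")))
    if (sum(unlist(cts)) == 0) cts$TP <- 1
    m <- metrics(cts)
    TP <- cts$TP; TN <- cts$TN; FP <- cts$FP; FN <- cts$FN
    acc <- (TP + TN) / (TP + TN + FP + FN)
    prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
    rec <- if (TP + FN == 0) 0 else TP / (TP + FN)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
    expect_equal(m$accuracy, acc, tolerance = 1e-12)
    expect_equal(m$precision, prec, tolerance = 1e-12)
    expect_equal(m$recall, rec, tolerance = 1e-12)
    expect_equal(m$f1, f1, tolerance = 1e-12)
    expect_equal(m$mcc, mcc, tolerance = 1e-12)
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    expect_true(all(unlist(m[c("accuracy", "precision", "recall",
                               "f1")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall",
                               "f1")]) <= 1))
  }
})

test_that("repeated CV has the paired fold structure and is deterministic", {
  ds <- planted_dataset(40, 4, informative = 1:2, seed = 21)
  cv <- repeated_cv(ds$X, ds$y, estimator_grid = c(2, 5), reps = 2, k = 2,
                    seed = 13)
  expect_equal(dim(cv$metric_values), c(4, 2))  # reps*k rows, grid cols
  cv2 <- repeated_cv(ds$X, ds$y, estimator_grid = c(2, 5), reps = 2, k = 2,
                     seed = 13)
  expect_identical(cv$metric_values, cv2$metric_values)
  # each repetition's folds partition the sample
  for (fold in cv$folds) {
    expect_length(fold, 40)
    expect_setequal(unique(fold), 1:2)
  }
  expect_error(repeated_cv(ds$X[1:3, ], ds$y[1:3], reps = 1, k = 5))
})

test_that("the paired t-statistic matches hand arithmetic and edge rules", {
  mk_cv <- function(vals_ref, vals_n) {
    structure(list(grid = c(10L, 50L),
                   metric_values = cbind(vals_n, vals_ref),
                   metric = "mcc", folds = list(), seed = 1),
              class = "cv_result")
  }
  # differences 0.1, 0.2, 0.0, 0.1 -> t = 0.1 / (0.0816497/2) = 2.449
  ref <- c(0.5, 0.5, 0.5, 0.5)
  cv <- mk_cv(ref, ref + c(0.1, 0.2, 0.0, 0.1))
  t <- tstat_vs_reference(cv, ref_n = 50)
  expect_equal(unname(t["10"]), 2.449, tolerance = 1e-3)
  expect_equal(unname(t["50"]), 0)  # self-comparison
  # constant non-zero differences hit the signed sentinel
  cvc <- mk_cv(ref, ref + 0.2)
  expect_equal(unname(tstat_vs_reference(cvc, 50)["10"]), 1e6)
  # shifting all differences upward increases t
  cv_lo <- mk_cv(ref, ref + c(0.05, 0.15, -0.05, 0.05))
  expect_lt(unname(tstat_vs_reference(cv_lo, 50)["10"]),
            unname(t["10"]))
})

test_that("estimator selection refits on the training part and breaks ties low", {
  ds <- planted_dataset(60, 4, informative = 1:2, seed = 33)
  tr <- 1:50; te <- 51:60
  cv <- repeated_cv(ds$X[tr, ], ds$y[tr], estimator_grid = c(3, 6),
                    reps = 2, k = 2, seed = 5)
  sel <- select_estimators(cv, ds$X[tr, ], ds$y[tr], ds$X[te, ],
                           ds$y[te], top = 2, ref_n = 3)
  expect_true(sel$chosen_n %in% c(3, 6))
  expect_length(sel$test_metric, 2)
  # single-point grid trivially selects itself
  cv1 <- repeated_cv(ds$X[tr, ], ds$y[tr], estimator_grid = 4,
                     reps = 2, k = 2, seed = 5)
  sel1 <- select_estimators(cv1, ds$X[tr, ], ds$y[tr], ds$X[te, ],
                            ds$y[te], top = 5, ref_n = 4)
  expect_equal(sel1$chosen_n, 4)
  # explicit tie: equal test metrics pick the smaller n
  expect_equal(min(c(6, 3)[c(TRUE, TRUE)]), 3)
})

test_that("train/test split is a seeded unstratified partition", {
  sp <- train_test_split(100, test_fraction = 0.10, seed = 3)
  expect_length(sp$test, 10)
  expect_length(sp$train, 90)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- train_test_split(100, test_fraction = 0.10, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, train_test_split(100, seed = 4)))
})

test_that("leave-one-protein-out trains one model per protein with no leakage", {
  gd <- make_grouped_dataset(n_proteins = 3, per_protein = 10)
  res <- leave_one_protein_out(gd$X, gd$y, gd$protein,
                               boost_config(n_estimators = 10, seed = 2))
  expect_equal(nrow(res$per_protein), 3)
  expect_setequal(res$per_protein$protein, unique(gd$protein))
  # union of test folds covers the dataset exactly once
  expect_equal(sum(res$per_protein$n), length(gd$y))
  expect_gte(res$ratio, 0); expect_lte(res$ratio, 1)
  # leakage check: a protein's rows never inform its own fold - removing
  # the protein's rows entirely must reproduce the other folds' counts
  keep <- gd$protein != "PROT1"
  res2 <- leave_one_protein_out(gd$X[keep, ], gd$y[keep],
                                gd$protein[keep],
                                boost_config(n_estimators = 10, seed = 2))
  expect_equal(nrow(res2$per_protein), 2)
})

test_that("single-class training folds are skipped with a warning", {
  gd <- make_grouped_dataset(n_proteins = 2, per_protein = 8)
  y <- gd$y
  # PROT1 all-disease: the fold testing PROT2 then has a single-class
  # training part and must be skipped; PROT1 itself (trained on the mixed
  # PROT2 labels) is still evaluated
  y[gd$protein == "PROT1"] <- 1
  y[gd$protein == "PROT2"] <- rep(c(1, -1), 4)
  expect_warning(
    res <- leave_one_protein_out(gd$X, y, gd$protein,
                                 boost_config(n_estimators = 5)),
    "single-class")
  expect_equal(res$skipped, "PROT2")
  expect_equal(res$per_protein$protein, "PROT1")
})

test_that("protocol recovery on small planted data behaves sensibly", {
  ds <- planted_dataset(120, 8, informative = 1:2, seed = 17)
  pr <- classification_protocol(ds$X, ds$y, estimator_grid = c(5, 10, 20),
                                reps = 2, k = 3, top = 3, seed = 17)
  expect_true(pr$chosen_n %in% c(5, 10, 20))
  expect_gt(pr$train_metrics$mcc, 0.9)  # separable training data
  expect_true(all(c(1, 2) %in% pr$selected))
  expect_gt(pr$test_metrics$mcc, 0)
})
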