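# QSAR protocol: tercile split, the five regressors, metrics, the
# factorial grid and the best-model rule.

test_that("tercile split holds out one low, one medium, one high compound", {
  recs <- planted_set()
  sp <- make_split(recs, seed = 1)
  expect_length(sp$test_ids, 3L)
  expect_length(sp$train_ids, 41L)
  expect_length(intersect(sp$test_ids, sp$train_ids), 0L)
  expect_setequal(c(sp$test_ids, sp$train_ids), recs$id)
  expect_identical(make_split(recs, seed = 1)$test_ids, sp$test_ids)

  toy <- compound_set(c("CCO", "CCC", "CCN", "CCCl", "CCBr", "CCF"),
                      activity_pct = c(0, 10, 50, 60, 90, 100))
  ts <- make_split(toy, seed = 3)$test_ids
  acts <- toy$activity_pct[match(ts, toy$id)]
  expect_true(any(acts %in% c(0, 10)))
  expect_true(any(acts %in% c(50, 60)))
  expect_true(any(acts %in% c(90, 100)))
  expect_error(make_split(toy[1:5, ], 1), "at least 6")
})

test_that("random forest predictions are the mean of the trees", {
  recs <- planted_set()
  dm <- planted_descriptors()
  y <- recs$activity_pct
  x <- dm$values[, c("nHBDon", "TPSA"), drop = FALSE]
  fp <- fit_predict("RF-6", x[1:40, ], y[1:40], x[41:44, ], seed = 2)
  expect_identical(fp$n_estimators, 6L)
  all_trees <- predict(fp$model, x[41:44, ], predict.all = TRUE)
  expect_identical(ncol(all_trees$individual), 6L)
  expect_equal(unname(rowMeans(all_trees$individual)),
               unname(fp$test_pred), tolerance = 1e-12)
})

test_that("an unpruned tree recalls training targets; MLR is exact on linear data", {
  x <- cbind(f = c(1, 2, 3, 4, 5, 6))
  y <- c(3, 5, 7, 9, 11, 13)          # y = 2x + 1
  dt <- fit_predict("DT", x, y, x, seed = 1)
  expect_equal(dt$train_pred, y)
  ml <- fit_predict("MLR", x, y, cbind(f = c(1.5, 7)), seed = 1)
  expect_equal(ml$test_pred, c(4, 15), tolerance = 1e-9)
  expect_error(fit_predict("GBM", x, y, x), "unknown method")
  expect_error(fit_predict("KNN", x, y, x, hyperparams = list(k = 10)),
               "exceeds")
  expect_warning(fit_predict("KNN", x, y, x, standardized = FALSE),
                 "standardization")
})

test_that("metrics match hand arithmetic and flag undefined R", {
  e <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(e), c(R = 1, MSE = 0, MAE = 0))
  e2 <- evaluate_predictions(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(unlist(e2), c(R = 1, MSE = 1, MAE = 1))
  e3 <- evaluate_predictions(c(0, 10), c(5, 5))
  expect_true(is.na(e3$R))
  expect_equal(e3$MSE, 25)
  expect_equal(e3$MAE, 5)
})

test_that("mae^2 <= mse holds on every grid evaluation", {
  set.seed(5)
  for (rep in 1:50) {
    y <- rnorm(10); p <- rnorm(10)
    e <- evaluate_predictions(y, p)
    expect_lte(e$MAE^2, e$MSE + 1e-12)
  }
  g <- memo("grid44", function() grid_evaluate(
    planted_set(), thresholds = c(0.2, 0.39, 0.8), split_seed = 1))
  done <- g[!g$failed, ]
  expect_gt(nrow(done), 0L)
  expect_true(all(done$mae^2 <= done$mse + 1e-9))
})

test_that("the factorial grid sweeps all cells and records failures", {
  g <- memo("grid44", function() grid_evaluate(
    planted_set(), thresholds = c(0.2, 0.39, 0.8), split_seed = 1))
  expect_identical(nrow(g), 6L * 3L * 2L)
  nf <- vapply(c(0.2, 0.39, 0.8), function(t)
    unique(g$n_features[g$threshold == t]), numeric(1))
  expect_true(all(diff(nf) <= 0))
  high <- grid_evaluate(planted_set(), methods = "MLR", thresholds = 1.0,
                        standardize_options = FALSE, split_seed = 1)
  expect_true(all(high$failed))
  expect_match(high$note[1], "no features")
})

test_that("the best-model rule picks RF-6 from the published grid, DT unconstrained", {
  grid <- reference_evaluation_grid()
  best <- select_best(grid, score_tolerance = 0.05,
                      require_ensemble = TRUE)
  expect_identical(best$method, "RF")
  expect_identical(best$n_estimators, 6L)
  unconstrained <- select_best(grid, score_tolerance = 0,
                               require_ensemble = FALSE)
  expect_identical(unconstrained$method, "DT")
  single <- select_best(grid[3, ], require_ensemble = TRUE)
  expect_identical(single$n_estimators, 6L)
  expect_error(select_best(grid[1, ], require_ensemble = TRUE),
               "no candidate")
})

test_that("library prediction attaches flags and averages over trees", {
  recs <- planted_set()
  fit <- fit_qsar(recs, method = "RF-6", threshold = 0.39,
                  split_seed = 1)
  cands <- compound_set(c("Cc1c[nH]c2ccccc12", "OCCO", "c1ccncc1"),
                        id = c("g1", "g2", "g3"))
  out <- predict_library(fit, cands)
  expect_identical(nrow(out), 3L)
  expect_true(all(is.finite(out$predicted_activity_pct)))
  expect_true(all(out$predicted_activity_pct[!out$out_of_range] >= 0 &
                  out$predicted_activity_pct[!out$out_of_range] <= 100))
  # per-candidate mean-of-trees verification
  dmc <- compute_descriptors(cands)
  xs <- dmc$values[, fit$features, drop = FALSE]
  trees <- predict(fit$model, xs, predict.all = TRUE)$individual
  expect_equal(unname(rowMeans(trees)), out$predicted_activity_pct,
               tolerance = 1e-12)
})
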