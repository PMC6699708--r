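# Random forest modelling: metrics, tuning, importance, simplification.

test_that("metrics implements both R-squared conventions", {
  m <- metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(unname(m["r2_paper"]), 2.5)           # can exceed 1
  expect_equal(unname(m["r2_conventional"]), 0.5)
  expect_equal(unname(m["rmse"]), sqrt(1 / 3))
  expect_equal(unname(m["mae"]), 1 / 3)

  y <- c(2, 4, 9, 1)
  perfect <- metrics(y, y)
  expect_equal(unname(perfect), c(1, 1, 0, 0))
  null <- metrics(y, rep(mean(y), 4))
  expect_equal(unname(null[c("r2_paper", "r2_conventional")]), c(0, 0))

  expect_error(metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(metrics(1:3, 1:4), "lengths differ")
})

test_that("the two R-squared forms coincide for least-squares fits", {
  for (seed in 1:10) {
    x <- with_seed(seed, rnorm(40))
    y <- with_seed(seed + 100, 2 * x + rnorm(40))
    yhat <- fitted(lm(y ~ x))
    m <- metrics(y, yhat)
    expect_equal(unname(m["r2_paper"]), unname(m["r2_conventional"]),
                 tolerance = 1e-10)
  }
})

test_that("forests are seeded-deterministic and range-contained", {
  n <- 80
  X <- with_seed(1, matrix(rnorm(n * 10), n, 10,
                           dimnames = list(NULL, paste0("x", 1:10))))
  y <- with_seed(2, X[, 1] + rnorm(n, 0, 0.3))
  f1 <- rf_fit(X, y, ntree = 100, seed = 5)
  f2 <- rf_fit(X, y, ntree = 100, seed = 5)
  expect_identical(predict(f1, X), predict(f2, X))
  Xnew <- with_seed(3, matrix(rnorm(50 * 10, sd = 4), 50, 10,
                              dimnames = list(NULL, paste0("x", 1:10))))
  pr <- predict(f1, Xnew)
  expect_true(all(pr >= min(y) & pr <= max(y)))      # averages of node means

  cfg <- rf_config(ntree = 100, mtry_grid = c(2, 5), cv_folds = 5,
                   cv_repeats = 1, seed = 9)
  r1 <- tune_fit(X, y, cfg)
  r2 <- tune_fit(X, y, cfg)
  expect_identical(r1$chosen_mtry, r2$chosen_mtry)
  expect_identical(r1$predictions$yhat, r2$predictions$yhat)
  expect_true(r1$chosen_mtry %in% c(2, 5))
})

test_that("tune_fit learns strong signal and ignores pure noise", {
  n <- 120
  X <- with_seed(11, matrix(rnorm(n * 20), n, 20,
                            dimnames = list(NULL, paste0("x", 1:20))))
  cfg <- rf_config(ntree = 150, mtry_grid = c(5, 10, 20), cv_folds = 5,
                   cv_repeats = 1, seed = 21)
  # y is an exact copy of one feature; CV should favour a large mtry
  rep_sig <- tune_fit(X, X[, 4], cfg)
  expect_gte(rep_sig$metrics_validation[["r2_conventional"]], 0.95)
  # y independent of X
  r2_null <- vapply(1:5, function(s) {
    y <- with_seed(300 + s, rnorm(n))
    cfg_s <- rf_config(ntree = 150, mtry_grid = c(3, 7), cv_folds = 5,
                       cv_repeats = 1, seed = s)
    tune_fit(X, y, cfg_s)$metrics_validation[["r2_conventional"]]
  }, numeric(1))
  expect_lte(mean(r2_null), 0.15)

  expect_error(tune_fit(X[1:10, ], rnorm(10), cfg), "at least 20")
  expect_error(tune_fit(X, c(rep(1, n - 1), NA), cfg), "non-finite")
})

test_that("permutation importance finds drivers and zeroes unused features", {
  n <- 120
  hits <- 0
  for (s in 1:10) {
    X <- with_seed(s, matrix(rnorm(n * 15), n, 15,
                             dimnames = list(NULL, paste0("x", 1:15))))
    y <- with_seed(s + 50, sin(X[, 1]) + 2 * X[, 1] + rnorm(n, 0, 0.2))
    f <- rf_fit(X, y, ntree = 150, seed = s)
    rk <- rf_importance(f, seed = s)
    hits <- hits + (rk$feature[rk$rank == 1] == "x1")
  }
  expect_gte(hits, 9)

  # a constant column is never split on: importance exactly zero
  X <- with_seed(7, matrix(rnorm(n * 5), n, 5,
                           dimnames = list(NULL, paste0("x", 1:5))))
  X[, 5] <- 1
  y <- with_seed(8, X[, 1] + rnorm(n, 0, 0.1))
  f <- rf_fit(X, y, ntree = 100, seed = 3)
  rk <- rf_importance(f, seed = 3)
  top <- max(rk$importance)
  expect_lt(abs(rk$importance[rk$feature == "x5"]), 0.01 * top)
})

test_that("duplicating a feature splits its importance roughly in half", {
  n <- 120
  ratio <- vapply(1:5, function(s) {
    X <- with_seed(s, matrix(rnorm(n * 6), n, 6,
                             dimnames = list(NULL, paste0("x", 1:6))))
    y <- with_seed(s + 10, X[, 1] + rnorm(n, 0, 0.3))
    f1 <- rf_fit(X, y, ntree = 200, seed = s)
    i1 <- rf_importance(f1, seed = s)
    Xd <- cbind(X, x1dup = X[, 1])
    f2 <- rf_fit(Xd, y, ntree = 200, seed = s)
    i2 <- rf_importance(f2, seed = s)
    pair <- sum(i2$importance[i2$feature %in% c("x1", "x1dup")])
    pair / i1$importance[i1$feature == "x1"]
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.3)
})

test_that("simplify keeps top-k and degenerates to the full model at k = p", {
  n <- 90
  X <- with_seed(31, matrix(rnorm(n * 12), n, 12,
                            dimnames = list(NULL, paste0("x", 1:12))))
  y <- with_seed(32, X[, 2] - X[, 5] + rnorm(n, 0, 0.4))
  cfg <- rf_config(ntree = 120, mtry_grid = c(2, 4), cv_folds = 5,
                   cv_repeats = 1, seed = 13)
  full <- tune_fit(X, y, cfg)
  rk <- rf_importance(full$fit, seed = 13)

  cmp <- simplify(X, y, rk, k = 10, config = cfg, full_report = full)
  expect_length(cmp$retained, 10)
  expect_true(all(cmp$retained %in% colnames(X)))
  expect_equal(cmp$simplified$p, 10)

  same <- simplify(X, y, rk, k = 12, config = cfg, full_report = full)
  expect_identical(same$simplified$chosen_mtry, full$chosen_mtry)
  expect_identical(same$simplified$metrics_validation, full$metrics_validation)
  expect_equal(same$r2_decrease_pct, 0)

  expect_error(simplify(X, y, rk, k = 0, config = cfg), "k must be")
})

test_that("importance categories partition the top 10", {
  fn <- feature_names()
  rk <- data.frame(feature = fn[c(1:5, 46:48, 52:53, 20:28)],
                   importance = seq(19, 1) / 10, rank = 1:19,
                   stringsAsFactors = FALSE)
  out <- summarize_importance_categories(list(sucrose = rk))
  expect_equal(out$color + out$texture + out$morphology, 10)
  expect_equal(out$color, 5)
  expect_equal(out$texture, 3)
  expect_equal(out$morphology, 2)
  all_color <- data.frame(feature = fn[1:12], importance = 12:1, rank = 1:12)
  out2 <- summarize_importance_categories(list(tss = all_color))
  expect_equal(unlist(out2[c("color", "texture", "morphology")],
                      use.names = FALSE), c(10, 0, 0))
})
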