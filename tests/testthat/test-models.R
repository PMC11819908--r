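# Independent metric oracle: plain-formula recomputation, kept separate
# from the implementation path on purpose.
oracle_metrics <- function(y, p) {
  e <- abs(y - p)
  list(mse = sum(e^2) / length(e), mae = sum(e) / length(e),
       r2 = 1 - sum((p - y)^2) / sum((y - mean(y))^2),
       medae = stats::median(e))
}

test_that("ic_metrics matches hand-worked cases", {
  m <- ic_metrics(c(0.2, 0.4, 0.9), c(0.2, 0.4, 0.9))
  expect_equal(unlist(m), c(mse = 0, mae = 0, r2 = 1, medae = 0))

  y <- c(0.1, 0.5, 0.9)
  m <- ic_metrics(y, rep(mean(y), 3))
  expect_equal(m$r2, 0)

  m <- ic_metrics(c(0, 1), c(0.5, 0.5))
  expect_equal(m$mse, 0.25)
  expect_equal(m$mae, 0.5)
  expect_equal(m$medae, 0.5)
  expect_equal(m$r2, 0)

  expect_error(ic_metrics(1:3, 1:2), class = "icapacity_input_error")
  expect_error(ic_metrics(numeric(0), numeric(0)),
               class = "icapacity_input_error")
  expect_warning(m <- ic_metrics(c(0.5, 0.5), c(0.4, 0.6)), "undefined")
  expect_true(is.nan(m$r2))
})

test_that("ic_metrics agrees with the brute-force oracle", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    y <- runif(n)
    p <- runif(n)
    got <- ic_metrics(y, p)
    want <- oracle_metrics(y, p)
    for (k in names(want)) expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
  }
})

test_that("model specs validate their grids and architectures", {
  expect_equal(model_spec("dense_nn", domain = "cognition")$layer_widths,
               c(16L, 32L, 16L))
  expect_equal(model_spec("dense_nn", domain = "locomotion")$layer_widths,
               rep(32L, 4))
  expect_equal(model_spec("dense_nn", domain = "vitality")$layer_widths,
               c(8L, 16L, 16L, 8L))
  expect_equal(model_spec("random_forest", tree_count = 200)$tree_count, 200L)
  expect_error(model_spec("random_forest", tree_count = 42),
               class = "icapacity_spec_error")
  expect_error(model_spec("support_vector"))  # unknown family
  expect_error(make_model(list(family = "linear")),
               class = "icapacity_spec_error")
})

test_that("random forest realizes its configured ensemble size", {
  set.seed(1)
  X <- matrix(runif(200), 50, 4)
  y <- X[, 1] + rnorm(50, 0, 0.1)
  m <- ic_train(model_spec("random_forest", tree_count = 10), list(X = X, y = y))
  expect_length(m$fit$trees, 10L)
  m <- ic_train(model_spec("gradient_boosting", tree_count = 50),
                list(X = X, y = y))
  expect_length(m$fit$trees, 50L)
})

test_that("training is reproducible under a fixed spec seed", {
  set.seed(123)
  X <- matrix(runif(400), 100, 4)
  y <- pmin(1, pmax(0, 0.5 + 0.3 * X[, 1] - 0.2 * X[, 2] + rnorm(100, 0, 0.05)))
  for (fam in c("random_forest", "gradient_boosting", "dense_nn")) {
    spec <- model_spec(fam, tree_count = 10, layer_widths = c(8, 8), seed = 7,
                       options = list(epochs = 5))
    p1 <- predict_ic(ic_train(spec, list(X = X, y = y)), X)
    p2 <- predict_ic(ic_train(spec, list(X = X, y = y)), X)
    expect_identical(p1, p2)
  }
})

test_that("predictions are clipped to the unit interval", {
  # labels outside [0,1] force raw linear outputs beyond the interval
  X <- matrix(seq(0, 1, length.out = 20), ncol = 1)
  m <- ic_train(model_spec("linear"), list(X = X, y = -0.5 + 2.2 * X[, 1]))
  pred <- predict_ic(m, X)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_equal(pred[1], 0)    # raw -0.5
  expect_equal(pred[20], 1)   # raw 1.7
  expect_equal(pred[10], -0.5 + 2.2 * X[10, 1])  # interior passes through

  expect_error(predict_ic(make_model(model_spec("linear")), X),
               class = "icapacity_state_error")
  expect_error(predict_ic(m, matrix(0, 2, 3)),
               class = "icapacity_input_error")
})

test_that("kfold_assign partitions are disjoint, exhaustive, reproducible", {
  for (n in c(10L, 101L, 1000L)) {
    f1 <- kfold_assign(n, 10L, seed = 4)
    f2 <- kfold_assign(n, 10L, seed = 4)
    expect_identical(f1, f2)
    expect_equal(sort(unique(f1)), 1:10)
    sizes <- tabulate(f1, 10)
    expect_lte(diff(range(sizes)), 1L)   # near-equal folds
    expect_equal(sum(sizes), n)          # exhaustive, disjoint by construction
    expect_false(identical(f1, kfold_assign(n, 10L, seed = 5)))
  }
  expect_error(kfold_assign(5, 6), class = "icapacity_input_error")
})

test_that("kfold_cv averages equal fold means exactly and folds partition", {
  set.seed(8)
  X <- matrix(runif(300), 100, 3)
  y <- pmin(1, pmax(0, 0.3 + 0.4 * X[, 1] + rnorm(100, 0, 0.05)))
  rep <- kfold_cv(model_spec("linear"), list(X = X, y = y), k = 10, seed = 2)
  for (part in c("test", "train")) {
    rows <- rep$per_fold[rep$per_fold$partition == part, ]
    expect_equal(nrow(rows), 10L)
    for (metric in c("mse", "mae", "r2", "medae")) {
      expect_identical(rep[[part]][[metric]], mean(rows[[metric]]))
    }
  }
  expect_error(kfold_cv(model_spec("linear"), list(X = X, y = y), k = 101),
               class = "icapacity_input_error")
  expect_error(kfold_cv(model_spec("linear"), list(X = X, y = y), k = 1),
               class = "icapacity_input_error")
})

test_that("a perfectly learnable law cross-validates to ~zero error", {
  set.seed(10)
  X <- matrix(runif(400), 100, 4)
  y <- 0.2 + 0.3 * X[, 1] - 0.1 * X[, 4]  # noiseless, inside [0,1]
  rep <- kfold_cv(model_spec("linear"), list(X = X, y = y), k = 10, seed = 3)
  expect_lt(rep$test$mae, 1e-10)
  expect_lt(rep$train$mse, 1e-20)
})

test_that("OLS recovers planted coefficients within 3 standard errors", {
  ds <- plant_linear_signal(clean_cohort_config(400, 3, seed = 17),
                            planted_coefficients(), noise_sd = 0.05,
                            domain = "cognition")
  fn <- attr(ds, "feature_names")
  # drop one marital level to avoid the aliased one-hot column
  keep <- setdiff(fn, "marital_status.never_married")
  df <- as.data.frame(ds[, keep])
  names(df) <- make.names(names(df))
  df$label <- ds$label
  fit <- stats::lm(label ~ ., data = df)
  est <- summary(fit)$coefficients
  truth <- planted_coefficients()
  for (nm in setdiff(names(truth), "(Intercept)")) {
    expect_lt(abs(est[nm, "Estimate"] - truth[[nm]]),
              3 * est[nm, "Std. Error"])
  }
})

test_that("dense network trains, early-stops, and beats the mean baseline", {
  ds <- plant_linear_signal(clean_cohort_config(250, 3, seed = 23),
                            planted_coefficients(), noise_sd = 0.05,
                            domain = "cognition")
  xy <- list(X = as.matrix(ds[, attr(ds, "feature_names")]), y = ds$label)
  spec <- model_spec("dense_nn", domain = "cognition", seed = 3,
                     options = list(epochs = 60))
  m <- ic_train(spec, xy)
  pred <- predict_ic(m, xy$X)
  base <- mean(abs(xy$y - mean(xy$y)))
  expect_lt(mean(abs(pred - xy$y)), base)
})

test_that("random forest overfits in the expected direction", {
  ds <- plant_linear_signal(clean_cohort_config(250, 3, seed = 29),
                            planted_coefficients(), noise_sd = 0.05,
                            domain = "cognition")
  rep <- kfold_cv(model_spec("random_forest", tree_count = 50, seed = 2),
                  ds, k = 5, seed = 2)
  expect_lte(rep$train$mse, rep$test$mse)
  expect_lte(rep$train$mae, rep$test$mae)
})

test_that("compare_models lays out one row per spec with 8 metric cells", {
  expect_equal(nrow(compare_models(list(X = matrix(1:20, 10), y = runif(10)),
                                   list(), k = 2)), 0L)
  ds <- plant_linear_signal(clean_cohort_config(100, 3, seed = 37),
                            planted_coefficients(), noise_sd = 0.05,
                            domain = "cognition")
  specs <- list(model_spec("linear"),
                model_spec("random_forest", tree_count = 10))
  out <- compare_models(ds, specs, k = 3, seed = 1)
  expect_equal(out$method, c("Linear Regression", "Random Forest (trees = 10)"))
  metric_cols <- c(outer(c("test_", "train_"),
                         c("mse", "mae", "r2", "medae"), paste0))
  expect_true(all(metric_cols %in% names(out)))
  expect_false(anyNA(out[, metric_cols]))
})
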