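#' Regression harness for IC prediction
#'
#' Four regressor families are benchmarked per domain: ordinary least
#' squares, random forest (bootstrap-aggregated CART trees with feature
#' subsampling), gradient boosting (shallow CART trees fit to residuals
#' with shrinkage), and a dense neural network whose hidden widths follow
#' the per-domain architecture table. Evaluation is 10-fold
#' cross-validation reporting MSE, MAE, R-squared and median absolute
#' error on both the held-out and the training partition of every fold.
#'
#' @name ic-models
NULL

#' Admissible ensemble sizes for the tree families
#' @return Integer vector of the tree-count grid.
#' @export
tree_count_grid <- function() c(10L, 50L, 100L, 200L, 300L, 500L)

#' Per-domain hidden-layer widths for the dense network
#' @param domain One of [ic_domains()].
#' @return Integer vector of hidden-layer widths.
#' @export
nn_architecture <- function(domain) {
  domain <- match.arg(domain, ic_domains())
  switch(domain,
    locomotion = c(32L, 32L, 32L, 32L),
    sensory = c(16L, 16L, 16L, 16L),
    psychology = c(16L, 16L, 16L, 16L),
    cognition = c(16L, 32L, 16L),
    vitality = c(8L, 16L, 16L, 8L)
  )
}

#' Specify a regressor
#'
#' @param family One of `"linear"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"dense_nn"`.
#' @param tree_count Ensemble size for the tree families; must come from
#'   [tree_count_grid()].
#' @param layer_widths Hidden widths for `dense_nn`; defaults to
#'   [nn_architecture()] of `domain` when given, else four layers of 16.
#' @param domain Optional domain, used to pick the default architecture.
#' @param seed Seed for all stochastic training (bootstraps, feature
#'   subsampling, weight init, batch order).
#' @param options Named list of family-specific training options. Tree
#'   families: `max_depth`, `min_node`, `mtry` (random forest),
#'   `learning_rate` (boosting, default 0.1), `gb_depth` (default 3).
#'   Dense net: `lr` (1e-3), `batch_size` (64), `epochs` (200),
#'   `patience` (20), `val_fraction` (0.1).
#' @return An `ic_model_spec`.
#' @export
model_spec <- function(family = c("linear", "random_forest",
                                  "gradient_boosting", "dense_nn"),
                       tree_count = 100L, layer_widths = NULL,
                       domain = NULL, seed = 1L, options = list()) {
  family <- match.arg(family)
  if (family %in% c("random_forest", "gradient_boosting")) {
    if (!(tree_count %in% tree_count_grid())) {
      ic_stop(sprintf("tree_count must be one of {%s}",
                      paste(tree_count_grid(), collapse = ", ")),
              "icapacity_spec_error")
    }
  }
  if (family == "dense_nn" && is.null(layer_widths)) {
    layer_widths <- if (!is.null(domain)) nn_architecture(domain)
                    else c(16L, 16L, 16L, 16L)
  }
  if (family == "dense_nn" && length(layer_widths) == 0L) {
    ic_stop("layer_widths must be non-empty for dense_nn",
            "icapacity_spec_error")
  }
  structure(list(family = family, tree_count = as.integer(tree_count),
                 layer_widths = layer_widths, domain = domain,
                 seed = as.integer(seed), options = options),
            class = "ic_model_spec")
}

#' Label for report rows
#' @param spec An `ic_model_spec`.
#' @return Human-readable method label.
#' @export
spec_label <- function(spec) {
  switch(spec$family,
    linear = "Linear Regression",
    random_forest = sprintf("Random Forest (trees = %d)", spec$tree_count),
    gradient_boosting = sprintf("Gradient Boosting (trees = %d)",
                                spec$tree_count),
    dense_nn = sprintf("Neural Network (%s)",
                       paste(spec$layer_widths, collapse = "-"))
  )
}

#' Instantiate an untrained model from a spec
#'
#' @param spec An [model_spec()].
#' @return An `ic_model` with a train/predict contract; see [ic_train()]
#'   and [predict_ic()].
#' @export
make_model <- function(spec) {
  if (!inherits(spec, "ic_model_spec")) {
    ic_stop("`spec` must come from model_spec()", "icapacity_spec_error")
  }
  structure(list(spec = spec, fit = NULL, feature_names = NULL),
            class = c(paste0("ic_model_", spec$family), "ic_model"))
}

opt <- function(spec, name, default) {
  if (!is.null(spec$options[[name]])) spec$options[[name]] else default
}

#' Train a model on a supervised dataset
#'
#' Training is seeded from the spec, so repeated runs are reproducible.
#'
#' @param model An untrained [make_model()] object (a spec is also
#'   accepted).
#' @param dataset An `ic_dataset`, or a list with elements `X` (numeric
#'   matrix) and `y`.
#' @return The fitted `ic_model`.
#' @export
ic_train <- function(model, dataset) {
  if (inherits(model, "ic_model_spec")) model <- make_model(model)
  xy <- if (is.list(dataset) && !is.data.frame(dataset) &&
            all(c("X", "y") %in% names(dataset))) {
    list(X = as.matrix(dataset$X), y = as.numeric(dataset$y),
         feature_names = colnames(dataset$X))
  } else {
    dataset_xy(dataset)
  }
  if (nrow(xy$X) == 0L) ic_stop("empty training set", "icapacity_input_error")
  if (length(xy$y) != nrow(xy$X)) {
    ic_stop("inconsistent feature/label lengths", "icapacity_input_error")
  }
  spec <- model$spec
  model$feature_names <- xy$feature_names
  model$n_features <- ncol(xy$X)
  model$fit <- with_seed(spec$seed, fit_family(spec, xy$X, xy$y))
  model
}

fit_family <- function(spec, X, y) {
  n <- nrow(X)
  p <- ncol(X)
  switch(spec$family,
    linear = {
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0  # aliased columns (e.g. full one-hot blocks)
      list(coefficients = coefs, rank = fit$qr$rank)
    },
    random_forest = {
      mtry <- opt(spec, "mtry", max(1L, floor(p / 3)))
      max_depth <- opt(spec, "max_depth", 30L)
      min_node <- opt(spec, "min_node", 5L)
      trees <- lapply(seq_len(spec$tree_count), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        cart_build(X, y, idx - 1L, mtry, max_depth, min_node)
      })
      list(trees = trees)
    },
    gradient_boosting = {
      lr <- opt(spec, "learning_rate", 0.1)
      depth <- opt(spec, "gb_depth", 3L)
      min_node <- opt(spec, "min_node", 10L)
      f0 <- mean(y)
      pred <- rep(f0, n)
      trees <- vector("list", spec$tree_count)
      all_rows <- seq_len(n) - 1L
      for (m in seq_len(spec$tree_count)) {
        tr <- cart_build(X, y - pred, all_rows, p, depth, min_node)
        trees[[m]] <- tr
        pred <- pred + lr * cart_predict(tr, X)
      }
      list(f0 = f0, trees = trees, learning_rate = lr)
    },
    dense_nn = {
      net <- nn_train(X, y, widths = spec$layer_widths,
                      lr = opt(spec, "lr", 1e-3),
                      batch_size = opt(spec, "batch_size", 64L),
                      epochs = opt(spec, "epochs", 200L),
                      patience = opt(spec, "patience", 20L),
                      val_fraction = opt(spec, "val_fraction", 0.1))
      list(net = net)
    }
  )
}

predict_raw <- function(model, X) {
  fit <- model$fit
  switch(model$spec$family,
    linear = as.numeric(cbind(1, X) %*% fit$coefficients),
    random_forest = {
      preds <- vapply(fit$trees, function(tr) cart_predict(tr, X),
                      numeric(nrow(X)))
      rowMeans(matrix(preds, nrow = nrow(X)))
    },
    gradient_boosting = {
      pred <- rep(fit$f0, nrow(X))
      for (tr in fit$trees) pred <- pred + fit$learning_rate * cart_predict(tr, X)
      pred
    },
    dense_nn = nn_predict(fit$net, X)
  )
}

#' Predict IC scores with a fitted model
#'
#' Raw regression output is clipped to the unit interval, since IC scores
#' live on `[0, 1]` by definition.
#'
#' @param model A fitted `ic_model`.
#' @param newdata Numeric matrix, data frame or `ic_dataset` whose
#'   feature columns match the training features; a bare numeric vector
#'   is treated as a single observation.
#' @return Numeric vector of predictions in `[0, 1]`.
#' @export
predict_ic <- function(model, newdata) {
  if (!inherits(model, "ic_model") || is.null(model$fit)) {
    ic_stop("model is not fitted; call ic_train() first",
            "icapacity_state_error")
  }
  X <- if (is.numeric(newdata) && is.null(dim(newdata))) {
    matrix(newdata, nrow = 1,
           dimnames = list(NULL, names(newdata)))
  } else if (is.data.frame(newdata)) {
    fn <- model$feature_names
    if (!is.null(fn) && all(fn %in% names(newdata))) {
      as.matrix(newdata[, fn, drop = FALSE])
    } else {
      as.matrix(newdata)
    }
  } else {
    as.matrix(newdata)
  }
  if (ncol(X) != model$n_features) {
    ic_stop("newdata feature length does not match the fitted model",
            "icapacity_input_error")
  }
  clip01(predict_raw(model, X))
}

#' Regression metrics: MSE, MAE, R-squared, MedAE
#'
#' R-squared is `1 - SS_res / SS_tot` with `SS_tot` taken about the mean
#' of `y_true`; for a constant `y_true` it is undefined and reported as
#' `NaN` with a warning.
#'
#' @param y_true,y_pred Equal-length nonzero numeric vectors.
#' @return Named list with `mse`, `mae`, `r2`, `medae`.
#' @export
ic_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    ic_stop("y_true and y_pred must be equal nonzero lengths",
            "icapacity_input_error")
  }
  err <- y_pred - y_true
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant y_true: R2 is undefined, reporting NaN")
    NaN
  } else {
    1 - sum(err^2) / ss_tot
  }
  list(mse = mean(err^2), mae = mean(abs(err)), r2 = r2,
       medae = stats::median(abs(err)))
}

#' Assign observations to k folds
#'
#' One shuffle with `seed`, then k near-equal contiguous chunks of the
#' shuffled order. The assignment is the partition used by [kfold_cv()].
#'
#' @param n Number of observations.
#' @param k Fold count.
#' @param seed Shuffle seed.
#' @return Integer vector of length `n` with fold ids in `1..k`.
#' @export
kfold_assign <- function(n, k, seed = 1L) {
  if (k < 2L || k > n) ic_stop("need 2 <= k <= n", "icapacity_input_error")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  fold_id <- integer(n)
  fold_id[perm] <- rep(seq_len(k), times = sizes)
  fold_id
}

#' k-fold cross-validation of one model spec
#'
#' The dataset is shuffled once with `seed` and split into `k`
#' near-equal contiguous folds; every example lands in exactly one test
#' fold. For each fold the model is trained on the remaining data and all
#' four metrics are computed on both the held-out fold and the training
#' portion. Averages are arithmetic means over folds; fold R-squared
#' values that are undefined (constant targets) are excluded from the
#' average with a warning.
#'
#' @param spec An [model_spec()].
#' @param dataset An `ic_dataset` or `list(X =, y =)`.
#' @param k Fold count (default 10); must satisfy `2 <= k <= n`.
#' @param seed Shuffle seed.
#' @return An `ic_cv_report`: list with `per_fold` (data frame), `test`
#'   and `train` averaged metric lists, `k`, `seed`, `spec`.
#' @export
kfold_cv <- function(spec, dataset, k = 10L, seed = 1L) {
  xy <- if (is.list(dataset) && !is.data.frame(dataset) &&
            all(c("X", "y") %in% names(dataset))) {
    list(X = as.matrix(dataset$X), y = as.numeric(dataset$y),
         feature_names = colnames(dataset$X))
  } else {
    dataset_xy(dataset)
  }
  n <- nrow(xy$X)
  if (k < 2L) ic_stop("k must be >= 2", "icapacity_input_error")
  if (k > n) ic_stop("k must not exceed the dataset size",
                     "icapacity_input_error")
  fold_id <- kfold_assign(n, k, seed)

  per_fold <- vector("list", 2L * k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    model <- ic_train(make_model(spec),
                      list(X = xy$X[train_idx, , drop = FALSE],
                           y = xy$y[train_idx]))
    for (part in c("test", "train")) {
      idx <- if (part == "test") test_idx else train_idx
      m <- ic_metrics(xy$y[idx],
                      predict_ic(model, xy$X[idx, , drop = FALSE]))
      per_fold[[(f - 1L) * 2L + (part == "train") + 1L]] <-
        data.frame(fold = f, partition = part, mse = m$mse, mae = m$mae,
                   r2 = m$r2, medae = m$medae)
    }
  }
  per_fold <- do.call(rbind, per_fold)

  avg <- function(part) {
    rows <- per_fold[per_fold$partition == part, ]
    r2s <- rows$r2
    if (anyNA(r2s)) {
      warning(sprintf("%d fold(s) had undefined R2; excluded from average",
                      sum(is.na(r2s))))
    }
    list(mse = mean(rows$mse), mae = mean(rows$mae),
         r2 = mean(r2s, na.rm = TRUE), medae = mean(rows$medae))
  }
  structure(list(per_fold = per_fold, test = avg("test"),
                 train = avg("train"), k = k, seed = seed, spec = spec),
            class = "ic_cv_report")
}

#' @export
print.ic_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s (seed %d)\n", x$k, spec_label(x$spec),
              x$seed))
  for (part in c("test", "train")) {
    m <- x[[part]]
    cat(sprintf("  %-5s MSE %.4f  MAE %.4f  R2 %.4f  MedAE %.4f\n",
                part, m$mse, m$mae, m$r2, m$medae))
  }
  invisible(x)
}

#' Compare model specs on one dataset
#'
#' One row per spec with test/train metric blocks, mirroring the usual
#' benchmark-table layout (Method x partition x MSE/MAE/R2/MedAE).
#'
#' @param dataset An `ic_dataset` or `list(X =, y =)`.
#' @param specs List of [model_spec()] objects.
#' @param k Fold count.
#' @param seed Shuffle seed (shared across specs so folds are identical).
#' @return Data frame with columns `method`, `test_mse`, `test_mae`,
#'   `test_r2`, `test_medae`, `train_mse`, `train_mae`, `train_r2`,
#'   `train_medae`.
#' @export
compare_models <- function(dataset, specs, k = 10L, seed = 1L) {
  rows <- lapply(specs, function(spec) {
    rep <- kfold_cv(spec, dataset, k = k, seed = seed)
    data.frame(method = spec_label(spec),
               test_mse = rep$test$mse, test_mae = rep$test$mae,
               test_r2 = rep$test$r2, test_medae = rep$test$medae,
               train_mse = rep$train$mse, train_mae = rep$train$mae,
               train_r2 = rep$train$r2, train_medae = rep$train$medae,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(0), test_mse = numeric(0),
               test_mae = numeric(0), test_r2 = numeric(0),
               test_medae = numeric(0), train_mse = numeric(0),
               train_mae = numeric(0), train_r2 = numeric(0),
               train_medae = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
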