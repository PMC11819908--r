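test_that("simulation is seed-deterministic", {
  cfg <- cohort_config(n_subjects = 30, n_waves = 3, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
  c2 <- simulate_cohort(cohort_config(n_subjects = 30, n_waves = 3, seed = 10))
  attr(c2, "config") <- NULL
  expect_false(identical(a, c2))
})

test_that("no missingness and no dropout gives a complete rectangle", {
  n <- 25L; w <- 3L
  tab <- simulate_cohort(clean_cohort_config(n, w, seed = 2))
  expect_equal(nrow(tab), n * w)
  expect_false(anyNA(tab))
})

test_that("generated values respect instrument ranges; ages advance by 2", {
  tab <- simulate_cohort(cohort_config(n_subjects = 80, n_waves = 4, seed = 3))
  dict <- ic_data_dictionary()
  for (i in seq_len(nrow(dict))) {
    v <- dict$variable[i]
    if (dict$transform[i] == "onehot") next
    x <- tab[[v]][!is.na(tab[[v]])]
    expect_true(all(x >= dict$lo[i] & x <= dict$hi[i]), label = v)
    if (dict$type[i] == "ordinal") {
      expect_true(all(x == round(x)), label = paste(v, "integer-coded"))
    }
  }
  expect_true(all(tab$marital_status[!is.na(tab$marital_status)] %in%
                    marital_categories()))
  for (s in unique(tab$subject_id)) {
    a <- tab$age[tab$subject_id == s]
    if (length(a) > 1) expect_equal(unique(diff(a)), 2)
  }
})

test_that("per-instrument missingness matches its configured rate", {
  cfg <- cohort_config(n_subjects = 2000, n_waves = 2, seed = 7,
                       missing_prob = c(default = 0.05, grip = 0.5,
                                        sppb = 0.5),
                       dropout_prob_per_wave = 0)
  tab <- simulate_cohort(cfg)
  n <- nrow(tab)
  for (case in list(list("grip_kg", 0.5), list("sppb_gait", 0.5),
                    list("moca_total", 0.05))) {
    p <- case[[2]]
    frac <- mean(is.na(tab[[case[[1]]]]))
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(frac - p), 3 * se)
  }
  # SPPB block goes missing together (single examination)
  sppb <- tab[, c("sppb_balance", "sppb_gait", "sppb_chair",
                  "gait_time_s", "chair_time_s")]
  miss <- is.na(sppb)
  expect_true(all(rowSums(miss) %in% c(0L, ncol(sppb))))
})

test_that("labels are positively autocorrelated across consecutive waves", {
  tab <- simulate_cohort(clean_cohort_config(300, 3, seed = 13))
  for (d in c("cognition", "psychology", "sensory")) {
    prof <- vapply(seq_len(nrow(tab)), function(i) {
      label_wave(tab[i, , drop = FALSE], d)
    }, numeric(1))
    byw <- split(prof, tab$wave_index)
    expect_gt(cor(byw[[1]], byw[[2]]), 0.3)
  }
})

test_that("plant_linear_signal is exactly linear in the noiseless limit", {
  ds <- plant_linear_signal(clean_cohort_config(80, 3, seed = 21),
                            planted_coefficients(), noise_sd = 0,
                            domain = "cognition")
  # a linear fit interpolates: residual MSE ~ 0
  model <- ic_train(model_spec("linear"), ds)
  xy <- list(X = as.matrix(ds[, attr(ds, "feature_names")]), y = ds$label)
  pred <- predict_ic(model, xy$X)
  expect_lt(mean((pred - xy$y)^2), 1e-20)
  # metadata records the generative coefficients
  beta <- attr(ds, "planted_coefficients")
  expect_equal(beta[["age"]], -0.1)
  expect_equal(attr(ds, "planted_intercept"), 0.5)
  expect_equal(attr(ds, "noise_sd"), 0)
})

test_that("null planted signal leaves nothing to explain", {
  # n large enough that OLS overfitting noise (~ -2p/n) stays small
  ds <- plant_linear_signal(clean_cohort_config(600, 3, seed = 31),
                            c("(Intercept)" = 0.5), noise_sd = 0.05,
                            domain = "cognition")
  rep <- kfold_cv(model_spec("linear"), ds, k = 5, seed = 1)
  expect_lt(abs(rep$test$r2), 0.15)  # no real signal to find
  expect_lt(abs(rep$test$mae - 0.05 * sqrt(2 / pi)), 0.01)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_waves = 1), class = "icapacity_config_error")
  expect_error(cohort_config(dropout_prob_per_wave = 1.2),
               class = "icapacity_config_error")
  expect_error(cohort_config(latent_wave_sd = -1),
               class = "icapacity_config_error")
  expect_error(simulate_cohort(list(n_subjects = 5)),
               class = "icapacity_config_error")
})
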