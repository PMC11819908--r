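test_that("domain scoring reproduces the worked examples", {
  # locomotion: total / 12
  cases <- list(list(12, 1), list(0, 0), list(6, 0.5))
  for (cs in cases) expect_equal(score_locomotion(cs[[1]]), cs[[2]])
  expect_equal(score_locomotion(balance = 4, gait = 4, chair = 4), 1)

  # vitality: min(0.13 * (6 - energy) + 0.09 * grip, 1)
  expect_equal(score_vitality(6, 0), 0)
  expect_equal(score_vitality(1, 40), 1)        # 0.65 + 3.6 clamps at 1
  expect_equal(score_vitality(5, 2), 0.31)      # 0.13 + 0.18

  # psychology bands
  cases <- list(list(3, 1), list(7, 0.75), list(12, 0.5), list(17, 0.25),
                list(27, 0), list(22, 0.15625), list(20, 0.21875))
  for (cs in cases) expect_equal(score_psychology(cs[[1]]), cs[[2]])

  # cognition: total / 30
  expect_equal(score_cognition(30), 1)
  expect_equal(score_cognition(0), 0)
  expect_equal(score_cognition(24), 0.8)

  # sensory: sum / 20
  expect_equal(score_sensory(5, 5, 5, 5), 1)
  expect_equal(score_sensory(1, 1, 1, 1), 0.2)
  expect_equal(score_sensory(5, 5, 2, 4), 0.8)
})

test_that("scores stay in [0,1] and are monotone over exhaustive grids", {
  loco <- vapply(0:12, score_locomotion, numeric(1))
  expect_true(all(loco >= 0 & loco <= 1))
  expect_true(all(diff(loco) >= 0))

  psy <- vapply(0:27, score_psychology, numeric(1))
  expect_true(all(psy >= 0 & psy <= 1))
  expect_true(all(diff(psy) <= 0))  # non-increasing across band boundaries

  cog <- vapply(0:30, score_cognition, numeric(1))
  expect_true(all(cog >= 0 & cog <= 1))
  expect_true(all(diff(cog) >= 0))

  grid <- expand.grid(h1 = 1:5, h2 = 1:5, v1 = 1:5, v2 = 1:5)
  sens <- mapply(score_sensory, grid$h1, grid$h2, grid$v1, grid$v2)
  expect_true(all(sens >= 0 & sens <= 1))
  # non-decreasing in each rating
  for (v in names(grid)) {
    lower <- grid[[v]] < 5
    bumped <- grid[lower, ]
    bumped[[v]] <- bumped[[v]] + 1
    expect_true(all(mapply(score_sensory, bumped$h1, bumped$h2, bumped$v1,
                           bumped$v2) >= sens[lower]))
  }

  vit_grid <- expand.grid(e = 1:6, g = seq(0, 15, by = 0.5))
  vit <- mapply(score_vitality, vit_grid$e, vit_grid$g)
  expect_true(all(vit >= 0 & vit <= 1))
  for (e in 1:6) {  # non-decreasing in grip at fixed energy answer
    expect_true(all(diff(vit[vit_grid$e == e]) >= 0))
  }
  for (g in unique(vit_grid$g)) {  # non-increasing in energy code
    expect_true(all(diff(vit[vit_grid$g == g]) <= 0))
  }
})

test_that("sensory score is permutation-invariant in its ratings", {
  set.seed(1)
  for (i in 1:25) {
    r <- sample(1:5, 4, replace = TRUE)
    base <- score_sensory(r[1], r[2], r[3], r[4])
    p <- sample(r)
    expect_identical(score_sensory(p[1], p[2], p[3], p[4]), base)
  }
})

test_that("vitality clamps exactly where the linear form reaches 1", {
  for (e in 1:6) {
    for (g in seq(0, 20, by = 0.25)) {
      raw <- 0.13 * (6 - e) + 0.09 * g
      if (raw >= 1) expect_identical(score_vitality(e, g), 1)
      else expect_equal(score_vitality(e, g), raw)
    }
  }
})

test_that("invalid scoring inputs raise domain-range errors", {
  expect_error(score_locomotion(13), class = "icapacity_range_error")
  expect_error(score_locomotion(-1), class = "icapacity_range_error")
  expect_error(score_locomotion(6.5), class = "icapacity_range_error")
  expect_error(score_psychology(28), class = "icapacity_range_error")
  expect_error(score_psychology(3.5), class = "icapacity_range_error")
  expect_error(score_cognition(31), class = "icapacity_range_error")
  expect_error(score_vitality(0, 10), class = "icapacity_range_error")
  expect_error(score_vitality(7, 10), class = "icapacity_range_error")
  expect_error(score_vitality(3, -1), class = "icapacity_range_error")
  expect_error(score_sensory(0, 3, 3, 3), class = "icapacity_range_error")
  expect_error(score_sensory(3, 3, 3, 6), class = "icapacity_range_error")
})

test_that("compute_profile scores available domains and flags the rest", {
  prof <- compute_profile(maxed_record())
  expect_s3_class(prof, "ic_profile")
  expect_equal(unname(unclass(prof)), rep(1, 5))

  # missing grip: vitality unavailable, others scored
  rec <- complete_record(list(grip_kg = NA))
  prof <- compute_profile(rec)
  expect_true(is.na(prof[["vitality"]]))
  expect_false(anyNA(prof[setdiff(ic_domains(), "vitality")]))

  # single instrument only
  prof <- compute_profile(list(phq9_total = 12))
  expect_equal(prof[["psychology"]], 0.5)
  expect_true(all(is.na(prof[setdiff(ic_domains(), "psychology")])))

  # malformed present value names the field
  expect_error(compute_profile(list(phq9_total = 40)),
               class = "icapacity_range_error")
  expect_error(compute_profile(complete_record(list(hear_left = 9))),
               "hear_left", class = "icapacity_range_error")
})

test_that("sppb_total is accepted directly and agrees with components", {
  rec <- complete_record()
  via_components <- compute_profile(rec)[["locomotion"]]
  rec2 <- rec
  rec2$sppb_balance <- rec2$sppb_gait <- rec2$sppb_chair <- NULL
  rec2$sppb_total <- 10
  expect_equal(compute_profile(rec2)[["locomotion"]], via_components)
})
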