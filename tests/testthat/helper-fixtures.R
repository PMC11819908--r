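# Shared fixtures, all built in code.

# One complete subject-wave record with every dictionary variable present.
complete_record <- function(overrides = list()) {
  rec <- list(
    subject_id = "S1", wave_index = 1L,
    age = 72, sex = 1, marital_status = "married", education = 4, bmi = 26.4,
    hear_left = 4, hear_right = 4, vision_far = 3, vision_near = 4,
    sppb_balance = 3, sppb_gait = 4, sppb_chair = 3,
    gait_time_s = 6.2, chair_time_s = 14.8,
    moca_total = 26, phq9_total = 4,
    sf12_q1 = 2, sf12_q2 = 1, sf12_q3 = 2, sf12_q4 = 2, sf12_q5 = 1,
    sf12_q6 = 2, sf12_q8 = 2, sf12_q10 = 3, sf12_q11 = 2,
    iadl_q1 = 1, iadl_q2 = 1, iadl_q3 = 1, iadl_q4 = 2, iadl_q5 = 1,
    iadl_q7 = 1, iadl_q8 = 1,
    ucla_q1 = 2, ucla_q2 = 1, ucla_q4 = 2, ucla_q11 = 1, ucla_q14 = 2,
    lubben_q6 = 3, lubben_q12 = 4,
    eq5d_q1 = 2, eq5d_q2 = 1, eq5d_q4 = 2, eq5d_q5 = 2,
    grip_kg = 28.5
  )
  utils::modifyList(rec, overrides)
}

# A record with every instrument at its score-maximizing value.
maxed_record <- function() {
  complete_record(list(
    hear_left = 5, hear_right = 5, vision_far = 5, vision_near = 5,
    sppb_balance = 4, sppb_gait = 4, sppb_chair = 4,
    moca_total = 30, phq9_total = 0, sf12_q10 = 1, grip_kg = 40
  ))
}

# Tiny hand-built wave table: n subjects x waves 1..w, all complete.
tiny_wave_table <- function(n_subjects, n_waves, drop = NULL) {
  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (t in seq_len(n_waves)) {
      if (!is.null(drop) && any(drop$subject == i & drop$wave == t)) next
      rec <- complete_record(list(
        subject_id = sprintf("S%02d", i), wave_index = t,
        age = 70 + 2 * (t - 1),
        moca_total = 26 - t, phq9_total = 3 + t
      ))
      rows[[length(rows) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Fully observed cohort configuration (no missingness or dropout).
clean_cohort_config <- function(n_subjects, n_waves, seed = 42L, ...) {
  cohort_config(n_subjects = n_subjects, n_waves = n_waves, seed = seed,
                missing_prob = c(default = 0, grip = 0, sppb = 0),
                dropout_prob_per_wave = 0, ...)
}

# The planted linear world used by parameter-recovery checks: coefficients
# on unit-scaled features (age, bmi, vision, energy item) and one z-scored
# total, small enough that labels stay inside (0, 1) almost surely.
planted_coefficients <- function() {
  c("(Intercept)" = 0.5, age = -0.1, bmi = -0.05, vision_far = 0.08,
    sf12_q10 = -0.08, moca_total = 0.03)
}

# 5000-example planted dataset at a given seed (1667 subjects x 4 waves,
# horizon 1 => 3 examples per subject). Memoized: two acceptance tests use
# the identical dataset and its construction dominates their runtime.
.planted_cache <- new.env(parent = emptyenv())
planted_dataset_5000 <- function(seed = 42L, noise_sd = 0.05) {
  key <- paste0("s", seed, "n", noise_sd)
  if (is.null(.planted_cache[[key]])) {
    .planted_cache[[key]] <- plant_linear_signal(
      clean_cohort_config(1667, 4, seed = seed),
      planted_coefficients(), noise_sd = noise_sd, domain = "cognition")
  }
  .planted_cache[[key]]
}
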