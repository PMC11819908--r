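#' Synthetic multi-wave cohort generation
#'
#' Emulates the structure of a two-yearly longitudinal aging panel: each
#' subject carries one latent health trait per IC domain, drawn at
#' baseline and degraded by a per-wave decline; instruments are emitted
#' from the latents through the inverse direction of the scoring maps
#' plus observation noise, rounded and clamped to instrument ranges.
#' Missingness is MCAR per instrument, with elevated rates for the
#' examiner-administered SPPB block and grip strength; subjects drop out
#' permanently with a per-wave probability. Age advances by exactly two
#' years per wave. The generator makes no attempt to match any real
#' study's marginal distributions -- its job is to give the pipeline
#' cross-wave predictability and realistic missingness structure.
#'
#' @name ic-cohort
NULL

#' Build a validated cohort configuration
#'
#' @param n_subjects Number of subjects.
#' @param n_waves Number of waves (>= 2); waves are two years apart.
#' @param seed RNG seed; identical seeds give byte-identical tables.
#' @param baseline_age_range Two integers, baseline age bounds in years.
#' @param latent_decline_per_wave Named per-domain decline of the latent
#'   trait per wave (unit-interval scale).
#' @param latent_wave_sd SD of the wave-to-wave latent jitter.
#' @param observation_noise_sd Named noise SDs per instrument class:
#'   `rating` (1-5/1-6 style items, in answer units), `moca` and `phq`
#'   (points), `sppb` (component points), `timing` (seconds), `grip` (kg),
#'   `bmi` (kg/m^2).
#' @param missing_prob Named missingness probabilities: `default` for
#'   ordinary instruments, `grip` and `sppb` elevated (default 0.5 each,
#'   reflecting measurements that require qualified personnel).
#' @param dropout_prob_per_wave Per-wave probability of permanent dropout.
#' @return An `ic_cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 500L,
                          n_waves = 4L,
                          seed = 1L,
                          baseline_age_range = c(60, 90),
                          latent_decline_per_wave = c(
                            locomotion = 0.04, sensory = 0.03,
                            psychology = 0.02, cognition = 0.03,
                            vitality = 0.04),
                          latent_wave_sd = 0.03,
                          observation_noise_sd = c(
                            rating = 0.5, moca = 1.5, phq = 1.5,
                            sppb = 0.5, timing = 2, grip = 3, bmi = 0.4),
                          missing_prob = c(default = 0.05, grip = 0.5,
                                           sppb = 0.5),
                          dropout_prob_per_wave = 0.05) {
  if (n_waves < 2) ic_stop("n_waves must be >= 2", "icapacity_config_error")
  if (n_subjects < 1) ic_stop("n_subjects must be >= 1", "icapacity_config_error")
  probs <- c(missing_prob, dropout = dropout_prob_per_wave)
  if (any(probs < 0 | probs > 1)) {
    ic_stop("probabilities must lie in [0,1]", "icapacity_config_error")
  }
  if (any(observation_noise_sd < 0) || latent_wave_sd < 0) {
    ic_stop("noise SDs must be non-negative", "icapacity_config_error")
  }
  if (!all(ic_domains() %in% names(latent_decline_per_wave))) {
    ic_stop("latent_decline_per_wave needs one entry per domain",
            "icapacity_config_error")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_waves = as.integer(n_waves),
    seed = as.integer(seed), baseline_age_range = baseline_age_range,
    latent_decline_per_wave = latent_decline_per_wave,
    latent_wave_sd = latent_wave_sd,
    observation_noise_sd = observation_noise_sd,
    missing_prob = missing_prob,
    dropout_prob_per_wave = dropout_prob_per_wave
  ), class = "ic_cohort_config")
}

# round + clamp to an integer instrument range
iclamp <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

#' Simulate a wave table from a cohort configuration
#'
#' @param config An [cohort_config()].
#' @return Data frame with one row per subject-wave, columns
#'   `subject_id`, `wave_index` plus every dictionary variable; attribute
#'   `config` records the generative settings.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "ic_cohort_config")) {
    ic_stop("`config` must come from cohort_config()", "icapacity_config_error")
  }
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  ns <- config$n_subjects
  nw <- config$n_waves
  noise <- config$observation_noise_sd
  decline <- config$latent_decline_per_wave[ic_domains()]

  # subject-level draws
  base_lat <- matrix(rbeta(ns * 5, 6, 2.5), ns, 5,
                     dimnames = list(NULL, ic_domains()))
  age0 <- sample(seq(config$baseline_age_range[1],
                     config$baseline_age_range[2]), ns, replace = TRUE)
  sex <- rbinom(ns, 1, 0.45)
  marital <- sample(marital_categories(), ns, replace = TRUE,
                    prob = c(0.50, 0.06, 0.04, 0.12, 0.20, 0.08))
  education <- sample(1:7, ns, replace = TRUE)
  bmi0 <- pmin(45, pmax(16, rnorm(ns, 27.5, 4)))

  # dropout: subject i contributes waves 1..last_wave[i]
  last_wave <- rep(nw, ns)
  for (i in seq_len(ns)) {
    for (t in 2:nw) {
      if (runif(1) < config$dropout_prob_per_wave) { last_wave[i] <- t - 1L; break }
    }
  }

  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    tw <- seq_len(last_wave[i])
    k <- length(tw)
    lat <- sapply(ic_domains(), function(d) {
      clip01(base_lat[i, d] - decline[[d]] * (tw - 1) +
               rnorm(k, 0, config$latent_wave_sd))
    })
    lat <- matrix(lat, nrow = k, dimnames = list(NULL, ic_domains()))
    gen <- rowMeans(lat)  # general-health latent for nonspecific items

    item <- function(g, lo, hi, worse_up = TRUE) {
      # worse_up: higher answer codes mean worse state (most instruments here)
      target <- if (worse_up) lo + (hi - lo) * (1 - g) else lo + (hi - lo) * g
      iclamp(target + rnorm(k, 0, noise[["rating"]]), lo, hi)
    }

    df <- data.frame(
      subject_id = sprintf("S%05d", i),
      wave_index = tw,
      age = age0[i] + 2 * (tw - 1),
      sex = sex[i],
      marital_status = marital[i],
      education = education[i],
      bmi = round(pmin(50, pmax(14, bmi0[i] + cumsum(rnorm(k, 0, noise[["bmi"]])))), 1),
      hear_left = item(lat[, "sensory"], 1, 5, worse_up = FALSE),
      hear_right = item(lat[, "sensory"], 1, 5, worse_up = FALSE),
      vision_far = item(lat[, "sensory"], 1, 5, worse_up = FALSE),
      vision_near = item(lat[, "sensory"], 1, 5, worse_up = FALSE),
      sppb_balance = iclamp(4 * lat[, "locomotion"] + rnorm(k, 0, noise[["sppb"]]), 0, 4),
      sppb_gait = iclamp(4 * lat[, "locomotion"] + rnorm(k, 0, noise[["sppb"]]), 0, 4),
      sppb_chair = iclamp(4 * lat[, "locomotion"] + rnorm(k, 0, noise[["sppb"]]), 0, 4),
      gait_time_s = round(pmin(60, pmax(2, 3 + 25 * (1 - lat[, "locomotion"]) +
                                          rnorm(k, 0, noise[["timing"]]))), 1),
      chair_time_s = round(pmin(90, pmax(5, 8 + 40 * (1 - lat[, "locomotion"]) +
                                           rnorm(k, 0, noise[["timing"]]))), 1),
      moca_total = iclamp(30 * lat[, "cognition"] + rnorm(k, 0, noise[["moca"]]), 0, 30),
      phq9_total = iclamp(27 * (1 - lat[, "psychology"]) * 0.6 +
                            rnorm(k, 0, noise[["phq"]]), 0, 27),
      sf12_q1 = item(gen, 1, 5),
      sf12_q2 = item(lat[, "locomotion"], 1, 3),
      sf12_q3 = item(lat[, "locomotion"], 1, 3),
      sf12_q4 = item(gen, 1, 5),
      sf12_q5 = item(gen, 1, 5),
      sf12_q6 = item(lat[, "psychology"], 1, 5),
      sf12_q8 = item(gen, 1, 5),
      sf12_q10 = iclamp(1 + 5 * (1 - lat[, "vitality"]) +
                          rnorm(k, 0, noise[["rating"]]), 1, 6),
      sf12_q11 = item(lat[, "psychology"], 1, 5),
      iadl_q1 = item(lat[, "locomotion"], 1, 3),
      iadl_q2 = item(lat[, "locomotion"], 1, 3),
      iadl_q3 = item(gen, 1, 3),
      iadl_q4 = item(gen, 1, 3),
      iadl_q5 = item(lat[, "locomotion"], 1, 3),
      iadl_q7 = item(lat[, "cognition"], 1, 3),
      iadl_q8 = item(lat[, "cognition"], 1, 3),
      ucla_q1 = item(lat[, "psychology"], 1, 4),
      ucla_q2 = item(lat[, "psychology"], 1, 4),
      ucla_q4 = item(lat[, "psychology"], 1, 4),
      ucla_q11 = item(lat[, "psychology"], 1, 4),
      ucla_q14 = item(lat[, "psychology"], 1, 4),
      lubben_q6 = item(lat[, "psychology"], 0, 5, worse_up = FALSE),
      lubben_q12 = item(lat[, "psychology"], 0, 5, worse_up = FALSE),
      eq5d_q1 = item(lat[, "locomotion"], 1, 5),
      eq5d_q2 = item(gen, 1, 5),
      eq5d_q4 = item(gen, 1, 5),
      eq5d_q5 = item(lat[, "psychology"], 1, 5),
      grip_kg = round(pmin(80, pmax(0, 5 + 35 * lat[, "vitality"] +
                                      12 * sex[i] + rnorm(k, 0, noise[["grip"]]))), 1),
      stringsAsFactors = FALSE
    )
    rows[[i]] <- df
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  # MCAR missingness: whole SPPB block together (one examination), grip
  # separately, ordinary instruments independently per column.
  p <- config$missing_prob
  demo <- c("subject_id", "wave_index", "age", "sex", "marital_status",
            "education")
  sppb_cols <- c("sppb_balance", "sppb_gait", "sppb_chair",
                 "gait_time_s", "chair_time_s")
  n <- nrow(tab)
  if (p[["sppb"]] > 0) {
    hit <- runif(n) < p[["sppb"]]
    tab[hit, sppb_cols] <- NA
  }
  if (p[["grip"]] > 0) {
    tab$grip_kg[runif(n) < p[["grip"]]] <- NA
  }
  if (p[["default"]] > 0) {
    ordinary <- setdiff(names(tab), c(demo, sppb_cols, "grip_kg"))
    for (v in ordinary) tab[[v]][runif(n) < p[["default"]]] <- NA
  }
  structure(tab, config = config)
}

#' Plant an exact linear signal for parameter-recovery checks
#'
#' Simulates a cohort, preprocesses it, and replaces the outcome with a
#' known linear function of the current-wave preprocessed features plus
#' Gaussian noise, clipped to the unit interval (a mild attenuation of
#' the signal at the boundaries). Emits one example per subject-wave that
#' has a wave t + h successor, mirroring the pairing geometry. The
#' generative coefficients are recorded in the output attributes, so
#' estimation error of any fitted model can be measured against truth.
#'
#' @param config A [cohort_config()]. Simulation is seeded from
#'   `config$seed`; the label noise from `config$seed + 1`.
#' @param coefficients Named numeric vector over a subset of
#'   [feature_names()] for `domain`; an optional `"(Intercept)"` entry
#'   (default 0.5) sets the baseline level.
#' @param noise_sd Label noise standard deviation.
#' @param domain Domain whose feature set (and horizon) is used.
#' @param policy Feature imputation policy.
#' @return An `ic_dataset` with attributes `planted_coefficients`,
#'   `planted_intercept`, `noise_sd` and `seed`.
#' @export
plant_linear_signal <- function(config, coefficients, noise_sd = 0.05,
                                domain = "cognition",
                                policy = "column-mean") {
  domain <- match.arg(domain, ic_domains())
  fnames <- feature_names(domain)
  intercept <- 0.5
  if ("(Intercept)" %in% names(coefficients)) {
    intercept <- coefficients[["(Intercept)"]]
    coefficients <- coefficients[names(coefficients) != "(Intercept)"]
  }
  if (!all(names(coefficients) %in% fnames)) {
    ic_stop("coefficient names must be feature names of the domain",
            "icapacity_config_error")
  }
  tab <- simulate_cohort(config)
  imputed <- impute_features(tab, policy)
  h <- domain_horizon(domain)
  key <- paste(tab$subject_id, tab$wave_index)
  eligible <- !is.na(match(paste(tab$subject_id, tab$wave_index + h), key))
  idx <- which(eligible)

  X <- build_feature_matrix(imputed[idx, , drop = FALSE], domain)

  beta <- stats::setNames(numeric(length(fnames)), fnames)
  beta[names(coefficients)] <- coefficients
  signal <- intercept + as.numeric(X %*% beta)
  eps <- with_seed(config$seed + 1L,
                   rnorm(length(idx), 0, noise_sd))
  label <- clip01(signal + eps)

  out <- data.frame(subject_id = tab$subject_id[idx],
                    wave_index = tab$wave_index[idx],
                    X, label = label, check.names = FALSE,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ic_dataset", "data.frame"),
            domain = domain, horizon = h, feature_names = fnames,
            planted_coefficients = beta, planted_intercept = intercept,
            noise_sd = noise_sd, seed = config$seed)
}
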