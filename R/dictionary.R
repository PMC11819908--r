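#' Canonical variable dictionary
#'
#' Every raw wave-table column is declared here with its type, its
#' instrument-defined range (scaling bounds are instrument constants, not
#' observed minima/maxima, so transforms are dataset-independent), the
#' transform the preprocessing layer applies, and the IC domains whose
#' feature vector includes it. The common block is shared by all five
#' domains; the SPPB block (three 0-4 point scores plus the two raw
#' timings behind them) feeds only the locomotion model and grip strength
#' only the vitality model, because examiner-administered measurements are
#' sparse in panel data. Resulting feature-vector lengths: locomotion 48,
#' sensory/psychology/cognition 43, vitality 44.
#'
#' @return Data frame with columns `variable`, `type` (ordinal, continuous
#'   or categorical), `transform` (`scale`, `zscore` or `onehot`), `lo`,
#'   `hi`, and one logical column per domain.
#' @export
ic_data_dictionary <- function() {
  row <- function(variable, type, transform, lo, hi,
                  domains = ic_domains()) {
    d <- as.list(ic_domains() %in% domains)
    names(d) <- ic_domains()
    c(list(variable = variable, type = type, transform = transform,
           lo = lo, hi = hi), d)
  }
  loco <- "locomotion"
  vit <- "vitality"
  rows <- list(
    row("age",          "continuous",  "scale",  50, 105),
    row("sex",          "ordinal",     "scale",  0, 1),
    row("marital_status", "categorical", "onehot", NA, NA),
    row("education",    "ordinal",     "scale",  1, 7),
    row("bmi",          "continuous",  "scale",  14, 50),
    row("hear_left",    "ordinal",     "scale",  1, 5),
    row("hear_right",   "ordinal",     "scale",  1, 5),
    row("vision_far",   "ordinal",     "scale",  1, 5),
    row("vision_near",  "ordinal",     "scale",  1, 5),
    row("sppb_balance", "ordinal",     "scale",  0, 4, loco),
    row("sppb_gait",    "ordinal",     "scale",  0, 4, loco),
    row("sppb_chair",   "ordinal",     "scale",  0, 4, loco),
    row("gait_time_s",  "continuous",  "scale",  2, 60, loco),
    row("chair_time_s", "continuous",  "scale",  5, 90, loco),
    row("moca_total",   "continuous",  "zscore", 0, 30),
    row("phq9_total",   "continuous",  "zscore", 0, 27),
    row("sf12_q1",      "ordinal",     "scale",  1, 5),
    row("sf12_q2",      "ordinal",     "scale",  1, 3),
    row("sf12_q3",      "ordinal",     "scale",  1, 3),
    row("sf12_q4",      "ordinal",     "scale",  1, 5),
    row("sf12_q5",      "ordinal",     "scale",  1, 5),
    row("sf12_q6",      "ordinal",     "scale",  1, 5),
    row("sf12_q8",      "ordinal",     "scale",  1, 5),
    row("sf12_q10",     "ordinal",     "scale",  1, 6),
    row("sf12_q11",     "ordinal",     "scale",  1, 5),
    row("iadl_q1",      "ordinal",     "scale",  1, 3),
    row("iadl_q2",      "ordinal",     "scale",  1, 3),
    row("iadl_q3",      "ordinal",     "scale",  1, 3),
    row("iadl_q4",      "ordinal",     "scale",  1, 3),
    row("iadl_q5",      "ordinal",     "scale",  1, 3),
    row("iadl_q7",      "ordinal",     "scale",  1, 3),
    row("iadl_q8",      "ordinal",     "scale",  1, 3),
    row("ucla_q1",      "ordinal",     "scale",  1, 4),
    row("ucla_q2",      "ordinal",     "scale",  1, 4),
    row("ucla_q4",      "ordinal",     "scale",  1, 4),
    row("ucla_q11",     "ordinal",     "scale",  1, 4),
    row("ucla_q14",     "ordinal",     "scale",  1, 4),
    row("lubben_q6",    "ordinal",     "scale",  0, 5),
    row("lubben_q12",   "ordinal",     "scale",  0, 5),
    row("eq5d_q1",      "ordinal",     "scale",  1, 5),
    row("eq5d_q2",      "ordinal",     "scale",  1, 5),
    row("eq5d_q4",      "ordinal",     "scale",  1, 5),
    row("eq5d_q5",      "ordinal",     "scale",  1, 5),
    row("grip_kg",      "continuous",  "scale",  0, 80, vit)
  )
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Marital-status categories used by the one-hot encoder
#'
#' Six categories, matching the civil-status breakdown of European panel
#' studies; the count is a configuration item and, together with the
#' variable dictionary, fixes the feature-vector lengths.
#' @return Character vector of category labels.
#' @export
marital_categories <- function() {
  c("married", "partnered", "separated", "divorced", "widowed",
    "never_married")
}

#' Standardization constants for the two cross-walked instruments
#'
#' Cognition and depression totals are measured with different instruments
#' across studies, so both are z-scored with literature means/SDs rather
#' than min-max scaled: MOCA mean 23.25, SD 4.82; PHQ-9 mean 5.79, SD 5.8.
#' Overridable wherever they are consumed.
#'
#' @return Named list of `list(mean=, sd=)` entries keyed by variable.
#' @export
standardization_constants <- function() {
  list(
    moca_total = list(mean = 23.25, sd = 4.82),
    phq9_total = list(mean = 5.79, sd = 5.8)
  )
}

#' Prediction horizon (in waves) for a domain
#'
#' Examiner-administered measurements (SPPB, grip strength) recur every
#' other wave -- four calendar years at two-year wave spacing -- so
#' locomotion and vitality are predicted at a two-wave horizon; the other
#' domains at one wave.
#' @param domain One of [ic_domains()].
#' @return Integer horizon in waves (1 or 2).
#' @export
domain_horizon <- function(domain) {
  domain <- match.arg(domain, ic_domains())
  if (domain %in% c("locomotion", "vitality")) 2L else 1L
}

# Raw variable names feeding `domain`'s feature vector, dictionary order.
domain_variables <- function(domain, dictionary = ic_data_dictionary()) {
  domain <- match.arg(domain, ic_domains())
  dictionary$variable[dictionary[[domain]]]
}

#' Expanded feature names for a domain
#'
#' One name per numeric feature after preprocessing: the marital block is
#' expanded to `marital_status.<category>` indicator names.
#' @inheritParams domain_horizon
#' @param dictionary Variable dictionary (see [ic_data_dictionary()]).
#' @param categories Marital category labels.
#' @return Character vector; length 48 for locomotion, 44 for vitality,
#'   43 otherwise.
#' @export
feature_names <- function(domain, dictionary = ic_data_dictionary(),
                          categories = marital_categories()) {
  vars <- domain_variables(domain, dictionary)
  unlist(lapply(vars, function(v) {
    tr <- dictionary$transform[dictionary$variable == v]
    if (tr == "onehot") paste(v, categories, sep = ".") else v
  }), use.names = FALSE)
}

#' Write the variable dictionary to a YAML file
#'
#' @param path Output file path.
#' @param dictionary Dictionary data frame.
#' @return `path`, invisibly.
#' @export
write_data_dictionary <- function(path, dictionary = ic_data_dictionary()) {
  entries <- lapply(seq_len(nrow(dictionary)), function(i) {
    r <- as.list(dictionary[i, ])
    list(type = r$type, transform = r$transform,
         lo = if (is.na(r$lo)) NULL else r$lo,
         hi = if (is.na(r$hi)) NULL else r$hi,
         categories = if (r$transform == "onehot") marital_categories() else NULL,
         domains = ic_domains()[unlist(r[ic_domains()])])
  })
  names(entries) <- dictionary$variable
  yaml::write_yaml(entries, path)
  invisible(path)
}
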