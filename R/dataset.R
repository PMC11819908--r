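#' Longitudinal supervised-dataset construction
#'
#' A supervised example pairs the preprocessed features of a subject at
#' wave t with the IC score of one domain computed from the same subject's
#' answers at wave t + h. Waves are two calendar years apart; h = 2 (four
#' years) for locomotion and vitality, whose measurements recur every
#' other wave, and h = 1 otherwise. Feature completeness is judged after
#' imputation; label completeness before any imputation -- labels are
#' never imputed, so missing label instruments silently drop the pair.
#'
#' @name ic-dataset
NULL

#' Compute the IC label of one domain from a (label-)wave record
#'
#' Delegates to the domain scoring functions on the raw record; any
#' missing instrument input yields `NA` (missing label), never an error.
#'
#' @param record Named list or one-row data frame of raw values.
#' @param domain One of [ic_domains()].
#' @return Unit-interval score, or `NA` if the domain's inputs are absent.
#' @export
label_wave <- function(record, domain) {
  domain <- match.arg(domain, ic_domains())
  compute_profile(record)[[domain]]
}

#' Pair waves into a per-domain supervised dataset
#'
#' For every subject and every wave t whose features are complete after
#' imputation, emits one example iff wave t + h exists for that subject
#' and yields a non-missing label (strict horizon: a later wave t + h',
#' h' > h, does not substitute). All eligible sliding pairs are emitted,
#' not just one per subject.
#'
#' @param table Wave table sorted by `subject_id` then `wave_index`, with
#'   no duplicated subject-wave rows.
#' @param domain One of [ic_domains()].
#' @param horizon Label horizon in waves; defaults to [domain_horizon()].
#' @param policy Feature imputation policy, see [impute_features()].
#' @param dictionary Variable dictionary.
#' @param constants Standardization constants.
#' @return An `ic_dataset`: data frame with `subject_id`, `wave_index`,
#'   the domain's feature columns and `label`; attributes `domain`,
#'   `horizon` and `feature_names`.
#' @export
pair_waves <- function(table, domain, horizon = domain_horizon(domain),
                       policy = "column-mean",
                       dictionary = ic_data_dictionary(),
                       constants = standardization_constants()) {
  domain <- match.arg(domain, ic_domains())
  if (!all(c("subject_id", "wave_index") %in% names(table))) {
    ic_stop("wave table needs `subject_id` and `wave_index` columns",
            "icapacity_input_error")
  }
  key <- paste(table$subject_id, table$wave_index)
  if (anyDuplicated(key)) {
    ic_stop("duplicated subject-wave rows", "icapacity_input_error")
  }
  ord <- order(table$subject_id, table$wave_index)
  if (!identical(ord, seq_len(nrow(table)))) {
    ic_stop("wave table must be sorted by subject_id then wave_index",
            "icapacity_input_error")
  }

  imputed <- impute_features(table, policy, dictionary)
  fnames <- feature_names(domain, dictionary)
  # label lookup: row index of (subject, wave + horizon), NA if absent
  target <- match(paste(table$subject_id, table$wave_index + horizon), key)

  # labels first (from the raw table): missing labels drop the pair
  has_target <- which(!is.na(target))
  labels <- rep(NA_real_, nrow(table))
  for (i in has_target) {
    labels[i] <- label_wave(table[target[i], , drop = FALSE], domain)
  }
  keep <- which(!is.na(labels))
  n_label_missing <- length(has_target) - length(keep)

  out <- if (length(keep)) {
    X <- build_feature_matrix(imputed[keep, , drop = FALSE], domain,
                              dictionary, constants)
    cbind(data.frame(subject_id = table$subject_id[keep],
                     wave_index = table$wave_index[keep],
                     stringsAsFactors = FALSE),
          as.data.frame(X, check.names = FALSE),
          data.frame(label = labels[keep]))
  } else {
    as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(fnames) + 3,
                         dimnames = list(NULL, c("subject_id", "wave_index",
                                                 fnames, "label"))),
                  check.names = FALSE)
  }
  rownames(out) <- NULL
  structure(out, class = c("ic_dataset", "data.frame"),
            domain = domain, horizon = horizon, feature_names = fnames,
            n_label_missing = n_label_missing)
}

#' Summarize a supervised dataset
#'
#' @param examples An `ic_dataset` (or any data frame with a `label`
#'   column).
#' @return List with the example count, domain/horizon (when present) and
#'   label distribution summaries.
#' @export
summarize_dataset <- function(examples) {
  n <- nrow(examples)
  lab <- if (n > 0) examples$label else numeric(0)
  list(
    domain = attr(examples, "domain"),
    horizon = attr(examples, "horizon"),
    n_examples = n,
    n_subjects = if (n > 0 && "subject_id" %in% names(examples))
      length(unique(examples$subject_id)) else 0L,
    label_mean = if (n > 0) mean(lab) else NA_real_,
    label_sd = if (n > 1) stats::sd(lab) else NA_real_,
    label_range = if (n > 0) range(lab) else c(NA_real_, NA_real_)
  )
}

# Split an ic_dataset (or planted dataset) into X matrix and y vector.
dataset_xy <- function(dataset) {
  fn <- attr(dataset, "feature_names")
  if (is.null(fn)) {
    fn <- setdiff(names(dataset), c("subject_id", "wave_index", "label"))
  }
  X <- as.matrix(dataset[, fn, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(dataset$label), feature_names = fn)
}
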