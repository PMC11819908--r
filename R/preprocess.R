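#' Preprocessing transforms
#'
#' Questionnaire answers are min-max scaled to the unit interval using
#' instrument-defined bounds, marital status is one-hot encoded (the only
#' non-quantitative categorical), and the cognition and depression totals
#' are z-scored with literature constants so that differently scaled
#' instruments land on a common axis. Z-scores are deliberately not
#' re-clipped to the unit interval; feature vectors are mixed-scale.
#'
#' @name ic-preprocessing
NULL

#' Min-max scale a value to the unit interval
#'
#' @param value Numeric value(s) within `[lo, hi]`.
#' @param lo,hi Instrument-defined bounds, `lo < hi`.
#' @return `(value - lo) / (hi - lo)`, elementwise.
#' @export
scale_unit <- function(value, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || is.na(lo) || is.na(hi) || lo >= hi) {
    ic_stop("scaling bounds must satisfy lo < hi", "icapacity_config_error")
  }
  if (!is.numeric(value) || anyNA(value)) {
    ic_stop("`value` must be numeric and non-missing", "icapacity_range_error")
  }
  if (any(value < lo | value > hi)) {
    ic_stop(sprintf("value outside [%s, %s]", format(lo), format(hi)),
            "icapacity_range_error")
  }
  (value - lo) / (hi - lo)
}

#' One-hot encode a marital-status code
#'
#' Full (non-dropped) encoding: exactly one indicator is 1.
#'
#' @param category Category label.
#' @param categories Configured category list.
#' @return Named 0/1 vector of length `length(categories)` summing to 1.
#' @export
one_hot_marital <- function(category, categories = marital_categories()) {
  if (length(category) != 1L || is.na(category) ||
      !(category %in% categories)) {
    ic_stop(sprintf("unknown marital-status category: %s", deparse(category)),
            "icapacity_encoding_error")
  }
  out <- as.numeric(categories == category)
  names(out) <- paste("marital_status", categories, sep = ".")
  out
}

#' Standardize a raw instrument total to a z-score
#'
#' @param raw Raw total(s).
#' @param constants A `list(mean=, sd=)` entry (see
#'   [standardization_constants()]).
#' @return `(raw - mean) / sd`.
#' @export
standardize <- function(raw, constants) {
  if (!is.list(constants) || is.null(constants$mean) || is.null(constants$sd) ||
      !is.numeric(constants$sd) || constants$sd <= 0) {
    ic_stop("standardization constants need a mean and a positive sd",
            "icapacity_config_error")
  }
  (raw - constants$mean) / constants$sd
}

#' Invert [standardize()]
#' @inheritParams standardize
#' @param z Z-score(s).
#' @return Raw-scale values.
#' @export
unstandardize <- function(z, constants) {
  z * constants$sd + constants$mean
}

#' Build a model-ready feature vector for one record and domain
#'
#' Applies the dictionary-declared transform to every variable in the
#' domain's list: unit scaling for ordinal and continuous entries, one-hot
#' encoding for marital status, z-scoring for the cognition and depression
#' totals. Values are expected complete (run [impute_features()] on the
#' table first); a missing variable raises an error naming it.
#'
#' @param record Named list or one-row data frame of raw values.
#' @param domain One of [ic_domains()].
#' @param dictionary Variable dictionary.
#' @param constants Standardization constants.
#' @param categories Marital categories.
#' @return Named numeric vector; length 48 (locomotion), 44 (vitality) or
#'   43 (other domains).
#' @export
build_features <- function(record, domain,
                           dictionary = ic_data_dictionary(),
                           constants = standardization_constants(),
                           categories = marital_categories()) {
  domain <- match.arg(domain, ic_domains())
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  vars <- domain_variables(domain, dictionary)
  parts <- lapply(vars, function(v) {
    val <- record[[v]]
    spec <- dictionary[dictionary$variable == v, ]
    if (is.null(val) || length(val) == 0L || is.na(val)) {
      ic_stop(sprintf("missing feature `%s` for domain %s", v, domain),
              "icapacity_missing_feature")
    }
    switch(spec$transform,
      scale = {
        out <- scale_unit(as.numeric(val), spec$lo, spec$hi)
        names(out) <- v
        out
      },
      zscore = {
        out <- standardize(as.numeric(val), constants[[v]])
        names(out) <- v
        out
      },
      onehot = one_hot_marital(as.character(val), categories)
    )
  })
  unlist(parts)
}

#' Build the feature matrix for every row of a wave table
#'
#' Vectorized batch counterpart of [build_features()]: applies the same
#' dictionary transforms column-wise, so large tables preprocess in
#' milliseconds instead of row-by-row. Any missing value in a required
#' column raises a missing-feature error naming the variable.
#'
#' @inheritParams build_features
#' @param table Wave table (data frame), typically after
#'   [impute_features()].
#' @return Numeric matrix, one row per table row, columns
#'   [feature_names()] of `domain`.
#' @export
build_feature_matrix <- function(table, domain,
                                 dictionary = ic_data_dictionary(),
                                 constants = standardization_constants(),
                                 categories = marital_categories()) {
  domain <- match.arg(domain, ic_domains())
  vars <- domain_variables(domain, dictionary)
  parts <- lapply(vars, function(v) {
    col <- table[[v]]
    spec <- dictionary[dictionary$variable == v, ]
    if (is.null(col) || anyNA(col)) {
      ic_stop(sprintf("missing feature `%s` for domain %s", v, domain),
              "icapacity_missing_feature")
    }
    switch(spec$transform,
      scale = {
        m <- matrix(scale_unit(as.numeric(col), spec$lo, spec$hi), ncol = 1)
        colnames(m) <- v
        m
      },
      zscore = {
        m <- matrix(standardize(as.numeric(col), constants[[v]]), ncol = 1)
        colnames(m) <- v
        m
      },
      onehot = {
        col <- as.character(col)
        if (!all(col %in% categories)) {
          ic_stop(sprintf("unknown marital-status category: %s",
                          paste(unique(setdiff(col, categories)),
                                collapse = ", ")),
                  "icapacity_encoding_error")
        }
        m <- vapply(categories, function(ct) as.numeric(col == ct),
                    numeric(length(col)))
        m <- matrix(m, ncol = length(categories))
        colnames(m) <- paste(v, categories, sep = ".")
        m
      })
  })
  do.call(cbind, parts)
}

#' Impute missing feature values in a wave table
#'
#' Fills missing entries of feature columns only; columns named `label_*`
#' (pre-computed outcome labels) are never touched, and the wave-pairing
#' stage always computes labels from the raw, unimputed table. Categorical
#' columns are imputed with the modal category, numeric columns with the
#' column mean or median.
#'
#' @param table Wave table (data frame).
#' @param policy One of `"column-mean"`, `"column-median"`,
#'   `"drop-incomplete"`.
#' @param dictionary Variable dictionary; only its variables are imputed.
#' @return Wave table with no missing values in the dictionary's feature
#'   columns (under the mean/median policies) or with incomplete rows
#'   dropped.
#' @export
impute_features <- function(table,
                            policy = c("column-mean", "column-median",
                                       "drop-incomplete"),
                            dictionary = ic_data_dictionary()) {
  policy <- match.arg(policy)
  feat_cols <- intersect(dictionary$variable, names(table))
  if (policy == "drop-incomplete") {
    keep <- stats::complete.cases(table[, feat_cols, drop = FALSE])
    return(table[keep, , drop = FALSE])
  }
  centre <- if (policy == "column-mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) stats::median(x, na.rm = TRUE)
  }
  for (v in feat_cols) {
    x <- table[[v]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) {
      ic_stop(sprintf("column `%s` is entirely missing; cannot impute", v),
              "icapacity_imputation_error")
    }
    tr <- dictionary$transform[dictionary$variable == v]
    if (tr == "onehot" || !is.numeric(x)) {
      tab <- table(x[!miss])
      x[miss] <- names(tab)[which.max(tab)]
    } else {
      x[miss] <- centre(x[!miss])
    }
    table[[v]] <- x
  }
  table
}
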