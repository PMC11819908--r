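#' End-to-end pipeline and report export
#'
#' Ties the stages together: (optionally) simulate a cohort, score every
#' subject's latest wave, build per-domain supervised datasets, benchmark
#' model specs under k-fold CV, train final models and attach predicted
#' profiles. Every output embeds the seed and a hash of the resolved
#' configuration, so a re-run with the same configuration reproduces all
#' deterministic outputs byte-identically. Scheduling (the platform
#' re-scores weekly as data arrive) is the caller's concern: the pipeline
#' is a pure batch run.
#'
#' @name ic-pipeline
NULL

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    input_csv = NULL,          # read a wave table instead of simulating
    cohort = list(),           # overrides for cohort_config()
    domains = ic_domains(),
    policy = "column-mean",
    k = 10L,
    models = list(list(family = "linear"))  # specs; empty = scoring only
  )
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

resolve_specs <- function(model_list, domain, seed) {
  lapply(model_list, function(m) {
    do.call(model_spec, modifyList(
      list(domain = domain, seed = seed), m))
  })
}

#' Run the full pipeline
#'
#' @param config Named list (merged over the defaults: `seed`, `out_dir`,
#'   `input_csv`, `cohort`, `domains`, `policy`, `k`, `models`) or the
#'   path to a YAML file with those keys. With no `input_csv` a synthetic
#'   cohort is simulated from `cohort` overrides; with an empty `models`
#'   list only scoring outputs are produced.
#' @return Invisibly, a list with the wave `table`, per-subject
#'   `profiles`, per-domain `datasets` and `metrics`, and the run
#'   `manifest`. When `out_dir` is set, writes `metrics.csv`,
#'   `profiles.json` and `manifest.json` there.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  # shallow merge: a caller's empty models list must override the default
  merged <- default_pipeline_config()
  for (nm in names(config)) merged[nm] <- list(config[[nm]])
  config <- merged
  config$domains <- match.arg(config$domains, ic_domains(),
                              several.ok = TRUE)
  hash <- config_hash(config)

  log_stage <- function(...) message(sprintf(...))

  # stage: input
  table <- if (!is.null(config$input_csv)) {
    if (!file.exists(config$input_csv)) {
      ic_stop(sprintf("input stage: file not found: %s", config$input_csv),
              "icapacity_config_error")
    }
    read.csv(config$input_csv, stringsAsFactors = FALSE)
  } else {
    cc <- do.call(cohort_config, modifyList(list(seed = config$seed),
                                            config$cohort))
    simulate_cohort(cc)
  }
  log_stage("input: %d rows, %d subjects", nrow(table),
            length(unique(table$subject_id)))

  # stage: score latest wave per subject
  last_rows <- tapply(seq_len(nrow(table)), table$subject_id,
                      function(i) i[which.max(table$wave_index[i])])
  profiles <- lapply(as.integer(last_rows), function(i) {
    list(subject_id = table$subject_id[i], wave_index = table$wave_index[i],
         profile = compute_profile(table[i, , drop = FALSE]))
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "subject_id")

  datasets <- list()
  metrics <- list()
  final_models <- list()
  for (domain in config$domains) {
    ds <- pair_waves(table, domain, policy = config$policy)
    log_stage("build-dataset [%s]: %d rows in, %d examples, %d dropped for missing labels",
              domain, nrow(table), nrow(ds),
              attr(ds, "n_label_missing"))
    datasets[[domain]] <- ds
    if (length(config$models) == 0L || nrow(ds) < max(2L, config$k)) next
    specs <- resolve_specs(config$models, domain, config$seed)
    cmp <- compare_models(ds, specs, k = config$k, seed = config$seed)
    cmp <- cbind(domain = domain, cmp, stringsAsFactors = FALSE)
    metrics[[domain]] <- cmp
    final_models[[domain]] <- ic_train(make_model(specs[[1]]), ds)
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL

  # predicted profile per subject: latest wave with complete features
  if (length(final_models)) {
    imputed <- impute_features(table, config$policy)
    for (nm in names(profiles)) {
      i <- as.integer(last_rows[[nm]])
      pred <- lapply(names(final_models), function(domain) {
        feats <- tryCatch(
          build_features(imputed[i, , drop = FALSE], domain),
          icapacity_missing_feature = function(e) NULL)
        if (is.null(feats)) NA_real_
        else predict_ic(final_models[[domain]], feats)
      })
      names(pred) <- names(final_models)
      full <- stats::setNames(rep(NA_real_, 5), ic_domains())
      full[names(pred)] <- unlist(pred)
      profiles[[nm]]$predicted <- do.call(ic_profile, as.list(full))
    }
  }

  manifest <- list(seed = config$seed, config_hash = hash,
                   package_version = as.character(utils::packageVersion("icapacity")),
                   n_rows = nrow(table),
                   n_subjects = length(unique(table$subject_id)),
                   domains = config$domains,
                   n_examples = vapply(datasets, nrow, integer(1)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(metrics)) {
      write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                row.names = FALSE)
    }
    prof_json <- lapply(profiles, function(p) {
      doc <- jsonlite::fromJSON(export_profile(p$profile, p$predicted),
                                simplifyVector = FALSE)
      c(list(subject_id = p$subject_id, wave_index = p$wave_index), doc)
    })
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash, profiles = unname(prof_json)),
      file.path(config$out_dir, "profiles.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(table = table, profiles = profiles, datasets = datasets,
                 metrics = metrics, models = final_models,
                 manifest = manifest))
}

#' Export a current/predicted profile pair as a radar-ready JSON document
#'
#' Five axes with current and predicted values plus availability flags.
#' Unavailable domains are flagged, never zero-filled, and the document
#' deliberately contains no aggregate-IC field: there is no standardized
#' formula for a total intrinsic-capacity score.
#'
#' @param profile Current [ic_profile()].
#' @param predicted Optional predicted profile.
#' @param path Optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
export_profile <- function(profile, predicted = NULL, path = NULL) {
  axis <- function(d) {
    cur <- profile[[d]]
    prd <- if (!is.null(predicted)) predicted[[d]] else NA_real_
    list(domain = d,
         current = if (is.na(cur)) NULL else cur,
         current_available = !is.na(cur),
         predicted = if (is.na(prd)) NULL else prd,
         predicted_available = !is.na(prd))
  }
  doc <- list(axes = lapply(ic_domains(), axis))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
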