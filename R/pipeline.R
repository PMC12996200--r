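#' Per-recording feature extraction for a cohort
#'
#' Preprocesses every recording and computes the nonlinear-dynamics and
#' acoustic feature banks, returning one row per subject with
#' site/source-suffixed feature columns (e.g. `mle_aortic_personnel`)
#' alongside the subject covariates. A per-recording chaos-screen table
#' accompanies the features.
#'
#' Two analysis series are derived from each recording: the full audio
#' band (`pre_cfg`) feeds the acoustic features, while the dynamical
#' invariants are estimated on the low-frequency hemodynamic band
#' (`nld_cfg`, default 20-200 Hz resampled to 500 Hz) where the beat-scale
#' turbulence dynamics live; at audio rates the divergence and
#' correlation-sum structure of a phonocardiogram is dominated by
#' sub-sample noise.
#'
#' @param cohort a `pcg_cohort`.
#' @param pre_cfg a [preprocess_config()] for the acoustic (audio-band)
#'   series.
#' @param nld_cfg a [preprocess_config()] for the series on which the
#'   dynamical invariants are estimated.
#' @param dim embedding dimension used for the per-recording dynamics
#'   (fixed by default; `NULL` for FNN selection per recording).
#' @param max_points cap on embedded points in neighbour searches.
#' @param dcorr_max chaos-screen dimension bound.
#' @return List with `features` (data.frame keyed by `id`) and `screen`
#'   (data.frame: id, site, source, mle, dcorr, pass).
#' @export
cohort_features <- function(cohort, pre_cfg = preprocess_config(),
                            nld_cfg = preprocess_config(
                              target_rate_hz = 500, band_hz = c(20, 200)),
                            dim = 3, max_points = 2500, dcorr_max = 3) {
  subjects <- cohort$subjects
  rows <- list()
  screen <- list()
  for (rec in cohort$recordings) {
    x <- preprocess(rec, pre_cfg)
    xl <- preprocess(rec, nld_cfg)
    nld <- nld_features(xl, nld_cfg$target_rate_hz, dim = dim,
                        max_points = max_points)
    ac <- acoustic_features(x, pre_cfg$target_rate_hz)
    sc <- chaos_screen(nld, dcorr_max = dcorr_max)
    key <- paste(rec$site, rec$source, sep = "_")
    feats <- c(nld[c("mle", "dcorr", "sampen", "renyi_q2", "hurst",
                     "higuchi_fd", "katz_fd")], ac)
    names(feats) <- paste(names(feats), key, sep = "_")
    rows[[rec$subject_id]] <- c(rows[[rec$subject_id]], feats)
    screen[[length(screen) + 1]] <- data.frame(
      id = rec$subject_id, site = rec$site, source = rec$source,
      mle = nld$mle, dcorr = nld$dcorr, pass = sc$pass,
      stringsAsFactors = FALSE)
  }
  feat_df <- do.call(rbind, lapply(names(rows), function(id) {
    as.data.frame(rows[[id]], check.names = FALSE)
  }))
  feat_df <- cbind(id = names(rows), feat_df, stringsAsFactors = FALSE)
  keep <- c("id", "age", "sex", "bmi", "bsa")
  feat_df <- merge(subjects[, keep], feat_df, by = "id", sort = TRUE)
  list(features = feat_df, screen = do.call(rbind, screen))
}

#' Pipeline configuration
#'
#' One config + one seed drives simulate, preprocess, features, qc, split,
#' train and evaluate. Stage seeds are fanned out deterministically from
#' the global seed by hashing stage names.
#'
#' @param cohort a [cohort_config()], or a directory containing WAVs and
#'   `subjects.csv` (see [load_cohort()]).
#' @param preprocess a [preprocess_config()] for the acoustic series.
#' @param nld_preprocess a [preprocess_config()] for the dynamical series.
#' @param feature_dim,feature_max_points see [cohort_features()].
#' @param test_frac,tuning_frac,k_range split-stage settings.
#' @param search a [predictor_search_config()].
#' @param models character subset of `c("AS1", "AS2", "AS3", "MR1")`.
#' @param seed global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            preprocess = preprocess_config(),
                            nld_preprocess = preprocess_config(
                              target_rate_hz = 500, band_hz = c(20, 200)),
                            feature_dim = 3, feature_max_points = 2500,
                            test_frac = 0.2, tuning_frac = 0.8,
                            k_range = 2:6,
                            search = predictor_search_config(),
                            models = c("AS1", "AS2", "AS3", "MR1"),
                            seed = 1L) {
  structure(list(cohort = cohort, preprocess = preprocess,
                 nld_preprocess = nld_preprocess,
                 feature_dim = feature_dim,
                 feature_max_points = feature_max_points,
                 test_frac = test_frac, tuning_frac = tuning_frac,
                 k_range = k_range, search = search, models = models,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> preprocess/features -> chaos screen -> cluster ->
#' split (with test-set firewall) -> KS/NMI quality control -> predictor
#' search and model fit on the tuning set only -> evaluation of the frozen
#' models on tuning, train holdout, train and test sets. Artifacts are
#' written under `out_dir` when given.
#'
#' @param config a [pipeline_config()] (or a path to a JSON file of its
#'   fields).
#' @param out_dir optional artifact directory.
#' @return A `cardiodyn_run`: list with `cohort`, `features`, `screen`,
#'   `split`, `qc`, `models`, `reports`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cohort <- if (is.character(config$cohort)) {
    load_cohort(config$cohort)
  } else {
    cc <- config$cohort
    cc$seed <- stage_seed(seed, "simulate")
    generate_cohort(cc)
  }
  ft <- cohort_features(cohort, config$preprocess,
                        nld_cfg = config$nld_preprocess,
                        dim = config$feature_dim,
                        max_points = config$feature_max_points)
  fit <- fit_cohort_models(ft$features, cohort$subjects, seed = seed,
                           test_frac = config$test_frac,
                           tuning_frac = config$tuning_frac,
                           k_range = config$k_range,
                           search = config$search, models = config$models)
  manifest <- list(
    config_hash = object_hash(unclass(config)),
    seed = seed,
    n_subjects = nrow(cohort$subjects),
    n_recordings = length(cohort$recordings),
    chaos_pass = sum(ft$screen$pass),
    chaos_total = nrow(ft$screen),
    model_hash = object_hash(fit$models),
    timestamp = format(Sys.time(), tz = "UTC"))
  run <- structure(c(list(cohort = cohort, features = ft$features,
                          screen = ft$screen),
                     fit, list(manifest = manifest)),
                   class = "cardiodyn_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' Cluster, split, search and evaluate on an extracted feature table
#'
#' The modelling half of the pipeline, exposed separately so feature
#' extraction (the expensive stage) can be reused across split/search
#' seeds.
#'
#' @param features feature data.frame from [cohort_features()].
#' @param subjects subject table (id, group, severity, avai, ...).
#' @param seed integer seed (fanned out per stage).
#' @param test_frac,tuning_frac,k_range,search,models as in
#'   [pipeline_config()].
#' @return List with `split`, `qc`, `models`, `reports`.
#' @export
fit_cohort_models <- function(features, subjects, seed = 1L,
                              test_frac = 0.2, tuning_frac = 0.8,
                              k_range = 2:6,
                              search = predictor_search_config(),
                              models = c("AS1", "AS2", "AS3", "MR1")) {
  stopifnot(identical(sort(features$id), sort(subjects$id)))
  features <- features[order(features$id), , drop = FALSE]
  subjects <- subjects[order(subjects$id), , drop = FALSE]
  cl_cols <- intersect(c("age", "sex", "bmi", "bsa",
                         "mle_aortic_personnel", "dcorr_aortic_personnel"),
                       names(features))
  labels_cl <- cluster_subjects(features[, cl_cols, drop = FALSE],
                                k_range = k_range,
                                seed = stage_seed(seed, "cluster"))
  split <- split_cohort(subjects, labels_cl, test_frac = test_frac,
                        seed = stage_seed(seed, "split"))
  train_groups <- subjects$group[match(split$train_ids, subjects$id)]
  split <- add_tuning_set(split, tuning_frac = tuning_frac,
                          seed = stage_seed(seed, "tuning"),
                          strata = train_groups)
  if (length(intersect(split$tuning_ids, split$test_ids))) {
    stop("test-set firewall violation: tuning set contains test ids")
  }
  feat_cols <- setdiff(names(features), "id")
  is_train <- features$id %in% split$train_ids
  is_test <- features$id %in% split$test_ids
  qc <- list(
    ks = ks_screen(features[is_train, feat_cols, drop = FALSE],
                   features[is_test, feat_cols, drop = FALSE]),
    nmi = nmi_collection_sources(features))
  holdout_ids <- setdiff(split$train_ids, split$tuning_ids)
  sets <- list(tuning = split$tuning_ids, train_holdout = holdout_ids,
               train = split$train_ids, test = split$test_ids)
  fitted <- list()
  reports <- list()
  for (mname in models) {
    outcome <- switch(mname,
      AS1 = , AS2 = , AS3 = subjects$group == "AS",
      MR1 = subjects$group == "MR")
    y <- stats::setNames(as.integer(outcome), subjects$id)
    tune_rows <- features[features$id %in% split$tuning_ids, , drop = FALSE]
    tune_y <- y[tune_rows$id]
    spec <- build_predictors(tune_rows[, feat_cols, drop = FALSE], tune_y,
                             seed = stage_seed(seed, paste0("search_", mname)),
                             config = search, split = split,
                             ids = tune_rows$id)
    P_tune <- apply_predictors(spec, tune_rows)
    model <- if (mname == "AS3") {
      avai <- subjects$avai[match(tune_rows$id, subjects$id)]
      fit_linear_avai(P_tune, avai, split = split, ids = tune_rows$id)
    } else {
      fit_logistic(P_tune, tune_y, split = split, ids = tune_rows$id)
    }
    model$threshold <- choose_threshold(predict_scores(model, P_tune), tune_y,
                                        split = split, ids = tune_rows$id)
    model$dependent <- switch(mname, AS3 = "AVAi (cm^2/m^2)",
                              MR1 = "MR diagnosis", "AS diagnosis")
    fitted[[mname]] <- list(spec = spec, model = model)
    reports[[mname]] <- lapply(names(sets), function(sn) {
      rows <- features[features$id %in% sets[[sn]], , drop = FALSE]
      evaluate_model(model, spec, rows, y[rows$id], set_name = sn)
    })
    names(reports[[mname]]) <- names(sets)
  }
  list(split = split, qc = qc, models = fitted, reports = reports)
}

# Mean per-feature NMI between personnel- and subject-collected aortic
# recordings, paired by subject.
nmi_collection_sources <- function(features, bins = 8) {
  pers <- grep("_aortic_personnel$", names(features), value = TRUE)
  base <- sub("_aortic_personnel$", "", pers)
  subj <- paste0(base, "_aortic_subject")
  keep <- subj %in% names(features)
  if (!any(keep)) return(NULL)
  a <- features[, pers[keep], drop = FALSE]
  b <- features[, subj[keep], drop = FALSE]
  names(a) <- names(b) <- base[keep]
  nmi_paired(a, b, bins = bins)
}

#' Summarize a pipeline run as a per-model metrics table
#'
#' One row per model and evaluation set: n, sensitivity, specificity, AUC,
#' accuracy and the confusion counts — the layout of a diagnostic
#' performance table.
#'
#' @param run a `cardiodyn_run` from [run_pipeline()], or an artifact
#'   directory written by it.
#' @return data.frame.
#' @export
report_summary <- function(run) {
  if (is.character(run)) run <- read_run_artifacts(run)
  reports <- run$reports
  if (is.null(reports)) stop("no model reports found")
  rows <- list()
  for (mname in names(reports)) {
    for (sn in names(reports[[mname]])) {
      r <- reports[[mname]][[sn]]
      rows[[length(rows) + 1]] <- data.frame(
        model = mname, set = sn, n = r$n,
        sensitivity = r$sensitivity, specificity = r$specificity,
        auc = round_half_away(r$auc), accuracy = r$accuracy,
        tp = r$counts$tp, fp = r$counts$fp, tn = r$counts$tn,
        fn = r$counts$fn, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(run$screen, file.path(out_dir, "chaos_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(report_summary(run), file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(cluster_of = as.list(run$split$cluster_of),
         train_ids = run$split$train_ids, test_ids = run$split$test_ids,
         tuning_ids = run$split$tuning_ids, seed = run$split$seed),
    file.path(out_dir, "split.json"), auto_unbox = TRUE)
  models_json <- lapply(run$models, function(m) {
    list(kind = m$model$kind, coefficients = m$model$coefficients,
         threshold = m$model$threshold, dependent = m$model$dependent,
         predictors = lapply(m$spec$predictors, function(p) {
           list(feature = p$feature, sign = p$sign)
         }),
         standardization = m$spec$standardization,
         objective = m$spec$objective, seed = m$spec$seed)
  })
  jsonlite::write_json(models_json, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

read_run_artifacts <- function(dir) {
  report_path <- file.path(dir, "report.csv")
  if (!file.exists(report_path)) {
    stop("malformed artifact directory: missing report.csv in ", dir)
  }
  tab <- utils::read.csv(report_path, stringsAsFactors = FALSE)
  reports <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    reports[[r$model]][[r$set]] <- structure(
      list(set_name = r$set, n = r$n,
           counts = confusion_counts(r$tp, r$fp, r$tn, r$fn),
           sensitivity = r$sensitivity, specificity = r$specificity,
           accuracy = r$accuracy, auc = r$auc),
      class = "evaluation_report")
  }
  list(reports = reports)
}

read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  if (!is.null(raw$models)) cfg$models <- raw$models
  if (!is.null(raw$test_frac)) cfg$test_frac <- raw$test_frac
  if (!is.null(raw$tuning_frac)) cfg$tuning_frac <- raw$tuning_frac
  if (!is.null(raw$cohort_dir)) cfg$cohort <- raw$cohort_dir
  if (!is.null(raw$cohort)) cfg$cohort <- do.call(cohort_config, raw$cohort)
  if (!is.null(raw$preprocess)) {
    cfg$preprocess <- do.call(preprocess_config, raw$preprocess)
  }
  if (!is.null(raw$search)) {
    cfg$search <- do.call(predictor_search_config, raw$search)
  }
  cfg
}
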