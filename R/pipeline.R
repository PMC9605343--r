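#' End-to-end screening pipeline
#'
#' Orchestrates the full method: synthesize (or load) records, preprocess
#' into labeled 60-s segments, decompose each segment by EMD, build the
#' requested IMF combination feature, then cross-validate the CNN with
#' rebalancing applied to training folds only. Optionally runs NCA feature
#' ranking on training data. Every stage draws its randomness from a seed
#' derived from the single global seed, so a configuration reruns to
#' identical results.
#'
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' Nested per-stage sections; every parameter has a default. Any element can
#' be overridden by passing a partial list, e.g.
#' `pipeline_config(synth = list(n_subjects = 4), cv = list(mode = "loso"))`.
#'
#' @param synth Overrides for [synth_config()].
#' @param preprocess List: `filter` ([filter_spec()] overrides or `NULL` to
#'   skip filtering), `quality` ([quality_rules()] overrides),
#'   `exclude_noisy`.
#' @param emd List: `max_imfs`, `stop` ([sift_config()] overrides).
#' @param feature IMF combination feature: "IMF1", "IMF2", "IMF12",
#'   "IMF123".
#' @param nca List: `enabled`, `lambda` (`NULL` tunes it), `tau`, `folds`.
#' @param rebalance List: `method` ("none"/"smote"/"ros"/"rus"), `k`.
#' @param model List: [cnn_spec()] overrides (without `input_len`).
#' @param train List: [cnn_train_config()] overrides (without `seed`).
#' @param cv List: `mode` ("kfold"/"loso"), `k`, `stratified`.
#' @param seed Global seed.
#' @param out_dir Optional directory for JSON/CSV artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = list(), preprocess = list(),
                            emd = list(), feature = "IMF12",
                            nca = list(), rebalance = list(),
                            model = list(), train = list(), cv = list(),
                            seed = 1L, out_dir = NULL) {
  feature <- match.arg(feature, c("IMF1", "IMF2", "IMF12", "IMF123"))
  merge_defaults <- function(defaults, user) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  cfg <- list(
    synth = synth,
    preprocess = merge_defaults(
      list(filter = list(), quality = list(), exclude_noisy = TRUE),
      preprocess),
    emd = merge_defaults(list(max_imfs = 6L, stop = list()), emd),
    feature = feature,
    nca = merge_defaults(
      list(enabled = FALSE, lambda = NULL, tau = 0.02, folds = 5L,
           n_imfs = 6L), nca),
    rebalance = merge_defaults(list(method = "smote", k = 5L), rebalance),
    model = merge_defaults(
      list(n_blocks = 4L, filters = 8L, kernel_size = 32L, fc_blocks = 2L,
           fc_units = 64L, dropout = 0.5), model),
    train = merge_defaults(
      list(epochs = 10L, batch_size = 32L, learning_rate = 3e-3), train),
    cv = merge_defaults(list(mode = "kfold", k = 5L, stratified = TRUE), cv),
    seed = as.integer(seed),
    out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

# Stage: records -> pooled segment set.
pipeline_preprocess <- function(records, cfg) {
  fspec <- if (is.null(cfg$preprocess$filter)) NULL else {
    do.call(filter_spec, cfg$preprocess$filter)
  }
  rules <- do.call(quality_rules, cfg$preprocess$quality)
  pool_segments(lapply(records, segment_record, spec = fspec, rules = rules,
                       exclude_noisy = cfg$preprocess$exclude_noisy))
}

# Stage: segment set -> per-segment ImfSets.
pipeline_decompose <- function(segments, cfg) {
  stop_cfg <- do.call(sift_config, cfg$emd$stop)
  need <- c(IMF1 = 1L, IMF2 = 2L, IMF12 = 2L, IMF123 = 3L)[[cfg$feature]]
  max_imfs <- max(cfg$emd$max_imfs, need)
  if (!isTRUE(cfg$nca$enabled)) max_imfs <- need
  lapply(seq_len(nrow(segments$x)), function(i) {
    emd_decompose(segments$x[i, ], max_imfs = max_imfs, stop = stop_cfg)
  })
}

# Stage: ImfSets -> feature matrix for the classifier.
pipeline_features <- function(imf_sets, segments, cfg) {
  n <- length(imf_sets)
  X <- matrix(NA_real_, n, ncol(segments$x))
  for (i in seq_len(n)) {
    X[i, ] <- build_imf_features(imf_sets[[i]], cfg$feature,
      segment_id = paste0(segments$subject[i], ":", segments$minute[i]))[[1L]]
  }
  X
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param records Optional list of `ecg_record`s; when `NULL`, records are
#'   synthesized from `config$synth`.
#' @return List of class `pipeline_result`: per-fold/subject `reports`,
#'   their `summary` (mean over units), the `best` report by Youden's index,
#'   the optional `nca` ranking, and a `manifest` (config, seeds, class
#'   counts before/after rebalancing, fold index audit trail).
#' @export
run_pipeline <- function(config = pipeline_config(), records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(records)) {
    records <- generate_dataset(
      do.call(synth_config, c(config$synth, list(seed = config$seed))))
  }
  segments <- pipeline_preprocess(records, config)
  if (nrow(segments$x) == 0L) {
    stop("pipeline aborted at stage 'preprocess': no segments survived",
         call. = FALSE)
  }
  imf_sets <- pipeline_decompose(segments, config)
  X <- pipeline_features(imf_sets, segments, config)
  y <- segments$label

  splits <- if (config$cv$mode == "loso") {
    loso_split(segments$subject)
  } else {
    folds <- kfold_split(y, k = config$cv$k,
                         seed = derive_seed(config$seed, 1L),
                         stratified = config$cv$stratified)
    lapply(seq_along(folds), function(i) {
      list(subject = paste0("fold", i),
           train = sort(unlist(folds[-i])), test = folds[[i]])
    })
  }

  nca_out <- NULL
  reports <- list()
  audit <- list()
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    fold_seed <- derive_seed(config$seed, 100L + si)
    xtr <- X[sp$train, , drop = FALSE]
    ytr <- y[sp$train]
    if (isTRUE(config$nca$enabled) && si == 1L) {
      tab <- imf_feature_table(imf_sets[sp$train], ytr,
                               n_imfs = config$nca$n_imfs)
      lambda <- config$nca$lambda
      if (is.null(lambda)) {
        lambda <- tune_nca_lambda(tab$x, tab$y, folds = config$nca$folds,
                                  seed = fold_seed)$best_lambda
      }
      w <- fit_nca(tab$x, tab$y, lambda = lambda, seed = fold_seed)
      nca_out <- nca_select(w, tau = config$nca$tau,
                            imf_map = tab$imf_of_column)
      nca_out$lambda <- lambda
    }
    counts_before <- table(factor(ytr, levels = c("N", "A")))
    bal <- rebalance_training(xtr, ytr, method = config$rebalance$method,
                              k = config$rebalance$k, seed = fold_seed)
    counts_after <- table(factor(bal$y, levels = c("N", "A")))
    spec <- do.call(cnn_spec, c(list(input_len = ncol(X)), config$model))
    model <- cnn_build(spec, seed = fold_seed)
    tcfg <- do.call(cnn_train_config,
                    c(config$train, list(seed = derive_seed(fold_seed, 1L))))
    model <- cnn_train(model, bal$x, bal$y, tcfg)
    prob <- cnn_predict_proba(model, X[sp$test, , drop = FALSE])
    rep <- score_predictions(y[sp$test], prob[, "apnea"])
    rep$unit <- sp$subject
    reports[[si]] <- rep
    audit[[si]] <- list(unit = sp$subject, train = sp$train, test = sp$test,
                        n_train_before = as.integer(counts_before),
                        n_train_after = as.integer(counts_after),
                        rebalance_log = bal$log)
  }
  summary <- aggregate_reports(reports, mode = "mean")
  best <- youden_select(reports)
  manifest <- list(
    config = unclass(config), seed = config$seed,
    feature = config$feature, cv_mode = config$cv$mode,
    n_segments = nrow(X), n_flagged = nrow(segments$flagged),
    class_counts = as.list(table(y)), folds = audit,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result <- structure(list(reports = reports, summary = summary, best = best,
                           nca = nca_out, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s, %d units, %d segments\n",
    x$manifest$cv_mode, length(x$reports), x$manifest$n_segments))
  print(x$summary)
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_unit <- do.call(rbind, lapply(result$reports, function(r) {
    data.frame(unit = r$unit, n = r$n, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               auc = r$auc, youden_j = r$youden_j)
  }))
  write.csv(per_unit, file.path(out_dir, "reports.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = result$summary$metrics,
         best_unit = result$best$unit,
         manifest = result$manifest[c("seed", "feature", "cv_mode",
                                      "n_segments", "n_flagged",
                                      "class_counts", "elapsed_s")]),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  # per-fold rebalancing draw log (SMOTE: base, neighbor, lambda); written
  # even when empty so the audit trail is always present
  logs <- lapply(result$manifest$folds, function(f) {
    if (is.data.frame(f$rebalance_log) && nrow(f$rebalance_log) > 0L) {
      cbind(unit = f$unit, f$rebalance_log)
    } else NULL
  })
  logs <- do.call(rbind, logs)
  if (is.null(logs)) {
    logs <- data.frame(unit = character(0), base = integer(0),
                       neighbor = integer(0), lambda = numeric(0))
  }
  write.csv(logs, file.path(out_dir, "rebalance_log.csv"), row.names = FALSE)
  if (!is.null(result$nca)) {
    jsonlite::write_json(
      list(weights = as.list(result$nca$w), tau = result$nca$tau,
           threshold = result$nca$threshold,
           lambda = result$nca$lambda,
           selected_columns = result$nca$selected_columns,
           selected_imfs = result$nca$selected_imfs),
      file.path(out_dir, "nca.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Audit a pipeline result for train/test leakage
#'
#' Verifies from the manifest that no test index of any fold appears in that
#' fold's training indices, and that the test sets partition all segments.
#'
#' @param result A `pipeline_result`.
#' @return `TRUE` (invisibly) when clean; otherwise an error describing the
#'   offending fold.
#' @export
audit_leakage <- function(result) {
  folds <- result$manifest$folds
  all_test <- integer(0)
  for (f in folds) {
    if (length(intersect(f$train, f$test))) {
      stop(sprintf("leakage: fold '%s' shares indices between train and test",
                   f$unit), call. = FALSE)
    }
    all_test <- c(all_test, f$test)
  }
  if (length(all_test) != result$manifest$n_segments ||
      anyDuplicated(all_test)) {
    stop("test sets do not partition the segments", call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a single named pipeline stage with file-backed caching
#'
#' Stages: `"simulate"` (no input), `"preprocess"` (needs records),
#' `"decompose"` (needs a segment set), `"features"` (needs the decompose
#' output). Results are cached on disk keyed by a hash of the stage name,
#' configuration, and input; re-running with unchanged inputs loads the
#' cache and reports a skip.
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @param input The upstream stage's artifact (`NULL` for `"simulate"`).
#' @param cache_dir Cache directory; `NULL` disables caching.
#' @return The stage artifact, with attribute `"cache_hit"`.
#' @export
run_stage <- function(name = c("simulate", "preprocess", "decompose",
                               "features"),
                      config = pipeline_config(), input = NULL,
                      cache_dir = NULL) {
  name <- match.arg(name)
  upstream <- c(simulate = NA, preprocess = "simulate",
                decompose = "preprocess", features = "decompose")[[name]]
  if (!is.na(upstream) && is.null(input)) {
    stop(sprintf("stage '%s' needs the output of stage '%s'; run that first",
                 name, upstream), call. = FALSE)
  }
  key <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    tmp <- tempfile()
    saveRDS(list(name, unclass(config), input), tmp)
    key <- unname(tools::md5sum(tmp))
    unlink(tmp)
    cache_file <- file.path(cache_dir, paste0(name, "-", key, ".rds"))
    if (file.exists(cache_file)) {
      out <- readRDS(cache_file)
      attr(out, "cache_hit") <- TRUE
      message(sprintf("stage '%s': cache hit (%s), skipping", name, key))
      return(out)
    }
  }
  out <- switch(name,
    simulate = generate_dataset(
      do.call(synth_config, c(config$synth, list(seed = config$seed)))),
    preprocess = pipeline_preprocess(input, config),
    decompose = {
      sets <- pipeline_decompose(input, config)
      list(segments = input, imf_sets = sets)
    },
    features = list(
      x = pipeline_features(input$imf_sets, input$segments, config),
      y = input$segments$label, subject = input$segments$subject))
  if (!is.null(cache_dir)) {
    saveRDS(out, file.path(cache_dir, paste0(name, "-", key, ".rds")))
  }
  attr(out, "cache_hit") <- FALSE
  out
}
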