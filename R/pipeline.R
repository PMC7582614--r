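#' End-to-end pipeline configuration
#'
#' Bundles the per-stage settings for [run_pipeline()]. The single global
#' `seed` derives the seeds of every stochastic stage (generation, split,
#' training), so a rerun with the same configuration reproduces every
#' artifact. The default regressor here is desk-scale (two hidden layers
#' of 32 units, 200-epoch budget) so a full pipeline run stays in the
#' seconds-to-minutes range; pass `hidden_widths = c(2048, 4096, 8192,
#' 2048)` for the full-scale architecture.
#'
#' @param synthetic List of [synth_config()] arguments.
#' @param preprocess List with `high_cut_hz`, `low_cut_hz`.
#' @param criteria List of [abnormal_criteria()] arguments.
#' @param gamma List with `k`, `C`.
#' @param selection List with `n_lowest`, `force_include`,
#'   `force_exclude`, and `use_reference_gamma` (rank by the shipped
#'   reference gamma table instead of gammas computed on the run's own
#'   data; default FALSE).
#' @param regressor List of [regressor_config()] arguments (minus
#'   `input_dim` and `seed`, which the pipeline sets).
#' @param seed Global seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(),
                            preprocess = list(),
                            criteria = list(),
                            gamma = list(),
                            selection = list(),
                            regressor = list(),
                            seed = 1L) {
  defaults <- list(
    synthetic = list(duration_s = 240, heart_rate_bpm = 70,
                     hr_jitter_sd_bpm = 3, amplitude_jitter_sd = 0.05,
                     wander_amplitude = 0.05, noise_amplitude = 0.01,
                     label_noise_sd_mmHg = 0),
    preprocess = list(high_cut_hz = 8, low_cut_hz = 0),
    criteria = list(),
    gamma = list(k = 1, C = 3),
    selection = list(n_lowest = 32, force_include = c("S1", "S2"),
                     force_exclude = c("sdAS", "sdDS"),
                     use_reference_gamma = FALSE),
    regressor = list(hidden_widths = c(32, 32), max_epochs = 200,
                     patience = 20, batch_size = 64)
  )
  cfg <- defaults
  user <- list(synthetic = synthetic, preprocess = preprocess,
               criteria = criteria, gamma = gamma, selection = selection,
               regressor = regressor)
  for (sec in names(user)) {
    unknown <- setdiff(names(user[[sec]]), c(names(defaults[[sec]]),
      names(formals(switch(sec,
        synthetic = synth_config, criteria = abnormal_criteria,
        regressor = regressor_config, function() NULL)))))
    if (length(unknown) > 0)
      stop("unknown ", sec, " config key(s): ",
           paste(unknown, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on a synthetic record
#'
#' Executes simulate -> preprocess -> segment -> extract features ->
#' standardize -> gamma ranking and selection -> split -> train ->
#' predict -> evaluate, writing each stage's artifact (waveform CSV,
#' cycle table, feature matrix, gamma report, training history,
#' predictions, evaluation report and a YAML run manifest recording every
#' default in effect) under `out_dir`. Cycles with a missing selected
#' feature are dropped before training and counted in the manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return List with `report` (a `bp_eval_report`), `selection`, `model`,
#'   `counts` (per-stage cycle bookkeeping) and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  pth <- function(f) if (write_out) file.path(out_dir, f) else NULL

  sc <- do.call(synth_config,
                c(config$synthetic, list(seed = config$seed + 1L)))
  record <- generate_record(sc)
  if (write_out) write_waveform(record, pth("record.csv"))

  prep <- do.call(preprocess_record,
                  c(list(record = record), config$preprocess))
  crit <- do.call(abnormal_criteria, config$criteria)
  seg <- segment_record(prep, criteria = crit)
  if (length(seg$segments) < 20)
    stop("segmentation stage: too few usable cycles (",
         length(seg$segments), ")")
  if (write_out) write_cycle_table(seg$segments, pth("cycles.csv"),
                                   record_id = record$record_id)

  fm <- compute_feature_matrix(seg$segments)
  if (write_out) {
    out <- data.frame(fm$features, check.names = FALSE)
    out$sbp_mmHg <- fm$sbp; out$dbp_mmHg <- fm$dbp
    utils::write.csv(out, pth("features.csv"), row.names = FALSE)
  }

  # gamma ranking: drop all-NA/constant columns from candidacy up front
  usable <- apply(fm$features, 2, function(col) {
    v <- col[is.finite(col)]
    length(v) >= 2 && sd_of(v, "population") > 0
  })
  std <- standardize_features(fm$features[, usable, drop = FALSE])
  gam <- if (isTRUE(config$selection$use_reference_gamma)) {
    reference_gamma()
  } else {
    g <- stats::setNames(rep(NA_real_, ncol(fm$features)),
                         colnames(fm$features))
    gi <- gamma_indices(std, k = config$gamma$k, C = config$gamma$C)
    g[names(gi)] <- gi
    g
  }
  n_lowest <- min(config$selection$n_lowest,
                  sum(is.finite(gam)) +
                    length(config$selection$force_include))
  sel <- rank_and_select(gam, n_lowest = n_lowest,
                         force_include = config$selection$force_include,
                         force_exclude = config$selection$force_exclude)
  feats <- selected_features(sel)
  if (write_out) utils::write.csv(as.data.frame(sel), pth("gamma_report.csv"),
                                  row.names = FALSE)

  X <- fm$features[, feats, drop = FALSE]
  Y <- cbind(SBP = fm$sbp, DBP = fm$dbp)
  complete <- stats::complete.cases(X) & stats::complete.cases(Y)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]; Y <- Y[complete, , drop = FALSE]

  rc <- do.call(regressor_config,
                c(list(input_dim = ncol(X), seed = config$seed + 3L),
                  config$regressor))
  parts <- split_dataset(X, Y, fractions = unname(rc$split_fractions),
                         seed = config$seed + 2L)
  fit <- train_regressor(rc, parts$train, parts$validation)
  if (write_out) utils::write.csv(fit$history, pth("training_history.csv"),
                                  row.names = FALSE)

  pred <- predict(fit, parts$test$features)
  if (write_out)
    utils::write.csv(data.frame(truth_sbp = parts$test$labels[, 1],
                                truth_dbp = parts$test$labels[, 2],
                                est_sbp = pred[, 1], est_dbp = pred[, 2]),
                     pth("predictions.csv"), row.names = FALSE)

  report <- evaluate_bp(parts$test$labels[, 1], parts$test$labels[, 2],
                        pred[, 1], pred[, 2])
  counts <- list(
    cycles_segmented = seg$removal_log$n_kept + seg$removal_log$n_removed,
    cycles_removed = seg$removal_log$n_removed,
    removal_by_rule = seg$removal_log[
      setdiff(names(seg$removal_log), c("n_removed", "n_kept"))],
    cycles_incomplete_features = n_dropped,
    cycles_trained = nrow(parts$train$features),
    features_selected = length(feats))
  if (write_out) {
    utils::write.csv(eval_report_table(report), pth("evaluation.csv"),
                     row.names = FALSE)
    manifest <- list(seed = config$seed,
                     synthetic = config$synthetic,
                     preprocess = config$preprocess,
                     criteria = unclass(crit),
                     gamma = config$gamma,
                     selection = c(config$selection,
                                   list(selected = feats)),
                     regressor = unclass(rc)[
                       c("hidden_widths", "batch_size", "learning_rate",
                         "max_epochs", "patience", "split_fractions")],
                     counts = counts)
    yaml::write_yaml(manifest, pth("manifest.yaml"))
  }
  list(report = report, selection = sel, model = fit, counts = counts,
       paths = if (write_out) normalizePath(out_dir) else NULL)
}
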