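# Orchestration of the full scaled transfer-learning study:
# generate two-domain cohorts -> pretrain Model 1 on the source domain ->
# evaluate on the source inter-observer set and the target test set ->
# fine-tune to Model 2 on a small target re-train set -> re-evaluate ->
# statistical report.

#' Study manifest
#'
#' Bundles the cohort specifications, sizes, seeds, network and training
#' configurations of one end-to-end study. The four cohorts (source
#' training, source inter-observer, target re-train, target test) use
#' disjoint seed streams; the target test set is never touched by any
#' training stage.
#'
#' The `"desk_scale"` preset runs the whole study on one CPU core: 64x64
#' slices, depth-3 network with 8 base channels, 40 source-training
#' subjects, 8 inter-observer subjects with 5 observers, 12 re-train
#' subjects (30% of the source sample, mirroring the small-local-cohort
#' setting) and 16 target-test subjects. The target domain differs from
#' the source by a +80 HU calibration offset, higher noise (90 vs 20 HU),
#' thicker slices (5 vs 3 mm), a larger tumour-size distribution, a
#' lower-attenuation tumour appearance (HU range (-130,-40) vs (20,90))
#' and feet-first patient orientation — a shift strong enough that the
#' source-trained model measurably degrades on the target domain.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed; all cohort and training seeds derive from it.
#' @param preset `"desk_scale"` (default) or `"full_scale"` training
#'   settings.
#' @param n_source_train,n_interobserver,n_retrain,n_target_test Cohort
#'   sizes.
#' @param source_spec,target_spec Optional [domain_spec()] overrides.
#' @param observer_cfg Optional [observer_sim_config()] override (its seed
#'   is still derived from `seed`).
#' @param network Optional [network_config()] override.
#' @param pretrain_cfg,finetune_cfg Optional [train_config()] overrides.
#' @param write_artifacts Persist cohorts, checkpoints and reports under
#'   `out_dir` (default `TRUE`).
#' @return Object of class `gtv_study_manifest`.
#' @export
study_manifest <- function(out_dir = tempfile("gtv_study_"), seed = 1L,
                           preset = c("desk_scale", "full_scale"),
                           n_source_train = 40L, n_interobserver = 8L,
                           n_retrain = 12L, n_target_test = 16L,
                           source_spec = NULL, target_spec = NULL,
                           observer_cfg = NULL, network = NULL,
                           pretrain_cfg = NULL, finetune_cfg = NULL,
                           write_artifacts = TRUE) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (is.null(source_spec))
    source_spec <- domain_spec(name = "source")
  if (is.null(target_spec))
    target_spec <- domain_spec(
      name = "target", n_slices_range = c(6L, 8L), slice_thickness_mm = 5,
      noise_sd_hu = 90, intensity_offset_hu = 80,
      tumour_hu_range = c(-130, -40),
      tumour_radius_range_mm = c(10, 16), orientation = "feet-first")
  if (is.null(observer_cfg)) observer_cfg <- observer_sim_config()
  observer_cfg$seed <- seed * 11L + 5L
  if (is.null(network))
    network <- network_config(input_size = 64L, depth = 3L,
                              base_channels = 8L)
  if (is.null(pretrain_cfg))
    pretrain_cfg <- train_config_preset(preset, "pretrain",
                                        seed = seed * 11L + 6L)
  if (is.null(finetune_cfg))
    finetune_cfg <- train_config_preset(preset, "finetune",
                                        seed = seed * 11L + 7L)
  structure(list(out_dir = out_dir, seed = seed, preset = preset,
                 sizes = c(source_train = as.integer(n_source_train),
                           interobserver = as.integer(n_interobserver),
                           retrain = as.integer(n_retrain),
                           target_test = as.integer(n_target_test)),
                 cohort_seeds = c(source_train = seed * 11L + 1L,
                                  interobserver = seed * 11L + 2L,
                                  retrain = seed * 11L + 3L,
                                  target_test = seed * 11L + 4L),
                 source_spec = source_spec, target_spec = target_spec,
                 observer_cfg = observer_cfg, network = network,
                 pretrain_cfg = pretrain_cfg, finetune_cfg = finetune_cfg,
                 init_seed = seed * 11L + 8L,
                 write_artifacts = isTRUE(write_artifacts)),
            class = "gtv_study_manifest")
}

#' Run the full transfer-learning study
#'
#' Executes generate -> preprocess -> pretrain (Model 1) -> evaluate ->
#' fine-tune (Model 2) -> re-evaluate -> report. Every stage is seeded
#' from the manifest, so re-running the same manifest reproduces every
#' number; artifacts (cohorts, checkpoints, per-epoch logs, records,
#' report) are persisted under `manifest$out_dir` when requested.
#'
#' @param manifest A [study_manifest()].
#' @param quiet Suppress progress messages.
#' @return Object of class `gtv_study`: `report` (a `gtv_report`),
#'   `records`, `consensus`, `model1`, `model2`, `histories`, `manifest`.
#' @export
run_study <- function(manifest, quiet = FALSE) {
  stopifnot(inherits(manifest, "gtv_study_manifest"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("study stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  mz <- manifest$sizes; cs <- manifest$cohort_seeds

  say("generating cohorts")
  cohorts <- stage("generate", list(
    source_train = generate_cohort(manifest$source_spec, mz["source_train"],
                                   cs["source_train"],
                                   id_prefix = "srctrain"),
    interobserver = generate_cohort(manifest$source_spec,
                                    mz["interobserver"],
                                    cs["interobserver"],
                                    observers = manifest$observer_cfg,
                                    id_prefix = "interobs"),
    retrain = generate_cohort(manifest$target_spec, mz["retrain"],
                              cs["retrain"], id_prefix = "retrain"),
    target_test = generate_cohort(manifest$target_spec, mz["target_test"],
                                  cs["target_test"], id_prefix = "tgttest")))
  # test-set quarantine: training only ever sees these cohorts
  train_ids <- c(vapply(cohorts$source_train, `[[`, "", "id"),
                 vapply(cohorts$retrain, `[[`, "", "id"))
  test_ids <- c(vapply(cohorts$interobserver, `[[`, "", "id"),
                vapply(cohorts$target_test, `[[`, "", "id"))
  stopifnot(length(intersect(train_ids, test_ids)) == 0)

  out <- manifest$out_dir
  if (manifest$write_artifacts) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    stage("persist-cohorts", for (nm in names(cohorts))
      write_cohort(cohorts[[nm]], file.path(out, "cohorts", nm)))
  }

  say("pretraining Model 1 (source domain)")
  model0 <- build_model(manifest$network, seed = manifest$init_seed)
  tr1 <- stage("pretrain", train(model0, cohorts$source_train,
                                 manifest$pretrain_cfg))
  model1 <- tr1$model

  say("fine-tuning Model 2 (target re-train set)")
  src_val <- structure(cohorts$source_train[seq_len(min(
    4L, length(cohorts$source_train)))], class = "gtv_cohort")
  tr2 <- stage("finetune", fine_tune(model1, cohorts$retrain,
                                     manifest$finetune_cfg,
                                     source_val = src_val))
  model2 <- tr2$model

  say("evaluating both models on both test sets")
  threshold <- manifest$pretrain_cfg$threshold
  io_preds <- stage("predict-interobserver", lapply(1:2, function(mi) {
    model <- if (mi == 1) model1 else model2
    lapply(cohorts$interobserver, function(s)
      predict_volume(model, window_normalize(s$volume),
                     threshold = threshold))
  }))
  records <- stage("evaluate", {
    rec <- list()
    for (mi in 1:2) {
      model <- if (mi == 1) model1 else model2
      lab <- paste0("model", mi)
      rec[[length(rec) + 1]] <-
        evaluate_model(model, cohorts$target_test, label = lab,
                       threshold = threshold) |>
        dplyr::mutate(test_set = "target_test", arm = lab)
      io <- dplyr::bind_rows(lapply(seq_along(cohorts$interobserver),
                                    function(i) {
        s <- cohorts$interobserver[[i]]
        model_vs_observers(io_preds[[mi]][[i]], s$observer_masks, s$id, lab)
      }))
      rec[[length(rec) + 1]] <-
        dplyr::mutate(io, test_set = "interobserver", arm = lab)
    }
    manual <- dplyr::bind_rows(lapply(cohorts$interobserver, function(s)
      pairwise_observer_dsc(s$observer_masks, s$id)))
    rec[[length(rec) + 1]] <-
      dplyr::mutate(manual, test_set = "interobserver", arm = "manual")
    dplyr::bind_rows(rec)
  })

  consensus <- stage("consensus", dplyr::bind_rows(lapply(
    seq_along(cohorts$interobserver), function(i) {
      s <- cohorts$interobserver[[i]]
      cr <- consensus_regions(s$observer_masks)
      dplyr::bind_rows(lapply(1:2, function(mi)
        consensus_recall(io_preds[[mi]][[i]], cr, s$id,
                         paste0("model", mi))))
    })))

  say("building report")
  report <- stage("report", build_report(records, consensus))

  histories <- list(pretrain = tr1$history, finetune = tr2$history)
  if (manifest$write_artifacts) {
    stage("persist-results", {
      save_checkpoint(model1, file.path(out, "model1.rds"),
                      provenance = list(cohort = "source_train"))
      save_checkpoint(model2, file.path(out, "model2.rds"),
                      provenance = list(cohort = "retrain"))
      for (nm in names(histories))
        utils::write.table(histories[[nm]],
                           file.path(out, paste0("history_", nm, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(records, file.path(out, "records.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_report(report, file.path(out, "report"))
    })
  }
  structure(list(report = report, records = records, consensus = consensus,
                 model1 = model1, model2 = model2, histories = histories,
                 manifest = manifest),
            class = "gtv_study")
}

#' @export
print.gtv_study <- function(x, ...) {
  cat("<gtv_study> preset:", x$manifest$preset,
      " seed:", x$manifest$seed, "\n")
  med <- x$records |>
    dplyr::group_by(.data$test_set, .data$arm) |>
    dplyr::summarise(median_dsc = stats::median(.data$dsc, na.rm = TRUE),
                     .groups = "drop")
  print(med)
  invisible(x)
}
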