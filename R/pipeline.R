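# End-to-end orchestration: synthesize/validate -> split -> train ->
# evaluate -> enumerate -> score -> funnel, with a JSON run manifest and
# seeded reproducibility.  Each stage writes its artifact once and never
# mutates a prior stage's output.

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param seed global seed; every stochastic component receives a named
#'   substream derived from it.
#' @param synth a [synthetic_spec()] (the demo pipeline is all-synthetic).
#' @param n_records record count for the synthetic dataset.
#' @param gtnn a [gtnn_config()]; defaults to [gtnn_config_reduced()].
#' @param split_mode split regime for model evaluation.
#' @param funnel a [funnel_config()].
#' @param scorers named list of scorer names: `potency`, `adme` (see
#'   [register_scorer()]); the yield scorer is the trained model.
#' @param surf optional path to an existing SURF file used instead of the
#'   synthetic dataset.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            synth = synthetic_spec(n_arenes = 20L,
                                                   n_acids = 15L,
                                                   seed = seed),
                            n_records = 1500L,
                            gtnn = gtnn_config_reduced(seed = seed,
                                                       max_epochs = 40L),
                            split_mode = "0D",
                            funnel = funnel_config(),
                            scorers = list(potency = "potency:synthetic",
                                           adme = "adme:toy-logp"),
                            surf = NULL) {
  assert_that(is.character(out_dir) && nzchar(out_dir), "argument_error",
              "out_dir required")
  if (!is.null(surf)) {
    assert_that(file.exists(surf), "validation_error",
                "surf file not found: %s", surf)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 n_records = as.integer(n_records), gtnn = gtnn,
                 split_mode = split_mode, funnel = funnel, scorers = scorers,
                 surf = surf),
            class = "pipeline_config")
}

stage_artifact <- function(out_dir, name) file.path(out_dir, name)

#' Run the full hit-expansion pipeline
#'
#' Executes, in order: data synthesis (or SURF ingestion), dataset summary,
#' split construction, GTNN training, test-set evaluation, virtual library
#' enumeration, candidate scoring (trained yield model + registered potency /
#' ADME scorers), and the prioritization funnel.  A JSON manifest recording
#' inputs, seeds, per-stage artifacts and summary metrics is written last;
#' re-running with the same configuration reproduces the artifacts.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress.
#' @return the manifest (list), invisibly also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  assert_that(inherits(config, "pipeline_config"), "argument_error",
              "config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  manifest <- list(seed = config$seed, started = format(t_start),
                   stages = list())
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  add_stage <- function(stage, ...) {
    manifest$stages[[stage]] <- list(...)
    manifest <<- manifest
    say("[%s] done (%.1fs elapsed)", stage,
        as.numeric(Sys.time() - t_start, units = "secs"))
  }

  # 1. data
  structures <- generate_structures(config$synth)
  if (is.null(config$surf)) {
    ds <- generate_dataset(config$synth, n_records = config$n_records,
                           structures = structures)
    surf_path <- stage_artifact(config$out_dir, "synthetic.surf")
    write_surf(ds, surf_path)
  } else {
    surf_path <- config$surf
    ds <- read_surf(surf_path)
  }
  summ <- dataset_summary(ds)
  add_stage("data", surf = surf_path, n = summ$n,
            positive_rate = summ$positive_rate)

  # 2. split
  split <- make_split(ds, config$split_mode, k = 4L,
                      seed = derive_seed(config$seed, "split"))
  split_path <- stage_artifact(config$out_dir, "split.json")
  write_split(split, split_path)
  add_stage("split", path = split_path, mode = split$mode, k = split$k)

  # 3. train
  gcfg <- config$gtnn
  gcfg$seed <- derive_seed(config$seed, "train")
  fit <- train_gtnn(ds, split, gcfg, target = "yield", fold = 1L)
  model_path <- stage_artifact(config$out_dir, "model.rds")
  save_gtnn(fit$model, model_path)
  add_stage("train", checkpoint = model_path, best_epoch = fit$best_epoch,
            best_val_mae = fit$best_val_mae)

  # 4. evaluate on the held-out test fold
  te <- ds$records[ds$records$reaction_id %in% fit$test_ids, , drop = FALSE]
  pred <- predict(fit$model, te)
  truth <- total_yield(te)
  bm <- binary_metrics(pred$predicted_yield, truth)
  eval_metrics <- list(mae = mae(pred$predicted_yield, truth),
                       pearson_r = pearson(pred$predicted_yield, truth),
                       accuracy = bm$accuracy, precision = bm$precision)
  pred_path <- stage_artifact(config$out_dir, "predictions.tsv")
  utils::write.table(pred, pred_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_stage("evaluate", predictions = pred_path,
            mae = eval_metrics$mae, pearson_r = eval_metrics$pearson_r,
            accuracy = eval_metrics$accuracy,
            precision = eval_metrics$precision)

  # 5. enumerate virtual library
  library_df <- enumerate_products(structures$scaffolds, structures$acids)
  lib_path <- stage_artifact(config$out_dir, "library.tsv")
  utils::write.table(library_df, lib_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_stage("enumerate", library = lib_path, n_products = nrow(library_df))

  # 6. score candidates
  cand <- data.frame(
    scaffold_smiles = structures$scaffolds$smiles[
      match(library_df$scaffold_id, structures$scaffolds$scaffold_id)],
    acid_smiles = structures$acids$smiles[
      match(library_df$acid_id, structures$acids$acid_id)],
    product_smiles = library_df$product,
    stringsAsFactors = FALSE)
  yield_scorer <- scorer_yield_gtnn(fit$model)
  cards <- data.frame(
    scaffold_id = library_df$scaffold_id,
    acid_id = library_df$acid_id,
    pic50_pred = get_scorer(config$scorers$potency)$fun(cand),
    yield_pred = yield_scorer(cand),
    logd = get_scorer(config$scorers$adme)$fun(cand),
    lysa = NA_real_, pgp_ratio = NA_real_, pampa = NA_real_,
    stringsAsFactors = FALSE)
  cards_path <- stage_artifact(config$out_dir, "scorecards.tsv")
  utils::write.table(cards, cards_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_stage("score", scorecards = cards_path, n = nrow(cards))

  # 7. funnel
  fr <- apply_funnel(cards, config$funnel)
  ranked_path <- stage_artifact(config$out_dir, "ranked.tsv")
  utils::write.table(fr$ranked, ranked_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_stage("funnel", ranked = ranked_path,
            counts = as.list(fr$counts[!is.na(fr$counts)]))

  manifest$finished <- format(Sys.time())
  manifest$elapsed_s <- as.numeric(Sys.time() - t_start, units = "secs")
  jsonlite::write_json(manifest,
                       stage_artifact(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
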