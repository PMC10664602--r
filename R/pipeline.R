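# pipeline: orchestration of the full retrospective evaluation.
#
# prepare -> pseudotime/stages -> regions -> scorer -> generator
# (fit/focus/sample) -> metrics (full and top-k cuts) -> cluster
# predictivity -> region NLL, with every artifact listed in a manifest
# carrying the configuration and content hashes so a run is reproducible
# from the manifest alone.

#' Run configuration
#'
#' All tunables and seeds of one evaluation run.  Defaults mirror the
#' reference workflow: 5000 samples, top-k cuts of 100 and 500, activity
#' thresholds (6, 7, 8), stage fractions (0.5, 0.25, 0.25), k-means k = 10.
#'
#' @param project_table path to the project CSV/XLSX.
#' @param out_dir output directory for all artifacts.
#' @param generated_set optional path to an externally generated SMILES set;
#'   when `NULL`, the built-in Markov generator is fitted and sampled.
#' @param pretrain_corpus optional path to a SMILES corpus for the Markov
#'   prior (and the novelty reference); defaults to the project compounds.
#' @param column_map column mapping for [load_project_table()].
#' @param thresholds pXC50 cutpoints, length 3.
#' @param stage_mode `"pseudo_time"` or `"dated"`.
#' @param stage_fractions pseudo-time stage fractions.
#' @param stage_cutpoints dated-mode cumulative count cutpoints.
#' @param focus_rule `"above_mean_early"` or `"region_alpha"`.
#' @param sample_n generator sample size.
#' @param top_k score-filter cut sizes.
#' @param markov_order,markov_smoothing,markov_lambda generator parameters.
#' @param novelty_reference `"union"`, `"corpus"` or `"focus"`.
#' @param kmeans_k cluster count.
#' @param fp_asnn_radius,fp_asnn_nbits aSNN fingerprint configuration.
#' @param seeds named list/vector with `scorer`, `kmeans`, `generator`.
#' @return object of class `run_config`.
#' @export
run_config <- function(project_table, out_dir,
                       generated_set = NULL, pretrain_corpus = NULL,
                       column_map = list(smiles = "SMILES", pxc50 = "pXC50",
                                         date = "date"),
                       thresholds = c(6, 7, 8),
                       stage_mode = c("pseudo_time", "dated"),
                       stage_fractions = c(0.5, 0.25, 0.25),
                       stage_cutpoints = NULL,
                       focus_rule = "above_mean_early",
                       sample_n = 5000, top_k = c(100, 500),
                       markov_order = 3, markov_smoothing = 0.01,
                       markov_lambda = 0.5,
                       novelty_reference = c("union", "corpus", "focus"),
                       kmeans_k = 10,
                       fp_asnn_radius = 2, fp_asnn_nbits = 2048,
                       seeds = list(scorer = 42, kmeans = 42, generator = 42)) {
  cfg <- list(
    project_table = project_table, out_dir = out_dir,
    generated_set = generated_set, pretrain_corpus = pretrain_corpus,
    column_map = column_map, thresholds = as.numeric(thresholds),
    stage_mode = match.arg(stage_mode),
    stage_fractions = stage_fractions, stage_cutpoints = stage_cutpoints,
    focus_rule = focus_rule, sample_n = sample_n, top_k = top_k,
    markov_order = markov_order, markov_smoothing = markov_smoothing,
    markov_lambda = markov_lambda,
    novelty_reference = match.arg(novelty_reference),
    kmeans_k = kmeans_k, fp_asnn_radius = fp_asnn_radius,
    fp_asnn_nbits = fp_asnn_nbits,
    seeds = lapply(seeds, as.integer)
  )
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' The YAML round-trips: `config_load(config_save(cfg, f))` reproduces the
#' configuration.
#'
#' @param config a [run_config()] object.
#' @param path YAML file path.
#' @export
config_save <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_save
#' @export
config_load <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

.cfg_thresholds <- function(config) {
  activity_thresholds(config$thresholds[1], config$thresholds[2],
                      config$thresholds[3])
}

.label_from_config <- function(config) {
  rec <- load_project_table(config$project_table,
                            column_map = config$column_map)
  label_dataset(rec, thresholds = .cfg_thresholds(config),
                fractions = config$stage_fractions,
                cutpoints = config$stage_cutpoints,
                mode = config$stage_mode)
}

#' Characterize a project dataset
#'
#' Labels the project (stages, classes, regions), writes the labelled table
#' and reports region sizes plus all pairwise region aSNN values among the
#' populated regions (the dataset-characterization analysis).
#'
#' @param config a [run_config()].
#' @param labelled optional pre-labelled records (skips re-loading).
#' @return list with `labelled`, `region_sizes`, `region_asnn`
#'   (data.frame query/reference/asnn) and written file paths.
#' @export
run_characterize <- function(config, labelled = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(labelled)) labelled <- .label_from_config(config)
  labelled_path <- file.path(config$out_dir, "labelled_project.csv")
  write_project_table(labelled, labelled_path)
  sizes <- table(labelled$region)
  present <- names(sizes)[sizes > 0 & names(sizes) != "none"]
  pairs <- expand.grid(query = present, reference = present,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$query != pairs$reference, , drop = FALSE]
  pairs$asnn <- mapply(function(a, b) {
    region_asnn(labelled, a, b, radius = config$fp_asnn_radius,
                nbits = config$fp_asnn_nbits)
  }, pairs$query, pairs$reference)
  report <- list(n = nrow(labelled),
                 region_sizes = as.list(sizes),
                 stage_sizes = as.list(table(labelled$stage)),
                 class_sizes = as.list(table(labelled$activity_class)),
                 region_asnn = pairs)
  char_path <- file.path(config$out_dir, "characterization.json")
  jsonlite::write_json(report, char_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  list(labelled = labelled, region_sizes = sizes, region_asnn = pairs,
       files = c(labelled = labelled_path, characterization = char_path))
}

#' Evaluate a generated compound set against a labelled project
#'
#' Produces the generation report (validity / uniqueness / novelty /
#' rediscovery) and the stratified aSNN tables for the full set and for
#' each top-k score cut.
#'
#' @param config a [run_config()].
#' @param generated_raw raw generated SMILES.
#' @param labelled labelled project records.
#' @param scores per-compound activity-model scores aligned with
#'   `generated_raw` (required when `config$top_k` is non-empty).
#' @param novelty_ref canonical SMILES reference for novelty.
#' @return named list of evaluations (`full`, `top100`, ...), each with
#'   `report` and `asnn_table`.
#' @export
run_evaluate <- function(config, generated_raw, labelled, scores = NULL,
                         novelty_ref = character(0)) {
  gamma_ref <- labelled$smiles_canonical[labelled$region == "gamma"]
  cuts <- list(full = generated_raw)
  for (k in config$top_k) {
    if (k > length(generated_raw)) next
    if (is.null(scores)) stop("top-k evaluation needs scores", call. = FALSE)
    cuts[[paste0("top", k)]] <- top_k_by_score(generated_raw, scores, k)
  }
  lapply(cuts, function(set) {
    rep <- generation_report(set, novelty_ref, gamma_ref)
    val <- validity(set)
    tab <- if (val$n_val > 0) {
      stratified_asnn(unique(val$valid_canonical), labelled,
                      radius = config$fp_asnn_radius,
                      nbits = config$fp_asnn_nbits)
    } else NULL
    list(report = rep, asnn_table = tab)
  })
}

#' Run the full retrospective evaluation workflow
#'
#' Characterization, scorer training, generator fit + focus + sampling,
#' metric evaluation (full and top-k), cluster predictivity and per-region
#' NLL, with every artifact written under `config$out_dir` and listed with
#' its SHA-256 hash in `manifest.json`.  Two runs with the same
#' configuration produce identical manifests.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly; artifacts on disk.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "characterize"
  manifest <- list(config = unclass(config))
  # config echo (contains machine-local paths, so not in the hashed list;
  # the manifest embeds the config itself)
  config_save(config, file.path(out, "config.yaml"))
  files <- character(0)
  tryCatch({
    char <- run_characterize(config)
    labelled <- char$labelled
    files <- c(files, char$files)
    message(sprintf("[characterize] n=%d | alpha=%d beta=%d gamma=%d",
                    nrow(labelled), sum(labelled$region == "alpha"),
                    sum(labelled$region == "beta"),
                    sum(labelled$region == "gamma")))

    stage <- "scorer"
    early <- labelled[labelled$stage == "early", , drop = FALSE]
    scorer <- train_scorer(early, seed = config$seeds$scorer)
    message(sprintf("[scorer] trained on %d early compounds; balanced accuracy %.3f",
                    nrow(early), scorer$balanced_accuracy_test))
    rs <- region_scores(scorer, labelled)
    rs_path <- file.path(out, "region_scores.csv")
    utils::write.csv(rs, rs_path, row.names = FALSE)
    files <- c(files, region_scores = rs_path)

    stage <- "generator"
    corpus <- if (!is.null(config$pretrain_corpus)) {
      load_generated_set(config$pretrain_corpus)$smiles
    } else labelled$smiles_canonical
    prior <- markov_fit(corpus, order = config$markov_order,
                        smoothing = config$markov_smoothing)
    focus <- focus_set(labelled, config$focus_rule)
    agent <- markov_focus(prior, focus$smiles_canonical,
                          lambda = config$markov_lambda)
    if (!is.null(config$generated_set)) {
      gen <- load_generated_set(config$generated_set)$smiles
    } else {
      gen <- markov_sample(agent, config$sample_n,
                           seed = config$seeds$generator)
      gen_path <- file.path(out, "generated.smi")
      writeLines(gen, gen_path)
      files <- c(files, generated = gen_path)
    }
    message(sprintf("[generator] corpus %d; focus %d; sampled %d",
                    length(corpus), nrow(focus), length(gen)))

    prior_path <- file.path(out, "generator_prior.json")
    markov_save(prior, prior_path)
    model_path <- file.path(out, "generator_model.json")
    markov_save(agent, model_path)
    files <- c(files, generator_prior = prior_path,
               generator_model = model_path)

    stage <- "evaluate"
    scores <- score_compounds(scorer, gen)
    scores_path <- file.path(out, "generated_scores.csv")
    utils::write.csv(data.frame(smiles = gen, score = scores),
                     scores_path, row.names = FALSE)
    files <- c(files, generated_scores = scores_path)
    novelty_ref <- switch(config$novelty_reference,
      corpus = unique(corpus),
      focus = unique(focus$smiles_canonical),
      union = unique(c(corpus, focus$smiles_canonical)))
    evals <- run_evaluate(config, gen, labelled, scores = scores,
                          novelty_ref = novelty_ref)
    eval_path <- file.path(out, "evaluation.json")
    jsonlite::write_json(
      lapply(evals, function(e) list(report = unclass(e$report),
                                     asnn = e$asnn_table)),
      eval_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- c(files, evaluation = eval_path)
    for (nm in names(evals)) {
      message(sprintf("[evaluate:%s] ", nm),
              sprintf("val %.1f%% uniq %.1f%% nov %.1f%% redis %.2f%%",
                      evals[[nm]]$report$validity_pct,
                      evals[[nm]]$report$uniqueness_pct,
                      evals[[nm]]$report$novelty_pct,
                      evals[[nm]]$report$rediscovery_pct))
    }

    stage <- "cluster"
    cp <- cluster_predictivity(labelled, k = config$kmeans_k,
                               seed = config$seeds$kmeans)
    cl_path <- file.path(out, "cluster_predictivity.csv")
    utils::write.csv(cp$table, cl_path, row.names = FALSE)
    files <- c(files, cluster_predictivity = cl_path)
    message(sprintf("[cluster] %d predictive / %d unpredictive / %d indeterminate",
                    cp$summary[1], cp$summary[2], cp$summary[3]))

    stage <- "nll"
    nll <- region_nll_summary(list(prior = prior, focused = agent), labelled)
    nll_path <- file.path(out, "region_nll.csv")
    utils::write.csv(nll, nll_path, row.names = FALSE)
    files <- c(files, region_nll = nll_path)
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage, "--", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$artifacts <- lapply(seq_along(files), function(i) {
    list(name = names(files)[i], file = basename(files[[i]]),
         sha256 = digest::digest(file = files[[i]], algo = "sha256"))
  })
  manifest$seeds <- config$seeds
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
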