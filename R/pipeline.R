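#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every
#' tunable at its documented default.  Any element may be overridden via
#' the `...` of `run_pipeline` or by a YAML file with the same keys.
#'
#' @return named list of configuration defaults.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "ghrs_run",
    seed = 1L,
    stages = c("delphi", "cohort", "selection", "model", "network",
               "multilayer"),
    # delphi
    n_experts = 54L,
    # cohort
    n_subjects = 660L,
    prevalence_target = 453 / 660,
    cohort_csv = NULL,        # optional: use an existing cohort instead
    # selection
    cv_folds = 10L,
    standardize = FALSE,
    # model
    test_fraction = 0.3,
    model_params = default_model_params(),
    grid = NULL,              # a named grid list enables grid search
    grid_folds = 5L,
    # network
    kb_dir = NULL,            # optional: snapshot directory instead
    kb_genes = 300L, kb_terms = 30L, kb_pathways = 20L,
    hub_fraction = 0.05,
    min_score = 0.4,
    hub_multiplier = 2,
    alpha = 0.05,
    top_n = 20L)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), as.list(config))
  if (!is.numeric(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  known <- c("delphi", "cohort", "selection", "model", "network",
             "multilayer")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (f in c("cohort_csv", "kb_dir")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("configured input does not exist: ", f, " = ", cfg[[f]],
           call. = FALSE)
    }
  }
  cfg
}

stage_dir <- function(out_dir, stage) {
  d <- file.path(out_dir, c(delphi = "01_delphi", cohort = "02_cohort",
                            selection = "03_selection", model = "04_model",
                            network = "05_network",
                            multilayer = "06_multilayer")[[stage]])
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

require_upstream <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s' needs output of stage '%s' (%s); run it first",
                 needed_by, stage, path), call. = FALSE)
  }
  path
}

#' Run the full syndrome-characterization pipeline
#'
#' Executes, in order, the enabled stages: Delphi item screening on a
#' simulated expert round calibrated to the packaged reference items;
#' synthetic (or supplied) cohort generation and description;
#' Lasso core-symptom selection at lambda.1se; boosted-tree model
#' training, threshold tuning and test-set evaluation; network-biology
#' analysis against a knowledge-base snapshot; and tripartite network
#' assembly and export.  Every stage persists its outputs under a
#' numbered subdirectory of `out_dir` and later stages reload persisted
#' upstream outputs, so any suffix of the pipeline can be re-run.  A
#' `manifest.json` records every tunable, all derived stage seeds and the
#' package version.
#'
#' @param config a configuration list, or the path of a YAML file; see
#'   [default_pipeline_config()] for the keys.
#' @param ... individual overrides applied on top of `config`.
#' @return the configuration (with derived seeds), invisibly; outputs on
#'   disk under `config$out_dir`.
#' @export
run_pipeline <- function(config = list(), ...) {
  cfg <- read_pipeline_config(config)
  cfg <- utils::modifyList(cfg, list(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stats::setNames(
    lapply(c("delphi", "cohort", "selection", "model", "network"),
           function(s) derive_seed(cfg$seed, s)),
    c("delphi", "cohort", "selection", "model", "network"))
  manifest <- c(cfg[setdiff(names(cfg), "stages")],
                list(stages = cfg$stages, stage_seeds = seeds,
                     package_version = as.character(
                       utils::packageVersion("ghrskit"))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  if ("delphi" %in% cfg$stages) pipeline_delphi(cfg, seeds$delphi)
  if ("cohort" %in% cfg$stages) pipeline_cohort(cfg, seeds$cohort)
  if ("selection" %in% cfg$stages) pipeline_selection(cfg, seeds$selection)
  if ("model" %in% cfg$stages) pipeline_model(cfg, seeds$model)
  if ("network" %in% cfg$stages) pipeline_network(cfg, seeds$network)
  if ("multilayer" %in% cfg$stages) pipeline_multilayer(cfg)
  message("pipeline complete: ", normalizePath(cfg$out_dir))
  invisible(cfg)
}

pipeline_delphi <- function(cfg, seed) {
  d <- stage_dir(cfg$out_dir, "delphi")
  fx <- load_reference_fixtures()
  items <- data.frame(item = fx$delphi_items$item,
                      mu = fx$delphi_items$mean_score)
  scores <- generate_expert_scores(cfg$n_experts, items, seed = seed)
  stats <- item_statistics(scores)
  thr <- deletion_thresholds(stats)
  res <- apply_deletion_rules(stats, thr)
  rel <- cronbach_alpha(scores)
  utils::write.csv(stats, file.path(d, "item_statistics.csv"),
                   row.names = FALSE)
  screen <- rbind(
    data.frame(item = res$retained, status = "retained", rules = "",
               stringsAsFactors = FALSE),
    data.frame(item = res$deleted$item, status = "deleted",
               rules = res$deleted$rules, stringsAsFactors = FALSE))
  utils::write.csv(screen, file.path(d, "screening.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(score_min = thr$score_min, cv_max = thr$cv_max,
         fullmark_min = thr$fullmark_min, cronbach_alpha = rel$alpha),
    file.path(d, "thresholds.json"), auto_unbox = TRUE, digits = NA)
}

pipeline_cohort <- function(cfg, seed) {
  d <- stage_dir(cfg$out_dir, "cohort")
  if (!is.null(cfg$cohort_csv)) {
    cohort <- read_cohort_csv(cfg$cohort_csv)
  } else {
    sim <- generate_clinical_cohort(n = cfg$n_subjects,
                                    prevalence_target = cfg$prevalence_target,
                                    seed = seed)
    cohort <- sim$cohort
    jsonlite::write_json(
      list(informative_symptoms = sim$truth$informative_symptoms,
           coefficients = sim$truth$coefficients,
           intercept = sim$truth$intercept,
           age_effect = sim$truth$age_effect),
      file.path(d, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  write_cohort_csv(cohort, file.path(d, "cohort.csv"))
  utils::write.csv(describe_cohort(cohort),
                   file.path(d, "cohort_description.csv"), row.names = FALSE)
}

load_stage_cohort <- function(cfg, needed_by) {
  read_cohort_csv(require_upstream(
    file.path(stage_dir(cfg$out_dir, "cohort"), "cohort.csv"),
    "cohort", needed_by))
}

pipeline_selection <- function(cfg, seed) {
  d <- stage_dir(cfg$out_dir, "selection")
  cohort <- load_stage_cohort(cfg, "selection")
  sel <- select_core_symptoms(cohort, k = cfg$cv_folds, seed = seed,
                              standardize = cfg$standardize)
  utils::write.csv(
    data.frame(lambda = sel$curve$lambda,
               mean_deviance = sel$curve$mean_deviance,
               se_deviance = sel$curve$se_deviance),
    file.path(d, "cv_curve.csv"), row.names = FALSE)
  utils::write.csv(sel$selected, file.path(d, "core_symptoms.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(lambda_min = sel$curve$lambda_min,
                            lambda_1se = sel$curve$lambda_1se),
                       file.path(d, "lambda.json"), auto_unbox = TRUE,
                       digits = NA)
}

pipeline_model <- function(cfg, seed) {
  d <- stage_dir(cfg$out_dir, "model")
  cohort <- load_stage_cohort(cfg, "model")
  split <- split_train_test(cohort, cfg$test_fraction,
                            derive_seed(seed, "split"))
  if (!is.null(cfg$grid)) {
    gs <- grid_search(split$train, cfg$grid, k = cfg$grid_folds,
                      seed = derive_seed(seed, "grid"))
    params <- gs$best_params
    utils::write.csv(gs$results, file.path(d, "grid_results.csv"),
                     row.names = FALSE)
  } else {
    params <- cfg$model_params
  }
  model <- fit_diagnostic_model(split$train, params,
                                seed = derive_seed(seed, "fit"))
  model$threshold <- optimal_threshold(model, split$train)
  metrics <- evaluate_model(model, split$test)
  roc <- roc_auc(label_vector(split$test), predict(model, split$test))
  utils::write.csv(roc$roc, file.path(d, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.csv(gain_importance(model), file.path(d, "gain.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(metrics[c("accuracy", "sensitivity", "omission_rate", "specificity",
                "mistake_rate", "auc", "threshold")],
      list(confusion = as.list(metrics$confusion), params = params)),
    file.path(d, "metrics.json"), auto_unbox = TRUE, digits = NA)
  xgboost::xgb.save(model$booster, file.path(d, "model.ubj"))
}

pipeline_network <- function(cfg, seed) {
  d <- stage_dir(cfg$out_dir, "network")
  core <- utils::read.csv(require_upstream(
    file.path(stage_dir(cfg$out_dir, "selection"), "core_symptoms.csv"),
    "selection", "network"), stringsAsFactors = FALSE)
  if (!is.null(cfg$kb_dir)) {
    kb <- read_knowledge_base(cfg$kb_dir)
  } else {
    cohort <- load_stage_cohort(cfg, "network")
    kb <- generate_knowledge_base(n_genes = cfg$kb_genes,
                                  n_terms = cfg$kb_terms,
                                  n_pathways = cfg$kb_pathways,
                                  hub_fraction = cfg$hub_fraction,
                                  seed = seed,
                                  symptoms = symptom_names(cohort))
    write_knowledge_base(kb, file.path(d, "kb"))
  }
  net <- run_network_analysis(core, kb, min_score = cfg$min_score,
                              multiplier = cfg$hub_multiplier,
                              alpha = cfg$alpha, top_n = cfg$top_n)
  writeLines(net$hubs, file.path(d, "hub_genes.txt"))
  utils::write.csv(net$enrichment, file.path(d, "enrichment.csv"),
                   row.names = FALSE)
  topo <- net$topology
  jsonlite::write_json(
    list(terms = net$terms, unmapped_symptoms = net$unmapped,
         n_genes = length(net$genes), n_hubs = length(net$hubs),
         hub_topology = topo[c("node_count", "edge_count", "average_degree",
                               "average_local_clustering", "median_degree")]),
    file.path(d, "topology.json"), auto_unbox = TRUE, digits = NA)
}

pipeline_multilayer <- function(cfg) {
  d <- stage_dir(cfg$out_dir, "multilayer")
  nd <- stage_dir(cfg$out_dir, "network")
  hubs <- readLines(require_upstream(file.path(nd, "hub_genes.txt"),
                                     "network", "multilayer"))
  enr <- utils::read.csv(file.path(nd, "enrichment.csv"),
                         stringsAsFactors = FALSE)
  kb_dir <- if (!is.null(cfg$kb_dir)) cfg$kb_dir else file.path(nd, "kb")
  kb <- read_knowledge_base(kb_dir)
  core <- utils::read.csv(require_upstream(
    file.path(stage_dir(cfg$out_dir, "selection"), "core_symptoms.csv"),
    "selection", "multilayer"), stringsAsFactors = FALSE)
  stm <- kb$symptom_term_map[intersect(core$symptom,
                                       names(kb$symptom_term_map))]
  net <- assemble_tripartite(stm, hubs, kb$term_gene_table, enr,
                             kb$pathway_sets)
  export_network(net, file.path(d, "network.graphml"), "graphml")
  export_network(net, file.path(d, "network.sif"), "sif")
  export_network(net, file.path(d, "nodes.csv"), "csv")
}
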