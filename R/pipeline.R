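#' Benchmark run configuration
#'
#' Collects every tunable of the pipeline with the benchmark's standard
#' defaults: biomass floor 10% of the wild-type maximum, differential
#' abundance and enrichment thresholds p <= 0.05 (nominal, uncorrected),
#' minimum 3 differential metabolites for ORA testability, 1000 GSEA
#' permutations, and uniqueness z threshold 2.
#'
#' @param model A `metabolic_model` or an SBML file path.
#' @param side_compound_path,category_path Optional sidecar files (used when
#'   `model` is a path).
#' @param biomass_id Biomass reaction id (when `model` is a path; default:
#'   the SBML active objective).
#' @param extracellular Extracellular compartment id(s).
#' @param floor_fraction Biomass floor fraction in `[0, 1]`.
#' @param n_samples Flux samples per state (>= 2).
#' @param thinning Sampler thinning.
#' @param seed Integer run seed.
#' @param alpha_da ORA differential-abundance threshold.
#' @param min_hits ORA testability minimum.
#' @param alpha_enrich Enrichment significance threshold.
#' @param n_perm GSEA permutations.
#' @param z_thr Uniqueness-score z threshold.
#' @param z_max z clipping bound.
#' @param methods Subset of `"ora"`, `"gsea_signed"`, `"gsea_absolute"`.
#' @param da_stat ORA DA statistic, `"signed"` or `"abs"`.
#' @param out_dir Optional output directory for TSV/GMT/GraphML reports.
#' @return A validated `run_config` list.
#' @export
run_config <- function(model, side_compound_path = NULL, category_path = NULL,
                       biomass_id = NULL, extracellular = "e",
                       floor_fraction = 0.1, n_samples = 5000, thinning = 100,
                       seed = 1, alpha_da = 0.05, min_hits = 3,
                       alpha_enrich = 0.05, n_perm = 1000, z_thr = 2,
                       z_max = 50,
                       methods = c("ora", "gsea_signed", "gsea_absolute"),
                       da_stat = "signed", out_dir = NULL) {
  validate_config(list(
    model = model, side_compound_path = side_compound_path,
    category_path = category_path, biomass_id = biomass_id,
    extracellular = extracellular, floor_fraction = floor_fraction,
    n_samples = n_samples, thinning = thinning, seed = seed,
    alpha_da = alpha_da, min_hits = min_hits, alpha_enrich = alpha_enrich,
    n_perm = n_perm, z_thr = z_thr, z_max = z_max, methods = methods,
    da_stat = da_stat, out_dir = out_dir
  ))
}

#' Validate and normalise a raw configuration
#'
#' Fills defaults, checks ranges, and reports every violation at once.
#'
#' @param config A named list of configuration entries (at least `model`).
#' @return A `run_config` list.
#' @export
validate_config <- function(config) {
  defaults <- list(
    model = NULL, side_compound_path = NULL, category_path = NULL,
    biomass_id = NULL, extracellular = "e", floor_fraction = 0.1,
    n_samples = 5000, thinning = 100, seed = 1, alpha_da = 0.05,
    min_hits = 3, alpha_enrich = 0.05, n_perm = 1000, z_thr = 2, z_max = 50,
    methods = c("ora", "gsea_signed", "gsea_absolute"), da_stat = "signed",
    out_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  errs <- character()
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  config <- modifyList(defaults, config[intersect(names(config), names(defaults))],
    keep.null = TRUE
  )
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  if (is.null(config$model)) errs <- c(errs, "model is required (path or metabolic_model)")
  if (!(is.numeric(config$floor_fraction) && config$floor_fraction >= 0 &&
    config$floor_fraction <= 1)) {
    errs <- c(errs, "floor_fraction must be in [0, 1]")
  }
  if (!in01(config$alpha_da)) errs <- c(errs, "alpha_da must be in (0, 1]")
  if (!in01(config$alpha_enrich)) errs <- c(errs, "alpha_enrich must be in (0, 1]")
  if (!(is.numeric(config$n_samples) && config$n_samples >= 2)) {
    errs <- c(errs, "n_samples must be >= 2")
  }
  if (!(is.numeric(config$thinning) && config$thinning >= 1)) {
    errs <- c(errs, "thinning must be >= 1")
  }
  if (!(is.numeric(config$min_hits) && config$min_hits >= 1)) {
    errs <- c(errs, "min_hits must be >= 1")
  }
  if (!(is.numeric(config$n_perm) && config$n_perm >= 1)) {
    errs <- c(errs, "n_perm must be >= 1")
  }
  if (!(is.numeric(config$z_thr) && config$z_thr >= 0)) {
    errs <- c(errs, "z_thr must be >= 0")
  }
  if (!(is.numeric(config$z_max) && config$z_max > 0)) {
    errs <- c(errs, "z_max must be > 0")
  }
  bad_m <- setdiff(config$methods, c("ora", "gsea_signed", "gsea_absolute"))
  if (length(bad_m) || !length(config$methods)) {
    errs <- c(errs, paste0(
      "methods must be a non-empty subset of ora/gsea_signed/gsea_absolute",
      if (length(bad_m)) paste0(" (got: ", paste(bad_m, collapse = ", "), ")")
    ))
  }
  if (!config$da_stat %in% c("signed", "abs")) {
    errs <- c(errs, "da_stat must be 'signed' or 'abs'")
  }
  if (length(errs)) abort(paste0("invalid configuration:\n- ", paste(errs, collapse = "\n- ")))
  structure(config, class = "run_config")
}

enrich_one <- function(profile, method, sets, background, config, run_seed) {
  switch(method,
    ora = run_ora(profile, sets, background,
      alpha_da = config$alpha_da, min_hits = config$min_hits,
      da_stat = config$da_stat
    ),
    gsea_signed = run_gsea(profile, sets,
      mode = "signed",
      n_perm = config$n_perm, seed = run_seed
    ),
    gsea_absolute = run_gsea(profile, sets,
      mode = "absolute",
      n_perm = config$n_perm, seed = run_seed
    ),
    abort(paste0("unknown method: ", method))
  )
}

#' Run the full knockout benchmark
#'
#' End-to-end: load/prune the model, derive pathway sets and the
#' exchangeable background, simulate every knockout scenario, run each
#' configured enrichment method on each profile, score the rates, and
#' compute the explanatory pathway properties (with TP-vs-FN comparisons
#' and a PCA when the labels allow). The input model file is never
#' modified; knockouts act on in-memory copies.
#'
#' @param config A [run_config()] (or raw list passed through
#'   [validate_config()]).
#' @return A `benchmark_run` list: `model` (pruned), `blocked_reactions`,
#'   `simulation` (profiles + scenario ledger), `enrichment` (tibble over
#'   scenario x method x pathway), `evaluations` (named list of
#'   `pa_evaluation`), `summary` (their glance rows), `properties`,
#'   `comparisons`, `pca`, `config`, `config_hash`.
#' @export
run_benchmark <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  model <- config$model
  if (is.character(model)) {
    model <- read_sbml_model(
      model,
      side_compound_path = config$side_compound_path,
      category_path = config$category_path,
      biomass_id = config$biomass_id,
      extracellular = config$extracellular
    )
  }
  stopifnot(inherits(model, "metabolic_model"))

  blocked <- find_blocked_reactions(model)
  pruned <- prune_model(model, blocked)
  sets <- metabolite_pathway_sets(pruned, include_side = TRUE)
  background <- exchangeable_background(pruned)

  sim <- run_all_scenarios(
    pruned,
    n_samples = config$n_samples, seed = config$seed,
    floor_fraction = config$floor_fraction, thinning = config$thinning,
    z_max = config$z_max
  )
  functional <- sim$ledger$pathway_id[sim$ledger$status == "functional"]
  profiles <- split(sim$profiles, sim$profiles$scenario)

  enrichment <- list()
  evaluations <- list()
  for (method in config$methods) {
    results <- purrr::imap(profiles, function(pr, pw) {
      enrich_one(
        pr, method, sets, background, config,
        run_seed = scenario_seed(config$seed, paste0(method, ":", pw))
      )
    })
    enrichment[[method]] <- purrr::imap_dfr(
      results, ~ mutate(.x, scenario = .y, .before = 1)
    )
    evaluations[[method]] <- evaluate_scenarios(
      results,
      alpha = config$alpha_enrich, universe = functional
    )
  }

  properties <- compute_pathway_properties(pruned, sim$profiles, thr = config$z_thr)
  labels <- purrr::map_dfr(evaluations, ~ .x$outcomes) %>%
    select(pathway_id = "scenario", "method", label = "target_label")
  comparisons <- tryCatch(
    compare_tp_fn(properties, labels),
    error = function(e) NULL
  )
  pca <- tryCatch(
    pathway_pca(filter(properties, .data$pathway_id %in% functional)),
    error = function(e) NULL
  )

  run <- structure(
    list(
      model = pruned,
      blocked_reactions = blocked,
      simulation = sim,
      enrichment = bind_rows(enrichment),
      evaluations = evaluations,
      summary = purrr::map_dfr(evaluations, glance),
      properties = properties,
      comparisons = comparisons,
      pca = pca,
      config = config,
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
    ),
    class = "benchmark_run"
  )
  if (!is.null(config$out_dir)) write_benchmark_reports(run, config$out_dir)
  run
}

#' Write the report bundle of a benchmark run
#'
#' Emits TSV tables (scenario ledger, profiles, enrichment, outcomes,
#' summary, properties, comparisons, PCA coordinates), the pathway sets as
#' GMT, and the overlap graph as TSV + GraphML, all stamped with the config
#' hash and seed in `run_info.tsv`.
#'
#' @param run A `benchmark_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  tsv(run$simulation$ledger, "scenario_ledger.tsv")
  tsv(run$simulation$profiles, "zscore_profiles.tsv")
  tsv(run$enrichment, "enrichment.tsv")
  tsv(purrr::map_dfr(run$evaluations, tidy), "scenario_outcomes.tsv")
  tsv(run$summary, "evaluation_summary.tsv")
  tsv(run$properties, "pathway_properties.tsv")
  if (!is.null(run$comparisons)) tsv(run$comparisons, "tp_fn_comparisons.tsv")
  if (!is.null(run$pca)) {
    tsv(run$pca$scores, "pca_scores.tsv")
    tsv(run$pca$loadings, "pca_loadings.tsv")
  }
  write_gmt(
    metabolite_pathway_sets(run$model, include_side = TRUE),
    file.path(dir, "pathway_sets.gmt")
  )
  pg <- build_pathway_graph(metabolite_pathway_sets(run$model, include_side = FALSE))
  write_pathway_graph(
    pg, file.path(dir, "pathway_graph_edges.tsv"),
    graphml_path = file.path(dir, "pathway_graph.graphml")
  )
  tsv(
    tibble(
      key = c("config_hash", "seed", "n_samples", "timestamp"),
      value = c(
        run$config_hash, run$config$seed, run$config$n_samples,
        format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    "run_info.tsv"
  )
  invisible(dir)
}

#' @export
print.benchmark_run <- function(x, ...) {
  cat("<benchmark_run> seed ", x$config$seed, ", config ", x$config_hash, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
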