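#' Run the full simulate -> build -> train -> evaluate -> explain pipeline
#'
#' End-to-end driver over the package's stages: generate (or load) a cohort,
#' build multi-modal brain graphs, run repeated split/train/test experiments,
#' explain a sample of subjects with the mask optimiser, extract the
#' top-percent edges per group and count intra-/inter-network connections.
#' Every numeric artefact is written under `out_dir` along with a JSON run
#' manifest (config snapshot, seed, package version, timestamps) sufficient
#' to re-run the pipeline deterministically.
#'
#' @param scenario preset name (see [preset_scenarios()]) or an
#'   `mgin_effect_spec`.
#' @param out_dir output directory (created if missing).
#' @param seed master seed for the run.
#' @param config `mgin_config`; default [synthetic_train_config()].
#' @param repeats repeated experiments for the metrics report.
#' @param explain_n how many subjects to explain (balanced over groups).
#' @param explainer `mgin_explainer_config`.
#' @param pct top-percent threshold for reported connections.
#' @return (invisibly) list with metrics report, explanation summaries and
#'   the manifest.
#' @export
run_pipeline <- function(scenario = "shared_signal", out_dir, seed = 1,
                         config = synthetic_train_config(seed = seed),
                         repeats = 5, explain_n = 20,
                         explainer = explainer_config(), pct = 5) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- if (inherits(scenario, "mgin_effect_spec")) scenario else {
    presets <- preset_scenarios(seed = seed)
    if (!scenario %in% names(presets))
      stop("config error: unknown scenario '", scenario, "'")
    presets[[scenario]]
  }
  message("[1/5] generating cohort (seed ", seed, ")")
  sim <- generate_cohort(spec)
  write_atlas(sim$atlas, file.path(out_dir, "atlas.csv"))
  write_metadata(sim$metadata, file.path(out_dir, "metadata.csv"))
  for (mod in names(sim$ground_truth))
    utils::write.csv(sim$ground_truth[[mod]],
                     file.path(out_dir, paste0("ground_truth_", mod, ".csv")),
                     row.names = FALSE)
  message("[2/5] building brain graphs")
  graphs <- build_cohort_graphs(sim$cohort, sim$metadata, sim$atlas,
                                modalities = config$modalities)
  message("[3/5] repeated split/train/test experiments")
  report <- bootstrap_protocol(graphs, config, repeats = repeats)
  utils::write.csv(report$per_repeat,
                   file.path(out_dir, "metrics_per_repeat.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "metrics_summary.csv"),
                   row.names = FALSE)
  message("[4/5] training final model and explaining subjects")
  final <- run_experiment(graphs, config, seed)
  set.seed(seed)
  labels <- sim$metadata$sex
  pick <- c(sample(which(labels == 0), min(explain_n %/% 2, sum(labels == 0))),
            sample(which(labels == 1), min(explain_n - explain_n %/% 2,
                                           sum(labels == 1))))
  bc_graphs <- apply_boxcox_cohort(graphs, final$split$train)$graphs
  expl <- explain_cohort(final$model, bc_graphs[pick], explainer)
  info <- data.frame(sex = labels[pick],
                     stage = vapply(graphs[pick], function(g) g$stage,
                                    character(1)))
  message("[5/5] aggregating masks and counting network connections")
  for (mod in config$modalities) {
    mm <- group_mask(expl, info, mod)
    edges <- top_percent_edges(mm, pct)
    write_edge_set(edges, sim$atlas,
                   file.path(out_dir, paste0("top_edges_", mod, ".csv")))
    utils::write.csv(network_counts(edges, sim$atlas),
                     file.path(out_dir, paste0("network_counts_", mod, ".csv")))
    utils::write.csv(report_rois(edges, sim$atlas, top_n = 20),
                     file.path(out_dir, paste0("roi_table_", mod, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "mginconn",
    version = as.character(utils::packageVersion("mginconn")),
    scenario = if (is.character(scenario)) scenario else "custom",
    seed = seed,
    config = unclass(config),
    explainer = unclass(explainer),
    repeats = repeats, explain_n = explain_n, pct = pct,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, final = final, explanations = expl,
                 manifest = manifest))
}
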