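#' MLP baseline on flattened connectivity features
#'
#' The fusion-ablation comparator: a single-hidden-layer perceptron
#' (`nnet::nnet`, logistic output, cross-entropy fit) on the concatenated
#' upper-triangle |r| values of every modality. One repeat splits, trains
#' and tests exactly like the graph model.
#'
#' @param graphs raw `mgin_graph` cohort.
#' @param config `mgin_config` (split ratios, modalities and seed are used).
#' @param repeats number of re-split repeats.
#' @param size hidden units.
#' @param decay L2 penalty passed to `nnet`.
#' @param maxit optimiser iterations.
#' @return `mgin_metrics_report`.
#' @export
mlp_baseline_protocol <- function(graphs, config, repeats = 10, size = 16,
                                  decay = 1e-3, maxit = 200) {
  labels <- vapply(graphs, function(g) g$label, integer(1))
  flat <- function(g) unlist(lapply(config$modalities, function(m) {
    A <- g$blocks[[m]]$adjacency
    A[upper.tri(A)]
  }), use.names = FALSE)
  X <- do.call(rbind, lapply(graphs, flat))
  rows <- list()
  for (r in seq_len(repeats)) {
    split <- stratified_split(labels, config$split_ratios, config$seed + r)
    set.seed(config$seed + r)
    fit <- nnet::nnet(x = X[split$train, , drop = FALSE],
                      y = labels[split$train], size = size, decay = decay,
                      maxit = maxit, entropy = TRUE, trace = FALSE,
                      MaxNWts = (ncol(X) + 2) * size + 10)
    p <- as.numeric(stats::predict(fit, X[split$test, , drop = FALSE]))
    rows[[r]] <- classification_metrics(p, labels[split$test])
  }
  summarise_repeats(rows)
}

#' Modality / layer-count / node-feature ablation harness
#'
#' Reruns the repeated-experiment protocol for each setting along the
#' requested axes: each single modality and the full set; 1-3 GIN layers;
#' eigen / degree / connection-profile node features. Optionally adds the
#' flattened-feature MLP baseline. Emits one row of mean +/- sd metrics per
#' configuration.
#'
#' @param cohort nested time-series list (see [load_cohort()]).
#' @param metadata subject metadata data.frame.
#' @param atlas `mgin_atlas`.
#' @param config base `mgin_config`.
#' @param axes subset of `c("modalities", "layers", "node_features")`.
#' @param repeats repeats per configuration.
#' @param include_mlp add the MLP baseline row.
#' @param layer_range layer counts tried on the `layers` axis.
#' @return list with `table` (data.frame: axis, setting, metric means/sds)
#'   and `reports` (named list of `mgin_metrics_report`).
#' @export
ablation_harness <- function(cohort, metadata, atlas, config,
                             axes = c("modalities", "layers", "node_features"),
                             repeats = 10, include_mlp = FALSE,
                             layer_range = 1:3) {
  axes <- match.arg(axes, several.ok = TRUE)
  graphs_profile <- build_cohort_graphs(cohort, metadata, atlas,
                                        modalities = config$modalities)
  reports <- list()
  rows <- list()
  add <- function(axis, setting, rep) {
    reports[[paste(axis, setting, sep = ":")]] <<- rep
    s <- rep$summary
    rows[[length(rows) + 1]] <<- data.frame(
      axis = axis, setting = setting,
      accuracy_mean = s$mean[s$metric == "accuracy"],
      accuracy_sd = s$sd[s$metric == "accuracy"],
      f1_mean = s$mean[s$metric == "f1"], f1_sd = s$sd[s$metric == "f1"],
      auc_mean = s$mean[s$metric == "auc"], auc_sd = s$sd[s$metric == "auc"])
  }
  if ("modalities" %in% axes) {
    settings <- c(as.list(config$modalities), list(config$modalities))
    for (mods in settings) {
      cfg <- config; cfg$modalities <- mods
      add("modalities", paste(mods, collapse = "+"),
          bootstrap_protocol(graphs_profile, cfg, repeats))
    }
  }
  if ("layers" %in% axes) {
    for (L in layer_range) {
      cfg <- config; cfg$layers <- L
      add("layers", as.character(L),
          bootstrap_protocol(graphs_profile, cfg, repeats))
    }
  }
  if ("node_features" %in% axes) {
    for (nf in c("eigen", "degree", "profile")) {
      g <- if (nf == "profile") graphs_profile else
        build_cohort_graphs(cohort, metadata, atlas,
                            modalities = config$modalities,
                            node_features = nf)
      add("node_features", nf, bootstrap_protocol(g, config, repeats))
    }
  }
  if (include_mlp)
    add("baseline", "mlp", mlp_baseline_protocol(graphs_profile, config,
                                                 repeats))
  list(table = do.call(rbind, rows), reports = reports)
}
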