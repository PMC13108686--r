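#' GNNExplainer optimisation settings
#'
#' Loss-term weights and optimiser settings for the mask optimisation:
#' prediction loss 1, feature-size loss 200, feature-element loss 20,
#' population-size loss 0, population-element loss 1000, weight decay 0,
#' 150 epochs at learning rate 0.5 (plain gradient descent — the large rate
#' is usable because the mask logits are the only free parameters).
#'
#' @param prediction,feature_size,feature_element,population_size,population_element
#'   non-negative loss weights.
#' @param weight_decay L2 penalty on mask logits.
#' @param epochs optimisation steps (0 returns the initial masks).
#' @param learning_rate gradient-descent step size.
#' @return `mgin_explainer_config`.
#' @export
explainer_config <- function(prediction = 1, feature_size = 200,
                             feature_element = 20, population_size = 0,
                             population_element = 1000, weight_decay = 0,
                             epochs = 150, learning_rate = 0.5) {
  w <- c(prediction, feature_size, feature_element, population_size,
         population_element, weight_decay)
  stopifnot(all(w >= 0), epochs >= 0, learning_rate > 0)
  structure(list(prediction = prediction, feature_size = feature_size,
                 feature_element = feature_element,
                 population_size = population_size,
                 population_element = population_element,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 learning_rate = learning_rate),
            class = "mgin_explainer_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Binary entropy of q in (0,1), elementwise, safe at the ends.
bin_entropy <- function(q) {
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  -q * log(q) - (1 - q) * log(1 - q)
}

# Apply per-modality edge (and optionally feature) masks to a graph.
mask_graph <- function(graph, masks, use_feature_mask = TRUE) {
  for (mod in names(masks)) {
    b <- graph$blocks[[mod]]
    b$adjacency <- b$adjacency * masks[[mod]]$edge_mask
    if (use_feature_mask && !is.null(masks[[mod]]$feature_mask))
      b$features <- sweep(b$features, 2, masks[[mod]]$feature_mask, "*")
    graph$blocks[[mod]] <- b
  }
  graph
}

#' Explain one subject's prediction with soft edge and feature masks
#'
#' Learns, per modality, a symmetric edge mask in [0,1] (sigmoid of
#' upper-triangle logits, zero diagonal) and a per-feature mask in [0,1],
#' by gradient descent on the weighted loss: cross-entropy of the model's
#' prediction on the masked graph against the model's own original
#' prediction, plus the feature-size (mean of the feature mask),
#' feature-element (mean binary entropy of the feature mask),
#' population-size (squared relative change in total retained edge mass) and
#' population-element (squared deviation of masked edge weights from the
#' originals, summed over edges) penalties. The prediction loss is evaluated
#' in two passes matching how each mask is interpreted: the edge mask is
#' applied with the original features and the feature mask with the original
#' edges. Logits start at 0, so the initial masks are 0.5 everywhere and the
#' optimisation is deterministic.
#'
#' @param model trained `mgin_model` (used frozen).
#' @param graph `mgin_graph` from the same atlas.
#' @param config `mgin_explainer_config`.
#' @return `mgin_explanation`: per modality a list with `edge_mask` (N x N,
#'   symmetric, zero diagonal), `feature_mask` (length d), plus the
#'   subject id, the model's original predicted class, and the loss trace.
#' @export
explain_subject <- function(model, graph, config = explainer_config()) {
  mods <- model$modalities
  N <- nrow(graph$blocks[[mods[1]]]$adjacency)
  ut <- upper.tri(matrix(0, N, N))
  p0 <- mgin_forward(graph, model)
  y0 <- as.integer(p0[2] > p0[1])
  # mask parameters: per modality, edge logits (upper triangle) and feature
  # logits; all start at 0 => masks at 0.5
  par <- list()
  for (m in mods)
    par[[m]] <- list(e = numeric(sum(ut)),
                     f = numeric(ncol(graph$blocks[[m]]$features)))
  masks_from_par <- function(par) {
    out <- list()
    for (m in mods) {
      E <- matrix(0, N, N)
      E[ut] <- sigmoid(par[[m]]$e)
      E <- E + t(E)
      out[[m]] <- list(edge_mask = E, feature_mask = sigmoid(par[[m]]$f))
    }
    out
  }
  trace <- numeric(0)
  for (step in seq_len(config$epochs)) {
    masks <- masks_from_par(par)
    # prediction loss in two passes, matching how each mask is read out:
    # the edge mask is judged with the original features, the feature mask
    # with the original edges
    gm_e <- mask_graph(graph, masks, use_feature_mask = FALSE)
    batch_e <- make_batch(list(gm_e), model)
    fwd_e <- forward_mgin(model, batch_e)
    bwd_e <- backward_mgin(model, batch_e, fwd_e, want_inputs = TRUE,
                           targets = y0)
    gm_f <- graph
    for (m in mods)
      gm_f$blocks[[m]]$features <-
        sweep(gm_f$blocks[[m]]$features, 2, masks[[m]]$feature_mask, "*")
    batch_f <- make_batch(list(gm_f), model)
    fwd_f <- forward_mgin(model, batch_f)
    bwd_f <- backward_mgin(model, batch_f, fwd_f, want_inputs = TRUE,
                           targets = y0)
    loss <- config$prediction * (cross_entropy(fwd_e$probs[, 2], y0) +
                                   cross_entropy(fwd_f$probs[, 2], y0))
    for (m in mods) {
      A <- graph$blocks[[m]]$adjacency
      H0 <- graph$blocks[[m]]$features
      Em <- masks[[m]]$edge_mask
      Fm <- masks[[m]]$feature_mask
      sigE <- Em[ut]
      sigF <- Fm
      dsigE <- sigE * (1 - sigE)
      dsigF <- sigF * (1 - sigF)
      # prediction-loss gradients through the masked inputs
      dA <- bwd_e$inputs[[m]]$dA * config$prediction
      dH0 <- bwd_f$inputs[[m]]$dH0 * config$prediction
      ge <- (dA[ut] + t(dA)[ut]) * A[ut] * dsigE
      gf <- colSums(dH0 * H0) * dsigF
      # regularisers
      loss <- loss + config$feature_size * mean(sigF) +
        config$feature_element * mean(bin_entropy(sigF))
      gf <- gf + config$feature_size * dsigF / length(sigF) +
        config$feature_element *
          (log((1 - pmin(pmax(sigF, 1e-12), 1 - 1e-12)) /
                 pmin(pmax(sigF, 1e-12), 1 - 1e-12))) * dsigF / length(sigF)
      # population-size: squared relative change in retained edge mass
      supp <- sum(A[ut] > 0)
      if (config$population_size > 0 && supp > 0) {
        rel <- (sum(sigE * (A[ut] > 0)) - supp) / supp
        loss <- loss + config$population_size * rel^2
        ge <- ge + config$population_size * 2 * rel / supp *
          (A[ut] > 0) * dsigE
      }
      # population-element: squared deviation of masked edge weights from
      # the originals, summed over edges (a mean-reduction would shrink the
      # per-edge gradient with N^2 and freeze the masks on realistic atlases)
      dev <- A[ut] * sigE - A[ut]
      loss <- loss + config$population_element * sum(dev^2)
      ge <- ge + config$population_element * (2 * dev * A[ut] * dsigE)
      if (config$weight_decay > 0) {
        loss <- loss + config$weight_decay / 2 *
          (sum(par[[m]]$e^2) + sum(par[[m]]$f^2))
        ge <- ge + config$weight_decay * par[[m]]$e
        gf <- gf + config$weight_decay * par[[m]]$f
      }
      par[[m]]$e <- par[[m]]$e - config$learning_rate * ge
      par[[m]]$f <- par[[m]]$f - config$learning_rate * gf
    }
    if (!is.finite(loss))
      stop("non-finite explainer loss; config: lr=", config$learning_rate,
           " epochs=", config$epochs)
    trace[step] <- loss
  }
  masks <- masks_from_par(par)
  structure(list(masks = masks, subject_id = graph$subject_id,
                 original_class = y0, loss_trace = trace),
            class = "mgin_explanation")
}

#' Explain a list of subjects
#'
#' @param model trained `mgin_model`.
#' @param graphs list of `mgin_graph`.
#' @param config `mgin_explainer_config`.
#' @return list of `mgin_explanation`.
#' @export
explain_cohort <- function(model, graphs, config = explainer_config()) {
  lapply(graphs, function(g) explain_subject(model, g, config))
}

#' Fraction of subjects whose predicted class survives edge masking
#'
#' @param model `mgin_model`.
#' @param graphs list of graphs.
#' @param explanations matching list from [explain_cohort()].
#' @return Proportion in [0,1] of subjects for which the model predicts the
#'   same class on the edge-masked graph as on the original.
#' @export
explainer_fidelity <- function(model, graphs, explanations) {
  same <- vapply(seq_along(graphs), function(i) {
    gm <- mask_graph(graphs[[i]], explanations[[i]]$masks,
                     use_feature_mask = FALSE)
    p <- mgin_forward(gm, model)
    as.integer(p[2] > p[1]) == explanations[[i]]$original_class
  }, logical(1))
  mean(same)
}

#' Group-level mean edge mask
#'
#' Entrywise mean of the per-subject edge masks within a stratum defined by
#' sex, stage and modality (any of which may be NULL to pool over it).
#'
#' @param explanations list of `mgin_explanation`.
#' @param info data.frame aligned with `explanations`, columns `sex` and
#'   `stage`.
#' @param modality paradigm whose masks to average.
#' @param sex,stage optional stratum filters.
#' @return N x N mean mask.
#' @export
group_mask <- function(explanations, info, modality, sex = NULL,
                       stage = NULL) {
  keep <- rep(TRUE, length(explanations))
  if (!is.null(sex)) keep <- keep & info$sex == sex
  if (!is.null(stage)) keep <- keep & info$stage == stage
  if (!any(keep))
    stop("empty group: sex=", if (is.null(sex)) "any" else sex,
         " stage=", if (is.null(stage)) "any" else stage,
         " modality=", modality)
  ms <- lapply(explanations[keep], function(e) e$masks[[modality]]$edge_mask)
  Reduce(`+`, ms) / length(ms)
}

#' Top-percent edges of a mean mask
#'
#' Ranks unique pairs (i < j) by mask weight descending (ties broken by
#' (i, j) lexicographic order) and keeps `floor(pct/100 * N(N-1)/2)` of them.
#'
#' @param mean_mask symmetric N x N mask.
#' @param pct percentage in (0, 100].
#' @return `mgin_edge_set`: data.frame with 1-based `i`, `j` (i < j) and
#'   `weight`.
#' @export
top_percent_edges <- function(mean_mask, pct = 5) {
  if (pct <= 0 || pct > 100) stop("config error: pct must be in (0, 100]")
  N <- nrow(mean_mask)
  ut <- which(upper.tri(mean_mask), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2], weight = mean_mask[ut])
  m <- floor(pct / 100 * N * (N - 1) / 2)
  df <- df[order(-df$weight, df$i, df$j), , drop = FALSE]
  out <- df[seq_len(m), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mgin_edge_set", "data.frame"), n_roi = N)
}

#' Intersection of edge sets
#'
#' Edges present in every set; weights are the mean of the contributing
#' weights.
#'
#' @param edge_sets list of >= 2 `mgin_edge_set` on the same atlas.
#' @return `mgin_edge_set` of the common edges.
#' @export
common_connections <- function(edge_sets) {
  stopifnot(length(edge_sets) >= 2)
  Ns <- vapply(edge_sets, function(e) attr(e, "n_roi") %||% NA_integer_,
               numeric(1))
  if (length(unique(Ns[!is.na(Ns)])) > 1)
    stop("structural error: edge sets come from different atlases")
  keys <- lapply(edge_sets, function(e) paste(e$i, e$j))
  common <- Reduce(intersect, keys)
  first <- edge_sets[[1]]
  out <- first[match(common, keys[[1]]), c("i", "j"), drop = FALSE]
  w <- rowMeans(do.call(cbind, lapply(seq_along(edge_sets), function(s)
    edge_sets[[s]]$weight[match(common, keys[[s]])])))
  out$weight <- if (length(common)) w else numeric(0)
  rownames(out) <- NULL
  structure(out, class = c("mgin_edge_set", "data.frame"),
            n_roi = Ns[!is.na(Ns)][1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intra-/inter-network connection counts
#'
#' Symmetric contingency table over functional-network labels: the diagonal
#' counts intra-network edges, off-diagonal cells inter-network edges; the
#' table total equals the edge count.
#'
#' @param edges `mgin_edge_set`.
#' @param atlas `mgin_atlas` supplying the network label per ROI.
#' @return Symmetric integer matrix with network-label dimnames.
#' @export
network_counts <- function(edges, atlas) {
  nets <- sort(unique(as.data.frame(atlas)$network))
  M <- matrix(0L, length(nets), length(nets), dimnames = list(nets, nets))
  lab <- as.data.frame(atlas)$network
  for (r in seq_len(nrow(edges))) {
    a <- lab[edges$i[r]]; b <- lab[edges$j[r]]
    lo <- min(a, b); hi <- max(a, b)
    M[lo, hi] <- M[lo, hi] + 1L
  }
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

#' ROI table for an edge set
#'
#' Ranks ROIs by the summed mask weight of their incident edges and reports
#' id, anatomical label, MNI coordinates and functional network.
#'
#' @param edges `mgin_edge_set`.
#' @param atlas `mgin_atlas`.
#' @param top_n rows to keep (default all involved ROIs).
#' @return data.frame with `roi_id`, `anatomical_name`, `x`, `y`, `z`,
#'   `network`, `incident_weight`.
#' @export
report_rois <- function(edges, atlas, top_n = Inf) {
  w <- numeric(n_roi(atlas))
  for (r in seq_len(nrow(edges))) {
    w[edges$i[r]] <- w[edges$i[r]] + edges$weight[r]
    w[edges$j[r]] <- w[edges$j[r]] + edges$weight[r]
  }
  ids <- which(w > 0)
  ids <- ids[order(-w[ids], ids)]
  if (is.finite(top_n)) ids <- utils::head(ids, top_n)
  ad <- as.data.frame(atlas)
  data.frame(roi_id = ids, anatomical_name = ad$anatomical_name[ids],
             x = ad$x[ids], y = ad$y[ids], z = ad$z[ids],
             network = ad$network[ids], incident_weight = w[ids],
             row.names = NULL)
}

#' Write an edge set as CSV with network annotations
#'
#' Columns: `roi_i, roi_j, network_i, network_j, mask_weight`.
#'
#' @param edges `mgin_edge_set`.
#' @param atlas `mgin_atlas`.
#' @param path output CSV.
#' @export
write_edge_set <- function(edges, atlas, path) {
  lab <- as.data.frame(atlas)$network
  df <- data.frame(roi_i = edges$i, roi_j = edges$j,
                   network_i = lab[edges$i], network_j = lab[edges$j],
                   mask_weight = edges$weight)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
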