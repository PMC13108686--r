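#' Single GIN layer forward pass
#'
#' Implements the graph-isomorphism-network update
#' `h_v <- MLP((1 + eps) * h_v + sum_{u in N(v)} w_uv * h_u)`:
#' the self term is scaled by (1 + eps) and neighbour features are summed,
#' weighted by the (possibly binary) adjacency. The MLP is affine -> ReLU ->
#' affine; passing `params` without `W1` applies the identity instead (useful
#' for analysing the bare aggregation).
#'
#' @param H N x d node feature matrix.
#' @param A symmetric N x N adjacency with zero diagonal (weights allowed).
#' @param params list with `eps` and optionally `W1`, `b1`, `W2`, `b2`.
#' @return N x d' matrix of updated node features.
#' @export
gin_layer_forward <- function(H, A, params) {
  H <- as.matrix(H); A <- as.matrix(A)
  if (ncol(A) != nrow(H))
    stop("structural error: adjacency size does not match feature rows")
  S <- (1 + params$eps) * H + A %*% H
  if (is.null(params$W1)) return(S)
  if (nrow(params$W1) != ncol(H))
    stop("structural error: MLP input width does not match feature width")
  U <- add_bias(S %*% params$W1, params$b1)
  R <- relu(U)
  add_bias(R %*% params$W2, params$b2)
}

#' Sum-readout over GIN layers
#'
#' Each layer's node features (including the layer-0 input, by default) are
#' summed over nodes and the per-layer sums concatenated into the graph
#' embedding.
#'
#' @param layer_outputs list of N x d_k matrices, k = 0..K.
#' @return Numeric vector: concatenated per-layer node sums.
#' @export
graph_readout <- function(layer_outputs) {
  if (!length(layer_outputs)) stop("structural error: empty layer list")
  unlist(lapply(layer_outputs, function(H) colSums(as.matrix(H))),
         use.names = FALSE)
}

#' Binary cross-entropy loss
#'
#' `L = -(1/n) sum(t log p + (1 - t) log(1 - p))` with p clamped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param p predicted probability of class 1 per subject.
#' @param t labels in {0, 1}.
#' @return Scalar loss.
#' @export
cross_entropy <- function(p, t) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  t <- as.numeric(t)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

# ---------------------------------------------------------------------------
# Multi-modal GIN model: initialisation, batched forward/backward, Adam.
# Parameters are a flat named list of numeric arrays; gradients mirror it.
# ---------------------------------------------------------------------------

# Row-broadcast bias add / ReLU without sweep()'s aperm overhead.
add_bias <- function(M, b) M + rep(b, each = nrow(M))
relu <- function(M) { M[M < 0] <- 0; M }

runif_mat <- function(nr, nc, fan_in) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise a multi-modal GIN classifier
#'
#' One stack of `layers` GIN layers per modality (each layer's MLP is
#' affine -> ReLU -> affine with hidden width = output width = `hidden_dim`),
#' sum readout concatenated over layers (optionally including the raw input
#' features), modality embeddings concatenated, then ReLU -> affine -> softmax
#' over two classes. Parameter init is scaled-uniform fan-in; epsilons start
#' at 0 and are learnable.
#'
#' @param modalities character vector of paradigm tags.
#' @param d_in named integer vector or single integer: input feature width
#'   per modality.
#' @param layers number of GIN layers K (default 2).
#' @param hidden_dim MLP hidden/output width (default 100).
#' @param readout_include_input include the layer-0 term in the readout.
#' @param weighted_aggregation use |r| edge weights in the neighbour sum
#'   (FALSE binarises the adjacency).
#' @param use_edge_attr multiply the adjacency elementwise by the cosine
#'   edge-attribute channel before aggregation.
#' @param seed RNG seed for initialisation.
#' @return `mgin_model` object.
#' @export
init_mgin <- function(modalities, d_in, layers = 2, hidden_dim = 100,
                      readout_include_input = TRUE,
                      weighted_aggregation = TRUE,
                      use_edge_attr = FALSE, seed = 1) {
  set.seed(seed)
  if (length(d_in) == 1 && is.null(names(d_in)))
    d_in <- stats::setNames(rep(d_in, length(modalities)), modalities)
  params <- list()
  widths <- 0
  for (m in modalities) {
    d_prev <- d_in[[m]]
    for (k in seq_len(layers)) {
      pre <- sprintf("%s.L%d.", m, k)
      params[[paste0(pre, "eps")]] <- 0
      params[[paste0(pre, "W1")]] <- runif_mat(d_prev, hidden_dim, d_prev)
      params[[paste0(pre, "b1")]] <- numeric(hidden_dim)
      params[[paste0(pre, "W2")]] <- runif_mat(hidden_dim, hidden_dim, hidden_dim)
      params[[paste0(pre, "b2")]] <- numeric(hidden_dim)
      d_prev <- hidden_dim
    }
    widths <- widths + layers * hidden_dim +
      if (readout_include_input) d_in[[m]] else 0
  }
  params[["fusion.W"]] <- runif_mat(widths, 2, widths)
  params[["fusion.b"]] <- numeric(2)
  structure(list(modalities = modalities, d_in = d_in, layers = layers,
                 hidden_dim = hidden_dim,
                 readout_include_input = readout_include_input,
                 weighted_aggregation = weighted_aggregation,
                 use_edge_attr = use_edge_attr,
                 params = params, seed = seed),
            class = "mgin_model")
}

#' @export
print.mgin_model <- function(x, ...) {
  cat(sprintf("mgin_model: %d GIN layer(s) x modalities [%s], hidden %d\n",
              x$layers, paste(x$modalities, collapse = ", "), x$hidden_dim))
  invisible(x)
}

# Stack a list of mgin_graph into one batched structure: per modality a
# block-diagonal sparse adjacency over subjects and row-stacked features.
make_batch <- function(graphs, model) {
  n <- length(graphs)
  N <- nrow(graphs[[1]]$blocks[[1]]$adjacency)
  per_mod <- list()
  for (m in model$modalities) {
    As <- vector("list", n)
    Hs <- vector("list", n)
    for (i in seq_len(n)) {
      b <- graphs[[i]]$blocks[[m]]
      if (is.null(b)) stop("structural error: graph ", i, " lacks modality ", m)
      A <- b$adjacency
      if (model$use_edge_attr && !is.null(b$edge_attr)) A <- A * b$edge_attr
      if (!model$weighted_aggregation) A <- (A > 0) * 1
      As[[i]] <- A
      Hs[[i]] <- b$features
    }
    Ab <- methods::as(Matrix::bdiag(As), "generalMatrix")
    per_mod[[m]] <- list(A = Ab, H0 = do.call(rbind, Hs))
  }
  labels <- vapply(graphs, function(g) g$label, integer(1))
  list(mods = per_mod, subj = rep(seq_len(n), each = N),
       labels = labels, n = n, N = N)
}

# Batched forward pass. Returns probabilities plus every intermediate needed
# for backpropagation.
forward_mgin <- function(model, batch) {
  p <- model$params
  caches <- list()
  embeds <- list()
  for (m in model$modalities) {
    A <- batch$mods[[m]]$A
    H <- batch$mods[[m]]$H0
    layers <- list()
    pools <- list()
    if (model$readout_include_input)
      pools[[length(pools) + 1]] <- rowsum(H, batch$subj, reorder = TRUE)
    for (k in seq_len(model$layers)) {
      pre <- sprintf("%s.L%d.", m, k)
      S <- (1 + p[[paste0(pre, "eps")]]) * H + as.matrix(A %*% H)
      U <- add_bias(S %*% p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
      R <- relu(U)
      Hn <- add_bias(R %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
      layers[[k]] <- list(Hprev = H, S = S, U = U, R = R)
      H <- Hn
      pools[[length(pools) + 1]] <- rowsum(H, batch$subj, reorder = TRUE)
    }
    caches[[m]] <- layers
    embeds[[m]] <- do.call(cbind, pools)
  }
  E <- do.call(cbind, embeds)            # n x total readout width
  F1 <- relu(E)
  logits <- add_bias(F1 %*% p[["fusion.W"]], p[["fusion.b"]])
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, logits = logits, E = E, F1 = F1, caches = caches,
       embeds = embeds)
}

# Backward pass of mean cross-entropy (+ optional L2 on weight matrices).
# Returns gradients for every parameter; if want_inputs, also gradients of
# the loss w.r.t. each modality's input features and (dense) adjacency —
# used by the explainer.
backward_mgin <- function(model, batch, fwd, weight_decay = 0,
                          want_inputs = FALSE, targets = NULL) {
  p <- model$params
  n <- batch$n
  t <- if (is.null(targets)) batch$labels else targets
  Tm <- cbind(1 - t, t)
  G <- list()
  dlogits <- (fwd$probs - Tm) / n
  G[["fusion.W"]] <- crossprod(fwd$F1, dlogits)
  G[["fusion.b"]] <- colSums(dlogits)
  dF1 <- tcrossprod(dlogits, p[["fusion.W"]])
  dE <- dF1 * (fwd$E > 0)
  d_inputs <- list()
  off <- 0
  for (m in model$modalities) {
    w_m <- ncol(fwd$embeds[[m]])
    dEm <- dE[, off + seq_len(w_m), drop = FALSE]
    off <- off + w_m
    # split modality embedding gradient back into per-layer pooled chunks
    chunk_dims <- c(if (model$readout_include_input) model$d_in[[m]],
                    rep(model$hidden_dim, model$layers))
    chunks <- list()
    coff <- 0
    for (d in chunk_dims) {
      chunks[[length(chunks) + 1]] <- dEm[, coff + seq_len(d), drop = FALSE]
      coff <- coff + d
    }
    A <- batch$mods[[m]]$A
    dA <- if (want_inputs) matrix(0, nrow(A), ncol(A))
    # gradient flowing into H_k from the pooled readout: broadcast rows
    k0 <- if (model$readout_include_input) 1 else 0
    dH <- chunks[[model$layers + k0]][batch$subj, , drop = FALSE]
    for (k in rev(seq_len(model$layers))) {
      pre <- sprintf("%s.L%d.", m, k)
      cc <- fwd$caches[[m]][[k]]
      G[[paste0(pre, "W2")]] <- crossprod(cc$R, dH)
      G[[paste0(pre, "b2")]] <- colSums(dH)
      dR <- tcrossprod(dH, p[[paste0(pre, "W2")]])
      dU <- dR * (cc$U > 0)
      G[[paste0(pre, "W1")]] <- crossprod(cc$S, dU)
      G[[paste0(pre, "b1")]] <- colSums(dU)
      dS <- tcrossprod(dU, p[[paste0(pre, "W1")]])
      G[[paste0(pre, "eps")]] <- sum(dS * cc$Hprev)
      if (want_inputs) dA <- dA + tcrossprod(dS, cc$Hprev) * 1
      dH <- (1 + p[[paste0(pre, "eps")]]) * dS +
        as.matrix(Matrix::crossprod(A, dS))
      if (k > 1) {
        dH <- dH + chunks[[k - 1 + k0]][batch$subj, , drop = FALSE]
      } else if (model$readout_include_input) {
        dH <- dH + chunks[[1]][batch$subj, , drop = FALSE]
      }
    }
    if (want_inputs) {
      # dA above only accounts for A %*% H terms: dL/dA = sum_k dS_k Hprev_k'
      # (computed incrementally); mask to the block-diagonal support is the
      # caller's concern (explainer uses single-subject batches).
      d_inputs[[m]] <- list(dH0 = dH, dA = dA)
    }
  }
  if (weight_decay > 0) {
    for (nm in names(G)) {
      if (grepl("\\.W[12]$", nm) || nm == "fusion.W")
        G[[nm]] <- G[[nm]] + weight_decay * p[[nm]]
    }
  }
  list(grads = G, inputs = d_inputs)
}

# Total loss matching backward_mgin: mean CE + (wd/2) * sum of squared
# weight-matrix entries.
mgin_loss <- function(model, batch, fwd = NULL, weight_decay = 0,
                      targets = NULL) {
  if (is.null(fwd)) fwd <- forward_mgin(model, batch)
  t <- if (is.null(targets)) batch$labels else targets
  l <- cross_entropy(fwd$probs[, 2], t)
  if (weight_decay > 0) {
    wsum <- 0
    for (nm in names(model$params))
      if (grepl("\\.W[12]$", nm) || nm == "fusion.W")
        wsum <- wsum + sum(model$params[[nm]]^2)
    l <- l + weight_decay / 2 * wsum
  }
  l
}

#' Class probabilities of a multi-modal GIN for one brain graph
#'
#' @param graph `mgin_graph`.
#' @param model `mgin_model` whose modalities match the graph's blocks.
#' @return Length-2 numeric vector (P(class 0), P(class 1)), summing to 1.
#' @export
mgin_forward <- function(graph, model) {
  missing_mods <- setdiff(model$modalities, names(graph$blocks))
  if (length(missing_mods))
    stop("structural error: graph lacks modality ",
         paste(missing_mods, collapse = ", "))
  batch <- make_batch(list(graph), model)
  as.numeric(forward_mgin(model, batch)$probs[1, ])
}

#' Predicted class-1 probabilities for a list of graphs
#'
#' @param model `mgin_model`.
#' @param graphs list of `mgin_graph`.
#' @return Numeric vector of P(class 1).
#' @export
predict_proba <- function(model, graphs) {
  batch <- make_batch(graphs, model)
  forward_mgin(model, batch)$probs[, 2]
}

#' Per-modality graph embedding (readout vector)
#'
#' Runs the GIN stack of a single modality and returns the concatenated
#' per-layer sum readout. Useful for expressiveness analyses.
#'
#' @param model `mgin_model`.
#' @param graph `mgin_graph`.
#' @param modality which block to embed (default first).
#' @return Numeric embedding vector.
#' @export
mgin_embed <- function(model, graph, modality = model$modalities[1]) {
  batch <- make_batch(list(graph), model)
  fwd <- forward_mgin(model, batch)
  as.numeric(fwd$embeds[[modality]][1, ])
}

# ---------------------------------------------------------------------------
# Adam optimiser on the flat parameter list.
# ---------------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# Weisfeiler-Lehman colour refinement.
# ---------------------------------------------------------------------------

#' Weisfeiler-Lehman label refinement
#'
#' Iteratively replaces every node label by an injective hash of the pair
#' (own label, sorted multiset of neighbour labels). The hash is a
#' canonical-string -> fresh-integer dictionary; passing the same `dict`
#' environment for two graphs makes their label ids directly comparable.
#'
#' @param A adjacency matrix (treated as unweighted: nonzero = edge).
#' @param init integer initial labels (default all 1).
#' @param iterations number of refinement rounds.
#' @param dict environment used as the shared hash dictionary.
#' @return List with `labels` (list of per-iteration integer label vectors,
#'   element 1 = initial) and `histograms` (per-iteration sorted label-count
#'   tables).
#' @export
wl_refine <- function(A, init = NULL, iterations = 3, dict = new.env()) {
  A <- as.matrix(A) != 0
  N <- nrow(A)
  lab <- if (is.null(init)) rep(1L, N) else as.integer(init)
  if (is.null(dict$counter)) dict$counter <- 0L
  hash <- function(key) {
    if (is.null(dict[[key]])) {
      dict$counter <- dict$counter + 1L
      assign(key, dict$counter, envir = dict)
    }
    dict[[key]]
  }
  labels <- list(lab)
  hists <- list(sort(table(lab)))
  for (it in seq_len(iterations)) {
    new_lab <- integer(N)
    for (v in seq_len(N)) {
      nb <- sort(lab[A[v, ]])
      key <- paste0("k", it, ":", lab[v], "|", paste(nb, collapse = ","))
      new_lab[v] <- hash(key)
    }
    lab <- new_lab
    labels[[it + 1]] <- lab
    hists[[it + 1]] <- sort(table(lab))
  }
  structure(list(labels = labels, histograms = hists), class = "mgin_wl")
}

#' Are two graphs distinguished by 1-WL refinement?
#'
#' Runs [wl_refine()] on both graphs with a shared hash dictionary and
#' compares the per-iteration label-count histograms.
#'
#' @param A1,A2 adjacency matrices.
#' @param iterations refinement rounds.
#' @return TRUE if the histograms differ at any iteration (including the
#'   trivial node-count difference at iteration 0).
#' @export
wl_distinguished <- function(A1, A2, iterations = 3) {
  dict <- new.env()
  r1 <- wl_refine(A1, iterations = iterations, dict = dict)
  r2 <- wl_refine(A2, iterations = iterations, dict = dict)
  for (k in seq_len(iterations + 1)) {
    h1 <- r1$histograms[[k]]
    h2 <- r2$histograms[[k]]
    if (length(h1) != length(h2)) return(TRUE)
    if (!identical(sort(names(h1)), sort(names(h2)))) return(TRUE)
    if (!identical(as.integer(h1[sort(names(h1))]),
                   as.integer(h2[sort(names(h2))]))) return(TRUE)
  }
  FALSE
}
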