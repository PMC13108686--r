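#' Pearson functional connectivity of an ROI time series
#'
#' Computes the N x N matrix of Pearson correlation coefficients
#' r = cov(X,Y) / (sigma_X * sigma_Y) between all ROI pairs. The diagonal is
#' exactly 1 and the matrix symmetric.
#'
#' @param ts `mgin_timeseries` (T x N, T >= 3, positive column variances).
#' @return `mgin_connectome`: N x N correlation matrix with `subject_id` and
#'   `modality` attributes.
#' @export
pearson_connectivity <- function(ts) {
  if (!inherits(ts, "mgin_timeseries")) {
    ts <- as.matrix(ts)
    if (nrow(ts) < 3) stop("data error: need at least 3 timepoints")
    v <- apply(ts, 2, stats::var)
    if (any(v <= 0))
      stop("data error: zero-variance time series for roi_id ",
           paste(which(v <= 0), collapse = ", "))
  }
  m <- stats::cor(unclass(ts))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  structure(m, subject_id = attr(ts, "subject_id"),
            modality = attr(ts, "modality"),
            class = c("mgin_connectome", "matrix", "array"))
}

#' Absolute-value connectome for adjacency use
#'
#' Takes entrywise absolute values of a correlation matrix and zeroes the
#' diagonal: edge weights are |r| and self-loops are excluded (the GIN layer
#' carries the self term through its (1+eps) factor, so a non-zero diagonal
#' would double-count it).
#'
#' @param fc `mgin_connectome` or symmetric matrix.
#' @return Matrix of |r| with zero diagonal.
#' @export
absolute_connectome <- function(fc) {
  m <- abs(unclass(fc))
  diag(m) <- 0
  structure(m, subject_id = attr(fc, "subject_id"),
            modality = attr(fc, "modality"))
}

#' Connection-profile node features
#'
#' Node v's feature vector is its row of the absolute connectome: the vector
#' of connection strengths from v to every ROI. This keeps the complete
#' pairwise-connectivity information at each node (an N x N feature matrix).
#'
#' @param fc_abs absolute connectome from [absolute_connectome()].
#' @return N x N feature matrix (row v = features of node v).
#' @export
connection_profile_features <- function(fc_abs) {
  m <- as.matrix(unclass(fc_abs))
  dimnames(m) <- NULL
  m
}

#' Alternative node features: weighted degree or eigenvector loadings
#'
#' `degree` returns the weighted degree (row sums of the adjacency) as an
#' N x 1 matrix. `eigen` returns the loadings of the top-k eigenvectors of
#' the adjacency, each sign-fixed so its largest-magnitude entry is positive.
#'
#' @param fc_abs absolute connectome (symmetric, non-negative).
#' @param kind `"degree"` or `"eigen"`.
#' @param k number of eigenvectors for `kind = "eigen"`.
#' @return N x 1 or N x k numeric matrix.
#' @export
alt_node_features <- function(fc_abs, kind = c("degree", "eigen"), k = 8) {
  kind <- match.arg(kind)
  A <- as.matrix(unclass(fc_abs))
  if (kind == "degree") return(matrix(rowSums(A), ncol = 1))
  k <- min(k, ncol(A))
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Cosine similarity between node feature vectors
#'
#' S[i,j] = x_i . x_j / (||x_i|| ||x_j||) over the rows of a feature matrix.
#' Zero-norm rows get similarity 0 (with a warning); the diagonal of any
#' non-degenerate row is 1.
#'
#' @param features N x d matrix, one row per node.
#' @return Symmetric N x N matrix with entries in [-1, 1].
#' @export
cosine_edge_attributes <- function(features) {
  X <- as.matrix(features)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("zero-norm feature row(s): ", paste(which(zero), collapse = ", "),
            "; cosine similarity set to 0")
    nrm[zero] <- 1
  }
  S <- tcrossprod(X / nrm)
  S[zero, ] <- 0
  S[, zero] <- 0
  S <- (S + t(S)) / 2
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S)[!zero] <- 1
  S
}

#' Spatial edge attributes from MNI centroid distances
#'
#' Alternative edge-attribute channel: similarity exp(-dist/tau) of the
#' Euclidean distance between ROI centroids, in millimetres.
#'
#' @param atlas `mgin_atlas`.
#' @param tau length scale in mm (default 50).
#' @return Symmetric N x N similarity matrix in (0, 1].
#' @export
spatial_edge_attributes <- function(atlas, tau = 50) {
  xyz <- as.matrix(as.data.frame(atlas)[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  exp(-d / tau)
}

#' Top-k-per-node sparsification of a weighted adjacency
#'
#' Keeps, for every node, its k strongest incident edges, then symmetrises by
#' union (an edge survives if either endpoint retains it).
#'
#' @param A symmetric non-negative adjacency with zero diagonal.
#' @param k edges kept per node; `k >= N-1` returns `A` unchanged.
#' @return Sparsified adjacency of the same shape.
#' @export
sparsify_topk <- function(A, k) {
  A <- as.matrix(A)
  N <- nrow(A)
  if (k >= N - 1) return(A)
  keep <- matrix(FALSE, N, N)
  for (v in seq_len(N)) {
    ord <- order(A[v, ], decreasing = TRUE)
    keep[v, ord[seq_len(k)]] <- TRUE
  }
  keep <- keep | t(keep)
  out <- A * keep
  diag(out) <- 0
  out
}

#' Assemble a multi-modal brain graph for one subject
#'
#' @param blocks named list (one entry per modality) of lists with elements
#'   `adjacency` (N x N, non-negative, zero diagonal), `features` (N x d)
#'   and `edge_attr` (N x N in [-1,1]).
#' @param subject_id,label,stage subject identifier, binary class label and
#'   stage label.
#' @return `mgin_graph` object.
#' @export
build_brain_graph <- function(blocks, subject_id, label, stage = NA_character_) {
  if (!length(blocks) || is.null(names(blocks)))
    stop("structural error: blocks must be a named per-modality list")
  Ns <- vapply(blocks, function(b) nrow(b$adjacency), integer(1))
  if (length(unique(Ns)) != 1)
    stop("structural error: modality blocks disagree on N (",
         paste(Ns, collapse = ", "), ")")
  for (mod in names(blocks)) {
    b <- blocks[[mod]]
    if (nrow(b$features) != Ns[[1]])
      stop("structural error: feature rows != N in modality ", mod)
    if (max(abs(b$adjacency - t(b$adjacency))) > 1e-8)
      stop("structural error: adjacency not symmetric in modality ", mod)
    if (any(diag(b$adjacency) != 0))
      stop("structural error: adjacency diagonal must be zero in modality ", mod)
  }
  structure(list(subject_id = as.character(subject_id),
                 label = as.integer(label),
                 stage = as.character(stage),
                 blocks = blocks),
            class = "mgin_graph")
}

#' @export
print.mgin_graph <- function(x, ...) {
  N <- nrow(x$blocks[[1]]$adjacency)
  cat(sprintf("mgin_graph subject=%s label=%d stage=%s | %d ROIs, modalities: %s\n",
              x$subject_id, x$label, x$stage, N,
              paste(names(x$blocks), collapse = ", ")))
  invisible(x)
}

#' Build the full graph cohort from time series
#'
#' Runs the construction chain per subject and modality: Pearson correlation,
#' absolute value with zero diagonal (adjacency), connection-profile (or
#' degree/eigen) node features, cosine (or spatial) edge attributes, and
#' optional top-k sparsification. Box-Cox normalisation of node features is
#' deliberately NOT done here: it must be fitted on a training split only
#' (see [fit_boxcox()] / [apply_boxcox_cohort()]).
#'
#' @param cohort nested list from [load_cohort()] or [generate_cohort()].
#' @param metadata data.frame with subject_id, sex, age.
#' @param atlas `mgin_atlas`.
#' @param modalities paradigms to include.
#' @param node_features `"profile"`, `"degree"` or `"eigen"`.
#' @param edge_attr `"cosine"` or `"spatial"`.
#' @param sparsify_k optional integer; if given, top-k sparsification.
#' @param eigen_k eigenvector count when `node_features = "eigen"`.
#' @param tau length scale for spatial edge attributes.
#' @return list of `mgin_graph`, one per subject, in metadata order.
#' @export
build_cohort_graphs <- function(cohort, metadata, atlas,
                                modalities = c("emoid", "nback"),
                                node_features = c("profile", "degree", "eigen"),
                                edge_attr = c("cosine", "spatial"),
                                sparsify_k = NULL, eigen_k = 8, tau = 50) {
  node_features <- match.arg(node_features)
  edge_attr <- match.arg(edge_attr)
  spatial <- if (edge_attr == "spatial") spatial_edge_attributes(atlas, tau)
  stage <- if (all(metadata$age >= 8 & metadata$age <= 22))
    assign_stage(metadata$age) else rep(NA_character_, nrow(metadata))
  graphs <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$subject_id[i]
    blocks <- list()
    for (mod in modalities) {
      ts <- cohort[[sid]][[mod]]
      if (is.null(ts)) stop("structural error: subject ", sid,
                            " lacks modality ", mod)
      Aabs <- absolute_connectome(pearson_connectivity(ts))
      feats <- switch(node_features,
                      profile = connection_profile_features(Aabs),
                      degree = alt_node_features(Aabs, "degree"),
                      eigen = alt_node_features(Aabs, "eigen", eigen_k))
      ea <- if (edge_attr == "cosine") cosine_edge_attributes(
              connection_profile_features(Aabs)) else spatial
      A <- if (is.null(sparsify_k)) Aabs else sparsify_topk(Aabs, sparsify_k)
      blocks[[mod]] <- list(adjacency = as.matrix(A),
                            features = as.matrix(feats),
                            edge_attr = ea)
    }
    graphs[[i]] <- build_brain_graph(blocks, sid, metadata$sex[i], stage[i])
  }
  graphs
}
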