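# Shared helpers: small deterministic graphs and cohorts built in code.

tiny_atlas <- function(n = 3, networks = c("A", "A", "B")) {
  validate_atlas(data.frame(roi_id = seq_len(n), x = seq_len(n), y = 0, z = 0,
                            network = rep_len(networks, n)))
}

rand_sym_adj <- function(N, seed = 1, weighted = TRUE) {
  set.seed(seed)
  A <- matrix(runif(N * N), N, N)
  A <- (A + t(A)) / 2
  if (!weighted) A <- (A > 0.5) * 1
  diag(A) <- 0
  A
}

# A small labelled multi-modal graph with random weights and features.
tiny_graph <- function(N = 5, d = 4, label = 1L, seed = 1,
                       modalities = c("emoid", "nback")) {
  set.seed(seed)
  blocks <- list()
  for (m in modalities) {
    A <- rand_sym_adj(N, seed = seed + match(m, modalities))
    blocks[[m]] <- list(adjacency = A,
                        features = matrix(rnorm(N * d), N, d),
                        edge_attr = matrix(1, N, N))
  }
  build_brain_graph(blocks, paste0("s", seed), label)
}

# Tiny synthetic cohort for fast end-to-end protocol tests.
tiny_cohort_graphs <- function(n_per_group = 8, n_rois = 10, timepoints = 60,
                               delta = 0.5, seed = 1) {
  spec <- effect_spec(n_per_group = n_per_group, n_rois = n_rois,
                      timepoints = timepoints, base_correlation = 0.1,
                      blocks = if (delta != 0)
                        list(list(rois = 1:4,
                                  modalities = c("emoid", "nback"),
                                  delta = delta)) else list(),
                      ar_coefficient = 0, seed = seed)
  sim <- generate_cohort(spec)
  list(graphs = build_cohort_graphs(sim$cohort, sim$metadata, sim$atlas),
       sim = sim)
}

# Graph with uniform unit features on one modality, for expressiveness tests.
wl_graph <- function(A) {
  N <- nrow(A)
  build_brain_graph(list(emoid = list(adjacency = A,
                                      features = matrix(1, N, 1),
                                      edge_attr = matrix(1, N, N))),
                    "wl", 0L)
}

cycle_adj <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    A[i, j] <- A[j, i] <- 1
  }
  A
}

path_adj <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

# Independent colour-refinement oracle: represents every node colour by its
# full recursive signature string, so no hash dictionary is involved at all.
wl_oracle_distinguished <- function(A1, A2, iterations = 3) {
  refine <- function(A) {
    A <- A != 0
    lab <- rep("x", nrow(A))
    out <- list(sort(table(lab)))
    for (k in seq_len(iterations)) {
      lab <- vapply(seq_len(nrow(A)), function(v)
        paste0("(", lab[v], "|",
               paste(sort(lab[A[v, ]]), collapse = ","), ")"), character(1))
      out[[k + 1]] <- sort(table(lab))
    }
    out
  }
  h1 <- refine(A1); h2 <- refine(A2)
  for (k in seq_along(h1)) {
    a <- h1[[k]]; b <- h2[[k]]
    if (length(a) != length(b) ||
        !identical(sort(names(a)), sort(names(b))) ||
        !identical(as.integer(a[sort(names(a))]),
                   as.integer(b[sort(names(b))]))) return(TRUE)
  }
  FALSE
}

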