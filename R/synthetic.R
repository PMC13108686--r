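#' Specification of a synthetic multi-paradigm cohort
#'
#' Describes a two-group cohort of multi-paradigm ROI time series whose
#' inter-ROI correlation differs between groups inside designated ROI blocks.
#' Group 0 has correlation `base_correlation` between every ROI pair; group 1
#' additionally gets `delta` added to the correlation of every pair inside
#' each block, in that block's modalities. Block pairs are the ground-truth
#' discriminative edges.
#'
#' @param n_per_group subjects per group.
#' @param n_rois ROIs N.
#' @param modalities paradigm tags.
#' @param timepoints scan length T.
#' @param base_correlation background inter-ROI correlation in [0, 0.9].
#' @param blocks list of blocks, each `list(rois = <indices>, modalities =
#'   <tags>, delta = <shift>)`; an empty list plants no effect (null cohort).
#' @param ar_coefficient AR(1) temporal autocorrelation in [0, 0.95).
#' @param noise_sd marginal standard deviation of each ROI signal.
#' @param stage_distribution named probabilities over the five adolescence
#'   stages (defaults to the 129/113/109/130/141 proportions of a 622-subject
#'   developmental cohort).
#' @param seed cohort seed; generation is a pure function of the spec.
#' @return `mgin_effect_spec` list.
#' @export
effect_spec <- function(n_per_group = 100, n_rois = 40,
                        modalities = c("emoid", "nback"), timepoints = 300,
                        base_correlation = 0.1, blocks = list(),
                        ar_coefficient = 0.3, noise_sd = 1,
                        stage_distribution = c(Pre = 129, Early = 113,
                                               Middle = 109, Late = 130,
                                               Post = 141) / 622,
                        seed = 1) {
  stopifnot(n_per_group >= 1, n_rois >= 2, timepoints >= 3,
            base_correlation >= 0, base_correlation <= 0.9,
            ar_coefficient >= 0, ar_coefficient < 1, noise_sd > 0)
  for (b in blocks) {
    stopifnot(all(b$rois >= 1), all(b$rois <= n_rois), length(b$rois) >= 2,
              all(b$modalities %in% modalities))
    if (b$delta == 0) stop("spec error: declared blocks must have delta != 0")
    if (base_correlation + b$delta <= -1 || base_correlation + b$delta >= 1)
      stop("spec error: base_correlation + delta must lie in (-1, 1)")
  }
  stopifnot(abs(sum(stage_distribution) - 1) < 1e-8)
  structure(list(n_per_group = n_per_group, n_rois = n_rois,
                 modalities = modalities, timepoints = timepoints,
                 base_correlation = base_correlation, blocks = blocks,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 stage_distribution = stage_distribution, seed = seed),
            class = "mgin_effect_spec")
}

#' Target covariance of one group in one modality
#'
#' Builds the target correlation matrix (background `base_correlation`
#' everywhere, plus each block's `delta` on within-block pairs for group 1
#' in the block's modalities), then repairs it to positive definiteness by
#' clipping eigenvalues at 1e-6. The repair must not move any entry by more
#' than 0.05, otherwise the spec is rejected as irreparably non-PD.
#'
#' @param spec `mgin_effect_spec`.
#' @param group 0 or 1.
#' @param modality paradigm tag.
#' @return N x N positive-definite covariance (unit-ish diagonal times
#'   `noise_sd^2`) with attribute `repair_magnitude`.
#' @export
build_group_covariance <- function(spec, group, modality) {
  N <- spec$n_rois
  C <- matrix(spec$base_correlation, N, N)
  diag(C) <- 1
  if (group == 1) {
    for (b in spec$blocks) {
      if (!modality %in% b$modalities) next
      idx <- b$rois
      C[idx, idx] <- C[idx, idx] + b$delta
    }
    diag(C) <- 1
  }
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-6) {
    vals <- pmax(eg$values, 1e-6)
    C2 <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(C2))
    C2 <- C2 / outer(d, d)
    repair <- max(abs(C2 - C))
    if (repair > 0.05)
      stop(sprintf("spec error: PD repair changes an entry by %.3f > 0.05",
                   repair))
    C <- C2
  } else repair <- 0
  out <- C * spec$noise_sd^2
  attr(out, "repair_magnitude") <- repair
  out
}

#' Sample an AR(1) Gaussian time series with a given stationary covariance
#'
#' `x_t = ar * x_{t-1} + e_t` with innovation covariance `(1 - ar^2) * cov`,
#' so the cross-sectional stationary covariance equals `cov` exactly; the
#' initial row is drawn from the stationary distribution.
#'
#' @param cov positive-definite N x N covariance.
#' @param timepoints T >= 3.
#' @param ar_coefficient phi in [0, 1).
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @return T x N numeric matrix.
#' @export
sample_timeseries <- function(cov, timepoints, ar_coefficient = 0, seed = 1) {
  if (ar_coefficient >= 1) stop("nonstationary error: ar coefficient must be < 1")
  N <- nrow(cov)
  set.seed(seed)
  L <- chol(cov)
  Z <- matrix(stats::rnorm(timepoints * N), timepoints, N) %*% L
  if (ar_coefficient == 0) return(Z)
  X <- matrix(0, timepoints, N)
  X[1, ] <- Z[1, ]
  s <- sqrt(1 - ar_coefficient^2)
  for (t in 2:timepoints)
    X[t, ] <- ar_coefficient * X[t - 1, ] + s * Z[t, ]
  X
}

#' Synthetic atlas with functional-network labels
#'
#' ROIs are assigned to ten Power-style functional networks in proportion
#' and given synthetic coordinates (cluster centroids per network plus
#' deterministic jitter). Intended to make network-level aggregation
#' meaningful on simulated cohorts; not a brain template.
#'
#' @param n_rois number of ROIs.
#' @param seed jitter seed.
#' @return `mgin_atlas`.
#' @export
synthetic_atlas <- function(n_rois, seed = 1) {
  nets <- c("DMN", "VIS", "SM Hand", "FRNT", "SAL", "CNG", "SUB",
            "SM Mouth", "CB", "UNK")
  props <- c(58, 31, 30, 25, 18, 14, 13, 5, 4, 66) / 264
  counts <- floor(props * n_rois)
  while (sum(counts) < n_rois) {
    i <- which.max(props * n_rois - counts)
    counts[i] <- counts[i] + 1
  }
  network <- rep(nets, counts)[seq_len(n_rois)]
  set.seed(seed)
  centroids <- matrix(stats::runif(length(nets) * 3, -60, 60), ncol = 3,
                      dimnames = list(nets, c("x", "y", "z")))
  jitter <- matrix(stats::rnorm(n_rois * 3, sd = 12), ncol = 3)
  xyz <- centroids[network, , drop = FALSE] + jitter
  validate_atlas(data.frame(roi_id = seq_len(n_rois),
                            x = round(xyz[, 1], 1), y = round(xyz[, 2], 1),
                            z = round(xyz[, 3], 1), network = network,
                            anatomical_name = paste0("synthetic region ",
                                                     seq_len(n_rois))))
}

#' Generate a full synthetic cohort
#'
#' Produces, per subject and modality, one ROI time series drawn from the
#' group's target covariance; balanced group labels; ages sampled from the
#' stage distribution (uniform within each stage interval) and staged with
#' [assign_stage()]; plus the ground-truth discriminative edge sets (all
#' within-block pairs, per modality).
#'
#' @param spec `mgin_effect_spec`.
#' @return list with `cohort` (nested subject -> modality time-series list),
#'   `metadata` (subject_id, sex = group label, age), `atlas`,
#'   `ground_truth` (per-modality data.frames of i < j block pairs), and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  n <- 2 * spec$n_per_group
  ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c(0L, 1L), each = spec$n_per_group)
  set.seed(spec$seed)
  stages <- sample(names(spec$stage_distribution), n, replace = TRUE,
                   prob = spec$stage_distribution)
  bounds <- list(Pre = c(8, 12), Early = c(12, 14), Middle = c(14, 16),
                 Late = c(16, 18), Post = c(18, 22))
  age <- vapply(stages, function(s)
    stats::runif(1, bounds[[s]][1], bounds[[s]][2] - 1e-3), numeric(1))
  metadata <- data.frame(subject_id = ids, sex = group,
                         age = round(unname(age), 2))
  covs <- list()
  for (g in 0:1)
    for (mod in spec$modalities)
      covs[[paste(g, mod)]] <- build_group_covariance(spec, g, mod)
  cohort <- list()
  atlas <- synthetic_atlas(spec$n_rois, seed = spec$seed)
  for (i in seq_len(n)) {
    cohort[[ids[i]]] <- list()
    for (mi in seq_along(spec$modalities)) {
      mod <- spec$modalities[mi]
      sseed <- spec$seed * 100000L + i * 10L + mi
      ts <- sample_timeseries(covs[[paste(group[i], mod)]], spec$timepoints,
                              spec$ar_coefficient, seed = sseed)
      cohort[[ids[i]]][[mod]] <- validate_timeseries(ts, atlas, ids[i], mod)
    }
  }
  gt <- list()
  for (mod in spec$modalities) {
    pairs <- NULL
    for (b in spec$blocks) {
      if (!mod %in% b$modalities) next
      cmb <- t(utils::combn(sort(b$rois), 2))
      pairs <- rbind(pairs, data.frame(i = cmb[, 1], j = cmb[, 2]))
    }
    gt[[mod]] <- if (is.null(pairs))
      data.frame(i = integer(0), j = integer(0)) else unique(pairs)
  }
  list(cohort = cohort, metadata = metadata, atlas = atlas,
       ground_truth = gt, spec = spec)
}

#' Named preset simulation scenarios
#'
#' \describe{
#'   \item{shared_signal}{one 8-ROI block (ROIs 1-8) with delta 0.3 in both
#'     paradigms — a strong effect visible to either modality.}
#'   \item{complementary}{two disjoint 8-ROI blocks, one per paradigm
#'     (ROIs 1-8 in emoid, 9-16 in nback), delta 0.15 each — fusing the
#'     modalities should beat either alone.}
#'   \item{weak}{the shared block at delta 0.15.}
#'   \item{null}{no planted effect; classification should sit at chance.}
#' }
#' All presets use N = 40 ROIs, T = 300 timepoints, 100 subjects per group,
#' background correlation 0.1 and AR(1) coefficient 0.3.
#'
#' @param seed cohort seed applied to every preset.
#' @return named list of `mgin_effect_spec`.
#' @export
preset_scenarios <- function(seed = 1) {
  base <- function(blocks) effect_spec(blocks = blocks, seed = seed)
  list(
    shared_signal = base(list(list(rois = 1:8,
                                   modalities = c("emoid", "nback"),
                                   delta = 0.3))),
    complementary = base(list(list(rois = 1:8, modalities = "emoid",
                                   delta = 0.15),
                              list(rois = 9:16, modalities = "nback",
                                   delta = 0.15))),
    weak = base(list(list(rois = 1:8, modalities = c("emoid", "nback"),
                          delta = 0.15))),
    null = base(list())
  )
}
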