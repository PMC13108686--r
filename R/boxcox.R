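#' Fit per-feature Box-Cox parameters on training data
#'
#' For each feature column, a shift `max(0, eps - min(x))` makes the training
#' values strictly positive, then the Box-Cox exponent lambda is estimated by
#' maximising the profile log-likelihood
#' `-(n/2) log(var(y_lambda)) + (lambda - 1) sum(log(x))` over
#' `lambda in [-2, 2]`. Constant columns get `lambda = 1` (identity up to a
#' shift) with a warning.
#'
#' @param train_features numeric matrix, rows = training observations,
#'   columns = features.
#' @param eps positivity margin for the shift (default 1e-6).
#' @param lambda_range search interval for lambda.
#' @return `mgin_boxcox`: list with numeric vectors `lambda` and `shift`
#'   (one entry per column) and `eps`.
#' @export
fit_boxcox <- function(train_features, eps = 1e-6, lambda_range = c(-2, 2)) {
  X <- as.matrix(train_features)
  p <- ncol(X)
  lambda <- numeric(p)
  shift <- numeric(p)
  const <- logical(p)
  for (j in seq_len(p)) {
    x <- X[, j]
    shift[j] <- max(0, eps - min(x))
    y <- x + shift[j]
    if (stats::var(y) <= .Machine$double.eps * max(1, mean(y)^2)) {
      lambda[j] <- 1
      const[j] <- TRUE
      next
    }
    lambda[j] <- stats::optimize(boxcox_loglik, interval = lambda_range,
                                 x = y, maximum = TRUE)$maximum
  }
  if (any(const))
    warning("constant feature column(s) ", paste(which(const), collapse = ", "),
            ": lambda fixed at 1")
  structure(list(lambda = lambda, shift = shift, eps = eps),
            class = "mgin_boxcox")
}

#' Box-Cox profile log-likelihood
#'
#' @param lambda exponent.
#' @param x strictly positive sample.
#' @return Profile log-likelihood value (up to an additive constant).
#' @export
boxcox_loglik <- function(lambda, x) {
  n <- length(x)
  y <- boxcox_transform(x, lambda)
  v <- stats::var(y) * (n - 1) / n
  -n / 2 * log(v) + (lambda - 1) * sum(log(x))
}

# Scalar-lambda Box-Cox on a positive vector.
boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Apply fitted Box-Cox parameters to a feature matrix
#'
#' y = ((x + shift)^lambda - 1)/lambda, or log(x + shift) at lambda = 0.
#' Values that are non-positive after the training shift (test values below
#' the training minimum) are clamped to `eps` with a warning.
#'
#' @param features numeric matrix with the same column count used in
#'   [fit_boxcox()].
#' @param params `mgin_boxcox`.
#' @return Transformed matrix of the same shape.
#' @export
apply_boxcox <- function(features, params) {
  X <- as.matrix(features)
  if (ncol(X) != length(params$lambda))
    stop("structural error: feature count does not match Box-Cox parameters")
  out <- X
  clamped <- FALSE
  for (j in seq_len(ncol(X))) {
    y <- X[, j] + params$shift[j]
    if (any(y <= 0)) {
      clamped <- TRUE
      y[y <= 0] <- params$eps
    }
    out[, j] <- boxcox_transform(y, params$lambda[j])
  }
  if (clamped)
    warning("values below the training minimum were clamped to eps before Box-Cox")
  out
}

#' Fit Box-Cox on training subjects and transform a whole graph cohort
#'
#' Parameters are fitted per modality and per feature column on the node
#' features of the training subjects only (all nodes of all training graphs
#' stacked row-wise), then applied to every graph. The split between fitting
#' and applying is the leakage boundary: validation/test subjects never
#' influence the fitted parameters.
#'
#' @param graphs list of `mgin_graph`.
#' @param train_idx integer indices of training graphs.
#' @return list with `graphs` (transformed) and `params` (per-modality
#'   `mgin_boxcox`).
#' @export
apply_boxcox_cohort <- function(graphs, train_idx) {
  mods <- names(graphs[[1]]$blocks)
  params <- list()
  for (mod in mods) {
    stacked <- do.call(rbind, lapply(graphs[train_idx],
                                     function(g) g$blocks[[mod]]$features))
    params[[mod]] <- fit_boxcox(stacked)
  }
  out <- lapply(graphs, function(g) {
    for (mod in mods)
      g$blocks[[mod]]$features <- apply_boxcox(g$blocks[[mod]]$features,
                                               params[[mod]])
    g
  })
  list(graphs = out, params = params)
}
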