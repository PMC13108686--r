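#' Training configuration
#'
#' Defaults mirror the published protocol for the real 264-ROI cohort:
#' Adam, learning rate 1e-5, 3000 epochs, weight decay 0.2, two GIN layers
#' with hidden width 100, an 80/10/10 train/validation/test split, and the
#' emoid + nback paradigms. For the bundled desk-scale synthetic scenarios
#' use [synthetic_train_config()], which is tuned to converge in seconds.
#'
#' @param learning_rate Adam step size.
#' @param epochs training epochs (full-batch).
#' @param weight_decay L2 penalty coefficient on MLP/fusion weight matrices.
#' @param modalities paradigms consumed by the model.
#' @param layers GIN layers per modality.
#' @param hidden_dim MLP hidden/output width.
#' @param split_ratios train/val/test proportions (must sum to 1).
#' @param seed base RNG seed for init and splitting.
#' @param eval_every epochs between validation-loss evaluations.
#' @param early_stop_loss stop when the training loss falls below this
#'   tolerance (the model has effectively converged); 0 disables.
#' @param readout_include_input,weighted_aggregation,use_edge_attr model
#'   structure flags, see [init_mgin()].
#' @param optimizer only `"adam"` is implemented.
#' @return list of class `mgin_config`.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 3000,
                         weight_decay = 0.2,
                         modalities = c("emoid", "nback"),
                         layers = 2, hidden_dim = 100,
                         split_ratios = c(0.8, 0.1, 0.1), seed = 1,
                         eval_every = 10, early_stop_loss = 1e-3,
                         readout_include_input = TRUE,
                         weighted_aggregation = TRUE, use_edge_attr = FALSE,
                         optimizer = "adam") {
  stopifnot(abs(sum(split_ratios) - 1) < 1e-8, all(split_ratios > 0),
            epochs >= 1, optimizer == "adam")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 weight_decay = weight_decay, modalities = modalities,
                 layers = as.integer(layers), hidden_dim = as.integer(hidden_dim),
                 split_ratios = split_ratios, seed = as.integer(seed),
                 eval_every = as.integer(eval_every),
                 early_stop_loss = early_stop_loss,
                 readout_include_input = readout_include_input,
                 weighted_aggregation = weighted_aggregation,
                 use_edge_attr = use_edge_attr, optimizer = optimizer),
            class = "mgin_config")
}

#' Desk-scale training configuration for the synthetic scenarios
#'
#' The bundled synthetic cohorts (40 ROIs, 200 subjects) carry much stronger
#' and cleaner effects than real fMRI data, so far fewer epochs and a larger
#' learning rate suffice: 150 epochs at 1e-3 with hidden width 32 and a mild
#' 1e-4 weight decay. These values are used by every simulation experiment in
#' the package; the methods vignette discusses how they were chosen.
#'
#' @param ... overrides forwarded to [train_config()].
#' @export
synthetic_train_config <- function(...) {
  args <- list(...)
  defaults <- list(learning_rate = 1e-3, epochs = 150, weight_decay = 1e-4,
                   hidden_dim = 32)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(train_config, args)
}

#' Stratified train/validation/test split
#'
#' Sizes follow the floor rule: `val = floor(r_val * n)`,
#' `test = floor(r_test * n)`, train takes the remainder. Within the
#' validation and test sets, class proportions are preserved by
#' largest-remainder allocation per class. If a class cannot appear in a
#' split (too few subjects), a stratification warning is emitted and the
#' split is completed at the stated sizes regardless.
#'
#' @param labels binary vector (the stratification variable, here sex).
#' @param ratios length-3 positive proportions summing to 1.
#' @param seed RNG seed; identical seeds give identical splits.
#' @return list of integer index vectors `train`, `val`, `test` — disjoint
#'   and covering `seq_along(labels)`.
#' @export
stratified_split <- function(labels, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  n <- length(labels)
  if (n < 10) stop("need at least 10 subjects to split")
  if (length(unique(labels)) < 2)
    stop("stratification error: both classes must be present")
  stopifnot(abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  set.seed(seed)
  classes <- sort(unique(labels))
  by_class <- lapply(classes, function(cl) sample(which(labels == cl)))
  alloc <- function(total) {
    cnt <- vapply(by_class, length, integer(1))
    exact <- total * cnt / sum(cnt)
    base <- floor(exact)
    rem <- total - sum(base)
    if (rem > 0) {
      ord <- order(exact - base, decreasing = TRUE)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    base
  }
  take_from <- function(quota) {
    out <- integer(0)
    for (i in seq_along(by_class)) {
      take <- min(quota[i], length(by_class[[i]]))
      if (take > 0) {
        out <- c(out, by_class[[i]][seq_len(take)])
        by_class[[i]] <<- by_class[[i]][-seq_len(take)]
      }
    }
    out
  }
  val <- take_from(alloc(n_val))
  test <- take_from(alloc(n_test))
  # top up if a stratum ran dry (degenerate tiny cohorts)
  pool <- unlist(by_class)
  while (length(val) < n_val) { val <- c(val, pool[1]); pool <- pool[-1] }
  while (length(test) < n_test) { test <- c(test, pool[1]); pool <- pool[-1] }
  train <- sort(pool)
  val <- sort(val); test <- sort(test)
  for (part in list(val = val, test = test)) {
    if (length(unique(labels[part])) < 2)
      warning("stratification note: a split contains a single class; ",
              "sizes kept per the floor rule")
  }
  list(train = train, val = val, test = test)
}

#' Train a multi-modal GIN classifier
#'
#' Full-batch Adam minimisation of the mean binary cross-entropy plus L2
#' weight decay on the MLP and fusion weight matrices. If validation graphs
#' are supplied, the checkpoint with the lowest validation loss (evaluated
#' every `config$eval_every` epochs) is retained alongside the final-epoch
#' weights.
#'
#' @param graphs list of `mgin_graph` (the training split, features already
#'   Box-Cox-transformed).
#' @param config `mgin_config`.
#' @param val_graphs optional validation graphs for checkpoint selection.
#' @return list with `model` (best-validation, or final if no validation),
#'   `final_model`, and `trace` (data.frame of epoch, train_loss, val_loss).
#' @export
train_model <- function(graphs, config, val_graphs = NULL) {
  if (!length(graphs)) stop("training split is empty")
  d_in <- vapply(config$modalities, function(m)
    ncol(graphs[[1]]$blocks[[m]]$features), integer(1))
  model <- init_mgin(config$modalities, d_in, layers = config$layers,
                     hidden_dim = config$hidden_dim,
                     readout_include_input = config$readout_include_input,
                     weighted_aggregation = config$weighted_aggregation,
                     use_edge_attr = config$use_edge_attr,
                     seed = config$seed)
  batch <- make_batch(graphs, model)
  val_batch <- if (!is.null(val_graphs) && length(val_graphs))
    make_batch(val_graphs, model)
  state <- adam_init(model$params)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  best <- list(loss = Inf, params = model$params)
  for (ep in seq_len(config$epochs)) {
    fwd <- forward_mgin(model, batch)
    loss <- mgin_loss(model, batch, fwd, config$weight_decay)
    if (!is.finite(loss))
      stop(sprintf("non-finite training loss at epoch %d (lr=%g)",
                   ep, config$learning_rate))
    bwd <- backward_mgin(model, batch, fwd, config$weight_decay)
    upd <- adam_step(model$params, bwd$grads, state, config$learning_rate)
    model$params <- upd$params
    state <- upd$state
    stop_now <- config$early_stop_loss > 0 && loss < config$early_stop_loss
    if (ep %% config$eval_every == 0 || ep == config$epochs || stop_now) {
      vl <- NA_real_
      if (!is.null(val_batch)) {
        vl <- mgin_loss(model, val_batch)
        if (vl < best$loss) best <- list(loss = vl, params = model$params)
      }
      trace <- rbind(trace, data.frame(epoch = ep, train_loss = loss,
                                       val_loss = vl))
    }
    if (stop_now) break
  }
  final_model <- model
  if (!is.null(val_batch) && is.finite(best$loss)) model$params <- best$params
  list(model = model, final_model = final_model, trace = trace)
}

#' Classification metrics: accuracy, F1 and AUC
#'
#' Accuracy thresholds the class-1 probability at 0.5 (ties go to class 0).
#' F1 is reported for class 1. AUC is the Mann-Whitney probability that a
#' class-1 subject scores above a class-0 subject, ties counted 1/2; it is
#' `NA` when only one class is present.
#'
#' @param p class-1 probabilities.
#' @param labels true labels in {0,1}.
#' @return list with `accuracy`, `f1`, `auc`.
#' @export
classification_metrics <- function(p, labels) {
  labels <- as.integer(labels)
  pred <- as.integer(p > 0.5)
  acc <- mean(pred == labels)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(p)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(accuracy = acc, f1 = f1, auc = auc)
}

#' Evaluate a trained model on labelled graphs
#'
#' @param model `mgin_model`.
#' @param graphs list of labelled `mgin_graph`.
#' @return list with `accuracy`, `f1`, `auc` (see
#'   [classification_metrics()]).
#' @export
evaluate <- function(model, graphs) {
  p <- predict_proba(model, graphs)
  labels <- vapply(graphs, function(g) g$label, integer(1))
  classification_metrics(p, labels)
}

#' One split-train-test experiment with a leakage audit
#'
#' Splits the cohort (stratified by label), fits Box-Cox normalisation on
#' the training subjects only, trains with validation-based checkpoint
#' selection, and evaluates on the held-out test set. The returned `audit`
#' records exactly which subject indices were visible to preprocessing
#' (Box-Cox fit) and to checkpoint selection, so tests can assert that test
#' indices were never touched before final evaluation.
#'
#' @param graphs raw (untransformed) `mgin_graph` cohort.
#' @param config `mgin_config`.
#' @param seed split/init seed for this experiment.
#' @return list with `metrics`, `split`, `model`, `trace`, `audit`.
#' @export
run_experiment <- function(graphs, config, seed = config$seed) {
  labels <- vapply(graphs, function(g) g$label, integer(1))
  split <- stratified_split(labels, config$split_ratios, seed)
  bc <- apply_boxcox_cohort(graphs, split$train)
  g2 <- bc$graphs
  cfg <- config
  cfg$seed <- seed
  fit <- train_model(g2[split$train], cfg, g2[split$val])
  metrics <- evaluate(fit$model, g2[split$test])
  audit <- list(boxcox_fit_idx = split$train,
                checkpoint_selection_idx = split$val,
                test_idx_first_use = "final evaluation")
  list(metrics = metrics, split = split, model = fit$model,
       trace = fit$trace, audit = audit, boxcox = bc$params)
}

summarise_repeats <- function(rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  summary <- data.frame(
    metric = c("accuracy", "f1", "auc"),
    mean = c(mean(df$accuracy), mean(df$f1), mean(df$auc, na.rm = TRUE)),
    sd = c(stats::sd(df$accuracy), stats::sd(df$f1),
           stats::sd(df$auc[!is.na(df$auc)])))
  structure(list(per_repeat = df, summary = summary,
                 repeats = nrow(df)), class = "mgin_metrics_report")
}

#' @export
print.mgin_metrics_report <- function(x, ...) {
  cat(sprintf("metrics over %d repeats (mean +/- sd, ddof = 1):\n", x$repeats))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-8s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Repeated re-split experiments
#'
#' Runs `repeats` independent experiments; each one re-splits the cohort
#' (seed + repeat index), re-fits preprocessing, re-trains and re-tests.
#' This is the repeated-experiment robustness protocol; a true
#' resampling-with-replacement bootstrap of the training set is available
#' with `mode = "resample"`.
#'
#' @param graphs raw graph cohort.
#' @param config `mgin_config`.
#' @param repeats number of repeats (>= 2).
#' @param mode `"resplit"` (default) or `"resample"`.
#' @return `mgin_metrics_report`: per-repeat metrics plus mean and sample
#'   (ddof = 1) standard deviation.
#' @export
bootstrap_protocol <- function(graphs, config, repeats = 10,
                               mode = c("resplit", "resample")) {
  mode <- match.arg(mode)
  stopifnot(repeats >= 2)
  rows <- list()
  failures <- 0
  for (r in seq_len(repeats)) {
    res <- tryCatch({
      if (mode == "resample") {
        labels <- vapply(graphs, function(g) g$label, integer(1))
        split <- stratified_split(labels, config$split_ratios,
                                  config$seed + r)
        set.seed(config$seed + 10000 + r)
        split$train <- sort(sample(split$train, length(split$train),
                                   replace = TRUE))
        bc <- apply_boxcox_cohort(graphs, unique(split$train))
        cfg <- config; cfg$seed <- config$seed + r
        fit <- train_model(bc$graphs[split$train], cfg, bc$graphs[split$val])
        evaluate(fit$model, bc$graphs[split$test])
      } else {
        run_experiment(graphs, config, config$seed + r)$metrics
      }
    }, error = function(e) e)
    if (inherits(res, "error")) failures <- failures + 1 else
      rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("all repeats failed")
  rep_out <- summarise_repeats(rows)
  rep_out$failures <- failures
  rep_out
}

#' Stratified k-fold cross-validation
#'
#' Each fold serves once as the test set; the model is trained on the
#' remaining folds (Box-Cox fitted on them alone) and evaluated on the fold.
#' Final-epoch weights are used (no inner validation split).
#'
#' @param graphs raw graph cohort.
#' @param config `mgin_config`.
#' @param k folds (default 10); `k = n` gives leave-one-out.
#' @return `mgin_metrics_report` over folds, with `fold_assignment`.
#' @export
kfold_protocol <- function(graphs, config, k = 10) {
  labels <- vapply(graphs, function(g) g$label, integer(1))
  n <- length(labels)
  stopifnot(n >= k, k >= 2)
  set.seed(config$seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  rows <- list()
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    if (length(unique(labels[test_idx])) < 2 && length(test_idx) > 1)
      warning("stratification note: fold ", f, " contains a single class")
    bc <- apply_boxcox_cohort(graphs, train_idx)
    cfg <- config; cfg$seed <- config$seed + f
    fit <- train_model(bc$graphs[train_idx], cfg)
    rows[[f]] <- evaluate(fit$model, bc$graphs[test_idx])
  }
  out <- summarise_repeats(rows)
  out$fold_assignment <- fold
  out
}

#' Paired two-sided t-test on per-repeat metrics
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on differences `d = a - b`, df = n - 1,
#' two-sided p from the Student t distribution. Zero-variance differences
#' are flagged as degenerate rather than given a fabricated p-value.
#'
#' @param a,b equal-length metric vectors (length >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) NaN else sign(md) * Inf, df = n - 1,
                p = if (md == 0) NA_real_ else 0, mean_diff = md,
                degenerate = TRUE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * stats::pt(-abs(tstat), n - 1),
       mean_diff = mean(d), degenerate = FALSE)
}
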