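test_that("zero-epoch explanation returns the sigmoid(0) initial masks", {
  g <- tiny_graph(N = 5, d = 5, seed = 2)
  model <- init_mgin(c("emoid", "nback"), 5, layers = 1, hidden_dim = 6,
                     seed = 3)
  cfg <- explainer_config(feature_size = 0, feature_element = 0,
                          population_element = 0, epochs = 0)
  ex <- explain_subject(model, g, cfg)
  em <- ex$masks$emoid$edge_mask
  expect_equal(em[upper.tri(em)], rep(0.5, 10))
  expect_equal(diag(em), rep(0, 5))
  expect_equal(ex$masks$nback$feature_mask, rep(0.5, 5))
})

test_that("masks stay in range and symmetric after optimisation", {
  g <- tiny_graph(N = 6, d = 6, seed = 4)
  model <- init_mgin(c("emoid", "nback"), 6, layers = 2, hidden_dim = 8,
                     seed = 5)
  ex <- explain_subject(model, g, explainer_config(epochs = 25))
  for (m in c("emoid", "nback")) {
    em <- ex$masks[[m]]$edge_mask
    expect_true(all(em >= 0 & em <= 1))
    expect_equal(em, t(em))
    expect_equal(diag(em), rep(0, 6))
    fm <- ex$masks[[m]]$feature_mask
    expect_true(all(fm >= 0 & fm <= 1))
  }
  expect_true(all(is.finite(ex$loss_trace)))
})

test_that("a stronger feature-size penalty shrinks the feature mask", {
  g <- tiny_graph(N = 6, d = 6, seed = 6)
  model <- init_mgin(c("emoid", "nback"), 6, layers = 1, hidden_dim = 6,
                     seed = 7)
  ex1 <- explain_subject(model, g, explainer_config(feature_size = 20,
                                                    epochs = 40))
  ex2 <- explain_subject(model, g, explainer_config(feature_size = 200,
                                                    epochs = 40))
  expect_lte(mean(ex2$masks$emoid$feature_mask),
             mean(ex1$masks$emoid$feature_mask))
})

test_that("a planted single strong edge is ranked first by the edge mask", {
  # cohort of tiny single-modality graphs whose label is carried entirely by
  # the weight of edge (1,2)
  set.seed(8)
  N <- 6
  graphs <- lapply(1:30, function(i) {
    A <- rand_sym_adj(N, seed = 700 + i) * 0.2
    lab <- as.integer(i %% 2 == 0)
    A[1, 2] <- A[2, 1] <- if (lab == 1) 0.95 else 0.05
    build_brain_graph(list(emoid = list(adjacency = A,
                                        features = connection_profile_features(A),
                                        edge_attr = matrix(1, N, N))),
                      paste0("t", i), lab)
  })
  cfg <- synthetic_train_config(seed = 9, epochs = 250, modalities = "emoid",
                                hidden_dim = 16, split_ratios = c(.6, .2, .2),
                                early_stop_loss = 0)
  labels <- vapply(graphs, function(g) g$label, integer(1))
  sp <- stratified_split(labels, cfg$split_ratios, 1)
  fit <- train_model(graphs[sp$train], cfg, graphs[sp$val])
  expect_gt(evaluate(fit$model, graphs)$accuracy, 0.9)
  # explain class-1 subjects; their mean mask must rank (1,2) first
  pos <- which(labels == 1)[1:5]
  ex <- explain_cohort(fit$model, graphs[pos])
  info <- data.frame(sex = 1, stage = NA)
  mm <- group_mask(ex, data.frame(sex = rep(1, 5), stage = NA), "emoid")
  top <- top_percent_edges(mm, pct = 100)
  expect_equal(c(top$i[1], top$j[1]), c(1, 2))
})

test_that("group masks average per stratum and reject empty groups", {
  mk <- function(v) structure(list(masks = list(emoid = list(
    edge_mask = matrix(v, 3, 3) - diag(3) * v, feature_mask = rep(v, 3))),
    subject_id = "s", original_class = 1L), class = "mgin_explanation")
  ex <- list(mk(0), mk(1))
  info <- data.frame(sex = c(1, 1), stage = c("Pre", "Pre"))
  mm <- group_mask(ex, info, "emoid", sex = 1, stage = "Pre")
  expect_equal(mm[1, 2], 0.5)
  expect_equal(group_mask(ex[1], info[1, ], "emoid")[1, 2], 0)
  expect_error(group_mask(ex, info, "emoid", sex = 0), "empty group")
})

test_that("top-percent edge extraction follows the floor-and-ties rule", {
  # a 264-ROI mask keeps floor(0.05 * 264*263/2) = 1735 edges
  set.seed(10)
  M <- matrix(runif(264^2), 264, 264)
  M <- (M + t(M)) / 2; diag(M) <- 0
  top <- top_percent_edges(M, 5)
  expect_equal(nrow(top), 1735)
  expect_true(all(top$i < top$j))
  # pct = 100 keeps all pairs
  expect_equal(nrow(top_percent_edges(M, 100)), 264 * 263 / 2)
  # exactly-3-nonzero mask with matching m returns those three pairs
  S <- matrix(0, 10, 10)
  S[1, 2] <- S[2, 1] <- 0.9
  S[3, 4] <- S[4, 3] <- 0.8
  S[5, 6] <- S[6, 5] <- 0.7
  m3 <- top_percent_edges(S, 100 * 3 / 45)
  expect_equal(nrow(m3), 3)
  expect_setequal(paste(m3$i, m3$j), c("1 2", "3 4", "5 6"))
  # ties break lexicographically by (i, j)
  Tie <- matrix(1, 4, 4); diag(Tie) <- 0
  t2 <- top_percent_edges(Tie, 100 * 2 / 6)
  expect_equal(paste(t2$i, t2$j), c("1 2", "1 3"))
  expect_error(top_percent_edges(S, 0), "config error")
})

test_that("common connections intersect edge sets with mean weights", {
  mk <- function(df) structure(df, class = c("mgin_edge_set", "data.frame"),
                               n_roi = 10L)
  a <- mk(data.frame(i = c(1, 2), j = c(2, 3), weight = c(0.9, 0.6)))
  b <- mk(data.frame(i = c(2, 3), j = c(3, 4), weight = c(0.8, 0.5)))
  cc <- common_connections(list(a, b))
  expect_equal(nrow(cc), 1)
  expect_equal(c(cc$i, cc$j), c(2, 3))
  expect_equal(cc$weight, 0.7)
  # disjoint -> empty; identical -> unchanged
  d <- mk(data.frame(i = 5, j = 6, weight = 1))
  expect_equal(nrow(common_connections(list(a, d))), 0)
  expect_equal(common_connections(list(a, a))$weight, a$weight)
})

test_that("network counts conserve the edge total", {
  atlas <- tiny_atlas(3, networks = c("A", "A", "B"))
  ed <- structure(data.frame(i = c(1, 1), j = c(2, 3), weight = c(1, 1)),
                  class = c("mgin_edge_set", "data.frame"), n_roi = 3L)
  M <- network_counts(ed, atlas)
  expect_equal(M["A", "A"], 1)
  expect_equal(M["A", "B"], 1)
  expect_equal(M["B", "A"], 1)   # symmetric table
  expect_equal(sum(M[upper.tri(M, diag = TRUE)]), nrow(ed))
  # conservation on random edge sets over the fixture atlas
  big <- load_atlas(fixture_atlas_path())
  set.seed(11)
  pairs <- t(replicate(50, sort(sample(264, 2))))
  eds <- structure(data.frame(i = pairs[, 1], j = pairs[, 2], weight = 1),
                   class = c("mgin_edge_set", "data.frame"), n_roi = 264L)
  Mc <- network_counts(eds, big)
  expect_equal(sum(Mc[upper.tri(Mc, diag = TRUE)]), 50)
})

test_that("ROI reports rank by incident weight and round-trip to CSV", {
  atlas <- tiny_atlas(8, networks = rep(c("A", "B"), 4))
  ed <- structure(data.frame(i = c(5, 5, 5, 1), j = c(6, 7, 8, 2),
                             weight = c(1, 1, 1, 0.5)),
                  class = c("mgin_edge_set", "data.frame"), n_roi = 8L)
  tab <- report_rois(ed, atlas)
  expect_equal(tab$roi_id[1], 5)            # star centre first
  expect_setequal(report_rois(structure(
    data.frame(i = 5, j = 7, weight = 1),
    class = c("mgin_edge_set", "data.frame"), n_roi = 8L), atlas)$roi_id,
    c(5, 7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_edge_set(ed, atlas, f)
  back <- read.csv(f)
  expect_equal(back$roi_i, ed$i)
  expect_equal(back$network_i, c("A", "A", "A", "A"))
  expect_equal(back$mask_weight, ed$weight)
})
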