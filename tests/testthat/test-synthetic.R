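test_that("group covariances encode the planted block effect", {
  spec <- effect_spec(n_per_group = 5, n_rois = 10, timepoints = 50,
                      base_correlation = 0.1,
                      blocks = list(list(rois = 1:2, modalities = "emoid",
                                         delta = 0.3)))
  c0 <- build_group_covariance(spec, 0, "emoid")
  c1 <- build_group_covariance(spec, 1, "emoid")
  expect_equal(c0[1, 2], 0.1)
  expect_equal(c1[1, 2], 0.4)
  expect_equal(c1[3, 4], 0.1)              # off-block untouched
  # modality not in the block: groups identical
  expect_equal(build_group_covariance(spec, 1, "nback"),
               build_group_covariance(spec, 0, "nback"))
  # positive definiteness
  expect_gt(min(eigen(c1, symmetric = TRUE)$values), 0)
  # delta = 0 blocks are rejected; empty block list is the null cohort
  expect_error(effect_spec(blocks = list(list(rois = 1:2,
                                              modalities = "emoid",
                                              delta = 0))), "delta != 0")
  null_spec <- effect_spec(blocks = list())
  expect_equal(build_group_covariance(null_spec, 1, "emoid"),
               build_group_covariance(null_spec, 0, "emoid"))
})

test_that("AR(1) sampler hits the requested stationary covariance", {
  Sigma <- diag(2) * 0.9 + 0.1
  x <- sample_timeseries(Sigma, 5000, ar_coefficient = 0, seed = 2)
  expect_lt(norm(cov(x) - Sigma, "F"), 0.05)
  Sigma <- diag(4) * 0.9 + 0.1
  # temporal autocorrelation appears with ar > 0 but the cross-sectional
  # covariance is preserved
  y <- sample_timeseries(Sigma, 20000, ar_coefficient = 0.5, seed = 3)
  expect_lt(norm(cov(y) - Sigma, "F"), 0.15)
  ac <- cor(y[-nrow(y), 1], y[-1, 1])
  expect_gt(ac, 0.4); expect_lt(ac, 0.6)
  # reproducibility is bitwise
  expect_identical(sample_timeseries(Sigma, 100, 0.3, seed = 9),
                   sample_timeseries(Sigma, 100, 0.3, seed = 9))
  # single-series variance within 3 standard errors at T = 2000
  v <- var(sample_timeseries(matrix(1), 2000, 0, seed = 4)[, 1])
  expect_lt(abs(v - 1), 3 * sqrt(2 / 1999))
  expect_error(sample_timeseries(Sigma, 100, 1.0), "nonstationary")
})

test_that("cohort generation is a pure function of the spec", {
  spec <- effect_spec(n_per_group = 3, n_rois = 6, timepoints = 30,
                      blocks = list(list(rois = 1:3,
                                         modalities = c("emoid", "nback"),
                                         delta = 0.2)), seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$metadata, b$metadata)
  expect_identical(unclass(a$cohort$S001$emoid), unclass(b$cohort$S001$emoid))
  # counts: 2 groups x 3 subjects x 2 modalities
  expect_length(a$cohort, 6)
  expect_equal(sum(vapply(a$cohort, length, integer(1))), 12)
  expect_equal(a$metadata$sex, rep(c(0L, 1L), each = 3))
  # stages consistent with ages
  expect_equal(assign_stage(a$metadata$age),
               unname(vapply(a$metadata$age, assign_stage, character(1))))
  # ground truth holds all within-block pairs
  expect_equal(nrow(a$ground_truth$emoid), 3)
})

test_that("empirical group difference on block pairs approaches delta", {
  spec <- effect_spec(n_per_group = 60, n_rois = 12, timepoints = 500,
                      base_correlation = 0.1,
                      blocks = list(list(rois = 1:4,
                                         modalities = c("emoid", "nback"),
                                         delta = 0.3)),
                      ar_coefficient = 0, seed = 21)
  sim <- generate_cohort(spec)
  block_pairs <- as.matrix(sim$ground_truth$emoid)
  mean_block_corr <- function(ids) {
    vals <- vapply(ids, function(sid) {
      r <- cor(unclass(sim$cohort[[sid]]$emoid))
      mean(r[block_pairs])
    }, numeric(1))
    mean(vals)
  }
  g0 <- sim$metadata$subject_id[sim$metadata$sex == 0]
  g1 <- sim$metadata$subject_id[sim$metadata$sex == 1]
  diff_block <- mean_block_corr(g1) - mean_block_corr(g0)
  expect_lt(abs(diff_block - 0.3), 0.05)
  # negative control: off-block pairs show no group difference
  off <- rbind(c(5, 6), c(7, 8), c(9, 10), c(11, 12), c(5, 9))
  mean_off <- function(ids) mean(vapply(ids, function(sid) {
    r <- cor(unclass(sim$cohort[[sid]]$emoid)); mean(r[off])
  }, numeric(1)))
  expect_lt(abs(mean_off(g1) - mean_off(g0)), 0.05)
})

test_that("estimation error shrinks as the scan lengthens", {
  err_at <- function(T) {
    spec <- effect_spec(n_per_group = 40, n_rois = 8, timepoints = T,
                        blocks = list(list(rois = 1:3,
                                           modalities = "emoid",
                                           delta = 0.3)),
                        ar_coefficient = 0, seed = 5)
    sim <- generate_cohort(spec)
    bp <- as.matrix(sim$ground_truth$emoid)
    d <- mean(vapply(sim$metadata$subject_id[sim$metadata$sex == 1],
                     function(s) mean(cor(unclass(sim$cohort[[s]]$emoid))[bp]),
                     numeric(1))) -
      mean(vapply(sim$metadata$subject_id[sim$metadata$sex == 0],
                  function(s) mean(cor(unclass(sim$cohort[[s]]$emoid))[bp]),
                  numeric(1)))
    abs(d - 0.3)
  }
  expect_lt(err_at(1000), err_at(200) + 0.02)
})

test_that("preset scenarios satisfy their declared structure", {
  pre <- preset_scenarios(seed = 3)
  expect_setequal(names(pre), c("shared_signal", "complementary", "weak",
                                "null"))
  for (s in pre) expect_s3_class(s, "mgin_effect_spec")
  expect_equal(pre$shared_signal$blocks[[1]]$delta, 0.3)
  expect_length(pre$null$blocks, 0)
  # complementary: two disjoint 8-ROI blocks on different paradigms
  b <- pre$complementary$blocks
  expect_length(b, 2)
  expect_length(intersect(b[[1]]$rois, b[[2]]$rois), 0)
  expect_false(identical(b[[1]]$modalities, b[[2]]$modalities))
  expect_equal(lengths(list(b[[1]]$rois, b[[2]]$rois)), c(8L, 8L))
})

test_that("synthetic atlas labels make network aggregation meaningful", {
  a <- synthetic_atlas(40, seed = 2)
  expect_equal(n_roi(a), 40)
  expect_true(all(c("DMN", "VIS") %in% a$network))
  expect_equal(a$roi_id, 1:40)
})
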