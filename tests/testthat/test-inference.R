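test_that("permutation p follows the smoothed counting rule and is reproducible", {
  co <- small_cohort(seed = 59, M = 24)
  d <- build_multilesion_design(co$ail, co$wmh, k = 3, "none")
  ps <- prepare_scores(co$table)
  pm <- permutation_p(d, ps$deficit, C = 0.01, P = 100, seed = 7)
  expect_true(all(pm$p >= 1 / 101 & pm$p <= 1))
  expect_equal(pm$p, (1 + pm$count) / 101)
  pm2 <- permutation_p(d, ps$deficit, C = 0.01, P = 100, seed = 7)
  expect_identical(pm$p, pm2$p)
  expect_false(identical(
    pm$p, permutation_p(d, ps$deficit, C = 0.01, P = 100, seed = 8)$p))
  expect_equal(pm$model_spec$retrained_per_permutation, "no")
  expect_warning(permutation_p(d, ps$deficit, C = 0.01, P = 50, seed = 1),
                 "coarse")
})

test_that("both lesion blocks share one permutation stream", {
  co <- small_cohort(seed = 61, M = 20)
  d <- build_multilesion_design(co$ail, co$wmh, k = 3, "none")
  ps <- prepare_scores(co$table)
  pm <- permutation_p(d, ps$deficit, C = 0.01, P = 120, seed = 3)
  expect_equal(length(pm$p), ncol(d$matrix))
  expect_equal(as.integer(table(pm$columns$lesion_type)[c("AIL", "WMH")]),
               unname(d$block_sizes))
})

test_that("a strongly planted column earns the smallest possible p", {
  # deficit exactly proportional to one column: its weight should beat
  # every shuffle, i.e. p = 1/(P+1)
  set.seed(9)
  X <- matrix(rbinom(40 * 30, 1, 0.3), 40, 30)
  X[, 7] <- rep(c(1, 0), each = 20)
  y <- 3 * X[, 7] + rnorm(40, 0, 0.1)
  g <- reference_grid(c(5, 5, 5), c(1, 1, 1))
  tn <- lesion_tensor(X, 1:30, g, "AIL")
  d <- build_single_design(tn, 1, "none")
  pm <- permutation_p(d, y, C = 1, P = 200, seed = 2)
  expect_equal(pm$p[7], 1 / 201)
})

test_that("connectivity semantics: corner contact merges only at 26", {
  g <- tiny_grid()
  # voxels (1,1,1) and (2,2,2): touching at a corner only
  vox <- coord_to_flat(rbind(c(1, 1, 1), c(2, 2, 2)), g)
  fake <- structure(list(
    beta = c(1, 2), count = c(0, 0), p = c(0.01, 0.01),
    columns = data.frame(lesion_type = "AIL", voxel_index = vox),
    blocks = "AIL", block_sizes = c(AIL = 2L), grid = g, P = 100L),
    class = "permutation_p_maps")
  c26 <- threshold_and_cluster(fake, 0.05, 26)
  c6 <- threshold_and_cluster(fake, 0.05, 6)
  expect_length(c26$clusters$AIL, 1)
  expect_length(c6$clusters$AIL, 2)
  # peak voxel carries the largest |beta|
  expect_equal(c26$clusters$AIL[[1]]$peak, vox[2])
  expect_equal(c26$clusters$AIL[[1]]$ml, 2 / 1000)
})

test_that("separated blobs give separate clusters; empty result allowed", {
  g <- tiny_grid()
  vox <- coord_to_flat(rbind(c(1, 1, 1), c(1, 2, 1), c(5, 5, 5)), g)
  fake <- structure(list(
    beta = c(1, 1, 1), count = c(0, 0, 0), p = c(0.01, 0.01, 0.01),
    columns = data.frame(lesion_type = "WMH", voxel_index = vox),
    blocks = "WMH", block_sizes = c(WMH = 3L), grid = g, P = 100L),
    class = "permutation_p_maps")
  cs <- threshold_and_cluster(fake, 0.05)
  expect_length(cs$clusters$WMH, 2)
  fake$p <- rep(0.5, 3)
  expect_length(threshold_and_cluster(fake, 0.05)$clusters$WMH, 0)
  expect_error(threshold_and_cluster(fake, 1.2), "alpha")
})

test_that("cluster extraction works from VLSM results too", {
  co <- small_cohort(seed = 67, M = 24)
  tn <- apply_min_subject_filter(co$ail, 3)
  vr <- vlsm_run(prepare_scores(co$table), tn, P = 100, seed = 1)
  cs <- threshold_and_cluster(vr, 0.9)   # loose alpha to get clusters
  expect_s3_class(cs, "cluster_set")
  ct <- cluster_table(cs)
  if (nrow(ct)) expect_true(all(ct$n_voxels >= 1))
})

test_that("atlas overlap report partitions significant voxels", {
  g <- tiny_grid()
  atlas <- array(0L, c(5, 5, 5))
  atlas[1:2, , ] <- 1L      # region 1: 50 voxels
  atlas[4:5, , ] <- 2L      # region 2: 50 voxels
  vox <- sort(coord_to_flat(rbind(c(1, 1, 1), c(2, 1, 1), c(4, 2, 2),
                                  c(3, 3, 3)), g))
  fake <- structure(list(
    beta = rep(1, 4), count = rep(0, 4), p = rep(0.01, 4),
    columns = data.frame(lesion_type = "AIL", voxel_index = vox),
    blocks = "AIL", block_sizes = c(AIL = 4L), grid = g, P = 100L),
    class = "permutation_p_maps")
  cs <- threshold_and_cluster(fake, 0.05)
  data <- matrix(0L, 3, 4); data[1, ] <- 1L; data[2, 1] <- 1L
  tn <- lesion_tensor(data, vox, g, "AIL", c("a", "b", "c"))
  rep <- atlas_overlap_report(cs, atlas, labels = data.frame(
    code = 1:2, name = c("anterior", "posterior")),
    tensors = list(AIL = tn), tested = list(AIL = vox))
  r1 <- rep[rep$region == "anterior", ]
  expect_equal(r1$region_size_voxels, 50)
  expect_equal(r1$significant_voxels, 2)
  expect_equal(r1$significant_pct, 4)
  expect_equal(r1$n_subjects_with_lesion, 2)   # a and b overlap region 1
  # partition: per-label counts plus unlabeled match the total
  expect_equal(sum(rep$significant_voxels), 4)
  expect_equal(rep$significant_voxels[rep$region == "unlabeled"], 1)
  bad <- array(0L, c(4, 4, 4))
  expect_error(atlas_overlap_report(cs, bad), "grid")
})
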