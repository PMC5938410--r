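test_that("voxelwise normalization entries equal 1/sqrt(volume) exactly", {
  # subject volumes in voxels: 3, 2, 4, 1 (1 mm3 voxels)
  tn <- tiny_tensor()
  d <- build_single_design(tn, k = 1, volume_mode = "voxelwise")
  expect_equal(d$matrix[3, d$matrix[3, ] > 0],
               rep(1 / sqrt(4), 4), tolerance = 1e-15)  # volume 4 -> 0.5
  expect_equal(unique(d$matrix[4, d$matrix[4, ] > 0]), 1,
               tolerance = 1e-15)                        # volume 1 -> 1
  expect_equal(d$matrix[1, d$matrix[1, ] > 0],
               rep(1 / sqrt(3), 3), tolerance = 1e-15)
})

test_that("binary modes produce the retained tensor columns unchanged", {
  tn <- tiny_tensor()
  d0 <- build_single_design(tn, k = 3, volume_mode = "none")
  expect_identical(dim(d0$matrix), c(4L, 2L))
  expect_true(all(d0$matrix %in% c(0, 1)))
  expect_equal(d0$columns$voxel_index, c(10L, 63L))
  dr <- build_single_design(tn, k = 3, volume_mode = "regress_out")
  expect_equal(dr$matrix, d0$matrix)  # scaling deferred to score prep
})

test_that("two-lesion design concatenates independently filtered blocks", {
  g <- tiny_grid()
  ail <- lesion_tensor(rbind(c(1, 0), c(1, 0), c(1, 1), c(0, 1)),
                       c(5L, 9L), g, "AIL", sprintf("s%d", 1:4))
  wmh <- lesion_tensor(rbind(c(0, 1), c(1, 1), c(1, 0), c(1, 0)),
                       c(9L, 30L), g, "WMH", sprintf("s%d", 1:4))
  d <- build_multilesion_design(ail, wmh, k = 3, "none")
  # AIL voxel 5 has prevalence 3; AIL voxel 9 prevalence 2 (dropped);
  # WMH voxel 9 prevalence 3; WMH voxel 30 prevalence 2 (dropped)
  expect_equal(d$block_sizes, c(AIL = 1L, WMH = 1L))
  expect_equal(d$columns$lesion_type, c("AIL", "WMH"))
  expect_equal(d$columns$voxel_index, c(5L, 9L))
  # per-type voxelwise scaling (volumes in voxels: AIL 1,1,2,1; WMH 1,2,1,1)
  dv <- build_multilesion_design(ail, wmh, k = 1, "voxelwise")
  expect_equal(dv$matrix[3, 1:2], c(1 / sqrt(2), 1 / sqrt(2)))
  expect_equal(dv$matrix[2, 3:4], c(1 / sqrt(2), 1 / sqrt(2)))
  # column count equals brute-force prevalence counting
  expect_equal(ncol(d$matrix),
               sum(colSums(ail$data) >= 3) + sum(colSums(wmh$data) >= 3))
})

test_that("exclusive lesion status propagates into the design", {
  co <- small_cohort(seed = 29, M = 20)
  d <- build_multilesion_design(co$ail, co$wmh, k = 1, "none")
  shared <- intersect(co$ail$voxel_index, co$wmh$voxel_index)
  for (v in head(shared, 10)) {
    ca <- d$matrix[, which(d$columns$lesion_type == "AIL" &
                             d$columns$voxel_index == v)]
    cw <- d$matrix[, which(d$columns$lesion_type == "WMH" &
                             d$columns$voxel_index == v)]
    expect_true(all(ca + cw <= 1))
  }
})

test_that("an all-zero second block reduces to the single-lesion design", {
  co <- small_cohort(seed = 31, M = 15)
  empty_wmh <- lesion_tensor(matrix(0L, 15, 0), integer(), co$wmh$grid,
                             "WMH", co$wmh$subject_ids,
                             volumes_ml = numeric(15))
  dm <- build_multilesion_design(co$ail, empty_wmh, k = 3, "none")
  ds <- build_single_design(apply_min_subject_filter(co$ail, 3), 1, "none")
  expect_equal(dm$block_sizes[["WMH"]], 0L)
  expect_equal(unname(dm$matrix), unname(ds$matrix))
  expect_equal(dm$columns$voxel_index, ds$columns$voxel_index)
})

test_that("zero-volume subjects under voxelwise mode warn and zero out", {
  g <- tiny_grid()
  wmh <- lesion_tensor(rbind(c(1, 1), c(0, 0), c(1, 1)), c(2L, 3L), g,
                       "WMH", c("a", "b", "c"))
  expect_warning(d <- build_single_design(wmh, 1, "voxelwise"), "zero")
  expect_true(all(d$matrix[2, ] == 0))
})

test_that("subject order mismatch errors", {
  co <- small_cohort(seed = 37, M = 6)
  wmh2 <- co$wmh
  wmh2$subject_ids <- rev(wmh2$subject_ids)
  expect_error(build_multilesion_design(co$ail, wmh2, 3, "none"),
               "subject order")
})

test_that("design export writes a matrix with a JSON sidecar", {
  dir <- withr::local_tempdir()
  tn <- tiny_tensor()
  d <- build_single_design(tn, 1, "none")
  p <- file.path(dir, "design.csv.gz")
  export_design(d, p)
  got <- read.csv(gzfile(p))
  expect_equal(unname(as.matrix(got)), unname(d$matrix))
  meta <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(meta$columns$voxel_index, d$columns$voxel_index)
  expect_equal(nrow(meta$columns), ncol(d$matrix))
})
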