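#' Multi-lesion SVR design matrix
#'
#' The concatenated lesion-type-specific column matrix: one indicator
#' column per (lesion type, retained voxel) pair, subjects in rows,
#' lesion-type blocks side by side (first block's retained voxels, then
#' the next block's). Under voxelwise volume control every subject's
#' entries in a block are scaled by `1 / sqrt(total lesion volume)` of
#' that block's lesion type (full-mask volume, in voxels).
#'
#' @name multilesion_design
NULL

make_design <- function(blocks, volume_mode) {
  cols <- do.call(rbind, lapply(blocks, function(b)
    data.frame(lesion_type = rep(b$lesion_type, length(b$voxel_index)),
               voxel_index = b$voxel_index, stringsAsFactors = FALSE)))
  mats <- lapply(blocks, `[[`, "mat")
  X <- do.call(cbind, mats)
  types <- vapply(blocks, `[[`, "", "lesion_type")
  structure(list(matrix = X, columns = cols,
                 blocks = types,
                 block_sizes = setNames(vapply(blocks, function(b)
                   length(b$voxel_index), 0L), types),
                 volume_mode = volume_mode,
                 grid = blocks[[1]]$grid,
                 subject_ids = blocks[[1]]$subject_ids),
            class = "multilesion_design")
}

#' @export
print.multilesion_design <- function(x, ...) {
  cat(sprintf("<multilesion_design> %d subjects x %d columns (%s); volume mode: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", x$blocks, x$block_sizes), collapse = ", "),
              x$volume_mode))
  invisible(x)
}

design_block <- function(tensor, k, volume_mode, allow_empty = FALSE) {
  keep <- colSums(tensor$data) >= k
  if (!any(keep) && !allow_empty)
    stop_mlsmap("no %s voxel survives the k=%d inclusion filter",
                tensor$lesion_type, k)
  mat <- tensor$data[, keep, drop = FALSE]
  storage.mode(mat) <- "double"
  if (volume_mode == "voxelwise") {
    # full-mask volume in voxels: keeps the linear kernel diagonal near 1,
    # so the C grid is searched on a well-conditioned problem (any other
    # consistent unit only rescales columns and shifts the optimal C)
    vol_vox <- tensor$volumes_ml / voxel_volume_ml(tensor$grid)
    zero <- vol_vox <= 0
    if (any(zero))
      warn_mlsmap("%d subject(s) have zero %s volume; their rows are all-zero under voxelwise normalization",
                  sum(zero), tensor$lesion_type)
    scale <- ifelse(zero, 0, 1 / sqrt(vol_vox))
    mat <- mat * scale                      # row scaling (recycled by column)
  }
  list(lesion_type = tensor$lesion_type, voxel_index = tensor$voxel_index[keep],
       mat = mat, grid = tensor$grid, subject_ids = tensor$subject_ids)
}

#' Build a single-lesion design matrix
#'
#' One block: a column per voxel retained by the minimum-subject filter.
#' `volume_mode = "voxelwise"` scales each subject's row by
#' `1/sqrt(full lesion volume in voxels)`; `"none"` and `"regress_out"` leave
#' the matrix binary (the latter's correction lives in the behavior
#' scores).
#'
#' @param tensor a [lesion_tensor()].
#' @param k minimum-subject inclusion threshold.
#' @param volume_mode `"none"`, `"voxelwise"` or `"regress_out"`.
#' @return A `multilesion_design` with a single block.
#' @export
build_single_design <- function(tensor, k = 3L,
                                volume_mode = c("none", "voxelwise",
                                                "regress_out")) {
  volume_mode <- match.arg(volume_mode)
  if (!is_count(k)) stop_mlsmap("k must be a positive integer")
  make_design(list(design_block(tensor, k, volume_mode)), volume_mode)
}

#' Build a two-lesion design matrix
#'
#' Column blocks `[first | second]` (by convention AIL then WMH), each
#' independently filtered at `k` and, under voxelwise volume control,
#' scaled by its own lesion type's `1/sqrt(volume)`. Blocks are ordered by
#' ascending voxel index. An all-empty block (e.g. a cohort without any
#' WMH) is allowed and yields zero columns for that block, which makes the
#' two-lesion model reduce exactly to the single-lesion one.
#'
#' @param ail,wmh [lesion_tensor()]s sharing grid and subject order.
#' @param k minimum-subject inclusion threshold (applied per block).
#' @param volume_mode `"none"`, `"voxelwise"` or `"regress_out"`.
#' @return A `multilesion_design` with two blocks.
#' @export
build_multilesion_design <- function(ail, wmh, k = 3L,
                                     volume_mode = c("none", "voxelwise",
                                                     "regress_out")) {
  volume_mode <- match.arg(volume_mode)
  if (!is_count(k)) stop_mlsmap("k must be a positive integer")
  if (!identical(ail$subject_ids, wmh$subject_ids))
    stop_mlsmap("lesion tensors disagree in subject order")
  if (!grids_compatible(ail$grid, wmh$grid))
    stop_mlsmap("lesion tensors live on different grids")
  make_design(list(design_block(ail, k, volume_mode, allow_empty = TRUE),
                   design_block(wmh, k, volume_mode, allow_empty = TRUE)),
              volume_mode)
}

# split a per-column vector into named per-block pieces
split_by_block <- function(values, design) {
  ends <- cumsum(design$block_sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- lapply(seq_along(design$blocks), function(i)
    if (design$block_sizes[i] == 0L) values[0] else
      values[starts[i]:ends[i]])
  names(out) <- design$blocks
  out
}

#' Export a design matrix with column metadata
#'
#' Writes the numeric matrix as gzipped CSV plus a JSON sidecar with
#' per-column lesion type, flat voxel index, grid coordinates and (when an
#' affine is present) world mm coordinates.
#'
#' @param design a `multilesion_design`.
#' @param path output CSV path (`.gz` honoured); the sidecar gets the same
#'   name with `.json` appended.
#' @return `path`, invisibly.
#' @export
export_design <- function(design, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  utils::write.csv(as.data.frame(design$matrix), con, row.names = FALSE)
  close(con)
  coords <- flat_to_coord(design$columns$voxel_index, design$grid)
  world <- coord_to_world(coords, design$grid)
  meta <- list(volume_mode = design$volume_mode,
               subject_ids = design$subject_ids,
               columns = data.frame(design$columns,
                                    i = coords[, 1], j = coords[, 2],
                                    k = coords[, 3],
                                    x_mm = world[, 1], y_mm = world[, 2],
                                    z_mm = world[, 3]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
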