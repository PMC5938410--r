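#' Subjects-by-voxels binary lesion tensor
#'
#' The working container of all mapping analyses: one binary matrix per
#' lesion type with subjects in rows and retained voxels in columns. Voxel
#' columns are identified by their flat grid index (1-based, column-major,
#' i.e. R's native array order). Per-subject volumes are computed from the
#' FULL mask at construction time and are carried unchanged through any
#' voxel filtering, because volume control normalizes by total lesion
#' burden, not by the burden inside the retained voxels.
#'
#' @param data M x V binary matrix (subjects x voxels).
#' @param voxel_index strictly increasing flat grid indices, length V.
#' @param grid a [reference_grid()].
#' @param lesion_type label, e.g. `"AIL"` or `"WMH"`.
#' @param subject_ids character vector of length M.
#' @param volumes_ml optional per-subject full-mask volumes in ml; computed
#'   from `data` when omitted (valid only when `data` still holds every
#'   lesioned voxel).
#' @return An object of class `lesion_tensor`.
#' @export
lesion_tensor <- function(data, voxel_index, grid, lesion_type = "lesion",
                          subject_ids = NULL, volumes_ml = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L)))
    stop_mlsmap("lesion tensor entries must be 0/1")
  voxel_index <- as.integer(voxel_index)
  if (ncol(data) != length(voxel_index))
    stop_mlsmap("voxel_index length must equal ncol(data)")
  if (length(voxel_index) &&
      (is.unsorted(voxel_index, strictly = TRUE) ||
       voxel_index[1] < 1L || voxel_index[length(voxel_index)] > n_voxels(grid)))
    stop_mlsmap("voxel_index must be strictly increasing and inside the grid")
  if (is.null(subject_ids))
    subject_ids <- rownames(data) %||% sprintf("sub-%03d", seq_len(nrow(data)))
  if (length(subject_ids) != nrow(data))
    stop_mlsmap("subject_ids length must equal nrow(data)")
  if (is.null(volumes_ml))
    volumes_ml <- rowSums(data) * voxel_volume_ml(grid)
  if (length(volumes_ml) != nrow(data))
    stop_mlsmap("volumes_ml length must equal nrow(data)")
  rownames(data) <- subject_ids
  structure(list(lesion_type = lesion_type, grid = grid,
                 subject_ids = as.character(subject_ids),
                 voxel_index = voxel_index, data = data,
                 volumes_ml = as.numeric(volumes_ml)),
            class = "lesion_tensor")
}

#' @export
print.lesion_tensor <- function(x, ...) {
  cat(sprintf("<lesion_tensor> %s: %d subjects x %d voxels on %s\n",
              x$lesion_type, nrow(x$data), ncol(x$data),
              format(x$grid)))
  invisible(x)
}

#' @rdname lesion_tensor
#' @param x a `lesion_tensor`.
#' @export
n_subjects <- function(x) nrow(x$data)

# volume restricted to the retained voxels (diagnostic; volume control
# always uses the full-mask volumes_ml)
volumes_retained_ml <- function(x) rowSums(x$data) * voxel_volume_ml(x$grid)

#' Load a lesion cohort from NIfTI masks and a cohort table
#'
#' @param manifest data frame (or TSV path) with columns `id`,
#'   `lesion_type`, `path`: one binary mask file per subject per lesion
#'   type, all on one grid.
#' @param table cohort data frame (or CSV path) with columns `id`, `age`,
#'   `sex`, `education` and at least one score column. Subject order is
#'   taken from this table. Columns `<type>_volume_ml` are recomputed from
#'   the masks when absent.
#' @param space space label recorded on the grid.
#' @return A list with `tensors` (named list of [lesion_tensor()], one per
#'   lesion type) and `table` (the cohort data frame with volume columns).
#' @details Masks must be strictly binary (values 0/1 after rounding at
#'   0.5 to absorb float encodings); masks coded e.g. 0/255 are rejected
#'   rather than rescaled. A mask whose shape or affine disagrees with the
#'   first mask read aborts with the offending subject named.
#' @export
load_cohort <- function(manifest, table, space = "unspecified") {
  if (is.character(manifest))
    manifest <- read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
  if (is.character(table))
    table <- read.csv(table, stringsAsFactors = FALSE)
  need <- setdiff(c("id", "lesion_type", "path"), names(manifest))
  if (length(need))
    stop_mlsmap("manifest lacks column(s): %s", paste(need, collapse = ", "))
  if (!"id" %in% names(table)) stop_mlsmap("cohort table lacks an id column")
  table$id <- as.character(table$id)
  manifest$id <- as.character(manifest$id)
  missing_files <- manifest$path[!file.exists(manifest$path)]
  if (length(missing_files))
    stop_mlsmap("mask file(s) not found: %s",
                paste(head(missing_files, 3), collapse = ", "))
  grid <- NULL
  tensors <- list()
  for (lt in unique(manifest$lesion_type)) {
    sub <- manifest[manifest$lesion_type == lt, ]
    if (!setequal(sub$id, table$id))
      stop_mlsmap("manifest subjects for %s do not match the cohort table", lt)
    sub <- sub[match(table$id, sub$id), ]
    rows <- vector("list", nrow(sub))
    for (j in seq_len(nrow(sub))) {
      nii <- read_nifti(sub$path[j])
      g <- reference_grid(dim(nii$img), nii$voxel_size, nii$affine, space)
      if (is.null(grid)) grid <- g
      if (!grids_compatible(grid, g))
        stop_mlsmap("mask grid mismatch for subject %s (%s)", sub$id[j], lt)
      v <- round(as.vector(nii$img))
      if (!all(v %in% c(0, 1)))
        stop_mlsmap(
          "mask for subject %s (%s) is not binary (values beyond 0/1)",
          sub$id[j], lt)
      rows[[j]] <- as.integer(v)
    }
    full <- do.call(rbind, rows)
    keep <- which(colSums(full) > 0L)
    tensors[[lt]] <- lesion_tensor(full[, keep, drop = FALSE], keep, grid,
                                   lesion_type = lt, subject_ids = table$id,
                                   volumes_ml = rowSums(full) *
                                     voxel_volume_ml(grid))
    vcol <- paste0(tolower(lt), "_volume_ml")
    if (!vcol %in% names(table)) table[[vcol]] <- tensors[[lt]]$volumes_ml
  }
  list(tensors = tensors, table = table)
}

#' Write a lesion tensor back to per-subject NIfTI masks
#'
#' @param tensor a [lesion_tensor()].
#' @param dir output directory (created if needed).
#' @param gz write gzipped `.nii.gz` files.
#' @return data frame manifest (`id`, `lesion_type`, `path`), invisibly.
#' @export
write_lesion_masks <- function(tensor, dir, gz = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gz) ".nii.gz" else ".nii"
  paths <- character(n_subjects(tensor))
  for (m in seq_len(n_subjects(tensor))) {
    vol <- array(0L, dim = tensor$grid$shape)
    vol[tensor$voxel_index] <- tensor$data[m, ]
    paths[m] <- file.path(dir, paste0(tensor$subject_ids[m], "_",
                                      tolower(tensor$lesion_type), ext))
    write_nifti(vol, paths[m], tensor$grid$voxel_size, tensor$grid$affine,
                datatype = "uint8")
  }
  invisible(data.frame(id = tensor$subject_ids,
                       lesion_type = tensor$lesion_type, path = paths,
                       stringsAsFactors = FALSE))
}

#' Minimum-subject voxel inclusion filter
#'
#' Retains exactly the voxels lesioned in at least `k` subjects. The usual
#' choice for cohorts under a hundred subjects is `k = 3`. Full-mask
#' subject volumes are unchanged. Idempotent.
#'
#' @param tensor a [lesion_tensor()].
#' @param k minimum number of lesioned subjects per voxel (>= 1).
#' @return The filtered `lesion_tensor`.
#' @export
apply_min_subject_filter <- function(tensor, k = 3L) {
  if (!is_count(k)) stop_mlsmap("k must be a positive integer")
  keep <- colSums(tensor$data) >= k
  if (!any(keep))
    stop_mlsmap(paste0("no voxel is lesioned in at least %d subjects; ",
                       "reduce k or enlarge the cohort"), k)
  out <- tensor
  out$data <- tensor$data[, keep, drop = FALSE]
  out$voxel_index <- tensor$voxel_index[keep]
  out
}

#' Lesion prevalence map
#'
#' Per-voxel count of subjects lesioned there, on the full grid (0 where no
#' retained voxel exists).
#'
#' @param tensor a [lesion_tensor()].
#' @return An integer 3-D array on the tensor's grid.
#' @export
prevalence_map <- function(tensor) {
  vol <- array(0L, dim = tensor$grid$shape)
  vol[tensor$voxel_index] <- as.integer(colSums(tensor$data))
  vol
}

#' Lesion-size topology map
#'
#' Per-voxel median total lesion volume (ml) among the subjects lesioned at
#' that voxel; `NA` background where no subject is lesioned. Summarizes how
#' large a lesion a patient tends to carry given damage at each location.
#'
#' @param tensor a [lesion_tensor()].
#' @return A numeric 3-D array (ml) with `NA` background.
#' @export
lesion_size_topology <- function(tensor) {
  vol <- array(NA_real_, dim = tensor$grid$shape)
  if (ncol(tensor$data)) {
    med <- apply(tensor$data, 2L, function(col) {
      hit <- col == 1L
      if (any(hit)) median(tensor$volumes_ml[hit]) else NA_real_
    })
    vol[tensor$voxel_index] <- med
  }
  vol
}

# place per-voxel values (aligned with voxel_index) onto the full grid
map_to_volume <- function(values, voxel_index, grid, background = NA_real_) {
  vol <- array(background, dim = grid$shape)
  vol[voxel_index] <- values
  vol
}
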