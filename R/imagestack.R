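#' Longitudinal image stack
#'
#' An `image_stack` holds a longitudinal collection of spatially normalized
#' scalar images (one column per subject-visit) in unfolded (masked, vector)
#' form together with the metadata needed by every downstream fit: subject
#' identifiers, within-subject visit ordinals, scan times, the binary
#' analysis mask and the voxel grid geometry.
#'
#' Columns are stored grouped by subject in ascending visit order; the
#' canonical unfolding order is R's array order over the mask voxels
#' (first axis fastest), so component maps are comparable across runs.
#'
#' @param data numeric matrix, `p` voxels x `J` images (one column per
#'   subject-visit), in the unfolding order of `mask`.
#' @param subject_id character (or coercible) vector of length `J`.
#' @param time numeric vector of length `J`; scan time of each image in a
#'   common unit (e.g. years since subject baseline).
#' @param mask binary array (2D or 3D) with exactly `p` nonzero voxels.
#'   Defaults to a `p x 1 x 1` all-ones grid, which is convenient for
#'   purely algebraic use.
#' @param visit_index optional integer vector of 1-based within-subject
#'   visit ordinals; derived from the time ranks when omitted.
#' @param voxel_size physical voxel edge lengths per axis in mm.
#' @param recenter_times if `TRUE` (default), each subject's times are
#'   re-expressed relative to its first visit so that `t[i1] = 0`; the
#'   subject-specific baseline component is anchored at `t = 0`, so all
#'   model fits in this package assume recentred times.
#'
#' @return an object of class `image_stack` with fields `data`,
#'   `subject_id`, `visit_index`, `time`, `mask`, `grid_shape`,
#'   `voxel_size` and `mask_index` (linear indices of mask voxels).
#' @export
image_stack <- function(data, subject_id, time, mask = NULL,
                        visit_index = NULL, voxel_size = NULL,
                        recenter_times = TRUE) {
  data <- as.matrix(data)
  if (!is.numeric(data))
    stop_data("image data must be numeric")
  J <- ncol(data)
  p <- nrow(data)
  subject_id <- as.character(subject_id)
  time <- as.numeric(time)
  if (length(subject_id) != J || length(time) != J)
    stop_dimension(sprintf(
      "metadata length (%d subjects, %d times) does not match %d images",
      length(subject_id), length(time), J))

  if (is.null(mask)) mask <- array(1L, dim = c(p, 1L, 1L))
  mask <- as.array(mask)
  grid_shape <- dim(mask)
  if (length(grid_shape) == 2L) {
    dim(mask) <- c(grid_shape, 1L)
    grid_shape <- dim(mask)
  }
  if (length(grid_shape) != 3L)
    stop_dimension("mask must be a 2D or 3D array")
  mask_index <- which(mask != 0)
  if (length(mask_index) != p)
    stop_dimension(sprintf("mask has %d nonzero voxels but data has %d rows",
                           length(mask_index), p))
  if (is.null(voxel_size)) voxel_size <- rep(1, 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)

  # canonical (subject, visit) ordering; stable so ties keep input order
  ord <- if (is.null(visit_index)) order(subject_id, time)
         else order(subject_id, as.integer(visit_index))
  data <- data[, ord, drop = FALSE]
  subject_id <- subject_id[ord]
  time <- time[ord]
  if (is.null(visit_index)) {
    visit_index <- stats::ave(seq_len(J), subject_id, FUN = seq_along)
  } else {
    visit_index <- as.integer(visit_index)[ord]
  }

  nv <- table(subject_id)
  if (any(nv < 2L))
    stop_design(sprintf("subject(s) with a single visit: %s",
                        paste(names(nv)[nv < 2L], collapse = ", ")))
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)
    stop_data(sprintf("non-finite value inside mask at voxel %d (image %d)",
                      bad[1, 1], bad[1, 2]))
  }
  if (recenter_times) {
    time <- time - stats::ave(time, subject_id, FUN = min)
  }

  structure(list(data = data, subject_id = subject_id,
                 visit_index = as.integer(visit_index), time = time,
                 mask = mask, grid_shape = grid_shape,
                 voxel_size = voxel_size, mask_index = mask_index),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d voxels x %d images, %d subjects\n",
              nrow(x$data), ncol(x$data), length(unique(x$subject_id))))
  cat(sprintf("  grid %s, voxel size %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

n_subjects <- function(stack) length(unique(stack$subject_id))

# split column indices by subject, preserving canonical order
subject_columns <- function(stack) {
  split(seq_along(stack$subject_id), factor(stack$subject_id,
                                            levels = unique(stack$subject_id)))
}

#' Load a longitudinal image stack from NIfTI volumes
#'
#' Reads one NIfTI volume per subject-visit plus a binary mask, unfolds each
#' volume over the mask voxels (R array order, first axis fastest) and
#' assembles an [image_stack] ordered by (subject, visit).
#'
#' @param image_paths character vector of volume files, or `NULL` to take
#'   them from a `file` column of `design`.
#' @param mask_path path to the binary mask volume.
#' @param design data frame (or path to a CSV/TSV file with a header) with
#'   columns `subject_id`, `visit`, `time` and optionally `file`, one row
#'   per image in the order of `image_paths`.
#' @param recenter_times passed to [image_stack()].
#' @return an [image_stack].
#' @export
load_stack <- function(image_paths = NULL, mask_path, design,
                       recenter_times = TRUE) {
  design <- read_table_file(design)
  if (is.null(image_paths)) {
    if (is.null(design$file))
      stop_validation("design table has no 'file' column and image_paths is NULL")
    image_paths <- design$file
  }
  if (nrow(design) != length(image_paths))
    stop_design(sprintf("design has %d rows but %d image files were given",
                        nrow(design), length(image_paths)))
  for (col in c("subject_id", "time"))
    if (is.null(design[[col]]))
      stop_validation(sprintf("design table lacks required column '%s'", col))
  if (!file.exists(mask_path))
    stop_io(sprintf("mask file not found: %s", mask_path))
  mask <- drop_nifti(RNifti::readNifti(mask_path))
  voxel_size <- nifti_voxel_size(mask_path)
  grid <- dim(as.array(mask))
  if (length(grid) == 2L) grid <- c(grid, 1L)
  mask_arr <- array(as.array(mask), dim = grid)
  idx <- which(mask_arr != 0)

  data <- matrix(NA_real_, nrow = length(idx), ncol = length(image_paths))
  for (j in seq_along(image_paths)) {
    vol <- as.array(drop_nifti(RNifti::readNifti(image_paths[j])))
    dv <- dim(vol); if (length(dv) == 2L) dv <- c(dv, 1L)
    if (!identical(as.integer(dv), as.integer(grid)))
      stop_dimension(sprintf(
        "volume %s has grid %s but mask has grid %s", image_paths[j],
        paste(dv, collapse = "x"), paste(grid, collapse = "x")))
    data[, j] <- array(vol, dim = grid)[idx]
  }
  image_stack(data, subject_id = design$subject_id, time = design$time,
              mask = mask_arr, visit_index = design$visit,
              voxel_size = voxel_size, recenter_times = recenter_times)
}

read_table_file <- function(x) {
  if (is.data.frame(x)) return(x)
  if (!is.character(x) || !file.exists(x))
    stop_io(sprintf("table file not found: %s", as.character(x)[1]))
  if (grepl("\\.tsv$|\\.txt$", x, ignore.case = TRUE))
    read.delim(x, stringsAsFactors = FALSE)
  else
    read.csv(x, stringsAsFactors = FALSE)
}

drop_nifti <- function(img) {
  a <- as.array(img)
  d <- dim(a)
  keep <- if (length(d) > 3L) d[seq_len(3L)] else d
  array(a, dim = keep)
}

nifti_voxel_size <- function(path) {
  hdr <- RNifti::niftiHeader(RNifti::readNifti(path))
  pd <- hdr$pixdim[2:4]
  pd[!is.finite(pd) | pd <= 0] <- 1
  pd
}

#' Fold an unfolded map back to a volume
#'
#' Places a `p`-length vector at the mask voxels of the stack's grid, filling
#' the background with 0. Inverse of the unfolding used by [load_stack()].
#'
#' @param vector numeric vector of length `p`.
#' @param stack an [image_stack] providing mask and grid.
#' @return numeric array with the stack's `grid_shape`.
#' @export
fold_map <- function(vector, stack) {
  if (length(vector) != length(stack$mask_index))
    stop_dimension(sprintf("vector has length %d but mask has %d voxels",
                           length(vector), length(stack$mask_index)))
  vol <- array(0, dim = stack$grid_shape)
  vol[stack$mask_index] <- vector
  vol
}

#' Unfold a volume over the stack's mask
#'
#' @param volume numeric array on the stack's grid.
#' @param stack an [image_stack].
#' @return numeric vector of length `p`.
#' @export
unfold_volume <- function(volume, stack) {
  volume <- as.array(volume)
  dv <- dim(volume); if (length(dv) == 2L) dv <- c(dv, 1L)
  if (!identical(as.integer(dv), as.integer(stack$grid_shape)))
    stop_dimension("volume grid does not match the stack grid")
  array(volume, dim = dv)[stack$mask_index]
}

# Dense one-axis convolution matrix for a normalized discrete Gaussian with
# zero padding at the boundary (rows near the edge sum to < 1).
gaussian_conv_matrix <- function(n, sigma) {
  if (n == 1L || sigma <= 0) return(diag(n))
  radius <- ceiling(4 * sigma)
  offs <- -radius:radius
  k <- dnorm(offs, sd = sigma)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (d in seq_along(offs)) {
    o <- offs[d]
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= n
    M[cbind(i[ok], j[ok])] <- k[d]
  }
  M
}

# Convolve axis `axis` of array X (any number of trailing dims) with matrix K.
conv_axis <- function(X, K, axis) {
  d <- dim(X)
  perm <- c(axis, setdiff(seq_along(d), axis))
  Xp <- aperm(X, perm)
  dp <- dim(Xp)
  Xp <- K %*% matrix(Xp, nrow = dp[1])
  dim(Xp) <- dp
  aperm(Xp, order(perm))
}

#' Gaussian smoothing of every image in a stack
#'
#' Each image is folded onto the full grid (zero background), smoothed with a
#' separable isotropic Gaussian kernel of the requested full width at half
#' maximum, then re-masked. The per-axis kernel standard deviation in voxels
#' is `fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size[axis]`. Axes of length 1
#' are left untouched, so 2D stacks run through the identical code path.
#'
#' @param stack an [image_stack].
#' @param fwhm_mm positive scalar smoothing kernel FWHM in mm.
#' @return a smoothed [image_stack].
#' @export
smooth_stack <- function(stack, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop_validation("fwhm_mm must be a positive scalar")
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / stack$voxel_size
  g <- stack$grid_shape
  J <- ncol(stack$data)
  X <- array(0, dim = c(g, J))
  flat <- matrix(X, nrow = prod(g))
  flat[stack$mask_index, ] <- stack$data
  X <- array(flat, dim = c(g, J))
  for (ax in 1:3) {
    if (g[ax] > 1L)
      X <- conv_axis(X, gaussian_conv_matrix(g[ax], sigma_vox[ax]), ax)
  }
  out <- stack
  out$data <- matrix(X, nrow = prod(g))[stack$mask_index, , drop = FALSE]
  out
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Write a stack to disk as NIfTI volumes plus a design table
#'
#' Writes one NIfTI volume per column, the mask, and a `design.csv` with
#' columns `file`, `subject_id`, `visit`, `time` — the format consumed by
#' [load_stack()].
#'
#' @param stack an [image_stack].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix for the volumes.
#' @return invisibly, the design data frame (with absolute file paths).
#' @export
write_stack <- function(stack, dir, prefix = "image") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_io(sprintf("cannot create directory %s", dir))
  J <- ncol(stack$data)
  files <- file.path(dir, sprintf("%s_%04d.nii.gz", prefix, seq_len(J)))
  for (j in seq_len(J))
    write_map_nifti(stack$data[, j], stack, files[j])
  mask_file <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(make_nifti(stack$mask, stack$voxel_size), mask_file)
  design <- data.frame(file = files, subject_id = stack$subject_id,
                       visit = stack$visit_index, time = stack$time,
                       stringsAsFactors = FALSE)
  write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  invisible(design)
}

make_nifti <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size[seq_along(dim(arr))]
  img
}

#' Write an unfolded map as a NIfTI volume
#'
#' @param map numeric vector of length `p`.
#' @param stack the [image_stack] giving mask and geometry.
#' @param file output path (`.nii` or `.nii.gz`).
#' @export
write_map_nifti <- function(map, stack, file) {
  RNifti::writeNifti(make_nifti(fold_map(map, stack), stack$voxel_size), file)
}
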