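#' Volume grid with analysis mask
#'
#' A `volume_grid` holds the 3-D lattice geometry of an analysis space: the
#' array shape, the voxel size in millimetres, and a binary in-analysis mask
#' (e.g. a grey-matter mask). All masked voxel vectors produced by the
#' package live in this space, linearized with the x axis fastest (R's
#' native column-major array order).
#'
#' @param shape integer triple, voxels per axis (all >= 1).
#' @param voxel_size_mm positive numeric triple, voxel edge lengths in mm.
#' @param mask_fill fraction in (0, 1]; `round(mask_fill * prod(shape))`
#'   voxels are selected (uniformly at random for `mask_fill < 1`).
#' @param seed integer seed controlling mask placement.
#'
#' @return A `volume_grid`: list with `shape`, `voxel_size`, `mask`
#'   (logical array of dim `shape`).
#' @examples
#' g <- make_grid(c(8, 8, 8), voxel_size_mm = c(2, 2, 2), mask_fill = 0.5, seed = 1)
#' n_masked(g)
#' @export
make_grid <- function(shape, voxel_size_mm = c(2, 2, 2), mask_fill = 1, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    stop_invalid("`shape` must be three integers >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop_invalid("`voxel_size_mm` must be three positive numbers")
  if (!is.numeric(mask_fill) || mask_fill <= 0 || mask_fill > 1)
    stop_invalid("`mask_fill` must lie in (0, 1]")
  total <- prod(shape)
  n_true <- max(1L, as.integer(round(mask_fill * total)))
  mask <- array(FALSE, dim = shape)
  if (n_true >= total) {
    mask[] <- TRUE
  } else {
    idx <- with_seed(seed, sample.int(total, n_true))
    mask[idx] <- TRUE
  }
  structure(
    list(shape = shape, voxel_size = voxel_size_mm, mask = mask),
    class = "volume_grid"
  )
}

#' Number of in-mask voxels of a grid
#' @param grid a `volume_grid`.
#' @return integer count of mask voxels.
#' @export
n_masked <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  sum(grid$mask)
}

#' Linear indices of in-mask voxels
#'
#' Indices into the full array (x fastest), in increasing order; position k
#' of any masked voxel vector corresponds to `mask_indices(grid)[k]`.
#' @param grid a `volume_grid`.
#' @return integer vector of linear array indices.
#' @export
mask_indices <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  which(grid$mask)
}

#' Voxel volume in cubic millimetres
#' @param grid a `volume_grid`.
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  prod(grid$voxel_size)
}

#' Embed a masked vector into a full 3-D array
#'
#' @param grid a `volume_grid`.
#' @param values numeric vector of length `n_masked(grid)`.
#' @param fill value for out-of-mask voxels (default `NA`).
#' @return numeric array of dim `grid$shape`.
#' @export
masked_to_volume <- function(grid, values, fill = NA_real_) {
  stopifnot(inherits(grid, "volume_grid"))
  if (length(values) != n_masked(grid))
    stop_invalid("`values` length (", length(values),
                 ") does not match mask voxel count (", n_masked(grid), ")")
  vol <- array(fill, dim = grid$shape)
  vol[mask_indices(grid)] <- values
  vol
}

#' Extract the masked vector from a full 3-D array
#' @param grid a `volume_grid`.
#' @param vol array with dim equal to `grid$shape`.
#' @return numeric vector over the mask.
#' @export
volume_to_masked <- function(grid, vol) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(as.integer(dim(vol)), grid$shape))
    stop_invalid("volume dimensions do not match the grid shape")
  vol[mask_indices(grid)]
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(x$voxel_size, collapse = " x "), "mm,",
      sum(x$mask), "in mask\n")
  invisible(x)
}
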