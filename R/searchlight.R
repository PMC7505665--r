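#' Voxel indices of a spherical searchlight
#'
#' Lattice points within Euclidean distance `radius` of the centre, in
#' voxel units (`radius = list(voxels = r)`) or millimetres
#' (`radius = list(mm = r)`, scaled by the grid's voxel size), intersected
#' with the analysis mask. Out-of-mask sphere voxels are simply dropped.
#'
#' @param grid a `volume_grid`.
#' @param center integer triple (1-based voxel coordinates); must be in
#'   the mask.
#' @param radius `list(voxels = r)` or `list(mm = r)`, r >= 0.
#' @return integer indices into the masked voxel vector.
#' @export
sphere_indices <- function(grid, center, radius = list(voxels = 3)) {
  stopifnot(inherits(grid, "volume_grid"))
  center <- as.integer(center)
  if (length(center) != 3 || any(center < 1) || any(center > grid$shape))
    stop_invalid("`center` must be a voxel coordinate inside the grid")
  if (!grid$mask[center[1], center[2], center[3]])
    stop_invalid("`center` is outside the analysis mask")
  offs <- sphere_offsets(grid, radius)
  pts <- sweep(offs, 2, center, "+")
  keep <- pts[, 1] >= 1 & pts[, 1] <= grid$shape[1] &
    pts[, 2] >= 1 & pts[, 2] <= grid$shape[2] &
    pts[, 3] >= 1 & pts[, 3] <= grid$shape[3]
  pts <- pts[keep, , drop = FALSE]
  strides <- c(1L, grid$shape[1], grid$shape[1] * grid$shape[2])
  lin <- drop((pts - 1L) %*% strides) + 1L
  lin <- lin[grid$mask[lin]]
  match(sort(lin), mask_indices(grid))
}

# Integer offsets within the radius; cached shape depends only on the
# radius spec and voxel size.
sphere_offsets <- function(grid, radius) {
  if (!is.list(radius) || length(radius) != 1 ||
      !names(radius) %in% c("voxels", "mm"))
    stop_invalid("`radius` must be list(voxels = r) or list(mm = r)")
  r <- radius[[1]]
  if (r < 0) stop_invalid("radius must be >= 0")
  unit <- if (names(radius) == "mm") grid$voxel_size else c(1, 1, 1)
  rv <- floor(r / unit)
  g <- as.matrix(expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2],
                             dz = -rv[3]:rv[3]))
  d2 <- (g[, 1] * unit[1])^2 + (g[, 2] * unit[2])^2 + (g[, 3] * unit[3])^2
  g[d2 <= r^2 + 1e-9, , drop = FALSE]
}

#' Searchlight within-modality and cross-modality prediction maps
#'
#' Around every in-mask centre voxel, features are restricted to the
#' spherical neighbourhood and the fold loop of [repeated_cv()] /
#' [cross_modality_eval()] is run with one shared fold partition: within-
#' modality cross-validation for both modalities and both between-modality
#' cross-predictions. Per centre a subject-level one-tailed binomial p is
#' computed for each of the four maps, each map is FDR-corrected across
#' centres, and the conjunction mask marks centres significant on all
#' four.
#'
#' @param dataset a `synth_dataset`.
#' @param modalities length-2 modality pair (A, B).
#' @param radius sphere radius spec, as [sphere_indices()].
#' @param scheme a `cv_scheme`; searchlights default to one repeat, so a
#'   scheme with `n_repeats = 1` is typical.
#' @param q FDR level for the per-map thresholding.
#' @param C margin penalty.
#' @param conditions condition pair.
#' @param verbose print progress every few hundred centres.
#' @return A `searchlight_map`: accuracy and p vectors over mask centres
#'   (`within_a`, `within_b`, `between_ab`, `between_ba`, `p_*`),
#'   thresholded logical maps, `conjunction` mask, `radius`, `grid`.
#' @export
searchlight_crosspred <- function(dataset, modalities = c("NS", "FE"),
                                  radius = list(voxels = 3), scheme,
                                  q = 0.05, C = 1,
                                  conditions = c("pain", "control"),
                                  verbose = FALSE) {
  grid <- dataset$grid
  stopifnot(inherits(scheme, "cv_scheme"))
  idx <- mask_indices(grid)
  coords <- arrayInd(idx, grid$shape)
  nc <- length(idx)
  acc <- matrix(NA_real_, nc, 4,
                dimnames = list(NULL, c("within_a", "within_b",
                                        "between_ab", "between_ba")))
  pmat <- matrix(NA_real_, nc, 4, dimnames = dimnames(acc))
  offs <- sphere_offsets(grid, radius)
  strides <- c(1L, grid$shape[1], grid$shape[1] * grid$shape[2])
  mask_pos <- integer(prod(grid$shape))
  mask_pos[idx] <- seq_len(nc)
  subjects <- scheme$subjects

  for (ci in seq_len(nc)) {
    pts <- sweep(offs, 2, coords[ci, ], "+")
    keep <- pts[, 1] >= 1 & pts[, 1] <= grid$shape[1] &
      pts[, 2] >= 1 & pts[, 2] <= grid$shape[2] &
      pts[, 3] >= 1 & pts[, 3] <= grid$shape[3]
    lin <- drop((pts[keep, , drop = FALSE] - 1L) %*% strides) + 1L
    vox <- mask_pos[lin]
    vox <- sort(vox[vox > 0])
    res <- tryCatch(
      searchlight_center_eval(dataset, modalities, conditions, scheme,
                              vox, C),
      error = function(e) NULL)
    if (!is.null(res)) {
      acc[ci, ] <- res$acc
      pmat[ci, ] <- res$p
    }
    if (verbose && ci %% 200 == 0)
      message("searchlight centre ", ci, " / ", nc)
  }
  thr <- apply(pmat, 2, function(p) {
    out <- rep(FALSE, nc)
    ok <- is.finite(p)
    if (any(ok)) out[ok] <- fdr_threshold(pmin(pmax(p[ok], 1e-300), 1), q)
    out
  })
  conj <- rowSums(thr) == 4
  structure(list(accuracy = acc, p = pmat, thresholded = thr,
                 conjunction = conj, radius = radius, q = q, grid = grid,
                 n_subjects = length(subjects)),
            class = "searchlight_map")
}

# One centre: per-fold training of both modality decoders on the sphere
# features, forced-choice scoring of the four train/test combinations.
searchlight_center_eval <- function(dataset, modalities, conditions,
                                    scheme, vox, C) {
  subjects <- scheme$subjects
  correct <- matrix(0, length(subjects), 4)
  nrep <- scheme$n_repeats
  ds <- dataset
  ds$images <- dataset$images[, vox, drop = FALSE]
  for (r in seq_len(nrep)) {
    fold_of <- scheme$assignment[[r]]
    for (f in seq_len(scheme$n_folds)) {
      tr <- subjects[fold_of != f]
      te <- subjects[fold_of == f]
      ma <- train_fold_model(ds, modalities[1], conditions, tr, C = C)
      mb <- train_fold_model(ds, modalities[2], conditions, tr, C = C)
      pa <- test_pairs(ds, modalities[1], conditions, te)
      pb <- test_pairs(ds, modalities[2], conditions, te)
      sel <- which(fold_of == f)
      correct[sel, 1] <- correct[sel, 1] +
        forced_choice(ma, pa$pos, pa$neg, TRUE)$per_subject_correct
      correct[sel, 2] <- correct[sel, 2] +
        forced_choice(mb, pb$pos, pb$neg, TRUE)$per_subject_correct
      correct[sel, 3] <- correct[sel, 3] +
        forced_choice(ma, pb$pos, pb$neg, TRUE)$per_subject_correct
      correct[sel, 4] <- correct[sel, 4] +
        forced_choice(mb, pa$pos, pa$neg, TRUE)$per_subject_correct
    }
  }
  correct <- correct / nrep
  acc <- colMeans(correct)
  n <- nrow(correct)
  p <- vapply(1:4, function(k)
    stats::binom.test(sum(correct[, k] == 1), n, 0.5,
                      alternative = "greater")$p.value, numeric(1))
  list(acc = acc, p = p)
}
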