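#' Voxel-wise one-sample group t-map
#'
#' Per-voxel one-sample t test against zero over subjects, with two-tailed
#' p from the t distribution (df = n - 1). Zero-variance voxels get t = 0,
#' p = 1 and are flagged.
#'
#' @param contrasts numeric matrix, subjects x voxels (e.g. per-subject
#'   pain-minus-control contrast images).
#' @return A `resample_map`: `stat` (t), `p`, `df`, `degenerate` flags,
#'   `method = "ttest"`, `n_samples`.
#' @export
group_ttest <- function(contrasts) {
  contrasts <- as.matrix(contrasts)
  n <- nrow(contrasts)
  if (n < 3) stop_invalid("need >= 3 subjects")
  m <- colMeans(contrasts)
  s <- col_sds(contrasts)
  degen <- s == 0
  tstat <- ifelse(degen, 0, m / (s / sqrt(n)))
  p <- ifelse(degen, 1, 2 * stats::pt(-abs(tstat), df = n - 1))
  structure(list(stat = tstat, p = p, df = n - 1, degenerate = degen,
                 method = "ttest", n_samples = n, thresholded = NULL),
            class = "resample_map")
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up rejection set at level `q` (via [stats::p.adjust()]).
#'
#' @param p p-value vector in (0, 1].
#' @param q FDR level.
#' @return logical rejection vector (empty input gives empty output).
#' @export
fdr_threshold <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_invalid("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

# 18-connectivity component labelling on a 3-D logical array
# (faces + edges, no corners: the SPM cluster convention).
label_components_18 <- function(mask_arr) {
  dims <- dim(mask_arr)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) %in% 1:2, , drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (start in which(mask_arr)) {
    if (lab[start]) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    frontier <- start
    while (length(frontier)) {
      cc <- arrayInd(frontier, dims)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        sweep(cc, 2, offs[i, ], "+")))
      keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- unique(drop((nb - 1L) %*% strides) + 1L)
      lin <- lin[mask_arr[lin] & lab[lin] == 0L]
      lab[lin] <- nxt
      frontier <- lin
    }
  }
  lab
}

#' Remove small clusters from a thresholded map
#'
#' Deletes 18-connected components whose volume (voxel count times voxel
#' volume) is below `min_mm3`. At 2 mm isotropic resolution clusters of
#' up to 12 voxels (96 mm^3) are removed and 13 voxels (104 mm^3) kept.
#'
#' @param mask logical 3-D array on `grid`, or a masked logical vector.
#' @param grid the `volume_grid`.
#' @param min_mm3 minimum cluster volume in mm^3.
#' @return object of the same form as `mask` with small clusters removed.
#' @export
extent_filter <- function(mask, grid, min_mm3 = 100) {
  stopifnot(inherits(grid, "volume_grid"))
  vectorised <- is.null(dim(mask))
  arr <- if (vectorised) {
    masked_to_volume(grid, as.logical(mask), fill = FALSE)
  } else {
    if (!identical(as.integer(dim(mask)), grid$shape))
      stop_invalid("mask dimensions do not match the grid")
    mask
  }
  arr <- arr & grid$mask
  lab <- label_components_18(arr)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes * voxel_volume(grid) < min_mm3)
    arr[lab %in% small] <- FALSE
  }
  if (vectorised) volume_to_masked(grid, arr) else arr
}

#' Conjunction of two thresholded maps
#'
#' Elementwise AND; with `sign_consistent = TRUE` only voxels whose
#' statistics agree in sign (both positive or both negative) survive.
#'
#' @param mask_a,mask_b logical vectors/arrays of identical form.
#' @param stat_a,stat_b optional statistic maps for the sign check.
#' @param sign_consistent logical.
#' @return logical conjunction of the same form as the inputs.
#' @export
conjunction <- function(mask_a, mask_b, stat_a = NULL, stat_b = NULL,
                        sign_consistent = FALSE) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      length(mask_a) != length(mask_b))
    stop_invalid("maps live on different grids")
  out <- mask_a & mask_b
  if (sign_consistent) {
    if (is.null(stat_a) || is.null(stat_b))
      stop_invalid("sign-consistent conjunction needs both statistic maps")
    out <- out & (sign(stat_a) == sign(stat_b)) & sign(stat_a) != 0
  }
  out
}

#' Spatial (Pearson) correlation of two maps
#'
#' @param map_a,map_b numeric vectors/arrays of identical length.
#' @param mask optional logical selection of common voxels.
#' @return Pearson r over the (masked) voxels.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  a <- as.numeric(map_a); b <- as.numeric(map_b)
  if (length(a) != length(b)) stop_invalid("maps differ in length")
  if (!is.null(mask)) {
    a <- a[mask]; b <- b[mask]
  }
  if (length(a) < 3) stop_invalid("need >= 3 common voxels")
  stats::cor(a, b)
}

# Fast t-maps (or mean maps) for many within-subject sign-flip
# permutations: per-voxel sums of squares are invariant to row sign
# flips, so only the means need recomputing.
signflip_stat_maps <- function(contrasts, signs, statistic = c("t", "mean")) {
  statistic <- match.arg(statistic)
  n <- nrow(contrasts)
  M <- (signs %*% contrasts) / n          # n_perm x voxels means
  if (statistic == "mean") return(M)
  ss <- colSums(contrasts^2)
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  M / sqrt(pmax(V, 0) / n)
}

#' Permutation test of the spatial similarity of two group maps
#'
#' Observed statistic: Pearson correlation between the group maps built
#' from two sets of per-subject contrast images. The null distribution
#' pools two shuffle directions: condition labels shuffled within subject
#' (equivalently, random sign flips of the contrast rows) for dataset A
#' with dataset B fixed, and vice versa, `n_perm` permutations per side.
#' The add-one p is `(1 + #{|r_null| >= |r_obs|}) / (1 + 2 n_perm)`
#' (two-sided default; a one-sided variant uses signed exceedance).
#'
#' @param contrasts_a,contrasts_b matrices, subjects x voxels.
#' @param n_perm permutations per shuffle direction.
#' @param seed integer seed.
#' @param statistic `"t"` (group t-map, default) or `"mean"`.
#' @param map_builder optional function(contrast matrix) -> map vector,
#'   overriding the built-in statistic (slower path).
#' @param alternative `"two.sided"` or `"greater"`.
#' @return A `perm_sim`: `r_obs`, `p`, per-direction p values, `n_perm`,
#'   `seed`, `null` (the pooled null correlations).
#' @export
permutation_similarity <- function(contrasts_a, contrasts_b, n_perm = 10000,
                                   seed = 1, statistic = c("t", "mean"),
                                   map_builder = NULL,
                                   alternative = c("two.sided", "greater")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  A <- as.matrix(contrasts_a); B <- as.matrix(contrasts_b)
  build <- map_builder %||% function(x) {
    if (statistic == "t") group_ttest(x)$stat else colMeans(x)
  }
  map_a <- build(A); map_b <- build(B)
  r_obs <- stats::cor(map_a, map_b)

  null_side <- function(X, fixed_map) {
    if (is.null(map_builder)) {
      S <- matrix(sample(c(-1, 1), n_perm * nrow(X), replace = TRUE),
                  n_perm, nrow(X))
      stats_m <- signflip_stat_maps(X, S, statistic)
      drop(stats::cor(t(stats_m), fixed_map))
    } else {
      vapply(seq_len(n_perm), function(i) {
        s <- sample(c(-1, 1), nrow(X), replace = TRUE)
        stats::cor(build(X * s), fixed_map)
      }, numeric(1))
    }
  }
  nulls <- with_seed(seed, {
    c(null_side(A, map_b), null_side(B, map_a))
  })
  exceed <- if (alternative == "two.sided") abs(nulls) >= abs(r_obs)
  else nulls >= r_obs
  p <- (1 + sum(exceed)) / (1 + length(nulls))
  half <- seq_len(n_perm)
  p_dir <- c(
    a_shuffled = (1 + sum(exceed[half])) / (1 + n_perm),
    b_shuffled = (1 + sum(exceed[-half])) / (1 + n_perm)
  )
  structure(list(r_obs = r_obs, p = p, p_per_direction = p_dir,
                 n_perm = n_perm, seed = seed, alternative = alternative,
                 null = nulls),
            class = "perm_sim")
}

#' @export
print.perm_sim <- function(x, ...) {
  cat(sprintf("perm_sim: r_obs = %.3f, p = %.4g (%s, %d perms/side)\n",
              x$r_obs, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Bootstrap reliability map of decoder weights
#'
#' Subjects are resampled with replacement `n_boot` times and the decoder
#' retrained on each bootstrap sample; per voxel, z = mean / sd of the
#' bootstrap weights, two-tailed normal p, then BH-FDR at `q` and a
#' cluster-extent filter of `min_mm3`.
#'
#' @param dataset a `synth_dataset`.
#' @param modality modality (or modalities) whose decoder is resampled.
#' @param n_boot number of bootstrap samples.
#' @param seed integer seed.
#' @param q FDR level for thresholding.
#' @param min_mm3 cluster-extent threshold (mm^3).
#' @param conditions condition pair for the decoder.
#' @param C margin penalty.
#' @param trainer optional function(dataset, subjects) -> weight vector,
#'   replacing the default scaled linear-SVM fit.
#' @return A `resample_map` with `stat` (z), `p`, `thresholded` (logical
#'   masked vector), `method = "bootstrap"`, `n_samples`.
#' @export
bootstrap_weights <- function(dataset, modality, n_boot = 10000, seed = 1,
                              q = 0.05, min_mm3 = 100,
                              conditions = c("pain", "control"), C = 1,
                              trainer = NULL) {
  subj <- unique(dataset$design$subject)
  if (length(subj) < 10) stop_invalid("need >= 10 subjects")
  train1 <- trainer %||% function(ds, subjects) {
    d <- ds$design
    pos <- neg <- integer(0)
    for (s in subjects) {           # with replacement: repeats kept
      pos <- c(pos, which(d$modality %in% modality &
                            d$condition == conditions[1] & d$subject == s))
      neg <- c(neg, which(d$modality %in% modality &
                            d$condition == conditions[2] & d$subject == s))
    }
    X <- ds$images[c(pos, neg), , drop = FALSE]
    y <- rep(c(1, -1), c(length(pos), length(neg)))
    scaler <- fit_scaler(X)
    train_decoder(apply_scaler(scaler, X), y, C = C)$weights
  }
  W <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      train1(dataset, sample(subj, replace = TRUE))
    }, numeric(ncol(dataset$images))))
  })
  m <- colMeans(W)
  s <- col_sds(W)
  degen <- s == 0
  z <- ifelse(degen, ifelse(m == 0, 0, sign(m) * Inf), m / s)
  p <- ifelse(degen & m != 0, .Machine$double.xmin,
              ifelse(degen, 1, 2 * stats::pnorm(-abs(z))))
  thr <- fdr_threshold(pmin(pmax(p, .Machine$double.xmin), 1), q)
  thr <- extent_filter(thr, dataset$grid, min_mm3)
  structure(list(stat = z, p = p, degenerate = degen, thresholded = thr,
                 method = "bootstrap", n_samples = n_boot, q = q,
                 min_mm3 = min_mm3, seed = seed),
            class = "resample_map")
}

#' Octant analysis of two joint weight maps
#'
#' Each weight vector is z-scored across masked voxels; every voxel's
#' angle `atan2(z_y, z_x)` assigns it to one of eight 45-degree sectors
#' ("octants") centred on the axes and diagonals: O1 (+y selective, 90),
#' O2 (shared positive, 45), O3 (+x selective, 0), O4 (+x/-y, -45), O5
#' (-y selective, -90), O6 (shared negative, -135), O7 (-x selective,
#' 180), O8 (-x/+y, 135). Sector boundaries belong to the
#' counterclockwise sector. Exact-zero (z_x, z_y) pairs are excluded and
#' counted. Per octant the SSD (sum of squared distances from the origin,
#' `sum(z_x^2 + z_y^2)`) combines voxel count and weight magnitude.
#'
#' @param w_x weight vector shown on the x axis (e.g. FE pattern).
#' @param w_y weight vector shown on the y axis (e.g. NS pattern).
#' @param standardize z-score the inputs across voxels (default); set
#'   `FALSE` when the inputs are already normalized.
#' @return An `octant_summary`: data frame (octant, count, ssd) with
#'   attributes `excluded_zero` and `octant_of` (per-voxel assignment, 0
#'   for excluded voxels).
#' @export
octant_analysis <- function(w_x, w_y, standardize = TRUE) {
  if (length(w_x) != length(w_y)) stop_invalid("weight vectors differ in length")
  if (standardize) {
    if (stats::sd(w_x) == 0 || stats::sd(w_y) == 0)
      stop_invalid("constant weight vector: z-scores undefined")
    zx <- as.numeric(scale(w_x))
    zy <- as.numeric(scale(w_y))
  } else {
    zx <- as.numeric(w_x)
    zy <- as.numeric(w_y)
  }
  zero <- zx == 0 & zy == 0
  oct <- integer(length(zx))
  if (any(!zero)) {
    theta <- atan2(zy[!zero], zx[!zero]) * 180 / pi   # (-180, 180]
    centre <- 45 * floor((theta + 22.5) / 45)         # sector centre
    oct[!zero] <- as.integer(((90 - centre) / 45) %% 8 + 1)
  }
  ssd2 <- zx^2 + zy^2
  summary <- data.frame(
    octant = 1:8,
    count = vapply(1:8, function(k) sum(oct == k), integer(1)),
    ssd = vapply(1:8, function(k) sum(ssd2[oct == k]), numeric(1))
  )
  structure(summary, class = c("octant_summary", "data.frame"),
            excluded_zero = sum(zero), octant_of = oct)
}
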