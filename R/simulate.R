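#' Plant ground-truth activation patterns in a masked volume
#'
#' Builds the generative ground truth used by the synthetic-data functions:
#' a shared (cross-modality) pattern, two modality-unique patterns and an
#' arousal confound pattern, each supported on a disjoint random voxel set,
#' then Gram-Schmidt orthogonalized (in the order shared, NS-unique,
#' FE-unique, arousal) and scaled to unit norm. Because the supports are
#' disjoint the patterns are exactly orthogonal already; the
#' orthogonalization guarantees the invariant under any later edits.
#'
#' @param grid a [make_grid()] `volume_grid`.
#' @param n_shared,n_ns,n_fe,n_arousal non-negative support sizes (voxels).
#' @param effect_sizes named numeric amplitudes of the condition loadings:
#'   `shared`, `ns_unique`, `fe_unique` (pain conditions), `arousal` (pain
#'   conditions) and `arousal_negative` (non-painful negative condition).
#' @param noise_sd per-voxel Gaussian noise standard deviation.
#' @param subject_sd standard deviation of the per-subject intercept image.
#' @param seed integer seed for support placement and pattern values.
#'
#' @return A `ground_truth` object with unit-norm, pairwise-orthogonal
#'   pattern vectors over the mask; `null_truth` is `TRUE` when all support
#'   sizes are zero.
#' @export
plant_patterns <- function(grid, n_shared = 50, n_ns = 50, n_fe = 50,
                           n_arousal = 50,
                           effect_sizes = c(shared = 0.8, ns_unique = 0.8,
                                            fe_unique = 0.8, arousal = 0.2,
                                            arousal_negative = 0.8),
                           noise_sd = 0.3, subject_sd = 0.3, seed = 1) {
  stopifnot(inherits(grid, "volume_grid"))
  counts <- c(shared = n_shared, ns_unique = n_ns, fe_unique = n_fe,
              arousal = n_arousal)
  if (any(counts < 0)) stop_invalid("support sizes must be non-negative")
  nv <- n_masked(grid)
  if (sum(counts) > nv)
    stop_invalid("total planted support (", sum(counts),
                 ") exceeds mask voxel count (", nv, ")")
  if (noise_sd < 0 || subject_sd < 0)
    stop_invalid("`noise_sd` and `subject_sd` must be non-negative")
  es <- effect_sizes
  needed <- c("shared", "ns_unique", "fe_unique", "arousal", "arousal_negative")
  if (!all(needed %in% names(es)))
    stop_invalid("`effect_sizes` must name: ", paste(needed, collapse = ", "))

  res <- with_seed(seed, {
    pool <- sample.int(nv)
    supports <- list()
    taken <- 0L
    for (nm in names(counts)) {
      k <- counts[[nm]]
      supports[[nm]] <- if (k > 0) sort(pool[seq_len(k) + taken]) else integer(0)
      taken <- taken + k
    }
    patterns <- lapply(supports, function(sup) {
      v <- numeric(nv)
      if (length(sup)) v[sup] <- rnorm(length(sup))
      v
    })
    list(supports = supports, patterns = patterns)
  })
  patterns <- orthonormalize_patterns(res$patterns)

  structure(
    list(grid = grid, patterns = patterns, supports = res$supports,
         effect_sizes = es[needed], noise_sd = noise_sd,
         subject_sd = subject_sd, seed = seed,
         null_truth = all(counts == 0)),
    class = "ground_truth"
  )
}

# Gram-Schmidt in list order; zero vectors stay zero, others unit norm.
orthonormalize_patterns <- function(patterns) {
  basis <- list()
  out <- patterns
  for (nm in names(patterns)) {
    v <- patterns[[nm]]
    for (b in basis) v <- v - sum(v * b) * b
    nrm <- sqrt(sum(v^2))
    if (nrm > 1e-12) {
      v <- v / nrm
      basis[[length(basis) + 1L]] <- v
    } else {
      v <- numeric(length(v))
    }
    out[[nm]] <- v
  }
  out
}

#' Plant a spatially compact shared pattern
#'
#' Variant of [plant_patterns()] whose shared support is a contiguous ball
#' of voxels (all in-mask voxels within `radius_vox` of a mask voxel chosen
#' near the grid centre) rather than a scattered random set. Synthetic
#' convenience for recovery tests of cluster-extent-thresholded maps, where
#' scattered single-voxel supports would be removed by any spatial extent
#' filter regardless of effect size.
#'
#' @inheritParams plant_patterns
#' @param radius_vox ball radius in voxel units for the shared support.
#' @return A `ground_truth`, as [plant_patterns()]; unique/arousal supports
#'   are drawn from voxels outside the ball.
#' @export
plant_cluster_truth <- function(grid, radius_vox = 2, n_ns = 0, n_fe = 0,
                                n_arousal = 0,
                                effect_sizes = c(shared = 0.8, ns_unique = 0.8,
                                                 fe_unique = 0.8, arousal = 0.2,
                                                 arousal_negative = 0.8),
                                noise_sd = 0.3, subject_sd = 0.3, seed = 1) {
  stopifnot(inherits(grid, "volume_grid"))
  nv <- n_masked(grid)
  idx <- mask_indices(grid)
  coords <- arrayInd(idx, grid$shape)
  centre_target <- (grid$shape + 1) / 2
  d2c <- colSums((t(coords) - centre_target)^2)
  centre <- coords[which.min(d2c), ]
  d2 <- colSums((t(coords) - centre)^2)
  shared_sup <- which(d2 <= radius_vox^2)
  if (!length(shared_sup)) stop_invalid("empty cluster support")
  remaining <- setdiff(seq_len(nv), shared_sup)
  if (n_ns + n_fe + n_arousal > length(remaining))
    stop_invalid("supports exceed mask voxel count")

  res <- with_seed(seed, {
    pool <- sample(remaining)
    supports <- list(shared = sort(shared_sup))
    taken <- 0L
    for (nm in c("ns_unique", "fe_unique", "arousal")) {
      k <- c(ns_unique = n_ns, fe_unique = n_fe, arousal = n_arousal)[[nm]]
      supports[[nm]] <- if (k > 0) sort(pool[seq_len(k) + taken]) else integer(0)
      taken <- taken + k
    }
    patterns <- lapply(supports, function(sup) {
      v <- numeric(nv)
      # constant-sign loading inside the ball: a coherent "region"
      if (length(sup)) v[sup] <- abs(rnorm(length(sup), mean = 1, sd = 0.1))
      v
    })
    list(supports = supports, patterns = patterns)
  })
  patterns <- orthonormalize_patterns(res$patterns)
  structure(
    list(grid = grid, patterns = patterns, supports = res$supports,
         effect_sizes = effect_sizes, noise_sd = noise_sd,
         subject_sd = subject_sd, seed = seed, null_truth = FALSE),
    class = "ground_truth"
  )
}

# Expected (noise-free) loading image for one condition cell.
condition_loading <- function(truth, modality, condition) {
  es <- truth$effect_sizes
  p <- truth$patterns
  v <- numeric(length(p$shared))
  if (condition == "pain") {
    v <- v + es[["shared"]] * p$shared + es[["arousal"]] * p$arousal
    if (modality == "NS") v <- v + es[["ns_unique"]] * p$ns_unique
    if (modality == "FE") v <- v + es[["fe_unique"]] * p$fe_unique
  } else if (condition == "negative") {
    v <- v + es[["arousal_negative"]] * p$arousal
  }
  # control / neutral conditions load nothing
  v
}

#' Simulate per-subject condition-average images
#'
#' Generative model per image: subject intercept image (Gaussian, sd
#' `truth$subject_sd`, shared across that subject's conditions, giving
#' realistic within-subject pairing) + condition loading (see below) +
#' i.i.d. Gaussian voxel noise (sd `truth$noise_sd`). Pain conditions load
#' on the shared pattern, the own-modality unique pattern and the arousal
#' pattern; the non-painful negative condition loads on arousal only;
#' control and neutral conditions load nothing.
#'
#' @param truth a `ground_truth` from [plant_patterns()].
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed.
#' @return A `synth_dataset`: `grid`, `images` (one row per image over the
#'   mask), `design` (subject, modality, condition), `truth`. Six images
#'   per subject: NS pain/control, FE pain/control, IAPS negative/neutral.
#' @export
simulate_subjects <- function(truth, n_subjects, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_subjects < 2) stop_invalid("`n_subjects` must be >= 2")
  cells <- data.frame(
    modality  = c("NS", "NS", "FE", "FE", "IAPS", "IAPS"),
    condition = c("pain", "control", "pain", "control", "negative", "neutral"),
    stringsAsFactors = FALSE
  )
  nv <- length(truth$patterns$shared)
  loadings <- t(vapply(seq_len(nrow(cells)), function(i)
    condition_loading(truth, cells$modality[i], cells$condition[i]),
    numeric(nv)))

  design <- data.frame(
    subject = rep(seq_len(n_subjects), each = nrow(cells)),
    modality = rep(cells$modality, n_subjects),
    condition = rep(cells$condition, n_subjects),
    stringsAsFactors = FALSE
  )
  images <- with_seed(seed, {
    X <- matrix(0, nrow(design), nv)
    for (s in seq_len(n_subjects)) {
      intercept <- rnorm(nv, sd = truth$subject_sd)
      rows <- which(design$subject == s)
      for (k in seq_along(rows)) {
        X[rows[k], ] <- intercept + loadings[k, ] +
          rnorm(nv, sd = truth$noise_sd)
      }
    }
    X
  })
  structure(list(grid = truth$grid, images = images, design = design,
                 truth = truth),
            class = "synth_dataset")
}

#' Simulate graded thermal-intensity images with ratings
#'
#' One image per subject per intensity level; the loading on the shared
#' pain pattern is `slope * level` plus Gaussian jitter (sd
#' `loading_noise`), on top of a per-subject intercept image and voxel
#' noise as in [simulate_subjects()]. Ratings are linear in level with
#' Gaussian noise (sd `rating_noise`), the simplest monotone
#' stimulus-response model. Levels map to nominal temperatures
#' `43.3 + level` (degrees Celsius), i.e. 44.3-49.3 for six levels.
#'
#' @inheritParams simulate_subjects
#' @param n_levels number of intensity levels (>= 2).
#' @param slope shared-pattern loading per level step.
#' @param rating_noise sd of rating noise (>= 0).
#' @param loading_noise sd of per-image loading jitter.
#' @return A `synth_dataset` whose design has `modality = "THERMAL"`,
#'   `condition = "level-k"`, plus `level`, `temperature` and `rating`
#'   columns.
#' @export
simulate_thermal <- function(truth, n_subjects = 33, n_levels = 6,
                             slope = 0.5, rating_noise = 0.5,
                             loading_noise = 0.1, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_subjects < 2) stop_invalid("`n_subjects` must be >= 2")
  if (n_levels < 2) stop_invalid("`n_levels` must be >= 2")
  if (rating_noise < 0) stop_invalid("`rating_noise` must be >= 0")
  nv <- length(truth$patterns$shared)
  design <- data.frame(
    subject = rep(seq_len(n_subjects), each = n_levels),
    modality = "THERMAL",
    condition = paste0("level-", rep(seq_len(n_levels), n_subjects)),
    level = rep(seq_len(n_levels), n_subjects),
    stringsAsFactors = FALSE
  )
  design$temperature <- 43.3 + design$level
  out <- with_seed(seed, {
    X <- matrix(0, nrow(design), nv)
    rating <- numeric(nrow(design))
    for (s in seq_len(n_subjects)) {
      intercept <- rnorm(nv, sd = truth$subject_sd)
      rows <- which(design$subject == s)
      for (k in seq_along(rows)) {
        lev <- design$level[rows[k]]
        load <- slope * lev + rnorm(1, sd = loading_noise)
        X[rows[k], ] <- intercept + load * truth$patterns$shared +
          rnorm(nv, sd = truth$noise_sd)
        rating[rows[k]] <- lev + rnorm(1, sd = rating_noise)
      }
    }
    list(X = X, rating = rating)
  })
  design$rating <- out$rating
  structure(list(grid = truth$grid, images = out$X, design = design,
                 truth = truth),
            class = "synth_dataset")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (peak ~5 s, undershoot ~15 s,
#' undershoot ratio 1/6), normalized to unit peak.
#'
#' @param t time in seconds (>= 0).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  peak <- stats::dgamma(5, shape = 6, rate = 1) -
    stats::dgamma(5, shape = 16, rate = 1) / 6
  h / peak
}

#' Simulate a blocked-design 4-D run
#'
#' Boxcar condition regressors (16 s blocks by default) convolved with the
#' canonical HRF drive the planted condition-loading images; slow
#' cosine drift, a motion-correlated nuisance signal and white Gaussian
#' noise are added, and a 6-column motion table (random-walk parameters)
#' is emitted.
#'
#' @inheritParams simulate_subjects
#' @param block_onsets_s block onset times in seconds.
#' @param block_labels condition label per block (e.g. "pain", "control").
#' @param tr_s repetition time in seconds.
#' @param n_volumes number of volumes in the run.
#' @param motion_sd random-walk step sd of the motion parameters (>= 0).
#' @param drift_amp per-voxel sd of the slow-drift amplitude (>= 0).
#' @param motion_leak scale of the motion-to-signal leakage (>= 0).
#' @param block_duration_s block duration in seconds.
#' @param modality modality whose condition loadings the blocks use.
#' @return A `synth_run`: `ts` (volumes x masked voxels), `motion`
#'   (volumes x 6 data frame), `grid`, `onsets_s`, `labels`, `tr_s`.
#' @export
simulate_run <- function(truth, block_onsets_s, block_labels, tr_s = 2,
                         n_volumes, motion_sd = 0.5, seed = 1,
                         drift_amp = 1, motion_leak = 0.2,
                         block_duration_s = 16, modality = "NS") {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(block_onsets_s) != length(block_labels))
    stop_invalid("onsets and labels differ in length")
  if (motion_sd < 0 || drift_amp < 0 || motion_leak < 0)
    stop_invalid("noise scales must be non-negative")
  run_len <- n_volumes * tr_s
  if (any(block_onsets_s < 0) || any(block_onsets_s + block_duration_s > run_len))
    stop_invalid("all blocks (onset + ", block_duration_s,
                 " s) must fit inside the run")
  ord <- order(block_onsets_s)
  on <- block_onsets_s[ord]
  if (length(on) > 1 && any(on[-1] < on[-length(on)] + block_duration_s))
    stop_invalid("overlapping blocks")

  nv <- length(truth$patterns$shared)
  t_vol <- (seq_len(n_volumes) - 1) * tr_s
  hrf <- canonical_hrf(seq(0, 32, by = tr_s))

  labs <- unique(block_labels)
  neural <- matrix(0, n_volumes, length(labs))
  colnames(neural) <- labs
  for (lab in labs) {
    box <- numeric(n_volumes)
    for (o in block_onsets_s[block_labels == lab])
      box[t_vol >= o & t_vol < o + block_duration_s] <- 1
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_volumes)]
    neural[, lab] <- conv
  }
  load_imgs <- vapply(labs, function(lab)
    condition_loading(truth, modality, lab), numeric(nv))

  with_seed(seed, {
    ts <- neural %*% t(load_imgs)
    if (drift_amp > 0) {
      dct <- cbind(cos(pi * (2 * t_vol / tr_s + 1) * 1 / (2 * n_volumes)),
                   cos(pi * (2 * t_vol / tr_s + 1) * 2 / (2 * n_volumes)))
      ts <- ts + dct %*% matrix(rnorm(2 * nv, sd = drift_amp), 2, nv)
    }
    motion <- matrix(0, n_volumes, 6)
    if (motion_sd > 0)
      motion <- apply(matrix(rnorm(n_volumes * 6, sd = motion_sd),
                             n_volumes, 6), 2, cumsum)
    colnames(motion) <- paste0("mp", 1:6)
    if (motion_leak > 0 && motion_sd > 0) {
      ts <- ts + scale(motion, scale = FALSE) %*%
        matrix(rnorm(6 * nv, sd = motion_leak), 6, nv)
    }
    if (truth$noise_sd > 0)
      ts <- ts + matrix(rnorm(n_volumes * nv, sd = truth$noise_sd),
                        n_volumes, nv)
    structure(list(ts = ts, motion = as.data.frame(motion),
                   grid = truth$grid, onsets_s = block_onsets_s,
                   labels = block_labels, tr_s = tr_s),
              class = "synth_run")
  })
}

#' Extract images of one modality/condition cell, ordered by subject
#'
#' @param dataset a `synth_dataset` (or compatible list with `images` and
#'   `design`).
#' @param modality modality to select (ignored if `NULL`).
#' @param condition condition to select (ignored if `NULL`).
#' @return matrix of images (rows in increasing subject order).
#' @export
dataset_images <- function(dataset, modality = NULL, condition = NULL) {
  d <- dataset$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(modality)) keep <- keep & d$modality %in% modality
  if (!is.null(condition)) keep <- keep & d$condition %in% condition
  rows <- which(keep)
  rows <- rows[order(d$subject[rows])]
  dataset$images[rows, , drop = FALSE]
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("synth_dataset:", nrow(x$images), "images x", ncol(x$images),
      "masked voxels;", length(unique(x$design$subject)), "subjects\n")
  invisible(x)
}
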