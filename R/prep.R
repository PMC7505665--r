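#' Build a motion-expansion nuisance design
#'
#' Expands 6 motion parameters into 24 motion-derived regressors: the
#' parameters, their squares, their backward differences (leading row 0)
#' and the squared differences. Optional per-volume outlier indicator
#' columns and a linear trend are appended.
#'
#' @param motion numeric matrix/data frame, volumes x 6 motion parameters.
#' @param outlier_flags optional logical vector (length = volumes); each
#'   flagged volume contributes one indicator column.
#' @return A `nuisance_design`: list with `matrix` (volumes x regressors)
#'   and `labels`.
#' @export
build_nuisance <- function(motion, outlier_flags = NULL) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop_invalid("need at least 2 time points")
  if (ncol(motion) != 6) stop_invalid("`motion` must have 6 columns")
  if (any(!is.finite(motion))) stop_invalid("non-finite motion values")
  n <- nrow(motion)
  d <- rbind(0, diff(motion))
  mat <- cbind(motion, motion^2, d, d^2)
  labels <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_sq"),
              paste0("mp", 1:6, "_diff"), paste0("mp", 1:6, "_diffsq"))
  if (!is.null(outlier_flags)) {
    stopifnot(length(outlier_flags) == n)
    for (i in which(outlier_flags)) {
      col <- numeric(n); col[i] <- 1
      mat <- cbind(mat, col)
      labels <- c(labels, paste0("outlier_", i))
    }
  }
  trend <- seq_len(n) - (n + 1) / 2
  mat <- cbind(mat, trend / max(abs(trend)))
  labels <- c(labels, "linear_trend")
  colnames(mat) <- labels
  structure(list(matrix = mat, labels = labels), class = "nuisance_design")
}

#' Discrete-cosine high-pass basis
#'
#' DCT regressors whose periods exceed `cutoff_s`; including them in a
#' nuisance design removes fluctuations slower than the cutoff.
#'
#' @param n_volumes number of volumes.
#' @param tr_s repetition time (s).
#' @param cutoff_s high-pass cutoff period (s).
#' @return matrix (possibly 0 columns) of DCT regressors.
#' @export
dct_highpass_basis <- function(n_volumes, tr_s, cutoff_s = 128) {
  total_s <- n_volumes * tr_s
  ks <- seq_len(max(0L, floor(2 * total_s / cutoff_s)))
  ks <- ks[2 * total_s / ks > cutoff_s]
  t0 <- 0:(n_volumes - 1)
  mat <- vapply(ks, function(k) cos(pi * (2 * t0 + 1) * k / (2 * n_volumes)),
                numeric(n_volumes))
  mat <- matrix(mat, nrow = n_volumes)
  if (ncol(mat)) colnames(mat) <- paste0("dct", ks)
  mat
}

#' Regress nuisance structure and slow drifts out of a time series
#'
#' Nuisance regression and high-pass filtering are carried out in a single
#' least-squares projection: the DCT drift regressors (periods above
#' `highpass_s`) are appended to the nuisance design together with an
#' intercept, and the residuals of the combined model are returned.
#' Rank-deficient designs are handled by the pivoted QR (equivalent to a
#' pseudo-inverse fit) with a warning.
#'
#' @param ts numeric matrix, volumes x voxels.
#' @param design a [build_nuisance()] `nuisance_design` (or `NULL` for
#'   drift-plus-intercept cleaning only).
#' @param highpass_s high-pass cutoff period in seconds.
#' @param tr_s repetition time in seconds.
#' @return residual matrix, same dimensions as `ts`.
#' @export
clean_timeseries <- function(ts, design = NULL, highpass_s = 128, tr_s) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  nuis <- if (is.null(design)) NULL else {
    stopifnot(inherits(design, "nuisance_design"))
    if (nrow(design$matrix) != n)
      stop_invalid("design rows (", nrow(design$matrix),
                   ") != time series rows (", n, ")")
    design$matrix
  }
  X <- cbind(intercept = rep(1, n), nuis,
             dct_highpass_basis(n, tr_s, highpass_s))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("rank-deficient nuisance design (rank ", qrX$rank, " of ",
            ncol(X), "); using pseudo-inverse fit")
  qr.resid(qrX, ts)
}

#' Average a time series within shifted block windows
#'
#' For each block, volumes are averaged over the window starting
#' `shift_trs` volumes after the block-onset volume (to allow for the
#' hemodynamic delay) and spanning `round(duration_s / tr_s)` volumes.
#' Onsets are mapped to the nearest earlier volume.
#'
#' @param ts numeric matrix, volumes x voxels.
#' @param onsets_s block onsets in seconds.
#' @param duration_s block duration in seconds.
#' @param tr_s repetition time in seconds.
#' @param shift_trs hemodynamic shift in volumes.
#' @return matrix, one row (block mean vector) per onset.
#' @export
average_blocks <- function(ts, onsets_s, duration_s = 16, tr_s,
                           shift_trs = 3) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  dur_vols <- round(duration_s / tr_s)
  out <- matrix(NA_real_, length(onsets_s), ncol(ts))
  for (b in seq_along(onsets_s)) {
    onset_vol <- floor(onsets_s[b] / tr_s)        # 0-based
    first <- onset_vol + shift_trs + 1L            # 1-based row
    last <- first + dur_vols - 1L
    if (first < 1L || last > n)
      stop_invalid("block ", b, " window (volumes ", first, "-", last,
                   ") exceeds the run (", n, " volumes)")
    out[b, ] <- colMeans(ts[first:last, , drop = FALSE])
  }
  out
}

#' Average block vectors into per-condition images
#'
#' @param block_vectors matrix, one row per block (e.g. from
#'   [average_blocks()]).
#' @param block_labels condition label per block.
#' @param conditions optional set of required conditions; an error names
#'   any condition with no block.
#' @return matrix with one row per condition (rownames = condition),
#'   each the mean of that condition's block vectors.
#' @export
condition_average <- function(block_vectors, block_labels,
                              conditions = NULL) {
  block_vectors <- as.matrix(block_vectors)
  if (nrow(block_vectors) != length(block_labels))
    stop_invalid("one label per block row required")
  labs <- unique(block_labels)
  if (!is.null(conditions)) {
    missing <- setdiff(conditions, labs)
    if (length(missing))
      stop_invalid("no blocks for condition(s): ",
                   paste(missing, collapse = ", "))
    labs <- conditions
  }
  out <- t(vapply(labs, function(lab) {
    rows <- which(block_labels == lab)
    colMeans(block_vectors[rows, , drop = FALSE])
  }, numeric(ncol(block_vectors))))
  rownames(out) <- labs
  out
}
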