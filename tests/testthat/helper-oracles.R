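# Independent oracles and small fixture builders used across the suite.

# Soft-margin linear SVM solved as the dual box-constrained quadratic
# program by pairwise coordinate descent on maximal violating pairs,
# iterated to a 1e-10 KKT gap -- written from the QP definition,
# independent of the libsvm path used by train_decoder().
qp_svm_oracle <- function(X, y, C = 1, eps = 1e-10, max_iter = 200000) {
  n <- nrow(X)
  K <- tcrossprod(X)
  alpha <- numeric(n)
  grad <- rep(-1, n)                      # grad of 1/2 a'Qa - 1'a at a = 0
  Q <- (y %o% y) * K
  for (it in seq_len(max_iter)) {
    Gy <- -y * grad
    up <- (y == 1 & alpha < C - 1e-14) | (y == -1 & alpha > 1e-14)
    lo <- (y == -1 & alpha < C - 1e-14) | (y == 1 & alpha > 1e-14)
    i <- which(up)[which.max(Gy[up])]
    j <- which(lo)[which.min(Gy[lo])]
    if (Gy[i] - Gy[j] < eps) break
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-14) eta <- 1e-14
    delta <- (Gy[i] - Gy[j]) / eta
    # alpha_i += y_i*delta, alpha_j -= y_j*delta, clipped to [0, C]
    rng_i <- if (y[i] == 1) c(-alpha[i], C - alpha[i]) else
      c(alpha[i] - C, alpha[i])
    rng_j <- if (y[j] == 1) c(alpha[j] - C, alpha[j]) else
      c(-alpha[j], C - alpha[j])
    delta <- min(max(delta, rng_i[1], rng_j[1]), rng_i[2], rng_j[2])
    alpha[i] <- alpha[i] + y[i] * delta
    alpha[j] <- alpha[j] - y[j] * delta
    grad <- grad + Q[, i] * y[i] * delta - Q[, j] * y[j] * delta
  }
  w <- drop(crossprod(X, alpha * y))
  free <- which(alpha > 1e-8 * C & alpha < C * (1 - 1e-8))
  b <- if (length(free)) {
    mean(y[free] - X[free, , drop = FALSE] %*% w)
  } else {
    Gy <- -y * grad
    up <- (y == 1 & alpha < C - 1e-14) | (y == -1 & alpha > 1e-14)
    lo <- (y == -1 & alpha < C - 1e-14) | (y == 1 & alpha > 1e-14)
    (max(Gy[up]) + min(Gy[lo])) / 2
  }
  list(weights = w, offset = b)
}

# Brute-force Benjamini-Hochberg step-up rule.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0L, which(ps <= seq_len(m) * q / m)))
  rej <- logical(m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Brute-force octant assignment from the angle rule (boundaries belong
# to the counterclockwise sector), on already-normalized (zx, zy) pairs.
octant_oracle <- function(zx, zy) {
  vapply(seq_along(zx), function(i) {
    if (zx[i] == 0 && zy[i] == 0) return(0L)
    th <- atan2(zy[i], zx[i]) * 180 / pi
    centres <- c(90, 45, 0, -45, -90, -135, 180, 135)
    for (k in 1:8) {
      lo <- centres[k] - 22.5
      hi <- centres[k] + 22.5
      # angle arithmetic on the circle
      d <- ((th - lo) %% 360)
      if (d >= 0 && d < 45) return(k)
    }
    stop("unassigned angle")
  }, integer(1))
}

# Small separable two-modality fixture with a strong shared pattern.
make_shared_fixture <- function(n_subjects = 12, shape = c(8, 8, 8),
                                mask_fill = 0.5, noise_sd = 0.2,
                                effect = c(shared = 1, ns_unique = 0,
                                           fe_unique = 0, arousal = 0,
                                           arousal_negative = 0.8),
                                seed = 1) {
  grid <- make_grid(shape, mask_fill = mask_fill, seed = seed)
  truth <- plant_patterns(grid, 20, 20, 20, 20, effect_sizes = effect,
                          noise_sd = noise_sd, subject_sd = 1,
                          seed = seed + 1)
  simulate_subjects(truth, n_subjects, seed = seed + 2)
}

# Null dataset: no planted components at all.
make_null_dataset <- function(n_subjects, n_voxels = 200, noise_sd = 1,
                              seed = 1, shape = NULL) {
  shape <- shape %||% c(n_voxels, 1, 1)
  grid <- make_grid(shape, mask_fill = 1, seed = seed)
  truth <- plant_patterns(grid, 0, 0, 0, 0, noise_sd = noise_sd,
                          subject_sd = 1, seed = seed)
  simulate_subjects(truth, n_subjects, seed = seed + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
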