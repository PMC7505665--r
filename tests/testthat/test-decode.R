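test_that("range scaling maps train min/max to [-1, 1] with affine extrapolation", {
  train <- cbind(c(0, 2, 4), c(3, 3, 3))
  sc <- fit_scaler(train)
  expect_equal(apply_scaler(sc, train)[, 1], c(-1, 0, 1))
  expect_equal(apply_scaler(sc, train)[, 2], c(0, 0, 0))  # constant voxel
  expect_equal(apply_scaler(sc, c(6, 7)), c(2, 0))        # beyond the range
  expect_error(fit_scaler(train[1, , drop = FALSE]), "2 training rows")
})

test_that("the decoder separates a trivial axis-aligned problem with the right sign", {
  X <- rbind(c(1, 0), c(-1, 0), c(1.1, 0.2), c(-0.9, -0.1))
  y <- c(1, -1, 1, -1)
  m <- train_decoder(X, y)
  expect_gt(m$weights[1], 0)
  expect_gt(abs(m$weights[1]), 10 * abs(m$weights[2]))
  # label flip negates the hyperplane
  m2 <- train_decoder(X, -y)
  expect_equal(m2$weights, -m$weights, tolerance = 1e-8)
  expect_equal(m2$offset, -m$offset, tolerance = 1e-8)
  expect_error(train_decoder(X, rep(1, 4)), "both classes")
})

test_that("decoder decision values match an independent quadratic-program solution", {
  set.seed(11)
  for (case in 1:3) {
    n <- c(20, 26, 30)[case]
    p <- c(2, 5, 3)[case]
    X <- matrix(rnorm(n * p), n, p) +
      rep(c(0.8, -0.8), each = n / 2)   # overlapping classes
    y <- rep(c(1, -1), each = n / 2)
    m <- train_decoder(X, y)
    o <- qp_svm_oracle(X, y)
    dec_pkg <- drop(X %*% m$weights) + m$offset
    dec_qp <- drop(X %*% o$weights) + o$offset
    expect_lt(max(abs(dec_pkg - dec_qp)), 1e-4)
  }
})

test_that("pattern expression is the plain dot product", {
  m <- structure(list(weights = c(1, -1), offset = 5, scaler = NULL, C = 1,
                      meta = list()), class = "pattern_model")
  expect_equal(pattern_expression(m, c(2, 1)), 1)   # offset excluded
  expect_equal(pattern_expression(m, c(0, 0)), 0)
  set.seed(4)
  w <- rnorm(50); x <- rnorm(50)
  mm <- structure(list(weights = w, offset = 0, scaler = NULL, C = 1,
                       meta = list()), class = "pattern_model")
  expect_equal(pattern_expression(mm, x), sum(w * x))
  expect_error(pattern_expression(mm, rnorm(49)), "length")
})

test_that("forced choice scores wins, ties and effect size as specified", {
  w <- c(1, 0)
  m <- structure(list(weights = w, offset = 0, scaler = NULL, C = 1,
                      meta = list()), class = "pattern_model")
  pos <- cbind(1:10, 0); neg <- cbind(rep(0, 10), 0)
  ev <- forced_choice(m, pos, neg)
  expect_equal(ev$accuracy_2afc, 1)
  expect_equal(ev$p_value, 0.5^10)    # exact binomial, 10/10
  # one tie among 10
  pos2 <- pos; pos2[1, 1] <- 0
  expect_equal(forced_choice(m, pos2, neg)$accuracy_2afc, 0.95)
  # differences (1, 2, 3): d = 2 / 1
  ev3 <- forced_choice(m, cbind(c(1, 2, 3), 0), cbind(c(0, 0, 0), 0))
  expect_equal(ev3$cohens_d, 2)
})

test_that("2AFC accuracy is invariant to adding a constant image to every pair", {
  ds <- make_shared_fixture(n_subjects = 10, noise_sd = 0.5, seed = 3)
  m <- train_final(ds, "NS")
  pos <- dataset_images(ds, "FE", "pain")
  neg <- dataset_images(ds, "FE", "control")
  base <- forced_choice(m, pos, neg)
  shift <- matrix(rep(rnorm(ncol(pos), sd = 5), each = nrow(pos)),
                  nrow(pos))
  shifted <- forced_choice(m, pos + shift, neg + shift)
  expect_equal(shifted$accuracy_2afc, base$accuracy_2afc)
  expect_equal(shifted$cohens_d, base$cohens_d, tolerance = 1e-8)
})

test_that("cv schemes partition subjects into near-equal subject-level folds", {
  sch <- make_cv_scheme(1:23, n_folds = 10, n_repeats = 3, seed = 2)
  for (a in sch$assignment) {
    expect_length(a, 23)
    sizes <- tabulate(a, 10)
    expect_lte(diff(range(sizes)), 1)
  }
  expect_identical(make_cv_scheme(1:23, 10, 3, seed = 2)$assignment,
                   sch$assignment)
  expect_error(make_cv_scheme(1:5, n_folds = 10), "fewer subjects")
})

test_that("repeated CV recovers a strong planted signal and is deterministic", {
  ds <- make_shared_fixture(n_subjects = 20, noise_sd = 0.1, seed = 5)
  sch <- make_cv_scheme(1:20, n_folds = 5, n_repeats = 2, seed = 7)
  ev <- repeated_cv(ds, "NS", sch)
  expect_gte(ev$accuracy_2afc, 0.95)
  ev2 <- repeated_cv(ds, "NS", sch)
  expect_identical(ev$per_fold_accuracy, ev2$per_fold_accuracy)
})

test_that("cross-modality evaluation with identical modalities equals within-modality CV", {
  ds <- make_shared_fixture(n_subjects = 12, noise_sd = 0.4, seed = 6)
  sch <- make_cv_scheme(1:12, n_folds = 4, n_repeats = 2, seed = 3)
  a <- repeated_cv(ds, "NS", sch)
  b <- cross_modality_eval(ds, "NS", "NS", sch)
  expect_equal(a$accuracy_2afc, b$accuracy_2afc)
  expect_equal(a$per_fold_accuracy, b$per_fold_accuracy)
})

test_that("the final pooled decoder aligns with the planted shared pattern", {
  ds <- make_shared_fixture(n_subjects = 30, noise_sd = 0.1, seed = 8)
  m <- train_final(ds)
  expect_gt(cosine_sim(m$weights, ds$truth$patterns$shared), 0.7)
  # single-modality final fit is just train_decoder on that modality
  mNS <- train_final(ds, "NS")
  pos <- dataset_images(ds, "NS", "pain")
  neg <- dataset_images(ds, "NS", "control")
  X <- rbind(pos, neg)
  sc <- fit_scaler(X)
  direct <- train_decoder(apply_scaler(sc, X),
                          rep(c(1, -1), each = nrow(pos)), scaler = sc)
  expect_equal(mNS$weights, direct$weights, tolerance = 1e-10)
})

test_that("learning curves trend upward on planted data and close at full sample", {
  ds <- make_shared_fixture(n_subjects = 24, noise_sd = 0.6, seed = 9)
  g <- ds$grid
  th <- simulate_thermal(ds$truth, 12, 6, slope = 1, seed = 10)
  eval_fn <- function(model) {
    s <- expression_series(model, th)
    expression_correlation(s, "level")$r
  }
  lc <- learning_curve(ds, c(6, 12, 24), eval_fn, n_draws = 3, seed = 2)
  expect_equal(lc$size, c(6, 12, 24))
  # non-decreasing up to at most one inversion
  expect_lte(sum(diff(lc$mean_score) < 0), 1)
  full <- eval_fn(train_final(ds))
  expect_equal(lc$mean_score[3], full, tolerance = 1e-10)
  expect_error(learning_curve(ds, c(6, 30), eval_fn), "exceeds")
})
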