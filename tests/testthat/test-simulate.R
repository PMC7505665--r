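test_that("make_grid places the requested number of mask voxels, reproducibly", {
  expect_equal(n_masked(make_grid(c(4, 4, 4), mask_fill = 1)), 64)
  expect_equal(n_masked(make_grid(c(6, 6, 6), mask_fill = 0.25, seed = 2)),
               54)  # round(0.25 * 216)
  g1 <- make_grid(c(10, 10, 10), mask_fill = 0.5, seed = 7)
  g2 <- make_grid(c(10, 10, 10), mask_fill = 0.5, seed = 7)
  expect_identical(g1$mask, g2$mask)
  g3 <- make_grid(c(10, 10, 10), mask_fill = 0.5, seed = 8)
  expect_false(identical(g1$mask, g3$mask))
  expect_error(make_grid(c(0, 4, 4)), "shape")
  expect_error(make_grid(c(4, 4, 4), mask_fill = 0), "mask_fill")
})

test_that("planted patterns have disjoint supports, unit norm and orthogonality", {
  g <- make_grid(c(6, 6, 6), mask_fill = 0.8, seed = 1)
  tr <- plant_patterns(g, 10, 15, 20, 5, seed = 3)
  expect_length(tr$supports$shared, 10)
  expect_equal(sum(tr$patterns$shared != 0), 10)
  sup <- unlist(tr$supports)
  expect_equal(anyDuplicated(sup), 0)
  P <- do.call(cbind, tr$patterns)
  G <- crossprod(P)
  expect_lt(max(abs(G - diag(4))), 1e-10)
  expect_error(plant_patterns(g, 100, 100, 100, 100), "exceeds")
})

test_that("all-zero supports give a flagged null truth", {
  g <- make_grid(c(4, 4, 4))
  tr <- plant_patterns(g, 0, 0, 0, 0)
  expect_true(tr$null_truth)
  expect_true(all(vapply(tr$patterns, function(p) all(p == 0), logical(1))))
})

test_that("noise-free null subjects reduce to their subject intercepts", {
  g <- make_grid(c(4, 4, 4))
  tr <- plant_patterns(g, 0, 0, 0, 0, noise_sd = 0, subject_sd = 1)
  ds <- simulate_subjects(tr, 3, seed = 5)
  expect_equal(nrow(ds$images), 18)  # 3 subjects x 6 cells
  for (s in 1:3) {
    rows <- ds$images[ds$design$subject == s, ]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
  diffs <- dataset_images(ds, "NS", "pain") - dataset_images(ds, "NS", "control")
  expect_equal(max(abs(diffs)), 0)
})

test_that("dataset layout: one image per subject per cell", {
  ds <- make_shared_fixture(n_subjects = 30)
  expect_equal(nrow(ds$images), 180)
  tab <- table(ds$design$subject, paste(ds$design$modality, ds$design$condition))
  expect_true(all(tab == 1))
})

test_that("group mean pain-control projection recovers the planted amplitude", {
  # Monte-Carlo check against the generative expectation, n = 200 pairs
  g <- make_grid(c(6, 6, 6), mask_fill = 1)
  tr <- plant_patterns(g, 20, 10, 10, 10,
                       effect_sizes = c(shared = 0.8, ns_unique = 0,
                                        fe_unique = 0, arousal = 0,
                                        arousal_negative = 0),
                       noise_sd = 1, subject_sd = 1, seed = 2)
  ds <- simulate_subjects(tr, 200, seed = 9)
  con <- dataset_images(ds, "NS", "pain") - dataset_images(ds, "NS", "control")
  proj <- drop(con %*% tr$patterns$shared)
  sem <- sd(proj) / sqrt(length(proj))
  expect_lt(abs(mean(proj) - 0.8), 3 * sem)
})

test_that("seeded determinism is bit-exact for subjects and thermal sets", {
  g <- make_grid(c(5, 5, 5), mask_fill = 0.8, seed = 1)
  tr <- plant_patterns(g, 10, 10, 10, 10, seed = 2)
  expect_identical(simulate_subjects(tr, 5, seed = 3)$images,
                   simulate_subjects(tr, 5, seed = 3)$images)
  expect_identical(simulate_thermal(tr, 5, 6, seed = 4)$images,
                   simulate_thermal(tr, 5, 6, seed = 4)$images)
  expect_error(simulate_subjects(tr, 1), "n_subjects")
})

test_that("thermal set has one image per subject per level with monotone structure", {
  g <- make_grid(c(5, 5, 5), mask_fill = 1)
  tr <- plant_patterns(g, 20, 0, 0, 0, noise_sd = 1e-4, subject_sd = 0,
                       seed = 2)
  th <- simulate_thermal(tr, 33, 6, slope = 1, rating_noise = 0,
                         loading_noise = 0, seed = 5)
  expect_equal(nrow(th$images), 198)
  expect_equal(th$design$rating, th$design$level)
  expect_equal(range(th$design$temperature), c(44.3, 49.3))
  proj <- drop(th$images %*% tr$patterns$shared)
  expect_gt(cor(proj, th$design$level), 0.999)
  # zero slope: expected expression flat across levels (only the tiny
  # voxel noise remains)
  th0 <- simulate_thermal(tr, 6, 6, slope = 0, rating_noise = 0,
                          loading_noise = 0, seed = 6)
  proj0 <- drop(th0$images %*% tr$patterns$shared)
  expect_lt(diff(range(proj0)), 1e-3)
})

test_that("simulated runs are seeded, boxcar-shaped and validated", {
  g <- make_grid(c(4, 4, 4))
  tr <- plant_patterns(g, 10, 0, 0, 0, noise_sd = 0, subject_sd = 0,
                       effect_sizes = c(shared = 1, ns_unique = 0,
                                        fe_unique = 0, arousal = 0,
                                        arousal_negative = 0), seed = 1)
  run <- simulate_run(tr, block_onsets_s = 20, block_labels = "pain",
                      tr_s = 2, n_volumes = 40, motion_sd = 0,
                      drift_amp = 0, seed = 1)
  # zero noise, one block: every voxel's series proportional to the
  # convolved boxcar
  active <- which(tr$patterns$shared != 0)
  ref <- run$ts[, active[1]]
  for (v in active[-1])
    expect_gt(abs(cor(ref, run$ts[, v])), 1 - 1e-10)
  expect_equal(max(abs(run$ts[, tr$patterns$shared == 0])), 0)

  r1 <- simulate_run(tr, c(10, 40), c("pain", "control"), tr_s = 2,
                     n_volumes = 40, seed = 3)
  r2 <- simulate_run(tr, c(10, 40), c("pain", "control"), tr_s = 2,
                     n_volumes = 40, seed = 3)
  expect_identical(r1$ts, r2$ts)
  expect_identical(r1$motion, r2$motion)
  expect_error(simulate_run(tr, c(10, 20), c("a", "b"), tr_s = 2,
                            n_volumes = 40), "overlap")
  expect_error(simulate_run(tr, 70, "a", tr_s = 2, n_volumes = 40),
               "inside the run")
})
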