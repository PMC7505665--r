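test_that("group t-maps match the hand-computed one-sample t", {
  X <- cbind(c(1, 2, 3), c(0, 0, 0), c(-1, 1, 0))
  m <- group_ttest(X)
  expect_equal(m$stat[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(m$df, 2)
  expect_equal(m$stat[2], 0)
  expect_equal(m$p[2], 1)
  expect_true(m$degenerate[2])
  # sign flip negates t, leaves two-tailed p unchanged
  mf <- group_ttest(-X)
  expect_equal(mf$stat, -m$stat)
  expect_equal(mf$p, m$p)
  expect_error(group_ttest(X[1:2, ]), "3 subjects")
})

test_that("BH thresholding matches the brute-force step-up rule", {
  expect_equal(sum(fdr_threshold(c(0.01, 0.02, 0.03, 0.5), 0.05)), 3)
  expect_false(any(fdr_threshold(rep(1, 10), 0.05)))
  expect_length(fdr_threshold(numeric(0)), 0)
  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(3:80, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(fdr_threshold(p, q), bh_oracle(p, q))
  }
})

test_that("BH rejections are monotone in q", {
  set.seed(22)
  p <- runif(200)^2
  r_lo <- fdr_threshold(p, 0.01)
  r_hi <- fdr_threshold(p, 0.10)
  expect_true(all(r_hi[r_lo]))
})

test_that("extent filtering removes clusters under 100 mm^3 at 2 mm resolution", {
  g <- make_grid(c(20, 10, 10), voxel_size_mm = c(2, 2, 2))
  arr <- array(FALSE, g$shape)
  arr[1:12, 1, 1] <- TRUE             # 12 voxels x 8 mm^3 = 96 < 100
  arr[1:13, 5, 5] <- TRUE             # 13 voxels x 8 mm^3 = 104 >= 100
  out <- extent_filter(arr, g)
  expect_false(any(out[, 1, 1]))
  expect_true(all(out[1:13, 5, 5]))
  expect_false(any(extent_filter(array(FALSE, g$shape), g)))
  # masked-vector form agrees with the array form
  vec <- volume_to_masked(g, arr)
  expect_equal(extent_filter(vec, g), volume_to_masked(g, out))
})

test_that("cluster labelling uses 18-connectivity (edges yes, corners no)", {
  g <- make_grid(c(5, 5, 5), voxel_size_mm = c(4, 4, 4))
  arr <- array(FALSE, g$shape)
  arr[2, 2, 2] <- TRUE
  arr[3, 3, 2] <- TRUE                # edge neighbour: connected
  out <- extent_filter(arr, g, min_mm3 = 100)  # 2 x 64 = 128 survives
  expect_true(all(out[cbind(c(2, 3), c(2, 3), c(2, 2))]))
  arr2 <- array(FALSE, g$shape)
  arr2[2, 2, 2] <- TRUE
  arr2[3, 3, 3] <- TRUE               # corner neighbour: separate singletons
  out2 <- extent_filter(arr2, g, min_mm3 = 100) # 64 < 100 each
  expect_false(any(out2))
})

test_that("conjunction is elementwise AND with optional sign consistency", {
  a <- c(TRUE, TRUE, FALSE); b <- c(TRUE, FALSE, FALSE)
  expect_equal(conjunction(a, a), a)
  expect_false(any(conjunction(a, rep(FALSE, 3))))
  expect_equal(conjunction(a, b), c(TRUE, FALSE, FALSE))
  sa <- c(1, 2, 3); sb <- c(-1, 2, 3)
  expect_equal(conjunction(a, a, sa, sb, sign_consistent = TRUE),
               c(FALSE, TRUE, FALSE))
  expect_error(conjunction(a, b[1:2]), "grids")
})

test_that("spatial correlation equals Pearson r over masked voxels", {
  set.seed(31)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), -1)
  expect_equal(spatial_correlation(a, b), cor(a, b))
  msk <- rep(c(TRUE, FALSE), 20)
  expect_equal(spatial_correlation(a, b, msk), cor(a[msk], b[msk]))
})

test_that("permutation similarity uses the add-one formula and detects strong similarity", {
  set.seed(32)
  shared_map <- rnorm(100)
  A <- matrix(rnorm(12 * 100, sd = 0.05), 12, 100) +
    rep(shared_map, each = 12)
  B <- matrix(rnorm(12 * 100, sd = 0.05), 12, 100) +
    rep(shared_map, each = 12)
  ps <- permutation_similarity(A, B, n_perm = 200, seed = 5)
  expect_gt(ps$r_obs, 0.9)
  expect_equal(ps$p, 1 / (2 * 200 + 1))  # exceeds every null draw
  # determinism
  ps2 <- permutation_similarity(A, B, n_perm = 200, seed = 5)
  expect_identical(ps$null, ps2$null)
  # voxel-order invariance
  perm <- sample(100)
  ps3 <- permutation_similarity(A[, perm], B[, perm], n_perm = 200, seed = 5)
  expect_equal(ps3$r_obs, ps$r_obs)
  expect_equal(ps3$p, ps$p)
  expect_warning(permutation_similarity(A, B, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("the fast sign-flip t-map path equals explicit recomputation", {
  set.seed(33)
  X <- matrix(rnorm(10 * 30), 10, 30)
  S <- matrix(sample(c(-1, 1), 5 * 10, replace = TRUE), 5, 10)
  fast <- sharedrep:::signflip_stat_maps(X, S, "t")
  for (i in 1:5) {
    expect_equal(fast[i, ], group_ttest(X * S[i, ])$stat, tolerance = 1e-10)
  }
})

test_that("bootstrap weight maps recover a planted cluster and stay seeded", {
  g <- make_grid(c(8, 8, 8), mask_fill = 1)
  truth <- plant_cluster_truth(g, radius_vox = 2,
                               effect_sizes = c(shared = 3, ns_unique = 0,
                                                fe_unique = 0, arousal = 0,
                                                arousal_negative = 0),
                               noise_sd = 0.2, subject_sd = 1, seed = 3)
  ds <- simulate_subjects(truth, 20, seed = 4)
  bm <- bootstrap_weights(ds, "NS", n_boot = 150, seed = 6)
  sup <- truth$supports$shared
  expect_gte(mean(bm$thresholded[sup]), 0.8)
  expect_lt(mean(bm$thresholded[-sup]), 0.05)
  bm2 <- bootstrap_weights(ds, "NS", n_boot = 150, seed = 6)
  expect_identical(bm$stat, bm2$stat)
  expect_error(bootstrap_weights(make_shared_fixture(n_subjects = 5), "NS",
                                 n_boot = 10), "10 subjects")
})

test_that("octant assignment follows the angle rule with counterclockwise boundaries", {
  # spec-level examples on already-normalized pairs
  oc <- function(zx, zy) attr(octant_analysis(c(zx, 9), c(zy, 9),
                                              standardize = FALSE),
                              "octant_of")[1]
  expect_equal(oc(0.1, 1.0), 1)       # ~84.3 degrees
  expect_equal(oc(-1, -1), 6)         # shared negative
  expect_equal(oc(1, 1), 2)           # shared positive
  expect_equal(oc(1, 0), 3)
  expect_equal(oc(0, -1), 5)
  s <- octant_analysis(c(1, 2, 5), c(1, 2, -5), standardize = FALSE)
  expect_equal(s$ssd[s$octant == 2], 2 + 8)
  # brute-force angle oracle on random pairs
  set.seed(34)
  zx <- rnorm(2000); zy <- rnorm(2000)
  got <- attr(octant_analysis(zx, zy, standardize = FALSE), "octant_of")
  expect_identical(got, octant_oracle(zx, zy))
})

test_that("octant counts partition the voxels and respect axis-swap equivariance", {
  set.seed(35)
  wx <- rnorm(500); wy <- rnorm(500)
  s <- octant_analysis(wx, wy)
  expect_equal(sum(s$count) + attr(s, "excluded_zero"), 500)
  swapped <- octant_analysis(wy, wx)
  mapping <- c(3, 2, 1, 8, 7, 6, 5, 4)  # O1<->O3, O5<->O7, O4<->O8
  expect_equal(swapped$count, s$count[mapping])
  expect_equal(swapped$ssd, s$ssd[mapping], tolerance = 1e-10)
  expect_error(octant_analysis(rep(1, 5), rnorm(5)), "constant")
})
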