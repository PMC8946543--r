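test_that("Manders hits the degenerate bounds exactly", {
  m <- matrix(0, 16, 16)
  m[4:9, 4:9] <- 1
  same <- manders_pair(m, m)
  expect_equal(same$m1, 1)
  expect_equal(same$m2, 1)

  other <- matrix(0, 16, 16)
  other[12:15, 12:15] <- 1
  disj <- manders_pair(m, other)
  expect_equal(disj$m1, 0)
  expect_equal(disj$m2, 0)
})

test_that("Manders matches direct summation and flags undefined cases", {
  ref <- c(0, 5) # positive only at voxel b
  qry <- c(10, 30)
  expect_equal(manders_pair(ref, qry)$m1, 30 / 40)

  set.seed(11)
  for (i in 1:30) {
    a <- matrix(sample(0:20, 36, TRUE), 6)
    b <- matrix(sample(0:20, 36, TRUE), 6)
    got <- manders_pair(a, b)
    want <- manders_oracle(a, b)
    expect_equal(got$m1, want$m1)
    expect_equal(got$m2, want$m2)
    # role swap: M1(A,B) == M2(B,A)
    swapped <- manders_pair(b, a)
    expect_identical(got$m1, swapped$m2)
    expect_identical(got$m2, swapped$m1)
    # scale invariance under positive rescaling of either channel
    expect_equal(manders_pair(a * 3.7, b)$m1, got$m1)
    expect_equal(manders_pair(a, b * 0.2)$m2, got$m2)
  }

  none <- matrix(0, 4, 4)
  some <- matrix(1, 4, 4)
  res <- manders_pair(none, some)
  expect_true(is.na(res$m2))
  expect_false(res$m2_defined)
  expect_equal(res$m1, 0)
  expect_error(manders_pair(none, none), "empty")
  expect_error(manders_pair(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("rank correlations hit their degenerate values", {
  a <- matrix(c(10, 40, 90, 200, 7, 13, 55, 128, 250), 3)
  expect_equal(spearman_rho(a, a), 1)
  expect_equal(spearman_rho(a, 255 - a), -1)
  expect_equal(kendall_taub(a, a), 1)
  expect_equal(kendall_taub(a, 255 - a), -1)
  expect_true(is.na(spearman_rho(a, a * 0 + 3)))
  expect_true(is.na(kendall_taub(a * 0, a)))
  expect_error(spearman_rho(1:2, 2:1), "3 voxels")
})

test_that("rho matches the rank-difference formula on tie-free samples", {
  expect_equal(
    spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)),
    rho_oracle_noties(c(1, 2, 3, 4), c(1, 3, 2, 4))
  )
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1000, 30)
    y <- sample(1000, 30)
    expect_equal(spearman_rho(x, y), rho_oracle_noties(x, y))
  }
})

test_that("fast tau-b equals O(n^2) pair counting, ties included", {
  expect_equal(
    kendall_taub(c(1, 2, 2, 3), c(1, 2, 3, 3)),
    taub_oracle(c(1, 2, 2, 3), c(1, 2, 3, 3))
  )
  set.seed(6)
  for (i in 1:40) {
    n <- sample(3:200, 1)
    levels <- sample(c(3, 8, 256), 1) # heavy to light tie regimes
    x <- sample(seq_len(levels), n, TRUE)
    y <- sample(seq_len(levels), n, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_taub(x, y), taub_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("rank correlations are invariant under increasing transforms", {
  set.seed(7)
  x <- sample(0:255, 60, TRUE)
  y <- sample(0:255, 60, TRUE)
  f <- function(v) log1p(v)^1.3
  expect_equal(spearman_rho(f(x), y), spearman_rho(x, y))
  expect_equal(kendall_taub(x, f(y)), kendall_taub(x, y))
  # monotone relationships give same-signed rho and tau
  for (i in 1:10) {
    x <- sample(0:255, 40, TRUE)
    noise <- rnorm(40, 0, 20)
    y <- x + noise
    expect_equal(
      sign(kendall_taub(x, y)), sign(spearman_rho(x, y))
    )
  }
})

test_that("Costes self-pairing is maximally significant and seeded", {
  img <- textured_image()
  p <- costes_test(img, img)
  expect_equal(p, 100)
  cfg <- costes_config(n_scrambles = 20, seed = 99)
  p1 <- costes_test(img, textured_image(seed = 8), cfg = cfg)
  p2 <- costes_test(img, textured_image(seed = 8), cfg = cfg)
  expect_identical(p1, p2)
  expect_error(
    costes_test(img[1:6, 1:6], img[1:6, 1:6]),
    "16"
  )
})

test_that("Costes p is roughly uniform for independent channels", {
  ps <- vapply(1:20, function(i) {
    costes_test(
      textured_image(seed = i), textured_image(seed = 100 + i),
      cfg = costes_config(n_scrambles = 50, seed = i)
    )
  }, numeric(1))
  expect_gt(mean(ps), 25)
  expect_lt(mean(ps), 75)
})

test_that("pairings recover construction-level colocalization", {
  sc <- generate_scene(tiny_config(
    coloc_fraction_pmp22_ec = 1, coloc_fraction_pmp22_hc = 0
  ))
  labs <- segment_nuclei(sc$stack)
  crop <- crop_nucleus(sc$stack, labs, 1L)
  masks <- chromatin_masks(crop)
  cl <- coloc_pairings(crop, masks, costes_cfg = NULL)
  expect_setequal(
    cl$pairing,
    c("EC_vs_TC", "EC_vs_HC", "PMP22_vs_EC", "PMP22_vs_HC", "PMP22_vs_LMNB1")
  )
  # all PMP22 was painted into euchromatin
  expect_equal(cl$m2[cl$pairing == "PMP22_vs_EC"], 1)
  # euchromatin and heterochromatin are disjoint and anticorrelated
  expect_equal(cl$m1[cl$pairing == "EC_vs_HC"], 0)
  expect_equal(cl$m2[cl$pairing == "EC_vs_HC"], 0)
  expect_lt(cl$rho[cl$pairing == "EC_vs_HC"], 0)

  half <- generate_scene(tiny_config(
    coloc_fraction_pmp22_ec = 0.5, coloc_fraction_pmp22_hc = 0
  ))
  labs <- segment_nuclei(half$stack)
  crop <- crop_nucleus(half$stack, labs, 1L)
  cl <- coloc_pairings(crop, chromatin_masks(crop), costes_cfg = NULL)
  expect_equal(cl$m2[cl$pairing == "PMP22_vs_EC"], 0.5, tolerance = 0.1)
})

test_that("a missing channel skips its pairings instead of failing", {
  sc <- generate_scene(tiny_config())
  labs <- segment_nuclei(sc$stack)
  crop <- crop_nucleus(sc$stack, labs, 1L)
  keep <- match(c("DAPI", "H3K4m3", "PMP22"), sc$stack$channel_roles)
  crop3 <- crop
  crop3$stack <- image_stack(
    crop$stack$voxels[, , , keep, drop = FALSE],
    c("DAPI", "H3K4m3", "PMP22"), crop$stack$voxel_size
  )
  cl <- coloc_pairings(crop3, chromatin_masks(crop3), costes_cfg = NULL)
  expect_false("PMP22_vs_LMNB1" %in% cl$pairing)
  expect_equal(nrow(cl), 4L)
})
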