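test_that("empty and single-object stacks segment correctly", {
  empty <- image_stack(array(0, c(4, 20, 20, 1)), "DAPI")
  labs <- segment_nuclei(empty)
  expect_equal(max(labs), 0L)

  ell <- ellipsoid_stack(level = 200)
  labs <- segment_nuclei(ell$stack)
  expect_equal(max(labs), 1L)
})

test_that("segmentation recovers every synthetic nucleus", {
  sc <- generate_scene(synthetic_config(
    n_nuclei = 10, seed = 3, noise_sd = 0, volume_mean = 100, volume_sd = 10
  ))
  labs <- segment_nuclei(sc$stack)
  expect_equal(max(labs), 10L)
})

test_that("volumes follow count times voxel volume", {
  labs <- array(0L, c(10, 10, 10))
  labs[1:10, 1:10, 1:10][seq_len(1000)] <- 1L
  v <- compute_volumes(labs, c(1, 0.379, 0.379))
  expect_equal(v$volume, 1000 * 1 * 0.379 * 0.379)

  labs1 <- array(0L, c(2, 2, 2))
  labs1[1] <- 1L
  expect_equal(compute_volumes(labs1, c(1, 1, 1))$volume, 1)
  expect_error(compute_volumes(array(0L, c(2, 2, 2))), "no nuclei")
})

test_that("a uniform ellipsoid's volume is recovered within 10%", {
  ell <- ellipsoid_stack(
    semi_um = c(5, 10, 10), level = 60,
    voxel_size = c(1, 0.379, 0.379), pad_px = 20
  )
  labs <- segment_nuclei(ell$stack)
  expect_equal(max(labs), 1L)
  v <- compute_volumes(labs, c(1, 0.379, 0.379))$volume
  expect_lt(abs(v - ell$volume) / ell$volume, 0.10)
})

test_that("label count is invariant to channel order", {
  sc <- generate_scene(tiny_config())
  n1 <- max(segment_nuclei(sc$stack))
  perm <- c(3, 1, 4, 2)
  shuffled <- image_stack(
    sc$stack$voxels[, , , perm, drop = FALSE],
    sc$stack$channel_roles[perm],
    sc$stack$voxel_size
  )
  expect_equal(max(segment_nuclei(shuffled)), n1)
  no_dapi <- image_stack(
    sc$stack$voxels[, , , 2:4, drop = FALSE],
    c("H3K4m3", "PMP22", "LMNB1"), sc$stack$voxel_size
  )
  expect_error(segment_nuclei(no_dapi), "DAPI")
})

test_that("total labelled volume cannot exceed the stack volume", {
  sc <- generate_scene(tiny_config())
  labs <- segment_nuclei(sc$stack)
  v <- compute_volumes(labs, sc$stack$voxel_size)
  expect_lte(
    sum(v$volume),
    prod(dim(labs)) * prod(sc$stack$voxel_size)
  )
})

test_that("per-label volumes match ellipsoid truth within 10% (noise-free)", {
  sc <- generate_scene(synthetic_config(
    n_nuclei = 6, seed = 9, noise_sd = 0
  ))
  labs <- segment_nuclei(sc$stack)
  m <- measure_nuclei(sc$stack, labs)
  truth_of <- vapply(seq_len(max(labs)), function(l) {
    tl <- sc$truth$labels[labs == l]
    as.integer(names(which.max(table(tl[tl > 0]))))
  }, integer(1))
  rel <- m$volume / sc$truth$nuclei$volume_true[truth_of] - 1
  expect_lt(max(abs(rel)), 0.10)
})

test_that("cropping clears extranuclear signal and keeps nuclear signal", {
  sc <- generate_scene(tiny_config())
  labs <- segment_nuclei(sc$stack)
  crop <- crop_nucleus(sc$stack, labs, 1L, margin = 3L)
  pm <- stack_channel(crop$stack, "PMP22")
  expect_true(all(pm[!crop$mask] == 0))

  # PMP22 lying wholly inside the nucleus keeps its total intensity
  inside_before <- sum(stack_channel(sc$stack, "PMP22")[labs == 1L])
  expect_equal(sum(pm[crop$mask]), inside_before)

  # margin 0 gives exactly the bounding box
  crop0 <- crop_nucleus(sc$stack, labs, 1L, margin = 0L)
  co <- which(labs == 1L, arr.ind = TRUE)
  expect_equal(
    dim(crop0$mask),
    as.integer(apply(co, 2, max) - apply(co, 2, min) + 1L)
  )
  expect_error(crop_nucleus(sc$stack, labs, 99L), "label")
})

test_that("mean intensities are measured on raw channels", {
  ell <- ellipsoid_stack(level = 60)
  labs <- segment_nuclei(ell$stack)
  m <- measure_nuclei(ell$stack, labs)
  # the blur used for mask-making must not leak into the measurement
  expect_equal(m$mean_DAPI, 60, tolerance = 0.05)
})
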