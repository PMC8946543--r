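# build a one-plane mask/channel pair from a logical matrix
plane_stack <- function(mask2d, values = NULL) {
  ch <- array(0, dim = c(1, dim(mask2d)))
  if (!is.null(values)) ch[1, , ] <- values
  mask <- array(mask2d, dim = c(1, dim(mask2d)))
  list(channel = ch, mask = mask)
}

disk_mask <- function(n = 21, ry = 8, rx = 8) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(y, x) {
    ((y - ctr) / ry)^2 + ((x - ctr) / rx)^2 <= 1
  })
}

test_that("vector lengths reflect the mask geometry", {
  d <- plane_stack(disk_mask())
  lon <- trace_vector(d$channel, d$mask, "longitudinal", 1)
  tra <- trace_vector(d$channel, d$mask, "transverse", 1)
  expect_lte(abs(nrow(lon) - nrow(tra)), 1)

  e <- plane_stack(disk_mask(31, ry = 5, rx = 14))
  lon <- trace_vector(e$channel, e$mask, "longitudinal", 1)
  tra <- trace_vector(e$channel, e$mask, "transverse", 1)
  expect_gt(nrow(lon), nrow(tra))
})

test_that("uniform masks give uniform samples and equal sector means", {
  d <- plane_stack(disk_mask(), values = 77)
  tr <- trace_vector(d$channel, d$mask, "transverse", 1)
  expect_true(all(tr$intensity == 77))
  s <- sector_assign(tr$intensity, "transverse")
  expect_equal(mean(s$peripheral), mean(s$central))
  expect_error(trace_vector(d$channel, d$mask, "transverse", 2), "outside|mask")
})

test_that("sectoring follows thirds (transverse) and quarters (longitudinal)", {
  s <- sector_assign(1:9, "transverse")
  expect_equal(sort(s$peripheral), c(1:3, 7:9))
  expect_equal(s$central, 4:6)

  s <- sector_assign(1:8, "longitudinal")
  expect_equal(sort(s$peripheral), c(1, 2, 7, 8))
  expect_equal(s$central, 3:6)

  expect_error(sector_assign(1:3, "transverse"), "4 samples")
})

test_that("sectors partition the samples with near-equal sizes", {
  for (kind in c("transverse", "longitudinal")) {
    for (n in 4:41) {
      s <- sector_assign(seq_len(n), kind)
      got <- sort(c(s$peripheral, s$central))
      expect_equal(got, seq_len(n)) # exact partition
      k <- if (kind == "transverse") 3 else 4
      n_central_sectors <- if (kind == "transverse") 1 else 2
      # every sector stays within one sample of the equal split
      expect_lte(abs(length(s$central) / n_central_sectors - n / k), 1)
      expect_lte(abs(length(s$peripheral) / 2 - (k - n_central_sectors) * n / (2 * k)), 1)
    }
  }
})

test_that("known radial layouts give the expected dominance", {
  n <- 41
  ctr <- (n + 1) / 2
  r <- outer(seq_len(n), seq_len(n), function(y, x) {
    sqrt(((y - ctr) / 14)^2 + ((x - ctr) / 18)^2)
  })
  mask2d <- r <= 1

  ring <- ifelse(r > 2 / 3 & mask2d, 200, ifelse(mask2d, 20, 0))
  d <- plane_stack(mask2d, ring)
  crop <- list(
    stack = image_stack(
      array(d$channel, c(1, n, n, 1)), "LMNB1", c(1, 1, 1)
    ),
    mask = d$mask, label = 1L, offset = c(0L, 0L, 0L)
  )
  class(crop) <- "nucleus_crop"
  pr <- peripheral_central_summary(crop, "LMNB1")
  pooled <- pr[pr$vector_kind == "pooled", ]
  expect_gt(pooled$peripheral_mean, pooled$central_mean)

  blob <- ifelse(mask2d, 220 * pmax(1 - r, 0), 0)
  crop$stack <- image_stack(array(blob, c(1, n, n, 1)), "DAPI", c(1, 1, 1))
  pr <- peripheral_central_summary(crop, "DAPI")
  pooled <- pr[pr$vector_kind == "pooled", ]
  expect_gt(pooled$central_mean, pooled$peripheral_mean)

  crop$stack <- image_stack(array(0, c(1, n, n, 1)), "PMP22", c(1, 1, 1))
  pr <- peripheral_central_summary(crop, "PMP22")
  expect_true(all(pr$peripheral_mean == 0))
  expect_true(all(pr$central_mean == 0))
})

test_that("synthetic presets show the published polarity per channel", {
  sc <- generate_scene(genotype_preset("Wt", n_nuclei = 3, seed = 8))
  labs <- segment_nuclei(sc$stack)
  diffs <- sapply(c("DAPI", "H3K4m3", "PMP22", "LMNB1"), function(role) {
    mean(sapply(seq_len(max(labs)), function(l) {
      crop <- crop_nucleus(sc$stack, labs, l)
      pr <- peripheral_central_summary(crop, role)
      pooled <- pr[pr$vector_kind == "pooled", ]
      pooled$peripheral_mean - pooled$central_mean
    }))
  })
  expect_lt(diffs[["DAPI"]], 0) # chromatin is central-dominant
  expect_lt(diffs[["H3K4m3"]], 0)
  expect_gt(diffs[["PMP22"]], 0) # membrane-associated marks peripheral
  expect_gt(diffs[["LMNB1"]], 0)
})
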