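# Small synthetic fixtures shared across test files.

# A compact two-genotype-style config: few, small nuclei so scenes build in
# well under a second.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_nuclei = 2, volume_mean = 60, volume_sd = 5, noise_sd = 0,
         seed = 42),
    list(...)
  )
  do.call(synthetic_config, args)
}

# One uniform ellipsoid painted into an otherwise empty single-channel
# stack; returns the stack and the analytic volume.
ellipsoid_stack <- function(semi_um = c(2, 3, 6), level = 60,
                            voxel_size = c(0.5, 0.19, 0.19),
                            pad_px = 18) {
  ax_vox <- semi_um / voxel_size
  shape <- ceiling(2 * ax_vox) + 2 * pad_px
  ctr <- (shape - 1) / 2
  zz <- ((seq_len(shape[1]) - 1 - ctr[1]) / ax_vox[1])^2
  yy <- ((seq_len(shape[2]) - 1 - ctr[2]) / ax_vox[2])^2
  xx <- ((seq_len(shape[3]) - 1 - ctr[3]) / ax_vox[3])^2
  r2 <- outer(outer(zz, yy, `+`), xx, `+`)
  arr <- array(0, dim = c(shape, 1))
  arr[, , , 1][r2 <= 1] <- level
  list(
    stack = image_stack(arr, "DAPI", voxel_size),
    volume = 4 / 3 * pi * prod(semi_um)
  )
}

# Deterministic textured matrix for Costes tests: smoothed white noise, so
# different seeds give spatially structured but mutually independent images.
textured_image <- function(n = 64, seed = 7) {
  set.seed(seed)
  raw <- matrix(rnorm(n * n), n, n)
  k <- dnorm(-4:4, sd = 1.5)
  k <- k / sum(k)
  sm <- t(apply(raw, 1, function(v) stats::filter(v, k, circular = TRUE)))
  sm <- apply(sm, 2, function(v) stats::filter(v, k, circular = TRUE))
  100 + 30 * sm / sd(sm)
}
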