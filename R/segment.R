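#' Segmentation configuration
#'
#' Defaults follow the published protocol: a Gaussian blur of sigma 5 pixels
#' applied to a duplicate of the DAPI channel, then a fixed intensity band
#' of low 30 to high 255 on the blurred image. The blur is for mask-making
#' only; intensities are always measured on the raw channels. `min_voxels`
#' discards speckle components.
#'
#' @param blur_sigma Gaussian sigma in pixels, applied per z-plane.
#' @param low_threshold,high_threshold inclusive intensity band on the
#'   blurred image.
#' @param min_voxels smallest component kept, voxels.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(blur_sigma = 5,
                                low_threshold = 30,
                                high_threshold = 255,
                                min_voxels = 50) {
  if (blur_sigma < 0) abort("blur_sigma must be >= 0.")
  if (!(low_threshold >= 0 && low_threshold <= high_threshold &&
        high_threshold <= 255)) {
    abort("Need 0 <= low_threshold <= high_threshold <= 255.")
  }
  structure(
    list(
      blur_sigma = blur_sigma, low_threshold = low_threshold,
      high_threshold = high_threshold, min_voxels = as.integer(min_voxels)
    ),
    class = "segmentation_config"
  )
}

# Per-plane 2-D Gaussian blur of a (z, y, x) array: separable convolution
# with a +-3 sigma kernel; outside the image is treated as zero (dark
# background), matching how empty borders behave in the protocol.
blur_stack <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      m[cbind(i[ok], j[ok])] <- m[cbind(i[ok], j[ok])] + k[o + r + 1]
    }
    m
  }
  by <- band(dim(arr)[2])
  bx <- band(dim(arr)[3])
  out <- arr
  for (z in seq_len(dim(arr)[1])) {
    out[z, , ] <- by %*% arr[z, , ] %*% bx # bx symmetric
  }
  out
}

# 26-connected components of a 3-D logical array. Returns an integer array,
# labels 1..N in order of first (column-major) foreground voxel.
label_components_3d <- function(fg) {
  shp <- dim(fg)
  fg_lin <- which(fg)
  n_fg <- length(fg_lin)
  if (n_fg == 0L) return(array(0L, dim = shp))
  rank <- array(0L, dim = shp)
  rank[fg_lin] <- seq_len(n_fg)
  coords <- arrayInd(fg_lin, shp)
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  keep <- apply(offsets, 1, function(o) {
    o[3] > 0 || (o[3] == 0 && (o[2] > 0 || (o[2] == 0 && o[1] > 0)))
  })
  offsets <- offsets[keep, , drop = FALSE] # 13 half-neighbourhood offsets
  edges <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] &
      nb[, 2] >= 1 & nb[, 2] <= shp[2] &
      nb[, 3] >= 1 & nb[, 3] <= shp[3]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * shp[1] +
      (nb[ok, 3] - 1L) * shp[1] * shp[2]
    nb_rank <- rank[nb_lin]
    hit <- nb_rank > 0L
    edges[[k]] <- cbind(which(ok)[hit], nb_rank[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel components by first foreground voxel so labels are deterministic
  first <- tapply(seq_len(n_fg), memb, min)
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  out <- array(0L, dim = shp)
  out[fg_lin] <- relab[memb]
  out
}

#' Segment nuclei in 3D from the DAPI channel
#'
#' Blurs a duplicate of the DAPI channel (sigma `cfg$blur_sigma`, per
#' z-plane), keeps voxels whose blurred intensity lies in
#' `[low_threshold, high_threshold]`, labels 26-connected 3-D components,
#' and discards components smaller than `min_voxels`.
#'
#' @param stack an [image_stack()] with a DAPI channel.
#' @param cfg a [segmentation_config()].
#' @return Integer label map `(z, y, x)`; background 0, nuclei 1..N.
#' @export
#' @examples
#' sc <- generate_scene(synthetic_config(n_nuclei = 2, seed = 3))
#' labs <- segment_nuclei(sc$stack)
#' max(labs)
segment_nuclei <- function(stack, cfg = segmentation_config()) {
  dapi <- stack_channel(stack, "DAPI")
  blurred <- blur_stack(dapi, cfg$blur_sigma)
  fg <- blurred >= cfg$low_threshold & blurred <= cfg$high_threshold
  labs <- label_components_3d(fg)
  if (max(labs) > 0L && cfg$min_voxels > 1L) {
    sizes <- tabulate(labs[labs > 0L])
    keep <- which(sizes >= cfg$min_voxels)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    pos <- labs > 0L
    labs[pos] <- relab[labs[pos]]
  }
  labs
}

#' Volumes of labelled nuclei
#'
#' Volume is voxel count times the physical voxel volume
#' `dz * dy * dx` (um^3).
#'
#' @param labels integer label map from [segment_nuclei()].
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return Tibble with `label`, `voxel_count`, `volume`.
#' @export
compute_volumes <- function(labels, voxel_size = c(1.00, 0.379, 0.379)) {
  if (max(labels) == 0L) {
    abort("Label map contains no nuclei.")
  }
  counts <- tabulate(labels[labels > 0L])
  tibble::tibble(
    label = seq_along(counts),
    voxel_count = counts,
    volume = counts * prod(voxel_size)
  )
}

#' Per-nucleus records: volume, centroid and raw mean intensities
#'
#' Mean intensities are measured on the raw (unblurred) channels over the
#' nuclear mask, i.e. fluorescence intensity per nuclear area in arbitrary
#' units.
#'
#' @param stack an [image_stack()].
#' @param labels label map from [segment_nuclei()].
#' @return Tibble with one row per nucleus: `label`, `voxel_count`,
#'   `volume`, `centroid_z/y/x` (0-based voxel coordinates) and one
#'   `mean_<role>` column per declared channel role.
#' @export
measure_nuclei <- function(stack, labels) {
  vols <- compute_volumes(labels, stack$voxel_size)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  co <- arrayInd(idx, dim(labels))
  out <- vols
  out$centroid_z <- as.numeric(tapply(co[, 1] - 1, lab, mean))
  out$centroid_y <- as.numeric(tapply(co[, 2] - 1, lab, mean))
  out$centroid_x <- as.numeric(tapply(co[, 3] - 1, lab, mean))
  for (role in stack$channel_roles[!is.na(stack$channel_roles)]) {
    ch <- stack_channel(stack, role)
    out[[paste0("mean_", role)]] <- as.numeric(tapply(ch[idx], lab, mean))
  }
  out
}

#' Crop one nucleus and clear extranuclear signal
#'
#' Crops the bounding box of a nucleus (plus `margin` voxels) and zeroes
#' every channel outside the nuclear mask, mirroring the protocol of
#' transferring the nuclear ROI onto each channel and clearing outside it.
#'
#' @param stack an [image_stack()].
#' @param labels label map from [segment_nuclei()].
#' @param label nucleus id to crop.
#' @param margin extra voxels kept around the bounding box (in y/x and z).
#' @return A `nucleus_crop`: list with `stack` (cropped [image_stack()],
#'   cleared outside the mask), `mask` (3-D logical), `label` and `offset`
#'   (0-based (z, y, x) of the crop origin in the parent stack).
#' @export
crop_nucleus <- function(stack, labels, label, margin = 2L) {
  idx <- which(labels == label)
  if (!length(idx)) abort(sprintf("No nucleus with label %s.", label))
  co <- arrayInd(idx, dim(labels))
  lo <- pmax(apply(co, 2, min) - margin, 1L)
  hi <- pmin(apply(co, 2, max) + margin, dim(labels))
  sub <- stack$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
  mask <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == label
  dim(mask) <- dim(sub)[1:3]
  for (ch in seq_len(dim(sub)[4])) {
    plane <- sub[, , , ch, drop = FALSE]
    dim(plane) <- dim(mask)
    plane[!mask] <- 0
    sub[, , , ch] <- plane
  }
  structure(
    list(
      stack = image_stack(sub, stack$channel_roles, stack$voxel_size),
      mask = mask,
      label = label,
      offset = as.integer(lo) - 1L
    ),
    class = "nucleus_crop"
  )
}
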