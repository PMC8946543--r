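#' Multi-channel confocal image stack
#'
#' An `image_stack` bundles a 4-D intensity array indexed `(z, y, x, channel)`
#' on the 8-bit scale `[0, 255]` with its physical voxel size and the
#' biological role of each channel. All downstream stages (segmentation,
#' chromatin classification, profiling, colocalization) consume this
#' container.
#'
#' @param voxels numeric array with dimensions `(z, y, x, channel)`; values
#'   must lie in `[0, 255]`. A 3-D array is promoted to a single-channel
#'   stack.
#' @param channel_roles character vector naming each channel's role; one of
#'   `"DAPI"`, `"H3K4m3"`, `"PMP22"`, `"LMNB1"` (or `NA` for an unused
#'   channel). Roles must not repeat.
#' @param voxel_size numeric length-3 vector `(dz, dy, dx)` in micrometres;
#'   defaults to the acquisition value `c(1.00, 0.379, 0.379)`.
#'
#' @return An object of class `image_stack`: a list with elements `voxels`,
#'   `channel_roles` and `voxel_size`.
#' @export
#' @examples
#' arr <- array(0, dim = c(2, 8, 8, 1))
#' st <- image_stack(arr, channel_roles = "DAPI")
#' dim(st$voxels)
image_stack <- function(voxels,
                        channel_roles,
                        voxel_size = c(1.00, 0.379, 0.379)) {
  if (length(dim(voxels)) == 3L) {
    dim(voxels) <- c(dim(voxels), 1L)
  }
  if (length(dim(voxels)) != 4L) {
    abort("`voxels` must be a (z, y, x, channel) array.")
  }
  if (anyNA(voxels) || min(voxels) < 0 || max(voxels) > 255) {
    abort("Intensities must be finite and lie in [0, 255].")
  }
  if (length(channel_roles) != dim(voxels)[4]) {
    abort(sprintf(
      "Stack has %d channel(s) but %d role(s) were declared.",
      dim(voxels)[4], length(channel_roles)
    ))
  }
  known <- c("DAPI", "H3K4m3", "PMP22", "LMNB1")
  bad <- setdiff(channel_roles[!is.na(channel_roles)], known)
  if (length(bad)) {
    abort(sprintf("Unknown channel role(s): %s", paste(bad, collapse = ", ")))
  }
  declared <- channel_roles[!is.na(channel_roles)]
  if (anyDuplicated(declared)) {
    abort("Channel roles must be distinct.")
  }
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive numbers (dz, dy, dx) in um.")
  }
  structure(
    list(
      voxels = voxels,
      channel_roles = as.character(channel_roles),
      voxel_size = as.numeric(voxel_size)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d z-plane(s) x %d x %d px, %d channel(s)\n",
    d[1], d[2], d[3], d[4]
  ))
  cat("  roles     :", paste(x$channel_roles, collapse = ", "), "\n")
  cat(sprintf(
    "  voxel size: dz=%.3f dy=%.3f dx=%.3f um\n",
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

#' Extract one channel of a stack as a 3-D array
#'
#' @param stack an [image_stack()].
#' @param role channel role name (e.g. `"DAPI"`).
#' @return 3-D numeric array `(z, y, x)`.
#' @export
stack_channel <- function(stack, role) {
  idx <- match(role, stack$channel_roles)
  if (is.na(idx)) {
    abort(sprintf("Stack declares no %s channel.", role))
  }
  array(stack$voxels[, , , idx, drop = FALSE], dim = dim(stack$voxels)[1:3])
}

#' Read a multi-channel z-stack from TIFF
#'
#' Reads either one multi-page TIFF whose pages carry all channels as
#' samples-per-pixel, or one single-channel multi-page TIFF per element of
#' `path` (channels supplied as separate files). Inputs of bit depth greater
#' than 8 are max-normalized onto `[0, 255]`; 8-bit inputs pass through
#' unchanged.
#'
#' @param path character vector of TIFF file path(s); length 1 for a
#'   channel-interleaved file, length `n_channels` for per-channel files.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_stack <- function(path,
                       channel_roles,
                       voxel_size = c(1.00, 0.379, 0.379)) {
  for (p in path) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  # planes come back normalized to [0, 1]; rescale by the recorded bit
  # depth, then max-normalize anything deeper than 8 bit onto [0, 255]
  read_planes <- function(p) {
    pl <- suppressWarnings(tiff::readTIFF(p, all = TRUE, info = TRUE))
    bps <- attr(pl[[1]], "bits.per.sample") %||% 8L
    pl <- lapply(pl, function(m) {
      m <- m * (2^bps - 1)
      if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
      m
    })
    attr(pl, "bps") <- bps
    pl
  }
  if (length(path) == 1L) {
    planes <- read_planes(path)
    nc <- dim(planes[[1]])[3]
    arr <- array(0, dim = c(length(planes), dim(planes[[1]])[1:2], nc))
    for (z in seq_along(planes)) arr[z, , , ] <- planes[[z]]
  } else {
    per_chan <- lapply(path, read_planes)
    nz <- length(per_chan[[1]])
    hw <- dim(per_chan[[1]][[1]])[1:2]
    arr <- array(0, dim = c(nz, hw, length(path)))
    for (ch in seq_along(per_chan)) {
      if (length(per_chan[[ch]]) != nz) {
        abort("Per-channel TIFFs must share the same number of planes.")
      }
      for (z in seq_len(nz)) arr[z, , , ch] <- per_chan[[ch]][[z]][, , 1]
    }
  }
  if (max(arr) > 255) {
    arr <- arr / max(arr) * 255
  }
  arr <- clip8(arr)
  image_stack(arr, channel_roles = channel_roles, voxel_size = voxel_size)
}

#' Write an image stack (or label map) to TIFF
#'
#' Multi-channel stacks are written as one page per z-plane with channels as
#' samples-per-pixel (at most 4 channels). Integer label maps are written as
#' 16-bit single-channel pages so up to 65535 nuclei round-trip.
#'
#' @param stack an [image_stack()] or a 3-D integer array (label map).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (inherits(stack, "image_stack")) {
    arr <- stack$voxels / 255
    pages <- lapply(seq_len(dim(arr)[1]), function(z) {
      m <- arr[z, , , , drop = FALSE]
      dim(m) <- dim(arr)[2:4]
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    arr <- stack / 65535
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write per-nucleus results to CSV
#'
#' Writes one row per nucleus with a deterministic column order (columns in
#' their order of first appearance). Missing values (e.g. a Costes test that
#' was skipped) are written as empty cells so that a read back with
#' [read_results()] reproduces the table, missingness included.
#'
#' @param records a data frame of per-nucleus rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  records <- tibble::as_tibble(records)
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return A tibble; empty cells become `NA`.
#' @export
read_results <- function(path) {
  readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE)
}
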