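#' Trace a longitudinal or transverse vector through a nucleus plane
#'
#' Reproduces the line-profile step deterministically: within one z-plane of
#' the nuclear mask, a line is anchored at the in-plane centroid and
#' directed along the mask's principal axis (`"longitudinal"`) or its
#' perpendicular (`"transverse"`). Intensities are sampled at 1-pixel steps,
#' clipped to the contiguous run of in-mask pixels through the centroid.
#'
#' @param channel 3-D numeric array `(z, y, x)` of the channel to sample
#'   (cleared outside the nucleus).
#' @param mask 3-D logical nuclear mask of the same shape.
#' @param kind `"longitudinal"` or `"transverse"`.
#' @param z 1-based plane index.
#' @return Tibble with `position` (pixel offset along the line, centred at
#'   0) and `intensity`, ordered along the line.
#' @export
trace_vector <- function(channel, mask,
                         kind = c("longitudinal", "transverse"), z) {
  kind <- match.arg(kind)
  if (z < 1L || z > dim(mask)[1]) {
    abort(sprintf("Plane %d outside the mask stack.", z))
  }
  m2 <- mask[z, , ]
  if (!any(m2)) abort(sprintf("Plane %d holds no mask voxels.", z))
  co <- which(m2, arr.ind = TRUE) # (y, x)
  ctr <- colMeans(co)
  dir <- principal_axis(co)
  if (kind == "transverse") dir <- c(-dir[2], dir[1])
  half <- max(dim(m2))
  ts <- -half:half
  ys <- round(ctr[1] + ts * dir[1])
  xs <- round(ctr[2] + ts * dir[2])
  ok <- ys >= 1 & ys <= nrow(m2) & xs >= 1 & xs <= ncol(m2)
  inside <- ok
  inside[ok] <- m2[cbind(ys[ok], xs[ok])]
  # contiguous in-mask run through the centre sample
  centre_i <- which(ts == 0)
  if (!inside[centre_i]) {
    # centroid pixel can fall outside a concave mask; fall back to the
    # nearest in-mask sample on the line
    if (!any(inside)) abort("Vector does not intersect the mask.")
    centre_i <- which(inside)[which.min(abs(ts[inside]))]
  }
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run_i <- which(starts <= centre_i & ends >= centre_i)
  sel <- starts[run_i]:ends[run_i]
  ch2 <- channel[z, , ]
  tibble::tibble(
    position = ts[sel],
    intensity = ch2[cbind(ys[sel], xs[sel])]
  )
}

# First principal axis (unit vector) of a set of (y, x) pixel coordinates.
principal_axis <- function(co) {
  cc <- sweep(co, 2, colMeans(co))
  if (nrow(co) < 3L || all(abs(cc) < .Machine$double.eps)) {
    return(c(0, 1))
  }
  ev <- eigen(crossprod(cc) / nrow(co), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v # fix sign, determinism
  v
}

#' Assign ordered line samples to peripheral and central sectors
#'
#' Transverse vectors are split into three equal-length sectors: the middle
#' third is central, the two distal thirds peripheral. Longitudinal vectors
#' are split into four quarters: the two middle quarters are central, the
#' two distal quarters peripheral. Remainder samples under integer division
#' are spread so no sector deviates by more than one sample: a single
#' transverse leftover widens the central third, two go one to each distal
#' third; longitudinal leftovers fill the distal quarters first.
#'
#' @param samples numeric vector of intensities ordered along the line.
#' @param kind `"longitudinal"` or `"transverse"`.
#' @return List with `peripheral` and `central` intensity vectors.
#' @export
#' @examples
#' sector_assign(1:9, "transverse")$central # samples 4..6
#' sector_assign(1:8, "longitudinal")$peripheral # samples 1,2,7,8
sector_assign <- function(samples, kind = c("longitudinal", "transverse")) {
  kind <- match.arg(kind)
  n <- length(samples)
  if (n < 4L) abort("Need at least 4 samples along the vector.")
  if (kind == "transverse") {
    # one leftover goes to the central third; two go one to each distal third
    side <- n %/% 3L + (n %% 3L == 2L)
    idx_per <- c(seq_len(side), seq.int(n - side + 1L, n))
  } else {
    # leftovers fill the distal quarters first, then the central pair
    quarter <- n %/% 4L
    rem <- n %% 4L
    left <- quarter + (rem >= 1L)
    right <- quarter + (rem >= 2L)
    idx_per <- c(seq_len(left), seq.int(n - right + 1L, n))
  }
  list(
    peripheral = samples[idx_per],
    central = samples[-idx_per]
  )
}

#' Peripheral-versus-central summary for one nucleus and channel
#'
#' Traces longitudinal and transverse vectors on every z-plane of the
#' nuclear mask (planes with at least 4 in-mask samples), sectors each
#' vector, and pools the raw peripheral and central intensity values across
#' planes and vector kinds.
#'
#' @param crop a `nucleus_crop` from [crop_nucleus()].
#' @param channel_role channel to profile (e.g. `"PMP22"`).
#' @param kinds vector kinds to pool (default both).
#' @return Tibble with one row per vector kind plus a `"pooled"` row:
#'   `channel_role`, `vector_kind`, `n_peripheral`, `n_central`,
#'   `peripheral_mean`, `central_mean`.
#' @export
peripheral_central_summary <- function(crop, channel_role,
                                       kinds = c(
                                         "longitudinal", "transverse"
                                       )) {
  ch <- stack_channel(crop$stack, channel_role)
  mask <- crop$mask
  acc <- list()
  for (kind in kinds) {
    per <- numeric()
    cen <- numeric()
    for (z in seq_len(dim(mask)[1])) {
      if (sum(mask[z, , ]) < 8L) next # cap planes carry too few pixels
      tr <- tryCatch(
        trace_vector(ch, mask, kind, z),
        error = function(e) NULL
      )
      if (is.null(tr) || nrow(tr) < 4L) next
      s <- sector_assign(tr$intensity, kind)
      per <- c(per, s$peripheral)
      cen <- c(cen, s$central)
    }
    acc[[kind]] <- tibble::tibble(
      channel_role = channel_role, vector_kind = kind,
      n_peripheral = length(per), n_central = length(cen),
      peripheral_mean = if (length(per)) mean(per) else 0,
      central_mean = if (length(cen)) mean(cen) else 0,
      peripheral_values = list(per), central_values = list(cen)
    )
  }
  out <- dplyr::bind_rows(acc)
  pooled_per <- unlist(out$peripheral_values)
  pooled_cen <- unlist(out$central_values)
  pooled <- tibble::tibble(
    channel_role = channel_role, vector_kind = "pooled",
    n_peripheral = length(pooled_per), n_central = length(pooled_cen),
    peripheral_mean = if (length(pooled_per)) mean(pooled_per) else 0,
    central_mean = if (length(pooled_cen)) mean(pooled_cen) else 0,
    peripheral_values = list(pooled_per), central_values = list(pooled_cen)
  )
  dplyr::bind_rows(out, pooled)
}
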