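#' Configuration for a synthetic nuclei scene
#'
#' Describes one field of view of ellipsoidal Schwann-cell-like nuclei with
#' four channels (DAPI, H3K4m3, PMP22, Lamin B1) and full ground truth, used
#' to exercise segmentation, chromatin classification, spatial profiling and
#' colocalization without microscope data.
#'
#' Intensity model, per nucleus voxel at normalized elliptical radius
#' `r` (0 at the centre, 1 at the surface):
#' * DAPI: euchromatic base `dapi_level` or heterochromatic
#'   `hc_dapi_level` (blob regions), both modulated by a mild parabolic
#'   central gradient so chromatin reads central-dominant along nuclear
#'   vectors, as observed for DAPI.
#' * H3K4m3: `h3k4m3_level` (with its own central gradient) on euchromatin,
#'   0 on heterochromatin.
#' * PMP22: `pmp22_nuclear_level` on a set of positive voxels;
#'   `coloc_fraction_pmp22_ec` / `coloc_fraction_pmp22_hc` of them are placed
#'   in euchromatin / heterochromatin, the remainder in DAPI-dim pockets
#'   (below the DAPI-light lower bound) so every ground-truth overlap
#'   fraction is realized exactly; a `peripheral_fraction_pmp22` share sits
#'   in the outer third of the normalized radius.
#' * Lamin B1: `lmnb1_level` on positive voxels, peripherally weighted by
#'   `peripheral_fraction_lmnb1`.
#'
#' Additive Gaussian read noise with sd `noise_sd` is applied to every
#' channel and the result clipped to `[0, 255]`.
#'
#' @param n_nuclei number of nuclei in the field.
#' @param genotype `"Wt"` or `"TrJ"` (a label carried into results).
#' @param volume_mean,volume_sd nuclear volume distribution, um^3.
#' @param pmp22_nuclear_level,lmnb1_level,dapi_level,h3k4m3_level mean 8-bit
#'   intensities of the respective signals (`dapi_level` is the euchromatic
#'   base; it must stay inside the DAPI-light band).
#' @param peripheral_fraction_pmp22,peripheral_fraction_lmnb1 fraction of
#'   positive voxels placed in the outer third of the normalized radius.
#' @param coloc_fraction_pmp22_ec,coloc_fraction_pmp22_hc fractions of
#'   PMP22-positive voxels placed in euchromatin / heterochromatin; their sum
#'   must not exceed 1.
#' @param hc_fraction fraction of nuclear voxels that are heterochromatic.
#' @param noise_sd Gaussian read-noise sd in intensity units.
#' @param seed integer RNG seed; identical seeds give bit-identical scenes.
#' @param voxel_size `(dz, dy, dx)` in um; the synthetic default samples
#'   finer than the panoramic acquisition grid (half-micron z-steps, about
#'   0.2 um in-plane, as used for cropped single-nucleus analysis) so that
#'   discretization error stays subordinate to the segmentation itself.
#' @param shape optional `(z, y, x)` stack shape in voxels; when omitted the
#'   scene is sized automatically to hold `n_nuclei` on a non-overlapping
#'   jittered grid.
#' @param axis_ratio relative ellipsoid semi-axes `(z, y, x)`; the default
#'   elongates nuclei in-plane as Schwann-cell nuclei are.
#' @param hc_blob_radius heterochromatin blob radius, voxels.
#' @param hc_dapi_level DAPI intensity of heterochromatin (must be in the
#'   DAPI-dark band).
#' @param dim_dapi_level DAPI intensity of the sub-threshold pockets hosting
#'   PMP22 voxels assigned to neither chromatin class.
#' @param pmp22_positive_fraction,lmnb1_positive_fraction fraction of nuclear
#'   voxels carrying each signal.
#' @param dapi_gradient,h3k4m3_gradient strength `g` of the central gradient
#'   multiplier `1 + g * (1 - 2 r^2)`.
#' @param hc_max_radius largest normalized radius heterochromatin may occupy
#'   (1 = anywhere in the nucleus).
#'
#' @return A `synthetic_config` list.
#' @seealso [genotype_preset()], [generate_scene()]
#' @export
synthetic_config <- function(n_nuclei = 12,
                             genotype = c("Wt", "TrJ"),
                             volume_mean = 250,
                             volume_sd = 38,
                             pmp22_nuclear_level = 80,
                             lmnb1_level = 150,
                             dapi_level = 55,
                             h3k4m3_level = 140,
                             peripheral_fraction_pmp22 = 0.80,
                             peripheral_fraction_lmnb1 = 0.85,
                             coloc_fraction_pmp22_ec = 0.85,
                             coloc_fraction_pmp22_hc = 0.05,
                             hc_fraction = 0.20,
                             noise_sd = 5,
                             seed = 1L,
                             voxel_size = c(0.50, 0.19, 0.19),
                             shape = NULL,
                             axis_ratio = c(1.4, 1.4, 3.5),
                             hc_blob_radius = 3,
                             hc_dapi_level = 160,
                             dim_dapi_level = 40,
                             pmp22_positive_fraction = 0.25,
                             lmnb1_positive_fraction = 0.20,
                             dapi_gradient = 0.25,
                             h3k4m3_gradient = 0.35,
                             hc_max_radius = 1) {
  genotype <- match.arg(genotype)
  cfg <- list(
    n_nuclei = as.integer(n_nuclei), genotype = genotype,
    volume_mean = volume_mean, volume_sd = volume_sd,
    pmp22_nuclear_level = pmp22_nuclear_level, lmnb1_level = lmnb1_level,
    dapi_level = dapi_level, h3k4m3_level = h3k4m3_level,
    peripheral_fraction_pmp22 = peripheral_fraction_pmp22,
    peripheral_fraction_lmnb1 = peripheral_fraction_lmnb1,
    coloc_fraction_pmp22_ec = coloc_fraction_pmp22_ec,
    coloc_fraction_pmp22_hc = coloc_fraction_pmp22_hc,
    hc_fraction = hc_fraction, noise_sd = noise_sd, seed = as.integer(seed),
    voxel_size = voxel_size, shape = shape, axis_ratio = axis_ratio,
    hc_blob_radius = hc_blob_radius, hc_dapi_level = hc_dapi_level,
    dim_dapi_level = dim_dapi_level,
    pmp22_positive_fraction = pmp22_positive_fraction,
    lmnb1_positive_fraction = lmnb1_positive_fraction,
    dapi_gradient = dapi_gradient, h3k4m3_gradient = h3k4m3_gradient,
    hc_max_radius = hc_max_radius
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  fr <- c(
    cfg$peripheral_fraction_pmp22, cfg$peripheral_fraction_lmnb1,
    cfg$coloc_fraction_pmp22_ec, cfg$coloc_fraction_pmp22_hc,
    cfg$hc_fraction, cfg$pmp22_positive_fraction, cfg$lmnb1_positive_fraction
  )
  if (any(fr < 0 | fr > 1)) abort("All fractions must lie in [0, 1].")
  if (cfg$coloc_fraction_pmp22_ec + cfg$coloc_fraction_pmp22_hc > 1 + 1e-12) {
    abort("coloc_fraction_pmp22_ec + coloc_fraction_pmp22_hc must be <= 1.")
  }
  lv <- c(
    cfg$pmp22_nuclear_level, cfg$lmnb1_level, cfg$dapi_level,
    cfg$h3k4m3_level, cfg$hc_dapi_level, cfg$dim_dapi_level
  )
  if (any(lv < 0 | lv > 255)) abort("Intensity levels must lie in [0, 255].")
  if (cfg$n_nuclei < 1) abort("Need at least one nucleus.")
  if (cfg$volume_mean <= 0 || cfg$volume_sd < 0) {
    abort("volume_mean must be positive and volume_sd non-negative.")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be non-negative.")
  invisible(cfg)
}

#' Genotype presets for the synthetic generator
#'
#' Encodes the qualitative wild-type versus Trembler-J contrasts: TrJ fields
#' hold more, smaller nuclei with higher nuclear PMP22 and overall DAPI,
#' lower H3K4m3 and Lamin B1, a larger heterochromatin fraction, and weaker
#' PMP22-euchromatin coupling.
#'
#' @param name `"Wt"` or `"TrJ"`.
#' @param ... overrides passed on to [synthetic_config()] (e.g. `n_nuclei`,
#'   `seed`, `noise_sd`).
#' @return A `synthetic_config`.
#' @export
#' @examples
#' wt <- genotype_preset("Wt")
#' trj <- genotype_preset("TrJ")
#' trj$volume_mean < wt$volume_mean
genotype_preset <- function(name, ...) {
  if (!name %in% c("Wt", "TrJ")) {
    abort(sprintf("Unknown genotype preset: %s", name))
  }
  base <- if (name == "Wt") {
    list(
      n_nuclei = 12, genotype = "Wt",
      volume_mean = 250, volume_sd = 38,
      pmp22_nuclear_level = 80, lmnb1_level = 150,
      dapi_level = 55, h3k4m3_level = 140, dapi_gradient = 0.25,
      coloc_fraction_pmp22_ec = 0.85, coloc_fraction_pmp22_hc = 0.05,
      hc_fraction = 0.20
    )
  } else {
    list(
      n_nuclei = 18, genotype = "TrJ",
      volume_mean = 160, volume_sd = 24,
      pmp22_nuclear_level = 120, lmnb1_level = 100,
      dapi_level = 58, h3k4m3_level = 100, dapi_gradient = 0.38,
      coloc_fraction_pmp22_ec = 0.70, coloc_fraction_pmp22_hc = 0.15,
      hc_fraction = 0.30
    )
  }
  do.call(synthetic_config, modifyList(base, list(...)))
}

# Semi-axes (um) of an ellipsoid with volume v and the given axis ratios.
ellipsoid_axes <- function(v, ratio) {
  s <- (3 * v / (4 * pi * prod(ratio)))^(1 / 3)
  s * ratio
}

#' Generate a ground-truthed synthetic scene
#'
#' Places `n_nuclei` axis-aligned ellipsoidal nuclei on a jittered grid (so
#' they can never overlap), paints the four channels according to the
#' configuration, adds clipped Gaussian read noise, and returns the stack
#' together with full ground truth.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements:
#'   * `stack`: the [image_stack()] (channels DAPI, H3K4m3, PMP22, LMNB1);
#'   * `truth`: a list with `labels` (3-D integer label map), `chromatin`
#'     (3-D integer map: 0 background, 1 euchromatin, 2 heterochromatin,
#'     3 DAPI-dim pocket), `pmp22`, `lmnb1` (3-D logical maps of true
#'     positive voxels), and `nuclei`, a tibble with one row per nucleus:
#'     label, centroid, semi-axes, analytic volume (um^3), voxel count, and
#'     realized overlap fractions `frac_pmp22_in_ec`, `frac_pmp22_in_hc`,
#'     `frac_pmp22_in_lmnb1`, `frac_hc`.
#' @export
#' @examples
#' sc <- generate_scene(synthetic_config(n_nuclei = 2, seed = 7))
#' sc$truth$nuclei$volume_true
generate_scene <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  vs <- cfg$voxel_size # (dz, dy, dx)
  n <- cfg$n_nuclei

  # worst-case extents drive the grid cell size
  vmax <- cfg$volume_mean + 3 * cfg$volume_sd
  ax_max <- ellipsoid_axes(vmax, cfg$axis_ratio)
  ext <- ceiling(ax_max / vs) # voxels per semi-axis (z, y, x)
  gap <- c(2L, 14L, 14L) # clearance so sigma-5 blur halos never merge
  cell <- 2L * ext + gap

  if (is.null(cfg$shape)) {
    gy <- ceiling(sqrt(n))
    gx <- ceiling(n / gy)
    grid <- c(1L, gy, gx)
    shape <- as.integer(cell * grid)
  } else {
    shape <- as.integer(cfg$shape)
    grid <- shape %/% cell
    if (prod(grid) < n) {
      abort(sprintf(
        "Cannot place %d nuclei without overlap in a %s stack (capacity %d).",
        n, paste(shape, collapse = "x"), prod(grid)
      ))
    }
  }

  labels <- array(0L, dim = shape)
  chrom <- array(0L, dim = shape)
  pmp22_pos <- array(FALSE, dim = shape)
  lmnb1_pos <- array(FALSE, dim = shape)
  dapi <- array(0, dim = shape)
  h3k <- array(0, dim = shape)
  pmp <- array(0, dim = shape)
  lmn <- array(0, dim = shape)

  cells <- which(array(TRUE, dim = grid), arr.ind = TRUE)[seq_len(n), ,
    drop = FALSE
  ]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- max(rnorm(1, cfg$volume_mean, cfg$volume_sd), 0.3 * cfg$volume_mean)
    ax <- ellipsoid_axes(v, cfg$axis_ratio) # um, (z, y, x)
    ax_vox <- ax / vs
    cell0 <- (cells[i, ] - 1L) * cell # 0-based cell origin
    slack <- pmax(cell / 2 - ax_vox - gap / 2, 0)
    centre <- cell0 + cell / 2 + runif(3, -1, 1) * slack # 0-based, voxels

    lo <- pmax(floor(centre - ax_vox), 0)
    hi <- pmin(ceiling(centre + ax_vox), shape - 1)
    zz <- lo[1]:hi[1]
    yy <- lo[2]:hi[2]
    xx <- lo[3]:hi[3]
    dz2 <- ((zz - centre[1]) / ax_vox[1])^2
    dy2 <- ((yy - centre[2]) / ax_vox[2])^2
    dx2 <- ((xx - centre[3]) / ax_vox[3])^2
    r2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    inside <- which(r2 <= 1)
    if (!length(inside)) next
    box_idx <- arrayInd(inside, dim(r2))
    gi <- cbind(
      zz[box_idx[, 1]] + 1L, yy[box_idx[, 2]] + 1L, xx[box_idx[, 3]] + 1L
    )
    lin <- gi[, 1] + (gi[, 2] - 1L) * shape[1] +
      (gi[, 3] - 1L) * shape[1] * shape[2]
    r <- sqrt(r2[inside])
    nvox <- length(lin)
    labels[lin] <- i

    # --- heterochromatin blobs, trimmed to the exact target count
    hc_target <- round(cfg$hc_fraction * nvox)
    hc_local <- logical(nvox)
    eligible <- r <= cfg$hc_max_radius
    guard <- 0L
    while (sum(hc_local) < hc_target && guard < 10L * nvox) {
      guard <- guard + 1L
      c_idx <- sample_n_of(which(eligible), 1)
      if (!length(c_idx)) c_idx <- sample.int(nvox, 1)
      d2 <- (gi[, 1] - gi[c_idx, 1])^2 + (gi[, 2] - gi[c_idx, 2])^2 +
        (gi[, 3] - gi[c_idx, 3])^2
      hc_local[d2 <= cfg$hc_blob_radius^2 & eligible] <- TRUE
    }
    if (sum(hc_local) > hc_target) {
      drop_n <- sum(hc_local) - hc_target
      on_idx <- which(hc_local)
      hc_local[sample(on_idx, drop_n)] <- FALSE
    }
    ec_local <- !hc_local

    # --- PMP22 placement with exact chromatin-class quotas
    np <- round(cfg$pmp22_positive_fraction * nvox)
    n_ec <- round(cfg$coloc_fraction_pmp22_ec * np)
    n_hc <- round(cfg$coloc_fraction_pmp22_hc * np)
    if (n_ec + n_hc > np) n_hc <- np - n_ec
    n_dim <- np - n_ec - n_hc
    peripheral <- r > 2 / 3
    pick_weighted <- function(pool, k, frac_per) {
      if (k <= 0 || !length(pool)) return(integer())
      k <- min(k, length(pool))
      kp <- round(k * frac_per)
      per <- pool[peripheral[pool]]
      cen <- pool[!peripheral[pool]]
      take_per <- sample_n_of(per, min(kp, length(per)))
      take_cen <- sample_n_of(cen, min(k - length(take_per), length(cen)))
      got <- c(take_per, take_cen)
      if (length(got) < k) {
        rest <- setdiff(pool, got)
        got <- c(got, sample_n_of(rest, k - length(got)))
      }
      got
    }
    ec_pool <- which(ec_local)
    hc_pool <- which(hc_local)
    p_ec <- pick_weighted(ec_pool, n_ec, cfg$peripheral_fraction_pmp22)
    p_hc <- pick_weighted(hc_pool, n_hc, cfg$peripheral_fraction_pmp22)
    dim_pool <- setdiff(ec_pool, p_ec)
    p_dim <- pick_weighted(dim_pool, n_dim, cfg$peripheral_fraction_pmp22)
    dim_local <- logical(nvox)
    dim_local[p_dim] <- TRUE
    ec_local[p_dim] <- FALSE
    p_all <- c(p_ec, p_hc, p_dim)

    # --- Lamin B1 placement (peripherally weighted, any chromatin class)
    nl <- round(cfg$lmnb1_positive_fraction * nvox)
    l_all <- pick_weighted(seq_len(nvox), nl, cfg$peripheral_fraction_lmnb1)

    # --- paint channels
    grad <- function(g) 1 + g * (1 - 2 * r^2)
    dapi_vals <- numeric(nvox)
    dapi_vals[ec_local] <- cfg$dapi_level * grad(cfg$dapi_gradient)[ec_local]
    dapi_vals[hc_local] <-
      cfg$hc_dapi_level * grad(cfg$dapi_gradient)[hc_local]
    dapi_vals[dim_local] <- cfg$dim_dapi_level
    h3k_vals <- numeric(nvox)
    h3k_vals[ec_local] <-
      cfg$h3k4m3_level * grad(cfg$h3k4m3_gradient)[ec_local]
    dapi[lin] <- dapi_vals
    h3k[lin] <- h3k_vals
    pmp[lin[p_all]] <- cfg$pmp22_nuclear_level
    lmn[lin[l_all]] <- cfg$lmnb1_level
    chrom[lin[ec_local]] <- 1L
    chrom[lin[hc_local]] <- 2L
    chrom[lin[dim_local]] <- 3L
    pmp22_pos[lin[p_all]] <- TRUE
    lmnb1_pos[lin[l_all]] <- TRUE

    n_p <- length(p_all)
    rows[[i]] <- tibble::tibble(
      label = i,
      genotype = cfg$genotype,
      centroid_z = centre[1], centroid_y = centre[2], centroid_x = centre[3],
      semi_z = ax[1], semi_y = ax[2], semi_x = ax[3],
      volume_true = 4 / 3 * pi * prod(ax),
      voxel_count = nvox,
      frac_hc = sum(hc_local) / nvox,
      frac_pmp22_in_ec = if (n_p) length(p_ec) / n_p else NA_real_,
      frac_pmp22_in_hc = if (n_p) length(p_hc) / n_p else NA_real_,
      frac_pmp22_in_lmnb1 =
        if (n_p) sum(p_all %in% l_all) / n_p else NA_real_
    )
  }

  add_noise <- function(a) {
    if (cfg$noise_sd > 0) a <- a + rnorm(length(a), 0, cfg$noise_sd)
    clip8(a)
  }
  voxels <- array(0, dim = c(shape, 4L))
  voxels[, , , 1] <- add_noise(dapi)
  voxels[, , , 2] <- add_noise(h3k)
  voxels[, , , 3] <- add_noise(pmp)
  voxels[, , , 4] <- add_noise(lmn)

  stack <- image_stack(
    voxels,
    channel_roles = c("DAPI", "H3K4m3", "PMP22", "LMNB1"),
    voxel_size = vs
  )
  list(
    stack = stack,
    truth = list(
      labels = labels, chromatin = chrom,
      pmp22 = pmp22_pos, lmnb1 = lmnb1_pos,
      nuclei = dplyr::bind_rows(rows)
    )
  )
}

# sample() without the length-1 surprise
sample_n_of <- function(x, k) {
  if (k <= 0 || !length(x)) return(integer())
  x[sample.int(length(x), k)]
}
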