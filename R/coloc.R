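#' Manders split co-occurrence coefficients
#'
#' `M1` is the fraction of the query channel's total intensity found at
#' voxels where the reference channel is positive; `M2` swaps the roles.
#' Binary masks are treated as 0/1 intensities, so on masks `M1` is the
#' fraction of reference-mask voxels inside the query mask's support
#' weighting aside, both coefficients reduce to voxel-overlap fractions.
#' Identical supports give `M1 = M2 = 1`; disjoint supports give 0. A
#' channel with zero total intensity makes the corresponding coefficient
#' undefined: it is returned as `NA` and flagged, never as 0.
#'
#' @param reference,query numeric arrays of identical shape, restricted to
#'   the nuclear ROI (zero outside).
#' @param partner_threshold a voxel counts as positive when its intensity is
#'   strictly above this value (default 0).
#' @param floor intensities at or below `floor` are zeroed in both channels
#'   before computing the sums; used to ignore a read-noise floor on signal
#'   channels (0 disables).
#' @return Tibble with `m1`, `m2`, and logical flags `m1_defined`,
#'   `m2_defined`.
#' @export
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' b <- matrix(c(0, 1, 1, 0), 2)
#' manders_pair(a, b) # partial overlap
manders_pair <- function(reference, query, partner_threshold = 0,
                         floor = 0) {
  if (!identical(dim(reference) %||% length(reference),
                 dim(query) %||% length(query))) {
    abort("reference and query must have identical shape.")
  }
  r <- as.numeric(reference)
  q <- as.numeric(query)
  if (floor > 0) {
    r[r <= floor] <- 0
    q[q <= floor] <- 0
  }
  if (all(r == 0) && all(q == 0)) {
    abort("Both channels are empty; Manders coefficients are undefined.")
  }
  sum_q <- sum(q)
  sum_r <- sum(r)
  m1 <- if (sum_q > 0) sum(q[r > partner_threshold]) / sum_q else NA_real_
  m2 <- if (sum_r > 0) sum(r[q > partner_threshold]) / sum_r else NA_real_
  tibble::tibble(
    m1 = m1, m2 = m2,
    m1_defined = !is.na(m1), m2_defined = !is.na(m2)
  )
}

# Shared guard for the rank correlations.
roi_values <- function(chan_a, chan_b, roi) {
  if (is.null(roi)) roi <- rep(TRUE, length(chan_a))
  a <- as.numeric(chan_a)[as.logical(roi)]
  b <- as.numeric(chan_b)[as.logical(roi)]
  if (length(a) < 3L) abort("Need at least 3 voxels in the ROI.")
  list(a = a, b = b)
}

#' Spearman rank correlation over an ROI
#'
#' Ties receive average ranks. A constant channel makes the coefficient
#' undefined (`NA`).
#'
#' @param chan_a,chan_b numeric arrays of identical shape.
#' @param roi optional logical array selecting the voxels to correlate.
#' @return Numeric `rho` in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(chan_a, chan_b, roi = NULL) {
  v <- roi_values(chan_a, chan_b, roi)
  if (sd(v$a) == 0 || sd(v$b) == 0) return(NA_real_)
  cor(v$a, v$b, method = "spearman")
}

#' Kendall tau-b rank correlation over an ROI
#'
#' Tie-corrected tau-b, computed by Knight's O(n log n)
#' sort-and-merge-count algorithm (concordant/discordant pair counting with
#' tie normalization). A constant channel makes the coefficient undefined.
#'
#' @inheritParams spearman_rho
#' @return Numeric `tau` in `[-1, 1]`, or `NA` if undefined.
#' @export
kendall_taub <- function(chan_a, chan_b, roi = NULL) {
  v <- roi_values(chan_a, chan_b, roi)
  if (sd(v$a) == 0 || sd(v$b) == 0) return(NA_real_)
  taub_fast(v$a, v$b)
}

#' Costes randomization configuration
#'
#' @param block_size square block edge, pixels.
#' @param n_scrambles number of block scrambles (at least 20).
#' @param seed RNG seed for the scrambles.
#' @param pass_threshold percent above which colocalization is accepted as
#'   non-random (the conventional 95).
#' @return A `costes_config` list.
#' @export
costes_config <- function(block_size = 3L, n_scrambles = 100L, seed = 1L,
                          pass_threshold = 95) {
  if (block_size < 1L) abort("block_size must be >= 1.")
  if (n_scrambles < 20L) abort("Need at least 20 scrambles.")
  structure(
    list(
      block_size = as.integer(block_size),
      n_scrambles = as.integer(n_scrambles),
      seed = as.integer(seed), pass_threshold = pass_threshold
    ),
    class = "costes_config"
  )
}

#' Costes block-scrambling significance test
#'
#' Builds a null distribution for the observed correlation by tiling the
#' ROI bounding box into `block_size` squares, permuting the blocks of one
#' channel uniformly at random, and recording the correlation of each
#' scrambled image with the unscrambled partner. The result is the percent
#' of scrambles whose correlation falls below the observed one; values
#' above `pass_threshold` (95 by convention) indicate non-random
#' colocalization. The correlation is Spearman's rho, consistent with the
#' package's avoidance of Pearson on non-normal intensities (classical
#' Pearson available via `method`).
#'
#' @param chan_a,chan_b 2-D numeric matrices (one z-slice).
#' @param roi optional logical matrix; correlations are computed over ROI
#'   pixels only.
#' @param cfg a [costes_config()].
#' @param method correlation flavour, `"spearman"` (default) or
#'   `"pearson"`.
#' @return Percentage in `[0, 100]`.
#' @export
costes_test <- function(chan_a, chan_b, roi = NULL,
                        cfg = costes_config(),
                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(chan_a), ncol(chan_a))
  co <- which(roi, arr.ind = TRUE)
  if (!nrow(co)) abort("Empty ROI.")
  lo <- apply(co, 2, min)
  hi <- apply(co, 2, max)
  bs <- cfg$block_size
  ny <- hi[1] - lo[1] + 1L
  nx <- hi[2] - lo[2] + 1L
  nby <- ceiling(ny / bs)
  nbx <- ceiling(nx / bs)
  if (nby * nbx < 16L) {
    abort("ROI too small: need at least 16 scrambling blocks.")
  }
  corr <- function(a, b) {
    av <- a[roi]
    bv <- b[roi]
    if (sd(av) == 0 || sd(bv) == 0) return(NA_real_)
    cor(av, bv, method = method)
  }
  r_obs <- corr(chan_a, chan_b)
  if (is.na(r_obs)) abort("Observed correlation undefined (constant channel).")

  # block index (row-block, col-block) of every pixel in the bounding box
  sub_y <- lo[1]:hi[1]
  sub_x <- lo[2]:hi[2]
  by <- (seq_len(ny) - 1L) %/% bs
  bx <- (seq_len(nx) - 1L) %/% bs
  block_id <- outer(by, bx, function(i, j) i + j * nby) + 1L
  n_blocks <- nby * nbx
  # positions of each block's pixels (equal-size blocks permute cleanly;
  # edge blocks are permuted with the rest by cycling within the block)
  a_sub <- chan_a[sub_y, sub_x]
  split_pos <- split(seq_along(block_id), block_id)
  with_seed(cfg$seed, {
    below <- 0L
    for (s in seq_len(cfg$n_scrambles)) {
      perm <- sample.int(n_blocks)
      scr <- a_sub
      for (b in seq_len(n_blocks)) {
        src <- split_pos[[perm[b]]]
        dst <- split_pos[[b]]
        if (length(src) >= length(dst)) {
          scr[dst] <- a_sub[src[seq_along(dst)]]
        } else {
          scr[dst] <- a_sub[rep_len(src, length(dst))]
        }
      }
      full <- chan_a
      full[sub_y, sub_x] <- scr
      r_s <- corr(full, chan_b)
      if (!is.na(r_s) && r_s < r_obs) below <- below + 1L
    }
    100 * below / cfg$n_scrambles
  })
}

# pairing table: operands and representation per the published items (i)-(v)
coloc_pairing_table <- function() {
  tibble::tibble(
    pairing = c(
      "EC_vs_TC", "EC_vs_HC", "PMP22_vs_EC", "PMP22_vs_HC", "PMP22_vs_LMNB1"
    ),
    mode = c("signal", "mask", "signal", "mask", "signal"),
    ref = c("TC", "hc_dapi_dark", "PMP22", "pmp22", "PMP22"),
    query = c("H3K4m3", "ec_h3k4m3", "H3K4m3", "hc_dapi_dark", "LMNB1")
  )
}

#' Colocalization coefficients for the five channel pairings
#'
#' Computes, per z-slice of one cropped nucleus, the Manders split
#' coefficients and the Spearman and Kendall correlations for the five
#' pairings: (i) euchromatin signal vs total chromatin (DAPI signal on the
#' DAPI-light plus DAPI-dark area), (ii) euchromatin vs heterochromatin
#' masks, (iii) PMP22 vs euchromatin signals, (iv) PMP22 vs heterochromatin
#' masks, (v) PMP22 vs Lamin B1 signals. Per-nucleus values are the median
#' across slices; the Costes test runs once per pairing on the mid-slice.
#' In the Manders formulas the denominator names the normalizing channel:
#' for each pairing M1 normalizes by the query operand listed above and M2
#' by the reference.
#'
#' Signal-level Manders apply a noise floor equal to the chromatin config's
#' signal threshold; mask pairings use the raw 0/1 values.
#'
#' @param crop a `nucleus_crop` from [crop_nucleus()].
#' @param masks mask set from [chromatin_masks()].
#' @param chromatin_cfg the [chromatin_config()] used for the masks.
#' @param costes_cfg a [costes_config()]; set to `NULL` to skip the Costes
#'   test.
#' @param min_roi_voxels slices with fewer ROI voxels are skipped.
#' @return Tibble with one row per computable pairing: `label`, `pairing`,
#'   `m1`, `m2`, `rho`, `tau`, `costes_p`, `n_slices`.
#' @export
coloc_pairings <- function(crop, masks,
                           chromatin_cfg = chromatin_config(),
                           costes_cfg = costes_config(),
                           min_roi_voxels = 10L) {
  stack <- crop$stack
  roi <- crop$mask
  roles <- stack$channel_roles
  tc_mask <- masks$ec_dapi_light | masks$hc_dapi_dark

  get_operand <- function(name, mode) {
    if (mode == "mask") {
      return(masks[[name]] * 1)
    }
    if (name == "TC") {
      return(stack_channel(stack, "DAPI") * tc_mask)
    }
    stack_channel(stack, name)
  }

  tab <- coloc_pairing_table()
  out <- vector("list", nrow(tab))
  nz <- dim(roi)[1]
  mid <- stats::median(which(apply(roi, 1, any)))
  mid <- floor(mid)

  for (k in seq_len(nrow(tab))) {
    mode <- tab$mode[k]
    needed_roles <- intersect(c(tab$ref[k], tab$query[k]), c(
      "DAPI", "H3K4m3", "PMP22", "LMNB1"
    ))
    if (mode == "signal") {
      if (tab$ref[k] == "TC") needed_roles <- union(needed_roles, "DAPI")
      if (!all(needed_roles %in% roles)) next
    } else if (is.null(masks[[tab$ref[k]]]) || is.null(masks[[tab$query[k]]])) {
      next
    }
    ref <- get_operand(tab$ref[k], mode)
    qry <- get_operand(tab$query[k], mode)
    floor_v <- if (mode == "signal") chromatin_cfg$signal_threshold else 0

    m1s <- m2s <- rhos <- taus <- rep(NA_real_, nz)
    used <- 0L
    for (z in seq_len(nz)) {
      sl_roi <- roi[z, , ]
      if (sum(sl_roi) < min_roi_voxels) next
      r2 <- ref[z, , ]
      q2 <- qry[z, , ]
      if (all(r2 == 0) && all(q2 == 0)) next
      mm <- tryCatch(
        manders_pair(r2, q2, floor = floor_v),
        error = function(e) tibble::tibble(m1 = NA_real_, m2 = NA_real_)
      )
      m1s[z] <- mm$m1
      m2s[z] <- mm$m2
      rhos[z] <- spearman_rho(r2, q2, sl_roi)
      taus[z] <- kendall_taub(r2, q2, sl_roi)
      used <- used + 1L
    }
    if (!used) next
    cp <- NA_real_
    if (!is.null(costes_cfg)) {
      cp <- tryCatch(
        costes_test(ref[mid, , ], qry[mid, , ], roi[mid, , ], costes_cfg),
        error = function(e) NA_real_
      )
    }
    out[[k]] <- tibble::tibble(
      label = crop$label,
      pairing = tab$pairing[k],
      m1 = median(m1s, na.rm = TRUE),
      m2 = median(m2s, na.rm = TRUE),
      rho = median(rhos, na.rm = TRUE),
      tau = median(taus, na.rm = TRUE),
      costes_p = cp,
      n_slices = used
    )
  }
  dplyr::bind_rows(out)
}
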