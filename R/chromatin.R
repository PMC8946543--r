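#' Chromatin classification configuration
#'
#' Defaults follow the published DAPI intensity bands: DAPI-light
#' euchromatin at intensities in `[50, 150)` and DAPI-dark heterochromatin
#' in `[150, 255]`. Voxels below `light_min` belong to neither class.
#' Signal masks for H3K4m3/PMP22/LMNB1 use a fixed threshold by default
#' (inclusive, `signal_threshold`), or Otsu's method.
#'
#' @param dark_threshold lowest intensity classified heterochromatic.
#' @param light_min lowest intensity classified euchromatic.
#' @param dark_max highest heterochromatic intensity.
#' @param signal_mask_method `"fixed"` or `"otsu"`.
#' @param signal_threshold fixed threshold for signal masks (inclusive).
#' @return A `chromatin_config` list.
#' @export
chromatin_config <- function(dark_threshold = 150,
                             light_min = 50,
                             dark_max = 255,
                             signal_mask_method = c("fixed", "otsu"),
                             signal_threshold = 50) {
  if (!(light_min < dark_threshold && dark_threshold <= dark_max)) {
    abort("Need light_min < dark_threshold <= dark_max.")
  }
  structure(
    list(
      dark_threshold = dark_threshold, light_min = light_min,
      dark_max = dark_max,
      signal_mask_method = match.arg(signal_mask_method),
      signal_threshold = signal_threshold
    ),
    class = "chromatin_config"
  )
}

#' Classify nuclear DAPI voxels into eu- and heterochromatin
#'
#' A voxel is heterochromatic (DAPI-dark) iff its intensity lies in
#' `[dark_threshold, dark_max]` and euchromatic (DAPI-light) iff it lies in
#' `[light_min, dark_threshold)`; dimmer voxels belong to neither class.
#' Both comparisons are inclusive at their stated lower bounds.
#'
#' @param dapi numeric array (any shape) of DAPI intensities restricted to a
#'   nuclear ROI (extranuclear voxels must already be 0 / excluded by
#'   `mask`).
#' @param cfg a [chromatin_config()].
#' @param mask optional logical array delimiting the nuclear ROI; voxels
#'   outside it are never classified.
#' @return List of two logical arrays, `ec` (DAPI-light) and `hc`
#'   (DAPI-dark), mutually exclusive by construction.
#' @export
#' @examples
#' strip <- matrix(0:255, nrow = 1)
#' cls <- classify_chromatin(strip)
#' min(strip[cls$hc]) # 150
#' min(strip[cls$ec]) # 50
classify_chromatin <- function(dapi, cfg = chromatin_config(), mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(dapi) %||% length(dapi))
  hc <- mask & dapi >= cfg$dark_threshold & dapi <= cfg$dark_max
  ec <- mask & dapi >= cfg$light_min & dapi < cfg$dark_threshold
  list(ec = ec, hc = hc)
}

#' Binarize a cleared signal channel
#'
#' Fixed thresholding keeps voxels at or above `signal_threshold`
#' (inclusive); Otsu's method computes the threshold from the within-ROI
#' intensity histogram. An all-zero channel under Otsu yields an empty mask
#' with a warning.
#'
#' @param channel numeric array of intensities, cleared outside the nucleus.
#' @param cfg a [chromatin_config()].
#' @param mask optional logical ROI array.
#' @return Logical array, `TRUE` on signal voxels; always a subset of
#'   `mask`.
#' @export
make_signal_mask <- function(channel, cfg = chromatin_config(), mask = NULL) {
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dim(channel) %||% length(channel))
  }
  if (cfg$signal_mask_method == "otsu") {
    vals <- channel[mask]
    if (all(vals == 0)) {
      warn("All-zero channel: Otsu mask is empty.")
      return(mask & FALSE)
    }
    thr <- EBImage::otsu(
      EBImage::Image(vals / 255, dim = c(length(vals), 1))
    ) * 255
    return(mask & channel > thr)
  }
  mask & channel >= cfg$signal_threshold
}

#' Build the full mask set for one cropped nucleus
#'
#' Classifies the DAPI channel into DAPI-light euchromatin and DAPI-dark
#' heterochromatin and binarizes the H3K4m3, PMP22 and Lamin B1 channels,
#' all restricted to the nuclear ROI.
#'
#' @param crop a `nucleus_crop` from [crop_nucleus()].
#' @param cfg a [chromatin_config()].
#' @return List of logical arrays `ec_dapi_light`, `hc_dapi_dark`,
#'   `ec_h3k4m3`, `pmp22`, `lmnb1` (entries present only for declared
#'   channels), plus the nuclear `roi`.
#' @export
chromatin_masks <- function(crop, cfg = chromatin_config()) {
  stack <- crop$stack
  roi <- crop$mask
  cls <- classify_chromatin(stack_channel(stack, "DAPI"), cfg, mask = roi)
  out <- list(
    ec_dapi_light = cls$ec,
    hc_dapi_dark = cls$hc,
    roi = roi
  )
  sig <- c(ec_h3k4m3 = "H3K4m3", pmp22 = "PMP22", lmnb1 = "LMNB1")
  for (nm in names(sig)) {
    if (sig[[nm]] %in% stack$channel_roles) {
      out[[nm]] <-
        make_signal_mask(stack_channel(stack, sig[[nm]]), cfg, mask = roi)
    }
  }
  out
}
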