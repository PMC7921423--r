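#' Parameters for condensate detection in fluorescence images
#'
#' The detection chain mirrors a standard particle-analysis macro:
#' Gaussian smoothing, local (adaptive mean) thresholding restricted to a
#' cell mask, connected-component labelling and a minimum-area filter.
#' The smoothing/threshold/area values are tuned on the synthetic spot
#' generator ([make_spot_image()]); they are deliberately exposed because
#' such parameters are instrument- and magnification-specific.
#'
#' @param sigma Gaussian smoothing sigma in px (> 0).
#' @param window Local-threshold window edge in px (odd, >= 3): a pixel is
#'   foreground when the smoothed value exceeds the mean over the
#'   `window x window` neighbourhood by more than `offset`.
#' @param offset Local-threshold offset in intensity units.
#' @param min_area Minimum particle area in px^2 (>= 1).
#' @param n_fields Fields imaged per sample in the in vitro assay.
#' @param bg_sigma Large-scale smoothing sigma (px) for the in vitro
#'   background correction (subtraction of a heavily blurred copy, the
#'   smoothing analogue of a rolling-ball correction).
#' @return A `quant_params` list.
#' @export
quant_params <- function(sigma = 1.5, window = 15L, offset = 0.02,
                         min_area = 4L, n_fields = 5L, bg_sigma = 24) {
  window <- as.integer(window)
  stopifnot(sigma > 0, window >= 3L, window %% 2L == 1L,
            min_area >= 1L, n_fields >= 1L, bg_sigma > 0)
  structure(list(sigma = sigma, window = window, offset = offset,
                 min_area = as.integer(min_area),
                 n_fields = as.integer(n_fields), bg_sigma = bg_sigma),
            class = "quant_params")
}

#' Detect condensates in a single fluorescence image
#'
#' Gaussian smoothing, local mean thresholding restricted to the cell
#' mask, 4-connected labelling and a minimum-area filter. An image with no
#' signal above the local threshold yields a count of 0 (not an error).
#'
#' @param image Numeric matrix (single-channel intensities).
#' @param mask Logical matrix of the same dimensions delimiting the cell
#'   (ROI); `NULL` uses the whole frame.
#' @param params A [quant_params()].
#' @return List: `count`, `areas` (px^2 per particle), `total_intensity`
#'   (sum of `image` over detected particles), `labels` (label matrix).
#' @export
detect_condensates <- function(image, mask = NULL, params = quant_params()) {
  image <- as.matrix(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- as.matrix(mask) > 0
  if (!all(dim(mask) == dim(image)))
    stop("image and mask dimensions differ")
  if (!any(mask)) stop("empty mask")

  smooth <- as.matrix(EBImage::gblur(image, sigma = params$sigma))
  half <- (params$window - 1L) / 2L
  binary <- as.matrix(EBImage::thresh(smooth, w = half, h = half,
                                      offset = params$offset)) > 0
  binary <- binary & mask
  labels <- as.matrix(EBImage::bwlabel(binary))
  sizes <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  qualify <- which(sizes >= params$min_area)
  keep <- labels %in% qualify & labels > 0
  relabel <- labels
  relabel[!keep] <- 0L
  areas <- sizes[qualify]
  list(count = length(qualify),
       areas = as.integer(areas),
       total_intensity = sum(image[keep]),
       labels = relabel)
}

#' Quantify in vitro condensation from field images
#'
#' Per field: background correction by subtracting a heavily smoothed copy
#' of the image (removing any image-wide offset and slowly varying
#' background), particle detection on the corrected image, and the total
#' corrected intensity over detected particles. The sample amount is the
#' mean of the per-field totals (default five fields per sample).
#'
#' @param fields List of numeric matrices (one per imaged field).
#' @param params A [quant_params()].
#' @return List: `amount` (mean total particle intensity across fields),
#'   `field_totals`, `field_counts`.
#' @export
quantify_invitro <- function(fields, params = quant_params()) {
  stopifnot(length(fields) >= 1L)
  totals <- numeric(length(fields))
  counts <- integer(length(fields))
  for (i in seq_along(fields)) {
    img <- as.matrix(fields[[i]])
    # cap the blur kernel so it always fits inside the field
    radius <- min(2L * ceiling(3 * params$bg_sigma) + 1L,
                  (min(dim(img)) %/% 2L) * 2L - 1L)
    bg <- as.matrix(EBImage::gblur(img, sigma = params$bg_sigma,
                                   radius = radius))
    corrected <- pmax(img - bg, 0)
    det <- detect_condensates(corrected, mask = NULL, params = params)
    totals[i] <- det$total_intensity
    counts[i] <- det$count
  }
  list(amount = mean(totals), field_totals = totals, field_counts = counts)
}

#' Normalize sample amounts to an internal standard
#'
#' Each sample amount is divided by the amount of the internal-standard
#' sample measured in the same experiment; optionally the standardized
#' values are further divided by the mean of the control samples, putting
#' different constructs/experiments on a common relative scale.
#'
#' @param amounts Numeric vector of sample amounts.
#' @param standard Amount of the internal standard (> 0).
#' @param control_mean Optional mean of standardized control samples
#'   (> 0) for the second normalization.
#' @return Numeric vector of relative amounts.
#' @export
normalize_to_standard <- function(amounts, standard, control_mean = NULL) {
  if (standard <= 0) stop("internal standard amount must be positive")
  out <- amounts / standard
  if (!is.null(control_mean)) {
    if (control_mean <= 0) stop("control mean must be positive")
    out <- out / control_mean
  }
  out
}

#' Trim extreme per-cell values
#'
#' The shared extreme-outlier rule ([trim_extreme()]) applied to a vector
#' of per-cell quantities (e.g. condensate counts per cell).
#'
#' @inheritParams trim_extreme
#' @return As [trim_extreme()].
#' @export
trim_extreme_values <- function(x, k = 5) trim_extreme(x, k = k)

#' Read a single-channel TIFF image as a matrix
#'
#' @param file Path to a TIFF file.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF files requires the 'tiff' package")
  img <- tiff::readTIFF(file)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
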