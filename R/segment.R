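#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling; eight-way connectivity by default, as used
#' for both the macrovessel area filter and the optically hollow disc.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  storage.mode(mask) <- "logical"
  .label_components_cpp(mask, as.integer(connectivity))
}

# 3x3 square structuring element morphology, vectorised via shifted copies.
# Outside-of-frame pixels are background (FALSE).
shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

erode3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_mask(m, dr, dc)
  }
  out
}

dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mask(m, dr, dc)
  }
  out
}

#' Morphological opening / closing with a 3x3 square element
#'
#' The smallest kernel that removes single-pixel noise without merging
#' capillaries; one iteration each, as used in [macrovessel_mask()].
#'
#' @param mask logical matrix.
#' @return Logical matrix.
#' @export
morph_open <- function(mask) dilate3(erode3(mask))

#' @rdname morph_open
#' @export
morph_close <- function(mask) erode3(dilate3(mask))

#' Global histogram equalization to the full 8-bit range
#'
#' Intensities are binned to 256 levels and remapped through the cumulative
#' histogram so the output spreads over `[0, 255]`. A constant image has no
#' equalizable contrast and maps to all zeros.
#'
#' @param img numeric matrix with intensities in `[0, 255]`.
#' @return Numeric matrix of equalized intensities in `[0, 255]`.
#' @export
equalize_hist <- function(img) {
  v <- round(pmin(pmax(img, 0), 255))
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h) / length(v)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min >= 1) return(matrix(0, nrow(img), ncol(img)))
  lut <- round(255 * (cdf - cdf_min) / (1 - cdf_min))
  lut <- pmin(pmax(lut, 0), 255)
  matrix(lut[v + 1L], nrow(img), ncol(img))
}

#' Segment the macrovasculature from the superficial layer
#'
#' Candidate pixels are those strictly above the given intensity percentile
#' of the image histogram (percentiles by linear interpolation between order
#' statistics). The strict inequality is the tie rule for degenerate images:
#' a constant image (or a constant background whose value equals the
#' percentile) yields an empty mask rather than flooding, while for
#' continuous intensities it coincides with the `>=` reading. The candidate
#' image is denoised by a morphological opening followed by a closing (3x3
#' square, one iteration each), and 8-connected components smaller than the
#' area threshold are removed, leaving macrovasculature only.
#'
#' The 250 px default area threshold is calibrated to a 245 x 245 grid and is
#' rescaled by `image_area / prod(ref_size)` for other grid sizes, since an
#' area cutoff is resolution-bound.
#'
#' @param superficial numeric matrix, the superficial-plexus en-face image.
#' @param percentile intensity percentile defining the threshold (default 88,
#'   i.e. the upper 88th percentile).
#' @param min_area_px minimum surviving component area at the reference grid
#'   size (default 250).
#' @param ref_size grid size the area threshold is calibrated to.
#' @return Logical matrix marking macrovessel pixels.
#' @export
macrovessel_mask <- function(superficial, percentile = 88,
                             min_area_px = 250L, ref_size = c(245L, 245L)) {
  stopifnot(is.matrix(superficial), length(superficial) > 0)
  assert_scalar_num(percentile, "percentile", lo = 0, hi = 100)
  thr <- quantile(superficial, percentile / 100, names = FALSE, type = 7)
  cand <- superficial > thr
  cand <- morph_close(morph_open(cand))
  min_area <- min_area_px * length(superficial) / prod(ref_size)
  lab <- label_components(cand, connectivity = 8L)
  k <- attr(lab, "n_components")
  if (k == 0L) return(cand)
  areas <- tabulate(lab[lab > 0], nbins = k)
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(superficial), ncol(superficial))
}

#' Optic nerve head optically hollow circle
#'
#' Bundles the disc segmentation as a circle: `center` is the centroid of
#' the largest dark component and `radius = sqrt(area / pi)`.
#'
#' @param center `(row, col)` in pixels.
#' @param radius positive radius in pixels.
#' @return An `onh_circle` object.
#' @export
onh_circle <- function(center, radius) {
  assert_scalar_num(radius, "radius", lo = .Machine$double.eps)
  structure(list(center = as.numeric(center), radius = radius),
            class = "onh_circle")
}

#' Segment the optic nerve head optically hollow area from the choroid
#'
#' The choroid image is histogram-equalized, thresholded at the given (lower)
#' percentile of the equalized intensities keeping the strictly darker
#' pixels (the strict inequality prevents a flat background tied with the
#' percentile value from flooding the mask), and all 8-connected components
#' except the largest are
#' discarded. The surviving component is summarized as a circle: centroid
#' center and radius `sqrt(area / pi)`.
#'
#' @param choroid numeric matrix, the choroid en-face image.
#' @param percentile lower percentile of the equalized histogram (default 40).
#' @return An [onh_circle()].
#' @export
onh_hollow_circle <- function(choroid, percentile = 40) {
  stopifnot(is.matrix(choroid), length(choroid) > 0)
  assert_scalar_num(percentile, "percentile", lo = 0, hi = 100)
  eq <- equalize_hist(choroid)
  thr <- quantile(eq, percentile / 100, names = FALSE, type = 7)
  cand <- eq < thr
  lab <- label_components(cand, connectivity = 8L)
  k <- attr(lab, "n_components")
  if (k == 0L) {
    stop("segmentation error: no optically hollow component found",
         call. = FALSE)
  }
  areas <- tabulate(lab[lab > 0], nbins = k)
  best <- which.max(areas)
  idx <- which(lab == best, arr.ind = TRUE)
  onh_circle(colMeans(idx)[c("row", "col")], sqrt(areas[best] / pi))
}
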