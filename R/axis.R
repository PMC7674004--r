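#' Panomap annotation: disc and fovea centroids
#'
#' Holds the two circle centroids delineated on a Panomap fundus image,
#' together with the eye laterality. Coordinates are `(row, col)` in pixels.
#'
#' @param disc_centroid,fovea_centroid numeric `(row, col)` pairs; must be
#'   distinct.
#' @param laterality `"OD"` or `"OS"`.
#' @param source_image optional H x W x 3 annotation image the centroids were
#'   detected on.
#' @param colors optional named character pair recording which annotation
#'   color marks which structure.
#' @return A `panomap_annotation` object.
#' @export
panomap_annotation <- function(disc_centroid, fovea_centroid,
                               laterality = c("OD", "OS"),
                               source_image = NULL, colors = NULL) {
  laterality <- match.arg(laterality)
  disc_centroid <- as.numeric(disc_centroid)
  fovea_centroid <- as.numeric(fovea_centroid)
  if (length(disc_centroid) != 2L || length(fovea_centroid) != 2L) {
    stop("centroids must be (row, col) pairs", call. = FALSE)
  }
  if (all(abs(disc_centroid - fovea_centroid) < 1e-9)) {
    stop("disc and fovea centroids must be distinct", call. = FALSE)
  }
  structure(list(disc_centroid = disc_centroid,
                 fovea_centroid = fovea_centroid,
                 laterality = laterality,
                 source_image = source_image,
                 colors = colors),
            class = "panomap_annotation")
}

#' Detect the annotated disc and fovea circle centroids
#'
#' Binarizes the Panomap around the device's pre-delineated circles (one
#' annotation color per structure), labels 8-connected components per color,
#' and returns the component centers of mass. Roles are assigned by color,
#' never by position. If a color yields several candidate components the
#' largest is kept with a warning; a color with no component at all is a
#' detection error.
#'
#' @param panomap_image H x W x 3 numeric array in `[0, 1]`.
#' @param laterality `"OD"` or `"OS"`.
#' @param colors named character pair among `"red"`, `"green"`, `"blue"`
#'   mapping the `disc` and `fovea` roles to channels.
#' @param threshold channel intensity above which a pixel counts as annotated.
#' @return A [panomap_annotation()].
#' @export
detect_circle_centroids <- function(panomap_image,
                                    laterality = c("OD", "OS"),
                                    colors = c(disc = "red", fovea = "green"),
                                    threshold = 0.5) {
  laterality <- match.arg(laterality)
  if (length(dim(panomap_image)) != 3L || dim(panomap_image)[3] < 3L) {
    stop("`panomap_image` must be an H x W x 3 array", call. = FALSE)
  }
  chan <- c(red = 1L, green = 2L, blue = 3L)
  centroid_for <- function(role) {
    ch <- chan[[colors[[role]]]]
    others <- setdiff(1:3, ch)
    m <- panomap_image[, , ch] > threshold &
      panomap_image[, , others[1]] <= threshold &
      panomap_image[, , others[2]] <= threshold
    lab <- label_components(m, connectivity = 8L)
    k <- attr(lab, "n_components")
    if (k < 1L) {
      stop("detection error: no ", colors[[role]], " annotation circle (",
           role, ") found", call. = FALSE)
    }
    if (k > 1L) {
      warning("multiple ", role, " circle candidates; keeping the largest",
              call. = FALSE)
    }
    areas <- tabulate(lab[lab > 0], nbins = k)
    best <- which.max(areas)
    idx <- which(lab == best, arr.ind = TRUE)
    colMeans(idx)[c("row", "col")]
  }
  panomap_annotation(centroid_for("disc"), centroid_for("fovea"),
                     laterality, source_image = panomap_image,
                     colors = colors)
}

#' Estimate the fovea-disc axis angle
#'
#' The angle alpha between the fovea and disc centroids, in degrees, used to
#' rotate sector masks to the zero-angle anatomical reference. Sign
#' convention: positive alpha means the fovea lies below the disc row in
#' image coordinates. For OS eyes the column difference is mirrored first so
#' that alpha is laterality-homologous (the same anatomical tilt gives the
#' same alpha in both eyes).
#'
#' @param ann a [panomap_annotation()].
#' @return A `fovea_disc_angle` object with fields `alpha_deg` and
#'   `laterality`.
#' @export
estimate_fovea_disc_angle <- function(ann) {
  stopifnot(inherits(ann, "panomap_annotation"))
  dy <- ann$fovea_centroid[1] - ann$disc_centroid[1]
  dx <- ann$fovea_centroid[2] - ann$disc_centroid[2]
  if (ann$laterality == "OS") dx <- -dx
  if (abs(dx) < 1e-12 && abs(dy) < 1e-12) {
    stop("coincident centroids: fovea-disc angle undefined", call. = FALSE)
  }
  fovea_disc_angle(atan2(dy, dx) * 180 / pi, ann$laterality)
}

#' @rdname estimate_fovea_disc_angle
#' @param alpha_deg angle in degrees, in `(-180, 180]`.
#' @param laterality `"OD"` or `"OS"`.
#' @export
fovea_disc_angle <- function(alpha_deg, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  assert_scalar_num(alpha_deg, "alpha_deg", lo = -180, hi = 180)
  structure(list(alpha_deg = alpha_deg, laterality = laterality),
            class = "fovea_disc_angle")
}

#' Rotate a binary mask to the zero-angle anatomical reference
#'
#' Rotates a mask (or every mask of a [build_roi_masks()] set) about `center`
#' by minus the fovea-disc axis angle, so that the anatomy aligns with the
#' zero-angle reference frame. OS masks are horizontally mirrored about the
#' center column before the rotation, making the two lateralities
#' anatomically homologous. Resampling is nearest-neighbour (binarity is
#' preserved); pixels rotated in from outside the frame are background.
#'
#' @param mask logical matrix, or a `roi_mask_set`.
#' @param angle a [fovea_disc_angle()] (or a plain number of degrees, taken
#'   as an OD angle).
#' @param center `(row, col)` rotation center, inside the mask grid.
#' @return Same type as `mask`.
#' @export
rotate_mask <- function(mask, angle, center) {
  if (is.numeric(angle)) angle <- fovea_disc_angle(angle, "OD")
  stopifnot(inherits(angle, "fovea_disc_angle"))
  if (inherits(mask, "roi_mask_set")) {
    out <- lapply(unclass(mask), rotate_mask, angle = angle, center = center)
    attributes(out) <- attributes(mask)
    return(out)
  }
  H <- nrow(mask); W <- ncol(mask)
  if (center[1] < 1 || center[1] > H || center[2] < 1 || center[2] > W) {
    stop("rotation `center` must lie inside the mask grid", call. = FALSE)
  }
  a <- angle$alpha_deg * pi / 180
  dr <- matrix(seq_len(H), H, W) - center[1]
  dc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  src_r <- dc * sin(a) + dr * cos(a)
  src_c <- dc * cos(a) - dr * sin(a)
  if (angle$laterality == "OS") src_c <- -src_c
  ri <- round(src_r + center[1])
  ci <- round(src_c + center[2])
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  out <- matrix(FALSE, H, W)
  out[ok] <- mask[cbind(ri[ok], ci[ok])]
  out
}
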