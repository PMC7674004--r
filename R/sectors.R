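#' Garway-Heath sector specification
#'
#' Angular widths of the six peripapillary sectors in the zero-angle OD
#' reference frame. Anatomical angle is measured from the disc-to-fovea
#' (temporal) direction, increasing through the superior sectors; the
#' temporal sector is centered on the fovea direction. The standard map is
#' temporal 90 degrees, ST/SN/IN/IT 40 degrees each, nasal 110 degrees; the
#' widths must cover 360 degrees exactly. Radii may be fixed here or derived
#' from the segmented disc in [build_roi_masks()].
#'
#' @param widths named numeric vector of angular widths in degrees for
#'   sectors `T`, `ST`, `SN`, `N`, `IN`, `IT`.
#' @param inner_radius,outer_radius optional fixed annulus radii in px;
#'   by default taken from the ONH circle and the image border.
#' @return A `sector_spec` object.
#' @export
sector_spec <- function(widths = c(T = 90, ST = 40, SN = 40, N = 110,
                                   IN = 40, IT = 40),
                        inner_radius = NULL, outer_radius = NULL) {
  need <- c("T", "ST", "SN", "N", "IN", "IT")
  if (!all(need %in% names(widths))) {
    stop("`widths` must name the six sectors T, ST, SN, N, IN, IT",
         call. = FALSE)
  }
  widths <- widths[need]
  if (any(widths <= 0) || abs(sum(widths) - 360) > 1e-9) {
    stop("sector widths must be positive and sum to 360 degrees",
         call. = FALSE)
  }
  structure(list(widths = widths, inner_radius = inner_radius,
                 outer_radius = outer_radius), class = "sector_spec")
}

# Anatomical polar angle in degrees, in [0, 360): 0 at the disc-to-fovea
# (temporal) direction, 90 at superior. `alpha_deg` is the subject's
# fovea-disc axis angle; OS columns are mirrored so sectors are homologous.
anatomical_angle <- function(rows, cols, center, alpha_deg, laterality) {
  dr <- rows - center[1]
  dc <- cols - center[2]
  if (laterality == "OS") dc <- -dc
  (atan2(-dr, dc) * 180 / pi + alpha_deg) %% 360
}

# Map anatomical angles to sector ids in octa_sectors()[1:6] order
# (ST, SN, N, IN, IT, T). Arcs are half-open [start, end).
sector_membership <- function(ang, spec = sector_spec()) {
  w <- spec$widths  # order T, ST, SN, N, IN, IT
  b <- (ang + w[["T"]] / 2) %% 360
  breaks <- cumsum(c(0, unname(w)))
  layout <- names(w)
  id_layout <- findInterval(as.vector(b), breaks, rightmost.closed = FALSE,
                            left.open = FALSE)
  id_layout[id_layout > 6L] <- 6L  # b == 360 cannot occur; guard fp edge
  lut <- match(layout, octa_sectors())
  matrix(lut[id_layout], nrow(ang), ncol(ang))
}

#' Build the seven Garway-Heath ROI masks
#'
#' Constructs the peripapillary annulus around the segmented optically hollow
#' disc and partitions it into the six Garway-Heath sectors plus the
#' circumpapillary union (CP). The inner radius is the disc radius; the outer
#' radius is the largest radius that keeps a full annulus inside the image
#' (the minimum distance from the disc center to any border), unless fixed in
#' the [sector_spec()]. Sector arcs are rotated by the fovea-disc axis angle
#' and mirrored for OS eyes; membership uses pixel centers with half-open arc
#' starts, so the six sector masks partition the CP annulus exactly.
#' Macrovessel and disc pixels are excluded later, in [compute_vim()].
#'
#' @param circle the [onh_circle()] of the optically hollow area.
#' @param angle a [fovea_disc_angle()] (or plain degrees, OD).
#' @param image_shape integer pair `(rows, cols)`.
#' @param spec a [sector_spec()].
#' @return A `roi_mask_set`: named list of 7 logical matrices (`ST`, `SN`,
#'   `N`, `IN`, `IT`, `T`, `CP`) with the construction parameters attached as
#'   attributes.
#' @export
build_roi_masks <- function(circle, angle, image_shape, spec = sector_spec()) {
  stopifnot(inherits(circle, "onh_circle"))
  if (is.numeric(angle)) angle <- fovea_disc_angle(angle, "OD")
  H <- image_shape[1]; W <- image_shape[2]
  cr <- circle$center[1]; cc <- circle$center[2]
  inner <- spec$inner_radius %||% circle$radius
  outer <- spec$outer_radius %||% min(cr - 1, H - cr, cc - 1, W - cc)
  if (outer <= inner) {
    stop("outer radius (", round(outer, 1), ") does not exceed inner radius (",
         round(inner, 1), "): disc too close to the image border",
         call. = FALSE)
  }
  rr <- matrix(seq_len(H), H, W)
  ccm <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (rr - cr)^2 + (ccm - cc)^2
  annulus <- d2 > inner^2 & d2 <= outer^2
  ang <- anatomical_angle(rr, ccm, circle$center, angle$alpha_deg,
                          angle$laterality)
  sid <- sector_membership(ang, spec)
  masks <- lapply(seq_len(6L), function(s) annulus & sid == s)
  names(masks) <- octa_sectors()[1:6]
  masks$CP <- annulus
  structure(masks, class = "roi_mask_set", circle = circle, angle = angle,
            spec = spec, inner_radius = inner, outer_radius = outer)
}

#' Microvascular intensity median (VIM) within an ROI
#'
#' Median pixel intensity over the ROI after excluding macrovessel pixels and
#' everything inside the optically hollow circle. The median (rather than the
#' mean) is robust to residual bright outliers. An ROI left empty after the
#' exclusions raises an error: silently imputing (e.g. zero) would mimic
#' disease.
#'
#' @param layer numeric matrix, one en-face layer image.
#' @param roi logical matrix, the ROI mask.
#' @param macro optional logical macrovessel mask to exclude.
#' @param onh optional [onh_circle()] to exclude.
#' @return The median intensity (numeric scalar, arbitrary units).
#' @export
compute_vim <- function(layer, roi, macro = NULL, onh = NULL) {
  stopifnot(is.matrix(layer), is.matrix(roi), all(dim(layer) == dim(roi)))
  eff <- roi
  if (!is.null(macro)) eff <- eff & !macro
  if (!is.null(onh)) {
    rr <- matrix(seq_len(nrow(layer)), nrow(layer), ncol(layer))
    cc <- matrix(seq_len(ncol(layer)), nrow(layer), ncol(layer), byrow = TRUE)
    inside <- (rr - onh$center[1])^2 + (cc - onh$center[2])^2 <= onh$radius^2
    eff <- eff & !inside
  }
  if (!any(eff)) {
    stop("undefined feature: ROI is empty after macrovessel/ONH exclusion",
         call. = FALSE)
  }
  median(layer[eff])
}

#' Extract the 42-dimensional VIM feature vector for one subject
#'
#' Runs the full per-subject image-processing chain: fovea-disc axis
#' estimation from the Panomap annotation, macrovessel segmentation anchored
#' on the superficial layer, optically hollow disc segmentation anchored on
#' the choroid, Garway-Heath ROI construction, and the VIM computation for
#' every (layer, sector) combination — 6 layers x 7 sectors = 42 features.
#'
#' @param stack an [layer_stack()] (`en_face_stack`).
#' @param panomap a [panomap_annotation()] for the same eye.
#' @param spec a [sector_spec()].
#' @param macro_percentile,min_area_px see [macrovessel_mask()].
#' @param onh_percentile see [onh_hollow_circle()].
#' @param subject_id,label,rnfl_um,vf_md_db optional metadata carried into
#'   the record.
#' @return A `feature_record`: list with the named 42-element `vim` vector
#'   (in [feature_columns()] order), metadata, and the segmentation
#'   provenance (`angle`, `onh_circle`).
#' @export
extract_feature_vector <- function(stack, panomap, spec = sector_spec(),
                                   macro_percentile = 88, min_area_px = 250L,
                                   onh_percentile = 40, subject_id = NA,
                                   label = NA, rnfl_um = NA, vf_md_db = NA) {
  stopifnot(inherits(stack, "en_face_stack"),
            inherits(panomap, "panomap_annotation"))
  if (stack$laterality != panomap$laterality) {
    stop("laterality mismatch between layer stack and Panomap annotation",
         call. = FALSE)
  }
  angle <- estimate_fovea_disc_angle(panomap)
  macro <- macrovessel_mask(stack$layers$superficial,
                            percentile = macro_percentile,
                            min_area_px = min_area_px)
  onh <- onh_hollow_circle(stack$layers$choroid, percentile = onh_percentile)
  rois <- build_roi_masks(onh, angle, dim(stack$layers$superficial), spec)
  vim <- numeric(0)
  for (ly in octa_layers()) {
    for (sec in octa_sectors()) {
      vim[paste(ly, sec, sep = "_")] <-
        compute_vim(stack$layers[[ly]], rois[[sec]], macro = macro, onh = onh)
    }
  }
  feature_record(vim, subject_id = subject_id, label = label,
                 laterality = stack$laterality, rnfl_um = rnfl_um,
                 vf_md_db = vf_md_db, angle = angle, onh = onh)
}

#' @rdname extract_feature_vector
#' @param vim named numeric vector of exactly 42 VIM values, names as in
#'   [feature_columns()].
#' @param laterality `"OD"` or `"OS"`.
#' @param angle,onh optional provenance objects.
#' @export
feature_record <- function(vim, subject_id = NA, label = NA,
                           laterality = c("OD", "OS"), rnfl_um = NA,
                           vf_md_db = NA, angle = NULL, onh = NULL) {
  laterality <- match.arg(laterality)
  cols <- feature_columns()
  if (length(vim) != 42L || !all(cols %in% names(vim))) {
    stop("`vim` must hold exactly 42 named (layer, sector) features",
         call. = FALSE)
  }
  if (!is.na(vf_md_db) && !is.na(label) &&
      label %in% c("mild", "moderate", "severe") &&
      severity_from_vf(vf_md_db) != label) {
    stop("severity label `", label, "` inconsistent with VF MD ", vf_md_db,
         " dB", call. = FALSE)
  }
  structure(list(subject_id = subject_id, label = label,
                 laterality = laterality, rnfl_um = rnfl_um,
                 vf_md_db = vf_md_db, vim = vim[cols],
                 angle = angle, onh = onh),
            class = "feature_record")
}

#' @rdname extract_feature_vector
#' @param x a `feature_record`.
#' @param ... unused.
#' @param row.names,optional passed through for the data.frame method
#'   contract (unused).
#' @export
as.data.frame.feature_record <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  cbind(data.frame(subject_id = x$subject_id, label = x$label,
                   laterality = x$laterality, rnfl_um = x$rnfl_um,
                   vf_md_db = x$vf_md_db, stringsAsFactors = FALSE),
        as.data.frame(as.list(x$vim), check.names = FALSE))
}

#' Glaucoma severity stratum from visual-field mean deviation
#'
#' Mild is VF MD above -6 dB, moderate between -12 and -6 dB, severe below
#' -12 dB.
#'
#' @param vf_md_db visual-field mean deviation in dB (vectorized).
#' @return Character vector of `"mild"`, `"moderate"`, `"severe"`.
#' @export
severity_from_vf <- function(vf_md_db) {
  ifelse(vf_md_db > -6, "mild",
         ifelse(vf_md_db >= -12, "moderate", "severe"))
}
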