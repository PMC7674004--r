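#' Phantom scan configuration
#'
#' Describes one synthetic 3x3 mm optic-disc-centred OCTA acquisition: image
#' grid, optic nerve head optically hollow (ONH-OH) disc geometry, macrovessel
#' tree, per-(layer, sector) microvascular background intensity, additive
#' Gaussian noise, fovea-disc axis angle and laterality. Intensities are in
#' the 8-bit range `[0, 255]` (the device reports arbitrary units).
#'
#' @param image_size integer pair, image rows and columns. Default 245 x 245,
#'   a typical 3x3 mm en-face grid.
#' @param onh_center numeric pair `(row, col)` of the disc centre; default the
#'   image centre.
#' @param onh_radius radius in px of the optically hollow disc (default 30).
#' @param macro_tree list with `n_branches`, `width_px` (range, px) and
#'   `intensity` of the bright macrovessel tree drawn on the superficial
#'   (and, attenuated, deep and whole-retina) layers. `NULL` disables it.
#' @param background microvascular background mean intensity: a scalar, a
#'   named per-layer vector, or a full 6 x 7 layer-by-sector matrix
#'   (rows in [octa_layers()] order, columns in [octa_sectors()] order,
#'   where the first six sectors are used; CP has no own background).
#' @param onh_intensity intensity inside the optically hollow disc.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param fovea_disc_angle fovea-disc axis angle alpha in degrees,
#'   in `(-180, 180]`; positive means the fovea lies below the disc row in
#'   image coordinates.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param seed integer seed; identical configurations with identical seeds
#'   generate bit-identical phantoms.
#' @return A `phantom_config` object (validated list).
#' @export
phantom_config <- function(image_size = c(245L, 245L),
                           onh_center = NULL,
                           onh_radius = 30,
                           macro_tree = list(n_branches = 8L,
                                             width_px = c(3L, 8L),
                                             intensity = 220),
                           background = NULL,
                           onh_intensity = 25,
                           noise_sd = 8,
                           fovea_disc_angle = 7,
                           laterality = c("OD", "OS"),
                           seed = 1L) {
  laterality <- match.arg(laterality)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 16L)) {
    stop("`image_size` must be two integers >= 16", call. = FALSE)
  }
  onh_center <- onh_center %||% (image_size + 1) / 2
  assert_scalar_num(onh_radius, "onh_radius", lo = 1)
  if (onh_radius >= min(image_size) / 2) {
    stop("`onh_radius` must be smaller than half the image size", call. = FALSE)
  }
  assert_scalar_num(noise_sd, "noise_sd", lo = 0)
  assert_scalar_num(onh_intensity, "onh_intensity", lo = 0, hi = 255)
  assert_scalar_num(fovea_disc_angle, "fovea_disc_angle", lo = -180, hi = 180)
  bg <- normalize_background(background)
  if (any(bg < 0 | bg > 255)) {
    stop("background intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.null(macro_tree)) {
    assert_scalar_num(macro_tree$intensity, "macro_tree$intensity", 0, 255)
    if (is.null(macro_tree$n_branches)) macro_tree$n_branches <- 8L
    if (is.null(macro_tree$width_px)) macro_tree$width_px <- c(3L, 8L)
  }
  structure(list(image_size = image_size, onh_center = as.numeric(onh_center),
                 onh_radius = onh_radius, macro_tree = macro_tree,
                 background = bg, onh_intensity = onh_intensity,
                 noise_sd = noise_sd, fovea_disc_angle = fovea_disc_angle,
                 laterality = laterality, seed = as.integer(seed)),
            class = "phantom_config")
}

# Per-layer defaults: no healthy-eye intensity statistics are published,
# so these are free parameters chosen once (see the methods vignette).
# Superficial/retina bright, avascular near-empty, choroid intermediate.
default_layer_background <- function() {
  c(superficial = 110, deep = 100, avascular = 40, retina = 105,
    choriocapillaris = 120, choroid = 90)
}

# Coerce scalar / per-layer vector / 6x7 matrix into a 6x6 layer-by-sector
# matrix of background means (CP is the union sector, no background of its own).
normalize_background <- function(background) {
  layers <- octa_layers()
  sect <- octa_sectors()[1:6]
  if (is.null(background)) background <- default_layer_background()
  if (is.matrix(background)) {
    bg <- background[, 1:6, drop = FALSE]
    rownames(bg) <- layers
    colnames(bg) <- sect
    return(bg)
  }
  if (length(background) == 1L) {
    background <- stats::setNames(rep(as.numeric(background), 6L), layers)
  }
  if (is.null(names(background)) || !all(layers %in% names(background))) {
    stop("per-layer `background` must be named with all six layers",
         call. = FALSE)
  }
  matrix(rep(as.numeric(background[layers]), 6L), nrow = 6L,
         dimnames = list(layers, sect))
}

#' En-face OCTA layer stack container
#'
#' Bundles one subject's six co-registered grayscale en-face projections with
#' the eye laterality. Images are numeric matrices of equal shape with
#' intensities in `[0, 255]`.
#'
#' @param layers named list of six numeric matrices, names as in
#'   [octa_layers()].
#' @param laterality `"OD"` or `"OS"`.
#' @param meta optional list of provenance (config, subject id, seed).
#' @return An `en_face_stack` object.
#' @export
layer_stack <- function(layers, laterality = c("OD", "OS"), meta = list()) {
  laterality <- match.arg(laterality)
  need <- octa_layers()
  missing <- setdiff(need, names(layers))
  if (length(missing)) {
    stop("missing layer image(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  layers <- layers[need]
  dims <- vapply(layers, dim, integer(2))
  if (any(dims != dims[, 1])) {
    bad <- need[which(colSums(dims != dims[, 1]) > 0)[1]]
    stop("layer image shape mismatch at layer: ", bad, call. = FALSE)
  }
  structure(list(layers = layers, laterality = laterality, meta = meta),
            class = "en_face_stack")
}

#' Generate a phantom en-face layer stack
#'
#' Renders six co-registered synthetic layer images: sector-wise constant
#' microvascular background, a bright connected macrovessel tree on the
#' superficial layer (attenuated copies on the deep and whole-retina layers),
#' a dark optically hollow disc on every layer, and additive Gaussian noise.
#' The avascular layer carries only its (low) background, i.e. near-zero
#' contrast. Output is bit-reproducible for a fixed configuration and seed.
#'
#' @param cfg a [phantom_config()].
#' @return An [layer_stack()] (`en_face_stack`) with `meta$config = cfg`.
#' @export
generate_layer_stack <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ang <- anatomical_angle(rr, cc, cfg$onh_center, cfg$fovea_disc_angle,
                          cfg$laterality)
  sector_id <- sector_membership(ang)
  disc <- (rr - cfg$onh_center[1])^2 + (cc - cfg$onh_center[2])^2 <=
    cfg$onh_radius^2

  with_seed(cfg$seed, {
    tree <- if (is.null(cfg$macro_tree)) {
      matrix(FALSE, H, W)
    } else {
      draw_macro_tree(H, W, cfg$onh_center, cfg$onh_radius, cfg$macro_tree)
    }
    layers <- list()
    for (ly in octa_layers()) {
      img <- matrix(cfg$background[ly, ][sector_id], H, W)
      if (!is.null(cfg$macro_tree)) {
        lvl <- cfg$macro_tree$intensity
        if (ly == "superficial" || ly == "retina") {
          img[tree] <- lvl
        } else if (ly == "deep") {
          img[tree] <- (img[tree] + lvl) / 2
        }
      }
      img[disc] <- cfg$onh_intensity
      if (cfg$noise_sd > 0) {
        img <- img + matrix(rnorm(H * W, sd = cfg$noise_sd), H, W)
      }
      layers[[ly]] <- pmin(pmax(img, 0), 255)
    }
    layer_stack(layers, cfg$laterality,
                meta = list(config = cfg, macro_truth = tree,
                            onh_truth = disc))
  })
}

# Stamp a branching macrovessel tree: trunks leave the disc rim at jittered
# evenly-spaced angles and wander to the image border; strokes are disk-stamped
# polylines of width 3-8 px so every component clears the 250-px area filter.
draw_macro_tree <- function(H, W, center, rim_radius, tree) {
  mask <- matrix(FALSE, H, W)
  widths <- tree$width_px
  stamp <- function(pts_r, pts_c, w) {
    rad <- w / 2
    off <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                       dc = -ceiling(rad):ceiling(rad))
    off <- off[off$dr^2 + off$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
    r <- rep(round(pts_r), each = nrow(off)) + off$dr
    c <- rep(round(pts_c), each = nrow(off)) + off$dc
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    mask[cbind(r[ok], c[ok])] <<- TRUE
  }
  walk <- function(r0, c0, theta, max_len) {
    n <- ceiling(max_len)
    dth <- cumsum(c(0, rnorm(n - 1, sd = 0.03)))
    th <- theta + dth
    pr <- r0 + cumsum(c(0, sin(th[-1])))
    pc <- c0 + cumsum(c(0, cos(th[-1])))
    keep <- pr >= 1 & pr <= H & pc >= 1 & pc <= W
    cbind(pr[keep], pc[keep])
  }
  nb <- tree$n_branches
  base_theta <- seq(0, 2 * pi, length.out = nb + 1)[-(nb + 1)]
  for (k in seq_len(nb)) {
    theta <- base_theta[k] + runif(1, -0.2, 0.2)
    r0 <- center[1] + (rim_radius + 1) * sin(theta)
    c0 <- center[2] + (rim_radius + 1) * cos(theta)
    w <- sample(seq(widths[1], widths[2]), 1)
    pts <- walk(r0, c0, theta, max(H, W))
    if (nrow(pts) < 2) next
    stamp(pts[, 1], pts[, 2], w)
    # one side branch midway, thinner but still above the survival threshold
    mid <- max(2L, floor(nrow(pts) / 2))
    side <- walk(pts[mid, 1], pts[mid, 2],
                 theta + sample(c(-1, 1), 1) * runif(1, 0.4, 0.8),
                 max(H, W) / 2)
    if (nrow(side) >= 2) stamp(side[, 1], side[, 2], max(3, w - 2))
  }
  mask
}

#' Generate a synthetic Panomap annotation
#'
#' Produces a fundus-style annotation whose disc and fovea circle centroids
#' subtend exactly the configured fovea-disc axis angle. For OD eyes the
#' fovea is placed temporally to the right of the disc (larger column), for
#' OS to the left, so the two lateralities are horizontal mirrors at equal
#' angle. A rendered RGB annotation image (filled circles in the configured
#' colors over a dark background) is attached as `source_image`.
#'
#' @param cfg a [phantom_config()]; uses `image_size`, `onh_center`,
#'   `fovea_disc_angle`, `laterality`.
#' @param distance_px fovea-disc centroid distance (default a third of the
#'   smaller image dimension).
#' @param disc_radius_px,fovea_radius_px radii of the two annotation circles.
#' @param colors named character pair mapping roles to annotation channels,
#'   e.g. `c(disc = "red", fovea = "green")` (the device palette is not
#'   standardised, so this is a documented option).
#' @return A [panomap_annotation()] with ground-truth centroids.
#' @export
generate_panomap <- function(cfg, distance_px = NULL, disc_radius_px = 18,
                             fovea_radius_px = 10,
                             colors = c(disc = "red", fovea = "green")) {
  stopifnot(inherits(cfg, "phantom_config"))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  L <- distance_px %||% (min(H, W) / 3)
  a <- cfg$fovea_disc_angle * pi / 180
  sgn <- if (cfg$laterality == "OD") 1 else -1
  disc <- cfg$onh_center
  fovea <- c(disc[1] + L * sin(a), disc[2] + sgn * L * cos(a))
  if (fovea[1] < 1 + fovea_radius_px || fovea[1] > H - fovea_radius_px ||
      fovea[2] < 1 + fovea_radius_px || fovea[2] > W - fovea_radius_px) {
    stop("fovea annotation circle falls outside the image; reduce ",
         "`distance_px` or the angle", call. = FALSE)
  }
  img <- array(0.1, dim = c(H, W, 3))
  chan <- c(red = 1L, green = 2L, blue = 3L)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  put_circle <- function(img, center, rad, channel) {
    m <- (rr - center[1])^2 + (cc - center[2])^2 <= rad^2
    pl <- img[, , channel]
    pl[m] <- 1
    img[, , channel] <- pl
    img
  }
  img <- put_circle(img, disc, disc_radius_px, chan[[colors[["disc"]]]])
  img <- put_circle(img, fovea, fovea_radius_px, chan[[colors[["fovea"]]]])
  panomap_annotation(disc, fovea, cfg$laterality, source_image = img,
                     colors = colors)
}
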