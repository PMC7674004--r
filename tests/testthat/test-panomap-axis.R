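test_that("fovea-disc angle matches hand trigonometry", {
  ann <- function(d, f, lat = "OD") panomap_annotation(d, f, lat)
  expect_equal(estimate_fovea_disc_angle(
    ann(c(100, 100), c(100, 200)))$alpha_deg, 0)
  expect_equal(estimate_fovea_disc_angle(
    ann(c(100, 100), c(110, 200)))$alpha_deg, atan2(10, 100) * 180 / pi,
    tolerance = 1e-10)
  expect_equal(estimate_fovea_disc_angle(
    ann(c(100, 100), c(110, 200)))$alpha_deg, 5.71, tolerance = 1e-2)
  expect_equal(estimate_fovea_disc_angle(
    ann(c(100, 100), c(200, 100)))$alpha_deg, 90)
  expect_error(panomap_annotation(c(5, 5), c(5, 5)), "distinct")
})

test_that("angle estimate is translation invariant", {
  for (i in 1:25) {
    d <- runif(2, 50, 150)
    f <- d + runif(2, -40, 40)
    if (all(abs(f - d) < 1e-6)) next
    off <- runif(2, -30, 30)
    a1 <- estimate_fovea_disc_angle(panomap_annotation(d, f))$alpha_deg
    a2 <- estimate_fovea_disc_angle(panomap_annotation(d + off, f + off))$alpha_deg
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})

test_that("synthetic Panomap round-trips the configured angle within 0.5 deg", {
  for (alpha in c(-25, 0, 7, 10, 40)) {
    for (lat in c("OD", "OS")) {
      cfg <- quiet_config(fovea_disc_angle = alpha, laterality = lat)
      pano <- generate_panomap(cfg)
      det <- detect_circle_centroids(pano$source_image, laterality = lat)
      est <- estimate_fovea_disc_angle(det)
      expect_lt(abs(est$alpha_deg - alpha), 0.5)
    }
  }
})

test_that("OD and OS place the fovea on opposite horizontal sides", {
  pod <- generate_panomap(quiet_config(fovea_disc_angle = 10))
  pos <- generate_panomap(quiet_config(fovea_disc_angle = 10,
                                       laterality = "OS"))
  expect_gt(pod$fovea_centroid[2], pod$disc_centroid[2])
  expect_lt(pos$fovea_centroid[2], pos$disc_centroid[2])
  expect_equal(pod$fovea_centroid[1], pos$fovea_centroid[1])
})

test_that("circle roles are assigned by color, not position", {
  cfg <- quiet_config(fovea_disc_angle = 0)
  swapped <- generate_panomap(cfg, colors = c(disc = "green", fovea = "red"))
  det <- detect_circle_centroids(swapped$source_image,
                                 colors = c(disc = "green", fovea = "red"))
  expect_equal(det$disc_centroid, cfg$onh_center, tolerance = 0.5)
})

test_that("single visible circle raises a detection error", {
  img <- array(0, dim = c(60, 60, 3))
  img[20:25, 20:25, 1] <- 1  # red disc only, no green fovea
  expect_error(detect_circle_centroids(img), "detection error")
})

test_that("rotation: identity, mirror symmetry, and round trip", {
  circ <- onh_circle(c(61, 61), 20)
  rois <- build_roi_masks(circ, fovea_disc_angle(0, "OD"), c(121, 121))
  m <- rois$IT
  expect_identical(rotate_mask(m, fovea_disc_angle(0, "OD"), c(61, 61)), m)
  # OS at alpha 0 is the horizontal mirror
  mir <- rotate_mask(m, fovea_disc_angle(0, "OS"), c(61, 61))
  expect_identical(mir, m[, ncol(m):1])
  # rotate by alpha then -alpha recovers the sector up to resampling
  r1 <- rotate_mask(m, fovea_disc_angle(23, "OD"), c(61, 61))
  r2 <- rotate_mask(r1, fovea_disc_angle(-23, "OD"), c(61, 61))
  jac <- sum(r2 & m) / sum(r2 | m)
  expect_gte(jac, 0.98)
})

test_that("rotation preserves sector-scale mask pixel counts within 2%", {
  circ <- onh_circle(c(61, 61), 20)
  rois <- build_roi_masks(circ, fovea_disc_angle(0, "OD"), c(121, 121))
  for (a in c(-60, -15, 30, 75)) {
    rot <- rotate_mask(rois$ST, fovea_disc_angle(a, "OD"), c(61, 61))
    expect_lt(abs(sum(rot) - sum(rois$ST)) / sum(rois$ST), 0.02)
  }
})

test_that("mask rotation agrees with analytic sector construction", {
  circ <- onh_circle(c(61, 61), 20)
  ref <- build_roi_masks(circ, fovea_disc_angle(0, "OD"), c(121, 121))
  tilted <- build_roi_masks(circ, fovea_disc_angle(30, "OD"), c(121, 121))
  # rotating the subject-frame mask by alpha must recover the reference
  back <- rotate_mask(tilted$IT, fovea_disc_angle(30, "OD"), c(61, 61))
  jac <- sum(back & ref$IT) / sum(back | ref$IT)
  expect_gte(jac, 0.95)
})
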