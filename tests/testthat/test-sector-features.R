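test_that("six sector masks partition the CP annulus exactly", {
  circ <- onh_circle(c(123, 123), 30)
  for (a in c(0, 17, -40)) {
    rois <- build_roi_masks(circ, fovea_disc_angle(a, "OD"), c(245, 245))
    six <- octa_sectors()[1:6]
    expect_equal(sum(vapply(six, function(s) sum(rois[[s]]), numeric(1))),
                 sum(rois$CP))
    # pairwise disjoint
    stackmask <- Reduce(`+`, lapply(six, function(s) rois[[s]]))
    expect_true(all(stackmask[rois$CP] == 1))
    expect_true(all(stackmask[!rois$CP] == 0))
  }
})

test_that("sector membership matches a polar-coordinate oracle", {
  circ <- onh_circle(c(123, 123), 30)
  rois <- build_roi_masks(circ, fovea_disc_angle(0, "OD"), c(245, 245))
  mid <- (30 + attr(rois, "outer_radius")) / 2
  # IT arc spans anatomical angles [-85, -45): inferior-temporal, i.e.
  # below the horizontal in image rows, temporal side
  probe <- function(a_deg) {
    th <- a_deg * pi / 180
    rc <- c(123 - mid * sin(th), 123 + mid * cos(th))  # image rows grow down
    vapply(octa_sectors(), function(s) rois[[s]][round(rc[1]), round(rc[2])],
           logical(1))
  }
  expect_identical(unname(probe(-65)[1:6]),
                   octa_sectors()[1:6] == "IT")
  expect_identical(unname(probe(65)[1:6]),
                   octa_sectors()[1:6] == "ST")
  expect_identical(unname(probe(180)[1:6]),
                   octa_sectors()[1:6] == "N")
  expect_identical(unname(probe(0)[1:6]),
                   octa_sectors()[1:6] == "T")
  expect_true(all(vapply(list(probe(-65), probe(65), probe(180), probe(0)),
                         function(p) p[["CP"]], logical(1))))
})

test_that("annulus pixel count approximates the analytic area", {
  circ <- onh_circle(c(123, 123), 30)
  rois <- build_roi_masks(circ, fovea_disc_angle(0, "OD"), c(245, 245))
  R <- attr(rois, "outer_radius")
  expect_lt(abs(sum(rois$CP) - pi * (R^2 - 30^2)) / (pi * (R^2 - 30^2)),
            0.03)
})

test_that("a disc touching the border is rejected", {
  expect_error(build_roi_masks(onh_circle(c(10, 123), 30), 0, c(245, 245)),
               "border")
})

test_that("VIM is the median with exclusions applied", {
  img <- matrix(0, 10, 10)
  roi <- matrix(FALSE, 10, 10)
  roi[1, 1:9] <- TRUE
  img[1, 1:9] <- 1:9
  macro <- matrix(FALSE, 10, 10)
  expect_equal(compute_vim(img, roi), 5)
  macro[1, 9] <- TRUE  # mask out the 9
  expect_equal(compute_vim(img, roi, macro), 4.5)
  expect_equal(compute_vim(img + 10, roi, macro), 14.5)
  # constant image
  expect_equal(compute_vim(matrix(7, 10, 10), roi), 7)
  # empty effective ROI errors, never imputes
  expect_error(compute_vim(img, roi, roi), "empty")
})

test_that("VIM ignores arbitrary edits inside the excluded masks", {
  st <- generate_layer_stack(quiet_config(noise_sd = 5, seed = 21))
  img <- st$layers$superficial
  macro <- macrovessel_mask(img)
  onh <- onh_hollow_circle(st$layers$choroid)
  rois <- build_roi_masks(onh, fovea_disc_angle(7, "OD"), dim(img))
  base <- compute_vim(img, rois$IT, macro, onh)
  poked <- img
  poked[macro] <- 255
  rr <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cc <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  inside <- (rr - onh$center[1])^2 + (cc - onh$center[2])^2 <= onh$radius^2
  poked[inside] <- 0
  expect_identical(compute_vim(poked, rois$IT, macro, onh), base)
})

test_that("extraction emits exactly 42 features", {
  cfg <- quiet_config(noise_sd = 6, seed = 8)
  rec <- extract_feature_vector(generate_layer_stack(cfg),
                                generate_panomap(cfg))
  expect_length(rec$vim, 42L)
  expect_identical(names(rec$vim), feature_columns())
  row <- as.data.frame(rec)
  expect_equal(ncol(row), 47L)
})

test_that("uniform phantom yields 42 identical features at the background", {
  cfg <- flat_config()
  rec <- extract_feature_vector(generate_layer_stack(cfg),
                                generate_panomap(cfg))
  expect_true(all(rec$vim == 100))
})

test_that("a superficial-IT deficit shows up in that feature alone", {
  bg <- matrix(rep(c(110, 100, 40, 105, 120, 90), 6), nrow = 6,
               dimnames = list(octa_layers(), octa_sectors()[1:6]))
  bg["superficial", "IT"] <- 80  # -30 a.u. deficit
  cfg <- phantom_config(background = bg, noise_sd = 0, fovea_disc_angle = 0,
                        seed = 13)
  rec <- extract_feature_vector(generate_layer_stack(cfg),
                                generate_panomap(cfg))
  expect_equal(rec$vim[["superficial_ST"]] - rec$vim[["superficial_IT"]],
               30, tolerance = 2)
  expect_equal(rec$vim[["deep_IT"]], rec$vim[["deep_ST"]], tolerance = 2)
})

test_that("mirrored OS phantom reproduces the OD feature vector", {
  cfg <- quiet_config(noise_sd = 0, fovea_disc_angle = 12, seed = 6)
  st <- generate_layer_stack(cfg)
  pano <- generate_panomap(cfg)
  od <- extract_feature_vector(st, pano)
  # build the exact mirror image stack and annotation
  W <- ncol(st$layers[[1]])
  mirror <- function(m) m[, W:1]
  st_os <- layer_stack(lapply(st$layers, mirror), "OS")
  pano_os <- panomap_annotation(
    c(cfg$onh_center[1], W + 1 - cfg$onh_center[2]),
    c(pano$fovea_centroid[1], W + 1 - pano$fovea_centroid[2]), "OS")
  os <- extract_feature_vector(st_os, pano_os)
  expect_equal(os$vim, od$vim, tolerance = 0.5)
})

test_that("CP VIM lies within the pixel range of the six sectors", {
  cfg <- quiet_config(noise_sd = 10, seed = 14)
  st <- generate_layer_stack(cfg)
  macro <- macrovessel_mask(st$layers$superficial)
  onh <- onh_hollow_circle(st$layers$choroid)
  rois <- build_roi_masks(onh, fovea_disc_angle(7, "OD"),
                          dim(st$layers[[1]]))
  img <- st$layers$deep
  cp <- compute_vim(img, rois$CP, macro, onh)
  px <- img[rois$CP & !macro]
  expect_gte(cp, min(px))
  expect_lte(cp, max(px))
})

test_that("severity labels inconsistent with VF MD are rejected", {
  vim <- stats::setNames(rep(100, 42), feature_columns())
  expect_error(feature_record(vim, label = "mild", vf_md_db = -10),
               "inconsistent")
  expect_silent(feature_record(vim, label = "moderate", vf_md_db = -10))
})
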