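#' Write / read a layer stack as six PNGs plus a JSON manifest
#'
#' Each layer is written as an 8-bit grayscale PNG; the manifest records the
#' subject id, laterality, seed and layer file names, plus the configuration
#' hash so outputs are traceable to their parameters.
#'
#' @param stack an [layer_stack()].
#' @param dir output directory (created if needed).
#' @param subject_id subject identifier used for the file names.
#' @return `write_layer_stack()` returns the manifest path invisibly;
#'   `read_layer_stack()` returns the validated `en_face_stack`.
#' @export
write_layer_stack <- function(stack, dir, subject_id = "subject") {
  stopifnot(inherits(stack, "en_face_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (ly in octa_layers()) {
    fn <- paste0(subject_id, "_", ly, ".png")
    png::writePNG(pmin(pmax(stack$layers[[ly]], 0), 255) / 255,
                  file.path(dir, fn))
    files[[ly]] <- fn
  }
  cfg <- stack$meta$config
  manifest <- list(subject_id = subject_id, laterality = stack$laterality,
                   seed = if (!is.null(cfg)) cfg$seed else NA,
                   config_hash = if (!is.null(cfg)) config_hash(cfg) else NA,
                   layers = files)
  path <- file.path(dir, paste0(subject_id, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layer_stack
#' @param manifest_path path to a manifest written by `write_layer_stack()`.
#' @export
read_layer_stack <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path)
  missing <- setdiff(octa_layers(), names(manifest$layers))
  if (length(missing)) {
    stop("manifest missing layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir <- dirname(manifest_path)
  layers <- lapply(octa_layers(), function(ly) {
    f <- file.path(dir, manifest$layers[[ly]])
    if (!file.exists(f)) {
      stop("missing image file for layer ", ly, ": ", f, call. = FALSE)
    }
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img * 255
  })
  names(layers) <- octa_layers()
  layer_stack(layers, manifest$laterality %||% "OD",
              meta = list(subject_id = manifest$subject_id,
                          manifest = manifest_path))
}

# Cheap content hash (no digest dependency): polynomial byte hash of the
# JSON serialization, reported as 8 hex digits.
config_hash <- function(x) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` to serialize.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$n_per_group <- as.list(lst$n_per_group)
  lst$sector_widths <- as.list(lst$sector_widths)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  as_pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the pipeline: cohort composition, phantom
#' rendering parameters, segmentation percentiles and area filter, sector
#' widths, and the (optional) classification stage. Unknown keys are
#' rejected, and the configuration round-trips losslessly through JSON.
#'
#' @param n_per_group named group sizes for the synthetic cohort.
#' @param noise_sd phantom noise SD.
#' @param effect_scale multiplier on [default_effect_map()] applied to the
#'   phantom backgrounds per severity step.
#' @param macro_percentile,min_area_px,onh_percentile segmentation tunables.
#' @param sector_widths named sector widths (see [sector_spec()]).
#' @param image_size phantom grid size.
#' @param evaluate logical: run the classification stage.
#' @param task,model,feature_set classification stage settings.
#' @param grid hyperparameter grid for the classification stage (default a
#'   reduced linear-SVM grid so the end-to-end run stays desk-scale).
#' @param n_boot bootstrap resamples for metric CIs.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(n_per_group = c(control = 10, glaucoma = 10),
                            noise_sd = 8, effect_scale = 1,
                            macro_percentile = 88, min_area_px = 250L,
                            onh_percentile = 40,
                            sector_widths = c(T = 90, ST = 40, SN = 40,
                                              N = 110, IN = 40, IT = 40),
                            image_size = c(245L, 245L), evaluate = FALSE,
                            task = "diagnosis", model = "svm",
                            feature_set = "all", grid = NULL,
                            n_boot = 1000L, seed = 1L, out_dir = tempdir()) {
  cfg <- list(n_per_group = n_per_group, noise_sd = noise_sd,
              effect_scale = effect_scale,
              macro_percentile = macro_percentile,
              min_area_px = min_area_px, onh_percentile = onh_percentile,
              sector_widths = sector_widths, image_size = image_size,
              evaluate = evaluate, task = task, model = model,
              feature_set = feature_set,
              grid = grid %||% data.frame(kernel = "linear",
                                          C = c(0.01, 1, 100),
                                          gamma = NA_real_),
              n_boot = n_boot, seed = seed, out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param lst a plain list (e.g. parsed from JSON) to validate into a
#'   configuration; unknown keys are rejected.
#' @export
as_pipeline_config <- function(lst) {
  allowed <- names(formals(pipeline_config))
  extra <- setdiff(names(lst), allowed)
  if (length(extra)) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(lst$grid)) lst$grid <- as.data.frame(lst$grid)
  if (!is.null(lst$n_per_group)) lst$n_per_group <- unlist(lst$n_per_group)
  if (!is.null(lst$sector_widths)) {
    lst$sector_widths <- unlist(lst$sector_widths)
  }
  if (!is.null(lst$image_size)) lst$image_size <- unlist(lst$image_size)
  do.call(pipeline_config, lst)
}

# QC overlay: superficial layer in gray, macrovessels green, ONH circle
# blue, sector boundaries red.
qc_overlay <- function(stack, macro, onh, rois) {
  base <- pmin(pmax(stack$layers$superficial, 0), 255) / 255
  img <- array(rep(base, 3), dim = c(dim(base), 3))
  g <- img[, , 2]; g[macro] <- 1; img[, , 2] <- g
  H <- nrow(base); W <- ncol(base)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (rr - onh$center[1])^2 + (cc - onh$center[2])^2
  ring <- abs(sqrt(d2) - onh$radius) < 1
  b <- img[, , 3]; b[ring] <- 1; img[, , 3] <- b
  sid <- matrix(0L, H, W)
  for (s in seq_len(6)) sid[rois[[s]]] <- s
  edge <- sid != shift_int(sid, 1, 0) | sid != shift_int(sid, 0, 1)
  edge <- edge & rois$CP
  r <- img[, , 1]; r[edge] <- 1; img[, , 1] <- r
  img
}

shift_int <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Generates one phantom per subject (sector backgrounds shifted by the
#' severity-step effect map, scaled by `effect_scale`), extracts the
#' 42-feature VIM vector through the full image-processing chain, writes the
#' cohort feature CSV and the univariate p-value grid, optionally runs the
#' nested classification stage, and writes a QC overlay PNG per subject.
#' Every output records the configuration hash and master seed; reruns with
#' the same configuration and seed are byte-identical. Any per-subject
#' failure aborts with a message naming the stage and subject.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the feature table, output paths and (if
#'   enabled) the metrics report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  spec <- sector_spec(config$sector_widths)
  emap <- default_effect_map() * config$effect_scale
  known_steps <- c(control = 0, mild = 1, moderate = 2, severe = 3,
                   glaucoma = 2, POAG = 2, NTG = 2)
  rows <- list()
  sid <- 0L
  for (g in names(config$n_per_group)) {
    step <- if (g %in% names(known_steps)) known_steps[[g]] else 1
    for (j in seq_len(config$n_per_group[[g]])) {
      sid <- sid + 1L
      id <- sprintf("S%04d", sid)
      sseed <- derive_seed(config$seed, paste0("subject", sid))
      res <- tryCatch({
        bg <- phantom_background_for_step(step, emap)
        cfg <- phantom_config(
          image_size = config$image_size, background = bg,
          noise_sd = config$noise_sd,
          fovea_disc_angle = with_seed(derive_seed(sseed, "angle"),
                                       rnorm(1, 7, 3)),
          laterality = if (sid %% 2L == 0L) "OS" else "OD",
          seed = sseed)
        stack <- generate_layer_stack(cfg)
        pano <- generate_panomap(cfg)
        rec <- extract_feature_vector(
          stack, pano, spec = spec,
          macro_percentile = config$macro_percentile,
          min_area_px = config$min_area_px,
          onh_percentile = config$onh_percentile,
          subject_id = id, label = g)
        macro <- macrovessel_mask(stack$layers$superficial,
                                  config$macro_percentile,
                                  config$min_area_px)
        rois <- build_roi_masks(rec$onh, rec$angle, dim(stack$layers[[1]]),
                                spec)
        png::writePNG(qc_overlay(stack, macro, rec$onh, rois),
                      file.path(config$out_dir, paste0(id, "_qc.png")))
        df <- as.data.frame(rec)
        df$group <- g
        df
      }, error = function(e) {
        stop("pipeline stage `features`, subject ", id, ": ",
             conditionMessage(e), call. = FALSE)
      })
      rows[[sid]] <- res
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  feature_csv <- file.path(config$out_dir, "features.csv")
  con <- file(feature_csv, "w")
  writeLines(sprintf("# octamls features config=%s seed=%d", hash,
                     config$seed), con)
  write.csv(table, con, row.names = FALSE)
  close(con)

  pgrid <- univariate_pvalue_grid(table, config$task)
  pcsv <- file.path(config$out_dir, "univariate_pvalues.csv")
  con <- file(pcsv, "w")
  writeLines(sprintf("# octamls pvalues config=%s seed=%d", hash,
                     config$seed), con)
  write.csv(pgrid, con, row.names = FALSE)
  close(con)

  metrics <- NULL
  if (isTRUE(config$evaluate)) {
    cv <- run_nested_evaluation(table, task = config$task,
                                model = config$model, grid = config$grid,
                                feature_set = config$feature_set,
                                seed = derive_seed(config$seed, "evaluate"))
    rep <- if (nlevels(cv$truth) > 2L) {
      score_multiclass(cv, n_boot = config$n_boot,
                       seed = derive_seed(config$seed, "boot"))
    } else {
      score_binary(cv, n_boot = config$n_boot,
                   seed = derive_seed(config$seed, "boot"))
    }
    metrics <- list(config_hash = hash, seed = config$seed,
                    task = config$task, model = config$model,
                    feature_set = config$feature_set,
                    metrics = as.list(stats::setNames(rep$estimate,
                                                      rep$metric)),
                    ci_low = as.list(stats::setNames(rep$ci_low,
                                                     rep$metric)),
                    ci_high = as.list(stats::setNames(rep$ci_high,
                                                      rep$metric)))
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(features = table, feature_csv = feature_csv,
                 pvalue_csv = pcsv, metrics = metrics,
                 config_hash = hash))
}

# Layer-by-sector background matrix for a severity step: healthy defaults
# plus step * effect (CP column has no background of its own).
phantom_background_for_step <- function(step, effect_map) {
  bg <- normalize_background(NULL)
  for (ly in octa_layers()) for (sec in octa_sectors()[1:6]) {
    bg[ly, sec] <- min(max(
      bg[ly, sec] + step * effect_map[[paste(ly, sec, sep = "_")]], 0), 255)
  }
  bg
}
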