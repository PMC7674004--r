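#' Cohort effect specification
#'
#' Describes a synthetic cohort at the feature level: group sizes, the
#' per-(layer, sector) additive shift of mean VIM per severity step (negative
#' = microvascular loss), the RNFL shift per step with its floor clamp, and
#' noise levels. Defaults reproduce the structure of the reference cohort:
#' 39 controls and 37/26/19 mild/moderate/severe glaucoma eyes, strongest
#' deficit at the superficial inferotemporal sector, RNFL thinning of 10 um
#' per step clamped at a 53 um floor (the "floor effect" of structural
#' measurements in advanced disease), VF MD strata consistent with the
#' -6 / -12 dB severity thresholds.
#'
#' Severity steps per group name: control 0, mild 1, moderate 2, severe 3;
#' the aggregate labels glaucoma / POAG / NTG count as step 2 (a mixed-
#' severity group). Unrecognized group names take steps 0, 1, 2, ... in the
#' order given.
#'
#' @param n_per_group named integer vector of group sizes (each >= 2).
#' @param effect_map named 42-vector of per-step VIM mean shifts in
#'   [feature_columns()] order/names; see [default_effect_map()].
#' @param rnfl_effect additive RNFL shift (um) per severity step.
#' @param floor_level lower clamp for RNFL (um).
#' @param feature_sd between-subject SD of each VIM feature (a.u.).
#' @param rnfl_sd between-subject SD of RNFL (um).
#' @param base_mean named 42-vector of healthy VIM means; defaults to the
#'   phantom per-layer backgrounds.
#' @param severity_steps optional named numeric vector overriding the step
#'   assigned to each group.
#' @param seed integer seed.
#' @return A `cohort_effect_spec` object.
#' @export
cohort_effect_spec <- function(n_per_group = c(control = 39, mild = 37,
                                               moderate = 26, severe = 19),
                               effect_map = default_effect_map(),
                               rnfl_effect = -10, floor_level = 53,
                               feature_sd = 17, rnfl_sd = 9,
                               base_mean = NULL, severity_steps = NULL,
                               seed = 1L) {
  if (is.null(names(n_per_group)) || any(n_per_group < 2)) {
    stop("`n_per_group` must be a named vector of group sizes >= 2",
         call. = FALSE)
  }
  cols <- feature_columns()
  if (!all(cols %in% names(effect_map))) {
    stop("`effect_map` must name all 42 (layer, sector) features",
         call. = FALSE)
  }
  base_mean <- base_mean %||% default_base_mean()
  if (!all(cols %in% names(base_mean))) {
    stop("`base_mean` must name all 42 (layer, sector) features",
         call. = FALSE)
  }
  assert_scalar_num(feature_sd, "feature_sd", lo = 0)
  assert_scalar_num(rnfl_sd, "rnfl_sd", lo = 0)
  assert_scalar_num(floor_level, "floor_level", lo = 0)
  known <- c(control = 0, mild = 1, moderate = 2, severe = 3,
             glaucoma = 2, POAG = 2, NTG = 2)
  steps <- known[names(n_per_group)]
  steps[is.na(steps)] <- seq_len(sum(is.na(steps))) - 1
  names(steps) <- names(n_per_group)
  if (!is.null(severity_steps)) steps[names(severity_steps)] <- severity_steps
  structure(list(n_per_group = n_per_group, effect_map = effect_map[cols],
                 rnfl_effect = rnfl_effect, floor_level = floor_level,
                 feature_sd = feature_sd, rnfl_sd = rnfl_sd,
                 base_mean = base_mean[cols], severity_steps = steps,
                 seed = as.integer(seed)),
            class = "cohort_effect_spec")
}

#' @rdname cohort_effect_spec
#' @details `default_effect_map()` builds the per-step shifts as
#'   `-18 * layer_weight * sector_weight` a.u.: the superficial layer loses
#'   most, retina and deep nearly as much, choroid and choriocapillaris
#'   little, the avascular layer nothing; the inferotemporal sector is the
#'   most affected, nasal and temporal the least. This mirrors the observed
#'   ranking of discriminative features (superficial IT strongest).
#' @export
default_effect_map <- function() {
  lw <- c(superficial = 1, deep = 0.9, avascular = 0, retina = 0.95,
          choriocapillaris = 0.15, choroid = 0.35)
  sw <- c(ST = 0.65, SN = 0.55, N = 0.5, IN = 0.6, IT = 1, T = 0.5, CP = 0.75)
  out <- numeric(0)
  for (ly in octa_layers()) for (sec in octa_sectors()) {
    out[paste(ly, sec, sep = "_")] <- -18 * lw[[ly]] * sw[[sec]]
  }
  out
}

#' @rdname cohort_effect_spec
#' @export
default_base_mean <- function() {
  bg <- default_layer_background()
  out <- numeric(0)
  for (ly in octa_layers()) for (sec in octa_sectors()) {
    out[paste(ly, sec, sep = "_")] <- bg[[ly]]
  }
  out
}

# VF MD (dB) sampling parameters per severity step, clamped to stay
# consistent with the -6 / -12 dB strata.
vf_md_for_step <- function(group, n) {
  switch(group,
         control = pmin(rnorm(n, 0.38, 0.78), 2),
         mild = pmin(pmax(rnorm(n, -2.4, 2.4), -5.9), 1),
         moderate = pmin(pmax(rnorm(n, -8.6, 1.7), -12), -6),
         severe = pmin(rnorm(n, -17.1, 4.1), -12.1),
         rnorm(n, -7.8, 6.4))
}

#' Generate a synthetic cohort feature table
#'
#' Draws a per-subject feature table directly at the feature level (a
#' shortcut past the image pipeline, for classifier and statistics work):
#' each of the 42 VIM features is Gaussian around
#' `base_mean + step * effect_map`, clamped to `[0, 255]`; RNFL is Gaussian
#' around `88.9 + step * rnfl_effect` um, clamped below at `floor_level`;
#' VF MD is drawn inside the stratum consistent with the group. Output is
#' reproducible for a fixed spec and seed.
#'
#' @param spec a [cohort_effect_spec()].
#' @return A data.frame with columns `subject_id`, `group`, `label`
#'   (control / glaucoma), `laterality`, `rnfl_um`, `vf_md_db` and the 42
#'   feature columns of [feature_columns()].
#' @export
generate_cohort_feature_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_effect_spec"))
  with_seed(spec$seed, {
    rows <- list()
    sid <- 0L
    for (g in names(spec$n_per_group)) {
      n <- spec$n_per_group[[g]]
      step <- spec$severity_steps[[g]]
      mu <- pmin(pmax(spec$base_mean + step * spec$effect_map, 0), 255)
      feats <- matrix(rnorm(n * 42L, mean = rep(mu, each = n),
                            sd = spec$feature_sd), n, 42L)
      feats <- pmin(pmax(feats, 0), 255)
      colnames(feats) <- feature_columns()
      rnfl <- pmax(rnorm(n, 88.9 + step * spec$rnfl_effect, spec$rnfl_sd),
                   spec$floor_level)
      df <- data.frame(
        subject_id = sprintf("S%04d", sid + seq_len(n)),
        group = g,
        label = if (g == "control") "control" else "glaucoma",
        laterality = sample(c("OD", "OS"), n, replace = TRUE),
        rnfl_um = rnfl,
        vf_md_db = vf_md_for_step(g, n),
        stringsAsFactors = FALSE)
      rows[[g]] <- cbind(df, as.data.frame(feats))
      sid <- sid + n
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
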