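#' Flag large-vessel voxels on a CBV map
#'
#' Marks voxels whose CBV exceeds the large-vessel threshold (10 ml/100 g by
#' convention in this model) as excluded. Excluded voxels are dropped from all
#' downstream means and counts but the values themselves are untouched, so
#' maps stay grid-complete for rendering.
#'
#' @param map A [cbv_map()].
#' @param threshold Large-vessel CBV threshold, ml/100 g (strictly-greater
#'   voxels are excluded).
#' @return The map with an `excluded` logical layer attached.
#' @examples
#' g <- grid_spec()
#' m <- cbv_map(matrix(5, g$n_rows, g$n_cols), g, 0)
#' sum(exclude_large_vessels(m)$excluded)
#' @export
exclude_large_vessels <- function(map, threshold = 10) {
  stopifnot(inherits(map, "cbv_map"))
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold < 0)
    abort("vessel threshold must be >= 0.", class = "strokecbv_parameter_error")
  map$excluded <- map$values > threshold
  map$vessel_threshold <- threshold
  map
}

#' Mean contralateral CBV
#'
#' Arithmetic mean CBV over non-excluded voxels of the hemisphere opposite the
#' occluded side. Large-vessel exclusion must have been applied first
#' ([exclude_large_vessels()]); the order matters because vessel voxels would
#' otherwise inflate the hemispheric mean that serves as the occlusion
#' threshold.
#'
#' @param map A vessel-excluded [cbv_map()].
#' @param atlas The [build_atlas()] atlas.
#' @return Mean contralateral CBV, ml/100 g.
#' @export
mean_contralateral_cbv <- function(map, atlas) {
  stopifnot(inherits(map, "cbv_map"))
  if (is.null(map$excluded))
    abort("apply exclude_large_vessels() before computing the contralateral mean.",
          class = "strokecbv_parameter_error")
  contra_side <- setdiff(c("left", "right"), map$occluded_side)
  roi <- hemisphere_mask(atlas, map$bregma_level, contra_side) & !map$excluded
  if (!any(roi))
    abort("contralateral ROI is empty after vessel exclusion.",
          class = "strokecbv_empty_roi_error")
  mean(map$values[roi])
}

#' Classify anterior choroidal artery occlusion from CBV maps
#'
#' Implements the two-stage thresholding call: (1) exclude large-vessel voxels
#' (CBV > `vessel_threshold`); (2) on the caudal slice, where the AChA
#' territory lies, threshold the map at the mean contralateral CBV and count
#' ipsilateral AChA-territory voxels at or above it. Absence of
#' supra-threshold signal (count <= `tolerance_voxels`) calls the AChA
#' occluded. The call is a pure function of the maps, the atlas and the
#' parameters — it never sees infarct outcomes or ground-truth flags.
#'
#' @param maps A single [cbv_map()] or a list of maps (one per bregma level).
#' @param atlas The [build_atlas()] atlas.
#' @param vessel_threshold Large-vessel CBV threshold, ml/100 g.
#' @param tolerance_voxels Maximum number of supra-threshold AChA voxels still
#'   compatible with an occluded call (0 = strict absence of signal).
#' @param pooled_contralateral If `TRUE`, pool the contralateral mean over all
#'   provided levels instead of using the caudal classification slice only.
#' @return A one-row tibble: `animal_id`, `slice_used` (bregma mm),
#'   `mean_contralateral_cbv`, `supra_threshold_voxels_in_acha`,
#'   `excluded_vessel_voxels` (across provided levels), `acha_occluded`.
#' @examples
#' atlas <- build_atlas()
#' cfg <- cohort_config(cbv_noise_sd = 0)
#' rec <- generate_cohort(cfg, seed = 1)[1, ]
#' classify_achao(generate_cbv_maps(rec, atlas, cfg, seed = 1), atlas)
#' @export
classify_achao <- function(maps, atlas, vessel_threshold = 10,
                           tolerance_voxels = 0L, pooled_contralateral = FALSE) {
  if (inherits(maps, "cbv_map")) maps <- list(maps)
  maps <- lapply(maps, exclude_large_vessels, threshold = vessel_threshold)
  levels <- vapply(maps, function(m) m$bregma_level, numeric(1))

  acha_counts <- vapply(maps, function(m) {
    lvl <- as.character(m$bregma_level)
    msk <- atlas$masks[[lvl]]
    if (is.null(msk)) abort(sprintf("no atlas level at %s mm.", lvl),
                            class = "strokecbv_geometry_error")
    sum(msk$acha_territory)
  }, numeric(1))
  if (all(acha_counts == 0))
    abort("AChA territory is empty at every provided level.",
          class = "strokecbv_geometry_error")
  caudal_i <- which(acha_counts > 0)
  caudal_i <- caudal_i[which.min(levels[caudal_i])]
  map <- maps[[caudal_i]]

  contra_mean <- if (pooled_contralateral) {
    vals <- unlist(lapply(maps, function(m) {
      contra_side <- setdiff(c("left", "right"), m$occluded_side)
      roi <- hemisphere_mask(atlas, m$bregma_level, contra_side) & !m$excluded
      m$values[roi]
    }))
    if (length(vals) == 0)
      abort("contralateral ROI is empty after vessel exclusion.",
            class = "strokecbv_empty_roi_error")
    mean(vals)
  } else {
    mean_contralateral_cbv(map, atlas)
  }

  ipsi_acha <- atlas$masks[[as.character(map$bregma_level)]]$acha_territory &
    hemisphere_mask(atlas, map$bregma_level, map$occluded_side)
  supra <- sum(map$values >= contra_mean & ipsi_acha & !map$excluded)

  tibble::tibble(
    animal_id = map$animal_id,
    slice_used = map$bregma_level,
    mean_contralateral_cbv = contra_mean,
    supra_threshold_voxels_in_acha = as.integer(supra),
    excluded_vessel_voxels = as.integer(sum(vapply(maps, function(m) sum(m$excluded), numeric(1)))),
    acha_occluded = supra <= tolerance_voxels)
}

#' Classify a whole cohort of CBV map sets
#'
#' @param map_sets Named list (one entry per animal) of per-level map lists as
#'   returned by [generate_cbv_maps()].
#' @param atlas The atlas.
#' @param ... Passed to [classify_achao()].
#' @return A tibble with one classification row per animal.
#' @export
classify_cohort <- function(map_sets, atlas, ...) {
  dplyr::bind_rows(lapply(map_sets, classify_achao, atlas = atlas, ...))
}

#' Predicted-infarct mask from a CBV map
#'
#' Thresholds the map at the infarct-prediction CBV level (2 ml/100 g by
#' convention): brain voxels with CBV strictly below the threshold are marked
#' as predicted to infarct.
#'
#' @param map A [cbv_map()].
#' @param atlas The atlas (supplies the brain mask).
#' @param threshold Infarct-prediction CBV threshold, ml/100 g.
#' @return Logical grid-shaped matrix.
#' @export
predicted_infarct_mask <- function(map, atlas, threshold = 2) {
  stopifnot(inherits(map, "cbv_map"))
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold < 0)
    abort("infarct threshold must be >= 0.", class = "strokecbv_parameter_error")
  brain <- atlas$masks[[as.character(map$bregma_level)]]$brain
  map$values < threshold & brain
}
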