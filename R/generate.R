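#' Construct a CBV map object
#'
#' One coronal slice of cerebral blood volume values (ml/100 g) tied to a
#' grid, a bregma level, an animal and the side of occlusion. Large-vessel
#' exclusion ([exclude_large_vessels()]) attaches an `excluded` logical layer;
#' values themselves are never modified.
#'
#' @param values Numeric matrix of CBV values (>= 0), grid-shaped.
#' @param grid The [grid_spec()].
#' @param bregma_level Slice position, mm from bregma.
#' @param animal_id Animal identifier.
#' @param occluded_side `"left"` or `"right"` (anatomical).
#' @param excluded Optional logical matrix of vessel-excluded voxels.
#' @return A `cbv_map` object.
#' @export
cbv_map <- function(values, grid, bregma_level, animal_id = NA_character_,
                    occluded_side = "right", excluded = NULL) {
  if (!is.matrix(values) || nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    abort("`values` must be a grid-shaped matrix.", class = "strokecbv_dimension_error")
  if (any(values < 0))
    abort("CBV values must be >= 0.", class = "strokecbv_parameter_error")
  if (!occluded_side %in% c("left", "right"))
    abort("`occluded_side` must be 'left' or 'right'.", class = "strokecbv_parameter_error")
  structure(list(values = values, grid = grid, bregma_level = bregma_level,
                 animal_id = animal_id, occluded_side = occluded_side,
                 excluded = excluded),
            class = "cbv_map")
}

#' @export
print.cbv_map <- function(x, ...) {
  cat(sprintf("<cbv_map> animal %s, bregma %s mm, occluded side %s, CBV %.2f-%.2f ml/100 g%s\n",
              x$animal_id, x$bregma_level, x$occluded_side,
              min(x$values), max(x$values),
              if (is.null(x$excluded)) "" else sprintf(", %d vessel voxels excluded",
                                                      sum(x$excluded))))
  invisible(x)
}

#' Generate per-level CBV maps for one animal
#'
#' Builds the voxel field the classifier consumes: normal tissue at the
#' baseline CBV plus Gaussian noise; the ipsilateral MCA territory scaled to
#' its residual fraction; the ipsilateral AChA territory scaled to its
#' (small) residual fraction when the record says the AChA is occluded, or
#' held above baseline (patent choroidal signal) when not; and a fixed number
#' of high-CBV large-vessel voxels planted per hemisphere. Values are clamped
#' at zero.
#'
#' @param record One cohort row (list or single-row tibble) with at least
#'   `id` and `acha_occluded`.
#' @param atlas A [build_atlas()] atlas.
#' @param config A [cohort_config()].
#' @param seed Integer seed (expanded to a per-animal, per-level substream).
#' @return Named list of [cbv_map()] objects, one per atlas bregma level.
#' @examples
#' atlas <- build_atlas()
#' rec <- generate_cohort(seed = 1)[1, ]
#' maps <- generate_cbv_maps(rec, atlas, cohort_config(), seed = 1)
#' @export
generate_cbv_maps <- function(record, atlas, config = cohort_config(), seed = 1L) {
  grid <- atlas$grid
  ipsi_side <- config$occluded_side
  maps <- lapply(names(atlas$masks), function(lv) {
    m <- atlas$masks[[lv]]
    ipsi_hemi <- hemisphere_mask(atlas, lv, ipsi_side)
    contra_hemi <- hemisphere_mask(atlas, lv, setdiff(c("left", "right"), ipsi_side))
    ipsi_mca <- m$mca_territory & ipsi_hemi
    ipsi_acha <- m$acha_territory & ipsi_hemi

    set.seed(substream_seed(seed, "cbv", record$id, lv))
    vals <- matrix(0, grid$n_rows, grid$n_cols)
    base <- config$cbv_baseline
    vals[m$brain] <- base
    vals[ipsi_mca] <- base * config$mca_residual_fraction
    vals[ipsi_acha] <- if (isTRUE(record$acha_occluded))
      base * config$acha_residual_fraction else base * config$acha_patent_factor
    if (config$cbv_noise_sd > 0)
      vals[m$brain] <- vals[m$brain] + rnorm(sum(m$brain), 0, config$cbv_noise_sd)
    for (hemi in list(ipsi_hemi, contra_hemi)) {
      idx <- which(hemi)
      k <- min(config$vessel_count, length(idx))
      if (k > 0) vals[sample(idx, k)] <- config$vessel_value
    }
    vals[vals < 0] <- 0
    cbv_map(vals, grid, as.numeric(lv), record$id, ipsi_side)
  })
  names(maps) <- names(atlas$masks)
  maps
}

# Sections are laid out on a fixed spacing so that the -0.3 and -2.3 mm
# bregma histology levels fall on sections.
section_positions <- function(n_sections, spacing) {
  n_above <- min(2L, n_sections - 1L)
  -0.3 + spacing * seq(n_above, n_above - n_sections + 1L)
}

#' Generate histology infarct traces for one animal
#'
#' Produces per-section binary infarct masks whose cortical and subcortical
#' volumes reproduce the record's volumes to within half a voxel-volume each,
#' together with per-section hemisphere masks in which the ipsilateral
#' hemisphere is uniformly expanded to `contra x (1 + swelling_fraction)`
#' (the edema the downstream correction removes). Infarct voxels are filled
#' outward from the MCA-territory centroid, inside the ipsilateral
#' cortex/subcortex masks of the atlas level nearest each section.
#'
#' @inheritParams generate_cbv_maps
#' @return An `infarct_trace_set`: section table (`position`, `level`), lists
#'   of `infarct`, `ipsi_hemisphere`, `contra_hemisphere` masks, grid and
#'   spacing metadata.
#' @export
generate_infarct_traces <- function(record, atlas, seed = 1L,
                                    config = cohort_config()) {
  grid <- atlas$grid
  spacing <- config$section_spacing
  positions <- section_positions(config$n_sections, spacing)
  levels <- vapply(positions, function(p) {
    lv <- as.numeric(names(atlas$masks))
    lv[which.min(abs(lv - p))]
  }, numeric(1))
  voxel_vol <- grid$pixel_size^2 * spacing
  ipsi_side <- config$occluded_side
  contra_side <- setdiff(c("left", "right"), ipsi_side)

  co <- grid_coords(grid, atlas$shape_params)
  ipsi_is_right <- (ipsi_side == "right") == (atlas$laterality_convention == "neurological")
  on_ipsi <- if (ipsi_is_right) co$u > 0 else co$u < 0

  # swollen ipsilateral hemisphere: smallest-rho voxels on the ipsi side,
  # exact voxel count per section
  contra_masks <- lapply(levels, function(lv) hemisphere_mask(atlas, lv, contra_side))
  ipsi_masks <- lapply(contra_masks, function(cm) {
    target <- round(sum(cm) * (1 + config$swelling_fraction))
    idx <- which(on_ipsi)
    idx <- idx[order(co$rho[idx])][seq_len(min(target, length(idx)))]
    out <- matrix(FALSE, grid$n_rows, grid$n_cols)
    out[idx] <- TRUE
    out
  })

  # growth ordering: distance from the ipsilateral MCA-territory centroid
  fill_order <- function(mask) {
    idx <- which(mask)
    idx[order(fill_dist[idx])]
  }
  caudal <- names(atlas$masks)[length(atlas$masks)]
  mca_ipsi <- atlas$masks[[caudal]][[paste0("mca_territory_", if (ipsi_is_right) "right" else "left")]]
  cen_u <- mean(co$u[mca_ipsi]); cen_v <- mean(co$v[mca_ipsi])
  fill_dist <- sqrt((co$u - cen_u)^2 + (co$v - cen_v)^2)

  infarct <- lapply(seq_along(positions), function(i) matrix(FALSE, grid$n_rows, grid$n_cols))
  for (comp in c("cortical", "subcortical")) {
    target_vol <- record[[paste0("infarct_volume_", comp)]]
    n_total <- round(target_vol / voxel_vol)
    comp_masks <- lapply(levels, function(lv) {
      m <- atlas$masks[[as.character(lv)]]
      base <- if (comp == "cortical") m$cortex else m$subcortex
      base & hemisphere_mask(atlas, lv, ipsi_side)
    })
    avail <- vapply(comp_masks, sum, numeric(1))
    if (n_total > sum(avail))
      abort(sprintf("requested %s infarct volume (%.1f mm^3) exceeds available territory (%.1f mm^3).",
                    comp, target_vol, sum(avail) * voxel_vol),
            class = "strokecbv_infeasible_volume_error")
    per_section <- apportion(n_total, avail)
    for (i in seq_along(positions)) {
      if (per_section[i] == 0) next
      take <- fill_order(comp_masks[[i]])[seq_len(per_section[i])]
      infarct[[i]][take] <- TRUE
    }
  }

  structure(list(
    sections = tibble::tibble(position = positions, level = levels),
    infarct = infarct,
    ipsi_hemisphere = ipsi_masks,
    contra_hemisphere = contra_masks,
    grid = grid, spacing = spacing,
    occluded_side = ipsi_side, animal_id = record$id),
    class = "infarct_trace_set")
}

#' @export
print.infarct_trace_set <- function(x, ...) {
  cat(sprintf("<infarct_trace_set> animal %s, %d sections at %.1f mm spacing, infarct %.1f mm^3\n",
              x$animal_id, nrow(x$sections), x$spacing,
              volume_from_traces(x, "infarct")))
  invisible(x)
}
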