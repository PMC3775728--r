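#' Volume of a traced mask set
#'
#' Integrates per-section mask areas over the section spacing:
#' volume = sum over sections of (voxel count x pixel_size^2 x spacing).
#'
#' @param traces An `infarct_trace_set` ([generate_infarct_traces()]).
#' @param mask_role Which mask to integrate: `"infarct"`, `"ipsi"` or
#'   `"contra"` (hemispheres).
#' @return Volume in mm^3.
#' @export
volume_from_traces <- function(traces, mask_role = c("infarct", "ipsi", "contra")) {
  mask_role <- match.arg(mask_role)
  masks <- switch(mask_role, infarct = traces$infarct,
                  ipsi = traces$ipsi_hemisphere, contra = traces$contra_hemisphere)
  for (m in masks)
    if (nrow(m) != traces$grid$n_rows || ncol(m) != traces$grid$n_cols)
      abort("inconsistent section mask shapes.", class = "strokecbv_dimension_error")
  sum(vapply(masks, sum, numeric(1))) * traces$grid$pixel_size^2 * traces$spacing
}

#' Edema-correct a raw infarct volume
#'
#' Rescales the raw traced infarct volume by the contralateral/ipsilateral
#' hemisphere volume ratio, removing the bias introduced by ipsilateral
#' swelling: corrected = raw x (contra / ipsi).
#'
#' @param raw Raw infarct volume, mm^3 (>= 0).
#' @param contra,ipsi Contralateral and ipsilateral hemisphere volumes, mm^3
#'   (> 0).
#' @return Corrected infarct volume, mm^3.
#' @examples
#' edema_correct(100, 500, 550)  # swelling shrinks the estimate
#' @export
edema_correct <- function(raw, contra, ipsi) {
  if (any(contra <= 0) || any(ipsi <= 0))
    abort("hemisphere volumes must be > 0.", class = "strokecbv_domain_error")
  if (any(raw < 0))
    abort("raw infarct volume must be >= 0.", class = "strokecbv_domain_error")
  raw * contra / ipsi
}

#' Partition an infarct into cortical and subcortical volumes
#'
#' Intersects each section's infarct mask with the cortex and subcortex masks
#' of the atlas level registered to that section. Because cortex and subcortex
#' tile the brain, the two parts sum to the total infarct volume.
#'
#' @param traces An `infarct_trace_set`.
#' @param atlas The [build_atlas()] atlas (same grid).
#' @return Named numeric vector `c(cortical =, subcortical =)`, mm^3.
#' @export
split_cortical_subcortical <- function(traces, atlas) {
  if (atlas$grid$n_rows != traces$grid$n_rows || atlas$grid$n_cols != traces$grid$n_cols)
    abort("trace grid does not match atlas grid.", class = "strokecbv_dimension_error")
  vv <- traces$grid$pixel_size^2 * traces$spacing
  counts <- purrr::map2(traces$infarct, traces$sections$level, function(inf, lv) {
    m <- atlas$masks[[as.character(lv)]]
    c(cortical = sum(inf & m$cortex), subcortical = sum(inf & m$subcortex))
  })
  tot <- Reduce(`+`, counts)
  tot * vv
}

#' Per-animal volume report
#'
#' Runs the full volumetry chain for one trace set: raw infarct volume,
#' hemisphere volumes, edema correction, and the cortical/subcortical split
#' (each compartment corrected by the same hemisphere ratio).
#'
#' @param traces An `infarct_trace_set`.
#' @param atlas The atlas.
#' @return One-row tibble: `animal_id`, `raw_volume`, `contra_volume`,
#'   `ipsi_volume`, `corrected_volume`, `corrected_cortical`,
#'   `corrected_subcortical` (mm^3).
#' @export
volume_report <- function(traces, atlas) {
  raw <- volume_from_traces(traces, "infarct")
  contra <- volume_from_traces(traces, "contra")
  ipsi <- volume_from_traces(traces, "ipsi")
  split <- split_cortical_subcortical(traces, atlas)
  tibble::tibble(
    animal_id = traces$animal_id,
    raw_volume = raw,
    contra_volume = contra,
    ipsi_volume = ipsi,
    corrected_volume = edema_correct(raw, contra, ipsi),
    corrected_cortical = edema_correct(split[["cortical"]], contra, ipsi),
    corrected_subcortical = edema_correct(split[["subcortical"]], contra, ipsi))
}

#' Infarct probability map across animals
#'
#' For a stack of registered binary infarct masks, computes the per-voxel
#' fraction of animals whose infarct covers the voxel (k/n), plus the
#' stacked-tracing rendering in which each animal's outline is composited at
#' 24% opacity, giving intensity 1 - (1 - 0.24)^k — the display in which
#' lighter regions are more commonly infarcted.
#'
#' @param mask_stack List of logical matrices (one per animal), same shape.
#' @param level Bregma level the masks come from, mm (metadata).
#' @param opacity Per-layer compositing opacity for the rendering.
#' @return An `infarct_probability_map`: `fraction` and `rendering` matrices,
#'   `n`, `level`, `opacity`.
#' @examples
#' m <- matrix(FALSE, 16, 16); m[4:8, 4:8] <- TRUE
#' pm <- probability_map(list(m, m, !m), level = -0.3)
#' range(pm$fraction)
#' @export
probability_map <- function(mask_stack, level = NA_real_, opacity = 0.24) {
  if (length(mask_stack) < 1L)
    abort("mask stack must contain at least one mask.", class = "strokecbv_input_error")
  d <- dim(mask_stack[[1]])
  for (m in mask_stack)
    if (!identical(dim(m), d))
      abort("masks in the stack must share a grid.", class = "strokecbv_dimension_error")
  n <- length(mask_stack)
  k <- Reduce(`+`, lapply(mask_stack, function(m) m * 1L))
  structure(list(fraction = k / n, counts = k, n = n, level = level,
                 opacity = opacity, rendering = 1 - (1 - opacity)^k),
            class = "infarct_probability_map")
}

#' @export
print.infarct_probability_map <- function(x, ...) {
  cat(sprintf("<infarct_probability_map> n = %d animals, level %s mm, max fraction %.2f\n",
              x$n, x$level, max(x$fraction)))
  invisible(x)
}
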