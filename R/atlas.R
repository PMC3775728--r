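#' Coronal imaging grid specification
#'
#' Describes the voxel grid shared by CBV maps, territory masks and histology
#' traces: in-plane matrix size, physical pixel size, slice thickness and the
#' rostro-caudal positions (mm from bregma) of the analysed coronal levels.
#'
#' The default reproduces the perfusion-CT acquisition scale of the rat MCAo
#' model this package targets — a 512x512 matrix over a 50 mm field of view
#' (pixel size 50/512 mm) with 2.4 mm slices analysed at bregma 0 mm and
#' -2.4 mm — but on a 128x128 grid at the same pixel size so that simulated
#' studies stay light. Pass `n_rows = 512, n_cols = 512` for the native matrix.
#'
#' @param n_rows,n_cols Grid dimensions in voxels (>= 16; `n_cols` must be
#'   even so the midline falls between columns and mirror symmetry is exact).
#' @param pixel_size Edge length of one voxel, mm.
#' @param slice_thickness Slice thickness, mm.
#' @param bregma_levels Strictly decreasing rostro-caudal slice positions, mm
#'   relative to bregma.
#' @return A `grid_spec` object.
#' @examples
#' grid_spec()
#' @export
grid_spec <- function(n_rows = 128L, n_cols = 128L, pixel_size = 50 / 512,
                      slice_thickness = 2.4, bregma_levels = c(0, -2.4)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 16L || n_cols < 16L)
    abort("grid must be at least 16x16 voxels.", class = "strokecbv_geometry_error")
  if (n_cols %% 2L != 0L)
    abort("`n_cols` must be even (midline between columns).", class = "strokecbv_geometry_error")
  stopifnot_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar_number(slice_thickness, "slice_thickness", positive = TRUE)
  if (length(bregma_levels) < 1L || is.unsorted(rev(bregma_levels), strictly = TRUE))
    abort("`bregma_levels` must be strictly decreasing (rostral to caudal).",
          class = "strokecbv_geometry_error")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size,
         slice_thickness = slice_thickness, bregma_levels = bregma_levels),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %dx%d voxels, %.4f mm/px, %.1f mm slices, levels: %s mm\n",
              x$n_rows, x$n_cols, x$pixel_size, x$slice_thickness,
              paste(x$bregma_levels, collapse = ", ")))
  invisible(x)
}

# Elliptical coordinates used by every territory shape: for each voxel centre,
# the signed lateral offset u (columns, + = image right), the vertical offset
# v (rows), and the normalised elliptical radius rho of the brain outline.
grid_coords <- function(grid, shape) {
  cx <- grid$n_cols / 2
  cy <- grid$n_rows / 2
  col <- matrix(rep(seq_len(grid$n_cols) - 0.5, each = grid$n_rows),
                nrow = grid$n_rows)
  row <- matrix(rep(seq_len(grid$n_rows) - 0.5, times = grid$n_cols),
                nrow = grid$n_rows)
  u <- col - cx
  v <- row - cy
  a <- shape$hemisphere_width_frac * grid$n_cols / 2
  b <- shape$hemisphere_height_frac * grid$n_rows / 2
  rho <- sqrt((u / a)^2 + (v / b)^2)
  list(u = u, v = v, rho = rho, a = a, b = b)
}

default_shape_params <- function() {
  list(
    hemisphere_width_frac = 0.84,   # full brain width as fraction of grid width
    hemisphere_height_frac = 0.72,
    subcortex_rho = 0.55,           # elliptical radius separating subcortex from cortex
    mca_inner_rho = 0.35,           # MCA sector: rho >= this ...
    mca_half_angle = 60,            # ... within +/- this many degrees of lateral horizontal
    acha_center_rho = 0.28,         # AChA blob centre along the ventro-medial axis
    acha_center_angle = 80,         # degrees ventral of the lateral horizontal
    acha_radius_frac = 0.08         # blob radius as fraction of hemisphere half-width
  )
}

#' Build a parametric coronal territory atlas
#'
#' Constructs per-level binary masks for the left/right hemispheres, cortex,
#' subcortex, the middle cerebral artery (MCA) territory and the anterior
#' choroidal artery (AChA) territory on a shared grid. The atlas is a
#' parametric stand-in for rat coronal anatomy: each hemisphere is a
#' half-ellipse, cortex is the outer elliptical shell, the MCA territory is a
#' lateral sector spanning cortex and subcortex, and the AChA territory is a
#' small ventro-medial subcortical blob present only on the caudal level
#' (the AChA supply is entirely subcortical and is assessed caudally).
#'
#' Masks are built on the image-right half and mirrored, so left/right masks
#' are exact mirror images about the inter-column midline. Laterality is
#' carried as explicit metadata (`laterality_convention`), never inferred from
#' pixel order.
#'
#' @param grid A [grid_spec()].
#' @param shape_params Named list of territory-shape parameters; see
#'   `default_shape_params` in the source for the full set. Partial lists are
#'   merged over the defaults.
#' @param laterality_convention Which anatomical side image-right is;
#'   `"neurological"` (image right = anatomical right, the default) or
#'   `"radiological"`.
#' @return A `territory_atlas`: the grid, the shape parameters, the laterality
#'   convention, and `masks[[level]][[name]]` logical matrices for each bregma
#'   level, with names `left_hemisphere`, `right_hemisphere`, `brain`,
#'   `cortex`, `subcortex`, `mca_territory`, `acha_territory` (territory masks
#'   are further split by `_left`/`_right` suffixed entries).
#' @examples
#' atlas <- build_atlas()
#' sapply(atlas$masks[["-2.4"]], sum)
#' @export
build_atlas <- function(grid = grid_spec(), shape_params = list(),
                        laterality_convention = c("neurological", "radiological")) {
  laterality_convention <- match.arg(laterality_convention)
  shape <- utils::modifyList(default_shape_params(), shape_params)
  co <- grid_coords(grid, shape)
  right_half <- co$u > 0

  brain <- co$rho <= 1
  right_hemi <- brain & right_half
  if (!any(right_hemi))
    abort("degenerate shape parameters: empty hemisphere.", class = "strokecbv_geometry_error")

  subcortex <- brain & co$rho <= shape$subcortex_rho
  cortex <- brain & !subcortex

  # lateral sector: angle measured from the outward horizontal of each side
  theta <- atan2(co$v, abs(co$u)) * 180 / pi
  mca <- brain & co$rho >= shape$mca_inner_rho & abs(theta) <= shape$mca_half_angle
  if (!any(mca & right_half))
    abort("degenerate shape parameters: empty MCA territory.", class = "strokecbv_geometry_error")
  if (!any(mca & cortex) || !any(mca & subcortex))
    abort("MCA territory must span cortex and subcortex.", class = "strokecbv_geometry_error")

  # AChA blob (right side), clipped to subcortex; mirrored for left
  ang <- shape$acha_center_angle * pi / 180
  acx <- shape$acha_center_rho * co$a * cos(ang)
  acy <- shape$acha_center_rho * co$b * sin(ang)
  ar <- shape$acha_radius_frac * co$a
  acha_r <- subcortex & sqrt((co$u - acx)^2 + (co$v - acy)^2) <= ar & right_half & !mca
  if (!any(acha_r))
    abort("degenerate shape parameters: empty AChA territory.", class = "strokecbv_geometry_error")

  mirror <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  caudal <- min(grid$bregma_levels)

  masks <- lapply(grid$bregma_levels, function(level) {
    acha_right <- if (level == caudal) acha_r else acha_r & FALSE
    list(
      left_hemisphere = mirror(right_hemi),
      right_hemisphere = right_hemi,
      brain = brain,
      cortex = cortex,
      subcortex = subcortex,
      mca_territory = mca,
      mca_territory_left = mirror(mca & right_half),
      mca_territory_right = mca & right_half,
      acha_territory = acha_right | mirror(acha_right),
      acha_territory_left = mirror(acha_right),
      acha_territory_right = acha_right
    )
  })
  names(masks) <- as.character(grid$bregma_levels)

  structure(
    list(grid = grid, shape_params = shape,
         laterality_convention = laterality_convention, masks = masks),
    class = "territory_atlas")
}

#' @export
print.territory_atlas <- function(x, ...) {
  cat(sprintf("<territory_atlas> %dx%d grid, levels %s mm, laterality: %s\n",
              x$grid$n_rows, x$grid$n_cols,
              paste(names(x$masks), collapse = ", "), x$laterality_convention))
  for (lv in names(x$masks))
    cat(sprintf("  level %s: brain %d vx, MCA %d vx, AChA %d vx\n", lv,
                sum(x$masks[[lv]]$brain), sum(x$masks[[lv]]$mca_territory),
                sum(x$masks[[lv]]$acha_territory)))
  invisible(x)
}

# Hemisphere mask for one side ("left"/"right"); side is anatomical under the
# atlas's declared convention.
hemisphere_mask <- function(atlas, level, side) {
  m <- atlas$masks[[as.character(level)]]
  if (is.null(m)) abort(sprintf("no atlas level at %s mm.", level),
                        class = "strokecbv_geometry_error")
  if (atlas$laterality_convention == "radiological") side <- setdiff(c("left", "right"), side)
  m[[paste0(side, "_hemisphere")]]
}

#' Physical volume of a binary mask set
#'
#' Sums voxel counts over slices and converts to mm^3 using the grid's pixel
#' size and slice thickness.
#'
#' @param mask A logical matrix or a list of logical matrices (one per slice).
#' @param grid The [grid_spec()] the masks live on.
#' @return Volume in mm^3.
#' @examples
#' g <- grid_spec()
#' m <- matrix(FALSE, g$n_rows, g$n_cols); m[1:10, 1:10] <- TRUE
#' mask_volume(m, g)
#' @export
mask_volume <- function(mask, grid) {
  if (is.matrix(mask)) mask <- list(mask)
  counts <- vapply(mask, function(m) {
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      abort("mask dimensions do not match the grid.", class = "strokecbv_dimension_error")
    sum(m)
  }, numeric(1))
  sum(counts) * grid$pixel_size^2 * grid$slice_thickness
}
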