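# Shared fixtures, built in code.

# Compact atlas covering the same physical extent on a quarter of the voxels;
# used where per-voxel layout does not matter.
make_test_atlas <- function() {
  build_atlas(grid_spec(n_rows = 64L, n_cols = 64L, pixel_size = 50 / 256))
}

make_zero_noise_config <- function(...) {
  cohort_config(cbv_noise_sd = 0, ...)
}

# Minimal hand-built trace set for volumetry arithmetic.
manual_trace_set <- function(infarct, grid, spacing, levels = NULL,
                             ipsi = NULL, contra = NULL) {
  if (is.matrix(infarct)) infarct <- list(infarct)
  n <- length(infarct)
  positions <- seq(0, by = -spacing, length.out = n)
  if (is.null(levels)) levels <- rep(grid$bregma_levels[1], n)
  empty <- matrix(FALSE, grid$n_rows, grid$n_cols)
  structure(list(
    sections = tibble::tibble(position = positions, level = levels),
    infarct = infarct,
    ipsi_hemisphere = ipsi %||% rep(list(empty), n),
    contra_hemisphere = contra %||% rep(list(empty), n),
    grid = grid, spacing = spacing,
    occluded_side = "right", animal_id = "manual"),
    class = "infarct_trace_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Affine-rescales a base vector to exact sample mean/SD; a pooled t computed
# from such samples depends only on the summary statistics.
sample_with_moments <- function(n, mean, sd, base = seq_len(n)) {
  x <- as.numeric(base)
  (x - mean(x)) / stats::sd(x) * sd + mean
}
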