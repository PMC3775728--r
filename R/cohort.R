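#' Synthetic cohort configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults encode
#' the study design this package emulates: 28 Wistar rats (300-500 g) in three
#' occlusion-duration groups — permanent (n = 13), 1 h (n = 8), 2 h (n = 7) —
#' with inadvertent AChA occlusion in 7, 2 and 1 animals respectively.
#' Stratum infarct-volume distributions use the published permanent-group
#' summaries (AChAo 144.5 +/- 11.72 mm^3; MCAo-alone 42.7 +/- 27.62 mm^3);
#' the temporary-group means, which were not published per stratum, are
#' back-calculated from the pooled and permanent summaries
#' ((18*24.6 - 6*42.7)/12 = 15.55 and (10*129.6 - 7*144.5)/3 = 94.83 mm^3)
#' with the pooled SD of the matching AChAo class.
#'
#' @param group_sizes Named integer vector `c(permanent=, h1=, h2=)`.
#' @param achao_counts Animals per group with AChA occlusion (same names).
#' @param volume_params Data frame with columns `group` ("permanent"/"h1"/"h2"),
#'   `achao` (logical), `mean`, `sd` (mm^3) and `cortical_frac` (mean share of
#'   the infarct that is cortical).
#' @param cortical_frac_sd SD of the per-animal cortical fraction (truncated
#'   to \[0, 1\]).
#' @param weight_range Body-weight range, g (uniform, independent of volume).
#' @param swelling_fraction Uniform ipsilateral edema swelling (ipsi volume =
#'   contra x (1 + fraction)).
#' @param contra_hemisphere_volume Nominal contralateral hemisphere volume,
#'   mm^3 (cohort-table bookkeeping; trace-derived volumes come from the atlas).
#' @param cbv_baseline Mean normal-tissue CBV, ml/100 g.
#' @param cbv_noise_sd Voxelwise CBV noise SD, ml/100 g.
#' @param mca_residual_fraction Fraction of baseline CBV remaining in the
#'   ipsilateral MCA territory after occlusion.
#' @param acha_residual_fraction Fraction remaining in the ipsilateral AChA
#'   territory when the AChA is occluded.
#' @param acha_patent_factor Multiple of baseline in the AChA territory when
#'   patent (>= 1; choroidal blood volume is conspicuous on CBV maps).
#' @param vessel_count Planted large-vessel voxels per hemisphere per slice.
#' @param vessel_value CBV assigned to planted vessel voxels, ml/100 g
#'   (must exceed the 10 ml/100 g large-vessel threshold).
#' @param n_sections,section_spacing Histology trace geometry: number of
#'   coronal sections and their spacing (mm). Sections are centred so that the
#'   -0.3 and -2.3 mm bregma levels used for probability maps are included.
#' @param occluded_side Anatomical side of the occlusion (`"right"` in this
#'   model).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(permanent = 13L, h1 = 8L, h2 = 7L),
                          achao_counts = c(permanent = 7L, h1 = 2L, h2 = 1L),
                          volume_params = default_volume_params(),
                          cortical_frac_sd = 0.08,
                          weight_range = c(300, 500),
                          swelling_fraction = 0.10,
                          contra_hemisphere_volume = 550,
                          cbv_baseline = 4,
                          cbv_noise_sd = 0.5,
                          mca_residual_fraction = 0.3,
                          acha_residual_fraction = 0.1,
                          acha_patent_factor = 1.3,
                          vessel_count = 6L,
                          vessel_value = 15,
                          n_sections = 8L,
                          section_spacing = 2,
                          occluded_side = "right") {
  groups <- c("permanent", "h1", "h2")
  if (!all(groups %in% names(group_sizes)) || !all(groups %in% names(achao_counts)))
    abort("group_sizes and achao_counts need names permanent/h1/h2.",
          class = "strokecbv_config_error")
  if (any(group_sizes < 0) || any(achao_counts < 0))
    abort("group sizes and AChAo counts must be >= 0.", class = "strokecbv_config_error")
  if (any(achao_counts[groups] > group_sizes[groups]))
    abort("AChAo count exceeds group size.", class = "strokecbv_config_error")
  if (any(volume_params$sd < 0) || cortical_frac_sd < 0 || cbv_noise_sd < 0)
    abort("SDs must be >= 0.", class = "strokecbv_config_error")
  for (f in c("mca_residual_fraction", "acha_residual_fraction"))
    if (get(f) < 0 || get(f) > 1)
      abort(sprintf("`%s` must lie in [0, 1].", f), class = "strokecbv_config_error")
  if (vessel_value <= 10)
    abort("`vessel_value` must exceed the 10 ml/100 g large-vessel threshold.",
          class = "strokecbv_config_error")
  if (swelling_fraction < 0)
    abort("`swelling_fraction` must be >= 0.", class = "strokecbv_config_error")
  structure(list(
    group_sizes = group_sizes[groups], achao_counts = achao_counts[groups],
    volume_params = volume_params, cortical_frac_sd = cortical_frac_sd,
    weight_range = weight_range, swelling_fraction = swelling_fraction,
    contra_hemisphere_volume = contra_hemisphere_volume,
    cbv_baseline = cbv_baseline, cbv_noise_sd = cbv_noise_sd,
    mca_residual_fraction = mca_residual_fraction,
    acha_residual_fraction = acha_residual_fraction,
    acha_patent_factor = acha_patent_factor,
    vessel_count = as.integer(vessel_count), vessel_value = vessel_value,
    n_sections = as.integer(n_sections), section_spacing = section_spacing,
    occluded_side = occluded_side), class = "cohort_config")
}

#' Default stratum infarct-volume distributions
#'
#' Published permanent-group summaries plus back-calculated temporary-group
#' means (see [cohort_config()]). Cortical fractions for the permanent strata
#' are the ratios of the published cortical means to the stratum totals
#' (85.2/144.5 and 14.2/42.7); temporary strata reuse their class's fraction.
#'
#' @return A tibble with one row per (group, AChAo) stratum.
#' @export
default_volume_params <- function() {
  tibble::tibble(
    group = rep(c("permanent", "h1", "h2"), each = 2),
    achao = rep(c(TRUE, FALSE), 3),
    mean = c(144.5, 42.7, 94.83333333333333, 15.55, 94.83333333333333, 15.55),
    sd = c(11.72, 27.62, 41.58, 23.38, 41.58, 23.38),
    cortical_frac = c(85.2 / 144.5, 14.2 / 42.7,
                      85.2 / 144.5, 14.2 / 42.7,
                      85.2 / 144.5, 14.2 / 42.7))
}

group_labels <- c(permanent = "permanent", h1 = "1h", h2 = "2h")
# Occlusion duration in hours; permanent is carried to the 24 h endpoint.
duration_coding <- c(permanent = 24, h1 = 1, h2 = 2)

#' Generate a synthetic cohort of animals
#'
#' Draws one row per animal: occlusion group, true AChA-occlusion status
#' (design margins, assigned to the first animals of each group), body weight
#' (uniform, independent of infarct volume), and total/cortical/subcortical
#' infarct volumes drawn from the stratum's normal distribution truncated at
#' zero. Each animal uses an independent substream keyed on (seed, id), so the
#' cohort is reproducible animal-by-animal.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `group`, `duration_h`, `acha_occluded`,
#'   `weight_g`, `infarct_volume_total`, `infarct_volume_cortical`,
#'   `infarct_volume_subcortical`, `contra_hemisphere_volume`,
#'   `ipsi_hemisphere_volume` (all volumes mm^3).
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' dplyr::count(cohort, group, acha_occluded)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  rows <- purrr::map(names(config$group_sizes), function(g) {
    n <- config$group_sizes[[g]]
    k <- config$achao_counts[[g]]
    if (n == 0L) return(NULL)
    tibble::tibble(
      id = sprintf("%s-%02d", toupper(substr(group_labels[[g]], 1, 4)), seq_len(n)),
      group = group_labels[[g]],
      duration_h = duration_coding[[g]],
      acha_occluded = seq_len(n) <= k,
      .group_key = g)
  })
  cohort <- dplyr::bind_rows(rows)

  params <- config$volume_params
  draws <- purrr::pmap(
    list(cohort$id, cohort$.group_key, cohort$acha_occluded),
    function(id, g, achao) {
      p <- params[params$group == g & params$achao == achao, ]
      if (nrow(p) != 1L)
        abort(sprintf("no volume parameters for stratum (%s, achao=%s).", g, achao),
              class = "strokecbv_config_error")
      set.seed(substream_seed(seed, "animal", id))
      total <- rnorm_trunc0(1L, p$mean, p$sd)
      frac <- rnorm_trunc0(1L, p$cortical_frac, config$cortical_frac_sd)
      frac <- min(frac, 1)
      weight <- runif(1L, config$weight_range[1], config$weight_range[2])
      tibble::tibble(weight_g = weight,
                     infarct_volume_total = total,
                     infarct_volume_cortical = total * frac,
                     infarct_volume_subcortical = total * (1 - frac))
    })
  out <- dplyr::bind_cols(dplyr::select(cohort, -".group_key"),
                          dplyr::bind_rows(draws))
  out$contra_hemisphere_volume <- config$contra_hemisphere_volume
  out$ipsi_hemisphere_volume <-
    config$contra_hemisphere_volume * (1 + config$swelling_fraction)
  out
}

#' Simulate the pooled two-stratum infarct-volume model
#'
#' Draws `n` animals from the pooled-cohort mixture: with probability `p_achao`
#' the animal has AChA occlusion and its volume is Normal(mean1, sd1),
#' otherwise Normal(mean0, sd0). Defaults are the published pooled group
#' summaries (129.6 +/- 41.58 vs 24.6 +/- 23.38 mm^3, 10 of 28 occluded).
#' Used for large-sample checks of the point-biserial correlation between the
#' occlusion indicator and volume; draws are plain normal by default.
#'
#' @param n Number of simulated animals.
#' @param seed Integer seed.
#' @param p_achao Mixing proportion.
#' @param mean1,sd1 AChAo stratum volume distribution, mm^3.
#' @param mean0,sd0 Non-AChAo stratum volume distribution, mm^3.
#' @param truncate If `TRUE`, truncate draws at 0 as [generate_cohort()] does.
#' @return A tibble with columns `acha_occluded` (0/1) and `volume` (mm^3).
#' @examples
#' sim <- simulate_pooled_volumes(5000, seed = 1)
#' pearson_r(sim$acha_occluded, sim$volume)$r
#' @export
simulate_pooled_volumes <- function(n, seed = 1L, p_achao = 10 / 28,
                                    mean1 = 129.6, sd1 = 41.58,
                                    mean0 = 24.6, sd0 = 23.38,
                                    truncate = FALSE) {
  set.seed(substream_seed(seed, "pooled-mixture"))
  z <- runif(n) < p_achao
  draw <- if (truncate) rnorm_trunc0 else rnorm
  vol <- numeric(n)
  vol[z] <- draw(sum(z), mean1, sd1)
  vol[!z] <- draw(sum(!z), mean0, sd0)
  tibble::tibble(acha_occluded = as.integer(z), volume = vol)
}
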