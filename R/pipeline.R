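#' Full study configuration
#'
#' Bundles the geometry, cohort, classification and statistics settings plus
#' the global seed into one serializable object; a study report embeds the
#' resolved configuration and its hash so every run is reproducible.
#'
#' @param grid A [grid_spec()].
#' @param shape_params Territory-shape overrides for [build_atlas()].
#' @param cohort A [cohort_config()].
#' @param vessel_threshold Large-vessel CBV threshold, ml/100 g.
#' @param tolerance_voxels AChA supra-threshold voxel tolerance.
#' @param infarct_threshold Infarct-prediction CBV threshold, ml/100 g.
#' @param screening_alpha Predictor screening level.
#' @param t_variant `"pooled"` or `"welch"`.
#' @param normality `"group"` or `"cell"` normality gating.
#' @param seed Global integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(grid = grid_spec(), shape_params = list(),
                         cohort = cohort_config(),
                         vessel_threshold = 10, tolerance_voxels = 0L,
                         infarct_threshold = 2,
                         screening_alpha = 0.10,
                         t_variant = "pooled", normality = "group",
                         seed = 1L) {
  structure(list(grid = grid, shape_params = shape_params, cohort = cohort,
                 vessel_threshold = vessel_threshold,
                 tolerance_voxels = as.integer(tolerance_voxels),
                 infarct_threshold = infarct_threshold,
                 screening_alpha = screening_alpha,
                 t_variant = t_variant, normality = normality,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid_args <- y$grid %||% list()
  cohort_args <- y$cohort %||% list()
  for (f in c("group_sizes", "achao_counts"))
    if (!is.null(cohort_args[[f]])) cohort_args[[f]] <- unlist(cohort_args[[f]])
  if (!is.null(cohort_args$volume_params))
    cohort_args$volume_params <- tibble::as_tibble(
      purrr::map_dfr(cohort_args$volume_params, tibble::as_tibble))
  rest <- y[setdiff(names(y), c("grid", "cohort", "shape_params"))]
  do.call(study_config, c(
    list(grid = do.call(grid_spec, grid_args),
         shape_params = y$shape_params %||% list(),
         cohort = do.call(cohort_config, cohort_args)),
    rest))
}

#' @rdname read_study_config
#' @param config A `study_config`.
#' @export
write_study_config <- function(config, path) {
  y <- list(
    grid = unclass(config$grid),
    shape_params = config$shape_params,
    cohort = {
      cc <- unclass(config$cohort)
      cc$group_sizes <- as.list(cc$group_sizes)
      cc$achao_counts <- as.list(cc$achao_counts)
      cc$volume_params <- purrr::transpose(as.list(cc$volume_params))
      cc
    },
    vessel_threshold = config$vessel_threshold,
    tolerance_voxels = config$tolerance_voxels,
    infarct_threshold = config$infarct_threshold,
    screening_alpha = config$screening_alpha,
    t_variant = config$t_variant, normality = config$normality,
    seed = config$seed)
  yaml::write_yaml(y, path, precision = 17L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

round_signif <- function(df, digits = 6) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double), ~ signif(.x, digits)))
}

#' Run the full simulated study
#'
#' End-to-end orchestration: build the atlas, generate the cohort, generate
#' per-animal CBV maps and classify AChA occlusion from the maps alone
#' (blinded to the planted truth and to infarct outcome), generate histology
#' traces and compute edema-corrected volumetry, build infarct probability
#' maps for the permanent group, and run the inference chain (group
#' comparisons, predictor screening at p < 0.10, standardized multiple
#' regression of corrected volume on the screened predictors). The regression
#' uses the map-derived AChAo call, not the generator's truth flag.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory; when given, cohort,
#'   classification, volume and statistics tables are written as CSV/JSON
#'   (doubles rounded to 6 significant digits) and probability maps as
#'   plain-text CSV grids.
#' @return A `study_report` list: `atlas`, `cohort`, `classification`,
#'   `volumes`, `analysis_table`, `comparisons`, `screening`, `regression`
#'   (or NULL if no predictor survives screening), `probability_maps`,
#'   `warnings`, `config`, `config_hash`, `seed`.
#' @examples
#' \donttest{
#' rep <- run_study(study_config(seed = 1))
#' rep$comparisons
#' }
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  atlas <- build_atlas(config$grid, config$shape_params)
  cohort <- generate_cohort(config$cohort, seed)

  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed for animal %s: %s", what, id,
                    conditionMessage(e)),
            class = "strokecbv_stage_error", parent = e)
    })
  }

  ids <- cohort$id
  map_sets <- lapply(seq_along(ids), function(i)
    stage("cbv-maps", ids[i],
          generate_cbv_maps(cohort[i, ], atlas, config$cohort, seed)))
  names(map_sets) <- ids
  classification <- classify_cohort(map_sets, atlas,
                                    vessel_threshold = config$vessel_threshold,
                                    tolerance_voxels = config$tolerance_voxels)

  traces <- lapply(seq_along(ids), function(i)
    stage("infarct-traces", ids[i],
          generate_infarct_traces(cohort[i, ], atlas, seed, config$cohort)))
  names(traces) <- ids
  volumes <- dplyr::bind_rows(lapply(traces, volume_report, atlas = atlas))

  # analysis table: corrected volumes + blinded AChAo call + predictors
  analysis <- cohort |>
    dplyr::select("id", "group", "duration_h", "weight_g") |>
    dplyr::left_join(dplyr::select(classification, id = "animal_id",
                                   acha_occluded = "acha_occluded"),
                     by = "id") |>
    dplyr::left_join(dplyr::select(volumes, id = "animal_id",
                                   "corrected_volume", "corrected_cortical",
                                   "corrected_subcortical"),
                     by = "id")

  comparisons <- run_group_comparisons(analysis, "corrected_volume",
                                       variant = config$t_variant,
                                       normality = config$normality)
  for (i in seq_len(nrow(comparisons)))
    if (!isTRUE(comparisons$analyzed[i]))
      note(sprintf("group %s: %s", comparisons$group[i], comparisons$note[i]))

  screening <- withCallingHandlers(
    screen_predictors(dplyr::mutate(analysis,
                                    acha_occluded = as.numeric(.data$acha_occluded)),
                      "corrected_volume",
                      c("acha_occluded", "duration_h", "weight_g"),
                      alpha = config$screening_alpha),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })

  kept <- screening$predictor[screening$included]
  regression <- if (length(kept) >= 1 && nrow(analysis) > length(kept) + 1) {
    fit_infarct_model(dplyr::mutate(analysis,
                                    acha_occluded = as.numeric(.data$acha_occluded)),
                      "corrected_volume", kept)
  } else {
    note("no predictor survived screening; regression skipped.")
    NULL
  }

  # probability maps: permanent-occlusion group at the two histology levels
  perm_ids <- cohort$id[cohort$group == "permanent"]
  prob_levels <- intersect(c(-0.3, -2.3),
                           round(traces[[1]]$sections$position, 6))
  probability_maps <- lapply(prob_levels, function(pos) {
    stack <- lapply(perm_ids, function(id) {
      i <- which(abs(traces[[id]]$sections$position - pos) < 1e-6)[1]
      traces[[id]]$infarct[[i]]
    })
    probability_map(stack, level = pos)
  })
  names(probability_maps) <- as.character(prob_levels)

  report <- structure(list(
    atlas = atlas, cohort = cohort, classification = classification,
    volumes = volumes, analysis_table = analysis,
    comparisons = comparisons, screening = screening, regression = regression,
    probability_maps = probability_maps, traces = traces,
    warnings = warnings, config = config, config_hash = rlang::hash(config),
    seed = seed), class = "study_report")

  if (!is.null(out_dir)) write_study_outputs(report, out_dir)
  report
}

write_study_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(round_signif(report$cohort), file.path(out_dir, "cohort.csv"))
  readr::write_csv(round_signif(report$classification),
                   file.path(out_dir, "classification.csv"))
  readr::write_csv(round_signif(report$volumes), file.path(out_dir, "volumes.csv"))
  readr::write_csv(round_signif(report$comparisons),
                   file.path(out_dir, "comparisons.csv"))
  readr::write_csv(round_signif(report$screening),
                   file.path(out_dir, "screening.csv"))
  stats_out <- list(
    config_hash = report$config_hash, seed = report$seed,
    warnings = report$warnings,
    screening = report$screening,
    regression = if (!is.null(report$regression))
      list(coefficients = tidy(report$regression),
           model = glance(report$regression)))
  jsonlite::write_json(stats_out, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE, force = TRUE)
  for (lv in names(report$probability_maps))
    utils::write.table(
      signif(report$probability_maps[[lv]]$fraction, 6),
      file.path(out_dir, sprintf("probability_map_bregma_%s.csv", lv)),
      sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}

#' Render a human-readable study report
#'
#' Formats the stratum summary (mean +/- SD), the group-comparison table with
#' its not-analyzed and normality flags, the screening table and the
#' standardized regression, with the configuration hash and seed embedded.
#'
#' @param report A `study_report` from [run_study()].
#' @return Character vector of report lines (one element per line).
#' @export
make_report <- function(report) {
  stopifnot(inherits(report, "study_report"))
  required <- c("cohort", "classification", "volumes", "comparisons", "screening")
  missing <- required[vapply(required, function(f) is.null(report[[f]]), logical(1))]
  if (length(missing))
    abort(paste("report is missing stage outputs:", paste(missing, collapse = ", ")),
          class = "strokecbv_report_error")

  lines <- c(
    "Simulated MCAo / AChAo study report",
    sprintf("seed: %d   config hash: %s", report$seed, report$config_hash),
    "",
    "Stratum summary (corrected infarct volume, mm^3):")
  summ <- report$analysis_table |>
    dplyr::mutate(group = factor(.data$group, levels = c("1h", "2h", "permanent"))) |>
    dplyr::group_by(.data$group, .data$acha_occluded) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$corrected_volume),
                     sd = sd(.data$corrected_volume), .groups = "drop") |>
    dplyr::arrange(.data$group, .data$acha_occluded)
  lines <- c(lines, sprintf("  %-10s AChAo=%s  n=%2d  %6.1f +/- %5.1f",
                            as.character(summ$group), ifelse(summ$acha_occluded, "yes", "no "),
                            summ$n, summ$mean, ifelse(is.na(summ$sd), 0, summ$sd)))

  lines <- c(lines, "", "Group comparisons (AChAo vs patent):")
  cmp <- report$comparisons
  lines <- c(lines, sprintf(
    "  %-10s n=%d vs %d  %s",
    cmp$group, cmp$n_achao, cmp$n_patent,
    ifelse(cmp$analyzed,
           sprintf("t=%.2f df=%.1f p=%.3g%s", cmp$t, cmp$df, cmp$p_value,
                   ifelse(cmp$note == "", "", paste0("  [", cmp$note, "]"))),
           paste0("[", cmp$note, "]"))))

  lines <- c(lines, "", "Predictor screening (Pearson, include if p < 0.10):")
  sc <- report$screening
  lines <- c(lines, sprintf("  %-15s r=%6s p=%8s %s", sc$predictor,
                            ifelse(is.na(sc$r), "--", sprintf("%.3f", sc$r)),
                            ifelse(is.na(sc$p_value), "--", sprintf("%.2e", sc$p_value)),
                            ifelse(sc$included, "included", "excluded")))

  if (!is.null(report$regression)) {
    co <- tidy(report$regression)
    lines <- c(lines, "", "Standardized multiple regression (corrected volume):",
               sprintf("  %-15s beta=%.3f p=%.2e", co$term, co$beta, co$p_value),
               sprintf("  adjusted r^2 = %.3f (n = %d)",
                       report$regression$adj_r_squared, report$regression$n))
  }
  if (length(report$warnings))
    lines <- c(lines, "", "Warnings:", paste0("  - ", report$warnings))
  lines
}
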