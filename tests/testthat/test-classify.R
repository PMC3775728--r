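atlas <- make_test_atlas()
grid <- atlas$grid
cfg0 <- make_zero_noise_config()

uniform_map <- function(value, level = -2.4, side = "right") {
  cbv_map(matrix(value, grid$n_rows, grid$n_cols), grid, level, "u", side)
}

test_that("large-vessel exclusion flags strictly supra-threshold voxels only", {
  m <- uniform_map(5)
  expect_equal(sum(exclude_large_vessels(m)$excluded), 0)
  m$values[10, 10] <- 12
  ex <- exclude_large_vessels(m)
  expect_equal(which(ex$excluded), which(m$values == 12))
  m$values[10, 10] <- 10            # boundary: exactly at threshold stays in
  expect_equal(sum(exclude_large_vessels(m)$excluded), 0)
  expect_error(exclude_large_vessels(m, threshold = -1),
               class = "strokecbv_parameter_error")
  # values themselves are never modified
  expect_identical(exclude_large_vessels(m)$values, m$values)
})

test_that("contralateral mean ignores excluded vessel voxels", {
  m <- uniform_map(3)
  expect_equal(mean_contralateral_cbv(exclude_large_vessels(m), atlas), 3)
  left <- which(atlas$masks[["-2.4"]]$left_hemisphere)
  m$values[left[1]] <- 50
  expect_equal(mean_contralateral_cbv(exclude_large_vessels(m), atlas), 3)
  expect_error(mean_contralateral_cbv(m, atlas), class = "strokecbv_parameter_error")
  m$values[] <- 50                  # every contralateral voxel excluded
  expect_error(mean_contralateral_cbv(exclude_large_vessels(m), atlas),
               class = "strokecbv_empty_roi_error")
})

test_that("classifier recovers planted truth for every animal at zero noise", {
  cohort <- generate_cohort(cfg0, seed = 1)
  for (i in seq_len(nrow(cohort))) {
    maps <- generate_cbv_maps(cohort[i, ], atlas, cfg0, seed = 1)
    res <- classify_achao(maps, atlas)
    expect_equal(res$acha_occluded, cohort$acha_occluded[i])
    expect_equal(res$slice_used, -2.4)
  }
})

test_that("classification is invariant to added vessel voxels", {
  rec <- generate_cohort(cfg0, seed = 3)[1, ]
  maps <- generate_cbv_maps(rec, atlas, cfg0, seed = 3)
  base <- classify_achao(maps, atlas)
  tampered <- maps
  acha <- which(atlas$masks[["-2.4"]]$acha_territory_right)
  left <- which(atlas$masks[["-2.4"]]$left_hemisphere)
  tampered[["-2.4"]]$values[c(acha[1:3], left[1:5])] <- 80
  res <- classify_achao(tampered, atlas)
  expect_equal(res$acha_occluded, base$acha_occluded)
  expect_equal(res$mean_contralateral_cbv, base$mean_contralateral_cbv)
})

test_that("raising AChA signal can never flip a patent call to occluded", {
  rec0 <- generate_cohort(cfg0, seed = 2)
  rec <- rec0[!rec0$acha_occluded, ][1, ]
  maps <- generate_cbv_maps(rec, atlas, cfg0, seed = 2)
  expect_false(classify_achao(maps, atlas)$acha_occluded)
  up <- maps
  acha <- atlas$masks[["-2.4"]]$acha_territory_right
  up[["-2.4"]]$values[acha] <- up[["-2.4"]]$values[acha] + 2
  expect_false(classify_achao(up, atlas)$acha_occluded)
})

test_that("the call is equivariant to rescaling CBV and the vessel threshold", {
  cohort <- generate_cohort(cohort_config(), seed = 4)
  for (i in c(1, 14)) {
    maps <- generate_cbv_maps(cohort[i, ], atlas, cohort_config(), seed = 4)
    base <- classify_achao(maps, atlas, vessel_threshold = 10)
    scaled <- lapply(maps, function(m) { m$values <- m$values * 3; m })
    res <- classify_achao(scaled, atlas, vessel_threshold = 30)
    expect_equal(res$acha_occluded, base$acha_occluded)
    expect_equal(res$supra_threshold_voxels_in_acha,
                 base$supra_threshold_voxels_in_acha)
  }
})

test_that("the classifier never reads ground-truth flags", {
  rec <- generate_cohort(cfg0, seed = 6)[1, ]
  maps <- generate_cbv_maps(rec, atlas, cfg0, seed = 6)
  before <- classify_achao(maps, atlas)
  rec$acha_occluded <- !rec$acha_occluded   # flip truth after maps exist
  after <- classify_achao(maps, atlas)
  expect_identical(before, after)
})

test_that("tolerance_voxels shifts the occlusion boundary as a count", {
  m <- uniform_map(0.4)
  left <- atlas$masks[["-2.4"]]$left_hemisphere
  m$values[left] <- 4
  acha <- which(atlas$masks[["-2.4"]]$acha_territory_right)
  m$values[acha[1:2]] <- 5          # exactly 2 supra-threshold AChA voxels
  expect_false(classify_achao(m, atlas)$acha_occluded)
  expect_false(classify_achao(m, atlas, tolerance_voxels = 1)$acha_occluded)
  expect_true(classify_achao(m, atlas, tolerance_voxels = 2)$acha_occluded)
})

test_that("maps without an AChA-bearing level raise a geometry error", {
  m <- uniform_map(4, level = 0)
  expect_error(classify_achao(m, atlas), class = "strokecbv_geometry_error")
})

test_that("predicted-infarct mask uses a strict sub-threshold rule on brain voxels", {
  m <- uniform_map(5)
  expect_equal(sum(predicted_infarct_mask(m, atlas)), 0)
  brain <- which(atlas$masks[["-2.4"]]$brain)
  m$values[brain[1]] <- 2.0          # boundary: exactly 2 is not predicted
  m$values[brain[2]] <- 1.99
  expect_equal(which(predicted_infarct_mask(m, atlas)), brain[2])
  # background below threshold is never included
  m$values[] <- 0; m$values[brain] <- 5
  expect_equal(sum(predicted_infarct_mask(m, atlas)), 0)
})

test_that("at a residual fraction putting the MCA territory below 2 ml/100 g the
           predicted mask is exactly the ipsilateral MCA territory", {
  cfg <- make_zero_noise_config(mca_residual_fraction = 0.375,  # 4 * 0.375 = 1.5
                                vessel_count = 0L)
  rec0 <- generate_cohort(cfg, seed = 1)
  rec <- rec0[!rec0$acha_occluded, ][1, ]                       # patent AChA
  maps <- generate_cbv_maps(rec, atlas, cfg, seed = 1)
  for (lv in names(maps)) {
    pred <- predicted_infarct_mask(maps[[lv]], atlas)
    expect_identical(pred, atlas$masks[[lv]]$mca_territory_right)
  }
})
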