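test_that("trajectory defaults peak at day 7 (edema) and day 28 (tissue)", {
  tr <- trajectory_spec()
  expect_equal(tr$days, c(0L, 7L, 14L, 21L, 28L))
  expect_equal(tr$days[which.max(tr$edema_mm3)], 7L)
  expect_equal(tr$days[which.max(tr$tissue_mm3)], 28L)
  expect_equal(tr$edema_mm3[tr$days == 0], 0)
  expect_equal(tr$tissue_mm3[tr$days == 0], 0)
  expect_error(trajectory_spec(days = c(7, 14)), "day 0")
})

test_that("label maps hit the trajectory volume targets within one voxel", {
  tr <- small_trajectory()
  vv <- voxel_volume(small_grid())
  for (day in tr$days) {
    map <- make_label_map(small_grid(), tr, day, seed = tr$seed)
    i <- match(day, tr$days)
    expect_lte(abs(sum(class_mask(map, "edema")) * vv - tr$edema_mm3[i]), vv)
    expect_lte(abs(sum(class_mask(map, "fibrotic_tissue")) * vv -
                     tr$tissue_mm3[i]), vv)
  }
})

test_that("day-0 maps carry no lesion or border voxels", {
  map <- small_map(day = 0L)
  expect_equal(sum(class_mask(map, c("edema", "fibrotic_tissue",
                                     "active_border"))), 0)
})

test_that("generated edema volumes peak at day 7 for an explicit target curve", {
  tr <- trajectory_spec(seed = 9)
  tr$edema_mm3 <- c(0, 800, 500, 300, 200)
  vols <- vapply(tr$days, function(d)
    sum(class_mask(make_label_map(small_grid(), tr, d, seed = 9),
                   "edema")), numeric(1))
  expect_equal(tr$days[which.max(vols)], 7L)
})

test_that("label maps are deterministic and structurally valid", {
  a <- make_label_map(small_grid(), small_trajectory(), 28, seed = 42)
  b <- make_label_map(small_grid(), small_trajectory(), 28, seed = 42)
  expect_identical(a$labels, b$labels)
  # lesions, vessels and border lie inside the lung region
  inside <- class_mask(a, c("vessel", "edema", "fibrotic_tissue",
                            "active_border"))
  expect_true(all(lung_of(a)[inside]))
  # border is parenchyma-adjacent-to-lesion: every border voxel touches a
  # lesion voxel via a face
  lesion <- class_mask(a, c("edema", "fibrotic_tissue"))
  border <- class_mask(a, "active_border")
  d <- distance_transform(lesion, a$grid)
  expect_lte(max(d[border]), max(a$grid$spacing) + 1e-9)
  expect_error(make_label_map(small_grid(), small_trajectory(), 3),
               "valid days: 0, 7")
})

test_that("oversized lesion targets are rejected", {
  tr <- small_trajectory()
  tr$edema_mm3[2] <- 1e6
  expect_error(make_label_map(small_grid(), tr, 7), "exceeds")
})

test_that("echo simulation follows the exponential decay model exactly", {
  map <- small_map()
  props <- tissue_properties()
  # closed form: pd 100, t2* 10 ms, te 1 ms -> 100 * exp(-0.1)
  props$proton_density[props$class == "vessel"] <- 100
  props$t2_star_ms[props$class == "vessel"] <- 10
  img <- simulate_echo(map, props, te_ms = 1, noise_sigma = 0)
  vess <- class_mask(map, "vessel")
  expect_equal(unique(img[vess]), 100 * exp(-0.1), tolerance = 1e-12)
  # monotone decay: later echo never brighter, voxelwise
  e <- small_echoes(noise_sigma = 0)
  expect_true(all(e$long <= e$short + 1e-12))
  # fibrotic voxels fade between echoes, fluid voxels do not
  ratio <- function(t2) exp(-(1 - 0.324) / t2)
  expect_equal(ratio(0.7), 0.3807, tolerance = 1e-4)
  expect_equal(ratio(10), 0.9346, tolerance = 1e-4)
  fib <- class_mask(map, "fibrotic_tissue")
  expect_equal(unique(e$long[fib] / e$short[fib]), ratio(0.7),
               tolerance = 1e-12)
})

test_that("unknown class ids in a label map are rejected", {
  map <- small_map()
  map$labels[1] <- 99L
  expect_error(simulate_echo(map, te_ms = 1, noise_sigma = 0), "99")
})

test_that("rician noise is reproducible and unbiased at high signal", {
  map <- small_map()
  a <- simulate_echo(map, te_ms = 0.324, noise_sigma = 5, seed = 7)
  b <- simulate_echo(map, te_ms = 0.324, noise_sigma = 5, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_echo(map, te_ms = 0.324, noise_sigma = 5, seed = 8)
  expect_false(identical(a, c2))
  # at signal >> sigma the magnitude mean approaches the true signal
  vess <- class_mask(map, "vessel")
  expect_equal(mean(a[vess]), 100 * exp(-0.324 / 20), tolerance = 0.02)
})

test_that("pet simulation conserves activity without blur or noise", {
  map <- small_map()
  pet <- simulate_pet(map, pet_grid = map$grid, psf_fwhm_mm = 0,
                      injected_dose_mbq = 35, lung_dose_fraction = 0.015,
                      count_scale = Inf)
  # lesion-free phantom: lung %ID equals the configured fraction exactly
  map0 <- small_map(day = 0L)
  pet0 <- simulate_pet(map0, pet_grid = map0$grid, psf_fwhm_mm = 0,
                       injected_dose_mbq = 35, lung_dose_fraction = 0.015,
                       count_scale = Inf)
  expect_equal(percent_id(pet0, lung_of(map0)), 1.5, tolerance = 1e-9)
  # per-class means equal the assigned densities (noiseless, PSF-free)
  props <- tissue_properties()
  for (cl in c("lung_parenchyma", "vessel", "edema", "fibrotic_tissue")) {
    m <- class_mask(map, cl)
    expect_equal(length(unique(pet$activity[m])), 1L)
    ratio <- unique(pet$activity[m]) /
      unique(pet$activity[class_mask(map, "vessel")])
    expect_equal(ratio, props$pet_uptake[props$class == cl] /
                   props$pet_uptake[props$class == "vessel"],
                 tolerance = 1e-12)
  }
  # diseased lung holds more than the healthy-reference fraction
  expect_gt(percent_id(pet, lung_of(map)), 1.5)
})

test_that("pet border uptake exceeds distant parenchyma uptake", {
  map <- small_map()
  pet <- simulate_pet(map, psf_fwhm_mm = 1.0, count_scale = 1e7, seed = 2)
  border_pet <- transfer_mask(class_mask(map, "active_border"), map$grid,
                              pet$grid)
  lesion <- class_mask(map, c("edema", "fibrotic_tissue", "active_border"))
  par_pet <- transfer_mask(class_mask(map, "lung_parenchyma"), map$grid,
                           pet$grid)
  d <- distance_transform(transfer_mask(lesion, map$grid, pet$grid),
                          pet$grid)
  distant <- par_pet & d > 2
  expect_gt(mean(pet$activity[border_pet]), mean(pet$activity[distant]))
})

test_that("pet grid must cover the phantom and poisson noise is seeded", {
  map <- small_map()
  tiny <- grid_spec(c(10, 10, 10), 1)
  expect_error(simulate_pet(map, pet_grid = tiny), "cover")
  a <- simulate_pet(map, count_scale = 1e6, seed = 3)
  b <- simulate_pet(map, count_scale = 1e6, seed = 3)
  expect_identical(a$activity, b$activity)
})

test_that("longitudinal series carry consistent ground truth", {
  series <- fixture("series_small", function()
    make_series(small_trajectory(), small_grid(), snr = 20,
                simulate_pet_volumes = FALSE))
  expect_length(series$days, 5)
  expect_equal(series$truth$day, c(0, 7, 14, 21, 28))
  expect_equal(series$truth$day[which.max(series$truth$tissue_mm3)], 28)
  expect_equal(series$truth$day[which.max(series$truth$edema_mm3)], 7)
  expect_true(all(series$truth$injected_dose_mbq >= 30 &
                    series$truth$injected_dose_mbq <= 40))
  # lesion geometry is consistent across days: day-28 fibrotic voxels grow
  # around the same blob layout as day 21
  f28 <- class_mask(series$days[[5]]$map, "fibrotic_tissue")
  f21 <- class_mask(series$days[[4]]$map, "fibrotic_tissue")
  expect_gt(dice(f28, f21), 0.5)
})
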