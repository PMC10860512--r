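test_that("subject generation is deterministic for a fixed (spec, seed)", {
  spec <- tiny_spec()
  a <- generate_subject(spec, 42L)
  b <- generate_subject(spec, 42L)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth_mask, b$truth_mask)
  c <- generate_subject(spec, 43L)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("noiseless zero-irregularity tumour is a discretized ellipsoid", {
  spec <- domain_spec(image_size = 64L, pixel_spacing_mm = 1,
                      slice_thickness_mm = 1, n_slices_range = c(14L, 14L),
                      tumour_radius_range_mm = c(8, 8),
                      tumour_irregularity = 0, noise_sd_hu = 0)
  s <- generate_subject(spec, 7L)
  # analytic ellipsoid volume: semi-axes (8, 8, 0.7*8) mm, 1 mm^3 voxels
  v_analytic <- 4 / 3 * pi * 8 * 8 * 5.6
  expect_lt(abs(sum(s$truth_mask) - v_analytic) / v_analytic, 0.08)

  # equatorial slice area vs brute-force pixel counting in the analytic
  # ellipse around the mask centroid
  areas <- apply(s$truth_mask, 3, sum)
  eq <- which.max(areas)
  idx <- which(s$truth_mask == 1L, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  count <- 0L
  for (i in 1:64) for (j in 1:64)
    if ((i - cx)^2 + (j - cy)^2 <= 64) count <- count + 1L
  expect_lt(abs(areas[eq] - count) / count, 0.06)
  expect_lt(abs(areas[eq] - pi * 64) / (pi * 64), 0.06)
})

test_that("the tumour sits inside a lung field and HU plateaus are present", {
  spec <- tiny_spec(noise_sd_hu = 0, tumour_irregularity = 0)
  s <- generate_subject(spec, 5L)
  vals <- sort(unique(round(as.numeric(s$volume$data))))
  expect_true(all(c(-1000, spec$lung_hu, spec$background_hu) %in% vals))
  # voxels just outside the tumour along the slice through its centroid
  # are lung (the blob is embedded in a lung field)
  idx <- which(s$truth_mask == 1L, arr.ind = TRUE)
  sl <- round(mean(idx[, 3]))
  ring <- s$volume$data[min(idx[, 1]) - 2, round(mean(idx[, 2])), sl]
  expect_equal(ring, spec$lung_hu)
})

test_that("cohort generation derives distinct reproducible subject seeds", {
  spec <- tiny_spec()
  co <- generate_cohort(spec, 3, seed = 99L)
  expect_length(co, 3)
  expect_length(unique(vapply(co, `[[`, "", "id")), 3)
  one <- generate_subject(spec, 99L, id = co[[1]]$id)
  expect_identical(co[[1]]$volume$data, one$volume$data)
  co2 <- generate_cohort(spec, 3, seed = 100L)
  expect_false(identical(co[[1]]$volume$data, co2[[1]]$volume$data))
})

test_that("tumour volumes across a cohort follow the configured radius range", {
  spec <- tiny_spec()
  co <- generate_cohort(spec, 200, seed = 7L)
  voxvol <- prod(co[[1]]$volume$spacing)
  vols <- vapply(co, function(s) sum(s$truth_mask) * voxvol, numeric(1))
  # radius ~ U(6, 10) mm, volume = 4/3 pi r^2 (0.7 r): median radius 8 mm
  # implies ~1500 mm^3; accept the middle half of the radius range
  med <- stats::median(vols)
  lo <- 4 / 3 * pi * 0.7 * 7^3
  hi <- 4 / 3 * pi * 0.7 * 9^3
  expect_gt(med, lo)
  expect_lt(med, hi)
})

test_that("domain knobs shift the normalized intensity distribution", {
  a <- tiny_spec()
  b <- tiny_spec(noise_sd_hu = 90, intensity_offset_hu = 80)
  sa <- generate_subject(a, 3L); sb <- generate_subject(b, 3L)
  va <- window_normalize(sa$volume)$data
  vb <- window_normalize(sb$volume)$data
  ks <- suppressWarnings(stats::ks.test(as.numeric(va), as.numeric(vb)))
  expect_gt(unname(ks$statistic), 0.05)
})

test_that("zero-perturbation observers reproduce the truth exactly", {
  s <- generate_subject(tiny_spec(), 21L)
  cfg <- observer_sim_config(boundary_sd_mm = 0, bias_mm = 0, seed = 1L)
  obs <- simulate_observers(s$truth_mask, cfg, s$volume$spacing)
  for (m in obs) expect_identical(m, s$truth_mask)
})

test_that("pure positive bias dilates every observer mask", {
  spec <- domain_spec(image_size = 48L, pixel_spacing_mm = 1,
                      slice_thickness_mm = 1, n_slices_range = c(14L, 14L),
                      tumour_radius_range_mm = c(8, 8), noise_sd_hu = 0)
  s <- generate_subject(spec, 3L)
  cfg <- observer_sim_config(boundary_sd_mm = 0, bias_mm = 2, seed = 1L)
  obs <- simulate_observers(s$truth_mask, cfg, s$volume$spacing)
  for (m in obs) {
    expect_true(all(m[s$truth_mask == 1L] == 1L))  # superset
    expect_gt(sum(m), sum(s$truth_mask))           # strict
  }
})

test_that("consensus regions from jittered observers bracket the truth", {
  spec <- domain_spec(image_size = 48L, pixel_spacing_mm = 1,
                      slice_thickness_mm = 1, n_slices_range = c(16L, 16L),
                      tumour_radius_range_mm = c(9, 9), noise_sd_hu = 0)
  s <- generate_subject(spec, 12L)
  cfg <- observer_sim_config(boundary_sd_mm = 1, bias_mm = 0, seed = 4L)
  obs <- simulate_observers(s$truth_mask, cfg, s$volume$spacing)
  cr <- consensus_regions(obs)
  full <- consensus_region(cr, 5)
  any1 <- consensus_region(cr, 1)
  # voxelwise vote counting: the unanimous region sits inside the truth and
  # the truth inside the union. With independent zero-mean boundary fields
  # sampled on a discrete grid the inclusion is almost-sure per voxel, not
  # certain, so allow a <0.5% discretization margin on each side.
  expect_gte(mean(s$truth_mask[full == 1L] == 1L), 0.995)
  expect_gte(mean(any1[s$truth_mask == 1L] == 1L), 0.995)
  expect_lt(sum(full), sum(s$truth_mask))   # core strictly smaller
  expect_gt(sum(any1), sum(s$truth_mask))   # union strictly larger
})

test_that("observer simulation is deterministic and rejects destructive cfg", {
  s <- generate_subject(tiny_spec(), 33L)
  cfg <- observer_sim_config(seed = 9L)
  o1 <- simulate_observers(s$truth_mask, cfg, s$volume$spacing)
  o2 <- simulate_observers(s$truth_mask, cfg, s$volume$spacing)
  expect_identical(o1, o2)
  bad <- observer_sim_config(boundary_sd_mm = 0, bias_mm = -100, seed = 1L)
  expect_error(simulate_observers(s$truth_mask, bad, s$volume$spacing),
               "emptied")
})

test_that("configuration invariants are enforced", {
  expect_error(domain_spec(tumour_radius_range_mm = c(50, 60)),
               "image_size too small")
  expect_error(domain_spec(lung_hu = 100), "lung_hu")
  expect_error(domain_spec(tumour_hu_range = c(300, 400)), "window")
  expect_error(observer_sim_config(n_observers = 1), "n_observers")
})

test_that("cohorts round-trip through NIfTI files and a manifest", {
  spec <- tiny_spec()
  co <- generate_cohort(spec, 2, seed = 55L,
                        observers = observer_sim_config(n_observers = 2,
                                                        seed = 3L))
  dir <- withr::local_tempdir()
  mf <- write_cohort(co, dir)
  back <- read_cohort(mf)
  expect_length(back, 2)
  expect_equal(back[[1]]$volume$data, co[[1]]$volume$data)
  expect_identical(back[[1]]$truth_mask, co[[1]]$truth_mask)
  expect_identical(back[[2]]$observer_masks, co[[2]]$observer_masks)
  expect_identical(back[[1]]$id, co[[1]]$id)
})
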