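# Synthetic lesion phantoms and growth series.

test_that("lesion specs validate their parameters", {
  expect_error(lesion_spec(c(0, 0), 5), "length-3")
  expect_error(lesion_spec(c(0, 0, 0), -1), "positive")
  expect_error(lesion_spec(c(0, 0, 0), 5, noise_fraction = 1.5), "\\[0, 1\\]")
  expect_error(digitation(c(0, 0, 0), 10, 2), "non-zero")
  expect_error(digitation(c(0, 1, 0), 10, 0), "> 0")
  expect_error(lesion_spec(c(0, 0, 0), 5, digitations = list(1)),
               "digitation")
})

test_that("a rasterized sphere recovers the analytic volume", {
  geo <- make_reference_geometry(c(31, 31, 31), 1)
  m <- make_ellipsoid_lesion(lesion_spec(c(0, 0, 0), 10), geo)
  analytic <- 4 / 3 * pi * 10^3 / 1000      # 4.19 cm^3
  expect_lt(abs(mask_volume(m, "cm3") - analytic) / analytic, 0.05)
  # ellipsoid too
  geo2 <- make_reference_geometry(c(41, 41, 41), 1)
  e <- make_ellipsoid_lesion(lesion_spec(c(0, 0, 0), c(12, 8, 6)), geo2)
  expect_lt(abs(mask_volume(e, "cm3") - 4 / 3 * pi * 12 * 8 * 6 / 1000) /
              (4 / 3 * pi * 12 * 8 * 6 / 1000), 0.05)
})

test_that("rasterization is deterministic; seeds touch only the boundary", {
  geo <- make_reference_geometry(c(41, 41, 41), 1)
  sp <- lesion_spec(c(-5, 3, 2), 8, noise_fraction = 0.3, seed = 4)
  m1 <- make_ellipsoid_lesion(sp, geo)
  m2 <- make_ellipsoid_lesion(sp, geo)
  expect_identical(m1$data, m2$data)
  sp0 <- lesion_spec(c(-5, 3, 2), 8)
  clean <- make_ellipsoid_lesion(sp0, geo)
  expect_true(sum(m1$data) < sum(clean$data))   # jitter removed voxels
  sp_other <- lesion_spec(c(-5, 3, 2), 8, noise_fraction = 0.3, seed = 99)
  m3 <- make_ellipsoid_lesion(sp_other, geo)
  differing <- which(m1$data != m3$data)
  expect_true(length(differing) > 0L)
  expect_true(all(clean$data[differing]))       # only within the clean lesion
  # differing voxels all lie on the clean surface shell
  interior <- clean$data
  idx <- which(clean$data, arr.ind = TRUE)
  keep <- idx[, 1] > 1 & idx[, 1] < 41 & idx[, 2] > 1 & idx[, 2] < 41 &
    idx[, 3] > 1 & idx[, 3] < 41
  idx <- idx[keep, , drop = FALSE]
  core <- clean$data[cbind(idx[, 1] + 1, idx[, 2], idx[, 3])] &
    clean$data[cbind(idx[, 1] - 1, idx[, 2], idx[, 3])] &
    clean$data[cbind(idx[, 1], idx[, 2] + 1, idx[, 3])] &
    clean$data[cbind(idx[, 1], idx[, 2] - 1, idx[, 3])] &
    clean$data[cbind(idx[, 1], idx[, 2], idx[, 3] + 1)] &
    clean$data[cbind(idx[, 1], idx[, 2], idx[, 3] - 1)]
  core_lin <- (idx[core, 3] - 1) * 41 * 41 + (idx[core, 2] - 1) * 41 +
    idx[core, 1]
  expect_length(intersect(differing, core_lin), 0L)
})

test_that("digitations extend the lesion along their direction", {
  geo <- make_reference_geometry(c(45, 61, 45), 2)
  core <- lesion_spec(c(-10, 0, 0), 8)
  digi <- lesion_spec(c(-10, 0, 0), 8,
                      digitations = list(digitation(c(0, 1, 0), 30, 4)))
  m_core <- make_ellipsoid_lesion(core, geo)
  m_digi <- make_diffuse_lesion(digi, geo)
  coords_core <- braingrid:::mask_foreground_coords(m_core)
  coords_digi <- braingrid:::mask_foreground_coords(m_digi)
  expect_gte(max(coords_digi[, 2]) - max(coords_core[, 2]), 25)
  # zero digitations: identical to the ellipsoid
  m_same <- make_diffuse_lesion(core, geo)
  expect_identical(m_same$data, m_core$data)
})

test_that("a digitation crossing the anterior-insular plane gains an S1 cell", {
  g <- brain_grid("MNI")
  geo <- whole_head_geometry(2)
  core <- lesion_spec(c(-10, 10, 0), 8)
  r_core <- classify_mask(make_ellipsoid_lesion(core, geo), g)
  expect_false(any(grepl("S1$", r_core$cells$label)))
  digi <- lesion_spec(c(-10, 10, 0), 8,
                      digitations = list(digitation(c(0, 1, 0), 30, 3)))
  r_digi <- classify_mask(make_diffuse_lesion(digi, geo), g)
  expect_true(any(grepl("S1$", r_digi$cells$label)))
})

test_that("lesions exceeding the field of view are rejected", {
  geo <- make_reference_geometry(c(21, 21, 21), 1)   # FOV +/- 10 mm
  expect_error(make_ellipsoid_lesion(lesion_spec(c(0, 0, 0), 15), geo),
               "exceeds the field of view")
  expect_error(
    make_diffuse_lesion(lesion_spec(c(0, 0, 0), 5,
                                    digitations = list(digitation(c(1, 0, 0),
                                                                  20, 2))),
                        geo),
    "exceeds the field of view")
  expect_error(make_growth_series(lesion_spec(c(0, 0, 0), 6), c(3, 0, 0), 3,
                                  geo, dilation_mm = 0),
               "step 3")
})

test_that("growth series are strictly nested with non-decreasing cell counts", {
  g <- brain_grid("MNI")
  geo <- whole_head_geometry(2)
  series <- make_growth_series(lesion_spec(c(-14, 0, 0), 5,
                                           noise_fraction = 0.1, seed = 2),
                               c(4, 2, 0), 5, geo, dilation_mm = 2)
  for (i in seq_len(length(series) - 1L)) {
    a <- series[[i]]$data; b <- series[[i + 1L]]$data
    expect_true(all(b[a]))            # nested
    expect_gt(sum(b), sum(a))         # strictly
  }
  n <- vapply(series, function(m) classify_mask(m, g)$n_cells, 1L)
  expect_true(all(diff(n) >= 0))
})

test_that("a series crossing the midline turns bilateral", {
  g <- brain_grid("MNI")
  geo <- whole_head_geometry(2)
  series <- make_growth_series(lesion_spec(c(-16, 0, 0), 6), c(8, 0, 0), 4,
                               geo, dilation_mm = 1)
  lat <- vapply(series, function(m) classify_mask(m, g)$laterality, "")
  expect_equal(lat[1], "left")
  expect_equal(lat[length(lat)], "bilateral")
  expect_true(all(lat[lat != "left"] == "bilateral"))
})

test_that("synthetic masks round-trip through NIfTI", {
  geo <- make_reference_geometry(c(31, 31, 31), 2)
  m <- make_diffuse_lesion(
    lesion_spec(c(0, 0, 0), 8,
                digitations = list(digitation(c(0, 0, 1), 15, 3)),
                noise_fraction = 0.2, seed = 8), geo)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_equal(m2$data, m$data)
  expect_equal(m2$affine, m$affine, tolerance = 1e-5)
})

test_that("simulated cohorts satisfy the cohort invariants", {
  co <- simulate_cohort(30, c(A3C2S2 = 0.7, A2C2S1 = 0.4), seed = 6)
  expect_equal(nrow(co), 30L)
  expect_true(all(co$bg_voxels >= 1L))
  expect_equal(co$bg_voxels, vapply(co$cells, length, 1L))
  expect_true(all(co$side %in% c("L", "R", "B")))
  # determinism
  co2 <- simulate_cohort(30, c(A3C2S2 = 0.7, A2C2S1 = 0.4), seed = 6)
  expect_identical(co$cells, co2$cells)
})
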