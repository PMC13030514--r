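test_that("species profiles carry the reported VIS/NIR anchor levels", {
  p <- generate_species_profile("Convolvulus arvensis")
  expect_equal(p$vis_level, 5)
  expect_equal(p$nir_level, 17)
  expect_equal(generate_species_profile("Amaranthus retroflexus")$nir_level, 26)
  for (sp in weed_species()) {
    pr <- generate_species_profile(sp)
    expect_gt(pr$nir_level, pr$vis_level)
    expect_true(pr$red_edge_center >= 690 && pr$red_edge_center <= 740)
  }
})

test_that("unknown species are rejected with the valid name list", {
  expect_error(generate_species_profile("Zea mays"), "valid species")
})

test_that("profile construction enforces vegetation invariants", {
  expect_error(species_profile("x", vis_level = 20, nir_level = 10),
               "nir_level must exceed")
  expect_error(species_profile("x", 5, 20, red_edge_center = 650),
               "red-edge region")
  expect_error(noise_model(pixel_gain_sd = -1), ">= 0")
})

test_that("rendered leaf spectra hit the VIS/NIR window anchors", {
  wl <- default_wavelengths(121)
  vis <- wl >= 500 & wl <= 700
  nir <- wl >= 700 & wl <= 780
  for (sp in weed_species()) {
    p <- generate_species_profile(sp)
    r <- render_spectrum(p, "leaf", wl)
    expect_lt(abs(mean(r[vis]) - p$vis_level), 1)
    expect_lt(abs(mean(r[nir]) - p$nir_level), 1)
    # red-edge rise dominates VIS for every default profile
    expect_gt(mean(r[nir]), mean(r[vis]))
  }
})

test_that("leaf spectra rise monotonically across the red edge", {
  wl <- seq(690, 740, by = 2)
  for (sp in weed_species()) {
    r <- render_spectrum(generate_species_profile(sp), "leaf", wl)
    expect_true(all(diff(r) >= 0), info = sp)
  }
})

test_that("below-ground and white-flower parts keep VIS >= NIR", {
  wl <- default_wavelengths(121)
  vis <- wl >= 550 & wl <= 750
  nir <- wl >= 750 & wl <= 780
  for (part in c("root", "root_collar", "basal", "flower_white")) {
    r <- render_spectrum(generate_species_profile("Convolvulus arvensis"),
                         part, wl)
    expect_gt(mean(r[vis]), mean(r[nir]))
  }
})

test_that("render_spectrum validates its wavelength grid", {
  p <- generate_species_profile("Chenopodium album")
  expect_error(render_spectrum(p, "leaf", numeric(0)), "empty")
  expect_error(render_spectrum(p, "leaf", c(500, 450)), "increasing")
  expect_error(render_spectrum(p, "leaf", c(300, 500)), "400-1000")
})

test_that("rendering with a seeded noise model is bit-identical", {
  p <- generate_species_profile("Sonchus arvensis")
  wl <- tiny_wavelengths()
  nm <- noise_model(seed = 99)
  expect_identical(render_spectrum(p, "leaf", wl, nm),
                   render_spectrum(p, "leaf", wl, nm))
  # and noise-free rendering is deterministic without any seed
  expect_identical(render_spectrum(p, "leaf", wl),
                   render_spectrum(p, "leaf", wl))
})

test_that("default cohort has 225 plants and plant-shared offsets", {
  co <- generate_cohort(seed = 3)
  tab <- roi_table(co)
  expect_equal(length(unique(tab$plant_id)), 225)
  expect_equal(length(unique(tab$species)), 9)
  expect_true(all(tab$pixel_count >= 50))
})

test_that("cohort honours per-species ROI count targets", {
  co <- generate_cohort(roi_counts = weed_roi_counts(), seed = 3)
  tab <- roi_table(co)
  expect_equal(nrow(tab), 601)
  counts <- table(tab$species)
  expect_equal(as.numeric(counts[names(weed_roi_counts())]),
               as.numeric(weed_roi_counts()))
})

test_that("zero plants gives an empty dataset without error", {
  co <- generate_cohort(n_species = 2, n_plants_per_species = 0, seed = 1)
  expect_length(co$rois, 0)
  expect_equal(nrow(roi_table(co)), 0)
})

test_that("identical seeds regenerate identical cohorts", {
  a <- roi_table(small_cohort(seed = 21))
  b <- roi_table(small_cohort(seed = 21))
  expect_identical(a, b)
  expect_false(identical(a, roi_table(small_cohort(seed = 22))))
})

test_that("sub-50-pixel ROIs trigger the purity warning", {
  expect_warning(generate_cohort(n_species = 1, n_plants_per_species = 1,
                                 pixels_per_roi = 30,
                                 wavelengths = tiny_wavelengths(), seed = 1),
                 "purity")
})

test_that("with all noise sds zero every pixel equals the rendered spectrum", {
  co <- generate_cohort(n_species = 2, n_plants_per_species = 2,
                        pixels_per_roi = 50,
                        wavelengths = tiny_wavelengths(),
                        noise = zero_noise(), seed = 7)
  for (r in co$rois) {
    ref <- render_spectrum(generate_species_profile(r$species), r$part,
                           co$wavelengths)
    for (i in seq_len(nrow(r$spectra))) {
      expect_equal(unname(r$spectra[i, ]), ref, tolerance = 1e-12)
    }
  }
})

test_that("ROI tables round-trip losslessly through delimited text", {
  co <- small_cohort()
  tab <- roi_table(co)
  f <- withr::local_tempfile()
  write_roi_table(tab, f)
  back <- read_roi_table(f)
  bands <- grep("^b[0-9]", names(tab))
  expect_equal(as.matrix(back[, bands]), as.matrix(tab[, bands]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$plant_id, tab$plant_id)
  expect_equal(attr(back, "wavelengths"), co$wavelengths)
})

test_that("cohort leaf means recover the species anchors (calibration bias)", {
  co <- generate_cohort(seed = 201)
  tab <- roi_table(co)
  wl <- roi_wavelengths(co)
  bands <- grep("^b[0-9]", names(tab))
  vis <- wl >= 500 & wl <= 700
  nir <- wl >= 700 & wl <= 780
  leaf <- tab[tab$part == "leaf", ]
  for (sp in weed_species()) {
    p <- generate_species_profile(sp)
    g <- as.matrix(leaf[leaf$species == sp, bands])
    plant <- leaf$plant_id[leaf$species == sp]
    plant_vis <- tapply(rowMeans(g[, vis]), plant, mean)
    plant_nir <- tapply(rowMeans(g[, nir]), plant, mean)
    expect_lt(abs(mean(plant_vis) - p$vis_level), 2 * stats::sd(plant_vis))
    expect_lt(abs(mean(plant_nir) - p$nir_level), 2 * stats::sd(plant_nir))
  }
})
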