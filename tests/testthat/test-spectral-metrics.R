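test_that("part_range takes extrema inside the metric window", {
  wl <- seq(400, 1000, by = 10)
  expect_equal(part_range(rep(20, length(wl)), wl)$r_min, 20)
  expect_equal(part_range(rep(20, length(wl)), wl)$r_max, 20)
  ramp <- 5 + (wl - 500) * 40 / 280
  pr <- part_range(ramp, wl, window = c(500, 780))
  expect_equal(pr$r_min, 5)
  expect_equal(pr$r_max, 45)
  expect_error(part_range(1:5, seq(400, 480, by = 20)), "does not cover")
})

test_that("synthetic leaf profiles reproduce their species anchors", {
  wl <- default_wavelengths(121)
  p <- generate_species_profile("Convolvulus arvensis")
  r <- render_spectrum(p, "leaf", wl)
  pr <- part_range(r, wl)
  expect_lt(abs(pr$r_min - 5), 1)
  # the NIR anchor is a window mean, so the in-window maximum (the plateau)
  # sits at or slightly above it
  expect_gte(pr$r_max, 17 - 0.5)
  expect_lt(pr$r_max, 17 + 3.5)
  expect_lt(abs(mean(r[wl >= 700 & wl <= 780]) - 17), 1)
})

test_that("wavelength statistics follow their closed forms", {
  ws <- wavelength_stats(500, 780)
  expect_equal(ws$sb, 280)
  expect_equal(ws$c, 1.56)
  expect_equal(ws$b_rel, 280 / 1280, tolerance = 1e-12)
  expect_equal(ws$c_norm, 280 / 780, tolerance = 1e-12)
  ws2 <- wavelength_stats(550, 780)
  expect_equal(ws2$sb, 230)
  expect_equal(ws2$c, 780 / 550, tolerance = 1e-12)
  expect_equal(ws2$b_rel, 230 / 1330, tolerance = 1e-12)
  expect_equal(ws2$c_norm, 230 / 780, tolerance = 1e-12)
  deg <- wavelength_stats(600, 600)
  expect_equal(unlist(deg), c(sb = 0, c = 1, b_rel = 0, c_norm = 0))
  expect_error(wavelength_stats(0, 700), "non-zero")
  expect_error(wavelength_stats(700, 600), "must not exceed")
})

test_that("normalised contrast obeys its algebraic identity with B_rel", {
  set.seed(20)
  lmin <- runif(50, 400, 700)
  lmax <- lmin + runif(50, 1, 300)
  ws <- wavelength_stats(lmin, lmax)
  expect_equal(ws$c_norm, ws$b_rel * (1 + lmin / lmax), tolerance = 1e-12)
})

test_that("species aggregation is the unweighted part mean", {
  one <- data.frame(r_min = 10, r_max = 20, lambda_min = 500,
                    lambda_max = 780)
  agg <- species_aggregate(one)
  expect_equal(agg$mu, 15)
  expect_equal(agg$delta_r, 10)
  expect_equal(agg$sb, 280)
  # duplicating every part changes nothing
  pr <- reported_part_ranges()
  g <- pr[pr$species == "Convolvulus arvensis", ]
  expect_equal(species_aggregate(rbind(g, g)), species_aggregate(g),
               tolerance = 1e-12)
  expect_error(species_aggregate(g[0, ]), "at least one part")
})

test_that("published reflectance aggregates are reproduced (golden table)", {
  st <- stats_table(reported_part_ranges())
  expected_mu <- c("Convolvulus arvensis" = 22.6, "Erigeron canadensis" = 20.9,
                   "Erysimum cheiranthoides" = 20.5, "Sonchus arvensis" = 21.1,
                   "Capsella bursa-pastoris" = 24.5, "Artemisia vulgaris" = 22.5,
                   "Ambrosia artemisiifolia" = 18.0,
                   "Amaranthus retroflexus" = 22.6, "Chenopodium album" = 24.8)
  expected_dr <- c("Convolvulus arvensis" = 16.8, "Erigeron canadensis" = 22.3,
                   "Erysimum cheiranthoides" = 17.4, "Sonchus arvensis" = 17.0,
                   "Capsella bursa-pastoris" = 18.4, "Artemisia vulgaris" = 20.7,
                   "Ambrosia artemisiifolia" = 19.0,
                   "Amaranthus retroflexus" = 18.5, "Chenopodium album" = 19.4)
  for (sp in names(expected_mu)) {
    row <- st[st$species == sp, ]
    expect_lt(abs(row$mu - expected_mu[[sp]]), 0.1)
    expect_lt(abs(row$delta_r - expected_dr[[sp]]), 0.1)
  }
})

test_that("published wavelength aggregates are reproduced (golden table)", {
  st <- stats_table(reported_part_ranges())
  # Amaranthus excluded: its published SB (238.0) is inconsistent with its
  # own part ranges under any unweighted mean (apparent typographic error).
  expected <- list(
    "Convolvulus arvensis" = c(246.7, 1.465, 0.188, 0.316),
    "Erigeron canadensis" = c(255.0, 1.489, 0.196, 0.327),
    "Erysimum cheiranthoides" = c(280.0, 1.560, 0.219, 0.359),
    "Sonchus arvensis" = c(280.0, 1.560, 0.219, 0.359),
    "Capsella bursa-pastoris" = c(280.0, 1.560, 0.219, 0.359),
    "Artemisia vulgaris" = c(255.0, 1.489, 0.196, 0.327),
    "Ambrosia artemisiifolia" = c(280.0, 1.560, 0.219, 0.359),
    "Chenopodium album" = c(270.0, 1.532, 0.210, 0.346))
  for (sp in names(expected)) {
    row <- st[st$species == sp, ]
    expect_lt(abs(row$sb - expected[[sp]][1]), 0.1)
    expect_lt(abs(row$c - expected[[sp]][2]), 0.005)
    expect_lt(abs(row$b_rel - expected[[sp]][3]), 0.005)
    expect_lt(abs(row$c_norm - expected[[sp]][4]), 0.005)
  }
})

test_that("the secondary descriptors are flagged as non-reconciled", {
  agg <- species_aggregate(reported_part_ranges()[1:6, ])
  expect_true(all(c("sigma", "cv", "me", "r_rate") %in%
                    attr(agg, "non_reconciled")))
})

test_that("stats_table is permutation-invariant and one row per species", {
  pr <- reported_part_ranges()
  st <- stats_table(pr)
  expect_equal(nrow(st), 9)
  set.seed(30)
  st2 <- stats_table(pr[sample(nrow(pr)), ])
  st2 <- st2[match(st$species, st2$species), ]
  expect_equal(st$mu, st2$mu, tolerance = 1e-12)
  expect_equal(st$sb, st2$sb, tolerance = 1e-12)
})

test_that("a measured cohort yields a full 9-species metric table", {
  co <- generate_cohort(n_plants_per_species = 4, pixels_per_roi = 50,
                        wavelengths = tiny_wavelengths(), seed = 17)
  st <- stats_table(co)
  expect_equal(nrow(st), 9)
  expect_true(all(st$c >= 1))
  expect_true(all(st$b_rel >= 0 & st$b_rel < 1))
  expect_true(all(st$c_norm >= 0 & st$c_norm < 1))
})
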