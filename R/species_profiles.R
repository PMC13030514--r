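#' The nine study weed species
#'
#' Returns the Latin binomials of the nine arable weed species covered by the
#' default spectral profiles, in a fixed canonical order.
#'
#' @return Character vector of length 9.
#' @export
weed_species <- function() {
  c("Convolvulus arvensis", "Erigeron canadensis", "Erysimum cheiranthoides",
    "Sonchus arvensis", "Capsella bursa-pastoris", "Artemisia vulgaris",
    "Ambrosia artemisiifolia", "Amaranthus retroflexus", "Chenopodium album")
}

#' Reported per-species region-of-interest counts
#'
#' Per-species ROI totals observed in the laboratory campaign the default
#' cohort emulates (601 ROIs across the nine species). Used as the default
#' imbalanced class sizes of [generate_cohort()] when `roi_counts` mirroring
#' the study is requested.
#'
#' @return Named integer vector (names are species) summing to 601.
#' @export
weed_roi_counts <- function() {
  c("Erysimum cheiranthoides" = 132L, "Erigeron canadensis" = 81L,
    "Capsella bursa-pastoris" = 67L, "Ambrosia artemisiifolia" = 66L,
    "Sonchus arvensis" = 62L, "Chenopodium album" = 54L,
    "Artemisia vulgaris" = 48L, "Convolvulus arvensis" = 45L,
    "Amaranthus retroflexus" = 46L)[weed_species()]
}

# Species-level spectral anchors. vis_level / nir_level are the whole-plant
# (leaf-dominated) mean reflectance % in the 500-700 and 700-780 nm windows.
# Red-edge centre/width and green-peak amplitude are shape parameters of the
# simulated signatures; centres sit inside the 690-740 nm red-edge region.
.species_table <- function() {
  data.frame(
    species = weed_species(),
    vis_level = c(5, 8, 6, 11, 14, 8, 6, 9, 14),
    nir_level = c(17, 23, 16, 25, 21, 19, 21, 26, 25),
    red_edge_center = c(712, 718, 703, 722, 700, 714, 707, 726, 717),
    red_edge_width = c(8, 11, 9, 13, 7, 14, 9, 12, 10),
    green_peak_amplitude = c(1.5, 2.0, 1.5, 2.5, 3.0, 1.8, 1.2, 2.2, 2.8),
    stringsAsFactors = FALSE
  )
}

.part_kinds <- function() {
  c("leaf", "stem", "root", "root_collar", "flower_white", "flower_yellow",
    "basal")
}

#' Morphological-part spectral modifier
#'
#' A part profile shifts the species-level VIS/NIR anchor levels and selects
#' the curve family used to render that part: chlorophyll-bearing parts
#' (`red_edge_rise`) show low VIS reflectance and a sigmoidal red-edge rise;
#' roots, basal zones and white flowers (`vis_plateau_nir_drop`) show a bright
#' 550-750 nm plateau followed by a drop; yellow flowers (`flat_bright`) show
#' an elevated, gently sloping signature.
#'
#' @param part_kind One of `"leaf"`, `"stem"`, `"root"`, `"root_collar"`,
#'   `"flower_white"`, `"flower_yellow"`, `"basal"`.
#' @param vis_offset,nir_offset Additive reflectance offsets (%) applied to the
#'   species VIS/NIR levels for this part.
#' @param shape_mode Curve family; one of `"red_edge_rise"`,
#'   `"vis_plateau_nir_drop"`, `"flat_bright"`.
#' @return A `part_profile` list.
#' @export
part_profile <- function(part_kind, vis_offset = 0, nir_offset = 0,
                         shape_mode = c("red_edge_rise",
                                        "vis_plateau_nir_drop",
                                        "flat_bright")) {
  part_kind <- match.arg(part_kind, .part_kinds())
  shape_mode <- match.arg(shape_mode)
  structure(list(part_kind = part_kind, vis_offset = vis_offset,
                 nir_offset = nir_offset, shape_mode = shape_mode),
            class = "part_profile")
}

# Default part modifiers shared by all species. Bright below-ground and white
# floral structures carry large positive VIS offsets; the plateau renderer
# caps the NIR tail at the plateau so VIS >= NIR always holds for these parts.
.default_part_profiles <- function() {
  list(
    leaf         = part_profile("leaf", 0, 0, "red_edge_rise"),
    stem         = part_profile("stem", 7, 3, "red_edge_rise"),
    root         = part_profile("root", 25, 3, "vis_plateau_nir_drop"),
    root_collar  = part_profile("root_collar", 22, 5, "vis_plateau_nir_drop"),
    basal        = part_profile("basal", 28, 2, "vis_plateau_nir_drop"),
    flower_white = part_profile("flower_white", 24, 8, "vis_plateau_nir_drop"),
    flower_yellow = part_profile("flower_yellow", 15, 8, "flat_bright")
  )
}

#' Default spectral profile of a study species
#'
#' Returns the simulation anchor values for one of the nine study species:
#' whole-plant VIS (500-700 nm) and NIR (700-780 nm) mean reflectance levels,
#' red-edge centre and width, green-peak amplitude and the per-part modifiers.
#' For chlorophyll-bearing parts the NIR level always exceeds the VIS level.
#'
#' @param species_name One of [weed_species()].
#' @return A `species_profile` list with fields `species_name`, `vis_level`,
#'   `nir_level`, `red_edge_center`, `red_edge_width`,
#'   `green_peak_amplitude`, `part_profiles`.
#' @examples
#' p <- generate_species_profile("Convolvulus arvensis")
#' p$vis_level  # 5
#' p$nir_level  # 17
#' @export
generate_species_profile <- function(species_name) {
  tab <- .species_table()
  i <- match(species_name, tab$species)
  if (is.na(i)) {
    stop("unknown species '", species_name, "'; valid species are: ",
         paste(tab$species, collapse = ", "), call. = FALSE)
  }
  species_profile(
    species_name = tab$species[i],
    vis_level = tab$vis_level[i],
    nir_level = tab$nir_level[i],
    red_edge_center = tab$red_edge_center[i],
    red_edge_width = tab$red_edge_width[i],
    green_peak_amplitude = tab$green_peak_amplitude[i]
  )
}

#' Construct a species spectral profile
#'
#' @param species_name Species label (free text for custom profiles).
#' @param vis_level,nir_level Mean reflectance % in the 500-700 / 700-780 nm
#'   windows, both in \[0, 100\]; `nir_level` must exceed `vis_level` (the
#'   red-edge rise of green vegetation).
#' @param red_edge_center Red-edge inflection wavelength (nm), within
#'   \[690, 740\].
#' @param red_edge_width Logistic width of the red-edge transition (nm).
#' @param green_peak_amplitude Amplitude (%) of the 550 nm green reflectance
#'   bump.
#' @param part_profiles Named list of [part_profile()] objects.
#' @return A `species_profile` object.
#' @export
species_profile <- function(species_name, vis_level, nir_level,
                            red_edge_center = 712, red_edge_width = 10,
                            green_peak_amplitude = 2,
                            part_profiles = .default_part_profiles()) {
  stopifnot(vis_level >= 0, vis_level <= 100, nir_level >= 0, nir_level <= 100)
  if (nir_level <= vis_level)
    stop("nir_level must exceed vis_level for vegetation profiles",
         call. = FALSE)
  if (red_edge_center < 690 || red_edge_center > 740)
    stop("red_edge_center must lie in the 690-740 nm red-edge region",
         call. = FALSE)
  structure(list(species_name = species_name, vis_level = vis_level,
                 nir_level = nir_level, red_edge_center = red_edge_center,
                 red_edge_width = red_edge_width,
                 green_peak_amplitude = green_peak_amplitude,
                 part_profiles = part_profiles),
            class = "species_profile")
}

#' Pixel/plant noise model for the synthetic cohort
#'
#' Describes the stochastic components layered on top of the deterministic
#' part signatures: per-pixel multiplicative gain and additive per-band sensor
#' noise (illumination/detector variability), and per-plant biological
#' variability (a shared multiplicative gain, an additive offset, a red-edge
#' position shift and a spectral-contrast factor). All standard deviations may
#' be zero; with every sd zero the generated pixels equal the noise-free
#' rendered spectra exactly.
#'
#' @param pixel_gain_sd Sd of the per-pixel multiplicative gain (unitless).
#' @param band_noise_sd Sd of additive per-band noise (reflectance %).
#' @param plant_offset_sd Sd of the per-plant additive offset (reflectance %).
#' @param plant_gain_sd Sd of the per-plant multiplicative gain (unitless).
#' @param plant_redshift_sd Sd of the per-plant red-edge centre shift (nm).
#' @param plant_contrast_sd Sd of the per-plant VIS-NIR contrast factor
#'   (unitless, multiplies `nir_level - vis_level`).
#' @param seed Optional integer; when set, [render_spectrum()] draws its pixel
#'   noise from this seed so repeated calls are bit-identical.
#' @return A `noise_model` list.
#' @export
noise_model <- function(pixel_gain_sd = 0.05, band_noise_sd = 0.5,
                        plant_offset_sd = 1.0, plant_gain_sd = 0.06,
                        plant_redshift_sd = 1.5, plant_contrast_sd = 0.04,
                        seed = NULL) {
  sds <- c(pixel_gain_sd, band_noise_sd, plant_offset_sd, plant_gain_sd,
           plant_redshift_sd, plant_contrast_sd)
  if (any(sds < 0)) stop("noise standard deviations must be >= 0",
                         call. = FALSE)
  structure(list(pixel_gain_sd = pixel_gain_sd, band_noise_sd = band_noise_sd,
                 plant_offset_sd = plant_offset_sd,
                 plant_gain_sd = plant_gain_sd,
                 plant_redshift_sd = plant_redshift_sd,
                 plant_contrast_sd = plant_contrast_sd, seed = seed),
            class = "noise_model")
}

#' Default VNIR wavelength grid
#'
#' Evenly spaced grid over 400-1000 nm. The full camera grid has 1200
#' channels (0.5 nm sampling); a coarser grid (default 61 bands, 10 nm) keeps
#' simulations fast without changing the curve shapes.
#'
#' @param n_bands Number of bands.
#' @return Numeric vector of wavelengths (nm).
#' @export
default_wavelengths <- function(n_bands = 61) {
  seq(400, 1000, length.out = n_bands)
}

# Deterministic spectral function for one species/part combination.
# For the red-edge family the baseline and rise amplitude are solved so that
# the 500-700 and 700-780 nm window means (on a 1 nm reference grid) equal the
# part's VIS/NIR levels exactly, making the generator's anchor parameters
# directly recoverable from window means of the rendered spectra.
.spectrum_function <- function(profile, part_kind) {
  pp <- profile$part_profiles[[part_kind]]
  if (is.null(pp))
    stop("no part profile for part kind '", part_kind, "'", call. = FALSE)
  V <- profile$vis_level + pp$vis_offset
  N <- profile$nir_level + pp$nir_offset
  if (pp$shape_mode == "red_edge_rise") {
    c0 <- profile$red_edge_center
    w <- profile$red_edge_width
    A <- profile$green_peak_amplitude
    fine <- 400:1000
    vis <- fine >= 500 & fine <= 700
    nir <- fine >= 700 & fine <= 780
    s <- function(l) stats::plogis((l - c0) / w)
    g <- function(l) A * exp(-(l - 550)^2 / (2 * 25^2))
    sbV <- mean(s(fine[vis])); sbN <- mean(s(fine[nir]))
    gbV <- mean(g(fine[vis])); gbN <- mean(g(fine[nir]))
    b <- ((N - gbN) - (V - gbV)) / (sbN - sbV)
    a <- V - gbV - b * sbV
    function(l) a + b * s(l) + g(l)
  } else if (pp$shape_mode == "vis_plateau_nir_drop") {
    P <- V
    Tl <- min(N, P)  # below-ground/white parts never rise across the red edge
    B <- 0.4 * P
    # plateau onset and drop track the species' pigment-driven spectral
    # position, so below-ground signatures stay species-specific too
    rise <- 565 + 0.5 * (profile$red_edge_center - 712)
    drop <- 750 + (profile$red_edge_center - 712)
    function(l) {
      B + (P - B) * stats::plogis((l - rise) / 12) +
        (Tl - P) * stats::plogis((l - drop) / 8)
    }
  } else {  # flat_bright
    function(l) V + (N - V) * pmin(pmax((l - 500) / 280, 0), 1)
  }
}

#' Render a reflectance spectrum for one plant part
#'
#' Evaluates the deterministic curve family of a species/part combination on a
#' wavelength grid and optionally adds pixel-level noise. Chlorophyll-bearing
#' parts are a baseline plus a Gaussian green bump (centre 550 nm) plus a
#' logistic red-edge rise between the VIS and NIR anchor levels; root, basal
#' and white-flower parts replace the rise with a bright 550-750 nm plateau
#' followed by a drop; yellow flowers ramp gently between elevated levels.
#'
#' @param profile A [species_profile()].
#' @param part_kind Part kind (see [part_profile()]).
#' @param wavelengths Strictly increasing wavelengths (nm) within
#'   \[400, 1000\].
#' @param noise Optional [noise_model()]; only its pixel-level components
#'   (`pixel_gain_sd`, `band_noise_sd`, `seed`) are applied here.
#' @return Numeric vector of reflectance % values, one per wavelength.
#' @examples
#' wl <- default_wavelengths(61)
#' p <- generate_species_profile("Convolvulus arvensis")
#' r <- render_spectrum(p, "leaf", wl)
#' mean(r[wl >= 500 & wl <= 700])  # ~5
#' @export
render_spectrum <- function(profile, part_kind, wavelengths, noise = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  if (length(wavelengths) == 0)
    stop("wavelength vector must not be empty", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (min(wavelengths) < 400 || max(wavelengths) > 1000)
    stop("wavelengths must lie within 400-1000 nm", call. = FALSE)
  f <- .spectrum_function(profile, part_kind)
  v <- f(wavelengths)
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    if (!is.null(noise$seed)) set.seed(noise$seed)
    gain <- 1 + stats::rnorm(1, 0, noise$pixel_gain_sd)
    v <- v * gain + stats::rnorm(length(v), 0, noise$band_noise_sd)
  }
  v
}
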