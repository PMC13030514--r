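#' Generate a labelled synthetic cohort of plant ROIs
#'
#' Simulates the study design the package's downstream stages expect: a fixed
#' number of plants per species, each contributing a few regions of interest
#' (ROIs) from different morphological parts, every ROI holding at least 50
#' pure pixel spectra. Plant-level biological variability (shared gain,
#' offset, red-edge shift, contrast factor) is drawn once per plant, so all
#' ROIs of a plant move together — which is what makes plant-wise train/test
#' splitting materially harder than ROI-wise splitting. A single global seed
#' deterministically derives one seed per plant, so any plant is regenerable
#' in isolation.
#'
#' @param n_species Number of species (taken from the head of
#'   [weed_species()]).
#' @param n_plants_per_species Plants per species (default 25).
#' @param rois_per_plant Candidate ROI counts per plant; by default 2 or 3,
#'   drawn uniformly. Ignored when `roi_counts` is supplied.
#' @param pixels_per_roi Pixels per ROI (default 60). Values below 50 violate
#'   the purity rule and raise a warning (not an error).
#' @param wavelengths Wavelength grid (default 61 bands over 400-1000 nm).
#' @param noise A [noise_model()].
#' @param roi_counts Optional named integer vector of per-species ROI totals
#'   (e.g. [weed_roi_counts()]); ROIs are then spread as evenly as possible
#'   over the plants of each species.
#' @param parts Part kinds cycled over the ROIs of each plant.
#' @param species Species names; defaults to the first `n_species` study
#'   species.
#' @param seed Global integer seed.
#' @return A `weed_cohort` object: list with `rois` (list of `weed_roi`),
#'   `wavelengths`, `species`, `seed`.
#' @examples
#' co <- generate_cohort(n_species = 2, n_plants_per_species = 3, seed = 1)
#' length(unique(roi_table(co)$plant_id))  # 6 plants
#' @export
generate_cohort <- function(n_species = 9, n_plants_per_species = 25,
                            rois_per_plant = c(2, 3), pixels_per_roi = 60,
                            wavelengths = default_wavelengths(61),
                            noise = noise_model(), roi_counts = NULL,
                            parts = c("leaf", "stem", "root"),
                            species = weed_species()[seq_len(n_species)],
                            seed = 1) {
  stopifnot(n_species >= 1, n_plants_per_species >= 0, pixels_per_roi >= 1)
  if (pixels_per_roi < 50)
    warning("pixels_per_roi < 50 violates the ROI purity rule (>= 50 pure ",
            "pixels per ROI)", call. = FALSE)
  profiles <- lapply(species, generate_species_profile)
  names(profiles) <- species
  n_plants_total <- length(species) * n_plants_per_species
  rois <- list()
  if (n_plants_total > 0) {
    set.seed(seed)
    plant_seeds <- sample.int(.Machine$integer.max, n_plants_total)
    idx <- 0
    for (si in seq_along(species)) {
      sp <- species[si]
      if (!is.null(roi_counts)) {
        tot <- roi_counts[[sp]]
        base <- tot %/% n_plants_per_species
        extra <- tot %% n_plants_per_species
        n_rois_plan <- rep(base, n_plants_per_species) +
          c(rep(1, extra), rep(0, n_plants_per_species - extra))
      } else {
        n_rois_plan <- NULL
      }
      for (pi in seq_len(n_plants_per_species)) {
        idx <- idx + 1
        plant_id <- sprintf("%s_p%02d", .species_abbrev(sp), pi)
        plant <- .generate_plant(profiles[[sp]], plant_id, wavelengths, noise,
                                 parts, pixels_per_roi,
                                 n_rois = if (is.null(n_rois_plan)) NULL else
                                   n_rois_plan[pi],
                                 rois_per_plant = rois_per_plant,
                                 plant_seed = plant_seeds[idx])
        rois <- c(rois, plant)
      }
    }
  }
  structure(list(rois = rois, wavelengths = wavelengths, species = species,
                 seed = seed),
            class = "weed_cohort")
}

# Unique short id per species: 4 letters of genus + 3 of epithet.
.species_abbrev <- function(sp) {
  w <- strsplit(sp, "[ -]")[[1]]
  paste0(substr(w[1], 1, 4), substr(w[2], 1, 3))
}

# Generate all ROIs of one plant from its own seed.
.generate_plant <- function(profile, plant_id, wavelengths, noise, parts,
                            pixels_per_roi, n_rois, rois_per_plant,
                            plant_seed) {
  set.seed(plant_seed)
  gain <- 1 + stats::rnorm(1, 0, noise$plant_gain_sd)
  offset <- stats::rnorm(1, 0, noise$plant_offset_sd)
  redshift <- stats::rnorm(1, 0, noise$plant_redshift_sd)
  contrast <- 1 + stats::rnorm(1, 0, noise$plant_contrast_sd)
  if (is.null(n_rois)) {
    n_rois <- if (length(rois_per_plant) == 1) rois_per_plant else
      sample(rois_per_plant, 1)
  }
  # plant-specific profile: shifted red edge (kept inside 690-740) and scaled
  # VIS-NIR contrast
  pp <- profile
  pp$red_edge_center <- min(740, max(690, profile$red_edge_center + redshift))
  pp$nir_level <- profile$vis_level +
    max(0.5, contrast * (profile$nir_level - profile$vis_level))
  out <- vector("list", n_rois)
  nb <- length(wavelengths)
  for (j in seq_len(n_rois)) {
    part <- parts[(j - 1) %% length(parts) + 1]
    base <- render_spectrum(pp, part, wavelengths)
    base <- base * gain + offset
    px_gain <- 1 + stats::rnorm(pixels_per_roi, 0, noise$pixel_gain_sd)
    spectra <- outer(px_gain, base) +
      matrix(stats::rnorm(pixels_per_roi * nb, 0, noise$band_noise_sd),
             pixels_per_roi, nb)
    out[[j]] <- new_weed_roi(species = profile$species_name,
                             plant_id = plant_id, part = part,
                             spectra = spectra, wavelengths = wavelengths)
  }
  out
}

#' Construct a region of interest
#'
#' @param species,plant_id,part Labels.
#' @param spectra Pixel-by-band matrix of reflectance %.
#' @param wavelengths Wavelengths (nm), one per column.
#' @param pixel_indices Optional two-column (line, sample) matrix.
#' @return A `weed_roi` object with a precomputed `mean_spectrum`.
#' @export
new_weed_roi <- function(species, plant_id, part, spectra, wavelengths,
                         pixel_indices = NULL) {
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(wavelengths))
  structure(list(species = species, plant_id = plant_id, part = part,
                 pixel_indices = pixel_indices, spectra = spectra,
                 mean_spectrum = colMeans(spectra), wavelengths = wavelengths),
            class = "weed_roi")
}

#' @export
print.weed_cohort <- function(x, ...) {
  tab <- roi_table(x)
  cat("<weed_cohort> ", length(x$rois), " ROIs, ",
      length(unique(tab$plant_id)), " plants, ",
      length(unique(tab$species)), " species, ",
      length(x$wavelengths), " bands\n", sep = "")
  invisible(x)
}

#' Flatten a cohort (or ROI list) to a mean-spectrum table
#'
#' One row per ROI: `species`, `plant_id`, `part`, `pixel_count`, then one
#' column per band (`b<wavelength>`) holding the ROI mean spectrum.
#'
#' @param x A `weed_cohort` or list of `weed_roi` objects.
#' @return A data.frame.
#' @export
roi_table <- function(x) {
  rois <- if (inherits(x, "weed_cohort")) x$rois else x
  if (length(rois) == 0) {
    return(data.frame(species = character(), plant_id = character(),
                      part = character(), pixel_count = integer()))
  }
  wl <- rois[[1]]$wavelengths
  mat <- t(vapply(rois, function(r) r$mean_spectrum, numeric(length(wl))))
  colnames(mat) <- sprintf("b%g", wl)
  cbind(data.frame(species = vapply(rois, `[[`, "", "species"),
                   plant_id = vapply(rois, `[[`, "", "plant_id"),
                   part = vapply(rois, `[[`, "", "part"),
                   pixel_count = vapply(rois, function(r) nrow(r$spectra), 0L),
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}

#' Write / read an ROI table as delimited text
#'
#' Tab-separated serialisation of [roi_table()] output; wavelengths are
#' recoverable from the band column names. The round trip is lossless at full
#' double precision.
#'
#' @param x Data frame from [roi_table()] (or a cohort, flattened first).
#' @param path File path.
#' @return `read_roi_table` returns the data.frame with an attribute
#'   `wavelengths`.
#' @export
write_roi_table <- function(x, path) {
  if (inherits(x, "weed_cohort")) x <- roi_table(x)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  bands <- grep("^b[0-9]", names(x))
  attr(x, "wavelengths") <- as.numeric(sub("^b", "", names(x)[bands]))
  x
}

#' Wavelengths attached to a cohort ROI table
#'
#' @param x A `weed_cohort` or an ROI table data.frame.
#' @return Numeric wavelength vector.
#' @export
roi_wavelengths <- function(x) {
  if (inherits(x, "weed_cohort")) return(x$wavelengths)
  wl <- attr(x, "wavelengths")
  if (is.null(wl)) {
    bands <- grep("^b[0-9]", names(x), value = TRUE)
    wl <- as.numeric(sub("^b", "", bands))
  }
  wl
}
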