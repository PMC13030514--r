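# Small deterministic fixtures shared across tests.

tiny_wavelengths <- function(n = 31) default_wavelengths(n)

# a small constant-valued cube with increasing wavelengths
constant_cube <- function(value = 20, lines = 4, samples = 5, bands = 6,
                          kind = "reflectance") {
  spectral_cube(array(value, c(lines, samples, bands)),
                seq(500, 700, length.out = bands), kind = kind)
}

zero_noise <- function() {
  noise_model(pixel_gain_sd = 0, band_noise_sd = 0, plant_offset_sd = 0,
              plant_gain_sd = 0, plant_redshift_sd = 0, plant_contrast_sd = 0)
}

small_cohort <- function(n_species = 3, n_plants = 4, seed = 11, ...) {
  generate_cohort(n_species = n_species, n_plants_per_species = n_plants,
                  pixels_per_roi = 50, wavelengths = tiny_wavelengths(),
                  seed = seed, ...)
}

# two well-separated Gaussian classes in p dimensions
separable_classes <- function(n_per_class = 30, p = 8, gap = 10, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(rep(c("A", "B"), each = n_per_class)),
       plant = paste0("pl", seq_len(2 * n_per_class)))
}
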