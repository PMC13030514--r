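#' Reflectance range of a part's mean spectrum
#'
#' Extrema of a mean spectrum restricted to the operational wavelength window
#' (500-780 nm by default, where whole plants show their spectral activity).
#' The returned wavelength bounds are the window limits intersected with the
#' spectrum's coverage.
#'
#' @param mean_spectrum Numeric spectrum, or a `weed_roi` (its mean spectrum
#'   is used).
#' @param wavelengths Wavelengths (nm); taken from the ROI if omitted.
#' @param window Length-2 wavelength window (nm).
#' @param part Optional part label carried through.
#' @return One-row data.frame: `part`, `r_min`, `r_max`, `lambda_min`,
#'   `lambda_max`.
#' @export
part_range <- function(mean_spectrum, wavelengths = NULL,
                       window = c(500, 780), part = NA_character_) {
  if (inherits(mean_spectrum, "weed_roi")) {
    wavelengths <- mean_spectrum$wavelengths
    part <- mean_spectrum$part
    mean_spectrum <- mean_spectrum$mean_spectrum
  }
  stopifnot(length(mean_spectrum) == length(wavelengths))
  inside <- wavelengths >= window[1] & wavelengths <= window[2]
  if (!any(inside))
    stop("spectrum does not cover the ", window[1], "-", window[2],
         " nm window", call. = FALSE)
  v <- mean_spectrum[inside]
  data.frame(part = part, r_min = min(v), r_max = max(v),
             lambda_min = max(window[1], min(wavelengths)),
             lambda_max = min(window[2], max(wavelengths)),
             stringsAsFactors = FALSE)
}

#' Wavelength-domain statistics of a spectral range
#'
#' For a wavelength interval \[`lambda_min`, `lambda_max`\] computes:
#' spectral bandwidth `SB = lambda_max - lambda_min` (nm), contrast ratio
#' `C = lambda_max / lambda_min` (requires `lambda_min > 0`), relative
#' bandwidth `B_rel = (lambda_max - lambda_min) / (lambda_max + lambda_min)`,
#' and normalised contrast
#' `C_norm = (lambda_max - lambda_min) / lambda_max`. All arguments are
#' vectorised.
#'
#' @param lambda_min,lambda_max Interval bounds (nm), `lambda_min > 0`,
#'   `lambda_min <= lambda_max`.
#' @return data.frame with columns `sb`, `c`, `b_rel`, `c_norm`.
#' @examples
#' wavelength_stats(500, 780)  # SB 280, C 1.56, B_rel 0.219, C_norm 0.359
#' @export
wavelength_stats <- function(lambda_min, lambda_max) {
  if (any(lambda_min <= 0))
    stop("contrast ratio undefined for lambda_min = 0 (xmin must be ",
         "non-zero)", call. = FALSE)
  if (any(lambda_min > lambda_max))
    stop("lambda_min must not exceed lambda_max", call. = FALSE)
  data.frame(sb = lambda_max - lambda_min,
             c = lambda_max / lambda_min,
             b_rel = (lambda_max - lambda_min) / (lambda_max + lambda_min),
             c_norm = (lambda_max - lambda_min) / lambda_max)
}

#' Species-level aggregation of part ranges
#'
#' Aggregates per-part reflectance and wavelength ranges into one row of
#' species-level statistics by an unweighted arithmetic mean over all listed
#' parts (including any whole-plant "General" row when `include_general` is
#' `TRUE`): the mean reflectance is the mean of the part midpoints
#' `(r_min + r_max)/2`; delta reflectance is the mean of the part ranges
#' `r_max - r_min`; SB, C, B_rel and C_norm are means of the per-part
#' [wavelength_stats()]. Duplicating every part leaves all values unchanged.
#'
#' The secondary descriptors sigma, CV, median and the rate of change are
#' computed from the same part set (sigma/median over the part midpoints;
#' rate = mean over parts of `100 * (r_max - r_min) / SB_part`, % per
#' 100 nm) but carry a `"non_reconciled"` attribute: with only range data as
#' input these definitions cannot reproduce values computed from raw pixel
#' spectra.
#'
#' @param part_ranges data.frame with columns `r_min`, `r_max`, `lambda_min`,
#'   `lambda_max` (optionally `part`).
#' @param include_general Keep a part labelled `"General"` in the mean
#'   (default `TRUE`).
#' @return One-row data.frame: `mu`, `sigma`, `cv`, `me`, `r_rate`,
#'   `delta_r`, `sb`, `c`, `b_rel`, `c_norm`; attribute `non_reconciled`
#'   names the columns not derivable from printed range data.
#' @export
species_aggregate <- function(part_ranges, include_general = TRUE) {
  pr <- part_ranges
  if (!include_general && "part" %in% names(pr))
    pr <- pr[pr$part != "General", , drop = FALSE]
  if (nrow(pr) == 0)
    stop("species_aggregate needs at least one part", call. = FALSE)
  need <- c("r_min", "r_max", "lambda_min", "lambda_max")
  miss <- setdiff(need, names(pr))
  if (length(miss))
    stop("part ranges missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mids <- (pr$r_min + pr$r_max) / 2
  rng <- pr$r_max - pr$r_min
  ws <- wavelength_stats(pr$lambda_min, pr$lambda_max)
  mu <- mean(mids)
  sigma <- sqrt(mean((mids - mu)^2))
  out <- data.frame(mu = mu, sigma = sigma,
                    cv = if (mu == 0) NA_real_ else 100 * sigma / mu,
                    me = stats::median(mids),
                    r_rate = mean(100 * rng / ws$sb),
                    delta_r = mean(rng),
                    sb = mean(ws$sb), c = mean(ws$c),
                    b_rel = mean(ws$b_rel), c_norm = mean(ws$c_norm))
  attr(out, "non_reconciled") <- c("sigma", "cv", "me", "r_rate")
  out
}

#' Species-by-species spectral statistics table
#'
#' Builds the species-level metric table either from a hand-entered part-range
#' table (columns `species`, `part`, `r_min`, `r_max`, `lambda_min`,
#' `lambda_max` — enabling reproduction of published range tables with no
#' imaging at all) or from a measured cohort, in which case each species/part
#' mean spectrum (average of its ROI mean spectra) is reduced to a range by
#' [part_range()] first.
#'
#' @param dataset A part-range data.frame with a `species` column, or a
#'   `weed_cohort`.
#' @param window Metric wavelength window for the cohort path.
#' @param include_general Passed to [species_aggregate()].
#' @return data.frame with one row per species (species with zero parts are
#'   omitted with a message); row order follows first appearance. Shuffling
#'   part order does not change the values.
#' @export
stats_table <- function(dataset, window = c(500, 780),
                        include_general = TRUE) {
  if (inherits(dataset, "weed_cohort")) {
    pr <- cohort_part_ranges(dataset, window = window)
  } else {
    pr <- dataset
  }
  species <- unique(pr$species)
  rows <- list()
  for (sp in species) {
    g <- pr[pr$species == sp, , drop = FALSE]
    if (nrow(g) == 0) {
      message("species ", sp, " omitted: no parts")
      next
    }
    rows[[sp]] <- cbind(data.frame(species = sp, stringsAsFactors = FALSE),
                        species_aggregate(g, include_general = include_general))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "non_reconciled") <- c("sigma", "cv", "me", "r_rate")
  out
}

#' Per-species, per-part ranges measured from a cohort
#'
#' Averages the ROI mean spectra of every species/part combination and
#' reduces each to its reflectance range within the metric window.
#'
#' @param cohort A `weed_cohort`.
#' @param window Wavelength window (nm).
#' @return data.frame with `species`, `part`, `r_min`, `r_max`,
#'   `lambda_min`, `lambda_max`.
#' @export
cohort_part_ranges <- function(cohort, window = c(500, 780)) {
  tab <- roi_table(cohort)
  wl <- roi_wavelengths(cohort)
  bands <- grep("^b[0-9]", names(tab))
  groups <- split(tab, list(tab$species, tab$part), drop = TRUE)
  rows <- lapply(groups, function(g) {
    ms <- colMeans(as.matrix(g[, bands, drop = FALSE]))
    cbind(data.frame(species = g$species[1], stringsAsFactors = FALSE),
          part_range(ms, wl, window = window, part = g$part[1]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published per-part spectral ranges of the nine study species
#'
#' The reported part-level reflectance ranges (%) and wavelength ranges (nm)
#' for every morphological part of the nine study species, as shipped in
#' `inst/extdata/reported_part_ranges.csv`. Feeding this table to
#' [stats_table()] reproduces the published species-level statistics.
#'
#' @return data.frame with `species`, `part`, `r_min`, `r_max`,
#'   `lambda_min`, `lambda_max`.
#' @export
reported_part_ranges <- function() {
  path <- system.file("extdata", "reported_part_ranges.csv",
                      package = "weedspec", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
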