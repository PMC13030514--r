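#' Extract labelled ROIs from a cube
#'
#' Collects the pixel spectra of each positive-valued mask region into a
#' `weed_roi`. Pixels with any band above `specular_ceiling` are treated as
#' specular artefacts and excluded before the pixel-count rule is applied.
#' Regions left with fewer than `min_pixels` pixels are dropped (with a
#' message), enforcing the >= 50 pure-pixel purity rule.
#'
#' @param cube A `spectral_cube`.
#' @param mask Integer matrix of the cube's spatial shape; 0 = background,
#'   positive values are region ids.
#' @param labels Optional data.frame with columns `region`, `species`,
#'   `plant_id`, `part` mapping region ids to labels.
#' @param min_pixels Minimum pixels per ROI (default 50).
#' @param specular_ceiling Reflectance ceiling for specular-pixel removal
#'   (default 120, the calibration clip level); `Inf` disables it.
#' @param mahalanobis_filter Optional chi-square quantile (e.g. 0.999) for a
#'   per-ROI Mahalanobis-distance outlier filter approximating
#'   spectral-homogeneity binarisation; `NULL` (default) disables it.
#' @return List of `weed_roi` objects.
#' @export
extract_rois <- function(cube, mask, labels = NULL, min_pixels = 50,
                         specular_ceiling = 120, mahalanobis_filter = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!identical(dim(mask), dim(cube$data)[1:2]))
    stop("mask shape must equal the cube's spatial shape", call. = FALSE)
  ids <- sort(unique(mask[mask > 0]))
  out <- list()
  for (id in ids) {
    idx <- which(mask == id, arr.ind = TRUE)
    spectra <- t(apply(idx, 1, function(ij) cube$data[ij[1], ij[2], ]))
    keep <- apply(spectra, 1, function(s) all(s < specular_ceiling))
    spectra <- spectra[keep, , drop = FALSE]
    idx <- idx[keep, , drop = FALSE]
    if (!is.null(mahalanobis_filter) && nrow(spectra) > ncol(spectra) + 1) {
      md <- stats::mahalanobis(spectra, colMeans(spectra), stats::cov(spectra))
      ok <- md <= stats::qchisq(mahalanobis_filter, df = ncol(spectra))
      spectra <- spectra[ok, , drop = FALSE]
      idx <- idx[ok, , drop = FALSE]
    }
    if (nrow(spectra) < min_pixels) {
      message("region ", id, " dropped: ", nrow(spectra), " pure pixels < ",
              min_pixels)
      next
    }
    lab <- if (!is.null(labels) && id %in% labels$region)
      labels[match(id, labels$region), ] else
      data.frame(species = NA_character_, plant_id = NA_character_,
                 part = sprintf("region_%d", id))
    out[[length(out) + 1]] <- new_weed_roi(
      species = lab$species, plant_id = lab$plant_id, part = lab$part,
      spectra = spectra, wavelengths = cube$wavelengths, pixel_indices = idx)
  }
  out
}

#' Plant-wise train/test split
#'
#' Randomly assigns whole plants of each species to training or testing, so
#' that ROIs from one plant never straddle the two sets. The per-species
#' training count is `floor(train_fraction * n_plants)` (25 plants at 0.7
#' give 17 train / 8 test).
#'
#' @param dataset A `weed_cohort`, ROI table data.frame, or any data.frame
#'   with `species` and `plant_id` columns.
#' @param train_fraction Fraction of plants per species assigned to training,
#'   in (0, 1).
#' @param seed Integer seed; identical seeds give identical plans.
#' @return A `split_plan` data.frame with columns `species`, `plant_id`,
#'   `role` (`"train"`/`"test"`) and attribute `seed`.
#' @export
plant_wise_split <- function(dataset, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  tab <- if (inherits(dataset, "weed_cohort")) roi_table(dataset) else dataset
  plants <- unique(tab[, c("species", "plant_id")])
  set.seed(seed)
  plan <- do.call(rbind, lapply(split(plants, plants$species), function(g) {
    n <- nrow(g)
    if (n < 2)
      stop("plant-wise split needs >= 2 plants per species", call. = FALSE)
    n_train <- floor(train_fraction * n)
    train_ids <- sample(g$plant_id, n_train)
    g$role <- ifelse(g$plant_id %in% train_ids, "train", "test")
    g
  }))
  rownames(plan) <- NULL
  attr(plan, "seed") <- seed
  class(plan) <- c("split_plan", "data.frame")
  plan
}

#' Apply a split plan to a dataset
#'
#' @param dataset A `weed_cohort` or ROI table data.frame.
#' @param plan A [plant_wise_split()] plan covering every plant in the
#'   dataset.
#' @return `list(train = , test = )`, each of the dataset's type; together
#'   they partition the ROIs.
#' @export
split_rois <- function(dataset, plan) {
  role_of <- stats::setNames(plan$role, plan$plant_id)
  if (inherits(dataset, "weed_cohort")) {
    ids <- vapply(dataset$rois, `[[`, "", "plant_id")
    orphan <- setdiff(ids, plan$plant_id)
    if (length(orphan))
      stop("plant id(s) missing from the split plan: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    pick <- function(role) {
      out <- dataset
      out$rois <- dataset$rois[role_of[ids] == role]
      out
    }
    return(list(train = pick("train"), test = pick("test")))
  }
  orphan <- setdiff(dataset$plant_id, plan$plant_id)
  if (length(orphan))
    stop("plant id(s) missing from the split plan: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  roles <- role_of[dataset$plant_id]
  list(train = dataset[roles == "train", , drop = FALSE],
       test = dataset[roles == "test", , drop = FALSE])
}

#' Write / read a split plan as delimited text
#'
#' @param plan A `split_plan`.
#' @param path File path.
#' @return `read_split_plan` returns the plan data.frame.
#' @export
write_split_plan <- function(plan, path) {
  utils::write.table(as.data.frame(plan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(x) <- c("split_plan", "data.frame")
  x
}
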