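#' Prominence-based local maxima (Fiji "Find Maxima" semantics)
#'
#' Finds 8-connected local maxima whose prominence above the surrounding
#' saddle exceeds the noise tolerance, one representative point per plateau
#' (the plateau centroid rounded to the nearest pixel, exact halves toward
#' the smaller index). A constant image has no maxima.
#'
#' @param image numeric matrix.
#' @param prominence noise tolerance (intensity units), `>= 0`.
#' @return integer matrix with columns `y`, `x` (1-based pixel coordinates).
#' @export
find_maxima <- function(image, prominence) {
  stopifnot(is.matrix(image), prominence >= 0)
  res <- cpp_find_maxima(image, prominence)
  colnames(res) <- c("y", "x")
  res
}

#' Maxima-seeded watershed segmentation of puncta
#'
#' Splits the supra-threshold mask into one labelled region per maximum by
#' descending-intensity priority flooding (the automated equivalent of the
#' manual single-pixel pencil-line splitting): touching puncta are divided
#' at their intensity saddle. Seeds falling outside the threshold mask are
#' dropped and recorded.
#'
#' @param image numeric matrix.
#' @param threshold same lower threshold used for the NMJ mask.
#' @param maxima matrix of seed coordinates from [find_maxima()] on this
#'   image.
#' @return integer label matrix (0 = background); attribute
#'   `dropped_seeds` lists seed rows that fell outside the mask.
#' @export
segment_spots <- function(image, threshold, maxima) {
  mask <- image > threshold
  if (nrow(maxima) == 0)
    return(structure(matrix(0L, nrow(image), ncol(image)),
                     dropped_seeds = integer(0)))
  inmask <- mask[cbind(maxima[, 1], maxima[, 2])]
  labels <- cpp_seeded_watershed(image, mask, maxima)
  structure(labels, dropped_seeds = which(!inmask))
}

#' Measure segmented puncta
#'
#' Per-label area, centroid and intensity statistics, measured on the
#' original image restricted to the label support (min-combine semantics).
#' Labels below the area cut-off are removed before any statistic is formed
#' (e.g. 0.0202 µm² for early-endosome analysis).
#'
#' @param labels integer label matrix from [segment_spots()].
#' @param image the original (uncleaned-intensity) image, same shape.
#' @param pixel_pitch_um pixel pitch (µm).
#' @param min_area_um2 exclusion cut-off; labels with area strictly below it
#'   are dropped (0 keeps everything).
#' @return a `spot_table`: data.frame with `label`, `area_um2`,
#'   `centroid_y`, `centroid_x`, `mean_intensity`, `integrated_intensity`;
#'   pitch and threshold carried as attributes.
#' @export
measure_spots <- function(labels, image, pixel_pitch_um, min_area_um2 = 0) {
  stopifnot(all(dim(labels) == dim(image)))
  sel <- labels > 0
  if (!any(sel)) {
    out <- data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      mean_intensity = numeric(0),
                      integrated_intensity = numeric(0))
  } else {
    lab <- labels[sel]
    val <- image[sel]
    rc <- which(sel, arr.ind = TRUE)
    npx <- tapply(val, lab, length)
    tot <- tapply(val, lab, sum)
    cy <- tapply(rc[, 1], lab, mean)
    cx <- tapply(rc[, 2], lab, mean)
    out <- data.frame(label = as.integer(names(npx)),
                      area_um2 = as.numeric(npx) * pixel_pitch_um^2,
                      centroid_y = as.numeric(cy), centroid_x = as.numeric(cx),
                      mean_intensity = as.numeric(tot / npx),
                      integrated_intensity = as.numeric(tot))
    out <- out[out$area_um2 >= min_area_um2, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "pixel_pitch_um") <- pixel_pitch_um
  attr(out, "min_area_um2") <- min_area_um2
  class(out) <- c("spot_table", "data.frame")
  out
}

#' NMJ-level punctum metrics
#'
#' Aggregates a spot table into the standard NMJ measures: mean punctum
#' area, punctum density (count / HRP-mask area), unweighted mean of
#' per-punctum mean intensities, total count, integrated density (sum of
#' all intensities inside the mask) and the mask area; NMJ length is
#' supplied from [skeleton_length()].
#'
#' @param spots a `spot_table` from [measure_spots()].
#' @param nmj_mask a `binary_mask` (the HRP mask, with pitch-derived area).
#' @param cleaned_image the cleaned signal projection, for the integrated
#'   density.
#' @param nmj_length_um optional NMJ length (µm).
#' @return list of class `nmj_metrics`; empty spot tables report `NA` mean
#'   area/intensity and count 0.
#' @export
nmj_metrics <- function(spots, nmj_mask, cleaned_image,
                        nmj_length_um = NA_real_) {
  area <- nmj_mask$area_um2
  if (!is.finite(area) || area <= 0) stop("mask has zero or unknown area")
  n <- nrow(spots)
  structure(list(
    total_spot_count = n,
    mean_spot_area_um2 = if (n) mean(spots$area_um2) else NA_real_,
    mean_spot_intensity = if (n) mean(spots$mean_intensity) else NA_real_,
    spot_density_per_um2 = n / area,
    total_intensity = sum(cleaned_image[nmj_mask$data]),
    nmj_area_um2 = area,
    nmj_length_um = nmj_length_um), class = "nmj_metrics")
}

#' Normalize metric values to a control group
#'
#' Scales values so the control-group mean maps to 100 (percent of control).
#' For rescue assays with an unspecific driver background, the background
#' group's mean is subtracted from every value first.
#'
#' @param values numeric measurements.
#' @param groups group label per value.
#' @param control_group label of the reference group (maps to 100).
#' @param background_group optional label whose mean is subtracted from all
#'   values before scaling.
#' @return numeric vector of percentages.
#' @export
normalize_to_control <- function(values, groups, control_group,
                                 background_group = NULL) {
  stopifnot(length(values) == length(groups))
  if (!any(groups == control_group)) stop("control group is empty")
  v <- values
  if (!is.null(background_group)) {
    if (!any(groups == background_group)) stop("background group is empty")
    v <- v - mean(v[groups == background_group])
  }
  ref <- mean(v[groups == control_group])
  if (ref == 0) stop("control mean is zero")
  100 * v / ref
}
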