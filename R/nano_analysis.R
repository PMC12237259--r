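#' Extract square AZ regions of interest from a two-channel STED frame
#'
#' Crops a `roi_px` x `roi_px` window of both channels around each AZ
#' center. Windows that would exceed the frame are skipped and logged.
#'
#' @param frame a 2-channel single-slice `image_stack`.
#' @param az_centers matrix of (y, x) centers in pixels.
#' @param roi_px ROI side length (default 53, i.e. 1.06 µm at 20-nm pitch).
#' @return list of per-AZ lists `roi1`, `roi2`, `origin` (1-based (y, x) of
#'   the ROI's top-left pixel); attribute `skipped` holds indices of AZs
#'   whose ROI exceeded the frame.
#' @export
extract_az_rois <- function(frame, az_centers, roi_px = 53) {
  c1 <- get_channel(frame, 1)
  c2 <- get_channel(frame, 2)
  half <- (roi_px - 1) %/% 2
  out <- list()
  skipped <- integer(0)
  for (i in seq_len(nrow(az_centers))) {
    y0 <- round(az_centers[i, 1]) - half
    x0 <- round(az_centers[i, 2]) - half
    if (y0 < 1 || x0 < 1 || y0 + roi_px - 1 > nrow(c1) ||
        x0 + roi_px - 1 > ncol(c1)) {
      skipped <- c(skipped, i)
      next
    }
    ys <- y0:(y0 + roi_px - 1)
    xs <- x0:(x0 + roi_px - 1)
    out[[length(out) + 1L]] <- list(roi1 = c1[ys, xs], roi2 = c2[ys, xs],
                                    origin = c(y = y0, x = x0))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Ring center of mass of a BRP ROI
#'
#' Subtracts the lowest pixel value of the ROI, then returns the
#' intensity-weighted centroid at subpixel precision (the XM/YM convention).
#'
#' @param brp_roi numeric matrix (non-constant).
#' @return named numeric `c(y, x)` in 1-based pixel coordinates.
#' @export
ring_center <- function(brp_roi) {
  w <- brp_roi - min(brp_roi)
  tw <- sum(w)
  if (tw == 0) stop("constant ROI: center of mass undefined")
  ys <- matrix(seq_len(nrow(w)), nrow(w), ncol(w))
  xs <- matrix(seq_len(ncol(w)), nrow(w), ncol(w), byrow = TRUE)
  c(y = sum(w * ys) / tw, x = sum(w * xs) / tw)
}

#' Local maxima of the partner channel within an ROI
#'
#' Thin wrapper over [find_maxima()] applied to the partner-channel ROI.
#'
#' @param partner_roi numeric matrix.
#' @param prominence noise tolerance.
#' @return integer matrix of (y, x) maxima.
#' @export
partner_maxima <- function(partner_roi, prominence) {
  find_maxima(partner_roi, prominence)
}

#' Ranked nearest-neighbor distances from an AZ center
#'
#' Euclidean distances from each partner point to the ring center, sorted
#' ascending and converted to nm; the minimum is k1. Missing ranks (fewer
#' than `k` points) are `NA`.
#'
#' @param center numeric (y, x) subpixel center.
#' @param points matrix of (y, x) point coordinates (integer pixel, the
#'   Find-Maxima convention); may have zero rows.
#' @param k number of ranks to report (default 5).
#' @param pitch_nm pixel pitch in nm.
#' @return numeric vector `k1 ... k<k>` in nm (all `NA` when no points).
#' @export
kneighbor <- function(center, points, k = 5, pitch_nm = 20) {
  out <- rep(NA_real_, k)
  names(out) <- paste0("k", seq_len(k))
  if (is.null(points) || nrow(points) == 0) return(out)
  d <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2) * pitch_nm
  d <- sort(d)
  out[seq_len(min(k, length(d)))] <- d[seq_len(min(k, length(d)))]
  out
}

#' AZ size bin from its area in pixels
#'
#' Bins: small `[1, 159]` px², middle `[160, 215]` px², big `> 215` px².
#'
#' @param az_area_px2 AZ area in pixel² (`>= 1`).
#' @return factor level `"small"`, `"middle"` or `"big"`.
#' @export
bin_by_area <- function(az_area_px2) {
  if (any(az_area_px2 < 1)) stop("AZ area must be >= 1 px^2")
  cut(az_area_px2, breaks = c(1, 159, 215, Inf),
      labels = c("small", "middle", "big"), include.lowest = TRUE,
      right = TRUE)
}

#' Count partner spots within a radius of the AZ center
#'
#' @param distances_nm numeric distances (NA ignored).
#' @param r_nm radius (default 400 nm); distances `<= r_nm` are counted.
#' @return integer count.
#' @export
count_within_radius <- function(distances_nm, r_nm = 400) {
  sum(distances_nm <= r_nm, na.rm = TRUE)
}

#' Full K-neighbor analysis of a synthetic or measured STED frame
#'
#' For each AZ ROI: ring center of mass of the BRP channel, partner-channel
#' local maxima, ranked center-to-spot distances, AZ area (supra-Moments
#' pixels of the BRP ROI), size bin, and the count within 400 nm.
#'
#' @param frame a 2-channel `image_stack` (BRP first, partner second).
#' @param az_centers matrix of approximate AZ centers (y, x) px.
#' @param prominence Find-Maxima tolerance for the partner channel.
#' @param pitch_nm pixel pitch (nm).
#' @param roi_px ROI side (default 53).
#' @param k ranks to keep.
#' @return data.frame, one row per analyzed AZ: `az_id`, `center_y`,
#'   `center_x` (frame coordinates, subpixel), `az_area_px2`, `size_bin`,
#'   `n_points`, `k1..k5` (nm), `count_within_400nm`.
#' @export
kneighbor_analysis <- function(frame, az_centers, prominence,
                               pitch_nm = 20, roi_px = 53, k = 5) {
  rois <- extract_az_rois(frame, az_centers, roi_px)
  rows <- list()
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    ctr <- ring_center(r$roi1)
    pts <- partner_maxima(r$roi2, prominence)
    dd <- kneighbor(ctr, pts, k = k, pitch_nm = pitch_nm)
    thr <- moments_threshold(r$roi1)
    area <- max(1, sum(r$roi1 > thr))
    row <- data.frame(az_id = i,
                      center_y = ctr["y"] + r$origin["y"] - 1,
                      center_x = ctr["x"] + r$origin["x"] - 1,
                      az_area_px2 = area, size_bin = bin_by_area(area),
                      n_points = nrow(pts))
    row <- cbind(row, as.data.frame(as.list(dd)))
    row$count_within_400nm <- count_within_radius(dd)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Moments-preserving (Tsai) automatic threshold
#'
#' Chooses the gray level whose binarization preserves the image's first
#' three gray-level moments: the below-threshold fraction p0 is obtained in
#' closed form from the moments, and the threshold is the histogram p-tile
#' at p0. Works on a 256-bin histogram over the image range, so adding a
#' constant to all pixels shifts the threshold by the same constant.
#'
#' @param image numeric matrix (non-constant).
#' @param n_bins histogram resolution.
#' @return threshold intensity (on the image's own scale).
#' @export
moments_threshold <- function(image, n_bins = 256) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) stop("constant image: threshold undefined")
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1)
  h <- tabulate(bin + 1L, nbins = n_bins) / length(v)
  if (sum(h > 0) < 2) stop("degenerate histogram (single populated level)")
  g <- seq_len(n_bins) - 1
  m1 <- sum(g * h); m2 <- sum(g^2 * h); m3 <- sum(g^3 * h)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  z0 <- 0.5 * (-c1 - sqrt(c1^2 - 4 * c0))
  z1 <- 0.5 * (-c1 + sqrt(c1^2 - 4 * c0))
  p0 <- (z1 - m1) / (z1 - z0) # fraction of pixels below threshold
  csum <- cumsum(h)
  t_bin <- which.min(abs(csum - p0)) - 1
  lo + (t_bin + 0.5) / n_bins * (hi - lo)
}

#' Radial intensity profiles around cluster centers
#'
#' Annulus-mean intensity versus radius, in both channels, around each
#' center; per-image aggregation is the median profile across centers.
#' Centers are typically obtained by Moments-thresholding the cluster
#' channel and running [find_maxima()] on it (see
#' [radial_profile_centers()]).
#'
#' @param frame a 2-channel `image_stack`.
#' @param centers matrix of (y, x) centers (px).
#' @param max_radius_nm largest radius (default 500).
#' @param bin_nm radial bin width (default 20, one STED pixel).
#' @param pitch_nm pixel pitch in nm (default from the stack's pitch).
#' @return list of class `radial_profile`: `radii_nm` (bin centers),
#'   `per_cluster` (list per channel of center x bin matrices),
#'   `median_profile` (per channel), `n_centers`, `truncated` (logical per
#'   center: annuli clipped by the frame border).
#' @export
radial_profile <- function(frame, centers, max_radius_nm = 500, bin_nm = 20,
                           pitch_nm = NULL) {
  if (is.null(pitch_nm)) pitch_nm <- frame$pixel_pitch_um * 1000
  c1 <- get_channel(frame, 1)
  c2 <- get_channel(frame, 2)
  # bins centered on multiples of bin_nm (0, bin, 2*bin, ...): a ring of
  # radius r peaks in the bin whose center is the nearest multiple of bin_nm
  nb <- floor(max_radius_nm / bin_nm) + 1L
  radii <- (seq_len(nb) - 1L) * bin_nm
  half_px <- ceiling(max_radius_nm / pitch_nm)
  prof <- function(img, cy, cx) {
    ys <- max(1, floor(cy - half_px)):min(nrow(img), ceiling(cy + half_px))
    xs <- max(1, floor(cx - half_px)):min(ncol(img), ceiling(cx + half_px))
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+")) * pitch_nm
    b <- floor(d / bin_nm + 0.5) + 1L
    keep <- b <= nb
    means <- rep(NA_real_, nb)
    agg <- tapply(img[ys, xs][keep], b[keep], mean)
    means[as.integer(names(agg))] <- agg
    means
  }
  n <- nrow(centers)
  p1 <- matrix(NA_real_, n, nb)
  p2 <- matrix(NA_real_, n, nb)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    truncated[i] <- cy - half_px < 1 || cx - half_px < 1 ||
      cy + half_px > nrow(c1) || cx + half_px > ncol(c1)
    p1[i, ] <- prof(c1, cy, cx)
    p2[i, ] <- prof(c2, cy, cx)
  }
  structure(list(radii_nm = radii,
                 per_cluster = list(p1, p2),
                 median_profile = list(apply(p1, 2, median, na.rm = TRUE),
                                       apply(p2, 2, median, na.rm = TRUE)),
                 n_centers = n, truncated = truncated),
            class = "radial_profile")
}

#' Cluster centers for radial profiling
#'
#' The center-detection recipe for radial profiles: background removal by
#' the Moments auto-threshold on the cluster channel, then prominence-based
#' local maxima on the thresholded image.
#'
#' @param cluster_image numeric matrix (the channel defining the clusters).
#' @param prominence Find-Maxima tolerance.
#' @return matrix of (y, x) centers.
#' @export
radial_profile_centers <- function(cluster_image, prominence) {
  thr <- moments_threshold(cluster_image)
  img <- cluster_image
  img[img <= thr] <- 0
  find_maxima(img, prominence)
}

#' Group-level aggregation of per-image median radial profiles
#'
#' Mean across images with a Student-t 95% confidence interval per radius
#' (n - 1 degrees of freedom); optional normalization of the group profile
#' to its maximum bin.
#'
#' @param profiles list of `radial_profile` objects (one per image).
#' @param channel which channel's median profiles to aggregate (1 or 2).
#' @param normalize logical; divide the group mean and CI by the maximum
#'   mean bin.
#' @return data.frame `radius_nm`, `mean`, `ci_low`, `ci_high`, `n_images`.
#' @export
aggregate_radial_profiles <- function(profiles, channel = 1,
                                      normalize = FALSE) {
  stopifnot(length(profiles) >= 1)
  radii <- profiles[[1]]$radii_nm
  mat <- t(vapply(profiles, function(p) p$median_profile[[channel]],
                  numeric(length(radii))))
  n <- nrow(mat)
  mu <- colMeans(mat, na.rm = TRUE)
  if (n > 1) {
    se <- apply(mat, 2, sd, na.rm = TRUE) / sqrt(n)
    tq <- qt(0.975, n - 1)
    lo <- mu - tq * se
    hi <- mu + tq * se
  } else {
    lo <- hi <- rep(NA_real_, length(mu))
  }
  if (normalize) {
    mx <- max(mu, na.rm = TRUE)
    mu <- mu / mx; lo <- lo / mx; hi <- hi / mx
  }
  data.frame(radius_nm = radii, mean = mu, ci_low = lo, ci_high = hi,
             n_images = n)
}
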