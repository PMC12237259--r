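#' Maximum-intensity projection of one channel
#'
#' Confocal z-stacks are reduced to a single plane by taking, at every (y, x)
#' position, the maximum over all optical slices.
#'
#' @param stack an `image_stack`.
#' @param channel channel label or index.
#' @return numeric matrix `(y, x)`.
#' @export
max_project <- function(stack, channel) {
  arr <- get_channel(stack, channel, drop = FALSE)
  apply(arr, c(2, 3), max)
}

#' Scalar background subtraction
#'
#' Estimates a scalar background from the image and subtracts it, clamping
#' negative results at zero. Strategies: `"fixed"` uses `value` directly;
#' `"mode"` uses the most frequent (integer-rounded) intensity, the usual
#' estimate for a dark background dominated image; `"roi_mean"` averages over
#' a rectangular region given as `c(y0, y1, x0, x1)` (1-based, inclusive).
#'
#' @param image numeric matrix.
#' @param strategy one of `"roi_mean"`, `"mode"`, `"fixed"`.
#' @param value_or_roi scalar (for `"fixed"`) or length-4 ROI (for
#'   `"roi_mean"`); ignored for `"mode"`.
#' @return the background-subtracted matrix; the estimate and strategy are
#'   attached as attributes `background` and `background_strategy`.
#' @export
subtract_background <- function(image, strategy = c("roi_mean", "mode", "fixed"),
                                value_or_roi = NULL) {
  strategy <- match.arg(strategy)
  bg <- switch(strategy,
    fixed = {
      stopifnot(is.numeric(value_or_roi), length(value_or_roi) == 1L)
      value_or_roi
    },
    mode = {
      tb <- table(round(image))
      as.numeric(names(tb)[which.max(tb)])
    },
    roi_mean = {
      r <- as.integer(value_or_roi)
      if (length(r) != 4L || r[1] < 1 || r[3] < 1 ||
          r[2] > nrow(image) || r[4] > ncol(image) || r[1] > r[2] || r[3] > r[4])
        stop("ROI outside frame")
      mean(image[r[1]:r[2], r[3]:r[4]])
    })
  if (bg < 0) stop("background estimate must be >= 0")
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  attr(out, "background_strategy") <- strategy
  out
}

#' Binary mask from an intensity threshold
#'
#' Pixels strictly above `threshold` are set. The threshold is recorded on
#' the mask so the same value can be reused for spot segmentation.
#'
#' @param image numeric matrix (or `(z, y, x)` array for per-slice masks).
#' @param threshold intensity cut; must be `>= 0`.
#' @param pixel_pitch_um optional pitch to derive the mask area in µm².
#' @return object of class `binary_mask`: list with `data` (logical),
#'   `threshold_value` and, when pitch is given, `area_um2`.
#' @export
make_mask <- function(image, threshold, pixel_pitch_um = NULL) {
  stopifnot(threshold >= 0)
  m <- image > threshold
  area <- if (!is.null(pixel_pitch_um)) sum(m) * pixel_pitch_um^2 else NA_real_
  structure(list(data = m, threshold_value = threshold, area_um2 = area),
            class = "binary_mask")
}

#' Per-slice muscle-signal exclusion ("cleaning")
#'
#' For channels with a muscle contribution, each optical slice of the signal
#' channel is restricted to an HRP mask computed in that same slice: a
#' per-slice mask of the membrane channel is thresholded and all signal
#' outside it is zeroed. A subsequent [max_project()] then contains only
#' in-envelope signal.
#'
#' @param stack an `image_stack`.
#' @param signal_channel channel to clean.
#' @param mask_channel membrane (HRP) channel providing the per-slice mask.
#' @param threshold intensity threshold for the per-slice mask.
#' @return a new `image_stack` with the signal channel cleaned.
#' @export
clean_stack_per_slice <- function(stack, signal_channel, mask_channel, threshold) {
  si <- channel_index(stack, signal_channel)
  mi <- channel_index(stack, mask_channel)
  out <- stack
  nz <- dim(stack$data)[2]
  for (zi in seq_len(nz)) {
    mask <- stack$data[mi, zi, , ] > threshold
    sig <- out$data[si, zi, , ]
    sig[!mask] <- 0
    out$data[si, zi, , ] <- sig
  }
  out
}

#' Rescale an image so its maximum is 256
#'
#' Linear rescaling used before colocalization analysis so image pairs share
#' an intensity scale; the target maximum is 256 exactly.
#'
#' @param image numeric matrix with `max(image) > 0`.
#' @return rescaled matrix with maximum 256.
#' @export
normalize_to_256 <- function(image) {
  mx <- max(image)
  if (mx <= 0) stop("normalize_to_256: image maximum must be > 0")
  image * (256 / mx)
}

#' Pixel-wise minimum of a mask image and an original image
#'
#' The ImageJ "min" image-calculator idiom: a binary mask coded as
#' 0 / saturation projected onto the unmodified image restricts intensities
#' to the mask support while leaving in-mask values untouched.
#'
#' @param mask_image numeric matrix, 0 outside and a saturating value inside.
#' @param original numeric matrix of the same shape.
#' @return pixel-wise minimum.
#' @export
min_combine <- function(mask_image, original) {
  if (!all(dim(mask_image) == dim(original))) stop("shape mismatch")
  pmin(mask_image, original)
}

# one pass of Zhang-Suen thinning; m is a logical matrix padded by callers
thin_pass <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqn <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  an <- matrix(0L, nr, nc)
  for (i in 1:8) an <- an + (!seqn[[i]] & seqn[[i + 1]])
  if (step == 1L) {
    cond <- m & bn >= 2 & bn <= 6 & an == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond <- m & bn >= 2 & bn <= 6 & an == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
  m & !cond
}

#' Skeleton length of a binary mask
#'
#' Surrogate for hand-drawn NMJ branch-length measurement: the mask is
#' reduced to a one-pixel-wide skeleton (Zhang-Suen thinning) and the total
#' geodesic length is the sum over adjacent skeleton pixel pairs, axial steps
#' counting 1 pixel and diagonal steps sqrt(2), converted to µm by the pitch.
#' Diagonal adjacencies short-cut by an axial path are not double counted.
#'
#' @param mask a `binary_mask` or logical matrix (2-D).
#' @param pixel_pitch_um pixel pitch in µm (required for a bare matrix; taken
#'   from nothing else).
#' @return total skeleton length in µm (0 for an empty mask).
#' @export
skeleton_length <- function(mask, pixel_pitch_um) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  stopifnot(is.matrix(m))
  m <- m > 0
  if (!any(m)) return(0)
  repeat {
    m1 <- thin_pass(m, 1L)
    m2 <- thin_pass(m1, 2L)
    if (identical(m2, m)) break
    m <- m2
  }
  nr <- nrow(m); nc <- ncol(m)
  right <- m[, -nc] & m[, -1]
  down <- m[-nr, ] & m[-1, ]
  # diagonals, counted only when not short-cut by the two axial corners
  dr <- m[-nr, -nc] & m[-1, -1] & !(m[-nr, -1] | m[-1, -nc])
  dl <- m[-nr, -1] & m[-1, -nc] & !(m[-nr, -nc] | m[-1, -1])
  (sum(right) + sum(down) + sqrt(2) * (sum(dr) + sum(dl))) * pixel_pitch_um
}
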