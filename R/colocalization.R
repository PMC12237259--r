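#' Pearson correlation over in-mask pixels
#'
#' @param a,b numeric matrices of equal shape.
#' @param mask optional logical matrix; `NULL` uses all pixels.
#' @return sample Pearson correlation.
#' @export
pearson <- function(a, b, mask = NULL) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  x <- a[mask]
  y <- b[mask]
  if (length(x) < 2) stop("need at least 2 in-mask pixels")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in a channel")
  cor(x, y)
}

# orthogonal (total least squares) regression of b on a
ortho_regression <- function(x, y) {
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxy == 0) stop("orthogonal regression undefined (zero covariance)")
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Costes automatic colocalization thresholds
#'
#' Walks candidate thresholds for channel 1 downward along the orthogonal
#' regression line (`T`, `slope * T + intercept`) and returns the highest
#' pair at which the Pearson correlation of the pixels *below* both
#' thresholds is zero or negative (or undefined because too few remain).
#'
#' @param a,b numeric matrices (channel 1, channel 2).
#' @param mask optional logical matrix restricting the analysis.
#' @param n_steps number of candidate levels between min and max of `a`.
#' @return list `threshold_a`, `threshold_b`, `slope`, `intercept`.
#' @export
costes_thresholds <- function(a, b, mask = NULL, n_steps = 256) {
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  x <- a[mask]
  y <- b[mask]
  reg <- ortho_regression(x, y)
  cand <- seq(max(x), min(x), length.out = n_steps)
  ta <- min(x); tb <- reg$intercept + reg$slope * min(x)
  for (t1 in cand) {
    t2 <- reg$intercept + reg$slope * t1
    below <- x < t1 & y < t2
    if (sum(below) < 2 || var(x[below]) == 0 || var(y[below]) == 0) {
      ta <- t1; tb <- t2
      break
    }
    if (cor(x[below], y[below]) <= 0) {
      ta <- t1; tb <- t2
      break
    }
  }
  list(threshold_a = ta, threshold_b = tb,
       slope = reg$slope, intercept = reg$intercept)
}

#' Pearson colocalization above automatic thresholds, with flipped control
#'
#' Computes the full-mask correlation, the Costes thresholds, the
#' correlation over pixels where at least one channel exceeds its threshold
#' (pixels sub-threshold in both channels are excluded — the plugin
#' convention), and a negative control in which channel 2 is mirrored
#' horizontally and the whole procedure repeated. Note the documented
#' caveat: a left-right symmetric image correlates perfectly with its own
#' mirror, so the control is only meaningful for asymmetric content.
#'
#' @param a,b numeric matrices (channel 1 e.g. Myo15, channel 2 e.g. actin).
#' @param mask optional logical matrix (e.g. the HRP mask).
#' @return list of class `coloc_result`: `r_full`, `r_above_threshold`,
#'   `thresholds`, `r_inverted_control`, `n_pixels_used`.
#' @export
pearson_above_threshold <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  r_full <- pearson(a, b, mask)
  th <- costes_thresholds(a, b, mask)
  keep <- mask & (a > th$threshold_a | b > th$threshold_b)
  if (sum(keep) < 2) stop("fewer than 2 supra-threshold pixels")
  r_above <- cor(a[keep], b[keep])
  b_flip <- b[, rev(seq_len(ncol(b))), drop = FALSE]
  mask_flip <- mask # channel 1 and its mask stay in place
  th_f <- try(costes_thresholds(a, b_flip, mask_flip), silent = TRUE)
  r_inv <- if (inherits(th_f, "try-error")) NA_real_ else {
    keep_f <- mask_flip & (a > th_f$threshold_a | b_flip > th_f$threshold_b)
    if (sum(keep_f) < 2) NA_real_ else cor(a[keep_f], b_flip[keep_f])
  }
  structure(list(r_full = r_full, r_above_threshold = r_above,
                 thresholds = c(a = th$threshold_a, b = th$threshold_b),
                 r_inverted_control = r_inv,
                 n_pixels_used = sum(keep)),
            class = "coloc_result")
}
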