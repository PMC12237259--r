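#' Construct an image stack
#'
#' Container for multi-channel 2-D or 3-D fluorescence data. Data are stored
#' as a 4-D array indexed `[channel, z, y, x]`; single-plane images use
#' `z = 1`. Physical calibration is carried along so that every downstream
#' area, density and distance is reported in micrometres.
#'
#' @param data numeric array `(c, z, y, x)`, or a matrix (promoted to a
#'   single-channel single-slice stack). Intensities must be non-negative.
#' @param channel_names character vector of unique channel labels.
#' @param pixel_pitch_um physical size of one pixel in x and y (µm).
#' @param z_step_um spacing between optical slices (µm).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, channel_names, pixel_pitch_um, z_step_um = 0.3) {
  if (is.matrix(data)) data <- array(data, c(1L, 1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (length(channel_names) != dim(data)[1])
    stop("channel_names must match the number of channels")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!is.numeric(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("pixel_pitch_um must be > 0")
  if (min(data) < 0) stop("intensities must be non-negative")
  structure(
    list(data = data, channel_names = as.character(channel_names),
         pixel_pitch_um = pixel_pitch_um, z_step_um = z_step_um),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d channel(s) [%s], %d slice(s), %d x %d px, pitch %g um\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
              x$pixel_pitch_um))
  invisible(x)
}

#' Extract one channel of a stack
#'
#' @param stack an `image_stack`.
#' @param channel channel label or index.
#' @param drop if `TRUE` (default) a single-slice channel is returned as a
#'   matrix, otherwise as a `(z, y, x)` array.
#' @return numeric matrix `(y, x)` or array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel, drop = TRUE) {
  ci <- channel_index(stack, channel)
  arr <- stack$data[ci, , , , drop = FALSE]
  dim(arr) <- dim(stack$data)[2:4]
  if (drop && dim(arr)[1] == 1L) {
    m <- arr[1, , ]
    dim(m) <- dim(arr)[2:3]
    return(m)
  }
  arr
}

channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    if (channel < 1 || channel > length(stack$channel_names))
      stop("channel index out of range")
    return(as.integer(channel))
  }
  ci <- match(channel, stack$channel_names)
  if (is.na(ci)) stop("unknown channel: ", channel)
  ci
}

#' Write an image stack to a multi-page 16-bit TIFF
#'
#' Pages are ordered channel-major (all slices of channel 1, then channel 2,
#' ...). Intensities must be integers in `[0, 65535]`; the generators in this
#' package emit integer photon-count-like values, so write/read round-trips
#' are bit-exact. Calibration and channel names are stored in a sidecar
#' `.json`-free plain-text header file `<path>.meta`.
#'
#' @param stack an `image_stack` with integer-valued data in `[0, 65535]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$data)
  if (max(stack$data) > 65535 || any(stack$data != round(stack$data)))
    stop("write_stack_tiff requires integer intensities in [0, 65535]")
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ci in seq_len(d[1])) for (zi in seq_len(d[2])) {
    m <- stack$data[ci, zi, , ]
    dim(m) <- d[3:4]
    pages[[k]] <- m / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(paste0("channels=", paste(stack$channel_names, collapse = ",")),
            paste0("n_z=", d[2]),
            paste0("pixel_pitch_um=", format(stack$pixel_pitch_um, digits = 17)),
            paste0("z_step_um=", format(stack$z_step_um, digits = 17)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF file path (its `.meta` sidecar must be present).
#' @return an `image_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta <- readLines(paste0(path, ".meta"))
  val <- function(key) sub(paste0("^", key, "="), "",
                           grep(paste0("^", key, "="), meta, value = TRUE)[1])
  channels <- strsplit(val("channels"), ",")[[1]]
  nz <- as.integer(val("n_z"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nchan <- length(pages) / nz
  dyx <- dim(pages[[1]])
  data <- array(0, c(nchan, nz, dyx[1], dyx[2]))
  k <- 1L
  for (ci in seq_len(nchan)) for (zi in seq_len(nz)) {
    data[ci, zi, , ] <- round(pages[[k]] * 65535)
    k <- k + 1L
  }
  image_stack(data, channels, as.numeric(val("pixel_pitch_um")),
              as.numeric(val("z_step_um")))
}
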