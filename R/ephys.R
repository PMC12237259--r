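#' Construct an electrophysiology trace
#'
#' Uniformly sampled sweep with stimulus-onset annotations. Sign convention:
#' inward currents are negative, potentials positive.
#'
#' @param signal numeric amplitude series (nA or mV).
#' @param sampling_hz sampling rate (Hz).
#' @param stim_times_s stimulus onset times (s), strictly increasing and
#'   within the record.
#' @param modality `"current"` or `"potential"`.
#' @return object of class `trace`.
#' @export
trace <- function(signal, sampling_hz, stim_times_s = numeric(0),
                  modality = c("current", "potential")) {
  modality <- match.arg(modality)
  stopifnot(sampling_hz > 0)
  if (length(stim_times_s)) {
    if (is.unsorted(stim_times_s, strictly = TRUE))
      stop("stim_times_s must be strictly increasing")
    if (max(stim_times_s) > length(signal) / sampling_hz)
      stop("stimulus times outside the record")
  }
  structure(list(signal = as.numeric(signal), sampling_hz = sampling_hz,
                 stim_times_s = stim_times_s, modality = modality),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s, %.3f s @ %g Hz, %d stimuli\n", x$modality,
              length(x$signal) / x$sampling_hz, x$sampling_hz,
              length(x$stim_times_s)))
  invisible(x)
}

#' Write / read a trace as two-column text
#'
#' Plain text: comment header lines (`# key=value` for sampling rate,
#' modality, stimulus times) followed by `time_s value` rows.
#'
#' @param tr a [trace()].
#' @param path file path.
#' @return `path` invisibly (write) or a `trace` (read).
#' @export
write_trace_txt <- function(tr, path) {
  hdr <- c(paste0("# sampling_hz=", format(tr$sampling_hz, digits = 17)),
           paste0("# modality=", tr$modality),
           paste0("# stim_times_s=",
                  paste(format(tr$stim_times_s, digits = 17), collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.10g %.10g",
                     (seq_along(tr$signal) - 1) / tr$sampling_hz, tr$signal),
             con)
  invisible(path)
}

#' @rdname write_trace_txt
#' @export
read_trace_txt <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(paste0("^# ", key, "="), "",
                            grep(paste0("^# ", key, "="), hdr, value = TRUE)[1])
  st <- getv("stim_times_s")
  st <- if (nchar(st)) as.numeric(strsplit(st, ",")[[1]]) else numeric(0)
  body <- lines[!grepl("^#", lines)]
  vals <- as.numeric(vapply(strsplit(body, " "), `[`, "", 2))
  trace(vals, as.numeric(getv("sampling_hz")), st, getv("modality"))
}

#' Gaussian low-pass filter
#'
#' Zero-phase convolution with a Gaussian kernel whose transfer function
#' satisfies `|H(fc)| = 1/2` (so a sine at the corner frequency is halved);
#' this fixes the time-domain sd at `sqrt(ln 2 / 2) / (pi * fc)`.
#'
#' @param tr a [trace()].
#' @param fc_hz corner frequency (default 500 Hz); must be below Nyquist.
#' @return a filtered `trace`.
#' @export
gaussian_lowpass <- function(tr, fc_hz = 500) {
  if (fc_hz >= tr$sampling_hz / 2) stop("fc must be below Nyquist")
  sigma_s <- sqrt(log(2) / 2) / (pi * fc_hz)
  sigma <- sigma_s * tr$sampling_hz
  half <- ceiling(4 * sigma)
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  x <- tr$signal
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- convolve(xp, k, type = "filter")
  out <- tr
  out$signal <- y
  out
}

# sliding-window sums via cumulative sums; returns sums of every length-N
# window, aligned to window start
roll_sum <- function(x, N) {
  cs <- cumsum(c(0, x))
  cs[(N + 1):length(cs)] - cs[1:(length(cs) - N)]
}

#' Scaled-template miniature-event detection
#'
#' Clements-Bekkers sliding template matching: at every offset the template
#' is optimally scaled and offset (least squares); the detection criterion
#' is the fitted scale divided by its standard error, and events are
#' criterion peaks above `criterion_threshold`, deduplicated within a
#' refractory window. The template sign must match the event sign (negative
#' for currents).
#'
#' The criterion calibration assumes residuals that are uncorrelated at the
#' sampling rate. After low-pass filtering (the 500-Hz Gaussian filter
#' applied to miniature recordings) the noise is band-limited, which
#' inflates the criterion; in that case detect on a decimated copy via
#' `decimate` (e.g. 8 at 10 kHz after a 500-Hz filter, so the residuals are
#' approximately white at the detection rate). Event times are always
#' reported on the original time base.
#'
#' @param tr a [trace()].
#' @param template numeric event waveform sampled at the trace rate (e.g. a
#'   unit-peak kernel times the expected signed amplitude); shorter than the
#'   trace.
#' @param criterion_threshold detection threshold (default 3.5).
#' @param refractory_s minimum event spacing (s).
#' @param decimate integer subsampling factor for the matching step.
#' @return data.frame `time_s`, `amplitude` (signed), `detection_score`.
#' @export
detect_minis <- function(tr, template, criterion_threshold = 3.5,
                         refractory_s = 0.005, decimate = 1L) {
  decimate <- max(1L, as.integer(decimate))
  x <- tr$signal
  if (decimate > 1L) {
    x <- x[seq(1L, length(x), by = decimate)]
    template <- template[seq(1L, length(template), by = decimate)]
  }
  fs_det <- tr$sampling_hz / decimate
  N <- length(template)
  if (N >= length(x)) stop("template must be shorter than the trace")
  St <- sum(template)
  Stt <- sum(template^2)
  den_t <- Stt - St^2 / N
  if (den_t <= 0) stop("degenerate template")
  Sy <- roll_sum(x, N)
  Syy <- roll_sum(x^2, N)
  Sty <- convolve(x, template, conj = TRUE, type = "filter") # sum t_i * y_(o+i)
  M <- length(Sy)
  Sty <- Sty[seq_len(M)]
  scale <- (Sty - St * Sy / N) / den_t
  offset <- (Sy - scale * St) / N
  sse <- Syy + scale^2 * Stt + N * offset^2 -
    2 * (scale * Sty + offset * Sy - scale * offset * St)
  sse[sse < 0] <- 0
  # fitting-error SE: residual standard deviation of the optimal fit. The
  # criterion therefore reads "fitted event = so-many times the residual
  # noise", which is why the template must carry a realistic amplitude.
  se <- sqrt(sse / (N - 1))
  crit <- scale / pmax(se, .Machine$double.eps)
  # one-sided: only template-sign events; numerical guard against exact-zero
  # residual windows on noiseless traces
  crit[scale < sqrt(.Machine$double.eps)] <- 0
  # one event per contiguous above-threshold excursion, at its criterion
  # peak (events closer than the template window fuse into one excursion and
  # are reported once -- a documented limitation of single-template matching)
  above <- crit > criterion_threshold
  if (!any(above))
    return(data.frame(time_s = numeric(0), amplitude = numeric(0),
                      detection_score = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- which(r$values)
  peaks <- vapply(segs, function(s) {
    ii <- starts[s]:ends[s]
    ii[which.max(crit[ii])]
  }, integer(1))
  # merge peaks closer than the refractory window, keeping the higher score
  refr <- max(1L, round(refractory_s * fs_det))
  ord <- peaks[order(crit[peaks], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || min(abs(taken - i)) > refr) taken <- c(taken, i)
  }
  taken <- sort(taken)
  peak_mag <- max(abs(template))
  sgn <- sign(template[which.max(abs(template))])
  data.frame(time_s = (taken - 1) / fs_det,
             amplitude = sgn * scale[taken] * peak_mag,
             detection_score = crit[taken])
}

#' Average detected events into a mean mini trace
#'
#' Events are cut out in a fixed window, baseline-subtracted (mean over the
#' pre-event samples) and averaged; the amplitude is the signed extremum of
#' the mean trace.
#'
#' @param tr a [trace()].
#' @param events data.frame with `time_s` (from [detect_minis()] or truth).
#' @param pre_s,post_s window before/after each event time (s).
#' @return list `mean_trace` (numeric, baseline at 0), `amplitude` (signed),
#'   `n_events`, `sampling_hz`.
#' @export
average_events <- function(tr, events, pre_s = 0.005, post_s = 0.04) {
  if (nrow(events) < 1) stop("no events to average")
  fs <- tr$sampling_hz
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  idx <- round(events$time_s * fs) + 1L
  keep <- idx - npre >= 1 & idx + npost <= length(tr$signal)
  idx <- idx[keep]
  if (!length(idx)) stop("no events fully inside the record")
  wins <- vapply(idx, function(i) {
    w <- tr$signal[(i - npre):(i + npost)]
    w - mean(w[seq_len(npre)])
  }, numeric(npre + npost + 1))
  avg <- rowMeans(wins)
  ext <- if (tr$modality == "current") min(avg) else max(avg)
  list(mean_trace = avg, amplitude = ext, n_events = length(idx),
       sampling_hz = fs)
}

# replace artifact samples following each aligned stimulus by linear
# interpolation between the bounding samples
excise_artifact <- function(w, at_idx, n_art) {
  i0 <- at_idx - 1L
  i1 <- at_idx + n_art
  if (i0 >= 1 && i1 <= length(w)) {
    ii <- (i0 + 1L):(i1 - 1L)
    w[ii] <- w[i0] + (w[i1] - w[i0]) * (ii - i0) / (i1 - i0)
  }
  w
}

#' Stimulus-aligned average of evoked responses
#'
#' Cuts one sweep per stimulus, subtracts a per-sweep baseline (mean over a
#' pre-stimulus window), excises the stimulus artifact (replaced by linear
#' interpolation over a configurable window) and averages the first `n`
#' sweeps.
#'
#' @param tr a [trace()] with stimulus annotations.
#' @param n number of sweeps to average (20 for 0.2-Hz and 10-ms paired
#'   pulse; 10 for 30-ms paired pulse). If fewer are present, all are used.
#' @param pre_s baseline window before each stimulus (s).
#' @param post_s sweep length after the stimulus (s).
#' @param artifact_s artifact-excision window after each onset (default
#'   1 ms).
#' @return list `mean_trace`, `sampling_hz`, `stim_index` (sample index of
#'   the stimulus within the sweep), `n_used`.
#' @export
average_evoked <- function(tr, n = 20, pre_s = 0.01, post_s = 0.06,
                           artifact_s = 0.001) {
  if (!length(tr$stim_times_s)) stop("trace carries no stimuli")
  fs <- tr$sampling_hz
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  n_art <- max(1L, round(artifact_s * fs))
  stims <- head(tr$stim_times_s, n)
  wins <- list()
  for (st in stims) {
    i <- round(st * fs) + 1L
    if (i - npre < 1 || i + npost > length(tr$signal)) next
    w <- tr$signal[(i - npre):(i + npost)]
    w <- w - mean(w[seq_len(npre)])
    w <- excise_artifact(w, npre + 1L, n_art)
    wins[[length(wins) + 1L]] <- w
  }
  if (!length(wins)) stop("no complete sweeps")
  avg <- Reduce(`+`, wins) / length(wins)
  list(mean_trace = avg, sampling_hz = fs, stim_index = npre + 1L,
       n_used = length(wins))
}

# linear-interpolated index (1-based, fractional) where y crosses level,
# searching the segment idx
cross_idx <- function(y, level, idx, first = TRUE) {
  s <- y[idx] - level
  ch <- which(s[-1] * s[-length(s)] <= 0 & s[-1] != s[-length(s)])
  if (!length(ch)) return(NA_real_)
  j <- if (first) ch[1] else ch[length(ch)]
  i0 <- idx[j]
  frac <- (level - y[i0]) / (y[i0 + 1] - y[i0])
  i0 + frac
}

#' 10-90% rise time of a mean evoked trace
#'
#' Time between the last 10%-of-peak crossing and the first 90% crossing on
#' the rising phase before the peak, linearly interpolated between samples.
#'
#' @param mean_trace numeric baseline-subtracted trace (list from
#'   [average_evoked()] or a bare numeric vector).
#' @param sampling_hz sampling rate (taken from the list if present).
#' @return rise time in ms.
#' @export
rise_time <- function(mean_trace, sampling_hz = NULL) {
  y <- if (is.list(mean_trace)) mean_trace$mean_trace else mean_trace
  fs <- if (is.list(mean_trace)) mean_trace$sampling_hz else sampling_hz
  m <- abs(y)
  pk <- which.max(m)
  amp <- m[pk]
  idx <- 1:pk
  i10 <- cross_idx(m, 0.10 * amp, idx, first = FALSE)
  i90 <- cross_idx(m, 0.90 * amp, idx, first = TRUE)
  if (is.na(i10) || is.na(i90)) stop("rise-phase crossings not found")
  # first 90% crossing before the peak but after the chosen 10% crossing
  if (i90 < i10) {
    i90 <- cross_idx(m, 0.90 * amp, ceiling(i10):pk, first = TRUE)
  }
  (i90 - i10) / fs * 1000
}

#' Exponential decay time constant of a mean evoked trace
#'
#' Fits `A * exp(-t / tau)` (nonlinear least squares on the magnitude trace,
#' log-linear start values) to the segment between the 60% and 5% of-peak
#' crossings after the peak.
#'
#' @inheritParams rise_time
#' @return decay tau in ms.
#' @export
decay_tau <- function(mean_trace, sampling_hz = NULL) {
  y <- if (is.list(mean_trace)) mean_trace$mean_trace else mean_trace
  fs <- if (is.list(mean_trace)) mean_trace$sampling_hz else sampling_hz
  m <- abs(y)
  pk <- which.max(m)
  amp <- m[pk]
  idx <- pk:length(m)
  i60 <- cross_idx(m, 0.60 * amp, idx, first = TRUE)
  i05 <- cross_idx(m, 0.05 * amp, idx, first = TRUE)
  if (is.na(i60)) stop("decay segment not found")
  if (is.na(i05)) i05 <- length(m)
  seg <- ceiling(i60):floor(i05)
  if (length(seg) < 5) stop("decay segment too short")
  tt <- (seg - pk) / fs * 1000
  yy <- m[seg]
  pos <- yy > 0
  fit0 <- lm(log(yy[pos]) ~ tt[pos])
  tau0 <- unname(-1 / coef(fit0)[2])
  A0 <- unname(exp(coef(fit0)[1]))
  fit <- try(minpack.lm::nlsLM(yy ~ A * exp(-tt / tau),
                               start = list(A = A0, tau = tau0)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(unname(tau0))
  unname(coef(fit)[["tau"]])
}

#' Charge transfer of a mean evoked trace
#'
#' Trapezoidal time-integral of the baseline-subtracted response, reported
#' in pC for current traces (nA x ms = pC).
#'
#' @inheritParams rise_time
#' @return signed charge in pC.
#' @export
charge <- function(mean_trace, sampling_hz = NULL) {
  y <- if (is.list(mean_trace)) mean_trace$mean_trace else mean_trace
  fs <- if (is.list(mean_trace)) mean_trace$sampling_hz else sampling_hz
  dt_ms <- 1000 / fs
  sum((y[-1] + y[-length(y)]) / 2) * dt_ms
}

#' Quantal content
#'
#' Evoked amplitude divided by the mean miniature amplitude of the same
#' cell (magnitudes; both must share the modality).
#'
#' @param evoked_amp signed evoked amplitude.
#' @param mean_mini_amp signed mean mini amplitude; must be non-zero.
#' @return estimated number of quanta per stimulus.
#' @export
quantal_content <- function(evoked_amp, mean_mini_amp) {
  if (mean_mini_amp == 0) stop("mini amplitude must be non-zero")
  abs(evoked_amp) / abs(mean_mini_amp)
}

# amplitude of response i: extremum within (onset + artifact, next onset]
# relative to the last sample before the artifact onset
train_amplitudes <- function(tr, artifact_s = 0.001, resp_s = NULL) {
  fs <- tr$sampling_hz
  st <- tr$stim_times_s
  n_art <- max(1L, round(artifact_s * fs))
  isi <- if (length(st) > 1) min(diff(st)) else 0.05
  win <- if (is.null(resp_s)) isi else resp_s
  amps <- numeric(length(st))
  base <- numeric(length(st))
  for (i in seq_along(st)) {
    at <- round(st[i] * fs) + 1L
    b <- tr$signal[at - 1L]
    lo <- at + n_art
    hi <- min(length(tr$signal), at + round(win * fs))
    seg <- tr$signal[lo:hi]
    ext <- if (tr$modality == "current") min(seg) else max(seg)
    amps[i] <- ext - b
    base[i] <- b
  }
  list(amplitudes = amps, baselines = base)
}

#' Paired-pulse ratio
#'
#' A2/A1 from a two-stimulus mean sweep: the first amplitude is measured
#' from the sweep baseline, the second from the last point before the second
#' stimulation artifact onset.
#'
#' @param tr a [trace()] with exactly 2 stimuli (a mean sweep works too if
#'   wrapped as a trace with its stimulus times).
#' @param artifact_s artifact window after each onset (s).
#' @return ratio A2 / A1.
#' @export
paired_pulse_ratio <- function(tr, artifact_s = 0.001) {
  if (length(tr$stim_times_s) != 2) stop("paired pulse requires exactly 2 stimuli")
  fs <- tr$sampling_hz
  st <- tr$stim_times_s
  n_art <- max(1L, round(artifact_s * fs))
  if (diff(st) <= artifact_s) stop("overlapping artifact windows")
  i1 <- round(st[1] * fs) + 1L
  i2 <- round(st[2] * fs) + 1L
  pre <- tr$signal[max(1, i1 - round(0.005 * fs)):(i1 - 1L)]
  b1 <- mean(pre)
  seg1 <- tr$signal[(i1 + n_art):(i2 - 1L)]
  a1 <- (if (tr$modality == "current") min(seg1) else max(seg1)) - b1
  b2 <- tr$signal[i2 - 1L]
  hi <- min(length(tr$signal), i2 + round(0.05 * fs))
  seg2 <- tr$signal[(i2 + n_art):hi]
  a2 <- (if (tr$modality == "current") min(seg2) else max(seg2)) - b2
  a2 / a1
}

#' Readily-releasable-pool estimate by cumulative back-extrapolation
#'
#' Per-stimulus amplitudes of a 100-Hz / 61-stimulation train are extracted
#' with the pre-artifact-baseline rule, converted to quanta with the cell's
#' mean mini amplitude, summed cumulatively, and an ordinary least-squares
#' line is fitted to the last 20 cumulative points. Its y-intercept is the
#' RRP size (quanta) and its slope the refilling rate (quanta/stimulus).
#'
#' @param tr a [trace()] train recording with stimulus annotations.
#' @param mean_mini_amp signed mean mini amplitude of the same cell.
#' @param fit_last number of final stimuli in the fit window (default 20).
#' @param artifact_s artifact window (s).
#' @return object of class `rrp_estimate`: `rrp_quanta`,
#'   `refill_quanta_per_stim`, `fit_window`, `r_squared`,
#'   `cumulative_quanta`.
#' @export
estimate_rrp <- function(tr, mean_mini_amp, fit_last = 20,
                         artifact_s = 0.001) {
  st <- tr$stim_times_s
  if (length(st) < fit_last + 1) stop("too few resolvable responses")
  qa <- train_amplitudes(tr, artifact_s)
  quanta <- abs(qa$amplitudes) / abs(mean_mini_amp)
  # all-zero responses give a flat zero line
  cum <- cumsum(quanta)
  i <- seq_along(cum)
  w <- (length(cum) - fit_last + 1):length(cum)
  fit <- lm(cum[w] ~ i[w])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((cum[w] - mean(cum[w]))^2)
  structure(list(rrp_quanta = unname(coef(fit)[1]),
                 refill_quanta_per_stim = unname(coef(fit)[2]),
                 fit_window = range(w),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 cumulative_quanta = cum),
            class = "rrp_estimate")
}

#' Normalize measurements within genotype for homeostatic-plasticity assays
#'
#' Each genotype's treated (+PhTx) and untreated (-PhTx) values are divided
#' by that genotype's own untreated mean, so every untreated group mean maps
#' to 1.00 exactly; genotypes never share reference values.
#'
#' @param values numeric measurements.
#' @param genotype factor/character genotype of each value.
#' @param treated logical, `TRUE` for +PhTx values.
#' @return numeric vector of normalized values.
#' @export
php_normalize <- function(values, genotype, treated) {
  stopifnot(length(values) == length(genotype), length(values) == length(treated))
  out <- numeric(length(values))
  for (g in unique(genotype)) {
    sel <- genotype == g
    ref <- mean(values[sel & !treated])
    if (!is.finite(ref) || ref == 0) stop("zero or empty reference group for ", g)
    out[sel] <- values[sel] / ref
  }
  out
}
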