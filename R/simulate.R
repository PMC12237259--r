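#' Parameters for the synthetic NMJ stack generator
#'
#' Defaults emulate a type-1b NMJ on muscle 4 imaged on a confocal at
#' 100-nm pixel pitch with 0.25-µm z-steps: a chain of boutons inside an
#' HRP membrane envelope, diffraction-limited puncta (PSF sd 0.15 µm) inside
#' the envelope and muscle-borne distractor puncta outside it.
#'
#' @param n_boutons number of boutons along the chain.
#' @param bouton_radius_um bouton radius (µm).
#' @param skeleton_length_um end-to-end length of the bouton chain (µm).
#' @param n_spots number of in-envelope puncta.
#' @param spot_sigma_um PSF standard deviation of one punctum (µm).
#' @param spot_peak peak intensity of one punctum (arbitrary counts).
#' @param spot_min_separation_um minimal center-to-center distance between
#'   in-envelope puncta; default 6 spot sigmas (well-separated regime).
#' @param muscle_spot_density distractor puncta per µm² outside the envelope.
#' @param hrp_peak plateau intensity of the membrane envelope channel.
#' @param noise_gaussian_sd additive Gaussian read-noise sd (counts).
#' @param noise_poisson logical; apply Poisson shot noise to the signal.
#' @param pixel_pitch_um pixel pitch (µm).
#' @param z_slices number of optical slices.
#' @param z_step_um z spacing (µm).
#' @param frame_px frame side length in pixels (square frame).
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return a list of validated parameters, class `nmj_sim_params`.
#' @export
nmj_sim_params <- function(n_boutons = 6, bouton_radius_um = 2,
                           skeleton_length_um = 20, n_spots = 50,
                           spot_sigma_um = 0.15, spot_peak = 600,
                           spot_min_separation_um = 6 * spot_sigma_um,
                           muscle_spot_density = 0.05, hrp_peak = 200,
                           noise_gaussian_sd = 2, noise_poisson = FALSE,
                           pixel_pitch_um = 0.1, z_slices = 5,
                           z_step_um = 0.25, frame_px = 288, seed = 1) {
  p <- as.list(environment())
  stopifnot(p$bouton_radius_um > 0, p$skeleton_length_um > 0,
            p$spot_sigma_um > 0, p$pixel_pitch_um > 0, p$n_spots >= 0,
            p$z_slices >= 1, p$frame_px >= 8)
  class(p) <- "nmj_sim_params"
  p
}

# additive gaussian spot rendered into img (matrix), center (y, x) in px
render_gaussian <- function(img, cy, cx, sigma_px, peak) {
  half <- ceiling(4 * sigma_px)
  ys <- max(1, round(cy) - half):min(nrow(img), round(cy) + half)
  xs <- max(1, round(cx) - half):min(ncol(img), round(cx) + half)
  g <- peak * exp(-(outer((ys - cy)^2, (xs - cx)^2, "+")) / (2 * sigma_px^2))
  img[ys, xs] <- img[ys, xs] + g
  img
}

#' Generate a synthetic NMJ z-stack with ground truth
#'
#' Produces a two-channel stack: an `"HRP"` membrane-envelope channel (a
#' smooth bouton chain, constant across z) and a `"spots"` punctum channel
#' with Gaussian puncta at known positions inside the envelope plus
#' distractor puncta outside it ("muscle" signal). Each punctum lives on one
#' z-slice with a Gaussian z-profile over neighboring slices. Intensities
#' are rounded to integer counts so TIFF round-trips are exact.
#'
#' @param params an [nmj_sim_params()] object.
#' @return list with `stack` (an `image_stack`) and `truth`: spot centroids
#'   (y, x in px, 1-based), spot z-slices, analytic half-max areas (µm²),
#'   total intensities, the envelope mask, muscle-spot centroids, and the
#'   parameter set.
#' @export
make_nmj_stack <- function(params) {
  stopifnot(inherits(params, "nmj_sim_params"))
  p <- params
  with_seed(p$seed, {
    pitch <- p$pixel_pitch_um
    n <- p$frame_px
    sigma_px <- p$spot_sigma_um / pitch
    r_px <- p$bouton_radius_um / pitch
    len_px <- p$skeleton_length_um / pitch
    margin <- r_px + 6 * sigma_px + 2
    if (len_px + 2 * margin > n)
      stop("NMJ geometry does not fit in the requested frame")
    # bouton chain along a gentle sine arc through the frame center
    t <- seq(0, 1, length.out = p$n_boutons)
    bx <- n / 2 + (t - 0.5) * len_px
    by <- n / 2 + 0.15 * len_px * sin(2 * pi * t)
    if (any(by < margin | by > n - margin))
      stop("NMJ geometry does not fit in the requested frame")
    yy <- matrix(seq_len(n), n, n)
    xx <- matrix(seq_len(n), n, n, byrow = TRUE)
    env <- matrix(FALSE, n, n)
    for (i in seq_len(p$n_boutons))
      env <- env | ((yy - by[i])^2 + (xx - bx[i])^2 <= r_px^2)
    # connect consecutive boutons with a tube of half the bouton radius
    for (i in seq_len(p$n_boutons - 1L)) {
      for (s in seq(0, 1, length.out = 8)) {
        cy <- by[i] + s * (by[i + 1] - by[i])
        cx <- bx[i] + s * (bx[i + 1] - bx[i])
        env <- env | ((yy - cy)^2 + (xx - cx)^2 <= (r_px / 2)^2)
      }
    }
    hrp2d <- round(p$hrp_peak * smooth_gauss(env * 1, 2))
    # in-envelope spot placement: rejection sampling with minimum separation,
    # kept clear of the envelope boundary so segmented blobs stay inside
    sep_px <- p$spot_min_separation_um / pitch
    interior <- smooth_gauss(env * 1, 2) > 0.9
    inner <- interior & yy > margin & yy < n - margin &
      xx > margin & xx < n - margin
    cand <- which(inner)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < p$n_spots) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place the requested spots at the requested separation")
      idx <- cand[sample.int(length(cand), 1L)]
      cyx <- c((idx - 1L) %% n + 1L, (idx - 1L) %/% n + 1L)
      jit <- runif(2, -0.5, 0.5)
      cyx <- cyx + jit
      if (nrow(centers) > 0 &&
          min(sqrt((centers[, 1] - cyx[1])^2 + (centers[, 2] - cyx[2])^2)) < sep_px)
        next
      centers <- rbind(centers, cyx)
    }
    # muscle distractors outside a dilated envelope
    out_area_um2 <- sum(!env) * pitch^2
    n_muscle <- rpois(1, p$muscle_spot_density * out_area_um2)
    keep_away <- smooth_gauss(env * 1, 3) > 0.01
    out_cand <- which(!keep_away & yy > margin & yy < n - margin &
                        xx > margin & xx < n - margin)
    muscle <- matrix(numeric(0), 0, 2)
    if (n_muscle > 0 && length(out_cand) > 0) {
      idx <- out_cand[sample.int(length(out_cand), min(n_muscle, length(out_cand)))]
      muscle <- cbind((idx - 1L) %% n + 1L, (idx - 1L) %/% n + 1L) +
        matrix(runif(2 * length(idx), -0.5, 0.5), ncol = 2)
    }
    # render: each spot on a home slice with gaussian z-profile (sd 0.8 slice)
    nz <- p$z_slices
    spots_z <- if (p$n_spots > 0) sample.int(nz, p$n_spots, replace = TRUE) else integer(0)
    muscle_z <- if (nrow(muscle) > 0) sample.int(nz, nrow(muscle), replace = TRUE) else integer(0)
    data <- array(0, c(2, nz, n, n))
    for (zi in seq_len(nz)) data[1, zi, , ] <- hrp2d
    zsd <- 0.8
    for (zi in seq_len(nz)) {
      sl <- matrix(0, n, n)
      for (s in seq_len(p$n_spots)) {
        w <- exp(-(zi - spots_z[s])^2 / (2 * zsd^2))
        if (w > 0.02)
          sl <- render_gaussian(sl, centers[s, 1], centers[s, 2], sigma_px,
                                p$spot_peak * w)
      }
      for (s in seq_len(nrow(muscle))) {
        w <- exp(-(zi - muscle_z[s])^2 / (2 * zsd^2))
        if (w > 0.02)
          sl <- render_gaussian(sl, muscle[s, 1], muscle[s, 2], sigma_px,
                                p$spot_peak * w)
      }
      data[2, zi, , ] <- sl
    }
    if (p$noise_poisson) {
      data[] <- rpois(length(data), as.vector(data))
    }
    if (p$noise_gaussian_sd > 0) {
      data[] <- data + rnorm(length(data), 0, p$noise_gaussian_sd)
    }
    data <- round(pmin(pmax(data, 0), 65535))
    stack <- image_stack(data, c("HRP", "spots"), pitch, p$z_step_um)
    # analytic area above half-peak: pi * (sigma*sqrt(2 ln 2))^2
    a_half <- pi * (p$spot_sigma_um * sqrt(2 * log(2)))^2
    truth <- list(
      spot_centroids = centers, spot_z = spots_z,
      spot_areas_um2 = rep(a_half, p$n_spots),
      spot_total_intensity = rep(2 * pi * sigma_px^2 * p$spot_peak, p$n_spots),
      envelope_mask = env, muscle_centroids = muscle,
      model_params = p)
    list(stack = stack, truth = truth)
  })
}

# separable gaussian blur with reflecting edges (small helper, not exported)
smooth_gauss <- function(m, sigma_px) {
  half <- ceiling(3 * sigma_px)
  k <- exp(-(-half:half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  pad <- function(x, n) x[c(pmin(pmax(seq_len(nrow(x) + 2 * n) - n, 1), nrow(x))), , drop = FALSE]
  conv1 <- function(x) {
    xp <- pad(x, half)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Generate a synthetic STED frame of annular AZ scaffolds with partner dots
#'
#' Each active zone (AZ) is an annulus ("BRP" channel, the C-terminal ring)
#' placed on a grid of 53 x 53-px regions of interest; the partner channel
#' carries point clusters at known offsets from each ring center. Truth
#' stores exact subpixel centers and offsets.
#'
#' @param ring_radius_nm annulus radius (nm).
#' @param n_azs number of AZs.
#' @param dots_per_az partner dots per AZ (ignored when `dot_offsets_nm`
#'   given).
#' @param dot_offsets_nm either `NULL` (random offsets within 450 nm), a
#'   2-column matrix of (dy, dx) offsets in nm applied to every AZ, or a
#'   list of such matrices (one per AZ).
#' @param pixel_pitch_nm pixel pitch (nm), default 20 (53 px = 1.06 µm).
#' @param ring_peak,dot_peak peak intensities (counts).
#' @param ring_width_nm Gaussian cross-sectional sd of the annulus (nm).
#' @param dot_sigma_nm Gaussian sd of a partner dot (nm).
#' @param roi_px ROI side length in pixels.
#' @param noise_gaussian_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return list with `frame` (2-channel `image_stack`, channels "BRP" and
#'   "partner") and `truth` (per-AZ ROI origins, exact centers, offsets in nm
#'   and px, overlap flag).
#' @export
make_sted_frame <- function(ring_radius_nm = 120, n_azs = 9, dots_per_az = 3,
                            dot_offsets_nm = NULL, pixel_pitch_nm = 20,
                            ring_peak = 800, dot_peak = 600,
                            ring_width_nm = 40, dot_sigma_nm = 30,
                            roi_px = 53, noise_gaussian_sd = 0, seed = 1) {
  stopifnot(ring_radius_nm > 0, n_azs >= 1)
  pitch <- pixel_pitch_nm
  if (2 * (ring_radius_nm + 3 * ring_width_nm) > roi_px * pitch)
    stop("ring does not fit inside the ROI at this pitch")
  with_seed(seed, {
    ncols <- ceiling(sqrt(n_azs))
    nrows <- ceiling(n_azs / ncols)
    gap <- 4L
    cell <- roi_px + gap
    H <- nrows * cell + gap
    W <- ncols * cell + gap
    brp <- matrix(0, H, W)
    par <- matrix(0, H, W)
    offs_list <- vector("list", n_azs)
    centers <- matrix(0, n_azs, 2)
    origins <- matrix(0L, n_azs, 2)
    for (a in seq_len(n_azs)) {
      gr <- (a - 1L) %/% ncols
      gc <- (a - 1L) %% ncols
      oy <- gap + gr * cell + 1L        # ROI origin (1-based)
      ox <- gap + gc * cell + 1L
      cy <- oy + (roi_px - 1) / 2 + runif(1, -1, 1)
      cx <- ox + (roi_px - 1) / 2 + runif(1, -1, 1)
      offs <- if (is.null(dot_offsets_nm)) {
        th <- runif(dots_per_az, 0, 2 * pi)
        rr <- runif(dots_per_az, 0, 450)
        cbind(rr * sin(th), rr * cos(th))
      } else if (is.list(dot_offsets_nm)) {
        as.matrix(dot_offsets_nm[[a]])
      } else as.matrix(dot_offsets_nm)
      # annulus: peak * exp(-(dist - R)^2 / 2w^2)
      half <- ceiling((ring_radius_nm + 4 * ring_width_nm) / pitch)
      ys <- (round(cy) - half):(round(cy) + half)
      xs <- (round(cx) - half):(round(cx) + half)
      d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+")) * pitch
      brp[ys, xs] <- brp[ys, xs] +
        ring_peak * exp(-(d - ring_radius_nm)^2 / (2 * ring_width_nm^2))
      for (j in seq_len(nrow(offs)))
        par <- render_gaussian(par, cy + offs[j, 1] / pitch,
                               cx + offs[j, 2] / pitch,
                               dot_sigma_nm / pitch, dot_peak)
      offs_list[[a]] <- offs
      centers[a, ] <- c(cy, cx)
      origins[a, ] <- c(oy, ox)
    }
    if (noise_gaussian_sd > 0) {
      brp <- brp + rnorm(length(brp), 0, noise_gaussian_sd)
      par <- par + rnorm(length(par), 0, noise_gaussian_sd)
    }
    data <- array(0, c(2, 1, H, W))
    data[1, 1, , ] <- round(pmin(pmax(brp, 0), 65535))
    data[2, 1, , ] <- round(pmin(pmax(par, 0), 65535))
    frame <- image_stack(data, c("BRP", "partner"), pitch / 1000, 0.1)
    truth <- list(roi_origins = origins, centers = centers,
                  dot_offsets_nm = offs_list,
                  dot_distances_nm = lapply(offs_list, function(o)
                    sort(sqrt(o[, 1]^2 + o[, 2]^2))),
                  overlap_warning = FALSE,
                  pixel_pitch_nm = pitch, roi_px = roi_px)
    list(frame = frame, truth = truth)
  })
}

#' Generate a correlated two-channel image pair
#'
#' Draws pixel pairs from a bivariate normal with a target population
#' correlation, clipped at zero (means are set high enough that clipping is
#' negligible at the defaults).
#'
#' @param rho_target population correlation in `[-1, 1]`.
#' @param n_px number of pixels (reshaped to a near-square image).
#' @param mean_intensity,sd_intensity marginal mean and sd of each channel.
#' @param seed RNG seed.
#' @return list with `frame` (2-channel single-slice `image_stack`, channels
#'   "ch1"/"ch2") and `truth` (`rho_target`, realized sample `r`).
#' @export
make_coloc_pair <- function(rho_target, n_px = 1e4, mean_intensity = 120,
                            sd_intensity = 20, seed = 1) {
  stopifnot(rho_target >= -1, rho_target <= 1)
  with_seed(seed, {
    w <- floor(sqrt(n_px))
    h <- ceiling(n_px / w)
    m <- w * h
    z1 <- rnorm(m)
    z2 <- rho_target * z1 + sqrt(max(0, 1 - rho_target^2)) * rnorm(m)
    a <- pmax(mean_intensity + sd_intensity * z1, 0)
    b <- pmax(mean_intensity + sd_intensity * z2, 0)
    data <- array(0, c(2, 1, h, w))
    data[1, 1, , ] <- round(matrix(a, h, w))
    data[2, 1, , ] <- round(matrix(b, h, w))
    frame <- image_stack(data, c("ch1", "ch2"), 0.1, 0.3)
    truth <- list(rho_target = rho_target,
                  realized_r = cor(as.vector(data[1, 1, , ]),
                                   as.vector(data[2, 1, , ])))
    list(frame = frame, truth = truth)
  })
}

# difference-of-exponentials kernel, unit peak, sampled at fs; length to
# ~6 decay time constants
event_kernel <- function(rise_ms, tau_ms, sampling_hz) {
  dt <- 1000 / sampling_hz # ms per sample
  t <- seq(0, 6 * tau_ms, by = dt)
  k <- exp(-t / tau_ms) - exp(-t / rise_ms)
  k / max(k)
}

#' Generate a miniature-event (mini) trace with ground truth
#'
#' Baseline plus Poisson-timed difference-of-exponential events plus
#' Gaussian noise. Currents are negative-going by convention.
#'
#' @param rate_hz mean event rate (Hz); 0 gives a pure-noise trace.
#' @param amp_mean mean event amplitude magnitude (nA or mV).
#' @param amp_cv coefficient of variation of amplitudes.
#' @param kernel_rise_ms,kernel_tau_ms kernel time constants (ms).
#' @param noise_sd Gaussian noise sd.
#' @param duration_s record duration; default 90 s.
#' @param sampling_hz sampling rate; default 10 kHz.
#' @param modality `"current"` (negative events) or `"potential"` (positive).
#' @param seed RNG seed.
#' @return list with `trace` (a [trace()]) and `truth` (`event_times_s`,
#'   `event_amps` signed).
#' @export
make_mini_trace <- function(rate_hz = 1, amp_mean = 0.7, amp_cv = 0.25,
                            kernel_rise_ms = 0.8, kernel_tau_ms = 6,
                            noise_sd = 0.05, duration_s = 90,
                            sampling_hz = 10000, modality = "current",
                            seed = 1) {
  stopifnot(rate_hz >= 0, duration_s > 0)
  bw <- 1 / (2 * pi * min(kernel_rise_ms, kernel_tau_ms) / 1000)
  if (sampling_hz < 2 * bw)
    stop("sampling rate below twice the kernel bandwidth")
  with_seed(seed, {
    n <- round(duration_s * sampling_hz)
    sgn <- if (modality == "current") -1 else 1
    n_ev <- rpois(1, rate_hz * duration_s)
    times <- sort(runif(n_ev, 0, duration_s))
    amps <- abs(amp_mean * (1 + amp_cv * rnorm(n_ev)))
    k <- event_kernel(kernel_rise_ms, kernel_tau_ms, sampling_hz)
    sig <- numeric(n + length(k))
    idx <- floor(times * sampling_hz) + 1L
    for (i in seq_len(n_ev))
      sig[idx[i]:(idx[i] + length(k) - 1L)] <-
        sig[idx[i]:(idx[i] + length(k) - 1L)] + sgn * amps[i] * k
    sig <- sig[seq_len(n)]
    if (noise_sd > 0) sig <- sig + rnorm(n, 0, noise_sd)
    tr <- trace(sig, sampling_hz, stim_times_s = numeric(0), modality = modality)
    list(trace = tr, truth = list(event_times_s = times,
                                  event_amps = sgn * amps))
  })
}

#' Parameters of the depressing-release train model
#'
#' Vesicle-pool recurrence: `released_i = p * pool_i`,
#' `pool_(i+1) = pool_i - released_i + refill`, response amplitude
#' `released_i * q`. Defaults follow the 100-Hz / 61-stimulation RRP
#' protocol (ISI 0.01 s).
#'
#' @param N0 initial pool size (vesicles).
#' @param p_release release probability per stimulus in `[0, 1]`.
#' @param refill_per_stim vesicles replenished per stimulus.
#' @param q quantal amplitude magnitude (nA or mV per vesicle).
#' @param n_stims number of stimuli (default 61).
#' @param isi_s inter-stimulus interval (default 0.01 s = 100 Hz).
#' @param sampling_hz sampling rate.
#' @param kernel_rise_ms,kernel_tau_ms response kernel time constants.
#' @param artifact_width_s stimulus-artifact duration (default 2 samples).
#' @param artifact_amp artifact magnitude (sign-alternating rectangle).
#' @param noise_sd Gaussian noise sd.
#' @param stochastic logical; draw binomial release instead of deterministic.
#' @param modality `"current"` or `"potential"`.
#' @param pre_s baseline time before the first stimulus.
#' @param seed RNG seed.
#' @return validated parameter list, class `release_model_params`.
#' @export
release_model_params <- function(N0 = 500, p_release = 0.3,
                                 refill_per_stim = 3, q = 0.7, n_stims = 61,
                                 isi_s = 0.01, sampling_hz = 10000,
                                 kernel_rise_ms = 0.3, kernel_tau_ms = 3,
                                 artifact_width_s = 2 / sampling_hz,
                                 artifact_amp = 50, noise_sd = 0,
                                 stochastic = FALSE, modality = "current",
                                 pre_s = 0.05, seed = 1) {
  p <- as.list(environment())
  stopifnot(p$p_release >= 0, p$p_release <= 1, p$N0 >= 0, p$n_stims >= 1,
            p$isi_s > 0)
  class(p) <- "release_model_params"
  p
}

#' Generate a depressing stimulus-train trace with ground truth
#'
#' Runs the vesicle-pool recurrence of [release_model_params()] and renders
#' per-stimulus responses (released vesicles x quantal size, convolved with
#' the event kernel) plus a brief rectangular stimulus artifact at each
#' onset. Paired-pulse variants are obtained with `n_stims = 2` and the
#' desired `isi_s` (0.01 or 0.03 s).
#'
#' @param params a [release_model_params()] object.
#' @return list with `trace` (a [trace()] carrying `stim_times_s`) and
#'   `truth` (`released` per stimulus, `pool_clamped` flag, the parameters).
#' @export
make_train_trace <- function(params) {
  stopifnot(inherits(params, "release_model_params"))
  p <- params
  with_seed(p$seed, {
    released <- numeric(p$n_stims)
    pool <- p$N0
    clamped <- FALSE
    for (i in seq_len(p$n_stims)) {
      rel <- if (p$stochastic) rbinom(1, round(pool), p$p_release)
             else p$p_release * pool
      released[i] <- rel
      pool <- pool - rel + p$refill_per_stim
      if (pool < 0) { pool <- 0; clamped <- TRUE }
    }
    stim_times <- p$pre_s + (seq_len(p$n_stims) - 1) * p$isi_s
    dur <- p$pre_s + p$n_stims * p$isi_s + 0.1
    n <- round(dur * p$sampling_hz)
    sgn <- if (p$modality == "current") -1 else 1
    k <- event_kernel(p$kernel_rise_ms, p$kernel_tau_ms, p$sampling_hz)
    sig <- numeric(n + length(k))
    for (i in seq_len(p$n_stims)) {
      at <- round(stim_times[i] * p$sampling_hz) + 1L
      sig[at:(at + length(k) - 1L)] <- sig[at:(at + length(k) - 1L)] +
        sgn * released[i] * p$q * k
    }
    sig <- sig[seq_len(n)]
    # rectangular biphasic artifact at each onset
    aw <- max(1L, round(p$artifact_width_s * p$sampling_hz))
    for (st in stim_times) {
      at <- round(st * p$sampling_hz) + 1L
      ii <- at:min(n, at + aw - 1L)
      sig[ii] <- sig[ii] + p$artifact_amp * rep_len(c(1, -1), length(ii))
    }
    if (p$noise_sd > 0) sig <- sig + rnorm(n, 0, p$noise_sd)
    tr <- trace(sig, p$sampling_hz, stim_times_s = stim_times,
                modality = p$modality)
    list(trace = tr,
         truth = list(released = released, pool_clamped = clamped,
                      model_params = p))
  })
}

#' Simulate reciprocal T-maze counts
#'
#' Two reciprocal runs (odor roles swapped); in each run every fly
#' independently avoids the shock-paired odor (CS+) with probability
#' `p_avoid_cs_plus`, i.e. ends up in the CS- arm.
#'
#' @param n_flies flies per run.
#' @param p_avoid_cs_plus avoidance probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return data.frame with columns `run`, `n_arm_cs_plus`, `n_arm_cs_minus`.
#' @export
make_tmaze_counts <- function(n_flies = 45, p_avoid_cs_plus = 0.7, seed = 1) {
  stopifnot(p_avoid_cs_plus >= 0, p_avoid_cs_plus <= 1, n_flies >= 1)
  with_seed(seed, {
    avoid <- rbinom(2, n_flies, p_avoid_cs_plus)
    data.frame(run = 1:2, n_arm_cs_plus = n_flies - avoid,
               n_arm_cs_minus = avoid)
  })
}

#' Inclusive length of a residue interval
#'
#' Length in amino acids of a 1-based inclusive residue interval, as used to
#' annotate simulated protein-domain deletion metadata (e.g. a deletion of
#' residues 1061-1171 removes 111 aa).
#'
#' @param start_aa,end_aa 1-based inclusive residue coordinates,
#'   `start_aa <= end_aa`.
#' @return number of residues, `end_aa - start_aa + 1`.
#' @export
interval_length_aa <- function(start_aa, end_aa) {
  stopifnot(start_aa >= 1)
  if (any(start_aa > end_aa)) stop("start_aa must be <= end_aa")
  end_aa - start_aa + 1
}
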