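test_that("ROI extraction crops exactly and skips border AZs", {
  st <- make_sted_frame(n_azs = 4, seed = 2)
  rois <- extract_az_rois(st$frame, st$truth$centers, roi_px = 53)
  expect_length(rois, 4)
  c1 <- get_channel(st$frame, 1)
  r1 <- rois[[1]]
  expect_equal(r1$roi1,
               c1[r1$origin["y"]:(r1$origin["y"] + 52),
                  r1$origin["x"]:(r1$origin["x"] + 52)])
  # a center at the frame border is skipped and logged
  rois2 <- extract_az_rois(st$frame, rbind(c(3, 3), st$truth$centers[1, ]))
  expect_length(rois2, 1)
  expect_equal(attr(rois2, "skipped"), 1L)
  # 53 px at 20 nm pitch is the stated 1.06 um
  expect_equal(53 * 20 / 1000, 1.06)
})

test_that("ring center of mass is accurate, translation-equivariant and pedestal-safe", {
  n <- 53
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  annulus <- function(cy, cx) {
    d <- sqrt((yy - cy)^2 + (xx - cx)^2)
    100 * exp(-(d - 6)^2 / 8)
  }
  a0 <- annulus(27, 27)
  ctr <- ring_center(a0)
  expect_lt(max(abs(ctr - c(27, 27))), 0.1)
  a3 <- annulus(27, 30)
  expect_equal(ring_center(a3)[["x"]] - ctr[["x"]], 3, tolerance = 0.05)
  # a pedestal equal to the ROI minimum is removed exactly
  expect_equal(ring_center(a0 + 5), ctr, tolerance = 1e-9)
  expect_error(ring_center(matrix(4, 9, 9)), "constant")
})

test_that("ranked distances equal the exhaustive pairwise sort", {
  # 3-4-5 arithmetic
  d <- kneighbor(c(0, 0), rbind(c(0, 3), c(4, 0)), k = 5, pitch_nm = 20)
  expect_equal(unname(d[1:2]), c(60, 80))
  expect_true(all(is.na(d[3:5])))
  expect_equal(unname(kneighbor(c(5, 5), rbind(c(5, 5)), pitch_nm = 20)[1]), 0)
  # random configurations against a brute-force sort
  set.seed(20)
  for (rep in 1:200) {
    ctr <- runif(2, 10, 40)
    pts <- matrix(runif(2 * sample(1:8, 1), 1, 52), ncol = 2)
    got <- kneighbor(ctr, pts, k = 5, pitch_nm = 20)
    brute <- sort(sqrt(colSums((t(pts) - ctr)^2)) * 20)
    kk <- min(5, length(brute))
    expect_equal(unname(got[seq_len(kk)]), brute[seq_len(kk)],
                 tolerance = 1e-12)
  }
  flagged <- kneighbor(c(1, 1), matrix(numeric(0), 0, 2))
  expect_true(all(is.na(flagged)))
})

test_that("size bins respect the printed edges", {
  expect_equal(as.character(bin_by_area(c(1, 159, 160, 215, 216, 400))),
               c("small", "small", "middle", "middle", "big", "big"))
  expect_error(bin_by_area(0.5), ">= 1")
})

test_that("counts within 400 nm use an inclusive boundary", {
  expect_equal(count_within_radius(c(500, 900)), 0)
  expect_equal(count_within_radius(c(399, 401)), 1)
  expect_equal(count_within_radius(c(400)), 1)
  expect_equal(count_within_radius(c(100, NA, 300)), 2)
})

test_that("full K-neighbor analysis recovers generator truth within half a pixel", {
  offs <- rbind(c(0, 120), c(-160, 0), c(200, 150))
  st <- make_sted_frame(dot_offsets_nm = offs, n_azs = 5, seed = 6)
  res <- kneighbor_analysis(st$frame, st$truth$centers, prominence = 200)
  truth_sorted <- sort(sqrt(rowSums(offs^2)))
  for (i in seq_len(nrow(res))) {
    got <- unlist(res[i, c("k1", "k2", "k3")])
    expect_true(all(abs(got - truth_sorted) <= 20),
                label = sprintf("AZ %d ranked distances near truth", i))
  }
  expect_true(all(res$count_within_400nm == 3))
})

test_that("moments threshold preserves moments and matches the scan oracle", {
  img <- matrix(c(rep(10, 80), rep(200, 20)), 10, 10)
  thr <- moments_threshold(img)
  expect_gt(thr, 10); expect_lt(thr, 200)
  set.seed(5)
  for (rep in 1:5) {
    im <- matrix(rpois(400, 20) + rep(c(0, 60), each = 200), 20, 20)
    t_imp <- moments_threshold(im)
    t_or <- oracle_moments_scan(im)
    binw <- (max(im) - min(im)) / 256
    expect_lt(abs(t_imp - t_or), 2 * binw)
  }
  img2 <- img + 37
  expect_equal(moments_threshold(img2), thr + 37)
  expect_error(moments_threshold(matrix(3, 4, 4)), "constant")
})

test_that("radial profiles peak at the ring radius and are flat on uniform images", {
  st <- make_sted_frame(ring_radius_nm = 120, n_azs = 6, dots_per_az = 0,
                        seed = 9)
  rp <- radial_profile(st$frame, st$truth$centers, max_radius_nm = 400,
                       bin_nm = 20)
  expect_equal(rp$radii_nm[which.max(rp$median_profile[[1]])], 120)
  # monotone non-increasing around a symmetric Gaussian
  n <- 61
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  g <- 100 * exp(-((yy - 31)^2 + (xx - 31)^2) / (2 * 16))
  arr <- array(0, c(2, 1, n, n))
  arr[1, 1, , ] <- round(g); arr[2, 1, , ] <- round(g)
  fr <- image_stack(arr, c("a", "b"), 0.02)
  rpg <- radial_profile(fr, rbind(c(31, 31)), max_radius_nm = 300, bin_nm = 20)
  expect_true(all(diff(rpg$median_profile[[1]]) <= 1e-9))
  # uniform image: flat profile at the uniform value
  fu <- image_stack(array(42, c(2, 1, 41, 41)), c("a", "b"), 0.02)
  rpu <- radial_profile(fu, rbind(c(21, 21)), max_radius_nm = 200, bin_nm = 20)
  expect_true(all(abs(rpu$median_profile[[1]] - 42) < 1e-9))
})

test_that("radial profile of symmetric truth is invariant to 90-degree rotation", {
  st <- make_sted_frame(ring_radius_nm = 120, n_azs = 1, dots_per_az = 0,
                        seed = 13)
  c1 <- get_channel(st$frame, 1)
  ctr <- st$truth$centers[1, , drop = FALSE]
  rot <- t(c1[nrow(c1):1, ]) # 90-degree rotation
  ctr_rot <- cbind(ctr[, 2], nrow(c1) + 1 - ctr[, 1])
  mk <- function(img) {
    arr <- array(0, c(2, 1, dim(img)))
    arr[1, 1, , ] <- img; arr[2, 1, , ] <- img
    image_stack(arr, c("a", "b"), 0.02)
  }
  f1 <- mk(c1)
  f2 <- mk(rot)
  p1 <- radial_profile(f1, ctr, max_radius_nm = 300, bin_nm = 20)
  p2 <- radial_profile(f2, ctr_rot, max_radius_nm = 300, bin_nm = 20)
  expect_equal(p1$median_profile[[1]], p2$median_profile[[1]],
               tolerance = 1e-9)
})

test_that("group aggregation gives t-based confidence intervals", {
  st <- lapply(1:4, function(s)
    make_sted_frame(ring_radius_nm = 120, n_azs = 4, dots_per_az = 0,
                    seed = s, noise_gaussian_sd = 10))
  profs <- lapply(st, function(x)
    radial_profile(x$frame, x$truth$centers, max_radius_nm = 300, bin_nm = 20))
  agg <- aggregate_radial_profiles(profs, channel = 1)
  expect_equal(agg$n_images[1], 4)
  expect_true(all(agg$ci_low <= agg$mean & agg$mean <= agg$ci_high))
  # 95% t interval with n=4: mean +- qt(.975, 3) * se
  mat <- t(sapply(profs, function(p) p$median_profile[[1]]))
  se <- apply(mat, 2, sd) / 2
  expect_equal(agg$ci_high - agg$mean, qt(0.975, 3) * se, tolerance = 1e-9)
  nrm <- aggregate_radial_profiles(profs, channel = 1, normalize = TRUE)
  expect_equal(max(nrm$mean), 1)
})
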