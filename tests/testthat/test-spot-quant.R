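gauss_img <- function(n, centers, sigma, peak) {
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(centers))) {
    yy <- matrix(seq_len(n), n, n)
    xx <- matrix(seq_len(n), n, n, byrow = TRUE)
    img <- img + peak * exp(-((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2) /
                              (2 * sigma^2))
  }
  img
}

test_that("well-separated Gaussians are found at their centers", {
  ctr <- rbind(c(10, 10), c(10, 30), c(32, 20))
  img <- gauss_img(42, ctr, sigma = 1.5, peak = 100)
  mx <- find_maxima(img, prominence = 50)
  expect_equal(nrow(mx), 3)
  ord <- order(mx[, 1], mx[, 2])
  expect_true(all(abs(mx[ord, ] - ctr[order(ctr[, 1], ctr[, 2]), ]) <= 1))
  expect_equal(nrow(find_maxima(matrix(7, 10, 10), 1)), 0)
})

test_that("maxima counts match the exhaustive prominence oracle on random images", {
  set.seed(10)
  for (rep in 1:8) {
    img <- matrix(sample(0:20, 100, replace = TRUE), 10, 10)
    tol <- sample(1:8, 1)
    expect_equal(nrow(find_maxima(img, tol)),
                 oracle_find_maxima_count(img, tol),
                 label = sprintf("rep %d tol %d", rep, tol))
  }
})

test_that("watershed splits a bridged pair at the saddle", {
  # two 1-D-profile Gaussians sharing a supra-threshold bridge
  ctr <- rbind(c(11, 8), c(11, 20))
  img <- gauss_img(22, ctr, sigma = 3, peak = 100)
  mx <- find_maxima(img, prominence = 20)
  expect_equal(nrow(mx), 2)
  labs <- segment_spots(img, threshold = 10, mx)
  expect_equal(length(unique(labs[labs > 0])), 2)
  # saddle at the midline: columns left of 14 one label, right the other
  expect_equal(length(unique(labs[11, c(8, 20)])), 2)
  left_lab <- labs[11, 8]
  expect_true(all(labs[11, 5:13][labs[11, 5:13] > 0] == left_lab))
  # one isolated disc, one seed: label area equals the supra-threshold area
  one <- gauss_img(21, rbind(c(11, 11)), sigma = 2.5, peak = 100)
  l1 <- segment_spots(one, 30, find_maxima(one, 50))
  expect_equal(sum(l1 > 0), sum(one > 30))
  # no maxima (constant image has none) -> empty labelling
  l0 <- segment_spots(one, 30, find_maxima(matrix(5, 21, 21), 1))
  expect_true(all(l0 == 0))
})

test_that("spot measurement applies the minimum-area cut-off before statistics", {
  labs <- matrix(0L, 10, 10)
  labs[2:3, 2:3] <- 1L # 4 px = 0.04 um2 at 0.1 um pitch
  labs[6, 6] <- 2L     # 1 px = 0.01 um2 < 0.0202 cut-off
  img <- matrix(10, 10, 10)
  tab <- measure_spots(labs, img, 0.1, min_area_um2 = 0.0202)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$label, 1L)
  tab_all <- measure_spots(labs, img, 0.1, min_area_um2 = 0)
  expect_equal(nrow(tab_all), 2)
  # 0.0150 um2 spot is excluded by the stated cut-off
  labs2 <- matrix(0L, 10, 10)
  labs2[1, 1] <- 1L # with pitch 0.1224...: area pitch^2*1 = 0.015
  tab2 <- measure_spots(labs2, img, sqrt(0.0150), min_area_um2 = 0.0202)
  expect_equal(nrow(tab2), 0)
})

test_that("disc areas and intensity identities are exact", {
  n <- 41
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  r <- 8
  img <- ifelse((yy - 21)^2 + (xx - 21)^2 <= r^2, 50, 0)
  labs <- segment_spots(img, 10, cbind(21, 21))
  tab <- measure_spots(labs, img, 0.1)
  # measured disc area within a 1-px ring of pi r^2
  expect_lt(abs(tab$area_um2 - pi * (r * 0.1)^2), 2 * pi * r * 0.1^2)
  expect_equal(tab$integrated_intensity,
               tab$mean_intensity * tab$area_um2 / 0.1^2)
  expect_equal(tab$centroid_y, 21, tolerance = 0.02)
})

test_that("NMJ metrics satisfy the density identity and handle empties", {
  labs <- matrix(0L, 50, 50)
  labs[cbind(seq(5, 45, by = 10), 10)] <- 1:5
  for (i in 1:5) labs[labs == i] <- i
  img <- matrix(20, 50, 50)
  mask <- make_mask(matrix(100, 50, 50), 1, pixel_pitch_um = 2) # 10000 um2? no: 2500*4
  spots <- measure_spots(labs, img, 2)
  met <- nmj_metrics(spots, mask, img)
  expect_equal(met$spot_density_per_um2 * met$nmj_area_um2,
               met$total_spot_count)
  expect_equal(met$total_intensity, 20 * 2500)
  empty <- measure_spots(matrix(0L, 5, 5), matrix(0, 5, 5), 1)
  m2 <- nmj_metrics(empty, make_mask(matrix(1, 5, 5), 0, 1), matrix(0, 5, 5))
  expect_equal(m2$total_spot_count, 0)
  expect_true(is.na(m2$mean_spot_area_um2))
})

test_that("intensity metrics are scale-equivariant, counts and areas invariant", {
  ctr <- rbind(c(10, 10), c(10, 26), c(26, 18))
  img <- gauss_img(36, ctr, 1.5, 100)
  run <- function(im, thr) {
    mx <- find_maxima(im, prominence = thr * 0.5)
    measure_spots(segment_spots(im, thr, mx), im, 0.1)
  }
  t1 <- run(img, 20)
  t3 <- run(img * 3, 60)
  expect_equal(nrow(t1), nrow(t3))
  expect_equal(t1$area_um2, t3$area_um2)
  expect_equal(t3$mean_intensity, 3 * t1$mean_intensity)
})

test_that("control normalization maps the control mean to 100 (or 0 after background)", {
  v <- c(2, 2, 2, 1, 1, 1)
  g <- rep(c("wt", "mut"), each = 3)
  out <- normalize_to_control(v, g, "wt")
  expect_equal(out, c(100, 100, 100, 50, 50, 50))
  # driver-background variant: background group maps to 0
  v2 <- c(10, 12, 11, 3, 3, 3)
  g2 <- c("oe", "oe", "oe", "bg", "bg", "bg")
  out2 <- normalize_to_control(v2, g2, "oe", background_group = "bg")
  expect_equal(mean(out2[g2 == "bg"]), 0)
  expect_equal(mean(out2[g2 == "oe"]), 100)
  expect_error(normalize_to_control(v, g, "absent"), "control")
})
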