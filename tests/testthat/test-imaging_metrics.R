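test_that("Otsu threshold splits bimodal images and rejects constants", {
  img <- matrix(c(rep(0, 200), rep(100, 200)), 20, 20)
  t0 <- otsu_threshold(img)
  expect_gt(t0, 0)
  expect_lt(t0, 100)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate")
  # planted Gaussian blobs recovered against the independent EBImage otsu
  set.seed(31)
  bg <- matrix(rnorm(128^2, 10, 2), 128, 128)
  blob <- screencall:::.disk_mask(128, 50, 60, 18) |
    screencall:::.disk_mask(128, 95, 90, 12)
  bg[blob] <- rnorm(sum(blob), 60, 5)
  bg <- pmax(bg, 0)
  mask <- bg > otsu_threshold(bg)
  expect_gte(sum(mask & blob) / sum(mask | blob), 0.9)
  skip_if_not_installed("EBImage")
  t_ref <- EBImage::otsu(bg / max(bg), range = c(0, 1), levels = 256) * max(bg)
  expect_equal(otsu_threshold(bg), t_ref, tolerance = 0.02 * max(bg))
})

test_that("thresholded Manders coefficients behave on planted overlaps", {
  set.seed(32)
  a <- matrix(runif(64^2, 0, 1), 64, 64)
  a[20:40, 20:40] <- a[20:40, 20:40] + 50
  expect_equal(manders_m1t(image2d(a), image2d(a))$M1t, 1.0)
  # disjoint foregrounds
  b <- matrix(0.1, 64, 64)
  b[50:60, 50:60] <- 60
  m <- manders_m1t(image2d(a), image2d(b))
  expect_equal(m$M1t, 0)
  # scale invariance of both channels
  p <- generate_coloc_pair(0.4, seed = 33)
  res1 <- manders_m1t(p$imgA, p$imgB)
  res2 <- manders_m1t(image2d(matrix(unclass(p$imgA) * 7.3, 128, 128)),
                      image2d(matrix(unclass(p$imgB) * 0.21, 128, 128)))
  expect_equal(res1$M1t, res2$M1t, tolerance = 1e-9)
  expect_false(res1$undefined)
  # half of A's above-threshold mass inside B
  ph <- generate_coloc_pair(0.5, seed = 34)
  expect_equal(manders_m1t(ph$imgA, ph$imgB)$M1t, 0.5, tolerance = 0.02)
})

test_that("line profiles interpolate and locate planted ridges", {
  flat <- image2d(matrix(7, 32, 32), 2)
  prof <- line_profile(flat, c(2, 16), c(30, 16))
  expect_true(all(prof$intensity == 7))
  expect_equal(prof$distance_um[2] - prof$distance_um[1], 2,
               tolerance = 0.1)
  # step edge crossed perpendicularly: monotone between plateaus
  step <- matrix(0, 32, 32)
  step[, 17:32] <- 10
  ps <- line_profile(image2d(step), c(4, 16), c(28, 16))
  expect_true(all(diff(ps$intensity) >= 0))
  expect_equal(range(ps$intensity), c(0, 10))
  # Gaussian ridge: peak within 1 px of planted center (col 20)
  ridge <- outer(rep(1, 40), dnorm(1:40, mean = 20, sd = 2))
  pr <- line_profile(image2d(ridge), c(5, 20), c(35, 20))
  peak_x <- 5 + pr$distance_um[which.max(pr$intensity)]
  expect_lt(abs(peak_x - 20), 1 + 1e-9)
  expect_error(line_profile(flat, c(0, 5), c(10, 5)), "bounds")
})

test_that("inside_fraction partitions the AUC exactly", {
  # piecewise-linear pulses: trapezoid integration is exact
  d <- seq(0, 20, by = 0.5)
  tri <- function(center, half, h) pmax(0, h * (1 - abs(d - center) / half))
  prof <- data.frame(distance_um = d,
                     intensity = tri(6, 2, 7) + tri(14, 2, 3))
  expect_equal(inside_fraction(prof, c(2, 10)), 0.7, tolerance = 1e-9)
  # all mass inside
  expect_equal(inside_fraction(prof, c(0, 20)), 1.0)
  prof_out <- data.frame(distance_um = d, intensity = tri(14, 2, 3))
  expect_equal(inside_fraction(prof_out, c(0, 10)), 0.0)
  # flat profile degenerates after background subtraction
  flatp <- data.frame(distance_um = d, intensity = rep(4, length(d)))
  r <- inside_fraction(flatp, c(0, 10))
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  expect_error(inside_fraction(prof, c(-1, 5)), "extent")
})

test_that("TGN states are classified from ring topology and satellites", {
  size <- 96
  annulus <- screencall:::.disk_mask(size, 48, 48, 20) &
    !screencall:::.disk_mask(size, 48, 48, 15)
  img <- matrix(0, size, size)
  img[annulus] <- 100
  r1 <- classify_tgn(image2d(img, 0.1))
  expect_equal(r1$state, "normal")
  expect_equal(r1$diameter_um, 4.0, tolerance = 0.2)
  # annulus + 4 detached blobs carrying ~20% of area
  img2 <- img
  for (cc in list(c(15, 15), c(80, 15), c(15, 80), c(80, 80))) {
    img2[screencall:::.disk_mask(size, cc[1], cc[2], 5.6)] <- 100
  }
  expect_equal(classify_tgn(image2d(img2, 0.1), sat_frac = 0.10)$state,
               "scattered")
  # blobs only: no ring
  img3 <- matrix(0, size, size)
  for (i in 1:6) {
    img3[screencall:::.disk_mask(size, 20 + 10 * i, 40 + 6 * (i %% 2),
                                 4)] <- 100
  }
  r3 <- classify_tgn(image2d(img3, 0.1))
  expect_equal(r3$state, "fragmented")
  expect_true(is.na(r3$diameter_um))
  expect_equal(classify_tgn(image2d(matrix(0, 8, 8), 1))$state,
               "unclassifiable")
})

test_that("neurite metrics measure skeleton length and quadruple points", {
  # 100-px straight line at 1 um/px: 99 unit steps
  m <- matrix(FALSE, 40, 120)
  m[20, 11:110] <- TRUE
  r <- neurite_metrics(image2d(m * 100, 1))
  expect_equal(r$total_branch_length_mm, 0.099, tolerance = 1e-9)
  expect_equal(r$n_quadruple_points, 0L)
  # X: one quadruple point; Y: none
  x <- matrix(FALSE, 61, 61)
  for (i in 1:61) {
    x[i, i] <- TRUE
    x[i, 62 - i] <- TRUE
  }
  rx <- neurite_metrics(image2d(x * 100, 1))
  expect_equal(rx$n_quadruple_points, 1L)
  y <- matrix(FALSE, 60, 60)
  for (i in 1:20) {
    y[20 + i, 30] <- TRUE      # stem
    y[21 - i, 30 - i] <- TRUE  # left arm
    y[21 - i, 30 + i] <- TRUE  # right arm
  }
  y[21, 30] <- TRUE
  ry <- neurite_metrics(image2d(y * 100, 1))
  expect_equal(ry$n_quadruple_points, 0L)
  expect_gte(ry$n_junctions, 1L)
  # empty image
  r0 <- neurite_metrics(image2d(matrix(0, 16, 16), 1))
  expect_equal(r0$total_branch_length_mm, 0)
  expect_equal(r0$n_quadruple_points, 0L)
  # diagonal length: sqrt(2) times its orthogonal projection
  d <- matrix(FALSE, 50, 50)
  for (i in 5:45) d[i, i] <- TRUE
  rd <- neurite_metrics(image2d(d * 100, 1))
  expect_equal(rd$total_branch_length_mm * 1000, 40 * sqrt(2),
               tolerance = 1e-9)
})

test_that("neurite length is invariant to 90-degree rotation", {
  g <- generate_neurite_image(list(rbind(c(15, 50), c(240, 50)),
                                   rbind(c(15, 120), c(200, 180))),
                              seed = 35)
  n1 <- neurite_metrics(g$image)
  m <- unclass(g$image)
  rot <- t(m)[ncol(m):1, ]
  n2 <- neurite_metrics(image2d(rot, 1))
  expect_equal(n1$total_branch_length_mm, n2$total_branch_length_mm,
               tolerance = 1e-12)
})

test_that("nuclear signal means and normalization are exact on constants", {
  labels <- matrix(0L, 30, 30)
  labels[5:10, 5:10] <- 1L
  labels[20:25, 20:25] <- 2L
  const <- image2d(matrix(3.5, 30, 30))
  r <- nuclear_signal(const, labels)
  expect_equal(r$mean_intensity, c(3.5, 3.5))
  expect_equal(signal_vs_reference(r$mean_intensity, r$mean_intensity), 100)
  zero <- nuclear_signal(image2d(matrix(0, 30, 30)), labels)
  expect_equal(signal_vs_reference(zero$mean_intensity, r$mean_intensity), 0)
  # reference 10, condition 3 -> 30%
  expect_equal(signal_vs_reference(c(3, 3), c(10, 10)), 30)
  # empty label skipped with a notice
  labels2 <- labels
  labels2[labels2 == 1L] <- 3L
  expect_message(nuclear_signal(const, labels2), "skipping")
})

test_that("LDH kinetics recover planted rates and relative cytotoxicity", {
  t <- seq(0, 4, by = 0.5)
  expect_equal(ldh_rate(t, 1.0 - 0.01 * t), 0.01, tolerance = 1e-12)
  expect_equal(ldh_rate(t, rep(0.8, length(t))), 0)
  expect_error(ldh_rate(c(0, 1), c(1, 0.9)), "3 time points")
  expect_error(ldh_rate(c(0, 1, 1), c(1, 0.9, 0.8)), "increasing")
  # a 22.4% reduction relative to the reference condition
  r_ref <- ldh_rate(t, 1.0 - 0.01 * t)
  r_cond <- ldh_rate(t, 1.0 - 0.00776 * t)
  expect_equal(100 - ldh_cytotoxicity(r_cond, r_ref), 22.4, tolerance = 1e-9)
})
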