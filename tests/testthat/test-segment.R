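test_that("liver statistics are mean / sample SD / max over the spherical ROI", {
  vol <- suv_volume(array(2, c(9, 9, 9)), spacing = c(10, 10, 10))
  s <- compute_liver_stats(vol, c(45, 45, 45), 15)
  expect_equal(c(s$suv_mean, s$suv_sd, s$suv_max), c(2, 0, 2))

  # sphere of radius 2.5 on (10, 10, 2) spacing covers exactly 3 voxels in z
  vals <- array(9, c(5, 5, 9))
  vals[3, 3, 4:6] <- c(1, 2, 3)
  vol2 <- suv_volume(vals, spacing = c(10, 10, 2))
  s2 <- compute_liver_stats(vol2, c(25, 25, 9), 2.5)
  expect_equal(c(s2$suv_mean, s2$suv_sd, s2$suv_max), c(2, 1, 3))

  expect_error(compute_liver_stats(vol2, c(25, 25, 9), 0.5), "fewer than 2")
  expect_error(compute_liver_stats(vol2, c(2, 2, 2), 30), "outside the")
})

test_that("the PERCIST threshold is 1.5 x liver mean + 2 SD", {
  expect_equal(percist_threshold(fake_liver(2.0, 0.3, 3)), 3.6)
  expect_equal(percist_threshold(fake_liver(0, 0, 0)), 0)
  expect_equal(percist_threshold(fake_liver(2.4, 0.25, 3)), 4.1)
})

test_that("absolute thresholding keeps exactly the voxels at or above the level", {
  vol <- toy_volume(array(1:8, c(2, 2, 2)))
  b <- whole_box(vol)
  expect_equal(apply_fixed_threshold(vol, b, 2.5)$n_voxels, 6L)
  expect_equal(apply_fixed_threshold(vol, b, 0)$n_voxels, 8L)
  m <- apply_fixed_threshold(vol, b, 100)
  expect_equal(m$n_voxels, 0L)          # empty is valid, not an error
  expect_error(apply_fixed_threshold(vol, b, -1), ">= 0")
})

test_that("fixed and percent-max thresholds agree exactly with triple-loop enumeration", {
  set.seed(314)
  for (r in 1:25) {
    d <- sample(4:9, 3, replace = TRUE)
    vol <- toy_volume(array(round(runif(prod(d), 0, 10), 2), d))
    lo <- pmax(sample(0:2, 3, replace = TRUE), 0)
    hi <- pmin(lo + sample(2:4, 3, replace = TRUE), d)
    b <- lesion_box(lo, hi)
    thr <- runif(1, 0, 10)
    expect_identical(apply_fixed_threshold(vol, b, thr)$n_voxels,
                     enumerate_threshold(vol, b, thr))
    frac <- runif(1, 0.2, 1)
    mx <- max(vol$values[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]])
    expect_identical(apply_percent_max_threshold(vol, b, frac)$n_voxels,
                     enumerate_threshold(vol, b, frac * mx))
  }
})

test_that("fixed-threshold masks are nested as the threshold rises", {
  set.seed(11)
  vol <- toy_volume(array(runif(216, 0, 5), c(6, 6, 6)))
  b <- whole_box(vol)
  thrs <- sort(runif(6, 0, 5))
  masks <- lapply(thrs, function(t) apply_fixed_threshold(vol, b, t)$indices)
  for (i in seq_len(length(thrs) - 1))
    expect_true(all(masks[[i + 1]] %in% masks[[i]]))
})

test_that("percent-max thresholding uses the in-box maximum", {
  vol <- toy_volume(c(1, 4, 4.1, 5, 10))
  m <- apply_percent_max_threshold(vol, whole_box(vol), 0.41)
  expect_equal(m$threshold, 4.1)
  expect_equal(m$n_voxels, 3L)
  m1 <- apply_percent_max_threshold(vol, whole_box(vol), 1.0)
  expect_equal(m1$n_voxels, 1L)         # only the maximum voxel
  z <- toy_volume(c(0, 0, 0))
  mz <- apply_percent_max_threshold(z, whole_box(z), 0.41)
  expect_equal(mz$n_voxels, 0L)
  expect_true("zero_box" %in% mz$flags)
})

test_that("merged vs split boxes change the percent-max result but not absolute thresholds", {
  tw <- two_lesion_volume(bright = 10, dim_suv = 4.05)
  split_n <- apply_percent_max_threshold(tw$vol, tw$box1)$n_voxels +
    apply_percent_max_threshold(tw$vol, tw$box2)$n_voxels
  merged_n <- apply_percent_max_threshold(tw$vol, tw$merged)$n_voxels
  # merged box thresholds at 4.1 > 4.05: the dim lesion disappears
  expect_equal(split_n, tw$n1 + tw$n2)
  expect_equal(merged_n, tw$n1)
  # absolute threshold is indifferent to the box decomposition
  abs_split <- apply_fixed_threshold(tw$vol, tw$box1, 2.5)$n_voxels +
    apply_fixed_threshold(tw$vol, tw$box2, 2.5)$n_voxels
  abs_merged <- apply_fixed_threshold(tw$vol, tw$merged, 2.5)$n_voxels
  expect_equal(abs_split, abs_merged)
})

test_that("enlarging a box leaves absolute methods unchanged but can change percent-max", {
  vals <- array(0, c(20, 8, 8))
  dimv <- dim(vals)
  idx <- petmtv:::sphere_indices(dimv, c(1, 1, 1), c(0, 0, 0), c(6, 4, 4), 2.2)
  vals[idx] <- 5
  vals[16, 4, 4] <- 10   # hotter voxel away from the lesion
  vol <- suv_volume(vals, c(1, 1, 1))
  small <- lesion_box(c(2, 0, 0), c(10, 8, 8))
  medium <- lesion_box(c(0, 0, 0), c(13, 8, 8))  # only background added
  big <- lesion_box(c(0, 0, 0), c(18, 8, 8))     # captures the hot voxel
  # no new suprathreshold voxel: absolute-method MTV has delta = 0 exactly
  for (thr in c(2.5, 3.3)) {
    expect_equal(apply_fixed_threshold(vol, small, thr)$n_voxels,
                 apply_fixed_threshold(vol, medium, thr)$n_voxels)
  }
  # percent-max is unchanged while the in-box maximum is unchanged ...
  expect_equal(apply_percent_max_threshold(vol, small)$n_voxels,
               apply_percent_max_threshold(vol, medium)$n_voxels)
  # ... but re-thresholds as soon as a hotter voxel enters the box
  m_small <- apply_percent_max_threshold(vol, small)
  m_big <- apply_percent_max_threshold(vol, big)
  expect_equal(m_small$threshold, 0.41 * 5)
  expect_equal(m_big$threshold, 0.41 * 10)
  expect_false(m_small$n_voxels == m_big$n_voxels)
})

test_that("background shells average the surrounding voxels with exclusions", {
  vol <- toy_volume(array(1, c(8, 8, 8)))
  b <- lesion_box(c(2, 2, 2), c(6, 6, 6))
  expect_equal(estimate_background(vol, b, 1), 1.0)

  # value depends only on x, symmetric about the box centre: shell mean is 2
  vals <- array(rep(c(1, 3), each = 4), c(8, 8, 8))
  vol2 <- suv_volume(vals, c(1, 1, 1))
  expect_equal(estimate_background(vol2, b, 1), 2.0)

  edge <- lesion_box(c(0, 0, 0), c(4, 4, 4))   # clipped at the grid corner
  expect_equal(estimate_background(vol, edge, 2), 1.0)
  expect_error(estimate_background(vol, whole_box(vol), 2), "empty")
  expect_error(estimate_background(vol, b, 0), "shell_width")
})

test_that("the Nestle threshold is beta x (core mean + background)", {
  vol <- toy_volume(c(10, 10, 9, 8, 2, 1, 1))
  m <- segment_nestle(vol, whole_box(vol), beta = 0.15, background = 1)
  expect_equal(m$i70, mean(c(10, 10, 9, 8)))   # core = voxels >= 7
  expect_equal(m$threshold, 0.15 * (9.25 + 1))
  expect_equal(m$n_voxels, 5L)                 # {10,10,9,8,2} >= 1.5375
  m0 <- segment_nestle(vol, whole_box(vol), beta = 0.15, background = 0)
  expect_equal(m0$threshold, 0.15 * 9.25)
  expect_error(segment_nestle(vol, whole_box(vol), background = 11), "indistinguishable")
  expect_error(segment_nestle(vol, whole_box(vol), beta = 1.2, background = 1), "beta")
})

test_that("Black iteration reaches its fixed point and matches brute force", {
  vol <- toy_volume(c(rep(10, 6), rep(0, 10)))
  m <- segment_black(vol, whole_box(vol))
  expect_equal(m$threshold, 0.307 * 10 + 0.588)
  expect_equal(m$n_voxels, 6L)
  expect_lte(m$iterations, 2L)

  # two-level lesion: enumerate the candidate masks by hand
  vol2 <- toy_volume(c(rep(10, 4), rep(4, 6), rep(0, 8)))
  m2 <- segment_black(vol2, whole_box(vol2))
  brute <- local({
    v <- c(rep(10, 4), rep(4, 6), rep(0, 8))
    cur <- v >= 4.1                       # the 41% start
    repeat {
      thr <- 0.307 * mean(v[cur]) + 0.588
      nxt <- v >= thr
      if (identical(nxt, cur)) return(list(n = sum(cur), thr = thr))
      cur <- nxt
    }
  })
  expect_equal(m2$n_voxels, brute$n)
  expect_equal(m2$threshold, brute$thr)

  expect_warning(m0 <- segment_black(vol, whole_box(vol), max_iter = 0), "41%")
  expect_true("iteration_cap" %in% m0$flags)
  expect_equal(m0$threshold, 4.1)
  # an aggressive update constant pushes the threshold above every voxel
  expect_error(segment_black(vol, whole_box(vol), a = 1.2), "escaped")
})

test_that("Daisne adapts to the signal-to-background ratio and degrades to fixed-fraction", {
  vol <- toy_volume(c(10, 9, 5, 2, 1, 1))
  # near-zero background: SBR huge, f -> c, same mask as fixed-fraction at c
  m <- segment_daisne(vol, whole_box(vol), calib = c(0.35, 0.6),
                      background = 1e-9)
  ref <- apply_percent_max_threshold(vol, whole_box(vol), 0.6)
  expect_equal(sort(m$indices), sort(ref$indices))
  expect_equal(m$fraction, 0.6, tolerance = 1e-6)
  flat <- toy_volume(rep(2, 6))
  expect_error(segment_daisne(flat, whole_box(flat), c(0.35, 0.6), background = 2),
               "insufficient contrast")
  expect_error(segment_daisne(vol, whole_box(vol), c(0.35, 0.6), background = 0),
               "background")
})

test_that("calibrated Daisne recovers a fresh blurred sphere within 15%", {
  cal <- calibrate_adaptive(rep(c(24, 36, 48, 60), times = 4),
                            rep(c(3, 5, 10, 12), each = 4))
  ph <- petmtv:::blurred_sphere_phantom(40, 8, 1, c(5.3, 5.3, 2), 4.4)
  m <- segment_daisne(ph$volume, ph$box, c(cal$m, cal$c), background = 1)
  true_vol <- 4 / 3 * pi * 20^3 / 1000
  expect_lt(abs(mask_volume_cm3(m) / true_vol - 1), 0.15)
})

test_that("adaptive calibration is deterministic, exact for two phantoms, and guards degeneracy", {
  a <- calibrate_adaptive(c(30, 50), c(4, 10))
  b <- calibrate_adaptive(c(30, 50), c(4, 10))
  expect_identical(a[c("m", "c")], b[c("m", "c")])
  # 2-point fit passes through both calibration points exactly
  pred <- a$m / a$table$sbr + a$c
  expect_equal(pred, a$table$fraction, tolerance = 1e-12)
  expect_error(calibrate_adaptive(c(30, 30), c(4, 4)), "degenerate")
  expect_error(calibrate_adaptive(30, 4), ">= 2")
})

test_that("without blur the recovered fraction is the threshold-plateau midpoint", {
  # exact derivation: values are {bg, uptake}; the closest-volume threshold is
  # the uptake itself, the plateau below it starts at bg, so the midpoint
  # fraction is (bg + uptake) / (2 uptake) = 0.5 + 0.5/SBR with SBR = contrast
  cal <- calibrate_adaptive(c(30, 40, 50), c(4, 8, 16), psf_fwhm_mm = 0)
  expect_equal(cal$table$fraction, 0.5 + 0.5 / cal$table$sbr, tolerance = 1e-10)
  expect_equal(cal$m, 0.5, tolerance = 1e-8)
  expect_equal(cal$c, 0.5, tolerance = 1e-8)
})

test_that("iterative methods terminate with near-monotone threshold traces on blurred spheres", {
  cal <- list(m = 0.35, c = 0.6)
  for (d_mm in c(30, 50)) {
    ph <- petmtv:::blurred_sphere_phantom(d_mm, 8, 1, c(5.3, 5.3, 2), 4.4)
    mb <- segment_black(ph$volume, ph$box)
    md <- segment_daisne(ph$volume, ph$box, c(cal$m, cal$c), background = 1)
    for (m in list(mb, md)) {
      expect_lte(m$iterations, 100L)
      if (length(m$trace) > 2) {
        d1 <- diff(m$trace[-1])
        expect_true(all(d1 >= -1e-9) || all(d1 <= 1e-9))
      }
    }
  }
})

test_that("the sphere-fit model recovers its own forward model almost exactly", {
  sp <- c(5.3, 5.3, 2)
  dimv <- c(16, 16, 40)
  ctr <- dimv * sp / 2
  sigma <- 4.4 / (2 * sqrt(2 * log(2)))
  ax <- lapply(1:3, function(a) (seq_len(dimv[a]) - 0.5) * sp[a])
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  r <- sqrt(rowSums(sweep(g, 2, ctr)^2))
  vals <- array(1 + 7 * petmtv:::blurred_sphere_profile(r, 15, sigma), dimv)
  vol <- suv_volume(vals, sp)
  m <- segment_fitting(vol, whole_box(vol), psf_fwhm_mm = 4.4)
  expect_true(m$fit$converged)
  expect_lt(abs(m$fit$diameter_mm / 30 - 1), 0.01)
})

test_that("sphere fitting handles the sharp limit and rejects unidentifiable boxes", {
  ph <- generate_phantom(single_sphere_config(radius_mm = 20, psf_fwhm_mm = 0),
                         seed = 1)
  bx <- place_observer_boxes(ph$truth, observer_model(0, 0, seed = 1))[[1]]
  m <- segment_fitting(ph$volume, bx, psf_fwhm_mm = 0)
  vox_truth <- mask_volume_cm3(sum(ph$volume$values == 10), ph$volume$spacing)
  shell <- 4 * pi * 20^2 * max(ph$volume$spacing) / 1000
  expect_lt(abs(m$volume_cm3 - vox_truth), shell)

  flat <- toy_volume(array(3, c(5, 5, 5)))
  expect_error(segment_fitting(flat, whole_box(flat)), "unidentifiable")
  tiny <- toy_volume(array(1:8, c(2, 2, 2)))
  expect_error(segment_fitting(tiny, whole_box(tiny)), "30 voxels")
})

test_that("mask volumes convert voxel counts with the voxel size", {
  expect_equal(mask_volume_cm3(100, c(5.3, 5.3, 2.0)), 5.618)
  expect_equal(mask_volume_cm3(0, c(5.3, 5.3, 2.0)), 0)
  expect_equal(mask_volume_cm3(1, c(10, 10, 10)), 1)
})

test_that("every method recovers large high-contrast blurred spheres within 25%", {
  cal <- calibrate_adaptive(rep(c(24, 36, 48, 60), times = 4),
                            rep(c(3, 5, 10, 12), each = 4))
  liver <- fake_liver(2.2, 0, 2.2)
  ms <- default_methods(calib = cal)
  for (d_mm in c(60, 80)) {
    ph <- petmtv:::blurred_sphere_phantom(d_mm, 8, 1, c(5.3, 5.3, 2), 4.4)
    true_vol <- 4 / 3 * pi * (d_mm / 2)^3 / 1000
    for (mn in names(ms)) {
      m <- segment_lesion(ph$volume, ph$box, ms[[mn]], liver = liver,
                          background = 1)
      expect_lt(abs(lesion_mtv_cm3(m) / true_vol - 1), 0.25,
                label = sprintf("%s at d=%d relative error", mn, d_mm))
    }
  }
})
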