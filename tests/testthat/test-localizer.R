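test_that("smoothing is the identity at FWHM 0 and preserves constants", {
  vol <- array(runif(9 * 9 * 9), c(9, 9, 9))
  expect_identical(smooth_volume(vol, 0, c(3, 3, 3)), vol)
  const <- array(7, c(9, 9, 9))
  expect_equal(smooth_volume(const, 3, c(3, 3, 3)), const, tolerance = 1e-12)
  expect_error(smooth_volume(vol, 3, c(0, 3, 3)), "positive")
})

test_that("a delta impulse reproduces the closed-form Gaussian kernel", {
  vol <- array(0, c(9, 9, 9))
  vol[5, 5, 5] <- 1
  out <- smooth_volume(vol, 3, c(3, 3, 3))
  sigma_vox <- 3 / (2 * sqrt(2 * log(2))) / 3  # sigma in voxels
  r <- ceiling(4 * sigma_vox)
  w <- dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)  # normalized discrete Gaussian, evaluated independently
  expected <- outer(outer(w, w), w)
  got <- out[(5 - r):(5 + r), (5 - r):(5 + r), (5 - r):(5 + r)]
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(sigma_vox * 3, 1.2739827, tolerance = 1e-6)  # sigma in mm
})

test_that("a voxel carrying the regressor correlates perfectly after one block", {
  d <- localizer_design()
  site <- site_config("s", 2, 8, c(8L, 8L))
  k <- make_hrf(canonical_hrf(), 2)
  reg <- bold_regressor(d, k)
  arr <- array(1000, c(8, 8, 8, n_scans(d)))
  arr[4, 4, 4, ] <- 1000 * (1 + reg / 100)     # the regressor itself
  arr[2, 2, 2, ] <- 1234                        # constant voxel
  vs <- volume_series(arr, 2)
  map <- incremental_localizer(scan_stream(vs), d, fwhm_mm = 0)
  expect_equal(map$per_block_r[[1]][4, 4, 4], 1, tolerance = 1e-9)
  # pooled over all blocks the per-block baseline referencing leaves the
  # correlation marginally below 1 (later baselines sit on the undershoot)
  expect_gt(map$r[4, 4, 4], 0.995)
  expect_true(is.nan(map$r[2, 2, 2]))
  expect_true(all(abs(map$r[!is.nan(map$r)]) <= 1 + 1e-12))
})

test_that("incremental correlation equals the one-shot brute-force oracle", {
  d <- localizer_design()
  site <- tiny_site(dims = c(10L, 10L), n_slices = 6L)
  subj <- subject_profile("o", 2.5, activation_center = c(5L, 5L, 3L),
                          activation_radius = 2, noise_sd_percent = 0.4,
                          drift_amplitude_percent = 0.1)
  vs <- simulate_run(d, subj, site, efforts = 1, seed = 21)
  map <- incremental_localizer(scan_stream(vs), d, fwhm_mm = 3)
  oracle <- oracle_localizer_r(vs$data, d, make_hrf(canonical_hrf(), 2),
                               fwhm_mm = 3, voxel_size_mm = vs$voxel_size_mm)
  expect_lt(max(abs(map$r - oracle), na.rm = TRUE), 1e-10)
  expect_equal(is.nan(map$r), is.nan(oracle))
})

test_that("pure-noise correlations match the empirical null tail", {
  d <- localizer_design()
  set.seed(77)
  nvox <- 10000
  used <- c(1:3, 6:8)
  reg <- bold_regressor(d, make_hrf(canonical_hrf(), 2))
  # implementation route: noise-only volumes through the localizer
  dims <- c(25L, 25L, 16L)  # 10000 voxels
  arr <- array(1000 * (1 + rnorm(prod(dims) * n_scans(d), sd = 0.5) / 100),
               c(dims, n_scans(d)))
  vs <- volume_series(arr, 2)
  map <- incremental_localizer(scan_stream(vs), d, fwhm_mm = 0)
  frac_impl <- mean(abs(map$r) > 0.95)
  # oracle route: same null, assembled independently scan by scan
  r_null <- replicate(nvox, {
    obs <- c(); y <- c()
    for (b in 1:5) {
      ts <- rnorm(12)
      obs <- c(obs, ts[used] - mean(ts[1:3]))
      y <- c(y, reg[(b - 1) * 12 + used])
    }
    cor(obs, y)
  })
  frac_null <- mean(abs(r_null) > 0.95)
  expect_lt(abs(frac_impl - frac_null), 0.005)
  expect_lt(frac_impl, 0.01)
})

test_that("ROI extraction recovers the generating blob and applies cluster rules", {
  site <- tiny_site()
  subj <- tiny_subject(amp = 2.5, noise = 0.2 * 2.5, radius = 2.5)
  d <- localizer_design()
  vs <- simulate_run(d, subj, site, efforts = 1, seed = 31)
  map <- incremental_localizer(scan_stream(vs), d, fwhm_mm = 3)
  roi <- extract_roi(map, 0.6, 5)
  truth <- activation_mask(subj, dim(map$r))
  expect_gte(dice(roi$mask, truth), 0.9)

  expect_error(extract_roi(map, 1.01, 5), "localization failure")

  # largest-cluster rule on a hand-built map
  r <- array(0, c(12, 12, 4))
  r[1:10, 1:4, 1] <- 0.9   # 40-voxel cluster
  r[1:6, 7:8, 3] <- 0.9    # 12-voxel cluster
  fake <- structure(list(r = r, fwhm_mm = 0, baseline_scans = 1:3,
                         response_scans = 6:8),
                    class = "activation_map")
  roi2 <- extract_roi(fake, 0.6, 30)
  expect_equal(roi2$n_voxels, 40)
  expect_true(all(roi2$mask[1:10, 1:4, 1]))
})

test_that("calibration stores the individual maximum as the 100% reference", {
  # explicit small series: max of [0.1, 2.4, 1.0] percent is 2.4
  d1 <- block_design(data.frame(segment = c("rest", "tapping", "rest"),
                                n_scans = c(2L, 2L, 8L)), 1)
  pct <- c(0, 0, 0, 0, 0.1, 2.4, 1.0, 0, 0, 0, 0, 0)
  arr <- array(rep(1000 * (1 + pct / 100), each = 8), c(2, 2, 2, 12))
  roi <- array(TRUE, c(2, 2, 2))
  prof <- calibrate(volume_series(arr, 2), roi, d1, convention = "scan_max")
  expect_equal(prof$max_bold_percent, 2.4, tolerance = 1e-10)

  # noiseless flat-blob subject: programmed 2.69% is recovered
  site <- tiny_site()
  subj <- tiny_subject(amp = 2.69, shape = "flat")
  d <- localizer_design()
  vs <- simulate_run(d, subj, site, efforts = 1, seed = 4)
  map <- incremental_localizer(scan_stream(vs), d, fwhm_mm = 0)
  roi2 <- extract_roi(map)
  prof2 <- calibrate(vs, roi2, d, convention = "scan_max")
  expect_equal(prof2$max_bold_percent, 2.69, tolerance = 1e-8)

  # gain invariance: scaling all intensities leaves the profile unchanged
  vs_g <- vs
  vs_g$data <- vs$data * 3.7
  prof_g <- calibrate(vs_g, roi2, d, convention = "scan_max")
  expect_equal(prof_g$max_bold_percent, prof2$max_bold_percent,
               tolerance = 1e-12)

  # a signal-free series fails calibration
  flat <- volume_series(array(1000, c(2, 2, 2, 12)), 2)
  expect_error(calibrate(flat, roi, d1), "calibration failure")
})

test_that("calibration profiles survive a JSON round trip", {
  site <- tiny_site()
  vs <- simulate_run(localizer_design(), tiny_subject(), site, seed = 6)
  map <- incremental_localizer(scan_stream(vs), localizer_design())
  roi <- extract_roi(map)
  prof <- calibrate(vs, roi, subject_id = "s01")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_calibration_profile(prof, path)
  prof2 <- read_calibration_profile(path)
  expect_equal(prof2$max_bold_percent, prof$max_bold_percent)
  expect_equal(prof2$subject_id, "s01")
  expect_equal(prof2$roi$mask, prof$roi$mask)
})

test_that("sliding-window activation averages scans 8-10 against the 5-scan baseline", {
  d <- main_design(seed = 1)
  expect_equal(segment_scans(d, "baseline"), 1:5)
  expect_equal(segment_scans(d, "tapping"), 6:7)
  vals <- numeric(n_scans(d))
  vals[block_scans(d, 1)[8:10]] <- c(1.2, 1.5, 1.2)
  sw <- sliding_window_activation(vals, d)
  expect_equal(sw$raw_response_percent[1], 1.3)
  expect_equal(sw$raw_response_percent[2], 0)   # constant block

  short <- block_design(data.frame(segment = c("baseline", "tapping"),
                                   n_scans = c(5L, 2L)), 2)
  expect_error(sliding_window_activation(numeric(14), short), "too short")
})

test_that("a noiseless block's raw response equals the closed-form window mean", {
  site <- tiny_site()
  subj <- tiny_subject(amp = 2.5, shape = "flat")
  d <- main_design(tiny_config(k = 1L), seed = 3)
  eff <- rep(c(0.6, 0), length.out = d$n_blocks)  # isolated active blocks
  vs <- simulate_run(d, subj, site, efforts = eff, seed = 8)
  roi <- activation_mask(subj, dim(vs$data)[1:3])
  sw <- sliding_window_activation(
    roi_block_percent(roi_mean_series(vs, roi), d), d)
  reg <- bold_regressor(d, make_hrf(canonical_hrf(), 2), efforts = eff)
  for (b in which(eff > 0)) {
    sc <- block_scans(d, b)
    expected <- 2.5 * (mean(reg[sc[8:10]]) - mean(reg[sc[1:5]]))
    expect_equal(sw$raw_response_percent[b], expected, tolerance = 1e-9)
  }
})
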