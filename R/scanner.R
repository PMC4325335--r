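#' Synthetic subject profile
#'
#' Describes the BOLD characteristics of one simulated subject: the true
#' maximal percent signal change in the activated sensorimotor region, the
#' location and spatial extent of the activation blob, noise and drift
#' levels, and a controllability map from intended effort to realized
#' fraction of the maximum amplitude.
#'
#' @param subject_id short identifier.
#' @param max_amplitude_percent true maximal BOLD percent signal change at
#'   full effort (> 0), e.g. 2.69.
#' @param activation_center voxel coordinate (1-based integer triple) of the
#'   blob center.
#' @param activation_radius blob radius in voxels; the blob is truncated at
#'   this radius.
#' @param noise_sd_percent per-voxel per-scan Gaussian noise SD in percent
#'   signal change (>= 0).
#' @param drift_amplitude_percent amplitude of the slow sinusoidal drift in
#'   percent (>= 0).
#' @param profile_shape `"gaussian"` for an isotropic Gaussian spatial
#'   profile (sigma = radius, so the truncation edge keeps
#'   `exp(-1/2) ~ 0.61` of the center amplitude), or `"flat"` for a plateau
#'   of full amplitude.
#' @param controllability function mapping intended effort in `[0, 1]` to the
#'   realized fraction of `max_amplitude_percent` (default: identity).
#' @export
subject_profile <- function(subject_id, max_amplitude_percent,
                            activation_center = c(16L, 16L, 8L),
                            activation_radius = 3,
                            noise_sd_percent = 0.2,
                            drift_amplitude_percent = 0.1,
                            profile_shape = c("gaussian", "flat"),
                            controllability = identity) {
  stopifnot(max_amplitude_percent > 0, activation_radius > 0,
            noise_sd_percent >= 0, drift_amplitude_percent >= 0,
            length(activation_center) == 3, is.function(controllability))
  structure(list(subject_id = as.character(subject_id),
                 max_amplitude_percent = max_amplitude_percent,
                 activation_center = as.integer(round(activation_center)),
                 activation_radius = activation_radius,
                 noise_sd_percent = noise_sd_percent,
                 drift_amplitude_percent = drift_amplitude_percent,
                 profile_shape = match.arg(profile_shape),
                 controllability = controllability),
            class = "subject_profile")
}

#' Scale a subject's signal characteristics by a site gain
#'
#' Site gain acts multiplicatively on every percent-signal field (amplitude,
#' noise SD, drift), emulating a scanner whose BOLD response is `gain` times
#' larger for the same physiology.
#'
#' @param subject a [subject_profile()].
#' @param gain positive multiplier.
#' @export
scale_subject_gain <- function(subject, gain) {
  stopifnot(inherits(subject, "subject_profile"), gain > 0)
  subject$max_amplitude_percent <- subject$max_amplitude_percent * gain
  subject$noise_sd_percent <- subject$noise_sd_percent * gain
  subject$drift_amplitude_percent <- subject$drift_amplitude_percent * gain
  subject
}

#' Draw a group of subject profiles
#'
#' Maximum amplitudes are drawn from a truncated normal. Defaults emulate the
#' study groups: 3T mean 2.25% (SD 0.8); the 7T group mean is 1.6 x the 3T
#' mean (3.6%, SD 1.0), i.e. about 60% higher.
#'
#' @param n number of subjects.
#' @param field `"3T"` or `"7T"`.
#' @param seed RNG seed.
#' @param dims volume dimensions used to place the blob.
#' @param ... further arguments passed to [subject_profile()].
#' @return list of [subject_profile()] objects.
#' @export
sample_subject_profiles <- function(n, field = c("3T", "7T"), seed = 1,
                                    dims = c(32L, 32L, 16L), ...) {
  field <- match.arg(field)
  mu <- if (field == "3T") 2.25 else 1.6 * 2.25
  sdv <- if (field == "3T") 0.8 else 1.0
  withr_seed(seed, {
    amp <- pmax(0.5, stats::rnorm(n, mu, sdv))
    lapply(seq_len(n), function(i) {
      subject_profile(sprintf("%s_subj%02d", field, i), amp[i],
                      activation_center = round(dims / 2), ...)
    })
  })
}

#' 4D synthetic volume series
#'
#' @param data 4D numeric array `(x, y, z, t)` of strictly positive
#'   intensities without NaN.
#' @param tr_seconds repetition time in seconds.
#' @param voxel_size_mm voxel edge lengths in mm (triple).
#' @param baseline_intensity nominal baseline intensity (for reference).
#' @export
volume_series <- function(data, tr_seconds, voxel_size_mm = c(3, 3, 4),
                          baseline_intensity = NA_real_) {
  stopifnot(length(dim(data)) == 4, tr_seconds > 0,
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (anyNA(data)) stop("volume series contains NaN/NA")
  if (any(data <= 0)) stop("volume series intensities must be positive")
  structure(list(data = data, tr_seconds = tr_seconds,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 baseline_intensity = baseline_intensity),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat("Volume series: ", paste(d[1:3], collapse = " x "), " voxels x ",
      d[4], " scans, TR ", x$tr_seconds, " s, voxel ",
      paste(x$voxel_size_mm, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Spatial weight map and mask of a subject's activation blob
#'
#' @param subject a [subject_profile()].
#' @param dims volume dimensions (integer triple).
#' @return `activation_weights`: 3D array of weights in `[0, 1]`;
#'   `activation_mask`: logical 3D array (weight > 0).
#' @export
activation_weights <- function(subject, dims) {
  ctr <- subject$activation_center
  r <- subject$activation_radius
  if (any(ctr - r < 1) || any(ctr + r > dims)) {
    stop("activation blob extends outside the volume")
  }
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  w <- if (subject$profile_shape == "flat") {
    as.numeric(d2 <= r^2)
  } else {
    ifelse(d2 <= r^2, exp(-d2 / (2 * r^2)), 0)
  }
  array(w, dims)
}

#' @rdname activation_weights
#' @export
activation_mask <- function(subject, dims) {
  activation_weights(subject, dims) > 0
}

#' Simulate a block-design BOLD run
#'
#' Every voxel inside the activation blob carries
#' `baseline * (1 + pct / 100)` where `pct` is the spatially weighted,
#' effort-scaled HRF-convolved task response plus Gaussian noise and a slow
#' sinusoidal drift; voxels outside the blob carry baseline + noise + drift
#' only. The realized per-block amplitude is
#' `controllability(effort) * max_amplitude_percent`, with the convolved
#' regressor normalized to unit single-block peak, so at full effort the
#' noiseless blob-center peak percent change equals `max_amplitude_percent`.
#'
#' @param design a [block_design()].
#' @param subject a [subject_profile()].
#' @param site a [site_config()] (geometry and TR).
#' @param efforts per-block intended effort in `[0, 1]` (recycled).
#' @param seed RNG seed; runs are bit-reproducible.
#' @param hrf a [canonical_hrf()].
#' @param baseline_intensity mean baseline intensity (arbitrary scanner
#'   units).
#' @param gain multiplicative hardware gain applied to all raw intensities
#'   (cancels in percent change).
#' @param drift_period_seconds period of the drift sinusoid (>= 60 s).
#' @return a [volume_series()].
#' @export
simulate_run <- function(design, subject, site, efforts = 1, seed = 1,
                         hrf = canonical_hrf(), baseline_intensity = 1000,
                         gain = 1, drift_period_seconds = 120) {
  stopifnot(inherits(design, "block_design"),
            inherits(subject, "subject_profile"),
            inherits(site, "site_config"),
            drift_period_seconds >= 60, gain > 0)
  efforts <- rep_len(efforts, design$n_blocks)
  stopifnot(all(efforts >= 0 & efforts <= 1))
  dims <- c(site$matrix_size, site$n_slices)
  nt <- n_scans(design)
  tr <- site$tr_seconds

  realized <- vapply(efforts, subject$controllability, 0)
  kernel <- make_hrf(hrf, tr)
  reg <- bold_regressor(design, kernel, efforts = realized)
  w <- activation_weights(subject, dims)
  nv <- prod(dims)

  withr_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    t_sec <- (seq_len(nt) - 1) * tr
    drift <- subject$drift_amplitude_percent *
      sin(2 * pi * t_sec / drift_period_seconds + phase)
    # percent-change field: signal (outer product) + drift + iid noise
    pct <- outer(as.vector(w), subject$max_amplitude_percent * reg) +
      rep(drift, each = nv)
    if (subject$noise_sd_percent > 0) {
      pct <- pct + stats::rnorm(nv * nt, sd = subject$noise_sd_percent)
    }
  })
  data <- array(gain * baseline_intensity * (1 + pct / 100), c(dims, nt))
  vs <- volume_series(data, tr, voxel_size_mm = c(3, 3, 4),
                      baseline_intensity = gain * baseline_intensity)
  vs$design <- design
  vs
}

#' Serve a volume series one scan per TR (real-time contract)
#'
#' Returns a stream object emulating acquisition order: `next_scan()` yields
#' `list(scan_index, volume)`; `volume(i)` retrieves an already-acquired scan
#' and errors for scans not yet yielded (causality); `consumed()` reports how
#' many scans have been served.
#'
#' @param series a [volume_series()].
#' @return an object of class `scan_stream`.
#' @export
scan_stream <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  nt <- dim(series$data)[4]
  pos <- 0L
  self <- new.env(parent = emptyenv())
  self$tr_seconds <- series$tr_seconds
  self$voxel_size_mm <- series$voxel_size_mm
  self$n_total <- nt
  self$has_next <- function() pos < nt
  self$consumed <- function() pos
  self$next_scan <- function() {
    if (pos >= nt) stop("stream exhausted after ", nt, " scans")
    pos <<- pos + 1L
    list(scan_index = pos, volume = series$data[, , , pos, drop = FALSE][, , , 1])
  }
  self$volume <- function(i) {
    if (i > pos) {
      stop("real-time contract violation: scan ", i,
           " requested but only ", pos, " scans acquired")
    }
    series$data[, , , i, drop = FALSE][, , , 1]
  }
  class(self) <- "scan_stream"
  self
}

#' Write / read a volume series as NIfTI-1
#'
#' @param series a [volume_series()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume_series <- function(series, path) {
  stopifnot(inherits(series, "volume_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size_mm, series$tr_seconds)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  volume_series(unclass(img)[, , , , drop = FALSE],
                tr_seconds = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2,
                voxel_size_mm = pd[1:3])
}
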