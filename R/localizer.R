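#' Gaussian spatial smoothing of a single volume
#'
#' Separable normalized Gaussian convolution. The FWHM in mm is converted to
#' a per-axis sigma in voxels (`sigma = fwhm / (2 sqrt(2 ln 2))`); the kernel
#' is truncated at 4 sigma and renormalized at the volume borders so a
#' constant volume is preserved exactly. `fwhm_mm = 0` is the identity.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm full width at half maximum in mm (>= 0).
#' @param voxel_size_mm voxel edge lengths in mm (triple, > 0).
#' @return smoothed 3D array.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm = c(3, 3, 4)) {
  stopifnot(length(dim(vol)) == 3, fwhm_mm >= 0)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  num <- vol
  den <- array(1, dim(vol))
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / voxel_size_mm[ax]
    r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
    w <- stats::dnorm(-r:r, sd = sigma_vox)
    w <- w / sum(w)
    num <- conv_axis(num, w, ax)
    den <- conv_axis(den, w, ax)
  }
  num / den
}

# zero-padded 1D convolution of a 3D array along axis ax with symmetric kernel w
conv_axis <- function(a, w, ax) {
  d <- dim(a)
  r <- (length(w) - 1L) %/% 2L
  out <- array(0, d)
  idx_full <- lapply(d, seq_len)
  for (k in seq_along(w)) {
    o <- k - r - 1L  # offset
    lo_dst <- max(1L, 1L + o); hi_dst <- min(d[ax], d[ax] + o)
    if (lo_dst > hi_dst) next
    dst <- idx_full; src <- idx_full
    dst[[ax]] <- lo_dst:hi_dst
    src[[ax]] <- (lo_dst - o):(hi_dst - o)
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] +
      w[k] * a[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Real-time functional localizer by growing-window correlation
#'
#' Consumes volumes in acquisition order. Within each localizer block the
#' baseline is the mean of block-local scans 1-3 and the analyzed response
#' samples are block-local scans 6-8 (covering the expected HRF maximum after
#' tapping at scans 3-4). For every voxel the statistic is the Pearson
#' correlation between the observed baseline-referenced percent signal and
#' the HRF-convolved task regressor restricted to the used scans, accumulated
#' incrementally (growing window) over completed blocks; the map is updated
#' after every block and the final map returned after the last one.
#'
#' @param stream a [scan_stream()] (or a [volume_series()], which is
#'   streamed).
#' @param design the localizer [block_design()].
#' @param hrf a [canonical_hrf()].
#' @param fwhm_mm smoothing kernel FWHM in mm applied to each incoming
#'   volume (default 3).
#' @param baseline_scans,response_scans block-local 1-based scan windows.
#' @return object of class `activation_map`: `r` (3D array of correlations,
#'   NaN where the voxel has zero variance over the used scans), `per_block_r`
#'   (list of intermediate maps), window metadata.
#' @export
incremental_localizer <- function(stream, design = localizer_design(),
                                  hrf = canonical_hrf(), fwhm_mm = 3,
                                  baseline_scans = 1:3,
                                  response_scans = 6:8) {
  if (inherits(stream, "volume_series")) stream <- scan_stream(stream)
  stopifnot(inherits(stream, "scan_stream"), inherits(design, "block_design"))
  tr <- stream$tr_seconds
  kernel <- make_hrf(hrf, tr)
  reg <- bold_regressor(design, kernel, efforts = 1)
  used_local <- sort(unique(c(baseline_scans, response_scans)))
  spb <- design$scans_per_block

  sx <- sy <- sxy <- sxx <- syy <- NULL
  n_acc <- 0L
  dims <- NULL
  per_block_r <- vector("list", design$n_blocks)
  buf <- NULL

  running_r <- function() {
    vx <- n_acc * sxx - sx^2
    vy <- n_acc * syy - sy^2
    r <- (n_acc * sxy - sx * sy) / sqrt(pmax(vx, 0) * vy)
    r[vx <= 0 | vy <= 0] <- NaN
    array(r, dims)
  }

  for (b in seq_len(design$n_blocks)) {
    for (s in seq_len(spb)) {
      sc <- stream$next_scan()
      vol <- smooth_volume(sc$volume, fwhm_mm, stream$voxel_size_mm)
      if (is.null(buf)) {
        dims <- dim(vol)
        buf <- matrix(0, prod(dims), spb)
        sx <- sy <- sxy <- sxx <- syy <- numeric(prod(dims))
      }
      buf[, s] <- vol
    }
    base <- rowMeans(buf[, baseline_scans, drop = FALSE])
    obs <- 100 * (buf[, used_local, drop = FALSE] / base - 1)
    y <- reg[(b - 1L) * spb + used_local]
    n_acc <- n_acc + length(used_local)
    sx <- sx + rowSums(obs)
    sxx <- sxx + rowSums(obs^2)
    sxy <- sxy + as.vector(obs %*% y)
    sy <- sy + sum(y)
    syy <- syy + sum(y^2)
    per_block_r[[b]] <- running_r()
  }

  structure(list(r = per_block_r[[design$n_blocks]],
                 per_block_r = per_block_r,
                 baseline_scans = baseline_scans,
                 response_scans = response_scans,
                 fwhm_mm = fwhm_mm, design = design),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat("Activation map: ", paste(dim(x$r), collapse = " x "),
      " voxels, windows baseline ", paste(range(x$baseline_scans),
                                          collapse = "-"),
      " / response ", paste(range(x$response_scans), collapse = "-"),
      ", smoothing ", x$fwhm_mm, " mm FWHM\n", sep = "")
  invisible(x)
}

# 6-connected components of a logical 3D mask; returns integer label array
label_clusters_6 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  coords <- arrayInd(idx, d)
  lut <- array(0L, d); lut[idx] <- seq_along(idx)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  lab <- 0L
  for (start in seq_along(idx)) {
    if (labels[idx[start]] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[idx[start]] <- lab
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      p <- coords[i, ]
      for (k in 1:6) {
        q <- p + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        j <- lut[q[1], q[2], q[3]]
        if (j != 0L && labels[idx[j]] == 0L) {
          labels[idx[j]] <- lab
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Extract the reference ROI from an activation map
#'
#' Thresholds the correlation map at `r_threshold` and keeps the largest
#' 6-connected cluster with at least `min_cluster_voxels` voxels. Failure to
#' localize any cluster signals that the measurement should be repeated.
#'
#' @param map an `activation_map` from [incremental_localizer()].
#' @param r_threshold correlation threshold (voxels with `r >= r_threshold`).
#' @param min_cluster_voxels minimum cluster size.
#' @return object of class `roi_mask`: logical 3D `mask`, `n_voxels`, and
#'   provenance fields.
#' @export
extract_roi <- function(map, r_threshold = 0.6, min_cluster_voxels = 5) {
  stopifnot(inherits(map, "activation_map"))
  supra <- !is.na(map$r) & !is.nan(map$r) & map$r >= r_threshold
  labels <- label_clusters_6(supra)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_cluster_voxels)
  if (length(keep) == 0) {
    stop("localization failure: no cluster of >= ", min_cluster_voxels,
         " voxels survives r >= ", r_threshold, "; repeat the measurement")
  }
  best <- keep[which.max(sizes[keep])]
  mask <- labels == best
  structure(list(mask = mask, n_voxels = sum(mask),
                 r_threshold = r_threshold,
                 min_cluster_voxels = min_cluster_voxels,
                 fwhm_mm = map$fwhm_mm),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("ROI mask: ", x$n_voxels, " voxels (r >= ", x$r_threshold,
      ", min cluster ", x$min_cluster_voxels, ", 6-connected)\n", sep = "")
  invisible(x)
}

#' Mean-ROI intensity per scan
#'
#' @param series a [volume_series()] or 4D array.
#' @param roi a [extract_roi()] `roi_mask` or logical 3D array.
#' @return numeric vector, one mean intensity per scan.
#' @export
roi_mean_series <- function(series, roi) {
  data <- if (inherits(series, "volume_series")) series$data else series
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  stopifnot(sum(mask) > 0)
  nt <- dim(data)[4]
  m <- matrix(data, ncol = nt)
  colMeans(m[as.vector(mask), , drop = FALSE])
}

#' Block-referenced percent signal change of a mean-ROI series
#'
#' Converts a raw mean-ROI intensity series to percent signal change, each
#' block referenced to the mean intensity of its own baseline scans.
#'
#' @param x numeric vector of mean-ROI intensities (one per scan).
#' @param design a [block_design()].
#' @param baseline_scans block-local 1-based baseline scan indices.
#' @return numeric vector of percent signal change, class `roi_timeseries`.
#' @export
roi_block_percent <- function(x, design, baseline_scans = 1:5) {
  stopifnot(length(x) == n_scans(design))
  out <- numeric(length(x))
  for (b in seq_len(design$n_blocks)) {
    sc <- block_scans(design, b)
    base <- mean(x[sc[baseline_scans]])
    out[sc] <- 100 * (x[sc] / base - 1)
  }
  structure(out, class = "roi_timeseries")
}

#' Calibrate a subject: the individual-maximum BOLD response as 100%
#'
#' The maximum detected BOLD signal of the mean-ROI trace during the
#' functional localizer is taken as the maximum achievable activation and set
#' to 100%. Three window conventions are supported:
#' \describe{
#'   \item{`"matched"` (default)}{per-block mean over the 3 scans starting
#'     immediately after tapping (localizer block-local scans 5-7) — the same
#'     post-tapping offsets as the main experiment's scans 8-10 window, so
#'     the HRF-window attenuation cancels exactly in the calibrated ratio.}
#'   \item{`"localizer"`}{per-block mean over the localizer correlation
#'     window, block-local scans 6-8.}
#'   \item{`"scan_max"`}{maximum over all single scans.}
#' }
#' Percent change is computed against the localizer baseline intensity: by
#' default the mean ROI intensity of the first baseline window of the run
#' (scans 1-3, acquired before any task response or undershoot can
#' contaminate it); with `baseline_reference = "block"` each block is
#' referenced to its own scans 1-3 instead. Either way the profile is
#' invariant to any multiplicative intensity gain.
#'
#' @param series the localizer [volume_series()] (or 4D array).
#' @param roi a [extract_roi()] `roi_mask`.
#' @param design the localizer [block_design()].
#' @param convention see Details.
#' @param subject_id identifier stored in the profile.
#' @param baseline_scans block-local baseline window (default 1-3).
#' @param baseline_reference `"run"` (reference = first block's baseline
#'   window) or `"block"` (per-block reference).
#' @return object of class `calibration_profile`: `max_bold_percent` (> 0,
#'   the 100% reference), `roi`, `baseline_intensity`, `convention`.
#' @export
calibrate <- function(series, roi, design = localizer_design(),
                      convention = c("matched", "localizer", "scan_max"),
                      subject_id = "subject", baseline_scans = 1:3,
                      baseline_reference = c("run", "block")) {
  convention <- match.arg(convention)
  baseline_reference <- match.arg(baseline_reference)
  stopifnot(inherits(roi, "roi_mask") || is.logical(roi))
  x <- roi_mean_series(series, roi)
  tap <- segment_scans(design, "tapping")
  win <- switch(convention,
                matched = max(tap) + 1:3,
                localizer = 6:8,
                scan_max = NULL)
  run_base <- mean(x[block_scans(design, 1)[baseline_scans]])
  per_block <- vapply(seq_len(design$n_blocks), function(b) {
    sc <- block_scans(design, b)
    base <- if (baseline_reference == "run") run_base else
      mean(x[sc[baseline_scans]])
    if (convention == "scan_max") {
      max(100 * (x[sc] / base - 1))
    } else {
      100 * (mean(x[sc[win]]) / base - 1)
    }
  }, 0)
  max_bold <- max(per_block)
  if (max_bold <= 0) {
    stop("calibration failure: maximum ROI BOLD response is not positive")
  }
  base_int <- if (baseline_reference == "run") run_base else
    mean(vapply(seq_len(design$n_blocks), function(b) {
      mean(x[block_scans(design, b)[baseline_scans]])
    }, 0))
  structure(list(subject_id = subject_id, roi = roi,
                 max_bold_percent = max_bold,
                 baseline_intensity = base_int,
                 convention = convention),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("Calibration profile '", x$subject_id, "': max BOLD ",
      sprintf("%.3f", x$max_bold_percent), "% = 100% reference (",
      x$convention, " window, ROI ",
      if (inherits(x$roi, "roi_mask")) x$roi$n_voxels else sum(x$roi),
      " voxels)\n", sep = "")
  invisible(x)
}

#' Write / read a calibration profile as JSON
#' @param profile a `calibration_profile`.
#' @param path output path.
#' @export
write_calibration_profile <- function(profile, path) {
  mask <- if (inherits(profile$roi, "roi_mask")) profile$roi$mask else profile$roi
  obj <- list(subject_id = profile$subject_id,
              max_bold_percent = profile$max_bold_percent,
              baseline_intensity = profile$baseline_intensity,
              convention = profile$convention,
              roi_dims = dim(mask),
              roi_voxels = which(mask))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_profile
#' @export
read_calibration_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- array(FALSE, obj$roi_dims)
  mask[obj$roi_voxels] <- TRUE
  roi <- structure(list(mask = mask, n_voxels = sum(mask),
                        r_threshold = NA_real_, min_cluster_voxels = NA_integer_,
                        fwhm_mm = NA_real_),
                   class = "roi_mask")
  structure(list(subject_id = obj$subject_id, roi = roi,
                 max_bold_percent = obj$max_bold_percent,
                 baseline_intensity = obj$baseline_intensity,
                 convention = obj$convention),
            class = "calibration_profile")
}

#' Per-block raw response by the sliding-window technique
#'
#' For every block, baseline = mean percent signal of block-local scans 1-5
#' (the five scans before finger tapping) and response = mean of the 3 scans
#' (6 s at TR 2 s) immediately following the two tapping scans (block-local
#' scans 8-10). The raw block response is response minus baseline in
#' percent-change units; the window slides block by block using only that
#' block's baseline and signal.
#'
#' @param values percent-signal-change series (e.g. from
#'   [roi_block_percent()]), one value per scan.
#' @param design a [block_design()] whose layout contains baseline and
#'   tapping segments.
#' @return data frame with `block`, `raw_response_percent`.
#' @export
sliding_window_activation <- function(values, design) {
  stopifnot(length(values) == n_scans(design))
  base_local <- segment_scans(design, "baseline")
  tap_local <- segment_scans(design, "tapping")
  stopifnot(length(base_local) > 0, length(tap_local) > 0)
  resp_local <- max(tap_local) + 1:3
  if (max(resp_local) > design$scans_per_block) {
    stop("block too short: response window needs scans up to ",
         max(resp_local), " but blocks have ", design$scans_per_block)
  }
  raw <- vapply(seq_len(design$n_blocks), function(b) {
    sc <- block_scans(design, b)
    mean(values[sc[resp_local]]) - mean(values[sc[base_local]])
  }, 0)
  data.frame(block = seq_len(design$n_blocks), raw_response_percent = raw)
}

#' Write an activation map or ROI mask as NIfTI
#' @param x an `activation_map` or `roi_mask`.
#' @param path output path.
#' @param voxel_size_mm voxel sizes recorded in the header.
#' @export
write_map_nifti <- function(x, path, voxel_size_mm = c(3, 3, 4)) {
  arr <- if (inherits(x, "activation_map")) x$r else x$mask * 1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
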