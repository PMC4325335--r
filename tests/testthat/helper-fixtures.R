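# Shared fixtures: everything is generated in code at test time.

tiny_site <- function(id = "siteA", field = "3T", dims = c(16L, 16L),
                      n_slices = 10L) {
  site_config(id, tr_seconds = 2, n_slices = n_slices, matrix_size = dims,
              field_label = field)
}

tiny_subject <- function(id = "subj", amp = 2.5, center = c(8L, 8L, 5L),
                         radius = 2.5, noise = 0, drift = 0,
                         shape = "gaussian") {
  subject_profile(id, amp, activation_center = center,
                  activation_radius = radius, noise_sd_percent = noise,
                  drift_amplitude_percent = drift, profile_shape = shape)
}

# small but structurally complete two-site config (k targets per region
# per task keeps sessions fast)
tiny_config <- function(k = 2L, trigger = 10L) {
  experiment_config(
    sites = list(tiny_site("siteA", "3T"), tiny_site("siteB", "7T")),
    output_channels = list(
      output_channel("siteA", location = "siteA_out.txt",
                     trigger_scans = trigger),
      output_channel("siteB", location = "siteB_out.txt",
                     trigger_scans = trigger)),
    receive_channels = list(
      receive_channel("siteA", location = "siteB_out.txt",
                      trigger_scans = trigger),
      receive_channel("siteB", location = "siteA_out.txt",
                      trigger_scans = trigger)),
    visualization = visualization_spec(
      list(list(id = "sphere_siteA", owner = "siteA", visible_to = "siteA"),
           list(id = "sphere_siteB", owner = "siteB", visible_to = "siteB")),
      "main", c(siteA = 1, siteB = 1)),
    schedule_params = list(
      tasks = c("single", "cooperation", "competition"),
      runs_per_task = 2L * k, targets_per_region_per_task = k,
      block_layout = data.frame(
        segment = c("baseline", "tapping", "rest", "feedback"),
        n_scans = c(5L, 2L, 7L, 1L))))
}

# Independent brute-force oracle for the localizer statistic: assembles the
# pooled observed / expected vectors with plain loops and uses stats::cor.
oracle_localizer_r <- function(data4d, design, kernel, fwhm_mm,
                               voxel_size_mm, baseline_scans = 1:3,
                               response_scans = 6:8) {
  reg <- bold_regressor(design, kernel, efforts = 1)
  used <- sort(unique(c(baseline_scans, response_scans)))
  nt <- dim(data4d)[4]
  sm <- array(0, dim(data4d))
  for (t in seq_len(nt)) {
    sm[, , , t] <- smooth_volume(data4d[, , , t], fwhm_mm, voxel_size_mm)
  }
  dims <- dim(data4d)[1:3]
  r <- array(NaN, dims)
  for (v in seq_len(prod(dims))) {
    ijk <- arrayInd(v, dims)
    obs <- c(); exp_ <- c()
    for (b in seq_len(design$n_blocks)) {
      sc <- block_scans(design, b)
      ts <- sm[ijk[1], ijk[2], ijk[3], sc]
      base <- mean(ts[baseline_scans])
      obs <- c(obs, 100 * (ts[used] / base - 1))
      exp_ <- c(exp_, reg[sc[used]])
    }
    if (stats::sd(obs) > 0) r[v] <- stats::cor(obs, exp_)
  }
  r
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

random_message <- function() {
  n <- sample(1:3, 1)
  keys <- sample(c("actlevel", "reward_human", "reward_opponent",
                   "stepsize"), n)
  payload <- stats::setNames(lapply(keys, function(k) {
    if (stats::runif(1) < 0.5) sample.int(100, 1) else
      as.numeric(sprintf("%.6f", stats::rnorm(1, 50, 30)))  # wire-format grid
  }), keys)
  exchange_message(sample(c("siteA", "siteB"), 1), sample.int(60, 1),
                   sample(c(10L, 15L), 1), payload,
                   timestamp = "2015-02-12T00:00:00")
}

make_estimate <- function(rel) {
  structure(list(block_index = 1L, raw_response_percent = rel / 100 * 2.5,
                 relative_percent = rel, band = classify_band(rel)),
            class = "activation_estimate")
}

paper_edl_fragment <- function() {
  paste0(
    '<EDL VERSION="1.2">',
    '<SITE ID="siteA" TR="2" NSLICES="31" MATRIX="64 64" FIELD="3T"/>',
    '<OUTPUTMODULE SITE="siteA" STATE="ON" TYPE="FILE" WRITETIMESTAMP="ON" ',
    'MODE="APPEND"><LOCATION>[IP]\\[PATH]\\[FILENAME].TXT</LOCATION>',
    '<CWOUTPUTSCAN>10</CWOUTPUTSCAN>',
    '<OUTPUTPARAMS OUT_TEMPLATE_ID="OFF" OUT_TEMPLATE_LABEL="OFF" ',
    'OUT_TEMPLATE_ACTLEVEL="ON" OUT_SOURCE_IMG="OFF" OUT_MONEY_HUMAN="ON" ',
    'OUT_MONEY_OPPONENT="OFF" OUT_HUMAN_STEPSIZE="OFF"></OUTPUTPARAMS>',
    '</OUTPUTMODULE></EDL>')
}
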