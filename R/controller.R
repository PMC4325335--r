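#' Did an activation estimate reach the target region?
#'
#' A target is reached iff the classified band matches it: strong (U) for an
#' upper target, weak (L) for a lower one. An insufficient activation never
#' reaches a target.
#'
#' @param estimate an [activation_estimate()] (or its band string).
#' @param target `"U"` or `"L"`.
#' @export
reach_target <- function(estimate, target) {
  band <- if (inherits(estimate, "activation_estimate")) estimate$band else
    estimate
  stopifnot(target %in% c("U", "L"))
  (target == "U" && band == "strong_U") ||
    (target == "L" && band == "weak_L")
}

score_result <- function(success_a, success_b, reward_a, reward_b,
                         flag = "") {
  list(success = c(success_a, success_b),
       reward_delta = c(as.integer(reward_a), as.integer(reward_b)),
       flag = flag)
}

#' Reward rules for the three tasks
#'
#' `score_single`: each subject is rewarded independently when it reaches the
#' target. `score_cooperation`: both are rewarded only when both reach the
#' target; otherwise neither. `score_competition`: among the participants
#' whose band matches the target, the one whose relative activation is
#' closest to the target band's reference point (L: 45, U: 80, the band
#' midpoints) wins the reward; exact ties reward both; if neither matches, no
#' reward. A competition success flag records whether the participant reached
#' the requested region (both can succeed; the reward goes to the more
#' accurate). In the social tasks a missing partner estimate invokes the
#' timeout rule: the block is unsuccessful for both and flagged `"timeout"`.
#'
#' @param a,b [activation_estimate()] objects (`b` may be `NULL` when the
#'   partner's message never arrived).
#' @param target `"U"` or `"L"`.
#' @param reference_points accuracy reference per band for competition.
#' @return list with `success` (logical pair), `reward_delta` (integer pair)
#'   and `flag` (`""` or `"timeout"`). `score_single` returns scalars.
#' @export
score_single <- function(a, target) {
  ok <- reach_target(a, target)
  list(success = ok, reward_delta = as.integer(ok), flag = "")
}

#' @rdname score_single
#' @export
score_cooperation <- function(a, b, target) {
  if (is.null(a) || is.null(b)) {
    return(score_result(FALSE, FALSE, 0, 0, flag = "timeout"))
  }
  both <- reach_target(a, target) && reach_target(b, target)
  score_result(both, both, both, both)
}

#' @rdname score_single
#' @export
score_competition <- function(a, b, target,
                              reference_points = c(L = 45, U = 80)) {
  if (is.null(a) || is.null(b)) {
    return(score_result(FALSE, FALSE, 0, 0, flag = "timeout"))
  }
  ref <- reference_points[[target]]
  ok_a <- reach_target(a, target)
  ok_b <- reach_target(b, target)
  if (!ok_a && !ok_b) return(score_result(FALSE, FALSE, 0, 0))
  if (ok_a && !ok_b) return(score_result(TRUE, FALSE, 1, 0))
  if (!ok_a && ok_b) return(score_result(FALSE, TRUE, 0, 1))
  da <- abs(a$relative_percent - ref)
  db <- abs(b$relative_percent - ref)
  score_result(TRUE, TRUE, da <= db, db <= da)
}

#' Simulated effort policy
#'
#' Maps a target region to an intended effort: a Gaussian draw around the
#' region's mean effort (defaults aim at the band midpoints, 45% for L and
#' 80% for U), clipped to `[0, 1]`, with an optional attention-lapse
#' probability producing near-zero effort. These are simulation devices for
#' synthetic subjects, not a model of the study's volunteers.
#'
#' @param means named pair of intended efforts for targets L and U.
#' @param sd behavioral noise SD on the effort scale.
#' @param lapse_prob probability of an attention lapse (effort 0.05).
#' @return function `(target) -> effort`, drawing from the current RNG
#'   stream.
#' @export
effort_policy <- function(means = c(L = 0.45, U = 0.80), sd = 0.08,
                          lapse_prob = 0) {
  stopifnot(all(c("L", "U") %in% names(means)), sd >= 0,
            lapse_prob >= 0, lapse_prob <= 1)
  function(target) {
    if (lapse_prob > 0 && stats::runif(1) < lapse_prob) return(0.05)
    min(1, max(0, stats::rnorm(1, means[[target]], sd)))
  }
}

run_site_localizer <- function(subject, site, seed, hrf, fwhm_mm = 3,
                               r_threshold = 0.6, min_cluster_voxels = 5,
                               convention = "matched", gain = 1) {
  design <- localizer_design()
  series <- simulate_run(design, subject, site, efforts = 1, seed = seed,
                         hrf = hrf, gain = gain)
  map <- incremental_localizer(scan_stream(series), design, hrf = hrf,
                               fwhm_mm = fwhm_mm)
  roi <- extract_roi(map, r_threshold, min_cluster_voxels)
  profile <- calibrate(series, roi, design, convention = convention,
                       subject_id = subject$subject_id)
  list(series = series, map = map, roi = roi, profile = profile)
}

sim_timestamp <- function(global_scan, tr) {
  format(as.POSIXct("2015-02-12 00:00:00", tz = "UTC") +
           (global_scan - 1) * tr,
         "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Run a complete two-site session
#'
#' Per site: functional localizer, ROI extraction and calibration, then the
#' main experiment on a shared randomized schedule. Within every main block
#' each site estimates its relative activation with the sliding-window
#' technique, writes its activation level and cumulative reward to its output
#' channel at the configured trigger scans, reads the partner's message at
#' the feedback scan, and scores the block with the task-appropriate reward
#' rule. The session is fully reproducible under its seeds: exchange
#' messages are stamped with a simulated clock derived from the scan index.
#'
#' @param config an [experiment_config()] with two sites.
#' @param subjects list of two [subject_profile()] objects.
#' @param policies list of two effort policies (see [effort_policy()]).
#' @param seed master seed; per-site simulation and behavior seeds are
#'   derived from it unless given explicitly.
#' @param platform_root directory for the exchange platform (channel file
#'   names are taken from the config locations).
#' @param site_seeds,behavior_seeds optional integer pairs; pass equal values
#'   to share the physiological / behavioral noise across sites (paired
#'   designs).
#' @param hrf a [canonical_hrf()].
#' @param fwhm_mm localizer smoothing FWHM (mm).
#' @param r_threshold,min_cluster_voxels ROI extraction parameters.
#' @param calibration_convention see [calibrate()].
#' @param intensity_gains multiplicative raw-intensity gain per site
#'   (scanner hardware scaling; percent change cancels it, so outcomes are
#'   invariant).
#' @param drop_messages optional function `(site_index, block) -> logical`;
#'   `TRUE` suppresses that site's outgoing message (to exercise the timeout
#'   rule).
#' @return object of class `session_log`: `log` (one [data.frame] row per
#'   block with both sites' estimates, successes, reward deltas and
#'   cumulative rewards), `summary` (a `session_summary`), `profiles`,
#'   `design`.
#' @export
run_session <- function(config, subjects, policies = NULL, seed = 1,
                        platform_root = tempfile("exchange"),
                        site_seeds = NULL, behavior_seeds = NULL,
                        hrf = canonical_hrf(), fwhm_mm = 3,
                        r_threshold = 0.6, min_cluster_voxels = 5,
                        calibration_convention = "matched",
                        intensity_gains = c(1, 1), drop_messages = NULL) {
  stopifnot(inherits(config, "experiment_config"),
            length(config$sites) == 2, length(subjects) == 2)
  if (is.null(policies)) policies <- list(effort_policy(), effort_policy())
  if (is.null(site_seeds)) site_seeds <- seed + c(101L, 202L)
  if (is.null(behavior_seeds)) behavior_seeds <- seed + c(303L, 404L)

  design <- main_design(config, seed = seed)
  n_blk <- design$n_blocks
  tr <- config$sites[[1]]$tr_seconds
  platform <- exchange_platform(platform_root)

  site_ids <- vapply(config$sites, `[[`, "", "site_id")
  find_channel <- function(channels, id) {
    for (ch in channels) if (ch$site == id) return(ch)
    stop("no channel declared for site '", id, "'")
  }
  out_ch <- lapply(site_ids, find_channel, channels = config$output_channels)
  rec_ch <- lapply(site_ids, find_channel, channels = config$receive_channels)

  # localizer + calibration per site
  loc <- lapply(1:2, function(i) {
    run_site_localizer(subjects[[i]], config$sites[[i]], site_seeds[i],
                       hrf, fwhm_mm, r_threshold, min_cluster_voxels,
                       calibration_convention, gain = intensity_gains[i])
  })

  # intended efforts per block per site (behavioral noise)
  efforts <- lapply(1:2, function(i) {
    withr_seed(behavior_seeds[i],
               vapply(design$targets, policies[[i]], 0))
  })

  # main runs
  main <- lapply(1:2, function(i) {
    simulate_run(design, subjects[[i]], config$sites[[i]],
                 efforts = efforts[[i]], seed = site_seeds[i] + 1L,
                 hrf = hrf, gain = intensity_gains[i])
  })

  # per-block estimates per site
  est <- lapply(1:2, function(i) {
    x <- roi_mean_series(main[[i]], loc[[i]]$roi)
    pct <- roi_block_percent(x, design,
                             baseline_scans = segment_scans(design, "baseline"))
    sw <- sliding_window_activation(pct, design)
    lapply(seq_len(n_blk), function(b) {
      activation_estimate(b, sw$raw_response_percent[b], loc[[i]]$profile)
    })
  })

  resp_end <- max(segment_scans(design, "tapping")) + 3L
  cum <- c(0L, 0L)
  cursors <- c(0L, 0L)
  rows <- vector("list", n_blk)
  for (b in seq_len(n_blk)) {
    partner_est <- list(NULL, NULL)
    for (s in seq_len(design$scans_per_block)) {
      g <- (b - 1L) * design$scans_per_block + s
      for (i in 1:2) {
        if (exchange_due(s, out_ch[[i]]) &&
            (is.null(drop_messages) || !isTRUE(drop_messages(i, b)))) {
          if (s < resp_end) {
            stop("trigger scan ", s, " precedes the end of the response ",
                 "window (scan ", resp_end, "); the activation level is ",
                 "not yet available")
          }
          payload <- list()
          if ("actlevel" %in% out_ch[[i]]$params) {
            payload$actlevel <- est[[i]][[b]]$relative_percent
          }
          if ("reward_human" %in% out_ch[[i]]$params) {
            payload$reward_human <- cum[i]
          }
          write_message(platform, out_ch[[i]],
                        exchange_message(site_ids[i], b, s, payload,
                                         timestamp = sim_timestamp(g, tr)))
        }
      }
      if (s == design$scans_per_block) {  # feedback scan: poll partner
        for (i in 1:2) {
          rm_ <- read_messages(platform, rec_ch[[i]], cursors[i])
          cursors[i] <- rm_$cursor
          for (m in rm_$messages) {
            if (m$block_index == b && !is.null(m$payload$actlevel)) {
              partner_est[[i]] <- structure(
                list(block_index = b, raw_response_percent = NA_real_,
                     relative_percent = m$payload$actlevel,
                     band = classify_band(m$payload$actlevel)),
                class = "activation_estimate")
            }
          }
        }
      }
    }
    task <- design$tasks[b]
    target <- design$targets[b]
    if (task == "single") {
      ra <- score_single(est[[1]][[b]], target)
      rb <- score_single(est[[2]][[b]], target)
      sc <- score_result(ra$success, rb$success,
                         ra$reward_delta, rb$reward_delta)
    } else {
      scorer <- if (task == "cooperation") score_cooperation else
        score_competition
      sc <- scorer(est[[1]][[b]], partner_est[[1]], target)
      # symmetric check from site B's perspective (same rule, same inputs)
      sc_b <- scorer(partner_est[[2]], est[[2]][[b]], target)
      sc$success[2] <- sc_b$success[2]
      sc$reward_delta[2] <- sc_b$reward_delta[2]
      if (sc_b$flag == "timeout") sc$flag <- "timeout"
    }
    cum <- cum + sc$reward_delta
    rows[[b]] <- data.frame(
      block = b, task = task, target = target,
      raw_a = est[[1]][[b]]$raw_response_percent,
      rel_a = est[[1]][[b]]$relative_percent,
      band_a = est[[1]][[b]]$band,
      raw_b = est[[2]][[b]]$raw_response_percent,
      rel_b = est[[2]][[b]]$relative_percent,
      band_b = est[[2]][[b]]$band,
      success_a = sc$success[1], success_b = sc$success[2],
      reward_a = sc$reward_delta[1], reward_b = sc$reward_delta[2],
      cum_reward_a = cum[1], cum_reward_b = cum[2],
      flag = sc$flag,
      stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, rows)
  structure(list(log = log,
                 summary = summarize_session(log, seed = seed),
                 profiles = lapply(loc, `[[`, "profile"),
                 rois = lapply(loc, `[[`, "roi"),
                 design = design,
                 site_ids = site_ids,
                 platform_root = platform$root),
            class = "session_log")
}

#' Summarize a session log
#'
#' Per-site and per-task success percentages plus a paired sign-flip
#' permutation test for a site (field-strength) effect on the per-block
#' success indicators.
#'
#' @param log the per-block data frame from [run_session()] (or a
#'   `session_log`).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation draw.
#' @return object of class `session_summary`.
#' @export
summarize_session <- function(log, n_perm = 2000, seed = 1) {
  if (inherits(log, "session_log")) log <- log$log
  tasks <- sort(unique(log$task))
  per_task <- t(vapply(tasks, function(tk) {
    sel <- log$task == tk
    c(site_a = 100 * mean(log$success_a[sel]),
      site_b = 100 * mean(log$success_b[sel]),
      n_blocks = sum(sel))
  }, c(site_a = 0, site_b = 0, n_blocks = 0)))
  overall <- c(site_a = 100 * mean(log$success_a),
               site_b = 100 * mean(log$success_b))
  d <- as.numeric(log$success_a) - as.numeric(log$success_b)
  obs <- abs(mean(d))
  p <- withr_seed(seed, {
    flips <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                    nrow = n_perm)
    perm <- abs(as.vector(flips %*% d) / length(d))
    (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  })
  structure(list(per_task = per_task, overall = overall,
                 site_difference = unname(overall[1] - overall[2]),
                 permutation_p = p, n_perm = n_perm),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat("Session summary (success %):\n")
  print(round(x$per_task, 1))
  cat(sprintf("overall: site A %.1f%%, site B %.1f%% (difference %.1f pp, permutation p = %.3f)\n",
              x$overall[1], x$overall[2], x$site_difference,
              x$permutation_p))
  invisible(x)
}

#' Write a session log as TSV and its summary as JSON
#'
#' @param session a `session_log` from [run_session()].
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
write_session_log <- function(session, dir) {
  stopifnot(inherits(session, "session_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(dir, "session_log.tsv")
  utils::write.table(session$log, log_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- session$summary
  sum_path <- file.path(dir, "session_summary.json")
  jsonlite::write_json(
    list(per_task = as.data.frame(cbind(task = rownames(s$per_task),
                                        as.data.frame(s$per_task))),
         overall = as.list(s$overall),
         site_difference = s$site_difference,
         permutation_p = s$permutation_p),
    sum_path, auto_unbox = TRUE, digits = NA)
  invisible(c(log = log_path, summary = sum_path))
}

#' Group amplitude summary: mean response curves and percent increase
#'
#' For each group, subjects' localizer response curves are averaged first and
#' the maximum of the group-mean curve is taken (this differs from the mean
#' of the individual maxima). The relative percent increase of group 2 over
#' group 1 is reported.
#'
#' @param group_a,group_b either a matrix (subjects x scans) of mean-ROI
#'   percent-signal curves, or a numeric vector treated as a single
#'   (group-mean) curve; a scalar is the group-mean maximum itself.
#' @return list with `mean_max` (pair of group-mean maximum amplitudes) and
#'   `percent_increase` (of group B over group A).
#' @export
group_amplitude_summary <- function(group_a, group_b) {
  gmax <- function(g) {
    if (is.matrix(g)) {
      if (nrow(g) == 0) stop("empty group")
      max(colMeans(g))
    } else {
      if (length(g) == 0) stop("empty group")
      max(as.numeric(g))
    }
  }
  a <- gmax(group_a); b <- gmax(group_b)
  list(mean_max = c(a, b), percent_increase = 100 * (b - a) / a)
}
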