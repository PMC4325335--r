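test_that("target reaching requires the matching band", {
  expect_true(reach_target(make_estimate(45), "L"))
  expect_false(reach_target(make_estimate(20), "L"))   # insufficient
  expect_false(reach_target(make_estimate(75), "L"))   # wrong region
  expect_true(reach_target(make_estimate(75), "U"))
  expect_false(reach_target(make_estimate(45), "U"))
  expect_false(reach_target(make_estimate(20), "U"))
})

test_that("single-task scoring is independent of the partner", {
  hit <- score_single(make_estimate(45), "L")
  expect_true(hit$success)
  expect_equal(hit$reward_delta, 1L)
  miss <- score_single(make_estimate(20), "L")
  expect_false(miss$success)
  expect_equal(miss$reward_delta, 0L)
})

test_that("cooperation rewards both only when both reach the target", {
  both <- score_cooperation(make_estimate(45), make_estimate(50), "L")
  expect_equal(both$reward_delta, c(1L, 1L))
  one <- score_cooperation(make_estimate(45), make_estimate(75), "L")
  expect_equal(one$reward_delta, c(0L, 0L))
  expect_false(any(one$success))
  none <- score_cooperation(make_estimate(10), make_estimate(5), "L")
  expect_equal(none$reward_delta, c(0L, 0L))
})

test_that("competition rewards the most accurate eligible participant", {
  # both in band: closer to the L reference point (45) wins the reward,
  # but both reached the requested region
  r <- score_competition(make_estimate(44), make_estimate(58), "L")
  expect_equal(r$reward_delta, c(1L, 0L))
  expect_equal(r$success, c(TRUE, TRUE))
  r2 <- score_competition(make_estimate(58), make_estimate(44), "L")
  expect_equal(r2$reward_delta, c(0L, 1L))
  # only one eligible: wins regardless of distance
  r3 <- score_competition(make_estimate(59.9), make_estimate(75), "L")
  expect_equal(r3$reward_delta, c(1L, 0L))
  # exact tie rewards both
  r4 <- score_competition(make_estimate(45), make_estimate(45), "L")
  expect_equal(r4$reward_delta, c(1L, 1L))
  # neither eligible: no reward
  r5 <- score_competition(make_estimate(10), make_estimate(75), "L")
  expect_equal(r5$reward_delta, c(0L, 0L))
  # U band uses the 80 reference
  r6 <- score_competition(make_estimate(78), make_estimate(95), "U")
  expect_equal(r6$reward_delta, c(1L, 0L))
})

test_that("a missing partner estimate invokes the timeout rule", {
  t1 <- score_cooperation(make_estimate(45), NULL, "L")
  expect_equal(t1$flag, "timeout")
  expect_equal(t1$reward_delta, c(0L, 0L))
  t2 <- score_competition(NULL, make_estimate(45), "L")
  expect_equal(t2$flag, "timeout")
  expect_false(any(t2$success))
})

test_that("noiseless subjects with ideal effort policies succeed in every task", {
  cfg <- tiny_config(k = 2L)
  subs <- list(tiny_subject("a", 2.5), tiny_subject("b", 4.0))
  ideal <- function(target) if (target == "L") 0.45 else 0.80
  pols <- list(function(t) ideal(t), function(t) ideal(t))
  ses <- run_session(cfg, subs, policies = pols, seed = 3)
  expect_true(all(ses$log$success_a))
  expect_true(all(ses$log$success_b))
  expect_equal(unname(ses$summary$overall), c(100, 100))
})

test_that("sessions are reproducible byte for byte under a seed", {
  cfg <- tiny_config(k = 1L)
  subs <- list(tiny_subject("a", 2.5, noise = 0.3, drift = 0.1),
               tiny_subject("b", 4.0, noise = 0.5, drift = 0.15))
  s1 <- run_session(cfg, subs, seed = 12)
  s2 <- run_session(cfg, subs, seed = 12)
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_session_log(s1, d1)
  write_session_log(s2, d2)
  expect_identical(readLines(file.path(d1, "session_log.tsv")),
                   readLines(file.path(d2, "session_log.tsv")))
  # and the exchange files are identical too (simulated clock)
  fa <- sort(list.files(s1$platform_root, full.names = TRUE))
  fb <- sort(list.files(s2$platform_root, full.names = TRUE))
  expect_identical(lapply(fa, readLines), lapply(fb, readLines))
})

test_that("reward accounting is conserved and consistent per task", {
  cfg <- tiny_config(k = 2L)
  subs <- list(tiny_subject("a", 2.5, noise = 0.4, drift = 0.1),
               tiny_subject("b", 4.0, noise = 0.6, drift = 0.1))
  pols <- list(effort_policy(sd = 0.15), effort_policy(sd = 0.15))
  ses <- run_session(cfg, subs, policies = pols, seed = 44)
  log <- ses$log
  coop <- log[log$task == "cooperation", ]
  expect_true(all(coop$reward_a + coop$reward_b %in% c(0L, 2L)))
  comp <- log[log$task == "competition", ]
  expect_true(all(comp$reward_a + comp$reward_b <= 2L))
  expect_equal(log$cum_reward_a, cumsum(log$reward_a))
  expect_equal(log$cum_reward_b, cumsum(log$reward_b))
  # schedule conservation
  expect_true(all(table(ses$design$tasks, ses$design$targets) == 2))
  # success flags consistent with the rules given the logged bands
  single <- log[log$task == "single", ]
  expect_equal(single$success_a,
               unname(mapply(function(b, t) reach_target(b, t),
                             single$band_a, single$target)))
})

test_that("single-task outcomes are unaffected by the partner's stream", {
  cfg <- tiny_config(k = 2L)
  subsA <- tiny_subject("a", 2.5, noise = 0.3)
  s1 <- run_session(cfg, list(subsA, tiny_subject("b", 4.0, noise = 0.5)),
                    seed = 19)
  s2 <- run_session(cfg, list(subsA, tiny_subject("b2", 1.4, noise = 0.2)),
                    seed = 19)
  sel <- s1$log$task == "single"
  expect_identical(s1$log$success_a[sel], s2$log$success_a[sel])
  expect_identical(s1$log$rel_a, s2$log$rel_a)
})

test_that("dropped messages are flagged as timeouts and scored unsuccessful", {
  cfg <- tiny_config(k = 1L)
  subs <- list(tiny_subject("a", 2.5), tiny_subject("b", 4.0))
  ideal <- list(function(t) if (t == "L") 0.45 else 0.80,
                function(t) if (t == "L") 0.45 else 0.80)
  ses <- run_session(cfg, subs, policies = ideal, seed = 3,
                     drop_messages = function(site, block) site == 2)
  social <- ses$log$task != "single"
  expect_true(all(ses$log$flag[social] == "timeout"))
  expect_true(all(!ses$log$success_a[social]))
  # single blocks are unaffected by the partner's silence
  expect_true(all(ses$log$success_a[!social]))
})

test_that("system-level gain invariance: intensity gain leaves outcomes unchanged", {
  cfg <- tiny_config(k = 1L)
  subs <- list(tiny_subject("a", 2.5, noise = 0.3), tiny_subject("b", 4.0))
  base <- run_session(cfg, subs, seed = 21)
  # same session but site A's scanner intensities multiplied by 2.4:
  # percent change cancels the gain, so the log is identical
  with_gain <- run_session(cfg, subs, seed = 21,
                           intensity_gains = c(2.4, 1))
  expect_equal(base$log, with_gain$log, tolerance = 1e-10)
})

test_that("group amplitude summary averages curves before taking the maximum", {
  # printed group means: 60% higher at 7T (rounds to 60)
  s <- group_amplitude_summary(2.17, 3.48)
  expect_equal(round(s$percent_increase), 60)
  expect_equal(s$mean_max, c(2.17, 3.48))
  expect_equal(group_amplitude_summary(2.5, 2.5)$percent_increase, 0)
  expect_error(group_amplitude_summary(numeric(0), 1), "empty")

  # mean of individual maxima differs from the max of the mean curve
  maxima_3t <- c(2.69, 2.95, 3.19, 1.28, 1.87, 1.51)
  expect_equal(mean(maxima_3t), 2.248, tolerance = 1e-3)
  # curves peaking at different lags: max of mean < mean of maxima
  lags <- seq(0, 30, by = 2)
  curves <- t(sapply(seq_along(maxima_3t), function(i) {
    maxima_3t[i] * dnorm(lags, mean = 8 + i, sd = 4) / dnorm(0, sd = 4)
  }))
  s2 <- group_amplitude_summary(curves, curves * 1.6)
  expect_lt(s2$mean_max[1], mean(maxima_3t))
  expect_equal(s2$percent_increase, 60, tolerance = 1e-9)
})
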