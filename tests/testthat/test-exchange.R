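test_that("message lines serialize to the documented tab format", {
  msg <- exchange_message("siteA", 3, 10,
                          list(actlevel = 45.0, reward_human = 2L),
                          timestamp = "2024-01-01T00:00:00")
  expect_equal(format_message_line(msg),
               "2024-01-01T00:00:00\tsiteA\t3\t10\tactlevel=45.000000\treward_human=2")
  expect_equal(format_message_line(msg, write_timestamp = FALSE),
               "siteA\t3\t10\tactlevel=45.000000\treward_human=2")
})

test_that("write/read round trips a message field for field", {
  plat <- exchange_platform(tempfile("exch"))
  ch_out <- output_channel("siteA", location = "a.txt")
  ch_in <- receive_channel("siteB", location = "a.txt")
  msg <- exchange_message("siteA", 3, 10,
                          list(actlevel = 45.0, reward_human = 2L),
                          timestamp = "2024-01-01T00:00:00")
  write_message(plat, ch_out, msg)
  got <- read_messages(plat, ch_in, 0L)
  expect_length(got$messages, 1)
  expect_equal(got$messages[[1]], msg)
  # cursor semantics: nothing new on a second poll
  again <- read_messages(plat, ch_in, got$cursor)
  expect_length(again$messages, 0)
  expect_equal(again$cursor, got$cursor)
})

test_that("writes append exactly one line each and never mutate history", {
  plat <- exchange_platform(tempfile("exch"))
  ch <- output_channel("siteA", location = "a.txt", trigger_scans = c(5L, 10L))
  path <- NULL
  prefix <- NULL
  for (i in 1:5) {
    msg <- exchange_message("siteA", i, 10, list(actlevel = i * 10.0),
                            timestamp = "2015-02-12T00:00:00")
    path <- write_message(plat, ch, msg)
    lines <- readLines(path)
    expect_length(lines, i)
    if (!is.null(prefix)) expect_identical(lines[seq_along(prefix)], prefix)
    prefix <- lines
  }
})

test_that("payload and trigger violations are rejected", {
  plat <- exchange_platform(tempfile("exch"))
  ch <- output_channel("siteA", location = "a.txt", trigger_scans = 10L)
  good <- exchange_message("siteA", 1, 10, list(actlevel = 1.0))
  expect_error(write_message(plat, ch,
                             exchange_message("siteA", 1, 7,
                                              list(actlevel = 1.0))),
               "not a trigger scan")
  expect_error(write_message(plat, ch,
                             exchange_message("siteA", 1, 10,
                                              list(source_img = 1.0))),
               "not in the channel")
  off <- output_channel("siteA", state = FALSE)
  expect_error(write_message(plat, off, good), "inactive")
  expect_error(read_messages(plat, off), "inactive")
})

test_that("exchange_due reflects the configured trigger scans", {
  ch <- output_channel("siteA", location = "a.txt", trigger_scans = c(5L, 10L))
  expect_true(exchange_due(10, ch))
  expect_false(exchange_due(9, ch))
  expect_true(exchange_due(5, ch))
})

test_that("partial trailing lines wait for the next poll; malformed lines are flagged", {
  plat <- exchange_platform(tempfile("exch"))
  ch <- receive_channel("siteA", location = "a.txt")
  path <- file.path(plat$root, "a.txt")
  writeLines("2015-02-12T00:00:00\tsiteB\t1\t10\tactlevel=50.000000", path)
  cat("2015-02-12T00:00:01\tsiteB\t2\t10\tactl", file = path, append = TRUE)
  got <- read_messages(plat, ch, 0L)
  expect_length(got$messages, 1)
  expect_equal(got$messages[[1]]$block_index, 1L)
  # complete the partial line: the next poll picks it up
  cat("evel=60.000000\n", file = path, append = TRUE)
  got2 <- read_messages(plat, ch, got$cursor)
  expect_length(got2$messages, 1)
  expect_equal(got2$messages[[1]]$payload$actlevel, 60)

  writeLines(c("garbage line", "2015-02-12T00:00:02\tsiteB\t3\t10\tactlevel=1.000000"),
             path)
  expect_error(read_messages(plat, ch, 0L), "line 1")
  got3 <- suppressWarnings(read_messages(plat, ch, 0L, on_error = "warn"))
  expect_length(got3$messages, 1)
  expect_equal(got3$messages[[1]]$block_index, 3L)
})

test_that("interleaved writers keep per-channel order", {
  plat <- exchange_platform(tempfile("exch"))
  chA <- output_channel("siteA", location = "a.txt")
  chB <- output_channel("siteB", location = "b.txt")
  written <- list(siteA = c(), siteB = c())
  set.seed(12)
  for (i in 1:20) {
    site <- sample(c("siteA", "siteB"), 1)
    ch <- if (site == "siteA") chA else chB
    write_message(plat, ch, exchange_message(site, i, 10,
                                             list(actlevel = i + 0.5),
                                             timestamp = "2015-02-12T00:00:00"))
    written[[site]] <- c(written[[site]], i)
  }
  gotA <- read_messages(plat, receive_channel("x", location = "a.txt"))
  gotB <- read_messages(plat, receive_channel("x", location = "b.txt"))
  expect_equal(vapply(gotA$messages, `[[`, 0L, "block_index"),
               written$siteA)
  expect_equal(vapply(gotB$messages, `[[`, 0L, "block_index"),
               written$siteB)
  expect_true(all(vapply(gotA$messages, `[[`, "", "site_id") == "siteA"))
})

test_that("random messages survive serialize/parse (property)", {
  set.seed(99)
  for (i in 1:200) {
    msg <- random_message()
    expect_equal(parse_message_line(format_message_line(msg)), msg)
  }
})
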