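#' Central exchange platform
#'
#' A directory acting as the shared information-exchange platform between
#' sites: every declared channel owns one append-only text file of
#' timestamped messages.
#'
#' @param root directory path; created if absent.
#' @return object of class `exchange_platform`.
#' @export
exchange_platform <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  structure(list(root = normalizePath(root)), class = "exchange_platform")
}

channel_file <- function(platform, channel) {
  loc <- channel$location
  if (grepl("^(/|[A-Za-z]:)", loc)) loc else file.path(platform$root,
                                                       basename(loc))
}

#' Construct an exchange message
#'
#' @param site_id sending site.
#' @param block_index block number.
#' @param scan_index block-local 1-based scan index at which the message is
#'   sent.
#' @param payload named list of parameter values (numeric or integer), keys
#'   restricted to the owning channel's configured parameters.
#' @param timestamp ISO-8601 string (`%Y-%m-%dT%H:%M:%S`).
#' @export
exchange_message <- function(site_id, block_index, scan_index, payload,
                             timestamp = format(Sys.time(),
                                                "%Y-%m-%dT%H:%M:%S",
                                                tz = "UTC")) {
  stopifnot(is.list(payload), length(names(payload)) == length(payload),
            all(nzchar(names(payload))))
  structure(list(timestamp = timestamp, site_id = as.character(site_id),
                 block_index = as.integer(block_index),
                 scan_index = as.integer(scan_index),
                 payload = payload),
            class = "exchange_message")
}

format_payload_value <- function(v) {
  if (is.integer(v)) sprintf("%d", v) else sprintf("%.6f", v)
}

#' Serialize / parse one message line
#'
#' One message per line, tab-separated: timestamp (omitted when the channel
#' does not write timestamps), site id, block index, scan index, then
#' `key=value` pairs in payload order. Doubles carry 6 decimals, integers
#' none; lines are `\n`-terminated UTF-8.
#'
#' @param msg an [exchange_message()].
#' @param write_timestamp include the timestamp field.
#' @export
format_message_line <- function(msg, write_timestamp = TRUE) {
  fields <- c(if (write_timestamp) msg$timestamp,
              msg$site_id, as.character(msg$block_index),
              as.character(msg$scan_index),
              vapply(seq_along(msg$payload), function(i) {
                paste0(names(msg$payload)[i], "=",
                       format_payload_value(msg$payload[[i]]))
              }, ""))
  paste(fields, collapse = "\t")
}

#' @rdname format_message_line
#' @param line one serialized message line (without the newline).
#' @export
parse_message_line <- function(line, write_timestamp = TRUE) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  need <- 3L + as.integer(write_timestamp)
  if (length(parts) < need) {
    stop("malformed message line: expected at least ", need,
         " fields, got ", length(parts))
  }
  off <- as.integer(write_timestamp)
  ts <- if (write_timestamp) parts[1] else NA_character_
  blk <- parts[off + 2]; scn <- parts[off + 3]
  if (!grepl("^[0-9]+$", blk) || !grepl("^[0-9]+$", scn)) {
    stop("malformed message line: non-numeric block/scan index")
  }
  kv <- parts[seq_len(length(parts) - need) + need]
  payload <- list()
  for (p in kv) {
    if (!grepl("^[^=]+=[^=]*$", p)) {
      stop("malformed payload field: '", p, "'")
    }
    key <- sub("=.*$", "", p)
    val <- sub("^[^=]*=", "", p)
    payload[[key]] <- if (grepl("^-?[0-9]+$", val)) {
      as.integer(val)
    } else {
      as.numeric(val)
    }
  }
  exchange_message(parts[off + 1], as.integer(blk), as.integer(scn),
                   payload, timestamp = ts)
}

#' Write a message to a channel file
#'
#' Appends exactly one line (APPEND mode) or rewrites the file (OVERWRITE
#' mode). The payload keys must be a subset of the channel's configured
#' parameters and the scan index must be one of the channel's trigger scans.
#'
#' @param platform an [exchange_platform()].
#' @param channel an active [output_channel()].
#' @param msg an [exchange_message()].
#' @return the channel file path, invisibly.
#' @export
write_message <- function(platform, channel, msg) {
  stopifnot(inherits(platform, "exchange_platform"),
            inherits(channel, "edl_channel"),
            inherits(msg, "exchange_message"))
  if (!channel$state) stop("channel for site '", channel$site, "' is inactive")
  bad <- setdiff(names(msg$payload), channel$params)
  if (length(bad)) {
    stop("payload key(s) not in the channel's output parameters: ",
         paste(bad, collapse = ", "))
  }
  if (!(msg$scan_index %in% channel$trigger_scans)) {
    stop("scan index ", msg$scan_index, " is not a trigger scan (",
         paste(channel$trigger_scans, collapse = ", "), ")")
  }
  path <- channel_file(platform, channel)
  line <- paste0(format_message_line(msg, channel$write_timestamp), "\n")
  con <- file(path, open = if (channel$mode == "append") "ab" else "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(line)), con)
  invisible(path)
}

#' Read new messages from a channel file
#'
#' Returns all complete (newline-terminated) messages after the byte cursor;
#' a partial trailing line is left for the next poll. A malformed complete
#' line raises a per-line error carrying the line number; pass
#' `on_error = "warn"` to skip such lines with a warning and return the rest.
#'
#' @param platform an [exchange_platform()].
#' @param channel an active [receive_channel()] (or [output_channel()]).
#' @param cursor byte offset returned by the previous call (0 at start).
#' @param on_error `"stop"` or `"warn"`.
#' @return list with `messages` (list of [exchange_message()]) and `cursor`.
#' @export
read_messages <- function(platform, channel, cursor = 0L,
                          on_error = c("stop", "warn")) {
  on_error <- match.arg(on_error)
  if (!channel$state) stop("channel for site '", channel$site, "' is inactive")
  path <- channel_file(platform, channel)
  if (!file.exists(path)) {
    return(list(messages = list(), cursor = cursor))
  }
  size <- file.size(path)
  if (size <= cursor) return(list(messages = list(), cursor = cursor))
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, where = cursor)
  raw <- readBin(con, "raw", n = size - cursor)
  nl <- which(raw == as.raw(10L))
  if (length(nl) == 0) return(list(messages = list(), cursor = cursor))
  complete <- raw[seq_len(max(nl))]
  txt <- rawToChar(complete)
  Encoding(txt) <- "UTF-8"
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  msgs <- list()
  for (i in seq_along(lines)) {
    m <- tryCatch(parse_message_line(lines[i], channel$write_timestamp),
                  error = function(e) e)
    if (inherits(m, "error")) {
      msg_txt <- paste0("line ", i, " after cursor: ", conditionMessage(m))
      if (on_error == "stop") stop(msg_txt) else warning(msg_txt)
    } else {
      msgs[[length(msgs) + 1L]] <- m
    }
  }
  list(messages = msgs, cursor = cursor + max(nl))
}

#' Is an exchange due at this scan?
#'
#' @param scan_index block-local 1-based scan index.
#' @param channel a channel spec with `trigger_scans`.
#' @return `TRUE` iff the scan index is one of the channel's trigger scans.
#' @export
exchange_due <- function(scan_index, channel) {
  scan_index %in% channel$trigger_scans
}
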