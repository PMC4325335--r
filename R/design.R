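#' Block designs for the localizer and the main experiment
#'
#' A `block_design` describes the scan-level timing of a run: every block has
#' the same within-block layout of labeled segments (cue-free; the task cue is
#' presented between blocks), plus per-block task and target-region labels for
#' the main experiment.
#'
#' @param layout data frame with columns `segment` (character, from the fixed
#'   vocabulary baseline/rest/tapping/feedback) and `n_scans` (positive
#'   integers).
#' @param n_blocks number of blocks.
#' @param tasks optional character vector (length `n_blocks`) of task labels.
#' @param targets optional character vector (length `n_blocks`) of target
#'   regions, `"U"` or `"L"`.
#' @return An object of class `block_design`.
#' @export
block_design <- function(layout, n_blocks, tasks = NULL, targets = NULL) {
  stopifnot(is.data.frame(layout), all(c("segment", "n_scans") %in% names(layout)))
  vocab <- c("baseline", "rest", "tapping", "feedback", "cue")
  if (!all(layout$segment %in% vocab)) {
    stop("unknown segment label(s): ",
         paste(setdiff(layout$segment, vocab), collapse = ", "))
  }
  stopifnot(all(layout$n_scans >= 1), n_blocks >= 1)
  if (!is.null(tasks)) stopifnot(length(tasks) == n_blocks)
  if (!is.null(targets)) {
    stopifnot(length(targets) == n_blocks, all(targets %in% c("U", "L")))
  }
  structure(
    list(layout = layout, n_blocks = as.integer(n_blocks),
         scans_per_block = as.integer(sum(layout$n_scans)),
         tasks = tasks, targets = targets),
    class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat("Block design: ", x$n_blocks, " blocks x ", x$scans_per_block,
      " scans (", n_scans(x), " total)\n  layout: ",
      paste(sprintf("%s:%d", x$layout$segment, x$layout$n_scans),
            collapse = " "), "\n", sep = "")
  if (!is.null(x$tasks)) {
    cat("  tasks: ", paste(names(table(x$tasks)), table(x$tasks),
                           sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Total number of scans in a design
#' @param design a [block_design()].
#' @export
n_scans <- function(design) design$n_blocks * design$scans_per_block

#' Block-local scan indices of a segment (1-based)
#'
#' @param design a [block_design()].
#' @param segment segment label.
#' @return integer vector of block-local scan indices.
#' @export
segment_scans <- function(design, segment) {
  ends <- cumsum(design$layout$n_scans)
  starts <- ends - design$layout$n_scans + 1L
  sel <- design$layout$segment == segment
  if (!any(sel)) return(integer(0))
  unlist(mapply(seq.int, starts[sel], ends[sel], SIMPLIFY = FALSE),
         use.names = FALSE)
}

#' Global scan indices of one block (1-based)
#' @param design a [block_design()].
#' @param block block index.
#' @export
block_scans <- function(design, block) {
  stopifnot(block >= 1, block <= design$n_blocks)
  (block - 1L) * design$scans_per_block + seq_len(design$scans_per_block)
}

#' Functional-localizer design
#'
#' Five blocks of twelve scans each: 2 scans rest, 2 scans finger tapping,
#' 8 scans rest. Tapping therefore occupies block-local scans 3-4.
#'
#' @return a [block_design()] with 60 scans.
#' @export
localizer_design <- function() {
  block_design(
    data.frame(segment = c("rest", "tapping", "rest"),
               n_scans = c(2L, 2L, 8L)),
    n_blocks = 5L)
}

#' Main-experiment design
#'
#' One 15-scan block per run: 5 baseline scans, 2 tapping scans, 7 rest
#' scans, and a final feedback scan (the 10 s task cue is presented between
#' blocks). Tasks are distributed in random order; within each task every
#' target region (U, L) appears `targets_per_region_per_task` times.
#'
#' @param config an [experiment_config()] (its `schedule_params` are used), or
#'   `NULL` for the defaults (3 tasks, 10 targets per region per task, hence
#'   20 runs per task and 60 blocks).
#' @param seed integer seed for the randomized block order.
#' @return a [block_design()] with per-block `tasks` and `targets`.
#' @export
main_design <- function(config = NULL, seed = 1) {
  sp <- if (is.null(config)) {
    list(tasks = c("single", "cooperation", "competition"),
         targets_per_region_per_task = 10L,
         runs_per_task = 20L)
  } else {
    stopifnot(inherits(config, "experiment_config"))
    config$schedule_params
  }
  if (sp$runs_per_task != 2L * sp$targets_per_region_per_task) {
    stop("inconsistent schedule parameters: runs_per_task (", sp$runs_per_task,
         ") must equal 2 x targets_per_region_per_task (",
         sp$targets_per_region_per_task, ")")
  }
  tasks <- rep(sp$tasks, each = sp$runs_per_task)
  targets <- rep(rep(c("U", "L"), each = sp$targets_per_region_per_task),
                 times = length(sp$tasks))
  ord <- withr_seed(seed, sample.int(length(tasks)))
  block_design(
    data.frame(segment = c("baseline", "tapping", "rest", "feedback"),
               n_scans = c(5L, 2L, 7L, 1L)),
    n_blocks = length(tasks),
    tasks = tasks[ord], targets = targets[ord])
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Expected BOLD regressor for a design
#'
#' Convolves the per-scan neural input (1 during tapping scans, scaled by the
#' per-block effort) with the sampled HRF kernel. The result is normalized by
#' the peak of a single isolated unit-effort block response, so a noiseless
#' voxel carrying `amplitude * bold_regressor(...)` reaches `amplitude`
#' percent signal change at the within-block peak scan.
#'
#' @param design a [block_design()].
#' @param kernel sampled HRF kernel from [make_hrf()].
#' @param efforts per-block effort in `[0, 1]` (scalar recycled).
#' @return numeric vector of length [n_scans()].
#' @export
bold_regressor <- function(design, kernel, efforts = 1) {
  n <- n_scans(design)
  efforts <- rep_len(efforts, design$n_blocks)
  tap_local <- segment_scans(design, "tapping")
  if (length(tap_local) == 0) return(numeric(n))  # rest-only design
  neural <- numeric(n)
  for (b in seq_len(design$n_blocks)) {
    neural[(b - 1L) * design$scans_per_block + tap_local] <- efforts[b]
  }
  x <- conv_causal(neural, kernel)
  # single-block unit response peak
  one <- numeric(design$scans_per_block + length(kernel))
  one[tap_local] <- 1
  x / max(conv_causal(one, kernel))
}

# causal discrete convolution, output trimmed to length(x)
conv_causal <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(k)) {
    if (k[j] == 0) next
    idx <- seq_len(n - j + 1L)
    out[idx + j - 1L] <- out[idx + j - 1L] + k[j] * x[idx]
  }
  out
}
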