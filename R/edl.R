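#' Experiment configuration (EDL-style XML)
#'
#' The experiment is declared in an XML scheme in the style of the Experiment
#' Description Language: per-site imaging parameters, transmitting
#' (`OUTPUTMODULE`) and receiving (`RECEIVEMODULE`) exchange channels with
#' `CWOUTPUTSCAN`/`CWRECEIVESCAN` trigger scans and `OUT_*` parameter flags, a
#' `VISUALIZEACTMODULE` carrying virtual objects, the schedule reference and
#' per-site `SCALEMAXVALUE` calibration scale factors, and a `SCHEDULE`
#' element with the main-experiment counts and block layout.
#'
#' @name edl_config
NULL

# canonical names of the exchange parameter flags, keyed by XML attribute
.edl_param_flags <- c(
  OUT_TEMPLATE_ID = "template_id",
  OUT_TEMPLATE_LABEL = "template_label",
  OUT_TEMPLATE_ACTLEVEL = "actlevel",
  OUT_SOURCE_IMG = "source_img",
  OUT_MONEY_HUMAN = "reward_human",
  OUT_MONEY_OPPONENT = "reward_opponent",
  OUT_HUMAN_STEPSIZE = "stepsize")

#' Site configuration
#'
#' @param site_id short string identifying the site.
#' @param tr_seconds scan repetition time in seconds (> 0).
#' @param n_slices number of slices (>= 1).
#' @param matrix_size integer pair of in-plane matrix dimensions (>= 8).
#' @param field_label informational field-strength label, e.g. `"3T"`.
#' @export
site_config <- function(site_id, tr_seconds = 2, n_slices = 31,
                        matrix_size = c(64L, 64L), field_label = "") {
  stopifnot(is.character(site_id), nzchar(site_id),
            tr_seconds > 0, n_slices >= 1,
            length(matrix_size) == 2, all(matrix_size >= 8))
  structure(list(site_id = site_id, tr_seconds = as.numeric(tr_seconds),
                 n_slices = as.integer(n_slices),
                 matrix_size = as.integer(matrix_size),
                 field_label = as.character(field_label)),
            class = "site_config")
}

new_channel <- function(class, site, state, transport, write_timestamp, mode,
                        location, trigger_scans, params) {
  mode <- match.arg(tolower(mode), c("append", "overwrite"))
  transport <- match.arg(tolower(transport), "file")
  ch <- structure(
    list(site = site, state = isTRUE(state), transport = transport,
         write_timestamp = isTRUE(write_timestamp), mode = mode,
         location = as.character(location),
         trigger_scans = as.integer(trigger_scans),
         params = as.character(params)),
    class = c(class, "edl_channel"))
  if (ch$state && !nzchar(ch$location)) {
    stop("active ", class, " for site '", site, "' has no LOCATION")
  }
  if (ch$state && grepl("\\[[A-Za-z0-9_]+\\]", ch$location)) {
    stop("unresolved placeholder in LOCATION of active channel for site '",
         site, "': ", ch$location)
  }
  if (!all(ch$params %in% .edl_param_flags)) {
    stop("unknown exchange parameter(s): ",
         paste(setdiff(ch$params, .edl_param_flags), collapse = ", "))
  }
  ch
}

#' Exchange channel specifications
#'
#' @param site owning site id.
#' @param state logical; an inactive channel needs no location.
#' @param transport only `"file"` is supported.
#' @param write_timestamp prepend an ISO-8601 timestamp to each message line.
#' @param mode `"append"` or `"overwrite"`.
#' @param location path of the channel message file (placeholders like
#'   `[ROOT]` must be resolved before the channel is active).
#' @param trigger_scans block-local 1-based scan indices at which the channel
#'   fires.
#' @param params canonical names of the exchanged parameters (subset of
#'   `template_id`, `template_label`, `actlevel`, `source_img`,
#'   `reward_human`, `reward_opponent`, `stepsize`).
#' @export
output_channel <- function(site, state = TRUE, transport = "file",
                           write_timestamp = TRUE, mode = "append",
                           location = "", trigger_scans = 10L,
                           params = c("actlevel", "reward_human")) {
  new_channel("output_channel", site, state, transport, write_timestamp,
              mode, location, trigger_scans, params)
}

#' @rdname output_channel
#' @export
receive_channel <- function(site, state = TRUE, transport = "file",
                            write_timestamp = TRUE, mode = "append",
                            location = "", trigger_scans = 10L,
                            params = c("actlevel", "reward_human")) {
  new_channel("receive_channel", site, state, transport, write_timestamp,
              mode, location, trigger_scans, params)
}

#' Visualization specification
#'
#' @param virt_objects list of object descriptors, each a list with `id`,
#'   `owner` (site id) and `visible_to` (character vector of site ids).
#' @param schedule_ref identifier of the block schedule shown to subjects.
#' @param scale_max_value named positive numeric, one calibration scale factor
#'   per site.
#' @export
visualization_spec <- function(virt_objects = list(), schedule_ref = "main",
                               scale_max_value = numeric(0)) {
  stopifnot(all(scale_max_value > 0))
  structure(list(virt_objects = virt_objects,
                 schedule_ref = as.character(schedule_ref),
                 scale_max_value = scale_max_value),
            class = "visualization_spec")
}

#' Full experiment configuration
#'
#' @param sites list of [site_config()] objects (>= 1).
#' @param output_channels,receive_channels lists of channel specs.
#' @param visualization a [visualization_spec()].
#' @param schedule_params list with `tasks` (character), `runs_per_task`,
#'   `targets_per_region_per_task` (must satisfy
#'   `runs_per_task == 2 * targets_per_region_per_task`) and `block_layout`
#'   (data frame as in [block_design()]).
#' @param rng_seed integer seed recorded with the configuration.
#' @export
experiment_config <- function(sites, output_channels = list(),
                              receive_channels = list(),
                              visualization = visualization_spec(),
                              schedule_params = NULL, rng_seed = 1L) {
  stopifnot(length(sites) >= 1,
            all(vapply(sites, inherits, TRUE, "site_config")))
  if (is.null(schedule_params)) {
    schedule_params <- list(
      tasks = c("single", "cooperation", "competition"),
      runs_per_task = 20L, targets_per_region_per_task = 10L,
      block_layout = data.frame(
        segment = c("baseline", "tapping", "rest", "feedback"),
        n_scans = c(5L, 2L, 7L, 1L)))
  }
  sp <- schedule_params
  if (sp$runs_per_task != 2L * sp$targets_per_region_per_task) {
    stop("inconsistent schedule parameters: runs_per_task must equal ",
         "2 x targets_per_region_per_task")
  }
  block_len <- sum(sp$block_layout$n_scans)
  for (ch in c(output_channels, receive_channels)) {
    stopifnot(inherits(ch, "edl_channel"))
    if (any(ch$trigger_scans < 1 | ch$trigger_scans > block_len)) {
      stop("trigger scan outside the ", block_len, "-scan block for site '",
           ch$site, "'")
    }
  }
  structure(list(sites = sites, output_channels = output_channels,
                 receive_channels = receive_channels,
                 visualization = visualization,
                 schedule_params = sp, rng_seed = as.integer(rng_seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration: ", length(x$sites), " site(s) [",
      paste(vapply(x$sites, `[[`, "", "site_id"), collapse = ", "), "]\n",
      "  channels: ", length(x$output_channels), " output, ",
      length(x$receive_channels), " receive\n",
      "  schedule: ", length(x$schedule_params$tasks), " tasks x ",
      x$schedule_params$runs_per_task, " runs\n", sep = "")
  invisible(x)
}

#' Default runnable two-site configuration
#'
#' Two sites emulating the study setup (a 3T site with 31 slices and a 7T
#' site with 20 slices, both 64 x 64, TR 2 s), one output and one receive
#' channel per site under `exchange_root`, one sphere per site, and the
#' default main-experiment schedule.
#'
#' @param n_sites currently 1 or 2.
#' @param seed recorded RNG seed.
#' @param exchange_root directory prefix for the channel message files.
#' @return an [experiment_config()].
#' @export
default_experiment_config <- function(n_sites = 2, seed = 1,
                                      exchange_root = "exchange") {
  stopifnot(n_sites %in% 1:2)
  sites <- list(site_config("siteA", 2, 31, c(64L, 64L), "3T"),
                site_config("siteB", 2, 20, c(64L, 64L), "7T"))[seq_len(n_sites)]
  ids <- vapply(sites, `[[`, "", "site_id")
  out <- lapply(ids, function(id) output_channel(
    id, location = file.path(exchange_root, paste0(id, "_out.txt"))))
  partner <- if (n_sites == 2) rev(ids) else ids
  rec <- lapply(seq_along(ids), function(i) receive_channel(
    ids[i], location = file.path(exchange_root, paste0(partner[i], "_out.txt"))))
  objs <- lapply(ids, function(id)
    list(id = paste0("sphere_", id), owner = id, visible_to = id))
  experiment_config(
    sites, out, rec,
    visualization_spec(objs, "main",
                       stats::setNames(rep(1, n_sites), ids)),
    rng_seed = seed)
}

resolve_placeholders <- function(s, substitutions) {
  for (key in names(substitutions)) {
    s <- gsub(paste0("[", toupper(key), "]"), substitutions[[key]], s,
              fixed = TRUE)
  }
  gsub("\\", "/", s, fixed = TRUE)
}

on_off <- function(x, default = FALSE) {
  if (is.na(x) || !nzchar(x)) return(default)
  switch(tolower(x), on = TRUE, off = FALSE,
         stop("expected ON/OFF, got '", x, "'"))
}

parse_params <- function(node, flags = .edl_param_flags) {
  if (is.na(node) || length(node) == 0) return(character(0))
  att <- xml2::xml_attrs(node)
  known <- intersect(names(att), names(flags))
  unname(flags[known][vapply(att[known], on_off, TRUE)])
}

parse_trigger <- function(nodes, what) {
  txt <- trimws(unlist(lapply(nodes, xml2::xml_text)))
  txt <- unlist(strsplit(txt[nzchar(txt)], "[,[:space:]]+"))
  if (length(txt) == 0) return(integer(0))
  if (any(!grepl("^[0-9]+$", txt))) {
    stop("non-numeric ", what, " value: ",
         paste(txt[!grepl("^[0-9]+$", txt)], collapse = ", "))
  }
  as.integer(txt)
}

parse_channel <- function(node, kind, substitutions) {
  ctor <- if (kind == "output") output_channel else receive_channel
  scan_el <- if (kind == "output") "CWOUTPUTSCAN" else "CWRECEIVESCAN"
  par_el <- if (kind == "output") "OUTPUTPARAMS" else "RECEIVEPARAMS"
  att <- xml2::xml_attrs(node)
  a <- function(name, default = "") {
    if (name %in% names(att)) att[[name]] else default
  }
  state <- on_off(a("STATE"), FALSE)
  loc_node <- xml2::xml_find_first(node, "./LOCATION")
  location <- if (inherits(loc_node, "xml_missing")) "" else
    resolve_placeholders(xml2::xml_text(loc_node), substitutions)
  if (state && !nzchar(location)) {
    stop("active ", toupper(kind), "MODULE is missing LOCATION",
         if (nzchar(a("SITE"))) paste0(" (site '", a("SITE"), "')"))
  }
  ctor(site = a("SITE", "site1"),
       state = state,
       transport = tolower(a("TYPE", "file")),
       write_timestamp = on_off(a("WRITETIMESTAMP"), FALSE),
       mode = tolower(a("MODE", "append")),
       location = location,
       trigger_scans = parse_trigger(
         xml2::xml_find_all(node, paste0("./", scan_el)), scan_el),
       params = parse_params(xml2::xml_find_first(node, paste0("./", par_el))))
}

#' Parse an EDL-style XML experiment configuration
#'
#' Unknown elements are ignored with a warning; ON/OFF attribute values are
#' case-insensitive; `[KEY]` placeholders in channel locations are resolved
#' from `substitutions` (an unresolved placeholder in an active channel is a
#' validation error).
#'
#' @param xml_text XML document as a string, or a file path.
#' @param substitutions named list/character vector of placeholder values.
#' @return a validated [experiment_config()].
#' @export
parse_edl <- function(xml_text, substitutions = list()) {
  doc <- xml2::read_xml(xml_text)
  root <- xml2::xml_root(doc)
  known <- c("SITE", "OUTPUTMODULE", "RECEIVEMODULE", "VISUALIZEACTMODULE",
             "SCHEDULE")
  kids <- xml2::xml_children(root)
  unknown <- setdiff(xml2::xml_name(kids), known)
  if (length(unknown)) {
    warning("ignoring unknown EDL element(s): ",
            paste(unique(unknown), collapse = ", "))
  }

  sites <- lapply(xml2::xml_find_all(root, "./SITE"), function(nd) {
    att <- xml2::xml_attrs(nd)
    ms <- as.integer(strsplit(trimws(att[["MATRIX"]]), "[[:space:]x]+")[[1]])
    site_config(att[["ID"]], as.numeric(att[["TR"]]),
                as.integer(att[["NSLICES"]]), ms,
                if ("FIELD" %in% names(att)) att[["FIELD"]] else "")
  })

  out <- lapply(xml2::xml_find_all(root, "./OUTPUTMODULE"),
                parse_channel, kind = "output", substitutions = substitutions)
  rec <- lapply(xml2::xml_find_all(root, "./RECEIVEMODULE"),
                parse_channel, kind = "receive", substitutions = substitutions)

  vis_node <- xml2::xml_find_first(root, "./VISUALIZEACTMODULE")
  vis <- visualization_spec()
  if (!inherits(vis_node, "xml_missing")) {
    objs <- lapply(xml2::xml_find_all(vis_node, "./VIRTOBJECT"), function(nd) {
      att <- xml2::xml_attrs(nd)
      list(id = att[["ID"]], owner = att[["OWNER"]],
           visible_to = strsplit(trimws(att[["VISIBLETO"]]),
                                 "[[:space:]]+")[[1]])
    })
    smv_nodes <- xml2::xml_find_all(vis_node, "./SCALEMAXVALUE")
    smv <- stats::setNames(
      vapply(smv_nodes, function(nd) as.numeric(xml2::xml_text(nd)), 0),
      vapply(smv_nodes, function(nd) xml2::xml_attr(nd, "SITE"), ""))
    rs <- xml2::xml_find_first(vis_node, "./RANDSTRUCT")
    ref <- if (inherits(rs, "xml_missing")) "main" else
      xml2::xml_attr(rs, "REF")
    vis <- visualization_spec(objs, ref, smv)
  }

  sched_node <- xml2::xml_find_first(root, "./SCHEDULE")
  sp <- NULL
  if (!inherits(sched_node, "xml_missing")) {
    att <- xml2::xml_attrs(sched_node)
    bl <- strsplit(strsplit(trimws(att[["BLOCKLAYOUT"]]),
                            "[[:space:]]+")[[1]], ":")
    sp <- list(
      tasks = strsplit(trimws(att[["TASKS"]]), "[[:space:]]+")[[1]],
      runs_per_task = as.integer(att[["RUNSPERTASK"]]),
      targets_per_region_per_task = as.integer(att[["TARGETSPERREGIONPERTASK"]]),
      block_layout = data.frame(
        segment = vapply(bl, `[[`, "", 1),
        n_scans = as.integer(vapply(bl, `[[`, "", 2))))
  }

  seed <- xml2::xml_attr(root, "SEED")
  experiment_config(sites, out, rec, vis, sp,
                    rng_seed = if (is.na(seed)) 1L else as.integer(seed))
}

serialize_params <- function(doc_node, el_name, params) {
  nd <- xml2::xml_add_child(doc_node, el_name)
  for (i in seq_along(.edl_param_flags)) {
    xml2::xml_set_attr(nd, names(.edl_param_flags)[i],
                       if (.edl_param_flags[i] %in% params) "ON" else "OFF")
  }
}

serialize_channel <- function(root, ch) {
  el <- if (inherits(ch, "output_channel")) "OUTPUTMODULE" else "RECEIVEMODULE"
  nd <- xml2::xml_add_child(root, el,
                            SITE = ch$site,
                            STATE = if (ch$state) "ON" else "OFF",
                            TYPE = toupper(ch$transport),
                            WRITETIMESTAMP = if (ch$write_timestamp) "ON" else "OFF",
                            MODE = toupper(ch$mode))
  xml2::xml_add_child(nd, "LOCATION", ch$location)
  for (ts in ch$trigger_scans) {
    xml2::xml_add_child(
      nd, if (inherits(ch, "output_channel")) "CWOUTPUTSCAN" else "CWRECEIVESCAN",
      as.character(ts))
  }
  serialize_params(nd,
                   if (inherits(ch, "output_channel")) "OUTPUTPARAMS" else
                     "RECEIVEPARAMS",
                   ch$params)
}

#' Serialize an experiment configuration to EDL-style XML
#'
#' `parse_edl(serialize_edl(config))` reproduces `config` on the configuration
#' data model.
#'
#' @param config an [experiment_config()].
#' @return XML document as a single string.
#' @export
serialize_edl <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  doc <- xml2::xml_new_root("EDL", VERSION = "1.2",
                            SEED = as.character(config$rng_seed))
  for (s in config$sites) {
    xml2::xml_add_child(doc, "SITE", ID = s$site_id,
                        TR = format(s$tr_seconds),
                        NSLICES = as.character(s$n_slices),
                        MATRIX = paste(s$matrix_size, collapse = " "),
                        FIELD = s$field_label)
  }
  for (ch in config$output_channels) serialize_channel(doc, ch)
  for (ch in config$receive_channels) serialize_channel(doc, ch)

  vis <- xml2::xml_add_child(doc, "VISUALIZEACTMODULE")
  for (ob in config$visualization$virt_objects) {
    xml2::xml_add_child(vis, "VIRTOBJECT", ID = ob$id, OWNER = ob$owner,
                        VISIBLETO = paste(ob$visible_to, collapse = " "))
  }
  xml2::xml_add_child(vis, "RANDSTRUCT",
                      REF = config$visualization$schedule_ref)
  smv <- config$visualization$scale_max_value
  for (i in seq_along(smv)) {
    xml2::xml_add_child(vis, "SCALEMAXVALUE", format(smv[[i]]),
                        SITE = names(smv)[i])
  }

  sp <- config$schedule_params
  xml2::xml_add_child(
    doc, "SCHEDULE",
    RUNSPERTASK = as.character(sp$runs_per_task),
    TASKS = paste(sp$tasks, collapse = " "),
    TARGETSPERREGIONPERTASK = as.character(sp$targets_per_region_per_task),
    BLOCKLAYOUT = paste(sprintf("%s:%d", sp$block_layout$segment,
                                sp$block_layout$n_scans), collapse = " "))
  as.character(doc)
}
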