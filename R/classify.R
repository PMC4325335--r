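#' Relative activation as percent of the individual maximum
#'
#' `100 * raw / max_bold_percent`. The result is deliberately not clipped
#' (values above 100% classify as strong, negative values as insufficient);
#' clipping happens only for display positioning.
#'
#' @param raw_response_percent raw block response in percent signal change.
#' @param profile a `calibration_profile` (or a positive number, the maximum
#'   BOLD percent).
#' @return relative activation in percent of the individual maximum.
#' @export
relative_activation <- function(raw_response_percent, profile) {
  mx <- if (inherits(profile, "calibration_profile")) {
    profile$max_bold_percent
  } else {
    profile
  }
  stopifnot(is.numeric(mx), mx > 0)
  100 * raw_response_percent / mx
}

#' Classify a relative activation into bands
#'
#' Below 30% of the individual maximum the activation is rated insufficient
#' (the task is not fulfilled); within the closed interval 30% to 60% it is a
#' weak activation ("L"); above 60% a strong activation ("U").
#'
#' @param relative_percent relative activation (vectorized).
#' @return character vector with values `"insufficient"`, `"weak_L"`,
#'   `"strong_U"`.
#' @export
classify_band <- function(relative_percent) {
  if (any(!is.finite(relative_percent))) {
    stop("relative activation is not finite; cannot classify")
  }
  ifelse(relative_percent < 30, "insufficient",
         ifelse(relative_percent <= 60, "weak_L", "strong_U"))
}

#' Per-block activation estimate
#'
#' @param block_index block number.
#' @param raw_response_percent raw block response.
#' @param profile calibration profile (or maximum BOLD percent).
#' @return object of class `activation_estimate` with `relative_percent` and
#'   `band`.
#' @export
activation_estimate <- function(block_index, raw_response_percent, profile) {
  rel <- relative_activation(raw_response_percent, profile)
  structure(list(block_index = as.integer(block_index),
                 raw_response_percent = raw_response_percent,
                 relative_percent = rel,
                 band = classify_band(rel)),
            class = "activation_estimate")
}

#' Map a classified activation to a virtual-object position
#'
#' The object region is U for a strong activation, L for a weak one and none
#' for an insufficient one; the continuous vertical position within the field
#' is `relative_percent / 100` clipped to `[0, 1]`.
#'
#' @param band band from [classify_band()].
#' @param relative_percent relative activation.
#' @param object_id identifier of the displayed object.
#' @return list with `object_id`, `vertical_position`, `region`.
#' @export
position_object <- function(band, relative_percent, object_id = "sphere") {
  stopifnot(band %in% c("insufficient", "weak_L", "strong_U"))
  region <- c(insufficient = "none", weak_L = "L", strong_U = "U")[[band]]
  list(object_id = object_id,
       vertical_position = min(1, max(0, relative_percent / 100)),
       region = region)
}
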