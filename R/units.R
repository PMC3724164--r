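# Internal working units are micrometers and seconds throughout.

.time_unit_seconds <- c(s = 1, sec = 1, min = 60, hour = 3600, day = 86400)

#' Convert a diffusivity between cm^2/s and um^2/s
#'
#' Internally the package works in um^2/s; inputs quoted in cm^2/s (the
#' conventional unit for macromolecular diffusivities) are converted on entry.
#'
#' @param value numeric diffusivity.
#' @param from,to units, one of `"cm2_per_s"` or `"um2_per_s"`.
#' @return the diffusivity expressed in `to` units.
#' @examples
#' convert_diffusivity(8e-9, from = "cm2_per_s")  # 0.8 um^2/s
#' @export
convert_diffusivity <- function(value, from = "cm2_per_s", to = "um2_per_s") {
  fac <- c(cm2_per_s = 1e8, um2_per_s = 1)  # 1 cm = 1e4 um
  if (!from %in% names(fac)) stop("unknown diffusivity unit: ", from)
  if (!to %in% names(fac)) stop("unknown diffusivity unit: ", to)
  value * fac[[from]] / fac[[to]]
}

#' Convert a time between units
#'
#' @param value numeric time.
#' @param from,to one of `"s"`, `"min"`, `"hour"`, `"day"`.
#' @return time in `to` units.
#' @export
convert_time <- function(value, from = "s", to = "min") {
  if (!from %in% names(.time_unit_seconds)) stop("unknown time unit: ", from)
  if (!to %in% names(.time_unit_seconds)) stop("unknown time unit: ", to)
  value * .time_unit_seconds[[from]] / .time_unit_seconds[[to]]
}
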