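#' Time-activity curves
#'
#' A time-activity curve (TAC) is tracer concentration in a voxel or region as
#' a function of time post-injection. TACs are plain tibbles with columns
#' `time_min` and `value` plus a `units` attribute, so they pipe straight into
#' dplyr/ggplot2 while still carrying their unit flag.
#'
#' @param time_min Sample times in minutes, strictly increasing.
#' @param value Concentrations, `kBq/mL` (default) or dimensionless `SUV`.
#' @param units Either `"kBq/mL"` or `"SUV"`.
#' @return A tibble of class `tac` with columns `time_min`, `value`.
#' @examples
#' tac(c(0, 1, 2), c(0, 5, 4))
#' @export
tac <- function(time_min, value, units = c("kBq/mL", "SUV")) {
  units <- match.arg(units)
  if (length(time_min) != length(value))
    abort("time_min and value must have equal length")
  if (any(!is.finite(time_min))) abort("TAC times must be finite")
  if (length(time_min) > 1L && any(diff(time_min) <= 0))
    abort("TAC times must be strictly increasing")
  out <- tibble(time_min = as.numeric(time_min), value = as.numeric(value))
  attr(out, "units") <- units
  class(out) <- c("tac", class(out))
  out
}

#' @rdname tac
#' @param x Object to query.
#' @export
tac_units <- function(x) attr(x, "units") %||% "kBq/mL"

#' Resample a time-activity curve by linear interpolation
#'
#' Values before the first sample are 0 (no tracer before the curve starts);
#' extrapolation past the last sample is refused.
#'
#' @param curve A [tac()] with at least 2 points.
#' @param new_times Target times (minutes) within `[0, max(curve$time_min)]`.
#' @return A [tac()] on `new_times`, same units.
#' @examples
#' resample_tac(tac(c(0, 2), c(2, 4)), 1)
#' @export
resample_tac <- function(curve, new_times) {
  stopifnot(inherits(curve, "tac"))
  if (nrow(curve) < 2L) abort("resampling needs a curve with >= 2 points")
  if (any(new_times < 0)) abort("new_times must be nonnegative")
  if (max(new_times) > max(curve$time_min) + 1e-9)
    abort("range-error: refusing to extrapolate past the last sample")
  v <- approx(curve$time_min, curve$value, xout = new_times,
              yleft = 0, rule = 2)$y
  tac(new_times, v, units = tac_units(curve))
}

#' @method autoplot tac
#' @export
autoplot.tac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time post-injection (min)",
                  y = paste0("activity (", tac_units(object), ")"))
}

#' Read/write a time-activity curve CSV
#'
#' The exchange format is a two-column CSV `time_min,kBq_per_mL` (or
#' `time_min,suv` for SUV-flagged curves) with a header row.
#'
#' @param path File path.
#' @param curve A [tac()].
#' @return `read_tac()` returns a [tac()]; `write_tac()` returns `path`
#'   invisibly.
#' @export
read_tac <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!"time_min" %in% names(x) || ncol(x) < 2L)
    abort("TAC CSV must have columns time_min and a value column")
  vcol <- setdiff(names(x), "time_min")[1]
  units <- if (identical(vcol, "suv")) "SUV" else "kBq/mL"
  tac(x$time_min, x[[vcol]], units = units)
}

#' @rdname read_tac
#' @export
write_tac <- function(curve, path) {
  stopifnot(inherits(curve, "tac"))
  vname <- if (identical(tac_units(curve), "SUV")) "suv" else "kBq_per_mL"
  df <- tibble(time_min = curve$time_min)
  df[[vname]] <- curve$value
  readr::write_csv(df, path)
  invisible(path)
}
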