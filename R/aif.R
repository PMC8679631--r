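#' Parametric bolus input function (tri-exponential)
#'
#' The simulator's whole-blood curve follows the classic tri-exponential bolus
#' form
#' `Cb(t') = (A1 t' - A2 - A3) exp(-l1 t') + A2 exp(-l2 t') + A3 exp(-l3 t')`
#' with `t' = t - delay` and 0 before the delay. The curve is continuous at
#' onset (value 0 at `t = delay`) and integrable.
#'
#' @param A1 Bolus slope, kBq/mL/min.
#' @param A2,A3 Recirculation/washout amplitudes, kBq/mL, `>= 0`.
#' @param lambda1,lambda2,lambda3 Decay rates, 1/min, with
#'   `lambda1 > lambda2 > lambda3 > 0`.
#' @param delay Bolus arrival delay, minutes.
#' @return An object of class `aif_params`.
#' @examples
#' feng_aif(aif_params(), seq(0, 60, by = 0.5))
#' @export
aif_params <- function(A1 = 300, A2 = 2, A3 = 4,
                       lambda1 = 4, lambda2 = 0.12, lambda3 = 0.012,
                       delay = 0.5) {
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 > 0))
    abort("invalid-aif: need lambda1 > lambda2 > lambda3 > 0")
  if (A2 < 0 || A3 < 0) abort("invalid-aif: A2 and A3 must be >= 0")
  if (A1 < 0) abort("invalid-aif: A1 must be >= 0")
  if (delay < 0) abort("invalid-aif: delay must be >= 0")
  structure(list(A1 = A1, A2 = A2, A3 = A3, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3, delay = delay),
            class = "aif_params")
}

#' @rdname aif_params
#' @param params An `aif_params` object.
#' @param times Evaluation times, minutes, `>= 0`.
#' @export
feng_aif <- function(params, times) {
  stopifnot(inherits(params, "aif_params"))
  if (any(times < 0)) abort("times must be >= 0")
  tp <- times - params$delay
  v <- ifelse(tp <= 0, 0,
              (params$A1 * tp - params$A2 - params$A3) * exp(-params$lambda1 * tp) +
                params$A2 * exp(-params$lambda2 * tp) +
                params$A3 * exp(-params$lambda3 * tp))
  v <- pmax(v, 0)
  tac(times, v)
}

# analytic integral of the tri-exponential over [delay, Inf)
feng_aif_integral <- function(params) {
  with(params, A1 / lambda1^2 - (A2 + A3) / lambda1 + A2 / lambda2 + A3 / lambda3)
}

#' Metabolite parent-fraction model
#'
#' Fraction of whole-blood activity that is still parent tracer, modelled as
#' the sigmoid `p(t) = floor + (1 - floor) / (1 + (t / half_time)^steepness)`.
#' `p(0) = 1`, `p` is nonincreasing, and `p(half_time) = (1 + floor) / 2`.
#' FLT is metabolized slowly (glucuronidation), so the defaults decline gently
#' to a high floor; the shape is a configurable simulation choice, not a
#' measured assay.
#'
#' @param half_time Time at which half the decline has occurred, minutes.
#' @param steepness Sigmoid steepness (dimensionless, > 0).
#' @param floor Asymptotic parent fraction in `[0, 1]`.
#' @return An object of class `parent_fraction_model`.
#' @examples
#' parent_fraction(parent_fraction_model(30, 2, 0.2), 30)  # 0.6
#' @export
parent_fraction_model <- function(half_time = 60, steepness = 1.5, floor = 0.7) {
  if (half_time <= 0 || steepness <= 0) abort("half_time and steepness must be > 0")
  if (floor < 0 || floor > 1) abort("floor must be in [0, 1]")
  structure(list(half_time = half_time, steepness = steepness, floor = floor),
            class = "parent_fraction_model")
}

#' @rdname parent_fraction_model
#' @param model A `parent_fraction_model`.
#' @param t Times in minutes, `>= 0`.
#' @export
parent_fraction <- function(model, t) {
  stopifnot(inherits(model, "parent_fraction_model"))
  model$floor + (1 - model$floor) / (1 + (t / model$half_time)^model$steepness)
}

#' Arterial input function (whole blood + metabolite-corrected plasma)
#'
#' Pairs the whole-blood curve `Cb(t)` with the metabolite-corrected
#' plasma-parent curve `Cp(t)` on a common strictly increasing time grid.
#' `Cp` drives the compartment model; `Cb` enters through the blood-volume
#' term.
#'
#' @param times Time grid, minutes, strictly increasing.
#' @param whole_blood,plasma_parent Concentrations, kBq/mL, `>= 0`.
#' @param plasma_to_blood Ceiling ratio used to validate
#'   `plasma_parent <= plasma_to_blood * whole_blood`.
#' @return A tibble of class `aif` with columns `time_min`, `whole_blood`,
#'   `plasma_parent`.
#' @export
aif <- function(times, whole_blood, plasma_parent, plasma_to_blood = 1) {
  if (length(times) != length(whole_blood) ||
      length(times) != length(plasma_parent))
    abort("AIF components must share one time grid")
  if (any(diff(times) <= 0)) abort("AIF times must be strictly increasing")
  if (any(whole_blood < 0) || any(plasma_parent < 0))
    abort("AIF concentrations must be >= 0")
  if (any(plasma_parent > plasma_to_blood * whole_blood + 1e-9))
    abort("plasma_parent exceeds plasma_to_blood * whole_blood")
  out <- tibble(time_min = as.numeric(times),
                whole_blood = as.numeric(whole_blood),
                plasma_parent = as.numeric(plasma_parent))
  class(out) <- c("aif", class(out))
  out
}

#' Image-derived whole-blood curve from a blood-pool ROI
#'
#' To limit partial-volume dilution without registration machinery, voxels in
#' the blood-pool mask are ranked by their early uptake (duration-weighted
#' integral over frames with mid-time in the first 2 minutes) and only the
#' hottest fraction contributes to the per-frame mean.
#'
#' @param series A [pet_series()].
#' @param blood_mask A [roi_mask()] over the blood pool.
#' @param hottest_fraction Fraction of blood-pool voxels retained, in `(0, 1]`;
#'   `1` reduces to [extract_tac()].
#' @param early_window_min End of the ranking window, minutes.
#' @return A whole-blood [tac()].
#' @export
extract_idaif <- function(series, blood_mask, hottest_fraction = 0.2,
                          early_window_min = 2) {
  stopifnot(inherits(series, "pet_series"))
  check_grid(dim(series$values), blood_mask)
  if (!is.finite(hottest_fraction) || hottest_fraction <= 0 || hottest_fraction > 1)
    abort("invalid-config: hottest_fraction must be in (0, 1]")
  nf <- dim(series$values)[4]
  m <- matrix(series$values, ncol = nf)[as.vector(blood_mask$mask), , drop = FALSE]
  early <- which(series$schedule$mid_min <= early_window_min)
  if (length(early) == 0L) early <- 1L
  score <- m[, early, drop = FALSE] %*% series$schedule$duration_min[early]
  keep <- ceiling(hottest_fraction * nrow(m))
  sel <- order(score, decreasing = TRUE)[seq_len(keep)]
  tac(series$schedule$mid_min, colMeans(m[sel, , drop = FALSE]))
}

#' Metabolite-correct a whole-blood curve into an arterial input function
#'
#' `plasma_parent(t) = whole_blood(t) * plasma_to_blood * p(t)` with `p` the
#' [parent_fraction()] of `model`. The plasma-to-whole-blood ratio is a
#' constant (default 1): time variation of the ratio is not identifiable from
#' the image data alone.
#'
#' @param whole_blood A whole-blood [tac()].
#' @param model A [parent_fraction_model()].
#' @param plasma_to_blood Constant plasma-to-whole-blood ratio, > 0.
#' @return An [aif()].
#' @export
metabolite_correct <- function(whole_blood, model = parent_fraction_model(),
                               plasma_to_blood = 1) {
  stopifnot(inherits(whole_blood, "tac"))
  if (any(whole_blood$value < 0)) abort("whole-blood curve must be nonnegative")
  if (plasma_to_blood <= 0) abort("plasma_to_blood must be > 0")
  p <- parent_fraction(model, whole_blood$time_min)
  aif(whole_blood$time_min, whole_blood$value,
      whole_blood$value * plasma_to_blood * p,
      plasma_to_blood = plasma_to_blood)
}

#' @method autoplot aif
#' @export
autoplot.aif <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_min",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time post-injection (min)", y = "activity (kBq/mL)",
                  colour = NULL)
}
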