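#' Two-tissue compartment parameters
#'
#' State of one lesion under the reversible two-tissue compartment model:
#' delivery `K1` (mL/min/g), efflux `k2` (1/min), trapping `k3` (1/min),
#' release `k4` (1/min) and fractional blood volume `vb` (dimensionless
#' fraction of voxel volume). The net influx constant is derived, not stored:
#' see [ki()].
#'
#' @param k1 Delivery rate, mL/min/g, `>= 0`.
#' @param k2,k3,k4 First-order rate constants, 1/min, `>= 0`.
#' @param vb Fractional blood volume in `[0, 1)`.
#' @return An object of class `two_tissue_params`.
#' @examples
#' two_tissue_params(0.31, 0.40, 0.24, 0.04, 0.019)
#' @export
two_tissue_params <- function(k1, k2, k3, k4 = 0, vb = 0) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, vb = vb)
  if (any(!is.finite(vals))) abort("kinetic parameters must be finite")
  if (any(vals[1:4] < 0)) abort("rate constants must be >= 0")
  if (vb < 0 || vb >= 1) abort("vb must be in [0, 1)")
  structure(as.list(vals), class = "two_tissue_params")
}

#' @export
print.two_tissue_params <- function(x, ...) {
  cat(sprintf("<2TCM> K1=%.3g mL/min/g k2=%.3g k3=%.3g k4=%.3g /min Vb=%.3g (Ki=%.3g)\n",
              x$k1, x$k2, x$k3, x$k4, x$vb, ki(x)))
  invisible(x)
}

#' Net influx constant Ki
#'
#' `Ki = K1 * k3 / (k2 + k3)`: the steady-state trapping rate per unit plasma
#' concentration, in mL/min/g. Defined as 0 when `k2 + k3 = 0`.
#'
#' @param x A [two_tissue_params()], a data frame with columns `k1`, `k2`,
#'   `k3`, or a numeric vector of `K1` values.
#' @param ... Passed to methods; for the numeric method, `k2` and `k3`
#'   vectors.
#' @return Ki in mL/min/g (vectorized for the numeric/data-frame methods).
#' @examples
#' ki(two_tissue_params(0.31, 0.40, 0.24))  # 0.11625
#' ki(0.11, k2 = 0.16, k3 = 0.04)           # 0.022
#' @export
ki <- function(x, ...) UseMethod("ki")

#' @rdname ki
#' @export
ki.two_tissue_params <- function(x, ...) ki(x$k1, k2 = x$k2, k3 = x$k3)

#' @rdname ki
#' @param k2,k3 Rate constants matching `x` (the `K1` vector).
#' @export
ki.numeric <- function(x, k2, k3, ...) {
  denom <- k2 + k3
  ifelse(denom == 0, 0, x * k3 / denom)
}

#' @rdname ki
#' @export
ki.data.frame <- function(x, ...) ki(x$k1, k2 = x$k2, k3 = x$k3)

# exact convolution of a piecewise-linear input with exp(-alpha * t) on an
# increasing grid: y(t_n) = int_0^{t_n} input(s) exp(-alpha (t_n - s)) ds.
# Recursive per segment; series expansion guards small alpha*dt against
# catastrophic cancellation.
exp_conv <- function(alpha, t, input) {
  n <- length(t)
  y <- numeric(n)
  if (n < 2L) return(y)
  dt <- diff(t)
  a <- input[-n]
  b <- diff(input) / dt
  ad <- alpha * dt
  small <- ad < 1e-4
  E <- exp(-ad)
  seg <- numeric(n - 1L)
  if (any(!small)) {
    i <- !small
    seg[i] <- (a[i] + b[i] * dt[i]) * (1 - E[i]) / alpha -
      b[i] * (1 - E[i] * (1 + ad[i])) / alpha^2
  }
  if (any(small)) {
    i <- small
    # int_0^{dt} (a + b s) e^{-alpha (dt - s)} ds expanded in alpha*dt
    seg[i] <- dt[i] * (a[i] + b[i] * dt[i] / 2) -
      alpha * dt[i]^2 * (a[i] / 2 + b[i] * dt[i] / 3) +
      alpha^2 * dt[i]^3 * (a[i] / 6 + b[i] * dt[i] / 8)
  }
  if (max(E) - min(E) < 1e-13) {
    # uniform grid: the recursion is a first-order recursive filter
    y[2:n] <- as.numeric(stats::filter(seg, E[1], method = "recursive"))
  } else {
    for (k in seq_len(n - 1L)) y[k + 1L] <- y[k] * E[k] + seg[k]
  }
  y
}

# linear operator mapping values of a piecewise-linear curve on grid `t` to
# per-frame time-averages (same quadrature as frame_average, precomputed once
# per fit)
frame_avg_matrix <- function(t, schedule) {
  n <- length(t)
  W <- matrix(0, nrow(schedule), n)
  interp_row <- function(x) {
    # coefficients expressing curve(x) as a linear combination of grid values
    r <- numeric(n)
    j <- findInterval(x, t, rightmost.closed = TRUE)
    j <- min(max(j, 1L), n - 1L)
    lam <- (x - t[j]) / (t[j + 1L] - t[j])
    r[j] <- 1 - lam; r[j + 1L] <- lam
    r
  }
  for (i in seq_len(nrow(schedule))) {
    a <- schedule$start_min[i]; b <- schedule$end_min[i]
    inside <- which(t > a & t < b)
    tt <- c(a, t[inside], b)
    u <- trapz_weights(tt)
    row <- numeric(n)
    row <- row + u[1] * interp_row(a) + u[length(u)] * interp_row(b)
    if (length(inside)) row[inside] <- row[inside] + u[2:(length(u) - 1L)]
    W[i, ] <- row / (b - a)
  }
  W
}

# eigenrates of the reversible 2TCM
tcm_eigenrates <- function(k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  sq <- sqrt(max(disc, 0))
  c((s - sq) / 2, (s + sq) / 2)
}

#' Forward model: tissue time-activity curve of the 2TCM
#'
#' Solves `dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2`,
#' `dC2/dt = k3 C1 - k4 C2` by the analytic bi-exponential convolution with
#' eigenrates `alpha_{1,2} = ((k2 + k3 + k4) -/+ sqrt((k2 + k3 + k4)^2 -
#' 4 k2 k4)) / 2`, and returns the measurable concentration
#' `C_T(t) = (1 - Vb)(C1 + C2) + Vb Cb(t)`. The input curves are linearly
#' interpolated onto a uniform fine grid (default 0.05 min) on which the
#' convolution is exact for piecewise-linear inputs.
#'
#' @param params A [two_tissue_params()].
#' @param aif An [aif()] whose grid spans `times`.
#' @param times Output times, minutes.
#' @param grid_dt Fine-grid step for the convolution, minutes.
#' @return A [tac()] at `times`.
#' @export
model_tac <- function(params, aif, times, grid_dt = 0.05) {
  stopifnot(inherits(params, "two_tissue_params"), inherits(aif, "aif"))
  if (max(times) > max(aif$time_min) + 1e-9)
    abort("range-error: AIF grid does not span the requested times")
  fine <- model_tac_fine(params, aif, t_max = max(times), grid_dt = grid_dt)
  tac(times, approx(fine$t, fine$ct, xout = times, yleft = 0, rule = 2)$y)
}

# shared fine-grid forward evaluation (also used by the fitter, which reuses
# the interpolated input curves across restarts)
model_tac_fine <- function(params, aif, t_max, grid_dt = 0.05,
                           fine = NULL) {
  if (is.null(fine)) fine <- interp_aif(aif, t_max, grid_dt)
  ct <- tcm_tissue_fine(params$k1, params$k2, params$k3, params$k4,
                        fine$t, fine$cp)
  list(t = fine$t, ct = (1 - params$vb) * ct + params$vb * fine$cb)
}

interp_aif <- function(aif, t_max, grid_dt) {
  t <- seq(0, t_max, by = grid_dt)
  if (t[length(t)] < t_max) t <- c(t, t_max)
  list(t = t,
       cp = approx(aif$time_min, aif$plasma_parent, xout = t,
                   yleft = 0, rule = 2)$y,
       cb = approx(aif$time_min, aif$whole_blood, xout = t,
                   yleft = 0, rule = 2)$y)
}

tcm_tissue_fine <- function(k1, k2, k3, k4, t, cp) {
  if (k1 == 0) return(numeric(length(t)))
  al <- tcm_eigenrates(k2, k3, k4)
  if (al[2] - al[1] < 1e-9) {
    # (near-)repeated eigenrate: split symmetrically; O(eps^2) error
    eps <- 5e-7
    al <- c(max(al[1] - eps, 0), al[2] + eps)
    if (al[2] - al[1] < 1e-9) al[2] <- al[1] + 1e-6
  }
  th1 <- k1 * (k3 + k4 - al[1]) / (al[2] - al[1])
  th2 <- k1 * (al[2] - k3 - k4) / (al[2] - al[1])
  th1 * exp_conv(al[1], t, cp) + th2 * exp_conv(al[2], t, cp)
}

#' Average a continuous model curve over acquisition frames
#'
#' Per-frame time-average of a finely sampled curve over
#' `[start, start + duration]`, by trapezoid integration with exact endpoint
#' interpolation. Matches the forward model to frame-integrated data.
#'
#' @param curve A [tac()] sampled densely enough to span the schedule.
#' @param schedule A [frame_schedule()].
#' @return A [tac()] at frame mid-times whose values are frame averages.
#' @export
frame_average <- function(curve, schedule) {
  stopifnot(inherits(curve, "tac"), inherits(schedule, "frame_schedule"))
  if (max(schedule$end_min) > max(curve$time_min) + 1e-9)
    abort("range-error: curve does not span the schedule")
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start_min[i]; b <- schedule$end_min[i]
    inside <- curve$time_min > a & curve$time_min < b
    tt <- c(a, curve$time_min[inside], b)
    vv <- approx(curve$time_min, curve$value, xout = tt, yleft = 0, rule = 2)$y
    trapz(tt, vv) / (b - a)
  }, numeric(1))
  tac(schedule$mid_min, vals, units = tac_units(curve))
}

#' Fitting configuration for the 2TCM
#'
#' @param n_starts Number of multistart initializations drawn from a seeded
#'   Latin hypercube over the parameter box.
#' @param seed Seed of the multistart draw (fixed so fits are reproducible).
#' @param weights Residual weighting: `"duration"` (frame duration, the usual
#'   count-statistics proxy and the default), `"uniform"`, or
#'   `"duration-over-value"`.
#' @param lower,upper Bounds on `(K1, k2, k3, k4, vb)`.
#' @param grid_dt Convolution grid step, minutes.
#' @param reversible If `FALSE`, `k4` is fixed at 0 (irreversible variant).
#' @return A list of class `tcm_fit_config`.
#' @export
fit_config <- function(n_starts = 20, seed = 20200101,
                       weights = c("duration", "uniform", "duration-over-value"),
                       lower = c(0, 0, 0, 0, 0),
                       upper = c(2, 2, 1, 0.5, 0.5),
                       grid_dt = 0.05, reversible = TRUE) {
  weights <- match.arg(weights)
  stopifnot(length(lower) == 5, length(upper) == 5, all(upper > lower | upper == lower))
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 weights = weights, lower = lower, upper = upper,
                 grid_dt = grid_dt, reversible = isTRUE(reversible)),
            class = "tcm_fit_config")
}

frame_weights <- function(tac_values, schedule, weights) {
  w <- switch(weights,
              uniform = rep(1, nrow(schedule)),
              duration = schedule$duration_min,
              `duration-over-value` =
                schedule$duration_min / pmax(tac_values, max(tac_values) * 0.01))
  w / mean(w)
}

#' Fit the reversible two-tissue compartment model to a lesion TAC
#'
#' Bounded weighted least squares over `(K1, k2, k3, k4, Vb)` with the
#' Levenberg-Marquardt algorithm, restarted from a fixed seeded Latin
#' hypercube of `config$n_starts` points spanning the parameter box; the best
#' restart (lowest weighted residual sum of squares) is returned. Approximate
#' per-parameter standard errors come from the local curvature at the optimum.
#'
#' @param lesion_tac A [tac()] of frame-averaged measurements at frame
#'   mid-times (at least 8 frames, the identifiability floor).
#' @param aif An [aif()] spanning the schedule.
#' @param schedule The [frame_schedule()] the TAC was measured on.
#' @param config A [fit_config()].
#' @return An object of class `tcm_fit`: fitted [two_tissue_params()],
#'   derived `ki`, `weighted_rss`, `se` (approximate standard errors),
#'   `success`, `n_restarts_used`, and the fitted curve. Supports [tidy()],
#'   [glance()] and `autoplot()`.
#' @export
fit_2tcm <- function(lesion_tac, aif, schedule, config = fit_config()) {
  stopifnot(inherits(lesion_tac, "tac"), inherits(aif, "aif"),
            inherits(schedule, "frame_schedule"),
            inherits(config, "tcm_fit_config"))
  if (nrow(lesion_tac) < 8L)
    abort("identifiability floor: need at least 8 frames to fit the 2TCM")
  if (nrow(lesion_tac) != nrow(schedule))
    abort("TAC length must match the schedule")
  t_max <- max(schedule$end_min)
  fine <- interp_aif(aif, t_max, config$grid_dt)
  y <- lesion_tac$value
  w <- frame_weights(y, schedule, config$weights)
  sw <- sqrt(w)

  free <- if (config$reversible) 1:5 else c(1:3, 5)
  lo <- config$lower; up <- config$upper

  W <- frame_avg_matrix(fine$t, schedule)
  predict_frames <- function(p) {
    ct <- tcm_tissue_fine(p[1], p[2], p[3], p[4], fine$t, fine$cp)
    ct <- (1 - p[5]) * ct + p[5] * fine$cb
    as.numeric(W %*% ct)
  }
  resid_fn <- function(pfree) {
    p <- numeric(5)
    p[free] <- pfree
    sw * (predict_frames(p) - y)
  }

  starts <- with_seed(config$seed, lhs::randomLHS(config$n_starts, length(free)))
  starts <- sweep(sweep(starts, 2, (up - lo)[free], "*"), 2, lo[free], "+")
  # one deterministic mid-box start alongside the hypercube
  starts <- rbind((lo + (up - lo) / 3)[free], starts)

  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    n_used <- i
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo[free], upper = up[free],
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = res, rss = rss)
  }
  if (is.null(best)) abort("fit-failure: every restart failed")

  p <- numeric(5)
  p[free] <- best$fit$par
  params <- two_tissue_params(p[1], p[2], p[3], p[4], min(p[5], 1 - 1e-12))
  se <- rep(NA_real_, 5)
  se[free] <- tryCatch({
    dof <- max(length(y) - length(free), 1L)
    sigma2 <- best$rss / dof
    sqrt(diag(sigma2 * solve(best$fit$hessian)))
  }, error = function(e) rep(NA_real_, length(free)))
  names(se) <- c("k1", "k2", "k3", "k4", "vb")

  fitted_curve <- tac(schedule$mid_min, predict_frames(p))
  structure(
    list(params = params, ki = ki(params), weighted_rss = best$rss,
         se = se, success = TRUE, n_restarts_used = n_used,
         config = config, observed = lesion_tac, fitted = fitted_curve,
         schedule = schedule),
    class = "tcm_fit"
  )
}

#' @export
print.tcm_fit <- function(x, ...) {
  cat("Two-tissue compartment fit\n")
  print(x$params)
  cat(sprintf("  weighted RSS %.4g over %d frames (%d restarts)\n",
              x$weighted_rss, nrow(x$observed), x$n_restarts_used))
  invisible(x)
}

#' @method tidy tcm_fit
#' @export
tidy.tcm_fit <- function(x, ...) {
  tibble(term = c("k1", "k2", "k3", "k4", "vb"),
         estimate = c(x$params$k1, x$params$k2, x$params$k3, x$params$k4,
                      x$params$vb),
         std.error = unname(x$se))
}

#' @method glance tcm_fit
#' @export
glance.tcm_fit <- function(x, ...) {
  tibble(ki = x$ki, weighted_rss = x$weighted_rss, n_frames = nrow(x$observed),
         n_restarts = x$n_restarts_used, success = x$success)
}

#' @method autoplot tcm_fit
#' @export
autoplot.tcm_fit <- function(object, ...) {
  obs <- dplyr::mutate(as_tibble(object$observed), what = "observed")
  fit <- dplyr::mutate(as_tibble(object$fitted), what = "fitted")
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point(data = obs) +
    ggplot2::geom_line(data = fit, colour = "red") +
    ggplot2::labs(x = "time post-injection (min)", y = "activity",
                  title = sprintf("2TCM fit: Ki = %.3f mL/min/g", object$ki))
}

#' Cohort summary of kinetic parameters
#'
#' Per-parameter mean and SD over a baseline cohort table; when a paired
#' post-treatment table is supplied (matched by `patient_id`), per-subject
#' percent changes and a Wilcoxon signed-rank p-value per parameter.
#'
#' @param baseline Data frame with `patient_id` and kinetic columns among
#'   `k1, k2, k3, k4, vb, ki`; `ki` is recomputed from `k1, k2, k3` when
#'   absent.
#' @param post Optional data frame of the same shape for the post-treatment
#'   scans.
#' @return A tibble with one row per parameter: `parameter`, `n`, `mean`,
#'   `sd`, and (when `post` is given) `mean_post`, `sd_post`,
#'   `mean_pct_change`, `p_value`.
#' @export
kinetic_cohort_summary <- function(baseline, post = NULL) {
  baseline <- as_tibble(baseline)
  if (nrow(baseline) < 2L) abort("cohort summary needs n >= 2")
  if (!"ki" %in% names(baseline)) baseline$ki <- ki(baseline)
  pars <- intersect(c("k1", "k2", "k3", "k4", "vb", "ki"), names(baseline))
  out <- purrr::map_dfr(pars, function(pn) {
    v <- baseline[[pn]]
    tibble(parameter = pn, n = sum(is.finite(v)),
           mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  })
  if (!is.null(post)) {
    post <- as_tibble(post)
    if (!"ki" %in% names(post)) post$ki <- ki(post)
    if (!setequal(baseline$patient_id, post$patient_id) ||
        nrow(post) != nrow(baseline))
      abort("pairing-error: post table must match baseline patient_ids")
    post <- post[match(baseline$patient_id, post$patient_id), ]
    extra <- purrr::map_dfr(pars, function(pn) {
      b <- baseline[[pn]]; a <- post[[pn]]
      pv <- tryCatch(
        suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value),
        error = function(e) NA_real_)
      tibble(parameter = pn, mean_post = mean(a, na.rm = TRUE),
             sd_post = sd(a, na.rm = TRUE),
             mean_pct_change = mean(100 * (a - b) / b, na.rm = TRUE),
             p_value = pv)
    })
    out <- dplyr::left_join(out, extra, by = "parameter")
  }
  out
}
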