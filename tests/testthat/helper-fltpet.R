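# shared fixtures built in code; computed once per test run

# default simulated input function (whole blood + metabolite-corrected plasma)
default_aif <- fltpet:::phantom_aif(phantom_config())
default_schedule <- default_frame_schedule()

# small deterministic 4D series for geometry-level tests
tiny_series <- function(dims = c(3, 3, 2), values = NULL,
                        schedule = frame_schedule(c(0, 1, 2), c(1, 1, 2))) {
  nf <- nrow(schedule)
  if (is.null(values)) {
    values <- array(seq_len(prod(dims) * nf) / 10, dim = c(dims, nf))
  }
  pet_series(values, voxel_mm = 3, schedule = schedule)
}

mask_at <- function(dims, idx, label = "roi") {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  roi_mask(m, label)
}

# noise-free frame-averaged measurement of one tissue under the default AIF
clean_frames <- function(params, aif = default_aif,
                         schedule = default_schedule) {
  fine <- fltpet:::model_tac_fine(params, aif, t_max = max(schedule$end_min))
  frame_average(tac(fine$t, fine$ct), schedule)
}

# small, fast phantom for tests that only need geometry + kinetics structure
small_phantom_config <- function(...) {
  args <- list(
    grid_dim = c(24, 24, 14), voxel_mm = 4,
    lesions = list(phantom_lesion(center = c(12, 12, 7), diameter_mm = 30))
  )
  extra <- list(...)
  for (nm in names(extra)) args[[nm]] <- extra[[nm]]
  do.call(phantom_config, args)
}

# independent adaptive-ODE forward model used to cross-check the analytic
# convolution
ode_oracle <- function(params, aif, times, rtol = 1e-9) {
  cp_f <- stats::approxfun(aif$time_min, aif$plasma_parent, yleft = 0, rule = 2)
  cb_f <- stats::approxfun(aif$time_min, aif$whole_blood, yleft = 0, rule = 2)
  rhs <- function(t, y, parms) {
    with(as.list(parms), list(c(
      k1 * cp_f(t) - (k2 + k3) * y[1] + k4 * y[2],
      k3 * y[1] - k4 * y[2])))
  }
  sol <- deSolve::ode(c(0, 0), c(0, times), rhs,
                      c(k1 = params$k1, k2 = params$k2, k3 = params$k3,
                        k4 = params$k4),
                      method = "lsoda", rtol = rtol, atol = 1e-10)
  (1 - params$vb) * (sol[-1, 2] + sol[-1, 3]) + params$vb * cb_f(times)
}
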