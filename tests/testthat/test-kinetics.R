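test_that("Ki derives from the rate constants with a zero-trapping limit", {
  expect_equal(ki(two_tissue_params(0.31, 0.40, 0.24)), 0.11625)
  expect_equal(ki(two_tissue_params(0.16, 0.10, 0.10)), 0.08)
  expect_equal(ki(0.11, k2 = 0.16, k3 = 0.04), 0.022)
  expect_equal(ki(two_tissue_params(0.5, 0.3, 0)), 0)
  expect_equal(ki(two_tissue_params(0.5, 0, 0)), 0)
  # monotone in k3, all else fixed
  k3s <- seq(0, 1, by = 0.05)
  expect_true(all(diff(ki(rep(0.3, 21), k2 = rep(0.4, 21), k3 = k3s)) >= 0))
})

test_that("forward model degenerates correctly without delivery", {
  p <- two_tissue_params(0, 0.3, 0.1, 0.02, 0.07)
  times <- seq(0.5, 59, by = 0.5)
  m <- model_tac(p, default_aif, times)
  cb <- approx(default_aif$time_min, default_aif$whole_blood, times)$y
  expect_equal(m$value, 0.07 * cb, tolerance = 1e-9)
})

test_that("forward model reduces to the one-tissue closed form", {
  # vb = 0, k3 = k4 = 0: C_T = K1 exp(-k2 t) (x) Cp; oracle by fine quadrature
  p <- two_tissue_params(0.4, 0.25, 0, 0, 0)
  times <- seq(1, 50, by = 1)
  m <- model_tac(p, default_aif, times)
  fine_t <- seq(0, 50, by = 0.002)
  cp <- approx(default_aif$time_min, default_aif$plasma_parent, fine_t,
               yleft = 0, rule = 2)$y
  oracle <- vapply(times, function(tt) {
    idx <- fine_t <= tt
    fltpet:::trapz(fine_t[idx],
                   cp[idx] * 0.4 * exp(-0.25 * (tt - fine_t[idx])))
  }, numeric(1))
  expect_equal(m$value, oracle, tolerance = 5e-4)
})

test_that("analytic convolution agrees with a stiff ODE integrator", {
  times <- seq(0.25, 59, by = 0.25)
  p3 <- two_tissue_params(0.31, 0.40, 0.24, 0.04, 0.019)
  m <- model_tac(p3, default_aif, times)
  ct <- ode_oracle(p3, default_aif, times)
  expect_lt(max(abs(m$value - ct) / pmax(abs(ct), 1e-3)), 1e-3)
  # random valid draws, including near-degenerate eigenrates
  set.seed(101)
  for (i in 1:10) {
    p <- two_tissue_params(runif(1, 0.05, 1), runif(1, 0.02, 1),
                           runif(1, 0, 0.5), runif(1, 0, 0.3),
                           runif(1, 0, 0.3))
    m <- model_tac(p, default_aif, times)
    ct <- ode_oracle(p, default_aif, times)
    expect_lt(max(abs(m$value - ct) / pmax(abs(ct), 1e-3)), 1e-3)
  }
})

test_that("frame averaging is exact for constants and linear curves", {
  sched <- frame_schedule(c(0, 1, 3), c(1, 2, 3))
  const <- tac(seq(0, 6, 0.5), rep(4.2, 13))
  expect_equal(frame_average(const, sched)$value, rep(4.2, 3))
  lin <- tac(seq(0, 6, 0.5), 2 + 3 * seq(0, 6, 0.5))
  expect_equal(frame_average(lin, sched)$value, 2 + 3 * sched$mid_min)
  # bi-exponential vs fine numeric quadrature
  tt <- seq(0, 6, by = 0.01)
  curve <- tac(tt, 5 * exp(-0.8 * tt) + 2 * exp(-0.05 * tt))
  got <- frame_average(curve, sched)$value
  oracle <- vapply(seq_len(3), function(i) {
    f <- function(x) 5 * exp(-0.8 * x) + 2 * exp(-0.05 * x)
    stats::integrate(f, sched$start_min[i], sched$end_min[i])$value /
      sched$duration_min[i]
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-4)
  expect_error(frame_average(const, frame_schedule(0, 10)), "range-error")
})

test_that("noise-free inverse-crime fits recover the generating parameters", {
  p3 <- two_tissue_params(0.31, 0.40, 0.24, 0.04, 0.019)
  obs <- clean_frames(p3)
  fit <- fit_2tcm(obs, default_aif, default_schedule)
  est <- unlist(fit$params)[c("k1", "k2", "k3", "k4", "vb")]
  truth <- unlist(p3)[c("k1", "k2", "k3", "k4", "vb")]
  expect_true(all(abs(est - truth) / truth < 0.01))
  expect_equal(fit$ki, ki(fit$params), tolerance = 1e-12)
  # objective at the optimum is no worse than at the truth
  w <- fltpet:::frame_weights(obs$value, default_schedule, "duration")
  rss_truth <- sum(w * (clean_frames(p3)$value - obs$value)^2)
  expect_lte(fit$weighted_rss, rss_truth + 1e-12)
})

test_that("a pure blood-volume TAC yields a near-zero delivery estimate", {
  p <- two_tissue_params(0, 0.3, 0.1, 0.02, 0.08)
  obs <- clean_frames(p)
  fit <- fit_2tcm(obs, default_aif, default_schedule,
                  fit_config(n_starts = 8))
  expect_lt(fit$params$k1, 1e-3)
  expect_equal(fit$params$vb, 0.08, tolerance = 0.01)
})

test_that("fit guards identifiability and exposes tidy/glance accessors", {
  p <- two_tissue_params(0.3, 0.3, 0.1, 0.02, 0.05)
  obs <- clean_frames(p)
  short <- tac(obs$time_min[1:5], obs$value[1:5])
  expect_error(fit_2tcm(short, default_aif,
                        frame_schedule(default_schedule$start_min[1:5],
                                       default_schedule$duration_min[1:5])),
               "at least 8 frames")
  fit <- fit_2tcm(obs, default_aif, default_schedule, fit_config(n_starts = 4))
  td <- tidy(fit)
  expect_equal(td$term, c("k1", "k2", "k3", "k4", "vb"))
  expect_equal(nrow(glance(fit)), 1L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("cohort kinetic summary reproduces table-level aggregates", {
  t2 <- load_table2()
  s <- kinetic_cohort_summary(t2)
  expect_equal(s$mean[s$parameter == "k1"], 0.303, tolerance = 1e-3)
  expect_equal(s$n[s$parameter == "k1"], 14L)
  # repeated single value has zero SD
  rep2 <- tibble::tibble(patient_id = 1:3, k1 = c(0.2, 0.2, 0.2),
                         k2 = 1, k3 = 1, k4 = 0, vb = 0)
  expect_equal(kinetic_cohort_summary(rep2)$sd[1], 0)
  # paired post table gives per-parameter changes and a signed-rank p
  post <- dplyr::mutate(t2, k1 = k1 * 0.4, k3 = k3 * 0.6)
  ps <- kinetic_cohort_summary(t2, post)
  expect_equal(ps$mean_pct_change[ps$parameter == "k1"], -60, tolerance = 1e-9)
  expect_lt(ps$p_value[ps$parameter == "k1"], 0.001)
  expect_error(kinetic_cohort_summary(t2, post[1:5, ]), "pairing-error")
})
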