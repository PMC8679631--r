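# two-class toy series: slab A washes out, slab B accumulates
toy_ksf_series <- function(noise = 0, seed = 1) {
  sched <- frame_schedule(0:5, rep(1, 6))
  d <- c(6, 4, 3)
  liver_curve <- c(8, 6, 4, 3, 2.5, 2)
  tumor_curve <- c(1, 2, 3.5, 5, 6, 7)
  vals <- array(0, c(d, 6))
  for (f in 1:6) {
    vals[1:3, , , f] <- liver_curve[f]
    vals[4:6, , , f] <- tumor_curve[f]
  }
  if (noise > 0) {
    set.seed(seed)
    vals <- pmax(vals + array(rnorm(length(vals), 0, noise), dim(vals)), 0)
  }
  liver <- array(FALSE, d); liver[1:3, , ] <- TRUE
  tumor <- array(FALSE, d); tumor[4:6, , ] <- TRUE
  list(series = pet_series(vals, 3, sched),
       masks = list(liver = roi_mask(liver, "liver"),
                    tumor = roi_mask(tumor, "tumor")))
}

test_that("templates are normalized per-class mean curves", {
  toy <- toy_ksf_series()
  tpl <- build_templates(toy$series, toy$masks)
  expect_setequal(levels(tpl$class), c("liver", "tumor"))
  for (cl in c("liver", "tumor")) {
    sub <- tpl[tpl$class == cl, ]
    expect_equal(fltpet:::trapz(sub$time_min, sub$value), 1, tolerance = 1e-9)
    expect_true(all(sub$value >= 0))
  }
  # one-voxel class: template is that voxel's normalized TAC
  one <- mask_at(dim(toy$series$values)[1:3], cbind(1, 1, 1), "one")
  tpl1 <- build_templates(toy$series, list(one = one))
  v <- extract_tac(toy$series, one)
  expect_equal(tpl1$value, v$value / fltpet:::trapz(v$time_min, v$value))
  # identical kinetics give identical templates regardless of voxel counts
  small <- mask_at(dim(toy$series$values)[1:3], cbind(1, 1, 1), "a")
  big <- roi_mask(toy$masks$liver$mask & !small$mask, "b")
  tpl2 <- build_templates(toy$series, list(a = small, b = big))
  expect_equal(tpl2$value[tpl2$class == "a"], tpl2$value[tpl2$class == "b"])
  # overlapping masks are refused
  expect_error(build_templates(toy$series,
                               list(liver = toy$masks$liver,
                                    dup = toy$masks$liver)),
               "mask-conflict")
})

test_that("voxels classify to the nearest template, scale-invariantly", {
  toy <- toy_ksf_series()
  tpl <- build_templates(toy$series, toy$masks)
  cm <- classify_voxels(toy$series, tpl)
  expect_true(all(cm[toy$masks$liver$mask] == "liver"))
  expect_true(all(cm[toy$masks$tumor$mask] == "tumor"))
  # scaling a voxel's TAC by 5 does not change its class
  scaled <- toy$series
  scaled$values[1, 1, 1, ] <- 5 * scaled$values[1, 1, 1, ]
  cm2 <- classify_voxels(pet_series(scaled$values, 3, toy$series$schedule), tpl)
  expect_equal(cm2[1, 1, 1], "liver")
  # all-zero TAC falls back to "other"
  z <- toy$series$values; z[6, 4, 3, ] <- 0
  cm3 <- classify_voxels(pet_series(z, 3, toy$series$schedule), tpl)
  expect_equal(cm3[6, 4, 3], "other")
  expect_error(classify_voxels(toy$series, tpl[tpl$class == "liver", ]),
               "at least 2 templates")
})

test_that("classification holds under both distances and normalizations", {
  toy <- toy_ksf_series(noise = 0.3)
  for (dist in c("normalized-L2", "one-minus-correlation")) {
    for (norm in c("unit-area", "unit-peak")) {
      cfg <- ksf_config(distance = dist, normalization = norm)
      tpl <- build_templates(toy$series, toy$masks, cfg)
      cm <- classify_voxels(toy$series, tpl, cfg)
      acc <- mean(c(cm[toy$masks$liver$mask] == "liver",
                    cm[toy$masks$tumor$mask] == "tumor"))
      expect_gt(acc, 0.95)
    }
  }
})

test_that("majority relabeling repairs isolated misclassifications", {
  toy <- toy_ksf_series()
  tpl <- build_templates(toy$series, toy$masks)
  cm <- classify_voxels(toy$series, tpl)
  cm[2, 2, 2] <- "tumor"  # isolated island inside the liver slab
  res <- apply_ksf(toy$series, cm, ksf_config(spatial_filter_radius = 1),
                   window = c(0, 6))
  expect_equal(res$class_map[2, 2, 2], "liver")
  expect_equal(res$filtered_summed[2, 2, 2], 0)
})

test_that("exclusion zeroes excluded classes and nothing else", {
  toy <- toy_ksf_series()
  tpl <- build_templates(toy$series, toy$masks)
  cm <- classify_voxels(toy$series, tpl)
  # empty exclusion set: identity on the summed image
  noop <- apply_ksf(toy$series, cm,
                    ksf_config(exclusion_classes = character(0)),
                    window = c(0, 6))
  expect_equal(noop$filtered_summed, noop$unfiltered_summed)
  # excluding everything suppresses the whole image
  all_liver <- array("liver", dim(toy$series$values)[1:3])
  tot <- apply_ksf(toy$series, all_liver, ksf_config(), window = c(0, 6))
  expect_true(all(tot$filtered_summed == 0))
  # filtered never exceeds unfiltered, and excluded voxels are exactly zero
  res <- apply_ksf(toy$series, cm, ksf_config(), window = c(0, 6))
  expect_true(all(res$filtered_summed <= res$unfiltered_summed + 1e-12))
  expect_true(all(res$filtered_summed[res$class_map == "liver"] == 0))
})

test_that("suppression is monotone in the exclusion set", {
  toy <- toy_ksf_series(noise = 0.2)
  tpl <- build_templates(toy$series, toy$masks)
  cm <- classify_voxels(toy$series, tpl)
  r1 <- apply_ksf(toy$series, cm, ksf_config(exclusion_classes = "liver"),
                  window = c(0, 6))
  r2 <- apply_ksf(toy$series, cm,
                  ksf_config(exclusion_classes = c("liver", "tumor")),
                  window = c(0, 6))
  expect_true(all(r2$filtered_summed <= r1$filtered_summed + 1e-12))
})

test_that("suppression metrics report percent reductions and the ratio", {
  toy <- toy_ksf_series()
  u <- summed_image(toy$series, c(0, 6))
  same <- list(unfiltered_summed = u, filtered_summed = u)
  m0 <- ksf_metrics(same, toy$masks$tumor, toy$masks$liver)
  expect_equal(m0$tumor_pct_reduction, 0)
  expect_equal(m0$liver_pct_reduction, 0)
  gone <- u; gone[toy$masks$liver$mask] <- 0
  m1 <- ksf_metrics(list(unfiltered_summed = u, filtered_summed = gone),
                    toy$masks$tumor, toy$masks$liver)
  expect_equal(m1$liver_pct_reduction, 100)
  expect_true(m1$liver_fully_suppressed)
  expect_equal(m1$post_filter_tumor_to_liver, Inf)
})

test_that("the default phantom suppresses liver while the tumor survives", {
  ph <- generate_phantom(small_phantom_config(seed = 3))
  masks <- ph$truth$class_masks
  tpl <- build_templates(ph$series, list(liver = masks$liver,
                                         tumor = masks$tumor_1,
                                         blood = masks$blood))
  cm <- classify_voxels(ph$series, tpl)
  acc_liver <- mean(cm[masks$liver$mask] == "liver")
  acc_tumor <- mean(cm[masks$tumor_1$mask] == "tumor")
  expect_gte(acc_liver, 0.95)
  expect_gte(acc_tumor, 0.95)
  res <- apply_ksf(ph$series, cm)
  met <- ksf_metrics(res, masks$tumor_1, masks$liver)
  expect_gt(met$liver_pct_reduction, 90)
  expect_lt(met$tumor_pct_reduction, 50)  # > 50% of tumor signal survives
})
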