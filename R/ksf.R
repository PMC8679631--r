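#' Kinetic spatial filter configuration
#'
#' The kinetic spatial filter (KSF) classifies every voxel's time-activity
#' curve against normalized tissue-class template curves, spatially
#' regularizes the class map by neighborhood-majority relabeling, and zeroes
#' voxels of the excluded classes (typically liver) in the summed image so
#' that physiologic hepatic uptake is suppressed.
#'
#' @param distance Curve distance: `"normalized-L2"` (Euclidean distance
#'   between normalized curves, the default) or `"one-minus-correlation"`.
#' @param normalization `"unit-area"` (trapezoid integral 1, isolating
#'   kinetic shape from amplitude; the default) or `"unit-peak"`.
#' @param spatial_filter_radius Radius, in voxels, of the cubic
#'   majority-relabeling neighborhood; 0 disables the spatial step.
#' @param exclusion_classes Template names whose voxels are zeroed.
#' @return A list of class `ksf_config`.
#' @export
ksf_config <- function(distance = c("normalized-L2", "one-minus-correlation"),
                       normalization = c("unit-area", "unit-peak"),
                       spatial_filter_radius = 1,
                       exclusion_classes = "liver") {
  distance <- match.arg(distance)
  normalization <- match.arg(normalization)
  if (spatial_filter_radius < 0) abort("spatial_filter_radius must be >= 0")
  structure(list(distance = distance, normalization = normalization,
                 spatial_filter_radius = as.integer(spatial_filter_radius),
                 exclusion_classes = as.character(exclusion_classes)),
            class = "ksf_config")
}

normalize_curve_values <- function(values, times, normalization) {
  scale <- switch(normalization,
                  `unit-area` = trapz(times, values),
                  `unit-peak` = max(values))
  if (!is.finite(scale) || scale <= 0) return(NULL)
  values / scale
}

#' Build tissue-class template curves from reference ROIs
#'
#' Per-class mean time-activity curve, normalized per the config so templates
#' encode kinetic shape rather than amplitude.
#'
#' @param series A [pet_series()].
#' @param class_masks Named list of disjoint [roi_mask()]s, one per tissue
#'   class (e.g. `liver`, `tumor`, `blood`). List the conservative class
#'   (liver) first: classification ties break by template order.
#' @param config A [ksf_config()].
#' @return A tibble of class `ksf_templates`: columns `class`, `time_min`,
#'   `value` (one normalized curve per class, in the given order).
#' @export
build_templates <- function(series, class_masks, config = ksf_config()) {
  stopifnot(inherits(series, "pet_series"), length(class_masks) >= 1L)
  if (is.null(names(class_masks)) || any(names(class_masks) == ""))
    abort("class_masks must be a named list")
  tot <- Reduce(`+`, lapply(class_masks, function(m) m$mask * 1L))
  if (any(tot > 1L)) abort("mask-conflict: class masks must be disjoint")
  out <- purrr::map_dfr(names(class_masks), function(nm) {
    cv <- extract_tac(series, class_masks[[nm]])
    v <- normalize_curve_values(cv$value, cv$time_min, config$normalization)
    if (is.null(v)) abort(paste0("template '", nm, "' has nonpositive scale"))
    tibble(class = nm, time_min = cv$time_min, value = v)
  })
  out$class <- factor(out$class, levels = names(class_masks))
  class(out) <- c("ksf_templates", class(out))
  out
}

#' Classify voxels by nearest kinetic template
#'
#' Each voxel's TAC is normalized per the config and assigned to the nearest
#' template under the configured distance. All-zero voxels (no measurable
#' activity, e.g. outside the body) are assigned the reserved class
#' `"other"`. Ties break in template order, so putting liver first yields
#' conservative suppression.
#'
#' @param series A [pet_series()].
#' @param templates A [build_templates()] result with at least 2 classes.
#' @param config A [ksf_config()].
#' @return A 3D character array of class labels.
#' @export
classify_voxels <- function(series, templates, config = ksf_config()) {
  stopifnot(inherits(series, "pet_series"), inherits(templates, "ksf_templates"))
  classes <- intersect(levels(templates$class),
                       unique(as.character(templates$class)))
  if (length(classes) < 2L) abort("need at least 2 templates")
  times <- unique(templates$time_min)
  if (!isTRUE(all.equal(times, series$schedule$mid_min)))
    abort("templates must be sampled at the series frame mid-times")
  nf <- length(times)
  Tm <- vapply(classes, function(cl)
    templates$value[templates$class == cl], numeric(nf))

  V <- matrix(series$values, ncol = nf)
  scale <- switch(config$normalization,
                  `unit-area` = as.numeric(V %*% trapz_weights(times)),
                  `unit-peak` = apply(V, 1L, max))
  ok <- is.finite(scale) & scale > 0
  Vn <- V[ok, , drop = FALSE] / scale[ok]

  if (config$distance == "normalized-L2") {
    # ||v - t||^2 = ||v||^2 - 2 v.t + ||t||^2; argmin over templates
    cross <- Vn %*% Tm
    d2 <- -2 * cross + matrix(colSums(Tm^2), nrow(Vn), ncol(Tm), byrow = TRUE)
  } else {
    vc <- Vn - rowMeans(Vn)
    tc <- sweep(Tm, 2, colMeans(Tm))
    denom <- outer(sqrt(rowSums(vc^2)), sqrt(colSums(tc^2)))
    r <- (vc %*% tc) / denom
    r[!is.finite(r)] <- 0
    d2 <- 1 - r
  }
  assign_idx <- max.col(-d2, ties.method = "first")

  lab <- rep("other", nrow(V))
  lab[ok] <- classes[assign_idx]
  array(lab, dim = dim(series$values)[1:3])
}

# neighborhood-majority (mode) relabeling of a label array within a cubic
# radius; ties keep the first class in `order_levels`
majority_filter <- function(class_map, radius, order_levels) {
  if (radius <= 0L) return(class_map)
  d <- dim(class_map)
  counts <- lapply(order_levels, function(cl) {
    b <- array(0, d)
    src <- array(as.numeric(class_map == cl), d)
    for (dx in -radius:radius) for (dy in -radius:radius) for (dz in -radius:radius) {
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
      b <- b + src[xs, ys, zs]
    }
    b
  })
  stacked <- array(unlist(counts), dim = c(d, length(order_levels)))
  flat <- matrix(stacked, ncol = length(order_levels))
  win <- max.col(flat, ties.method = "first")
  array(order_levels[win], dim = d)
}

#' Apply the kinetic spatial filter
#'
#' Majority-relabels the class map within the configured radius, computes the
#' summed image over the window, and zeroes every voxel whose (relabeled)
#' class is in `exclusion_classes`.
#'
#' @param series A [pet_series()].
#' @param class_map 3D label array from [classify_voxels()].
#' @param config A [ksf_config()].
#' @param window Summed-image window `(start, end)` minutes.
#' @return An object of class `ksf_result`: `class_map` (after relabeling),
#'   `filtered_summed`, `unfiltered_summed`, `config`, `window`.
#' @export
apply_ksf <- function(series, class_map, config = ksf_config(),
                      window = c(50, 60)) {
  stopifnot(inherits(series, "pet_series"))
  if (!identical(dim(class_map), dim(series$values)[1:3]))
    abort("geometry-error: class map grid does not match the series")
  lev <- unique(as.vector(class_map))
  # keep liver-first ordering if present so majority ties stay conservative
  lev <- c(intersect(c("liver", "tumor", "blood"), lev),
           setdiff(lev, c("liver", "tumor", "blood")))
  relabeled <- majority_filter(class_map, config$spatial_filter_radius, lev)
  unfiltered <- summed_image(series, window)
  filtered <- unfiltered
  filtered[relabeled %in% config$exclusion_classes] <- 0
  structure(list(class_map = relabeled, filtered_summed = filtered,
                 unfiltered_summed = unfiltered, config = config,
                 window = window),
            class = "ksf_result")
}

#' Signal-suppression metrics of a KSF run
#'
#' Per-ROI percent signal reduction
#' `100 * (1 - mean(filtered) / mean(unfiltered))` and the post-filter
#' tumor-to-liver ratio (filtered tumor max over filtered liver mean). A zero
#' filtered liver mean (complete background removal) reports the ratio as
#' `Inf` and sets `liver_fully_suppressed`.
#'
#' @param ksf A [apply_ksf()] result (or a list with `filtered_summed` and
#'   `unfiltered_summed` arrays).
#' @param tumor_mask,liver_mask [roi_mask()]s on the image grid.
#' @return A one-row tibble: `tumor_pct_reduction`, `liver_pct_reduction`,
#'   `post_filter_tumor_to_liver`, `liver_fully_suppressed`.
#' @export
ksf_metrics <- function(ksf, tumor_mask, liver_mask) {
  u <- ksf$unfiltered_summed; f <- ksf$filtered_summed
  check_grid(dim(u), tumor_mask); check_grid(dim(u), liver_mask)
  pct_red <- function(mask) {
    mu <- mean(u[mask$mask])
    if (mu <= 0) abort("degenerate-roi: unfiltered ROI mean is zero")
    100 * (1 - mean(f[mask$mask]) / mu)
  }
  liver_mean_f <- mean(f[liver_mask$mask])
  tibble(
    tumor_pct_reduction = pct_red(tumor_mask),
    liver_pct_reduction = pct_red(liver_mask),
    post_filter_tumor_to_liver =
      if (liver_mean_f > 0) max(f[tumor_mask$mask]) / liver_mean_f else Inf,
    liver_fully_suppressed = liver_mean_f <= 0
  )
}

#' @method autoplot ksf_result
#' @export
autoplot.ksf_result <- function(object, slice = NULL, ...) {
  d <- dim(object$unfiltered_summed)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- dplyr::bind_rows(
    tibble(x = rep(seq_len(d[1]), d[2]),
           y = rep(seq_len(d[2]), each = d[1]),
           value = as.vector(object$unfiltered_summed[, , slice]),
           panel = "unfiltered"),
    tibble(x = rep(seq_len(d[1]), d[2]),
           y = rep(seq_len(d[2]), each = d[1]),
           value = as.vector(object$filtered_summed[, , slice]),
           panel = "filtered")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "kBq/mL") +
    ggplot2::labs(title = sprintf("kinetic spatial filter, slice z = %d", slice))
}
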