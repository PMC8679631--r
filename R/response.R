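#' Percent change in SUV after treatment
#'
#' `100 * (post - pre) / pre`; a -20 means a 20% reduction.
#'
#' @param pre Baseline SUV, must be positive.
#' @param post Post-treatment SUV.
#' @return Percent change, vectorized.
#' @examples
#' percent_change(10, 8)  # -20
#' @export
percent_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    abort("invalid-baseline: baseline SUV must be positive")
  100 * (post - pre) / pre
}

response_levels <- c("responder", "nonresponder", "not_evaluable")

#' PET response from percent SUV change
#'
#' A lesion responds when its SUV60_mean falls by at least `threshold`
#' percent; the boundary is inclusive (a change of exactly `-threshold`
#' responds), following the test-retest reproducibility rationale for the
#' 20% cutoff. `NA` changes propagate as `not_evaluable`.
#'
#' @param change_mean Percent change in SUV60_mean (negative = reduction);
#'   `NA` for not-evaluable lesions.
#' @param threshold Response threshold in percent (default 20).
#' @return Factor with levels `responder`, `nonresponder`, `not_evaluable`.
#' @examples
#' pet_response(c(-55.5, -12.2, -20, NA))
#' @export
pet_response <- function(change_mean, threshold = 20) {
  out <- ifelse(is.na(change_mean), "not_evaluable",
                ifelse(change_mean <= -threshold, "responder", "nonresponder"))
  factor(out, levels = response_levels)
}

#' Dichotomize an mRECIST category
#'
#' Complete and partial responses count as `responder`; stable and
#' progressive disease as `nonresponder`; `NE` (or `NA`) as `not_evaluable`.
#'
#' @param category Character/factor of mRECIST categories
#'   (`CR`, `PR`, `SD`, `PD`, `NE`).
#' @return Factor with levels `responder`, `nonresponder`, `not_evaluable`.
#' @examples
#' mrecist_binary(c("CR", "PR", "SD", "PD", "NE"))
#' @export
mrecist_binary <- function(category) {
  category <- as.character(category)
  category[is.na(category)] <- "NE"
  bad <- setdiff(unique(category), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad))
    abort(paste0("schema-error: unknown mRECIST category: ",
                 paste(bad, collapse = ", ")))
  out <- dplyr::case_match(category,
                           c("CR", "PR") ~ "responder",
                           c("SD", "PD") ~ "nonresponder",
                           "NE" ~ "not_evaluable")
  factor(out, levels = response_levels)
}

#' Cohen kappa for two binary raters
#'
#' Chance-corrected agreement from the 2x2 contingency table:
#' `kappa = (p_o - p_e) / (1 - p_e)`. The confidence interval uses the
#' large-sample (Fleiss) standard error; the p-value tests `kappa = 0` with
#' the standard error under the null.
#'
#' @param x,y Two binary label vectors (factors/characters/logicals) of equal
#'   length, or `x` a 2x2 count matrix with `y` omitted.
#' @param conf_level Confidence level for the interval.
#' @return A list of class `concordance`: `kappa`, `se`, `conf_low`,
#'   `conf_high`, `p_value`, `counts` (2x2), `n`, `p_observed`, `p_expected`.
#'   Has [tidy()] and `print()` methods.
#' @examples
#' cohen_kappa(matrix(c(12, 2, 2, 8), 2, byrow = TRUE))
#' @export
cohen_kappa <- function(x, y = NULL, conf_level = 0.95) {
  if (is.matrix(x)) {
    counts <- x
    if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
      abort("counts must be a nonnegative 2x2 matrix")
  } else {
    if (length(x) != length(y)) abort("label vectors must have equal length")
    x <- if (is.factor(x)) droplevels(x) else factor(x)
    y <- factor(as.character(y), levels = levels(x))
    if (nlevels(x) > 2L) abort("labels must be binary")
    counts <- table(x, y)
    counts <- matrix(as.numeric(counts), nrow(counts))
  }
  n <- sum(counts)
  if (n < 2L) abort("kappa needs n >= 2")
  p <- counts / n
  row_m <- rowSums(p); col_m <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(row_m * col_m)
  if (1 - p_e < 1e-12)
    abort("undefined-kappa: degenerate marginals (p_e = 1)")
  kappa <- (p_o - p_e) / (1 - p_e)

  # Fleiss large-sample variance
  idx <- seq_len(nrow(p))
  termA <- sum(diag(p) * (1 - (row_m + col_m) * (1 - kappa))^2)
  termB <- 0
  for (i in idx) for (j in idx) if (i != j)
    termB <- termB + p[i, j] * (col_m[i] + row_m[j])^2
  termB <- termB * (1 - kappa)^2
  termC <- (kappa - p_e * (1 - kappa))^2
  se <- sqrt((termA + termB - termC) / (n * (1 - p_e)^2))
  # variance under H0: kappa = 0
  var0 <- (p_e + p_e^2 - sum(row_m * col_m * (row_m + col_m))) /
    (n * (1 - p_e)^2)
  z <- kappa / sqrt(var0)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(kappa = kappa, se = se,
         conf_low = kappa - zq * se, conf_high = kappa + zq * se,
         p_value = 2 * pnorm(-abs(z)), counts = counts, n = n,
         p_observed = p_o, p_expected = p_e, conf_level = conf_level),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Cohen kappa = %.3f (%.0f%% CI %.3f-%.3f), p = %.2g, n = %d\n",
              x$kappa, 100 * x$conf_level, x$conf_low, x$conf_high,
              x$p_value, x$n))
  invisible(x)
}

#' @method tidy concordance
#' @export
tidy.concordance <- function(x, ...) {
  tibble(kappa = x$kappa, std.error = x$se, conf.low = x$conf_low,
         conf.high = x$conf_high, p.value = x$p_value, n = x$n)
}

#' Wilcoxon rank test between or within groups
#'
#' Rank-sum for independent groups, signed-rank when `paired`; exact
#' small-sample null distribution where the data permit (no ties), following
#' [stats::wilcox.test()].
#'
#' @param group_a,group_b Numeric vectors, each with at least 3 values.
#' @param paired Use the signed-rank test on paired differences.
#' @return A one-row tibble: `statistic`, `p_value`, `method`.
#' @export
wilcoxon_rank <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    abort("each group needs n >= 3")
  if (length(unique(c(group_a, group_b))) == 1L)
    abort("degenerate-test: all observations are tied")
  res <- suppressWarnings(wilcox.test(group_a, group_b, paired = paired))
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         method = res$method)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (set `correct = TRUE` for Yates).
#'
#' @param counts 2x2 nonnegative count matrix.
#' @param correct Apply the continuity correction.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  if (!is.matrix(counts) || !all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    abort("counts must be a nonnegative 2x2 matrix")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort("degenerate-table: a marginal total is zero")
  res <- suppressWarnings(chisq.test(counts, correct = correct))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
}

visual_category <- function(x) {
  x <- tolower(as.character(x))
  dplyr::case_when(
    grepl("rim", x) ~ "rim",
    grepl("mixed", x) ~ "mixed",
    grepl("hyper", x) ~ "hyperintense",
    grepl("hypo", x) ~ "hypotense",
    grepl("iso", x) ~ "isotense",
    TRUE ~ NA_character_
  )
}

#' Load the packaged lesion-level response table
#'
#' Reads the lesion table fixture (26 HCC lesions, 16 patients) or any CSV in
#' the same schema. `"NE"` entries become `NA` with the corresponding
#' `*_evaluable` flags set to `FALSE`; the verbatim visual-uptake text is kept
#' alongside a derived 5-level category.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A tibble with one row per lesion: identifiers, size, visual
#'   category, baseline SUVs, mRECIST, percent changes, evaluability flags
#'   and derived response labels.
#' @examples
#' load_table1()
#' @export
load_table1 <- function(path = fltpet_example("table1_lesions.csv")) {
  raw <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(paste0("parse-error: ", conditionMessage(e))))
  need <- c("patient_id", "lesion_location", "size_mm", "visual_uptake",
            "background_suv_mean", "suv60_mean_pre", "suv60_max_pre",
            "mrecist", "pct_change_mean", "pct_change_max")
  miss <- setdiff(need, names(raw))
  if (nrow(raw) == 0L || length(miss))
    abort(paste0("parse-error: missing or empty columns: ",
                 paste(miss, collapse = ", ")))
  num_ne <- function(x) suppressWarnings(as.numeric(ifelse(x == "NE", NA, x)))
  out <- tibble(
    patient_id = as.integer(raw$patient_id),
    lesion_location = raw$lesion_location,
    size_mm = as.numeric(raw$size_mm),
    visual_uptake = visual_category(raw$visual_uptake),
    visual_uptake_verbatim = raw$visual_uptake,
    background_suv_mean = as.numeric(raw$background_suv_mean),
    suv60_mean_pre = as.numeric(raw$suv60_mean_pre),
    suv60_max_pre = as.numeric(raw$suv60_max_pre),
    mrecist = factor(ifelse(raw$mrecist == "NE", "NE", raw$mrecist),
                     levels = c("CR", "PR", "SD", "PD", "NE")),
    pct_change_mean = num_ne(raw$pct_change_mean),
    pct_change_max = num_ne(raw$pct_change_max),
    pfs_months = num_ne(raw$pfs_months %||% rep(NA_character_, nrow(raw))),
    note = raw$note %||% rep(NA_character_, nrow(raw))
  )
  if (any(out$size_mm <= 0, na.rm = TRUE))
    abort("parse-error: lesion sizes must be positive")
  if (any(out$pct_change_mean <= -100, na.rm = TRUE))
    abort("parse-error: percent changes must be > -100")
  out$pet_evaluable <- !is.na(out$pct_change_mean)
  out$mrecist_evaluable <- out$mrecist != "NE"
  out$pet_label <- pet_response(out$pct_change_mean)
  out$mrecist_label <- mrecist_binary(as.character(out$mrecist))
  out
}

#' Load the packaged baseline kinetic-parameter table
#'
#' Reads the two-tissue-compartment fixture (14 subjects) or any CSV in the
#' same schema. The blood-volume column is transcribed verbatim; entries that
#' parse outside the physical fraction range `[0, 1)` are kept but flagged via
#' `vb_flag` rather than corrected. `ki` is recomputed from the rate
#' constants; `ki_printed` keeps the published rounding.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A tibble: `patient_id`, `k1`, `k2`, `k3`, `k4`, `vb`,
#'   `vb_verbatim`, `vb_flag`, `ki_printed`, `ki`.
#' @examples
#' load_table2()
#' @export
load_table2 <- function(path = fltpet_example("table2_kinetics.csv")) {
  raw <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(paste0("parse-error: ", conditionMessage(e))))
  need <- c("patient_id", "k1", "k2", "k3", "k4", "vb", "ki_printed")
  miss <- setdiff(need, names(raw))
  if (nrow(raw) == 0L || length(miss))
    abort(paste0("parse-error: missing or empty columns: ",
                 paste(miss, collapse = ", ")))
  vb <- suppressWarnings(as.numeric(raw$vb))
  out <- tibble(
    patient_id = as.integer(raw$patient_id),
    k1 = as.numeric(raw$k1), k2 = as.numeric(raw$k2),
    k3 = as.numeric(raw$k3), k4 = as.numeric(raw$k4),
    vb = vb, vb_verbatim = raw$vb,
    vb_flag = !is.finite(vb) | vb < 0 | vb >= 1,
    ki_printed = as.numeric(raw$ki_printed)
  )
  out$ki <- ki(out)
  out
}

#' Cohort aggregates of the lesion table
#'
#' Mean, SD and median of baseline SUVs and percent changes over evaluable
#' lesions (not-evaluable rows are excluded from each aggregate they cannot
#' contribute to), plus responder counts under the PET rule and under
#' mRECIST.
#'
#' @param records A [load_table1()]-schema tibble.
#' @param threshold PET response threshold in percent.
#' @return A one-row tibble of aggregates.
#' @export
cohort_summary <- function(records, threshold = 20) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("no-data: empty record set")
  pet_lab <- pet_response(records$pct_change_mean, threshold)
  mr_lab <- mrecist_binary(as.character(records$mrecist))
  pet_ok <- pet_lab != "not_evaluable"
  mr_ok <- mr_lab != "not_evaluable"
  if (!any(pet_ok) && !any(mr_ok)) abort("no-data: no evaluable lesion")
  tibble(
    n_lesions = nrow(records),
    n_patients = dplyr::n_distinct(records$patient_id),
    mean_suv60_mean_pre = mean(records$suv60_mean_pre),
    sd_suv60_mean_pre = sd(records$suv60_mean_pre),
    mean_suv60_max_pre = mean(records$suv60_max_pre),
    sd_suv60_max_pre = sd(records$suv60_max_pre),
    n_pet_evaluable = sum(pet_ok),
    mean_pct_change_mean = mean(records$pct_change_mean[pet_ok]),
    sd_pct_change_mean = sd(records$pct_change_mean[pet_ok]),
    median_pct_change_mean = median(records$pct_change_mean[pet_ok]),
    mean_pct_change_max = mean(records$pct_change_max[pet_ok]),
    sd_pct_change_max = sd(records$pct_change_max[pet_ok]),
    pet_responders = sum(pet_lab == "responder"),
    n_mrecist_evaluable = sum(mr_ok),
    mrecist_responders = sum(mr_lab == "responder")
  )
}

#' Concordance between PET and mRECIST response over a lesion table
#'
#' Restricts to lesions evaluable under both systems and runs
#' [cohen_kappa()] on the paired binary labels.
#'
#' @inheritParams cohort_summary
#' @return A `concordance` object (see [cohen_kappa()]).
#' @export
response_concordance <- function(records, threshold = 20) {
  records <- as_tibble(records)
  pet_lab <- pet_response(records$pct_change_mean, threshold)
  mr_lab <- mrecist_binary(as.character(records$mrecist))
  both <- pet_lab != "not_evaluable" & mr_lab != "not_evaluable"
  cohen_kappa(droplevels(pet_lab[both]), droplevels(mr_lab[both]))
}
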