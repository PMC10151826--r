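#' Counter-current climbing index
#'
#' Weighted average of negative-geotaxis performance over five successive
#' counter-current trials. With `n0` the number of flies that failed the
#' first trial and `n1..n5` the numbers that passed each successive trial,
#' the index is
#' \deqn{CI = \frac{\sum_{i=0}^{5} i\,n_i}{5\sum_{i=0}^{5} n_i}}
#' ranging from 0 (all flies in chamber 0) to 1 (all flies in chamber 5).
#' Deterministic; invariant to uniform scaling of the counts and monotone in
#' moving flies to higher chambers.
#'
#' @param counts Numeric vector `c(n0, n1, n2, n3, n4, n5)` of non-negative
#'   chamber counts summing to at least 1.
#' @return The climbing index in `[0, 1]`.
#' @examples
#' climbing_index(c(0, 0, 0, 0, 0, 12))  # perfect climbers -> 1
#' @export
climbing_index <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 6L || any(is.na(counts)) || any(counts < 0))
    mrdam_stop("counts must be six non-negative values n0..n5",
               "mrdam_validation_error")
  total <- sum(counts)
  if (total < 1)
    mrdam_stop("at least one fly required for a climbing index",
               "mrdam_validation_error")
  sum((0:5) * counts) / (5 * total)
}

#' CAFE capillary feeding consumption
#'
#' Converts graduated-microcapillary displacements to volume and reports
#' intake per fly (and per fly per hour): with displacements `d_c` (mm) over
#' the vial's capillaries, calibration `k` (mm per microlitre, from the 1-ul
#' graduation marks) and `N` flies feeding for `T` hours,
#' \deqn{intake = \frac{\sum_c d_c / k}{N} \ \mu l/fly,\qquad
#'       rate = intake / T \ \mu l/fly/h.}
#' Missing capillary readings (`NA`) are skipped with a warning; negative
#' displacements are a data-entry error.
#'
#' @param displacement_mm Numeric vector of per-capillary displacements (mm);
#'   the standard vial carries 6 capillaries.
#' @param calibration_mm_per_ul Millimetres of capillary per microlitre.
#' @param n_flies Number of flies in the vial (>= 1).
#' @param duration_h Feeding duration in hours (the standard protocol uses
#'   19 h).
#' @return List: `ul_per_fly`, `ul_per_fly_per_h`, `total_ul`.
#' @examples
#' cafe_consumption(rep(32.5, 6), calibration_mm_per_ul = 6.5, n_flies = 8)
#' @export
cafe_consumption <- function(displacement_mm, calibration_mm_per_ul,
                             n_flies, duration_h = 19) {
  if (calibration_mm_per_ul <= 0)
    mrdam_stop("calibration must be positive", "mrdam_validation_error")
  if (n_flies < 1)
    mrdam_stop("n_flies must be >= 1", "mrdam_validation_error")
  if (any(displacement_mm < 0, na.rm = TRUE))
    mrdam_stop("negative capillary displacement: data-entry error",
               "mrdam_validation_error")
  if (anyNA(displacement_mm)) {
    warning(sprintf("%d capillary reading(s) missing; computing over the %d recorded",
                    sum(is.na(displacement_mm)), sum(!is.na(displacement_mm))))
  }
  total_ul <- sum(displacement_mm / calibration_mm_per_ul, na.rm = TRUE)
  per_fly <- total_ul / n_flies
  list(ul_per_fly = per_fly, ul_per_fly_per_h = per_fly / duration_h,
       total_ul = total_ul)
}

#' Comparative-Ct (delta-delta-Ct) fold changes with CV exclusion
#'
#' Technical replicates are averaged per (sample, gene) after excluding any
#' whose coefficient of variation of raw Ct (SD/mean, percent) exceeds
#' `cv_threshold` (default 3%). Then, per sample,
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt - mean dCt of the control
#' group` (per target gene), and `fold change = 2^(-ddCt)`, so the
#' control-group mean has fold change exactly 1.
#'
#' @param plate Long-format `data.frame`: `sample_id`, `group`, `gene`, `ct`
#'   (one row per technical replicate; >= 2 replicates per sample/gene).
#' @param reference_gene Housekeeping gene name (e.g. `"rp49"`).
#' @param control_group Name of the calibrator group.
#' @param cv_threshold Replicate-CV exclusion threshold, percent.
#' @return List: `fold_changes` (`sample_id`, `group`, `gene`, `d_ct`,
#'   `dd_ct`, `fold_change` for each target gene) and `excluded`
#'   (`sample_id`, `gene`, `cv_percent`).
#' @export
ddct_fold_change <- function(plate, reference_gene, control_group,
                             cv_threshold = 3) {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(plate)))
    mrdam_stop("plate needs columns sample_id, group, gene, ct",
               "mrdam_format_error")
  if (any(plate$ct <= 0, na.rm = TRUE))
    mrdam_stop("Ct values must be positive", "mrdam_validation_error")
  if (!reference_gene %in% plate$gene)
    mrdam_stop("reference gene absent from plate", "mrdam_validation_error")
  key <- interaction(plate$sample_id, plate$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(plate, key), function(d) {
    if (nrow(d) < 2L)
      mrdam_stop(sprintf("need >= 2 technical replicates for %s/%s",
                         d$sample_id[1], d$gene[1]), "mrdam_validation_error")
    cv <- stats::sd(d$ct) / mean(d$ct) * 100
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               gene = d$gene[1], ct = mean(d$ct), cv_percent = cv,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  bad <- agg$cv_percent > cv_threshold
  excluded <- agg[bad, c("sample_id", "gene", "cv_percent")]
  agg <- agg[!bad, ]
  ref <- agg[agg$gene == reference_gene, ]
  targets <- agg[agg$gene != reference_gene, ]
  targets$ref_ct <- ref$ct[match(targets$sample_id, ref$sample_id)]
  targets <- targets[!is.na(targets$ref_ct), ]
  targets$d_ct <- targets$ct - targets$ref_ct
  out <- do.call(rbind, lapply(split(targets, targets$gene), function(d) {
    ctrl <- d$d_ct[d$group == control_group]
    if (!length(ctrl))
      mrdam_stop(sprintf("control group '%s' empty after exclusions for gene %s",
                         control_group, d$gene[1]), "mrdam_validation_error")
    d$dd_ct <- d$d_ct - mean(ctrl)
    d$fold_change <- 2^(-d$dd_ct)
    d[, c("sample_id", "group", "gene", "d_ct", "dd_ct", "fold_change")]
  }))
  rownames(out) <- NULL
  list(fold_changes = out, excluded = excluded)
}

#' Normalize readouts to a per-sample reference
#'
#' Elementwise ratio of assay values to a positive reference measurement
#' (e.g. plate absorbances divided by Bradford protein concentration, or
#' total weight divided by the number of flies weighed).
#'
#' @param values Numeric vector of readouts.
#' @param reference Positive numeric vector of the same length.
#' @return `values / reference`.
#' @export
normalize_per_reference <- function(values, reference) {
  if (length(values) != length(reference))
    mrdam_stop("values and reference must have the same length",
               "mrdam_validation_error")
  if (any(reference <= 0, na.rm = TRUE))
    mrdam_stop("reference values must be strictly positive",
               "mrdam_validation_error")
  values / reference
}
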