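#' Harmonize exposure and outcome GWAS summary statistics
#'
#' Aligns two per-variant summary-statistic tables to the same effect
#' allele. Variants are intersected on `variant_id`; when the outcome's
#' alleles are swapped relative to the exposure's, the outcome beta sign and
#' effect-allele frequency are flipped; allele pairs that differ by strand
#' (A/C vs T/G etc.) are complemented and re-tried; incompatible pairs are
#' dropped with a logged reason. Palindromic variants (A/T or C/G), whose
#' strand cannot be resolved from the alleles, are oriented by allele
#' frequency when both frequencies are informative and dropped as ambiguous
#' when `min(eaf, 1 - eaf)` exceeds `palindrome_maf` (default 0.42) under
#' the default `"maf"` policy (`"drop"` drops all palindromes, `"keep"`
#' keeps them as-is).
#'
#' @param exposure,outcome `data.frame`s with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, and optionally `eaf`.
#' @param palindrome_policy `"maf"`, `"drop"` or `"keep"`.
#' @param palindrome_maf Ambiguity threshold on `min(eaf, 1-eaf)`.
#' @return `data.frame` of class `harmonized_stats`: `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf_exposure`, `eaf_outcome`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `harmonized`; dropped variants with reasons in attribute `"dropped"`.
#' @export
harmonize <- function(exposure, outcome, palindrome_policy = c("maf", "drop", "keep"),
                      palindrome_maf = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  for (tab in list(exposure, outcome))
    if (!all(need %in% names(tab)))
      mrdam_stop(paste("summary statistics need columns:",
                       paste(need, collapse = ", ")), "mrdam_format_error")
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (!length(shared))
    mrdam_stop("no shared variants between exposure and outcome",
               "mrdam_validation_error")
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]
  comp <- function(a) chartr("ACGT", "TGCA", a)
  ex_eaf <- if ("eaf" %in% names(ex)) ex$eaf else rep(NA_real_, nrow(ex))
  ou_eaf <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, nrow(ou))
  keep <- rep(TRUE, length(shared))
  reason <- rep(NA_character_, length(shared))
  beta_out <- ou$beta
  eaf_out <- ou_eaf
  for (i in seq_along(shared)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    oea <- ou$effect_allele[i]; ooa <- ou$other_allele[i]
    palindromic <- ea == comp(oa)
    if (palindromic) {
      if (!setequal(c(oea, ooa), c(ea, oa))) {
        keep[i] <- FALSE; reason[i] <- "allele_mismatch"; next
      }
      if (palindrome_policy == "drop") {
        keep[i] <- FALSE; reason[i] <- "palindromic"; next
      }
      if (palindrome_policy == "keep") {
        if (oea != ea) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i] }
        next
      }
      # "maf" policy: orient by allele frequency, drop when ambiguous
      maf_ex <- min(ex_eaf[i], 1 - ex_eaf[i])
      maf_ou <- min(ou_eaf[i], 1 - ou_eaf[i])
      if (is.na(maf_ex) || is.na(maf_ou) ||
          maf_ex > palindrome_maf || maf_ou > palindrome_maf) {
        keep[i] <- FALSE; reason[i] <- "palindromic_ambiguous"; next
      }
      concordant <- (ex_eaf[i] < 0.5) == (ou_eaf[i] < 0.5)
      if (!concordant) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i] }
      next
    }
    if (oea == ea && ooa == oa) next                     # aligned
    if (oea == oa && ooa == ea) {                        # swapped
      beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]; next
    }
    if (comp(oea) == ea && comp(ooa) == oa) next         # strand flip
    if (comp(oea) == oa && comp(ooa) == ea) {            # strand flip + swap
      beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]; next
    }
    keep[i] <- FALSE; reason[i] <- "allele_mismatch"
  }
  out <- data.frame(variant_id = shared, effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    eaf_exposure = ex_eaf, eaf_outcome = eaf_out,
                    beta_exposure = ex$beta, se_exposure = ex$se,
                    beta_outcome = beta_out, se_outcome = ou$se,
                    harmonized = TRUE, stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(variant_id = shared[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  class(out) <- c("harmonized_stats", "data.frame")
  out
}

mr_estimate_row <- function(method, beta, se, n_instruments, seed = NA_integer_) {
  z <- beta / se
  data.frame(method = method, beta = beta, se = se,
             ci_low = beta - stats::qnorm(0.975) * se,
             ci_high = beta + stats::qnorm(0.975) * se,
             pval = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
             n_instruments = as.integer(n_instruments),
             seed = as.integer(seed), stringsAsFactors = FALSE)
}

# per-variant Wald ratios with delta-method SEs.
# weights = "first": s_j = se_out/|beta_exp| (the field-standard first-order
# weights; independent of the noisy outcome beta, so IVW weights do not
# correlate with estimation error). weights = "second": full delta formula
# including the exposure term.
wald_ratios <- function(beta_exp, se_exp, beta_out, se_out,
                        weights = c("first", "second")) {
  weights <- match.arg(weights)
  if (any(beta_exp == 0))
    mrdam_stop("weak instrument: beta_exposure is zero", "mrdam_weak_instrument_error")
  r <- beta_out / beta_exp
  s <- if (weights == "first") {
    se_out / abs(beta_exp)
  } else {
    ifelse(beta_out == 0,
           se_out / abs(beta_exp),
           abs(r) * sqrt(se_out^2 / beta_out^2 + se_exp^2 / beta_exp^2))
  }
  list(ratio = r, se = s)
}

#' Single-instrument Wald ratio causal estimate
#'
#' The causal effect of the exposure on the outcome from one genetic
#' instrument: the gene-outcome association divided by the gene-exposure
#' association, `beta = beta_out / beta_exp`, with the first-order
#' delta-method standard error
#' `se = |beta| * sqrt(se_out^2/beta_out^2 + se_exp^2/beta_exp^2)`
#' (reducing to `se_out/|beta_exp|` when `beta_out = 0` or `se_exp = 0`),
#' a Wald z test and a normal 95% CI.
#'
#' @param beta_exp,se_exp Gene-exposure association and its SE.
#' @param beta_out,se_out Gene-outcome association and its SE.
#' @return One-row `MREstimate` `data.frame` (`method = "wald"`).
#' @examples
#' wald_ratio(0.5, 0.05, 0.25, 0.05)
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  stopifnot(length(beta_exp) == 1L, se_exp >= 0, se_out > 0)
  w <- wald_ratios(beta_exp, se_exp, beta_out, se_out, weights = "second")
  mr_estimate_row("wald", w$ratio, w$se, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Precision-weighted average of the per-instrument Wald ratios `r_j` with
#' weights `w_j = s_j^-2` (delta-method ratio SEs):
#' `beta = sum(w_j r_j) / sum(w_j)`. Fixed-effect SE is
#' `(sum w_j)^-1/2`; the random-effects (multiplicative overdispersion)
#' variant inflates it by `max(1, sqrt(Q/(J-1)))` where `Q` is Cochran's
#' heterogeneity statistic, never deflating below the fixed-effect SE.
#'
#' Ratio SEs default to modified second-order delta-method weights: the
#' delta formula is evaluated at the pooled causal estimate rather than at
#' each noisy per-variant ratio
#' (`s_j^2 = (se_out^2 + beta^2 se_exp^2) / beta_exp^2`, iterated from the
#' first-order fit), which accounts for exposure-side uncertainty without
#' letting the weights correlate with the per-variant estimation error.
#' `weights = "first"` gives the plain `se_out/|beta_exp|` convention and
#' `weights = "second"` the per-variant full delta formula. A
#' single-instrument input collapses to [wald_ratio()] (identical beta and
#' SE).
#'
#' @param stats A [harmonize()]d summary-statistic table (>= 1 instrument,
#'   all `beta_exposure` nonzero).
#' @param mode `"fixed"` (default) or `"random"`.
#' @param weights `"modified"` (default), `"first"` or `"second"`
#'   delta-method ratio SEs.
#' @return One-row `MREstimate` `data.frame`.
#' @export
mr_ivw <- function(stats, mode = c("fixed", "random"),
                   weights = c("modified", "first", "second")) {
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  J <- nrow(stats)
  if (J < 1L) mrdam_stop("IVW requires at least one instrument",
                         "mrdam_validation_error")
  if (J == 1L) {   # single-instrument collapse: report the Wald ratio
    row <- wald_ratio(stats$beta_exposure, stats$se_exposure,
                      stats$beta_outcome, stats$se_outcome)
    row$method <- paste0("ivw_", mode)
    return(row)
  }
  if (weights == "modified") {
    w <- wald_ratios(stats$beta_exposure, stats$se_exposure,
                     stats$beta_outcome, stats$se_outcome, weights = "first")
    ratio <- w$ratio
    beta <- sum(ratio / w$se^2) / sum(1 / w$se^2)
    for (it in 1:2) {
      s2 <- (stats$se_outcome^2 + beta^2 * stats$se_exposure^2) /
        stats$beta_exposure^2
      wt <- 1 / s2
      beta <- sum(wt * ratio) / sum(wt)
    }
  } else {
    w <- wald_ratios(stats$beta_exposure, stats$se_exposure,
                     stats$beta_outcome, stats$se_outcome, weights = weights)
    ratio <- w$ratio
    wt <- 1 / w$se^2
    beta <- sum(wt * ratio) / sum(wt)
  }
  se <- sqrt(1 / sum(wt))
  if (mode == "random" && J > 1L) {
    Q <- sum(wt * (ratio - beta)^2)
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  mr_estimate_row(paste0("ivw_", mode), beta, se, J)
}

#' Weighted-median causal estimate
#'
#' The weighted 50th percentile of the ordered per-instrument Wald ratios
#' with normalized inverse-variance weights: with ratios
#' `r_(1) <= ... <= r_(J)` and cumulative weight midpoints
#' `p_j = (sum_{k<=j} w_k - w_j/2) / sum w`, the estimate is the linear
#' interpolation of `r` over `p` at 0.5. Consistent whenever valid
#' instruments carry more than half of the total weight. The SE comes from a
#' seeded parametric bootstrap: each `beta_exposure`/`beta_outcome` is
#' resampled from a normal with its reported SE and the estimator
#' recomputed.
#'
#' Ratio SEs default to the full (second-order) delta formula - the same
#' algebra as [wald_ratio()] - which additionally downweights instruments
#' with inflated gene-outcome effects and so reduces finite-sample bias
#' under directional pleiotropy; `weights = "first"` gives the plain
#' `se_out/|beta_exp|` convention.
#'
#' @param stats A [harmonize()]d table with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed (default 20230421); identical seeds give
#'   identical SEs.
#' @param weights `"second"` (default) or `"first"` delta-method ratio SEs.
#' @return One-row `MREstimate` `data.frame` (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(stats, n_boot = 1000, seed = 20230421,
                               weights = c("second", "first")) {
  weights <- match.arg(weights)
  J <- nrow(stats)
  if (J < 3L) mrdam_stop("weighted median requires >= 3 instruments",
                         "mrdam_validation_error")
  point <- weighted_median_point(stats$beta_exposure, stats$se_exposure,
                                 stats$beta_outcome, stats$se_outcome, weights)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, stats$beta_exposure, stats$se_exposure)
      by <- stats::rnorm(J, stats$beta_outcome, stats$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      weighted_median_point(bx, stats$se_exposure, by, stats$se_outcome, weights)
    }, numeric(1))
  })
  est <- mr_estimate_row("weighted_median", point, stats::sd(boots), J,
                         seed = seed)
  est
}

weighted_median_point <- function(beta_exp, se_exp, beta_out, se_out,
                                  weights = "first") {
  w <- wald_ratios(beta_exp, se_exp, beta_out, se_out, weights = weights)
  o <- order(w$ratio)
  r <- w$ratio[o]
  wt <- (1 / w$se^2)[o]
  wt <- wt / sum(wt)
  p <- cumsum(wt) - wt / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(p)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Run a full Mendelian-randomisation analysis
#'
#' Harmonizes the exposure and outcome summary statistics, then runs every
#' requested estimator. Single-instrument inputs are automatically routed to
#' the Wald ratio (to which IVW is identical in that case); estimator
#' failures (e.g. the weighted median with fewer than 3 instruments) are
#' collected per method without aborting the others.
#'
#' @param exposure,outcome Summary-statistic `data.frame`s (see
#'   [harmonize()]). Instruments are assumed pre-selected upstream (scan
#'   rejections or eQTL hits); no p-value re-thresholding happens here.
#' @param methods Subset of `c("wald", "ivw", "weighted_median")`.
#' @param ivw_mode,palindrome_policy,n_boot,seed,weights Passed through.
#' @return List of class `mr_result`: `estimates` (rbound `MREstimate`
#'   rows), `instruments` (the harmonized per-instrument table with ratios
#'   and delta-method SEs), `dropped` (harmonization log), `errors` (named
#'   list of per-method failure messages).
#' @export
mr_analysis <- function(exposure, outcome,
                        methods = c("wald", "ivw", "weighted_median"),
                        ivw_mode = "fixed", palindrome_policy = "maf",
                        n_boot = 1000, seed = 20230421, weights = "modified") {
  methods <- match.arg(methods, c("wald", "ivw", "weighted_median"),
                       several.ok = TRUE)
  h <- harmonize(exposure, outcome, palindrome_policy = palindrome_policy)
  J <- nrow(h)
  if (J < 1L) mrdam_stop("no instruments survive harmonization",
                         "mrdam_validation_error")
  # per-instrument table always reports the per-variant (first-order) SEs
  w <- wald_ratios(h$beta_exposure, h$se_exposure, h$beta_outcome,
                   h$se_outcome, weights = "first")
  inst <- cbind(as.data.frame(h), ratio = w$ratio, ratio_se = w$se)
  wm_weights <- if (weights == "first") "first" else "second"
  ests <- list(); errs <- list()
  for (m in methods) {
    res <- tryCatch({
      if (m == "wald") {
        if (J == 1L) wald_ratio(h$beta_exposure, h$se_exposure,
                                h$beta_outcome, h$se_outcome)
        else mrdam_stop("wald ratio requires exactly one instrument; use ivw",
                        "mrdam_validation_error")
      } else if (m == "ivw") {
        mr_ivw(h, mode = ivw_mode, weights = weights)
      } else {
        mr_weighted_median(h, n_boot = n_boot, seed = seed,
                           weights = wm_weights)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) errs[[m]] <- conditionMessage(res)
    else ests[[m]] <- res
  }
  structure(list(estimates = if (length(ests)) do.call(rbind, ests) else NULL,
                 instruments = inst,
                 dropped = attr(h, "dropped"),
                 errors = errs),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat("<mr_result>", nrow(x$instruments), "instrument(s)\n")
  if (!is.null(x$estimates)) print(x$estimates, row.names = FALSE)
  if (length(x$errors))
    for (m in names(x$errors)) cat(sprintf("  [%s failed: %s]\n", m, x$errors[[m]]))
  if (nrow(x$dropped)) cat(" dropped:", nrow(x$dropped), "variant(s)\n")
  invisible(x)
}
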