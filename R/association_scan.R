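#' Ordinary least squares with a user-supplied design matrix
#'
#' QR-based OLS with standard errors from the residual variance and
#' two-sided p-values from the t distribution on `n - k` degrees of freedom.
#' Rank-deficient designs raise an explicit singular-design error rather
#' than silently dropping columns.
#'
#' @param response Numeric response vector.
#' @param design Numeric design matrix (include an intercept column
#'   yourself); `nrow(design)` must equal `length(response)` and exceed
#'   `ncol(design)`.
#' @return `data.frame` with one row per design column: `term`, `estimate`,
#'   `se`, `t`, `pval`; residual degrees of freedom and residual sum of
#'   squares as attributes `"df"` and `"rss"`.
#' @examples
#' x <- 1:5
#' fit_linear_model(2 * x + 1, cbind(intercept = 1, x = x))
#' @export
fit_linear_model <- function(response, design) {
  design <- as.matrix(design)
  n <- length(response)
  k <- ncol(design)
  if (nrow(design) != n)
    mrdam_stop("design rows must match response length", "mrdam_validation_error")
  if (n <= k)
    mrdam_stop("need more observations than design columns", "mrdam_validation_error")
  qx <- qr(design)
  if (qx$rank < k)
    mrdam_stop("singular design matrix (rank deficient)", "mrdam_singular_error")
  coef <- qr.coef(qx, response)
  res <- qr.resid(qx, response)
  rss <- sum(res^2)
  df <- n - k
  sigma2 <- rss / df
  # unscaled covariance (X'X)^-1 from R, undoing any column pivoting
  Rinv <- backsolve(qr.R(qx), diag(k))
  unscaled <- tcrossprod(Rinv)
  piv <- qx$pivot
  unscaled[piv, piv] <- unscaled
  se <- sqrt(sigma2 * diag(unscaled))
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  out <- data.frame(term = colnames(design) %||% paste0("x", seq_len(k)),
                    estimate = as.numeric(coef), se = se, t = as.numeric(tval),
                    pval = as.numeric(pval), stringsAsFactors = FALSE)
  attr(out, "df") <- df
  attr(out, "rss") <- rss
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure: sort the m p-values ascending, reject hypotheses
#' `1..i*` where `i*` is the largest `i` with `p(i) <= i*q/m`; q-values are
#' `min over j >= i of m*p(j)/j`, capped at 1, returned in the original
#' order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (no `NA`s).
#' @param q Target FDR level.
#' @return List: `q_values`, `rejected` (logical), both in input order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
#' @export
adjust_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(q_values = numeric(0), rejected = logical(0)))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    mrdam_stop("p-values must lie in [0, 1]", "mrdam_validation_error")
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  qv_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  qv_sorted <- pmin(qv_sorted, 1)
  pass <- which(ps <= seq_len(m) * q / m)
  rej_sorted <- logical(m)
  if (length(pass)) rej_sorted[seq_len(max(pass))] <- TRUE
  q_values <- numeric(m)
  rejected <- logical(m)
  q_values[o] <- qv_sorted
  rejected[o] <- rej_sorted
  list(q_values = q_values, rejected = rejected)
}

#' Per-SNP covariate-adjusted linear association scan
#'
#' Fits one linear regression per SNP
#' (`phenotype ~ intercept + dosage + covariates`) over complete cases,
#' reports the raw per-dosage effect with its 95% CI and a scaled estimate
#' (the coefficient with both phenotype and dosage z-standardized, equal to
#' `beta * SD(dosage)/SD(phenotype)`), and controls the FDR across the scan
#' with [adjust_fdr()]. Monomorphic SNPs are flagged (`note =
#' "monomorphic"`) and excluded from the FDR family rather than dropped.
#'
#' @param cohort A `cohort_table` (or any `data.frame` holding the phenotype
#'   and covariate columns).
#' @param genotypes A `genotype_matrix` row-aligned with `cohort`.
#' @param phenotype Name of the response column.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param fdr_q FDR level for rejection flags.
#' @return `data.frame` of class `association_scan`: `variant_id`,
#'   `phenotype`, `beta`, `se`, `t_statistic`, `pval`, `scaled_estimate`,
#'   `ci_low`, `ci_high`, `q_value`, `rejected`, `note`; scan metadata
#'   (n used, rows dropped, family size m, q) in attribute `"log"`.
#' @export
scan_snps <- function(cohort, genotypes, phenotype, covariates = character(),
                      fdr_q = 0.05) {
  validate_genotypes(genotypes)
  cols <- c(phenotype, covariates)
  if (!all(cols %in% names(cohort)))
    mrdam_stop(paste("missing cohort columns:",
                     paste(setdiff(cols, names(cohort)), collapse = ", ")),
               "mrdam_validation_error")
  if (nrow(cohort) != nrow(genotypes$dosages))
    mrdam_stop("cohort rows must match genotype rows", "mrdam_validation_error")
  y_all <- cohort[[phenotype]]
  covmat <- if (length(covariates))
    as.matrix(as.data.frame(cohort)[covariates]) else NULL
  cc <- stats::complete.cases(as.data.frame(cohort)[cols])
  dropped <- sum(!cc)
  k <- 2L + length(covariates)
  if (sum(cc) < k + 2L)
    mrdam_stop("fewer complete cases than parameters + 2", "mrdam_validation_error")
  m_all <- ncol(genotypes$dosages)
  sd_y <- stats::sd(y_all[cc])
  beta <- se <- tstat <- pval <- scaled <- lo <- hi <- rep(NA_real_, m_all)
  note <- rep(NA_character_, m_all)
  for (j in seq_len(m_all)) {
    g <- genotypes$dosages[, j]
    use <- cc & !is.na(g)
    gj <- g[use]
    if (stats::sd(gj) == 0) {
      note[j] <- "monomorphic"
      next
    }
    design <- cbind(intercept = 1, dosage = gj,
                    if (!is.null(covmat)) covmat[use, , drop = FALSE])
    fit <- fit_linear_model(y_all[use], design)
    tcrit <- stats::qt(0.975, df = attr(fit, "df"))
    beta[j] <- fit$estimate[2]; se[j] <- fit$se[2]
    tstat[j] <- fit$t[2]; pval[j] <- fit$pval[2]
    scaled[j] <- beta[j] * stats::sd(gj) / sd_y
    lo[j] <- beta[j] - tcrit * se[j]; hi[j] <- beta[j] + tcrit * se[j]
  }
  out <- data.frame(variant_id = genotypes$snps$variant_id,
                    phenotype = phenotype, beta = beta, se = se,
                    t_statistic = tstat, pval = pval,
                    scaled_estimate = scaled, ci_low = lo, ci_high = hi,
                    note = note, stringsAsFactors = FALSE)
  in_family <- is.na(out$note)
  out$q_value <- NA_real_
  out$rejected <- NA
  if (any(in_family)) {
    adj <- adjust_fdr(out$pval[in_family], q = fdr_q)
    out$q_value[in_family] <- adj$q_values
    out$rejected[in_family] <- adj$rejected
  }
  attr(out, "log") <- list(n = sum(cc), dropped_rows = dropped,
                           m = sum(in_family), q = fdr_q)
  class(out) <- c("association_scan", "data.frame")
  out
}
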