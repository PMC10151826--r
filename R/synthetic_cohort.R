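#' Describe a panel of biallelic SNPs
#'
#' Builds the instrument table used by the genotype and cohort simulators.
#' Each row is one biallelic variant with its minor-allele frequency, its
#' effect on the exposure per effect-allele copy, and an optional direct
#' (pleiotropic) effect on the outcome. A valid Mendelian-randomisation
#' instrument has `beta_exposure != 0` (relevance) and
#' `beta_direct_outcome = 0` (exclusion restriction); setting
#' `beta_direct_outcome` nonzero deliberately violates instrument validity.
#'
#' @param variant_id Character vector of variant identifiers.
#' @param effect_allele,other_allele Single nucleotides (`A`, `C`, `G`, `T`).
#' @param maf Effect-allele frequency in `(0, 0.5]`.
#' @param beta_exposure Effect on the exposure per dosage unit.
#' @param beta_direct_outcome Direct effect on the outcome per dosage unit.
#' @return A `data.frame` of class `snp_spec`.
#' @examples
#' snp_spec("rs1", "A", "G", maf = 0.3, beta_exposure = 0.2)
#' @export
snp_spec <- function(variant_id, effect_allele, other_allele, maf,
                     beta_exposure = 0, beta_direct_outcome = 0) {
  n <- length(variant_id)
  spec <- data.frame(
    variant_id = as.character(variant_id),
    effect_allele = rep_len(toupper(as.character(effect_allele)), n),
    other_allele = rep_len(toupper(as.character(other_allele)), n),
    maf = rep_len(as.numeric(maf), n),
    beta_exposure = rep_len(as.numeric(beta_exposure), n),
    beta_direct_outcome = rep_len(as.numeric(beta_direct_outcome), n),
    stringsAsFactors = FALSE
  )
  validate_snp_spec(spec)
  class(spec) <- c("snp_spec", "data.frame")
  spec
}

validate_snp_spec <- function(spec) {
  nt <- c("A", "C", "G", "T")
  if (anyDuplicated(spec$variant_id))
    mrdam_stop("duplicated variant_id in SNP specification", "mrdam_validation_error")
  if (!all(spec$effect_allele %in% nt) || !all(spec$other_allele %in% nt))
    mrdam_stop("alleles must be single nucleotides A/C/G/T", "mrdam_validation_error")
  if (any(spec$effect_allele == spec$other_allele))
    mrdam_stop("effect_allele must differ from other_allele", "mrdam_validation_error")
  if (any(!is.finite(spec$maf)) || any(spec$maf <= 0) || any(spec$maf > 0.5))
    mrdam_stop("maf must lie in (0, 0.5]", "mrdam_validation_error")
  invisible(spec)
}

#' Ground truth for a simulated cohort
#'
#' Records the data-generating parameters alongside every simulated cohort so
#' that parameter-recovery tests have a known answer.
#'
#' @param theta Causal effect of the exposure on the outcome.
#' @param confounder_effects Length-2 numeric: loadings of the shared latent
#'   confounder on (exposure, outcome).
#' @param noise_sds Length-2 numeric: independent Gaussian noise SDs for
#'   (exposure, outcome).
#' @param seed Integer seed used for the cohort draw.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(theta, confounder_effects = c(0.5, 0.5),
                         noise_sds = c(1, 1), seed = 1L) {
  stopifnot(length(theta) == 1L, is.finite(theta),
            length(confounder_effects) == 2L, all(is.finite(confounder_effects)),
            length(noise_sds) == 2L, all(noise_sds >= 0))
  structure(list(theta = as.numeric(theta),
                 confounder_effects = as.numeric(confounder_effects),
                 noise_sds = as.numeric(noise_sds),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws additive effect-allele dosages independently per SNP as
#' `Binomial(2, maf)` (Hardy-Weinberg equilibrium, no linkage
#' disequilibrium between SNPs).
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param snps A [snp_spec()] table.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `genotype_matrix`: list with `dosages` (individuals x SNPs
#'   integer matrix with values 0/1/2), `snps`, and `individual_ids`.
#' @examples
#' g <- simulate_genotypes(10, snp_spec("rs1", "A", "G", 0.4), seed = 1)
#' table(g$dosages)
#' @export
simulate_genotypes <- function(n_individuals, snps, seed) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L || n_individuals < 1)
    mrdam_stop("n_individuals must be a positive count", "mrdam_validation_error")
  n_individuals <- as.integer(n_individuals)
  validate_snp_spec(snps)
  m <- nrow(snps)
  dos <- with_seed(seed, {
    vapply(seq_len(m),
           function(j) stats::rbinom(n_individuals, 2L, snps$maf[j]),
           integer(n_individuals))
  })
  dos <- matrix(as.integer(dos), nrow = n_individuals, ncol = m,
                dimnames = list(NULL, snps$variant_id))
  structure(list(dosages = dos,
                 snps = snps,
                 individual_ids = sprintf("id%06d", seq_len(n_individuals))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

validate_genotypes <- function(genotypes) {
  if (!inherits(genotypes, "genotype_matrix"))
    mrdam_stop("expected a genotype_matrix", "mrdam_validation_error")
  if (ncol(genotypes$dosages) != nrow(genotypes$snps))
    mrdam_stop("genotype column count does not match SNP count", "mrdam_validation_error")
  if (!all(genotypes$dosages %in% 0:2))
    mrdam_stop("dosages must be in {0,1,2}", "mrdam_validation_error")
  invisible(genotypes)
}

#' Simulate an exposure/outcome cohort from genotypes
#'
#' Builds a continuous exposure (waist-to-hip-ratio-like) from additive SNP
#' effects plus a shared latent confounder and Gaussian noise, and a
#' continuous outcome (sleep-duration-like, hours) as
#' `theta * exposure + direct SNP effects + confounder + noise`:
#' \deqn{x_i = \sum_j \beta^{exp}_j g_{ij} + a U_i + \varepsilon_i,\qquad
#'       y_i = \theta x_i + \sum_j \beta^{dir}_j g_{ij} + b U_i + \eta_i}
#' with `U`, `eps`, `eta` independent standard Gaussians scaled by the stated
#' loadings/SDs. Optional covariates are generated per plan and added to both
#' traits; the latent confounder is retained in the output for testing only.
#'
#' @param genotypes A `genotype_matrix`.
#' @param truth A [ground_truth()] object (its `seed` drives the draw).
#' @param covariate_plan Optional named list; each element is a list with
#'   `dist` (`"normal"` or `"binary"`), its parameters (`mean`/`sd` or `p`),
#'   and loadings `beta_exposure`, `beta_outcome` (default 0).
#' @return A `data.frame` (class `cohort_table`) with columns
#'   `individual_id`, `exposure`, `outcome`, one column per covariate and
#'   `confounder`; the generating `truth` is attached as attribute `"truth"`.
#' @export
simulate_cohort <- function(genotypes, truth, covariate_plan = NULL) {
  validate_genotypes(genotypes)
  stopifnot(inherits(truth, "ground_truth"))
  G <- genotypes$dosages
  n <- nrow(G)
  snps <- genotypes$snps
  with_seed(truth$seed, {
    U <- stats::rnorm(n)
    eps <- stats::rnorm(n, sd = truth$noise_sds[1])
    eta <- stats::rnorm(n, sd = truth$noise_sds[2])
    covs <- NULL
    cov_x <- cov_y <- 0
    if (length(covariate_plan)) {
      if (is.null(names(covariate_plan)) || any(names(covariate_plan) == ""))
        mrdam_stop("covariate_plan must be a named list", "mrdam_validation_error")
      covs <- lapply(covariate_plan, function(p) {
        dist <- match.arg(p$dist, c("normal", "binary"))
        if (dist == "normal") {
          stats::rnorm(n, mean = p$mean %||% 0, sd = p$sd %||% 1)
        } else {
          stats::rbinom(n, 1L, p$p %||% 0.5)
        }
      })
      for (k in seq_along(covs)) {
        p <- covariate_plan[[k]]
        cov_x <- cov_x + (p$beta_exposure %||% 0) * covs[[k]]
        cov_y <- cov_y + (p$beta_outcome %||% 0) * covs[[k]]
      }
    }
    exposure <- as.vector(G %*% snps$beta_exposure) +
      truth$confounder_effects[1] * U + cov_x + eps
    outcome <- truth$theta * exposure +
      as.vector(G %*% snps$beta_direct_outcome) +
      truth$confounder_effects[2] * U + cov_y + eta
    out <- data.frame(individual_id = genotypes$individual_ids,
                      exposure = exposure, outcome = outcome,
                      stringsAsFactors = FALSE)
    for (nm in names(covs)) out[[nm]] <- covs[[nm]]
    out$confounder <- U
    attr(out, "truth") <- truth
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate two-sample GWAS summary statistics
#'
#' Draws two independent cohorts from the same SNP panel and ground truth and
#' reduces each to per-variant marginal regression summary statistics: the
#' exposure sample yields gene-exposure associations, the outcome sample
#' gene-outcome associations. This is the input contract of the two-sample
#' Mendelian-randomisation estimators.
#'
#' @param snps A [snp_spec()] table.
#' @param n_exposure,n_outcome Sample sizes of the two cohorts.
#' @param truth A [ground_truth()]; the two cohorts use seeds derived from
#'   `truth$seed` and are independent.
#' @param seed Optional integer overriding `truth$seed` as the base seed.
#' @return List with `exposure` and `outcome` summary-statistic
#'   `data.frame`s (columns `variant_id`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`, `n`).
#' @export
simulate_summary_stats <- function(snps, n_exposure, n_outcome, truth,
                                   seed = NULL) {
  base <- if (is.null(seed)) truth$seed else as.integer(seed)
  # keep derived seeds inside 32-bit integer range
  s1 <- (base * 2L) %% .Machine$integer.max
  s2 <- (base * 2L + 1L) %% .Machine$integer.max
  one_sample <- function(n, s, trait) {
    g <- simulate_genotypes(n, snps, seed = s)
    t2 <- truth
    t2$seed <- (s + 7L) %% .Machine$integer.max
    coh <- simulate_cohort(g, t2)
    fit <- marginal_ols(g$dosages, coh[[trait]])
    data.frame(variant_id = snps$variant_id,
               effect_allele = snps$effect_allele,
               other_allele = snps$other_allele,
               eaf = colMeans(g$dosages) / 2,
               beta = fit$beta, se = fit$se, pval = fit$pval, n = n,
               stringsAsFactors = FALSE)
  }
  list(exposure = one_sample(n_exposure, s1, "exposure"),
       outcome = one_sample(n_outcome, s2, "outcome"))
}

#' Write/read the package's tabular dialects
#'
#' Plain TSV writers and readers for genotype matrices, phenotype tables and
#' GWAS summary statistics, matching the column layouts consumed elsewhere in
#' the package.
#'
#' @param genotypes A `genotype_matrix`.
#' @param cohort A `cohort_table`.
#' @param stats A summary-statistic `data.frame`.
#' @param path File path.
#' @return The input, invisibly (writers); a `data.frame` (readers).
#' @name mrdam-io
NULL

#' @rdname mrdam-io
#' @export
write_genotype_tsv <- function(genotypes, path) {
  validate_genotypes(genotypes)
  df <- data.frame(individual_id = genotypes$individual_ids,
                   genotypes$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(genotypes)
}

#' @rdname mrdam-io
#' @export
write_phenotype_tsv <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cohort)
}

#' @rdname mrdam-io
#' @export
write_summary_stats_tsv <- function(stats, path) {
  need <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta", "se")
  if (!all(need %in% names(stats)))
    mrdam_stop(paste("summary statistics must contain columns:",
                     paste(need, collapse = ", ")), "mrdam_format_error")
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stats)
}

#' @rdname mrdam-io
#' @export
read_summary_stats_tsv <- function(path) {
  stats <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  if (!all(need %in% names(stats)))
    mrdam_stop(paste0("missing required summary-statistic columns in ", path),
               "mrdam_format_error")
  stats
}
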