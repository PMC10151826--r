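test_that("harmonize aligns, flips and drops as stated", {
  ex <- sumstats(c("rs1", "rs2", "rs3"), c("A", "C", "G"), c("G", "T", "C"),
                 beta = c(0.2, -0.1, 0.3), se = c(0.02, 0.03, 0.04),
                 eaf = c(0.3, 0.2, 0.5))
  # identical annotations: identity restricted to shared variants
  ou <- ex; ou$beta <- c(0.05, 0.02, 0.01)
  h <- harmonize(ex, ou[1:2, ])
  expect_equal(h$variant_id, c("rs1", "rs2"))
  expect_equal(h$beta_outcome, c(0.05, 0.02))
  expect_equal(h$beta_exposure, c(0.2, -0.1))
  expect_true(all(h$harmonized))

  # outcome coded on the other allele: sign flipped, eaf -> 1 - eaf
  ou_sw <- ex
  ou_sw$effect_allele <- ex$other_allele
  ou_sw$other_allele <- ex$effect_allele
  ou_sw$beta <- c(0.05, 0.02, 0.01)
  ou_sw$eaf <- 1 - ex$eaf
  h <- harmonize(ex[1:2, ], ou_sw[1:2, ])
  expect_equal(h$beta_outcome, c(-0.05, -0.02))
  expect_equal(h$eaf_outcome, ex$eaf[1:2])

  # strand-flipped outcome (A/G reported as T/C) resolves without flipping
  ou_st <- ex[1, ]; ou_st$effect_allele <- "T"; ou_st$other_allele <- "C"
  ou_st$beta <- 0.07
  h <- harmonize(ex[1, ], ou_st)
  expect_equal(h$beta_outcome, 0.07)

  # incompatible allele pair dropped with a reason
  ou_bad <- ex[1, ]; ou_bad$effect_allele <- "A"; ou_bad$other_allele <- "C"
  h <- harmonize(ex[1:2, ], rbind(ou_bad, ex[2, ]))
  expect_equal(h$variant_id, "rs2")
  expect_equal(attr(h, "dropped")$reason, "allele_mismatch")

  expect_error(harmonize(ex[0, ], ex[0, ]), class = "mrdam_validation_error")
  expect_error(harmonize(ex["beta" != names(ex)], ex),
               class = "mrdam_format_error")
})

test_that("palindromic variants follow the stated MAF policy", {
  pal <- sumstats("rs9", "A", "T", beta = 0.1, se = 0.02, eaf = 0.5)
  h <- harmonize(pal, pal)   # eaf 0.5 -> min(eaf, 1-eaf) = 0.5 > 0.42
  expect_equal(nrow(h), 0L)
  expect_equal(attr(h, "dropped")$reason, "palindromic_ambiguous")

  # unambiguous palindrome (eaf 0.1) kept; discordant eaf implies a flip
  pal <- sumstats("rs9", "A", "T", beta = 0.1, se = 0.02, eaf = 0.1)
  out <- pal; out$eaf <- 0.9; out$beta <- 0.3
  h <- harmonize(pal, out)
  expect_equal(h$beta_outcome, -0.3)
  h2 <- harmonize(pal, pal)
  expect_equal(h2$beta_outcome, 0.1)
  # policy = "drop" removes all palindromes regardless of eaf
  h3 <- harmonize(pal, pal, palindrome_policy = "drop")
  expect_equal(nrow(h3), 0L)
})

test_that("harmonization is idempotent", {
  set.seed(71)
  ex <- sumstats(paste0("rs", 1:6), c("A", "C", "G", "T", "A", "C"),
                 c("G", "T", "A", "C", "C", "G"),
                 beta = rnorm(6), se = runif(6, 0.01, 0.05),
                 eaf = runif(6, 0.05, 0.4))
  ou <- ex; ou$beta <- rnorm(6); ou$se <- runif(6, 0.01, 0.05)
  h1 <- harmonize(ex, ou)
  # re-harmonize the harmonized pair: must be the identity
  ex2 <- data.frame(variant_id = h1$variant_id, effect_allele = h1$effect_allele,
                    other_allele = h1$other_allele, eaf = h1$eaf_exposure,
                    beta = h1$beta_exposure, se = h1$se_exposure)
  ou2 <- data.frame(variant_id = h1$variant_id, effect_allele = h1$effect_allele,
                    other_allele = h1$other_allele, eaf = h1$eaf_outcome,
                    beta = h1$beta_outcome, se = h1$se_outcome)
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$beta_outcome, h1$beta_outcome, tolerance = 1e-15)
  expect_equal(h2$beta_exposure, h1$beta_exposure, tolerance = 1e-15)
  expect_equal(nrow(h2), nrow(h1))
})

test_that("allele relabeling leaves causal estimates unchanged", {
  snps <- make_instruments(10, seed = 81)
  ss <- simulate_summary_stats(snps, 3000, 3000, ground_truth(0.3, seed = 82))
  base <- mr_analysis(ss$exposure, ss$outcome, methods = "ivw")
  # relabel the exposure's alleles: swap effect/other, negate beta, 1 - eaf
  ex_fl <- ss$exposure
  ex_fl$effect_allele <- ss$exposure$other_allele
  ex_fl$other_allele <- ss$exposure$effect_allele
  ex_fl$beta <- -ss$exposure$beta
  ex_fl$eaf <- 1 - ss$exposure$eaf
  flipped <- mr_analysis(ex_fl, ss$outcome, methods = "ivw")
  expect_equal(flipped$estimates$beta, base$estimates$beta, tolerance = 1e-12)
  expect_equal(flipped$estimates$se, base$estimates$se, tolerance = 1e-12)
})

test_that("wald_ratio follows the stated arithmetic and limits", {
  est <- wald_ratio(0.5, 0.02, 0.25, 0.03)
  expect_equal(est$beta, 0.5)
  # first-order delta method
  expect_equal(est$se, 0.5 * sqrt(0.03^2 / 0.25^2 + 0.02^2 / 0.5^2),
               tolerance = 1e-12)
  expect_equal(est$ci_low, est$beta - qnorm(0.975) * est$se, tolerance = 1e-12)

  # beta_out = 0 with se_exp = 0: se = se_out / |beta_exp|
  est <- wald_ratio(0.5, 0, 0, 0.04)
  expect_equal(est$beta, 0)
  expect_equal(est$se, 0.04 / 0.5, tolerance = 1e-12)

  # se_exp = 0 generally: se = se_out / |beta_exp| exactly
  est <- wald_ratio(-0.4, 0, 0.1, 0.05)
  expect_equal(est$se, 0.05 / 0.4, tolerance = 1e-12)

  expect_error(wald_ratio(0, 0.01, 0.1, 0.05),
               class = "mrdam_weak_instrument_error")
})

test_that("IVW collapses to the Wald ratio for one instrument", {
  set.seed(91)
  for (i in 1:20) {
    bx <- rnorm(1, 0.3, 0.1); sx <- runif(1, 0.01, 0.05)
    by <- rnorm(1, 0.1, 0.1); sy <- runif(1, 0.01, 0.05)
    h <- data.frame(beta_exposure = bx, se_exposure = sx,
                    beta_outcome = by, se_outcome = sy)
    ivw <- mr_ivw(h)
    wr <- wald_ratio(bx, sx, by, sy)
    expect_equal(ivw$beta, wr$beta, tolerance = 1e-12)
    expect_equal(ivw$se, wr$se, tolerance = 1e-12)
  }
})

test_that("IVW is the stated precision-weighted average", {
  # all ratio SEs equal: beta = unweighted mean of ratios (se_exp = 0 makes
  # the delta SE = se_out/|beta_exp|, held constant)
  h <- data.frame(beta_exposure = c(0.5, 0.5, 0.5), se_exposure = 0,
                  beta_outcome = c(0.10, 0.20, 0.60), se_outcome = 0.05)
  expect_equal(mr_ivw(h)$beta, mean(h$beta_outcome / 0.5), tolerance = 1e-12)

  # 3 instruments: hand-computed weighted average, all by explicit arithmetic
  h <- data.frame(beta_exposure = c(0.5, 0.4, 0.25),
                  se_exposure = c(0.05, 0.04, 0.05),
                  beta_outcome = c(0.25, 0.10, 0.20),
                  se_outcome = c(0.05, 0.06, 0.04))
  r <- c(0.25 / 0.5, 0.10 / 0.4, 0.20 / 0.25)
  # first-order weights, s_j = se_out / |beta_exp|
  s1 <- c(0.05 / 0.5, 0.06 / 0.4, 0.04 / 0.25)
  w1 <- 1 / s1^2
  est <- mr_ivw(h, weights = "first")
  expect_equal(est$beta, sum(w1 * r) / sum(w1), tolerance = 1e-12)
  expect_equal(est$se, 1 / sqrt(sum(w1)), tolerance = 1e-12)

  # default modified weights: hand iteration of the delta SE evaluated at
  # the pooled estimate, two refinement steps from the first-order fit
  b <- sum(w1 * r) / sum(w1)
  for (it in 1:2) {
    wm <- h$beta_exposure^2 / (h$se_outcome^2 + b^2 * h$se_exposure^2)
    b <- sum(wm * r) / sum(wm)
  }
  est_mod <- mr_ivw(h)
  expect_equal(est_mod$beta, b, tolerance = 1e-12)
  expect_equal(est_mod$se, 1 / sqrt(sum(wm)), tolerance = 1e-12)
  # behind the flag: full (second-order) delta-method SEs
  s2 <- c(abs(r[1]) * sqrt(0.05^2 / 0.25^2 + 0.05^2 / 0.5^2),
          abs(r[2]) * sqrt(0.06^2 / 0.10^2 + 0.04^2 / 0.4^2),
          abs(r[3]) * sqrt(0.04^2 / 0.20^2 + 0.05^2 / 0.25^2))
  w2 <- 1 / s2^2
  est2 <- mr_ivw(h, weights = "second")
  expect_equal(est2$beta, sum(w2 * r) / sum(w2), tolerance = 1e-12)
  expect_equal(est2$se, 1 / sqrt(sum(w2)), tolerance = 1e-12)

  # random-effects SE never deflates below fixed-effect
  expect_gte(mr_ivw(h, mode = "random")$se, est_mod$se)
  expect_error(mr_ivw(h[0, ]), class = "mrdam_validation_error")
})

test_that("weighted median handles degenerate and hand-computed cases", {
  # all ratios equal: beta = that ratio
  h <- data.frame(beta_exposure = c(0.2, 0.4, 0.5), se_exposure = 0,
                  beta_outcome = c(0.1, 0.2, 0.25),
                  se_outcome = c(0.02, 0.03, 0.04))
  est <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)

  # odd J, equal weights, symmetric spacing: beta = middle ratio
  h <- data.frame(beta_exposure = rep(1, 5), se_exposure = 0,
                  beta_outcome = c(0.1, 0.2, 0.3, 0.4, 0.5),
                  se_outcome = 0.3)
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)

  # 7 high-weight instruments at ratio ~0.5 + 3 outliers at ratio 3 carrying
  # < 50% of weight: estimate stays within 0.05 of 0.5.
  # hand check of the weighted-percentile interpolation: valid weights are
  # 7 * (1/0.02^2) vs invalid 3 * (1/0.05^2) -> valid share ~ 0.936, so the
  # 50% point falls inside the tight cluster at 0.5.
  ratios <- c(rep(0.5, 7), rep(3, 3))
  h <- data.frame(beta_exposure = rep(1, 10), se_exposure = 0,
                  beta_outcome = ratios,
                  se_outcome = c(rep(0.02, 7), rep(0.05, 3)))
  w <- c(rep(1 / 0.02^2, 7), rep(1 / 0.05^2, 3))
  expect_lt(sum(w[8:10]) / sum(w), 0.5)
  est <- mr_weighted_median(h, n_boot = 100, seed = 2)
  expect_lt(abs(est$beta - 0.5), 0.05)

  expect_error(mr_weighted_median(h[1:2, ]), class = "mrdam_validation_error")
})

test_that("weighted-median bootstrap is seed-deterministic", {
  snps <- make_instruments(8, seed = 95)
  ss <- simulate_summary_stats(snps, 2000, 2000, ground_truth(0.3, seed = 96))
  h <- harmonize(ss$exposure, ss$outcome)
  a <- mr_weighted_median(h, n_boot = 300, seed = 777)
  b <- mr_weighted_median(h, n_boot = 300, seed = 777)
  c <- mr_weighted_median(h, n_boot = 300, seed = 778)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
})

test_that("mr_analysis orchestrates estimators and propagates errors", {
  snps <- make_instruments(1, seed = 97)
  ss <- simulate_summary_stats(snps, 2000, 2000, ground_truth(0.3, seed = 98))
  res <- mr_analysis(ss$exposure, ss$outcome, methods = c("ivw", "wald"))
  expect_equal(nrow(res$estimates), 2L)
  expect_equal(res$estimates$beta[1], res$estimates$beta[2], tolerance = 1e-12)
  expect_equal(res$estimates$se[1], res$estimates$se[2], tolerance = 1e-12)

  # weighted median impossible with one instrument: error collected, others run
  res <- mr_analysis(ss$exposure, ss$outcome,
                     methods = c("ivw", "weighted_median"))
  expect_equal(nrow(res$estimates), 1L)
  expect_match(res$errors$weighted_median, "3 instruments")
  expect_equal(nrow(res$instruments), 1L)
})

test_that("IVW covers the true effect and weighted median resists pleiotropy", {
  # scaled-down screening versions (the full 200-replicate designs run in
  # the acceptance suite): 40 replicates each
  covered <- logical(40)
  for (s in 1:40) {
    snps <- make_instruments(20, seed = 1100 + s)
    ss <- simulate_summary_stats(snps, 5000, 5000,
                                 ground_truth(0.3, seed = 1200 + s))
    est <- mr_ivw(harmonize(ss$exposure, ss$outcome))
    covered[s] <- est$ci_low <= 0.3 && 0.3 <= est$ci_high
  }
  expect_gte(mean(covered), 0.85)

  wm_closer <- logical(40)
  for (s in 1:40) {
    snps <- make_instruments(20, seed = 2100 + s, n_pleiotropic = 6,
                             beta_direct = 0.1)
    ss <- simulate_summary_stats(snps, 5000, 5000,
                                 ground_truth(0.3, seed = 2200 + s))
    h <- harmonize(ss$exposure, ss$outcome)
    wm <- mr_weighted_median(h, n_boot = 50, seed = s)
    ivw <- mr_ivw(h)
    wm_closer[s] <- abs(wm$beta - 0.3) < abs(ivw$beta - 0.3)
  }
  expect_gte(mean(wm_closer), 0.8)
})
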