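# shared builders for the test suite; everything is generated in code

# an instrument panel in the style of the MR recovery designs:
# beta_exposure ~ N(0.2, 0.05^2), MAF ~ U(0.1, 0.5)
make_instruments <- function(m, seed, n_pleiotropic = 0, beta_direct = 0.1) {
  set.seed(seed)
  bdir <- rep(0, m)
  if (n_pleiotropic > 0) bdir[seq_len(n_pleiotropic)] <- beta_direct
  snp_spec(sprintf("rs%04d", seq_len(m)),
           effect_allele = "A", other_allele = "G",
           maf = runif(m, 0.1, 0.5),
           beta_exposure = rnorm(m, 0.2, 0.05),
           beta_direct_outcome = bdir)
}

# hand-built activity record: counts vector on the 30-s grid starting at
# lights-on (ZT0 = 08:00)
toy_record <- function(counts, fly_id = "toy") {
  activity_record(fly_id, counts,
                  start = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
                  bin_s = 30, lights_on = "08:00:00")
}

# minimal summary-stats table for the harmonizer/estimators
sumstats <- function(variant_id, ea, oa, beta, se, eaf = NA_real_) {
  data.frame(variant_id = variant_id, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, stringsAsFactors = FALSE)
}
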