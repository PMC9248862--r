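# Shared fixtures, built in code at test time.

fixture_harmonized <- function() {
  tabs <- mr_example_tables()
  harmonize(tabs$exposure, tabs$outcome)
}

# a random harmonized-style instrument set (bypasses allele bookkeeping;
# used for numerical property tests of the estimators)
random_hset <- function(l, seed) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    bx <- stats::runif(l, 0.01, 0.1) * sample(c(-1, 1), l, replace = TRUE)
    data.frame(
      rsid = sprintf("rs%03d", seq_len(l)),
      beta_exp = bx,
      se_exp = stats::runif(l, 0.001, 0.01),
      beta_out = stats::rnorm(l, 0.1 * bx, 0.01),
      se_out = stats::runif(l, 0.005, 0.02),
      eaf_exp = stats::runif(l, 0.1, 0.9),
      eaf_out = NA_real_,
      stringsAsFactors = FALSE
    )
  })
}

# harmonized set straight from an unscrambled simulation (codings already
# aligned, so this is just column plumbing)
hset_from_sim <- function(sim) {
  data.frame(
    rsid = sim$exposure$rsid,
    beta_exp = sim$exposure$beta,
    se_exp = sim$exposure$se,
    beta_out = sim$outcome$beta,
    se_out = sim$outcome$se,
    eaf_exp = sim$exposure$eaf,
    eaf_out = sim$outcome$eaf,
    stringsAsFactors = FALSE
  )
}

# write an association table (or any data.frame) to a temp TSV
write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
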