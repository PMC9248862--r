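test_that("the packaged tables harmonize with exactly two allele flips", {
  h <- fixture_harmonized()
  expect_s3_class(h, "mr_harmonized")
  expect_equal(nrow(h), 6L)
  expect_equal(nrow(attr(h, "dropped")), 0L)
  expect_equal(sort(h$rsid[h$flipped]), c("rs10741657", "rs17216707"))
  # the flip negates the outcome beta and complements its EAF
  r17 <- h[h$rsid == "rs17216707", ]
  expect_equal(r17$beta_out, 0.0156)
  expect_equal(r17$eaf_out, 0.81)
  expect_equal(r17$ea, "T")
  # directly matching record untouched
  r37 <- h[h$rsid == "rs3755967", ]
  expect_equal(r37$beta_out, 0.0056)
  expect_false(r37$flipped)
  # C/G palindromic variant retained via EAF (0.82 vs 0.81, both far from 0.5)
  r80 <- h[h$rsid == "rs8018720", ]
  expect_true(r80$palindromic)
  expect_false(r80$flipped)
  expect_equal(r80$beta_out, 0.0058)
})

test_that("harmonizing an already-aligned outcome is the identity", {
  tabs <- mr_example_tables()
  h <- harmonize(tabs$exposure, tabs$outcome)
  aligned <- association_table(data.frame(
    rsid = h$rsid, ea = h$ea, nea = h$nea, eaf = h$eaf_out,
    beta = h$beta_out, se = h$se_out, stringsAsFactors = FALSE))
  h2 <- harmonize(tabs$exposure, aligned)
  expect_equal(sum(h2$flipped), 0L)
  expect_equal(h2$ratio, h$ratio)
  expect_equal(h2$beta_out, h$beta_out)
})

test_that("swapping EA/NEA in both inputs leaves the ratios unchanged", {
  tabs <- mr_example_tables()
  h <- harmonize(tabs$exposure, tabs$outcome)
  swap <- function(tab, rsids) {
    df <- as.data.frame(tab)
    i <- df$rsid %in% rsids
    tmp <- df$ea[i]; df$ea[i] <- df$nea[i]; df$nea[i] <- tmp
    df$beta[i] <- -df$beta[i]
    df$eaf[i] <- 1 - df$eaf[i]
    association_table(df)
  }
  for (r in c("rs3755967", "rs10741657")) {
    h2 <- harmonize(swap(tabs$exposure, r), swap(tabs$outcome, r))
    expect_equal(h2$ratio, h$ratio, tolerance = 1e-12)
  }
})

test_that("strand-complemented outcome codings are recognized", {
  tabs <- mr_example_tables()
  h <- harmonize(tabs$exposure, tabs$outcome)
  flip_strand <- function(tab, rsids) {
    df <- as.data.frame(tab)
    i <- df$rsid %in% rsids
    comp <- function(a) chartr("ACGT", "TGCA", a)
    df$ea[i] <- comp(df$ea[i]); df$nea[i] <- comp(df$nea[i])
    association_table(df)
  }
  # rs10741657 is A/G: reporting it as T/C is the same association
  h2 <- harmonize(tabs$exposure, flip_strand(tabs$outcome, "rs10741657"))
  expect_equal(h2$ratio, h$ratio)
  expect_equal(nrow(attr(h2, "dropped")), 0L)
})

test_that("palindromic SNPs are dropped when frequency cannot orient them", {
  exp_df <- data.frame(rsid = c("rs_pal", "rs_ok"), ea = c("A", "A"),
                       nea = c("T", "G"), eaf = c(0.48, 0.3),
                       beta = c(0.05, 0.04), se = c(0.01, 0.01))
  out_df <- data.frame(rsid = c("rs_pal", "rs_ok"), ea = c("A", "A"),
                       nea = c("T", "G"), eaf = c(0.52, 0.3),
                       beta = c(0.01, 0.01), se = c(0.01, 0.01))
  h <- harmonize(association_table(exp_df), association_table(out_df))
  expect_equal(h$rsid, "rs_ok")
  drp <- attr(h, "dropped")
  expect_equal(drp$reason[drp$rsid == "rs_pal"], "palindromic_ambiguous_eaf")
  # missing EAF on a palindromic SNP also drops it, with its own reason
  out_df2 <- out_df; out_df2$eaf[1] <- NA
  h2 <- harmonize(association_table(exp_df), association_table(out_df2))
  drp2 <- attr(h2, "dropped")
  expect_equal(drp2$reason[drp2$rsid == "rs_pal"], "palindromic_missing_eaf")
  # but an unambiguous palindromic SNP on the opposite orientation flips
  exp_df3 <- exp_df; exp_df3$eaf[1] <- 0.8
  out_df3 <- out_df; out_df3$eaf[1] <- 0.25
  h3 <- harmonize(association_table(exp_df3), association_table(out_df3))
  p <- h3[h3$rsid == "rs_pal", ]
  expect_true(p$flipped)
  expect_equal(p$beta_out, -0.01)
  expect_equal(p$eaf_out, 0.75)
})

test_that("drop reasons, discordance flags and hard errors are reported", {
  exp_df <- data.frame(rsid = c("rs1", "rs2", "rs3"), ea = "A", nea = "G",
                       eaf = c(0.10, 0.3, 0.3), beta = c(0.05, 0, 0.04),
                       se = 0.01)
  out_df <- data.frame(rsid = c("rs1", "rs2", "rs4"), ea = "A", nea = "G",
                       eaf = c(0.52, 0.3, 0.3), beta = 0.01, se = 0.01)
  expect_warning(h <- harmonize(association_table(exp_df),
                                association_table(out_df)),
                 "discordance")
  # rs1 kept but flagged: EAF 0.10 vs 0.52 on the same allele
  expect_true(h$eaf_discordant[h$rsid == "rs1"])
  drp <- attr(h, "dropped")
  expect_setequal(drp$reason[drp$rsid == "rs2"], "zero_exposure_beta")
  expect_true("missing_in_outcome" %in% drp$reason[drp$rsid == "rs3"])
  expect_true("missing_in_exposure" %in% drp$reason[drp$rsid == "rs4"])
  # disjoint tables are a hard error
  out_disjoint <- out_df; out_disjoint$rsid <- c("rx1", "rx2", "rx3")
  expect_error(harmonize(association_table(exp_df),
                         association_table(out_disjoint)), "no shared")
})
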