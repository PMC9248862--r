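test_that("Cochran Q partitions exactly into per-SNP contributions", {
  h <- fixture_harmonized()
  q <- mr_cochran_q(h)
  expect_equal(sum(q$contributions), q$q)
  expect_equal(q$df, 5L)
  # naive term-by-term loop as independent oracle
  theta <- mr_ivw(h, "fixed")$theta
  acc <- 0
  for (j in seq_len(nrow(h))) {
    wj <- h$beta_exp[j]^2 / h$se_out[j]^2
    acc <- acc + wj * (h$beta_out[j] / h$beta_exp[j] - theta)^2
  }
  expect_equal(q$q, acc, tolerance = 1e-12)
  expect_equal(q$p, pchisq(q$q, 5, lower.tail = FALSE))
  # identical ratios are perfectly homogeneous
  hom <- data.frame(rsid = c("a", "b", "c"), beta_exp = c(0.02, 0.05, 0.08),
                    se_exp = 0.01, beta_out = c(0.004, 0.01, 0.016),
                    se_out = 0.01)
  qh <- mr_cochran_q(hom)
  expect_equal(qh$q, 0)
  expect_equal(qh$p, 1)
  expect_error(mr_cochran_q(hom[1, ]), "at least 2")
})

test_that("leave-one-out rows equal IVW on the corresponding subsets", {
  h <- fixture_harmonized()
  inf <- mr_influence(h)
  expect_equal(nrow(inf$loo), 6L)
  expect_equal(nrow(inf$single_snp), 6L)
  for (j in c(1, 4, 6)) {
    direct <- mr_ivw(h[-j, ], "random")
    expect_equal(inf$loo$theta[j], direct$theta)
    expect_equal(inf$loo$se[j], direct$se)
  }
  # L = 3: each LOO row is the IVW of the complementary pair
  h3 <- h[1:3, ]
  inf3 <- mr_influence(h3)
  expect_equal(inf3$loo$theta[1], mr_ivw(h3[2:3, ])$theta)
  expect_equal(inf3$loo$theta[3], mr_ivw(h3[1:2, ])$theta)
  # single-SNP rows are the Wald ratios; rs3755967's is negative
  expect_equal(inf$single_snp$theta, h$beta_out / h$beta_exp)
  expect_lt(inf$single_snp$theta[inf$single_snp$rsid == "rs3755967"], 0)
  expect_error(mr_influence(h[1:2, ]), "at least 3")
})

test_that("the pleiotropy RSS test is seeded, bounded, and validated", {
  h <- fixture_harmonized()
  p1 <- mr_presso(h, n_sim = 300, seed = 42)
  p2 <- mr_presso(h, n_sim = 300, seed = 42)
  expect_identical(p1$global_p, p2$global_p)
  expect_identical(p1$per_snp_p, p2$per_snp_p)
  expect_gte(p1$global_p, 1 / 301)
  expect_lte(p1$global_p, 1)
  expect_true(all(p1$per_snp_p <= 1))
  expect_error(mr_presso(h, n_sim = 50, seed = 1), "n_sim")
  expect_error(mr_presso(h[1:2, ], n_sim = 300, seed = 1), "at least 3")
  h_na <- h; h_na$se_exp[2] <- NA
  expect_error(mr_presso(h_na, n_sim = 300, seed = 1), "se_exp")
})

test_that("a spiked pleiotropic SNP is flagged as an outlier", {
  sim <- simulate_two_sample(mr_scenario(l = 10, theta = 0.05, seed = 314))
  h <- harmonize(sim$exposure, sim$outcome)
  spiked <- h
  j <- 4
  spiked$beta_out[j] <- spiked$beta_out[j] + 10 * spiked$se_out[j]
  res <- mr_presso(spiked, n_sim = 1000, seed = 7)
  expect_lt(res$global_p, 0.01)
  expect_true(spiked$rsid[j] %in% res$outliers)
  # the clean set shows neither signal
  clean <- mr_presso(h, n_sim = 1000, seed = 7)
  expect_length(clean$outliers, 0)
  expect_gt(clean$global_p, 0.05)
})

test_that("the global RSS p-value is roughly uniform under the null", {
  # 10 null replicates, wide Kolmogorov-Smirnov sanity band
  ps <- vapply(1:10, function(i) {
    sim <- simulate_two_sample(mr_scenario(l = 20, theta = 0.1,
                                           seed = 1000 + i))
    h <- hset_from_sim(sim)
    mr_presso(h, n_sim = 500, seed = i)$global_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)
})
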