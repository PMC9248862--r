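test_that("Wald ratios divide the harmonized effects", {
  h <- fixture_harmonized()
  w1 <- mr_wald_ratio(h[h$rsid == "rs3755967", ])
  expect_equal(w1$theta, 0.0056 / -0.089)
  expect_equal(w1$se, 0.0074 / 0.089)
  expect_equal(w1$p, 2 * pnorm(-abs(w1$theta / w1$se)))
  # the EAF-inferred flip gives rs17216707 a positive ratio of 0.6
  w2 <- mr_wald_ratio(h[h$rsid == "rs17216707", ])
  expect_equal(w2$theta, 0.6)
  # null outcome effect: theta 0, p 1
  one <- h[1, ]; one$beta_out <- 0
  w3 <- mr_wald_ratio(one)
  expect_equal(w3$theta, 0)
  expect_equal(w3$p, 1)
  # zero exposure beta has no ratio
  one$beta_exp <- 0
  expect_error(mr_wald_ratio(one), "zero exposure")
})

test_that("IVW closed form equals weighted regression through the origin", {
  for (seed in 1:20) {
    set <- random_hset(l = sample(3:30, 1), seed = seed)
    fit <- mr_ivw(set, "fixed")
    # independent oracle: lm through the origin with weights 1/se_out^2
    ref <- lm(beta_out ~ 0 + beta_exp, data = set, weights = 1 / set$se_out^2)
    expect_equal(fit$theta, unname(coef(ref)[1]), tolerance = 1e-10)
  }
})

test_that("random-effects IVW inflates the fixed SE by the floored scale", {
  h <- fixture_harmonized()
  fe <- mr_ivw(h, "fixed")
  re <- mr_ivw(h, "random")
  expect_equal(re$theta, fe$theta)
  q <- mr_cochran_q(h)
  expect_equal(re$se, fe$se * sqrt(q$q / q$df))
  # homogeneity limit: identical ratios -> Q = 0, floor engages, SEs equal
  hom <- data.frame(rsid = c("a", "b"), beta_exp = c(0.05, 0.08),
                    se_exp = 0.01, beta_out = c(0.01, 0.016), se_out = 0.01)
  expect_equal(mr_ivw(hom, "random")$se, mr_ivw(hom, "fixed")$se)
  expect_equal(mr_ivw(hom, "random")$theta, 0.2)
  # a single instrument is not poolable
  expect_error(mr_ivw(h[1, ]), "mr_wald_ratio")
})

test_that("estimators are invariant to SNP order and joint sign flips", {
  set <- random_hset(12, seed = 99)
  perm <- set[sample(nrow(set)), ]
  flip <- set
  i <- c(2, 5, 7)
  flip$beta_exp[i] <- -flip$beta_exp[i]
  flip$beta_out[i] <- -flip$beta_out[i]
  for (variant_set in list(perm, flip)) {
    expect_equal(mr_ivw(variant_set, "random")$theta,
                 mr_ivw(set, "random")$theta, tolerance = 1e-12)
    expect_equal(mr_egger(variant_set)$slope$theta,
                 mr_egger(set)$slope$theta, tolerance = 1e-12)
    expect_equal(mr_median(variant_set, "weighted", 10, seed = 1)$theta,
                 mr_median(set, "weighted", 10, seed = 1)$theta,
                 tolerance = 1e-12)
  }
})

test_that("Egger with the intercept constrained to zero is IVW", {
  # algebraic identity, checked numerically: centre the regression by hand
  set <- random_hset(10, seed = 3)
  s <- sign(set$beta_exp)
  bx <- set$beta_exp * s; by <- set$beta_out * s; w <- 1 / set$se_out^2
  slope0 <- sum(w * bx * by) / sum(w * bx^2) # no-intercept WLS
  expect_equal(slope0, mr_ivw(set, "fixed")$theta, tolerance = 1e-12)
})

test_that("Egger preconditions: enough SNPs, non-collinear exposure betas", {
  h <- fixture_harmonized()
  expect_error(mr_egger(h[1:2, ]), "at least 3")
  col <- data.frame(rsid = letters[1:4], beta_exp = 0.05, se_exp = 0.01,
                    beta_out = c(0.01, 0.02, 0.015, 0.02), se_out = 0.01)
  expect_error(mr_egger(col), "collinear")
})

test_that("Egger SEs use WLS with floored residual scale and t p-values", {
  h <- fixture_harmonized()
  e <- mr_egger(h)
  # oracle: R's own weighted lm; its SEs carry the residual scale, which
  # exceeds 1 here, so they equal ours
  s <- sign(h$beta_exp)
  ref <- lm(I(h$beta_out * s) ~ I(h$beta_exp * s), weights = 1 / h$se_out^2)
  sm <- summary(ref)
  expect_gt(e$scale, 1)
  expect_equal(e$slope$theta, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(e$slope$se, unname(sm$coefficients[2, 2]), tolerance = 1e-10)
  expect_equal(e$intercept$se, unname(sm$coefficients[1, 2]), tolerance = 1e-10)
  expect_equal(e$slope$p, unname(sm$coefficients[2, 4]), tolerance = 1e-10)
  expect_equal(e$slope$df, 4)
})

test_that("weighted median interpolation agrees with the L1 grid oracle", {
  for (seed in 1:15) {
    set.seed(seed)
    l <- sample(3:15, 1)
    r <- rnorm(l)
    w <- runif(l, 0.1, 2)
    est <- mr2s:::.wmedian(r, w)
    # the weighted median minimizes the weighted absolute deviation; find
    # the flat minimizing region on a dense grid
    grid <- seq(min(r), max(r), length.out = 4001)
    loss <- vapply(grid, function(t) sum(w * abs(r - t)), numeric(1))
    flat <- grid[loss <= min(loss) + 1e-9 * max(loss)]
    resolution <- max(diff(sort(r)))
    expect_lte(min(abs(est - flat)), resolution)
    # estimate always inside the ratio range
    expect_gte(est, min(r)); expect_lte(est, max(r))
  }
})

test_that("median family limits: equal weights, even-L mean, dominance", {
  set.seed(21)
  # equal weights reproduce the sample median exactly, odd and even L
  for (l in c(5, 6, 9, 12)) {
    r <- rnorm(l)
    expect_equal(mr2s:::.wmedian(r, rep(1, l)), median(r))
  }
  # a SNP with most of the weight pins the estimate to its ratio
  r <- c(-1, 0.3, 1.2, 2)
  w <- c(0.01, 0.97, 0.01, 0.01)
  expect_equal(mr2s:::.wmedian(r, w), 0.3, tolerance = 0.05)
})

test_that("median estimators: seeding, preconditions, bootstrap SE", {
  h <- fixture_harmonized()
  expect_error(mr_median(h, "weighted"), "seed")
  expect_error(mr_median(h, "weighted", n_boot = 1, seed = 1), "n_boot")
  expect_error(mr_median(h[1:2, ], "weighted", seed = 1), "at least 3")
  m1 <- mr_median(h, "weighted", n_boot = 200, seed = 5)
  m2 <- mr_median(h, "weighted", n_boot = 200, seed = 5)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$se, m2$se)
  # a single SNP still admits a simple median (its own ratio)
  s1 <- mr_median(h[1, ], "simple", n_boot = 50, seed = 2)
  expect_equal(s1$theta, h$ratio[1])
  # the bootstrap does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(mr_median(h, "simple", n_boot = 20, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("mr_fit assembles the requested estimates with methods", {
  h <- fixture_harmonized()
  fit <- mr_fit(h, seed = 7, n_boot = 100)
  expect_s3_class(fit, "mr_fit")
  expect_equal(nrow(fit$estimates), 7L) # egger adds slope + intercept
  expect_setequal(fit$estimates$method,
                  c("ivw_fe", "ivw_re", "egger_slope", "egger_intercept",
                    "simple_median", "weighted_median",
                    "penalized_weighted_median"))
  expect_equal(unname(coef(fit)["ivw_fe"]), mr_ivw(h, "fixed")$theta)
  ci <- confint(fit)
  expect_equal(unname(ci["ivw_fe", 1]),
               fit$estimates$ci_low[fit$estimates$method == "ivw_fe"])
  # subsets work without a seed when nothing stochastic is requested
  fit2 <- mr_fit(h, methods = c("ivw_fe", "egger"))
  expect_equal(nrow(fit2$estimates), 3L)
  expect_error(mr_fit(h, methods = "weighted_median"), "seed")
  expect_output(print(fit), "ivw_fe")
  expect_output(print(summary(fit)), "outcome")
})
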