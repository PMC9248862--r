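## Causal-effect estimators: Wald ratio, IVW, MR-Egger, median family.
##
## All estimates live on the log-odds scale per unit of exposure; the
## odds-ratio columns are exponentiated copies. 95% confidence intervals use
## the 1.96 normal quantile throughout; p-values use the normal reference
## except MR-Egger, which uses t with L - 2 degrees of freedom.

.Z95 <- stats::qnorm(0.975)

.mr_estimate <- function(method, theta, se, p, n_snp, df = NA_real_) {
  structure(list(
    method = method, theta = theta, se = se,
    ci_low = theta - .Z95 * se, ci_high = theta + .Z95 * se,
    or = exp(theta), or_low = exp(theta - .Z95 * se),
    or_high = exp(theta + .Z95 * se),
    p = p, n_snp = n_snp, df = df
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s: OR %.*f (95%% CI %.*f-%.*f), P = %.3g  [%d SNP(s)]\n",
              x$method, digits, x$or, digits, x$or_low, digits, x$or_high,
              x$p, x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, theta = x$theta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, or = x$or,
             or_low = x$or_low, or_high = x$or_high, p = x$p, df = x$df,
             stringsAsFactors = FALSE)
}

#' Single-SNP Wald ratio estimate
#'
#' The causal effect identified by one instrument: `theta = beta_out /
#' beta_exp`, with the first-order (delta-method, exposure uncertainty
#' ignored) standard error `se_out / |beta_exp|` and a two-sided normal
#' p-value.
#'
#' @param inst one row of a harmonized set from [harmonize()].
#' @return an `mr_estimate` (list with `theta`, `se`, `ci_low`, `ci_high`,
#'   `or`, `or_low`, `or_high`, `p`, `n_snp`, `df`).
#' @export
mr_wald_ratio <- function(inst) {
  inst <- .as_hset(inst, 1L, "mr_wald_ratio")
  if (nrow(inst) != 1L)
    stop("mr_wald_ratio() takes a single instrument; see mr_ivw() for several",
         call. = FALSE)
  theta <- inst$beta_out / inst$beta_exp
  se <- inst$se_out / abs(inst$beta_exp)
  .mr_estimate(paste0("wald_ratio:", inst$rsid), theta, se,
               2 * stats::pnorm(-abs(theta / se)), 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' The IVW estimate pools the per-SNP Wald ratios with weights
#' `beta_exp^2 / se_out^2` — algebraically the slope of the weighted
#' regression of `beta_out` on `beta_exp` through the origin with weights
#' `1 / se_out^2`:
#' `theta = sum(beta_exp * beta_out / se_out^2) / sum(beta_exp^2 / se_out^2)`.
#'
#' The fixed-effect standard error is `1 / sqrt(sum(beta_exp^2 / se_out^2))`;
#' the multiplicative random-effects model inflates it by the residual scale
#' `sqrt(Q / (L - 1))`, floored at 1, where Q is Cochran's heterogeneity
#' statistic about the IVW estimate (see [mr_cochran_q()]). Under
#' homogeneity the two coincide.
#'
#' @param set harmonized instrument set from [harmonize()] with at least two
#'   SNPs.
#' @param effects_model `"fixed"` or `"random"`.
#' @return an `mr_estimate`; the residual `scale` and `q` are attached as
#'   attributes.
#' @examples
#' tabs <- mr_example_tables()
#' h <- harmonize(tabs$exposure, tabs$outcome)
#' mr_ivw(h, "fixed")
#' mr_ivw(h, "random")
#' @export
mr_ivw <- function(set, effects_model = c("random", "fixed")) {
  effects_model <- match.arg(effects_model)
  set <- .as_hset(set, 2L, "mr_ivw")
  L <- nrow(set)
  w <- set$beta_exp^2 / set$se_out^2
  theta <- sum(set$beta_exp * set$beta_out / set$se_out^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (set$beta_out / set$beta_exp - theta)^2)
  scale <- 1
  if (effects_model == "random") {
    scale <- max(1, sqrt(q / (L - 1)))
    se <- se * scale
  }
  est <- .mr_estimate(paste0("ivw_", substr(effects_model, 1, 1), "e"),
                      theta, se, 2 * stats::pnorm(-abs(theta / se)), L)
  attr(est, "scale") <- scale
  attr(est, "q") <- q
  est
}

#' MR-Egger regression: pleiotropy-robust slope and intercept test
#'
#' Weighted least squares of the outcome betas on the exposure betas with an
#' unconstrained intercept and weights `1 / se_out^2`, after orienting every
#' SNP to a positive exposure effect (negating both betas where needed; the
#' intercept is only interpretable in that orientation). The slope estimates
#' the causal effect even when all instruments are pleiotropic, provided the
#' pleiotropic effects are independent of instrument strength; the intercept
#' estimates the average directional pleiotropy, and an intercept
#' indistinguishable from zero (P > 0.05) is read as no directional
#' pleiotropy.
#'
#' Standard errors are the weighted-least-squares ones inflated by the
#' residual scale floored at 1 (multiplicative random effects); p-values use
#' t with `L - 2` degrees of freedom, while the 95% CIs use the normal
#' 1.96 quantile.
#'
#' @param set harmonized instrument set with at least three SNPs whose
#'   oriented exposure betas are not all equal.
#' @return list of class `"mr_egger"` with elements `slope` and `intercept`
#'   (both `mr_estimate`s) and `scale` (residual scale before flooring).
#' @examples
#' tabs <- mr_example_tables()
#' h <- harmonize(tabs$exposure, tabs$outcome)
#' mr_egger(h)
#' @export
mr_egger <- function(set) {
  set <- .as_hset(set, 3L, "mr_egger")
  L <- nrow(set)
  s <- sign(set$beta_exp)
  bx <- set$beta_exp * s
  by <- set$beta_out * s
  w <- 1 / set$se_out^2
  xbar <- sum(w * bx) / sum(w)
  sxx <- sum(w * (bx - xbar)^2)
  if (sxx <= .Machine$double.eps * sum(w * bx^2))
    stop("exposure betas are collinear after orientation; MR-Egger is undefined",
         call. = FALSE)
  slope <- sum(w * (bx - xbar) * (by - sum(w * by) / sum(w))) / sxx
  intercept <- sum(w * by) / sum(w) - slope * xbar
  resid <- by - intercept - slope * bx
  sigma <- sqrt(sum(w * resid^2) / (L - 2))
  infl <- max(1, sigma)
  se_slope <- sqrt(1 / sxx) * infl
  se_int <- sqrt(1 / sum(w) + xbar^2 / sxx) * infl
  pt2 <- function(est, se) 2 * stats::pt(-abs(est / se), df = L - 2)
  out <- list(
    slope = .mr_estimate("egger_slope", slope, se_slope,
                         pt2(slope, se_slope), L, df = L - 2),
    intercept = .mr_estimate("egger_intercept", intercept, se_int,
                             pt2(intercept, se_int), L, df = L - 2),
    scale = sigma
  )
  class(out) <- "mr_egger"
  out
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope, ...)
  cat(sprintf("egger_intercept: %.3f (se %.3f), P = %.3g%s\n",
              x$intercept$theta, x$intercept$se, x$intercept$p,
              if (x$intercept$p > 0.05) "  [no directional pleiotropy]" else ""))
  invisible(x)
}

## Weighted median by interpolation of the standardized cumulative weights.
## Ties in the sorted ratios are broken by input order (stable sort);
## a median position outside [p_1, p_L] clamps to the end ratio.
.wmedian <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5)$y
}

.median_weights <- function(bx, by, sx, so, variant, weights) {
  if (variant == "simple") return(rep(1, length(bx)))
  if (weights == "second") 1 / (so^2 / bx^2 + by^2 * sx^2 / bx^4)
  else bx^2 / so^2
}

.median_point <- function(bx, by, sx, so, variant, weights) {
  r <- by / bx
  w <- .median_weights(bx, by, sx, so, variant, weights)
  if (variant == "penalized") {
    th <- .wmedian(r, w)
    qj <- stats::pchisq(w * (r - th)^2, df = 1, lower.tail = FALSE)
    w <- w * pmin(1, 20 * qj)
  }
  .wmedian(r, w)
}

#' Median-based causal estimators
#'
#' The median of the per-SNP Wald ratios is a consistent causal estimate
#' even when up to half the instruments (simple) or half the weight
#' (weighted) comes from invalid instruments. The estimate interpolates the
#' sorted ratios at standardized cumulative weight position 0.5
#' (`p_j = (cum_j - w_j/2) / sum(w)`), with weights:
#' \describe{
#'   \item{simple}{equal, `1/L`;}
#'   \item{weighted}{inverse Wald-ratio variance — by default the
#'     delta-method variance `se_out^2/beta_exp^2 +
#'     beta_out^2 se_exp^2/beta_exp^4` (`weights = "second"`), optionally
#'     the first-order `beta_exp^2/se_out^2` (`weights = "first"`);}
#'   \item{penalized}{the weighted weights further multiplied by
#'     `min(1, 20 q_j)`, where `q_j` is the upper-tail chi-square(1)
#'     probability of SNP j's heterogeneity contribution
#'     `w_j (ratio_j - theta_WM)^2` about the weighted-median estimate —
#'     down-weighting SNPs with outlying ratios.}
#' }
#'
#' No closed-form standard error exists; the SE is the standard deviation of
#' the estimate over `n_boot` parametric-bootstrap replicates in which both
#' studies' betas are redrawn from `N(beta, se)` and the weights (and
#' penalties) recomputed. CI and p-value are normal.
#'
#' @param set harmonized instrument set; at least 3 SNPs for the
#'   weighted/penalized variants, 1 for the simple median.
#' @param variant `"weighted"` (default), `"simple"`, or `"penalized"`.
#' @param n_boot bootstrap replicates for the SE (default 1000; must be
#'   at least 2).
#' @param seed RNG seed for the bootstrap, required for reproducibility.
#'   The caller's RNG state is left untouched.
#' @param weights Wald-ratio weighting for the weighted/penalized variants:
#'   `"second"` (delta method, default) or `"first"` (first-order).
#' @return an `mr_estimate`.
#' @examples
#' tabs <- mr_example_tables()
#' h <- harmonize(tabs$exposure, tabs$outcome)
#' mr_median(h, "weighted", seed = 1)
#' @export
mr_median <- function(set, variant = c("weighted", "simple", "penalized"),
                      n_boot = 1000, seed, weights = c("second", "first")) {
  variant <- match.arg(variant)
  weights <- match.arg(weights)
  set <- .as_hset(set, if (variant == "simple") 1L else 3L,
                  paste0(variant, " median"))
  if (missing(seed))
    stop("'seed' is required: the bootstrap SE is stochastic", call. = FALSE)
  .check_scalar(n_boot, "n_boot", 2, Inf)
  if (variant != "simple" && any(is.na(set$se_exp)))
    stop("bootstrap needs se_exp for every SNP", call. = FALSE)
  bx <- set$beta_exp; by <- set$beta_out
  sx <- set$se_exp; so <- set$se_out
  L <- length(bx)
  theta <- .median_point(bx, by, sx, so, variant, weights)
  boot <- .with_seed(seed, {
    bxs <- matrix(stats::rnorm(L * n_boot, bx, sx), nrow = L)
    bys <- matrix(stats::rnorm(L * n_boot, by, so), nrow = L)
    vapply(seq_len(n_boot), function(b)
      .median_point(bxs[, b], bys[, b], sx, so, variant, weights),
      numeric(1))
  })
  se <- stats::sd(boot)
  label <- switch(variant, simple = "simple_median",
                  weighted = "weighted_median",
                  penalized = "penalized_weighted_median")
  .mr_estimate(label, theta, se, 2 * stats::pnorm(-abs(theta / se)), L)
}

#' Fit the full set of two-sample MR estimators
#'
#' The central model-fitting function: takes a harmonized instrument set and
#' returns every requested causal-effect estimate plus the heterogeneity
#' summary, as a classed object with `print`, `summary`, `coef`, `confint`
#' and `plot` methods.
#'
#' @param set harmonized instrument set from [harmonize()].
#' @param methods subset of `c("ivw_fe", "ivw_re", "egger", "simple_median",
#'   "weighted_median", "penalized_weighted_median")`. MR-Egger contributes
#'   two rows (slope and intercept).
#' @param n_boot parametric-bootstrap replicates for the median SEs.
#' @param seed RNG seed (required when any median method is requested).
#' @param median_weights passed to [mr_median()].
#' @return object of class `"mr_fit"`: list with `estimates` (data.frame,
#'   one row per method), `heterogeneity` ([mr_cochran_q()] result),
#'   `data` (the harmonized set), `n_boot`, `seed`, `call`.
#' @examples
#' tabs <- mr_example_tables()
#' h <- harmonize(tabs$exposure, tabs$outcome)
#' fit <- mr_fit(h, seed = 7)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(set,
                   methods = c("ivw_fe", "ivw_re", "egger", "simple_median",
                               "weighted_median", "penalized_weighted_median"),
                   n_boot = 1000, seed = NULL,
                   median_weights = c("second", "first")) {
  methods <- match.arg(methods, several.ok = TRUE)
  median_weights <- match.arg(median_weights)
  set <- .as_hset(set, 1L, "mr_fit")
  needs_boot <- any(grepl("median", methods))
  if (needs_boot && is.null(seed))
    stop("'seed' is required when median estimators are requested",
         call. = FALSE)
  ests <- list()
  for (m in methods) {
    ests[[m]] <- switch(
      m,
      ivw_fe = mr_ivw(set, "fixed"),
      ivw_re = mr_ivw(set, "random"),
      egger = mr_egger(set),
      simple_median = mr_median(set, "simple", n_boot, seed,
                                weights = median_weights),
      weighted_median = mr_median(set, "weighted", n_boot, seed,
                                  weights = median_weights),
      penalized_weighted_median = mr_median(set, "penalized", n_boot, seed,
                                            weights = median_weights)
    )
  }
  rows <- lapply(ests, function(e) {
    if (inherits(e, "mr_egger"))
      rbind(as.data.frame(e$slope), as.data.frame(e$intercept))
    else as.data.frame(e)
  })
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  het <- if (nrow(set) >= 2) mr_cochran_q(set) else NULL
  structure(list(estimates = estimates, heterogeneity = het, data = set,
                 n_boot = if (needs_boot) n_boot else NA_integer_,
                 seed = seed, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR fit: %d instrument(s)\n", nrow(x$data)))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    if (est$method[i] == "egger_intercept") {
      cat(sprintf("  %-26s %+.*f (se %.*f)          P = %.3g\n",
                  est$method[i], digits, est$theta[i], digits, est$se[i],
                  est$p[i]))
    } else {
      cat(sprintf("  %-26s OR %.*f (%.*f-%.*f)  P = %.3g\n",
                  est$method[i], digits, est$or[i], digits, est$or_low[i],
                  digits, est$or_high[i], est$p[i]))
    }
  }
  if (!is.null(x$heterogeneity))
    cat(sprintf("  Cochran Q = %.3f (df %d), P = %.3f\n",
                x$heterogeneity$q, x$heterogeneity$df, x$heterogeneity$p))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object,
                 screen = outcome_screen(object$data)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit, ...)
  cat("Per-SNP outcome screen (Bonferroni", format(x$screen$threshold[1],
                                                   digits = 3), "):",
      if (all(x$screen$pass)) "no SNP directly associated with the outcome"
      else paste("flagged:", paste(x$screen$rsid[!x$screen$pass],
                                   collapse = ", ")), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$theta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$theta - z * est$se, est$theta + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Forest-style plot of the fitted MR estimates
#'
#' Draws each method's odds ratio and 95% CI on a log axis, with the null
#' at OR = 1. The Egger intercept row (not an odds ratio) is omitted.
#'
#' @param x an [mr_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  est <- x$estimates[x$estimates$method != "egger_intercept", ]
  k <- nrow(est)
  graphics::plot(est$or, seq_len(k), log = "x",
                 xlim = range(c(est$or_low, est$or_high, 1)),
                 ylim = c(0.5, k + 0.5), yaxt = "n", pch = 15,
                 xlab = "Odds ratio per unit exposure", ylab = "", ...)
  graphics::segments(est$or_low, seq_len(k), est$or_high, seq_len(k))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(k), labels = est$method, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}
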