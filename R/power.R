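## Binary-outcome MR power via the normal non-centrality approximation.

.power_ncp_scale <- function(n, case_fraction, r2) {
  .check_scalar(n, "n", 2, Inf, open_lower = TRUE)
  .check_scalar(case_fraction, "case_fraction", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
  .check_scalar(r2, "r2", 0, 1, open_upper = TRUE)
  sqrt(n * r2 * case_fraction * (1 - case_fraction))
}

#' Power of a binary-outcome two-sample MR design
#'
#' Normal-approximation power of the two-sided test of no causal effect.
#' The non-centrality parameter of the IVW estimate for a binary outcome
#' with `n` subjects, case fraction `K`, and instruments jointly explaining
#' fraction `r2` of the exposure variance is
#' `ncp = ln(OR) * sqrt(n * r2 * K * (1 - K))`, and
#' `power = pnorm(|ncp| - z) + pnorm(-|ncp| - z)` with `z` the two-sided
#' `1 - alpha/2` normal quantile (the second, far-tail term makes the null
#' power equal alpha exactly; away from the null it is negligible).
#'
#' @param n outcome-study sample size.
#' @param case_fraction proportion of cases K, in (0, 1).
#' @param r2 exposure variance explained by the instruments, in \[0, 1).
#'   Passing 0 warns: the test then has only its type-I error rate.
#' @param or causal odds ratio per unit exposure to detect.
#' @param alpha two-sided significance level (default 0.05).
#' @return list of class `"mr_power"` with `power`, `ncp` and the inputs.
#' @examples
#' mr_power(n = 1030836, case_fraction = 60620 / 1030836, r2 = 0.0284,
#'          or = 0.931)
#' @export
mr_power <- function(n, case_fraction, r2, or, alpha = 0.05) {
  .check_scalar(or, "or", 0, Inf, open_lower = TRUE)
  .check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  scale <- .power_ncp_scale(n, case_fraction, r2)
  if (r2 == 0)
    warning("r2 = 0: no instrument signal, power equals the significance level",
            call. = FALSE)
  ncp <- abs(log(or)) * scale
  z <- stats::qnorm(1 - alpha / 2)
  power <- stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
  structure(list(power = power, ncp = ncp, n = n,
                 case_fraction = case_fraction, r2 = r2, or = or,
                 alpha = alpha),
            class = "mr_power")
}

#' Minimal detectable odds ratio at a target power
#'
#' Inverts the power formula: the closed form
#' `|ln OR| = (z_{1 - alpha/2} + z_{power}) / sqrt(n * r2 * K * (1 - K))`
#' (exact when the far tail of the two-sided test is negligible), refined
#' numerically so that [mr_power()] of the result reproduces the target
#' power exactly even at low powers. Returns the protective-side OR
#' (`exp(-|ln OR|)`, below 1) by default.
#'
#' @inheritParams mr_power
#' @param power target power, strictly greater than `alpha`.
#' @param side `"protective"` (OR below 1, default) or `"risk"`.
#' @return list of class `"mr_power"` with `detectable_or`, `ncp` and the
#'   inputs.
#' @examples
#' # the largest study-design question this package answers:
#' mr_detectable_or(n = 1030836, case_fraction = 60620 / 1030836,
#'                  r2 = 0.0284, power = 0.80)
#' @export
mr_detectable_or <- function(n, case_fraction, r2, power = 0.80,
                             alpha = 0.05, side = c("protective", "risk")) {
  side <- match.arg(side)
  .check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  .check_scalar(power, "power", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (power <= alpha)
    stop("target power must exceed alpha: the test rejects at rate alpha ",
         "even under the null", call. = FALSE)
  scale <- .power_ncp_scale(n, case_fraction, r2)
  if (scale == 0) stop("r2 = 0: no odds ratio is detectable", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  lnor <- (z + stats::qnorm(power)) / scale
  ## the closed form drops the far-tail term of the two-sided power; refine
  ## so that mr_power() of the result returns the target exactly
  two_tail <- function(l) stats::pnorm(l * scale - z) +
    stats::pnorm(-l * scale - z) - power
  if (two_tail(lnor) > 0)
    lnor <- stats::uniroot(two_tail, c(0, lnor), tol = 1e-12)$root
  or <- if (side == "protective") exp(-lnor) else exp(lnor)
  structure(list(detectable_or = or, ncp = lnor * scale, n = n,
                 case_fraction = case_fraction, r2 = r2, power = power,
                 alpha = alpha, side = side),
            class = "mr_power")
}

#' @export
print.mr_power <- function(x, ...) {
  if (is.null(x$detectable_or))
    cat(sprintf("MR power: %.3f to detect OR %.3f (n = %s, K = %.4f, R2 = %.4f, alpha = %.3g)\n",
                x$power, x$or, format(x$n, big.mark = ","), x$case_fraction,
                x$r2, x$alpha))
  else
    cat(sprintf("Minimal detectable OR (%s side): %.3f at %.0f%% power (n = %s, K = %.4f, R2 = %.4f, alpha = %.3g)\n",
                x$side, x$detectable_or, 100 * x$power,
                format(x$n, big.mark = ","), x$case_fraction, x$r2, x$alpha))
  invisible(x)
}
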