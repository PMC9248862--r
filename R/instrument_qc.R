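## Instrument strength and outcome-association screening.

#' Proportion of exposure variance explained by one SNP
#'
#' For an additive per-allele effect `beta` on a trait with standard
#' deviation `sd`, a variant with effect-allele frequency `eaf` explains
#' `r2 = 2 * eaf * (1 - eaf) * (beta / sd)^2` of the trait variance under
#' Hardy-Weinberg equilibrium. GWAS of standardized (or natural-log, unit
#' SD) traits use `sd = 1`.
#'
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param beta per-allele effect estimate.
#' @param sd trait standard deviation (default 1, the scale of the packaged
#'   exposure study).
#' @return variance explained as a fraction (not percent).
#' @examples
#' variance_explained(0.28, -0.089)  # 0.00319 -> 0.319%
#' @export
variance_explained <- function(eaf, beta, sd = 1) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1))
    stop("'eaf' must lie strictly inside (0, 1): a fixed allele explains no variance",
         call. = FALSE)
  .check_scalar(sd, "sd", 0, Inf, open_lower = TRUE)
  2 * eaf * (1 - eaf) * (beta / sd)^2
}

#' F-statistic of an instrument from its variance explained
#'
#' `F = r2 * (n - 2) / (1 - r2)`, the single-regressor F for a variant
#' explaining fraction `r2` of the exposure variance in a study of `n`
#' individuals. An F-statistic above 10 is the conventional threshold for a
#' low risk of weak-instrument bias.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n exposure-study sample size (> 2).
#' @return the F-statistic (vectorized over `r2`).
#' @examples
#' f_statistic(variance_explained(0.28, -0.089), 79366)  # 254.28
#' @export
f_statistic <- function(r2, n) {
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 >= 1))
    stop("'r2' must lie in [0, 1)", call. = FALSE)
  .check_scalar(n, "n", 2, Inf, open_lower = TRUE)
  r2 * (n - 2) / (1 - r2)
}

#' Per-SNP instrument strength table
#'
#' Computes each instrument's variance explained and F-statistic from its
#' exposure-study EAF and beta, and classifies instruments with F > 10 as
#' strong.
#'
#' @param x an [association_table()] (exposure study) or a harmonized set
#'   from [harmonize()] (its `eaf_exp`/`beta_exp` columns are used).
#' @param n exposure-study sample size; defaults to the table's `n` column
#'   when present and constant.
#' @inheritParams variance_explained
#' @return data.frame with columns `rsid`, `r2`, `f_stat`, `strong`.
#' @examples
#' tabs <- mr_example_tables()
#' instrument_strength(tabs$exposure)
#' @export
instrument_strength <- function(x, n = NULL, sd = 1) {
  if (all(c("beta_exp", "eaf_exp") %in% names(x))) {
    eaf <- x$eaf_exp; beta <- x$beta_exp
  } else {
    eaf <- x$eaf; beta <- x$beta
    if (is.null(n) && !is.null(x$n)) {
      nn <- unique(x$n[!is.na(x$n)])
      if (length(nn) == 1L) n <- nn
    }
  }
  if (is.null(n))
    stop("'n' (exposure sample size) is required", call. = FALSE)
  if (any(is.na(eaf)))
    stop("variance explained needs the effect-allele frequency; missing for ",
         paste(x$rsid[is.na(eaf)], collapse = ", "), call. = FALSE)
  r2 <- variance_explained(eaf, beta, sd = sd)
  f <- f_statistic(r2, n)
  data.frame(rsid = x$rsid, r2 = r2, f_stat = f, strong = f > 10,
             stringsAsFactors = FALSE)
}

#' Bonferroni screen of instruments against direct outcome association
#'
#' A variant strongly associated with the outcome in its own right is a
#' candidate pleiotropic instrument. Each SNP's two-sided normal p-value is
#' recomputed from `beta_out / se_out` (published p columns are rounded) and
#' compared to the Bonferroni-corrected level `alpha / L` for `L`
#' instruments.
#'
#' @param set harmonized instrument set from [harmonize()].
#' @param alpha family-wise significance level before correction
#'   (default 0.05).
#' @return data.frame with columns `rsid`, `p`, `threshold`, `pass`
#'   (`TRUE` = no direct outcome association at the corrected level).
#' @export
outcome_screen <- function(set, alpha = 0.05) {
  set <- .as_hset(set, 1L, "outcome_screen")
  .check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  p <- 2 * stats::pnorm(-abs(set$beta_out / set$se_out))
  thr <- alpha / nrow(set)
  data.frame(rsid = set$rsid, p = p, threshold = thr, pass = p >= thr,
             stringsAsFactors = FALSE)
}
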