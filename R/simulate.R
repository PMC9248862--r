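## Synthetic two-sample summary statistics with known ground truth.

#' Define a synthetic two-sample MR scenario
#'
#' Describes the generative model for [simulate_two_sample()]: `l`
#' independent instruments with allele frequencies drawn from `eaf_range`,
#' true per-allele exposure effects sized to give per-SNP variance explained
#' drawn uniformly from `r2_range` (on an exposure with unit SD, the scale
#' the instrument-strength formulas assume), a linear causal effect `theta`
#' (log-odds of the binary outcome per exposure unit), and optional direct
#' SNP-to-outcome (horizontal pleiotropy) effects
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` attached to the
#' exposure-increasing allele — a nonzero mean is directional pleiotropy,
#' the violation MR-Egger's intercept targets.
#'
#' Defaults mirror the packaged vitamin D / atrial fibrillation design:
#' exposure study of 79,366, outcome study of 1,030,836 with case fraction
#' 60,620/1,030,836, and per-SNP R-squared in the range genome-wide
#' significant hits of such a study show (about 0.05% to 0.3%).
#'
#' @param l number of instruments.
#' @param theta true causal effect (log-OR per exposure unit).
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of the direct per-allele
#'   SNP-outcome effects (defaults 0: valid instruments).
#' @param n_exp,n_out exposure and outcome study sizes.
#' @param case_fraction outcome case fraction K in (0, 1).
#' @param eaf_range interval for allele-frequency sampling, inside (0, 1).
#' @param r2_range interval for per-SNP exposure variance explained.
#' @param scramble_alleles if `TRUE`, each outcome record independently
#'   swaps its allele order (negating its beta and complementing its EAF)
#'   and/or flips strand with probability 1/2 each — deliberately scrambled
#'   codings that [harmonize()] must undo.
#' @param seed RNG seed; generation is bit-reproducible given the scenario.
#' @return list of class `"mr_scenario"`.
#' @export
mr_scenario <- function(l = 50, theta = 0, pleiotropy_mean = 0,
                        pleiotropy_sd = 0, n_exp = 79366, n_out = 1030836,
                        case_fraction = 60620 / 1030836,
                        eaf_range = c(0.1, 0.9),
                        r2_range = c(5e-4, 3e-3),
                        scramble_alleles = FALSE, seed = 1) {
  .check_scalar(l, "l", 1, Inf)
  .check_scalar(theta, "theta")
  .check_scalar(pleiotropy_mean, "pleiotropy_mean")
  .check_scalar(pleiotropy_sd, "pleiotropy_sd", 0, Inf)
  .check_scalar(n_exp, "n_exp", 2, Inf, open_lower = TRUE)
  .check_scalar(n_out, "n_out", 2, Inf, open_lower = TRUE)
  .check_scalar(case_fraction, "case_fraction", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
  stopifnot(length(eaf_range) == 2L, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2],
            length(r2_range) == 2L, r2_range[1] > 0, r2_range[2] < 1,
            r2_range[1] <= r2_range[2])
  structure(list(l = as.integer(l), theta = theta,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 n_exp = n_exp, n_out = n_out,
                 case_fraction = case_fraction, eaf_range = eaf_range,
                 r2_range = r2_range,
                 scramble_alleles = isTRUE(scramble_alleles),
                 seed = as.integer(seed)),
            class = "mr_scenario")
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates exposure and outcome association tables under the scenario's
#' linear causal model. Per SNP j: allele frequency
#' `p_j ~ U(eaf_range)`; true exposure effect `gamma_j > 0` (the effect
#' allele is defined as the exposure-increasing one) with
#' `gamma_j = sqrt(r2_j / (2 p_j (1 - p_j)))`, `r2_j ~ U(r2_range)`;
#' exposure sampling SE `1 / sqrt(2 p_j (1 - p_j) n_exp)` for a unit-SD
#' trait; true outcome effect `theta * gamma_j + alpha_j` with sampling SE
#' `1 / sqrt(2 p_j (1 - p_j) n_out K (1 - K))`, the binary-trait (log-odds)
#' scaling; observed betas drawn normally around the true ones. Allele
#' pairs are drawn from the non-palindromic combinations so that
#' harmonization is always resolvable from the labels. With
#' `scramble_alleles` the outcome records are re-coded at random (allele
#' swap and/or strand flip), leaving their information content unchanged.
#'
#' @param scenario an [mr_scenario()].
#' @return list with `exposure` and `outcome` ([association_table()]s) and
#'   `truth` (list: `theta`, per-SNP `gamma`, `alpha`, `eaf`, `r2`, and the
#'   scramble flags `swapped`, `strand_flipped`).
#' @examples
#' sim <- simulate_two_sample(mr_scenario(l = 20, theta = 0.1, seed = 42))
#' h <- harmonize(sim$exposure, sim$outcome)
#' mr_ivw(h, "fixed")
#' @export
simulate_two_sample <- function(scenario) {
  if (!inherits(scenario, "mr_scenario"))
    stop("'scenario' must come from mr_scenario()", call. = FALSE)
  sc <- scenario
  .with_seed(sc$seed, {
    l <- sc$l
    eaf <- stats::runif(l, sc$eaf_range[1], sc$eaf_range[2])
    r2 <- stats::runif(l, sc$r2_range[1], sc$r2_range[2])
    het <- 2 * eaf * (1 - eaf)
    gamma <- sqrt(r2 / het)
    se_exp <- 1 / sqrt(het * sc$n_exp)
    beta_exp <- stats::rnorm(l, gamma, se_exp)
    alpha <- stats::rnorm(l, sc$pleiotropy_mean, sc$pleiotropy_sd)
    K <- sc$case_fraction
    se_out <- 1 / sqrt(het * sc$n_out * K * (1 - K))
    beta_out <- stats::rnorm(l, sc$theta * gamma + alpha, se_out)

    ## non-palindromic allele pairs only, so labels always resolve strand
    pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                   c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
    pick <- sample.int(nrow(pairs), l, replace = TRUE)
    ea <- pairs[pick, 1]; nea <- pairs[pick, 2]
    rsid <- sprintf("snp%04d", seq_len(l))
    chr_pos <- sprintf("%d:%d", 1 + (seq_len(l) - 1) %% 22,
                       1e6 + 1000 * seq_len(l))
    pclamp <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)),
                                  .Machine$double.xmin)
    exposure <- association_table(data.frame(
      rsid = rsid, chr_pos = chr_pos, ea = ea, nea = nea, eaf = eaf,
      beta = beta_exp, se = se_exp, pval = pclamp(beta_exp, se_exp),
      n = sc$n_exp, stringsAsFactors = FALSE),
      study_label = "synthetic-exposure", trait = "synthetic exposure")

    ea_o <- ea; nea_o <- nea; eaf_o <- eaf; beta_o <- beta_out
    swapped <- rep(FALSE, l); strand <- rep(FALSE, l)
    if (sc$scramble_alleles) {
      swapped <- stats::runif(l) < 0.5
      strand <- stats::runif(l) < 0.5
      tmp <- ea_o[swapped]
      ea_o[swapped] <- nea_o[swapped]
      nea_o[swapped] <- tmp
      beta_o[swapped] <- -beta_o[swapped]
      eaf_o[swapped] <- 1 - eaf_o[swapped]
      ea_o[strand] <- .complement(ea_o[strand])
      nea_o[strand] <- .complement(nea_o[strand])
    }
    outcome <- association_table(data.frame(
      rsid = rsid, chr_pos = chr_pos, ea = ea_o, nea = nea_o, eaf = eaf_o,
      beta = beta_o, se = se_out, pval = pclamp(beta_o, se_out),
      n = sc$n_out, stringsAsFactors = FALSE),
      study_label = "synthetic-outcome", trait = "synthetic outcome")

    list(exposure = exposure, outcome = outcome,
         truth = list(theta = sc$theta, gamma = gamma, alpha = alpha,
                      eaf = eaf, r2 = r2, swapped = swapped,
                      strand_flipped = strand))
  })
}
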