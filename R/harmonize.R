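## Allele harmonization between exposure and outcome studies.

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, nea) .complement(ea) == nea

#' Harmonize outcome effects to the exposure effect allele
#'
#' Two GWAS rarely report the same variant on the same allele: the outcome
#' study may code the effect on the other allele, or on the opposite strand.
#' Harmonization rewrites each outcome record so that both betas refer to a
#' single common effect allele — the exposure study's — flipping the sign of
#' the outcome beta and complementing its allele frequency where the codings
#' differ.
#'
#' Per shared SNP the rules are: (a) alleles match directly — keep as is;
#' (b) outcome alleles are swapped relative to the exposure — negate the
#' outcome beta, complement its EAF, set `flipped`; (c) alleles match only
#' after strand complementation (A<->T, C<->G) — complement, then apply
#' (a)/(b); (d) palindromic pairs (A/T or C/G), where allele labels cannot
#' distinguish a strand flip from an allele swap — the orientation is
#' inferred from allele-frequency agreement, provided both studies' EAFs lie
#' farther than `palindromic_maf_limit` from 0.5; otherwise the SNP is
#' dropped with a reason. SNPs absent from either table, with irreconcilable
#' alleles, or with a zero exposure beta (no Wald ratio exists) are likewise
#' dropped with a reason rather than raising an error.
#'
#' After alignment the two studies' frequencies of the common effect allele
#' should roughly agree; a discrepancy beyond `eaf_tolerance` raises a
#' warning and sets the `eaf_discordant` flag (the record is kept — the
#' threshold is a tripwire for mismatched builds or mislabeled alleles, not
#' a hard filter).
#'
#' @param exposure,outcome [association_table()]s sharing at least one rsid.
#' @param eaf_tolerance maximum tolerated |EAF difference| between studies
#'   after alignment before a record is flagged (default 0.2).
#' @param palindromic_maf_limit minimum distance of both EAFs from 0.5
#'   required to orient a palindromic SNP by frequency (default 0.08, i.e.
#'   EAF outside \[0.42, 0.58\]).
#' @return data.frame of class `"mr_harmonized"`, one row per retained SNP
#'   in exposure order, with columns `rsid`, `ea`, `nea` (the common
#'   coding), `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`,
#'   `eaf_out`, `ratio` (Wald ratio `beta_out/beta_exp`), `ratio_se`
#'   (first-order `se_out/|beta_exp|`), and flags `flipped`, `palindromic`,
#'   `eaf_discordant`. Dropped SNPs and their reasons are in
#'   `attr(, "dropped")`.
#' @examples
#' tabs <- mr_example_tables()
#' h <- harmonize(tabs$exposure, tabs$outcome)
#' h[h$flipped, "rsid"]
#' @export
harmonize <- function(exposure, outcome, eaf_tolerance = 0.2,
                      palindromic_maf_limit = 0.08) {
  if (!is.data.frame(exposure) || !is.data.frame(outcome))
    stop("'exposure' and 'outcome' must be association tables", call. = FALSE)
  .check_scalar(eaf_tolerance, "eaf_tolerance", 0, 1)
  .check_scalar(palindromic_maf_limit, "palindromic_maf_limit", 0, 0.5,
                open_upper = TRUE)
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L)
    stop("no shared rsids between exposure and outcome tables", call. = FALSE)

  dropped <- data.frame(rsid = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- function(rsid, reason)
    rbind(dropped, data.frame(rsid = rsid, reason = reason,
                              stringsAsFactors = FALSE))
  for (r in setdiff(exposure$rsid, outcome$rsid))
    dropped <- drop(r, "missing_in_outcome")
  for (r in setdiff(outcome$rsid, exposure$rsid))
    dropped <- drop(r, "missing_in_exposure")

  rows <- vector("list", length(shared))
  keep <- logical(length(shared))
  ## preserve exposure row order
  shared <- exposure$rsid[exposure$rsid %in% shared]
  for (i in seq_along(shared)) {
    r <- shared[i]
    e <- exposure[exposure$rsid == r, ]
    o <- outcome[outcome$rsid == r, ]
    pal <- .is_palindromic(e$ea, e$nea)

    beta_out <- o$beta
    eaf_out <- o$eaf
    flipped <- FALSE
    if (pal) {
      ## allele labels are uninformative; orient by allele frequency
      if (!.is_palindromic(o$ea, o$nea) ||
          !all(c(o$ea, o$nea) %in% c(e$ea, e$nea, .complement(e$ea)))) {
        dropped <- drop(r, "allele_mismatch"); next
      }
      if (is.na(e$eaf) || is.na(o$eaf)) {
        dropped <- drop(r, "palindromic_missing_eaf"); next
      }
      if (abs(e$eaf - 0.5) <= palindromic_maf_limit ||
          abs(o$eaf - 0.5) <= palindromic_maf_limit) {
        dropped <- drop(r, "palindromic_ambiguous_eaf"); next
      }
      if (sign(e$eaf - 0.5) != sign(o$eaf - 0.5)) {
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
        flipped <- TRUE
      }
    } else {
      direct <- (o$ea == e$ea && o$nea == e$nea) ||
        (.complement(o$ea) == e$ea && .complement(o$nea) == e$nea)
      swapped <- (o$ea == e$nea && o$nea == e$ea) ||
        (.complement(o$ea) == e$nea && .complement(o$nea) == e$ea)
      if (direct) {
        ## keep as is
      } else if (swapped) {
        beta_out <- -beta_out
        eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
        flipped <- TRUE
      } else {
        dropped <- drop(r, "allele_mismatch"); next
      }
    }
    if (e$beta == 0) {
      dropped <- drop(r, "zero_exposure_beta"); next
    }
    discordant <- !is.na(e$eaf) && !is.na(eaf_out) &&
      abs(e$eaf - eaf_out) > eaf_tolerance
    rows[[i]] <- data.frame(
      rsid = r, ea = e$ea, nea = e$nea,
      beta_exp = e$beta, se_exp = e$se,
      beta_out = beta_out, se_out = o$se,
      eaf_exp = e$eaf, eaf_out = eaf_out,
      ratio = beta_out / e$beta,
      ratio_se = o$se / abs(e$beta),
      flipped = flipped, palindromic = pal, eaf_discordant = discordant,
      stringsAsFactors = FALSE
    )
    keep[i] <- TRUE
  }
  if (!any(keep))
    stop("harmonization dropped every shared SNP", call. = FALSE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  if (any(out$eaf_discordant))
    warning("effect-allele frequency discordance beyond eaf_tolerance for ",
            paste(out$rsid[out$eaf_discordant], collapse = ", "),
            call. = FALSE)
  attr(out, "dropped") <- dropped
  class(out) <- c("mr_harmonized", "data.frame")
  out
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %d SNP(s), %d flipped, %d palindromic\n",
              nrow(x), sum(x$flipped), sum(x$palindromic)))
  print.data.frame(x, digits = 4, ...)
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && nrow(dropped))
    cat("Dropped:", paste(sprintf("%s (%s)", dropped$rsid, dropped$reason),
                          collapse = "; "), "\n")
  invisible(x)
}

## internal: coerce + sanity-check a harmonized set inside estimators
.as_hset <- function(set, min_snps = 1L, caller = "estimator") {
  if (!is.data.frame(set) ||
      !all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(set)))
    stop("expected a harmonized instrument set (see harmonize())",
         call. = FALSE)
  if (nrow(set) < min_snps)
    stop(sprintf("%s requires at least %d instrument(s), got %d%s", caller,
                 min_snps, nrow(set),
                 if (min_snps >= 2 && nrow(set) == 1L)
                   "; use mr_wald_ratio() for a single SNP" else ""),
         call. = FALSE)
  if (any(set$beta_exp == 0))
    stop("zero exposure beta in harmonized set", call. = FALSE)
  if (any(set$se_out <= 0) || any(set$se_exp <= 0, na.rm = TRUE))
    stop("non-positive standard error in harmonized set", call. = FALSE)
  set
}
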