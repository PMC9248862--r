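#' Build a validated per-SNP association table
#'
#' An association table holds one GWAS's per-SNP summary statistics: one row
#' per variant with its alleles, effect-allele frequency, additive effect
#' estimate, standard error, p-value and sample size. Exposure effects are on
#' the scale of the exposure trait (here, natural-log 25-hydroxyvitamin D per
#' allele); binary-outcome effects are log-odds per allele.
#'
#' Validation enforces: unique non-empty rsIDs; alleles in A/C/G/T with
#' effect allele distinct from the other allele; `se > 0`; `eaf` in \[0, 1\]
#' (missing allowed, flagged downstream where it is actually needed);
#' p-values in (0, 1]. P-values that underflowed double precision on input
#' (printed values such as 1e-343) are clamped to the smallest positive
#' double. When both `pval` and `beta`/`se` are available the reported
#' p-value is loosely cross-checked against the two-sided normal p-value
#' implied by `beta/se`; gross disagreement raises a warning, not an error,
#' since published tables are rounded.
#'
#' @param df data.frame with columns `rsid`, `ea`, `nea`, `beta`, `se`
#'   (mandatory) and optionally `chr_pos` (1-based "chrom:pos", informational
#'   only), `eaf`, `pval`, `n`.
#' @param study_label,trait short strings identifying the study and trait.
#' @return data.frame of class `"mr_assoc"` with standardized columns and
#'   attributes `study_label` and `trait`.
#' @seealso [read_summary_table()], [mr_example_tables()]
#' @export
association_table <- function(df, study_label = "study", trait = "trait") {
  if (!is.data.frame(df)) stop("'df' must be a data.frame", call. = FALSE)
  if (nrow(df) == 0L) stop("association table is empty", call. = FALSE)
  mandatory <- c("rsid", "ea", "nea", "beta", "se")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  optional <- c("chr_pos", "eaf", "pval", "n")
  for (col in setdiff(optional, names(df))) df[[col]] <- NA
  out <- data.frame(
    rsid = as.character(df$rsid),
    chr_pos = as.character(df$chr_pos),
    ea = toupper(as.character(df$ea)),
    nea = toupper(as.character(df$nea)),
    eaf = as.numeric(df$eaf),
    beta = as.numeric(df$beta),
    se = as.numeric(df$se),
    pval = as.numeric(df$pval),
    n = as.numeric(df$n),
    stringsAsFactors = FALSE
  )
  ## printed p-values such as 1e-343 underflow double precision on read
  underflow <- !is.na(out$pval) & out$pval == 0
  out$pval[underflow] <- .Machine$double.xmin

  .validate_assoc(out)
  attr(out, "study_label") <- study_label
  attr(out, "trait") <- trait
  class(out) <- c("mr_assoc", "data.frame")
  out
}

.validate_assoc <- function(x) {
  bad_rsid <- is.na(x$rsid) | !nzchar(x$rsid)
  if (any(bad_rsid)) stop("missing rsid in row(s) ",
                          paste(which(bad_rsid), collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$rsid))
    stop("duplicated rsid(s): ",
         paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "),
         call. = FALSE)
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad <- !ok_allele(x$ea) | !ok_allele(x$nea) | x$ea == x$nea
  if (any(bad))
    stop("invalid allele coding for ", paste(x$rsid[bad], collapse = ", "),
         " (alleles must be A/C/G/T and effect allele != other allele)",
         call. = FALSE)
  bad_se <- is.na(x$se) | x$se <= 0
  if (any(bad_se))
    stop("non-positive or missing standard error for ",
         paste(x$rsid[bad_se], collapse = ", "), call. = FALSE)
  if (any(is.na(x$beta)))
    stop("missing beta for ", paste(x$rsid[is.na(x$beta)], collapse = ", "),
         call. = FALSE)
  bad_eaf <- !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)
  if (any(bad_eaf))
    stop("effect-allele frequency outside [0,1] for ",
         paste(x$rsid[bad_eaf], collapse = ", "), call. = FALSE)
  bad_p <- !is.na(x$pval) & (x$pval <= 0 | x$pval > 1)
  if (any(bad_p))
    stop("p-value outside (0,1] for ",
         paste(x$rsid[bad_p], collapse = ", "), call. = FALSE)
  ## loose self-consistency check: reported p vs normal p implied by beta/se.
  ## Only moderate p-values are checked: tiny published p's often come from
  ## multi-stage meta-analyses whose z differs from the printed beta/se.
  implied <- 2 * stats::pnorm(-abs(x$beta / x$se))
  chk <- !is.na(x$pval) & x$pval > 1e-10 & implied > 1e-250
  off <- chk & abs(log10(implied) - log10(x$pval)) > 1
  if (any(off))
    warning("reported p-value inconsistent with beta/se for ",
            paste(x$rsid[off], collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Read a GWAS summary-statistic table from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row into a validated
#' association table. Column names are configurable because summary-statistic
#' formats vary widely across consortia: `column_map` maps the standard names
#' (`rsid`, `chr_pos`, `ea`, `nea`, `eaf`, `beta`, `se`, `pval`, `n`) to the
#' names actually present in the file.
#'
#' @param path path to a `.tsv`/`.csv` file with a header row.
#' @param column_map optional named character vector, e.g.
#'   `c(rsid = "SNP", ea = "effect_allele")`; standard names not listed are
#'   assumed to appear verbatim in the file.
#' @inheritParams association_table
#' @return an [association_table()].
#' @examples
#' path <- system.file("extdata", "vitd_exposure.tsv", package = "mr2s")
#' exposure <- read_summary_table(path, trait = "log 25(OH)D")
#' head(exposure)
#' @export
read_summary_table <- function(path, column_map = NULL,
                               study_label = basename(path), trait = "trait") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file is empty: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = FALSE)
  if (nrow(df) == 0L)
    stop("no data rows in ", path, " (header only)", call. = FALSE)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(!nzchar(names(column_map))))
      stop("'column_map' must be a named character vector", call. = FALSE)
    absent <- setdiff(unname(column_map), names(df))
    if (length(absent))
      stop("column_map refers to absent column(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    for (std in names(column_map)) df[[std]] <- df[[column_map[[std]]]]
  }
  mandatory <- c("rsid", "ea", "nea", "beta", "se")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  association_table(df, study_label = study_label, trait = trait)
}

#' The packaged vitamin D / atrial fibrillation instrument table
#'
#' Loads the six-SNP instrument set relating circulating 25-hydroxyvitamin D
#' (exposure; SUNLIGHT consortium meta-GWAS, N = 79,366, effects per unit
#' natural-log 25(OH)D) to atrial fibrillation (outcome; Nielsen et al.
#' meta-GWAS, N = 1,030,836 with 60,620 cases, effects in log-odds). The
#' outcome records carry each contributing study's own allele coding — two
#' variants are coded on the opposite allele — so [harmonize()] is a real,
#' testable step of the worked example rather than a no-op.
#'
#' @return list with elements `exposure` and `outcome`, both
#'   [association_table()]s, plus `n_exposure`, `n_outcome`, `n_cases`.
#' @examples
#' tabs <- mr_example_tables()
#' h <- harmonize(tabs$exposure, tabs$outcome)
#' mr_fit(h, seed = 1)
#' @export
mr_example_tables <- function() {
  exp_path <- system.file("extdata", "vitd_exposure.tsv", package = "mr2s")
  out_path <- system.file("extdata", "af_outcome.tsv", package = "mr2s")
  list(
    exposure = read_summary_table(exp_path, study_label = "SUNLIGHT",
                                  trait = "log 25(OH)D"),
    outcome = read_summary_table(out_path, study_label = "Nielsen-AF",
                                 trait = "atrial fibrillation"),
    n_exposure = 79366,
    n_outcome = 1030836,
    n_cases = 60620
  )
}

#' Write and re-read a fitted MR result table
#'
#' `write_mr_results()` serializes the estimate table of an [mr_fit()] object
#' (one row per method: point estimate, SE, 95% CI on both log-odds and
#' odds-ratio scales, p-value, SNP count, degrees of freedom) as
#' tab-delimited text. Heterogeneity diagnostics attached to the fit are
#' written as `#`-prefixed comment lines so the file remains a single
#' machine-readable table. `read_mr_results()` reads the table back; values
#' round-trip at full double precision.
#'
#' @param fit an [mr_fit()] object, or a data.frame shaped like its
#'   `estimates` element.
#' @param path output file path.
#' @return `write_mr_results()` returns `path` invisibly;
#'   `read_mr_results()` returns the estimates data.frame.
#' @export
write_mr_results <- function(fit, path) {
  est <- if (inherits(fit, "mr_fit")) fit$estimates else fit
  if (!is.data.frame(est) || nrow(est) == 0L)
    stop("no estimates to write", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (inherits(fit, "mr_fit") && !is.null(fit$heterogeneity)) {
    q <- fit$heterogeneity
    writeLines(sprintf("# cochran_q\t%.15g\tdf\t%d\tp\t%.15g",
                       q$q, q$df, q$p), con)
  }
  utils::write.table(format(est, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mr_results
#' @export
read_mr_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @export
print.mr_assoc <- function(x, ...) {
  trait <- attr(x, "trait"); study <- attr(x, "study_label")
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNP(s)\n",
              if (is.null(trait)) "trait" else trait,
              if (is.null(study)) "study" else study, nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
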