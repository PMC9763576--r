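#' Read a table of SNP summary associations
#'
#' Reads tab- or comma-delimited GWAS summary statistics (one row per SNP)
#' into a validated `snp_assoc` data frame. Required columns are the rsid,
#' the effect allele, the per-allele effect (`beta`) and its standard error
#' (`se`); chromosome, other allele, effect-allele frequency and p-value are
#' optional and kept as `NA` when absent.
#'
#' @param path Path to a delimited text file with a header row. Files whose
#'   header contains a tab are read as TSV, otherwise as CSV.
#' @param column_map Named character vector mapping the canonical field names
#'   (`rsid`, `chrom`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`) to the column names used in the file. Fields not mentioned are
#'   looked up under their canonical name.
#' @return A data frame of class `snp_assoc` with the canonical columns, rows
#'   in file order.
#' @examples
#' path <- system.file("extdata", "hcy_exposure.tsv", package = "hcymr")
#' exposure <- read_summary_table(path)
#' head(exposure)
#' @export
read_summary_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  fields <- c("rsid", "chrom", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pvalue")
  required <- c("rsid", "effect_allele", "beta", "se")
  resolve <- function(field) {
    nm <- if (!is.null(column_map) && field %in% names(column_map))
      column_map[[field]] else field
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  for (field in required) {
    if (is.null(resolve(field))) {
      stop("required column '", field, "' not found in ", path,
           " (supply a column_map entry if it is named differently)",
           call. = FALSE)
    }
  }
  parse_num <- function(field) {
    x <- resolve(field)
    if (is.null(x)) return(rep(NA_real_, nrow(raw)))
    x[x == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", field, "' at data row ",
           bad[1], " of ", path, call. = FALSE)
    }
    val
  }
  parse_chr <- function(field) {
    x <- resolve(field)
    if (is.null(x)) return(rep(NA_character_, nrow(raw)))
    x[x == ""] <- NA_character_
    x
  }
  out <- data.frame(
    rsid = parse_chr("rsid"),
    chrom = parse_chr("chrom"),
    effect_allele = toupper(parse_chr("effect_allele")),
    other_allele = toupper(parse_chr("other_allele")),
    eaf = parse_num("eaf"),
    beta = parse_num("beta"),
    se = parse_num("se"),
    pvalue = parse_num("pvalue"),
    stringsAsFactors = FALSE
  )
  snp_assoc(out)
}

#' Construct and validate a `snp_assoc` table
#'
#' @param df Data frame with at least `rsid`, `effect_allele`, `beta`, `se`;
#'   optional `chrom`, `other_allele`, `eaf`, `pvalue` are filled with `NA`.
#' @return `df` with canonical columns, classed `snp_assoc`.
#' @export
snp_assoc <- function(df) {
  stopifnot(is.data.frame(df))
  for (field in c("chrom", "other_allele")) {
    if (is.null(df[[field]])) df[[field]] <- NA_character_
  }
  for (field in c("eaf", "pvalue")) {
    if (is.null(df[[field]])) df[[field]] <- NA_real_
  }
  df <- df[, c("rsid", "chrom", "effect_allele", "other_allele",
               "eaf", "beta", "se", "pvalue")]
  if (any(is.na(df$rsid) | df$rsid == "")) {
    stop("empty rsid in summary table", call. = FALSE)
  }
  if (anyDuplicated(df$rsid)) {
    stop("duplicate rsids in summary table: ",
         paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "),
         call. = FALSE)
  }
  bad_se <- !is.na(df$beta) & (is.na(df$se) | df$se <= 0)
  if (any(bad_se)) {
    stop("non-positive or missing standard error for: ",
         paste(df$rsid[bad_se], collapse = ", "), call. = FALSE)
  }
  bad_eaf <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  if (any(bad_eaf)) {
    stop("effect-allele frequency outside [0,1] for: ",
         paste(df$rsid[bad_eaf], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("snp_assoc", "data.frame")
  df
}

#' Write a `snp_assoc` table to TSV
#'
#' @param assocs `snp_assoc` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(assocs, path) {
  utils::write.table(assocs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  !is.na(ea) & !is.na(oa) &
    ((ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
     (ea == "C" & oa == "G") | (ea == "G" & oa == "C"))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure's effect allele, SNP by SNP.
#' Where the outcome reports the opposite allele, the outcome beta is negated
#' and the frequency complemented; the flip is recorded. SNPs absent from the
#' outcome, or with allele pairs that are neither identical nor swapped, are
#' dropped with a warning. Palindromic SNPs (A/T or C/G pairs) cannot be
#' strand-checked from summary data alone and are handled per `policy`.
#'
#' @param exposure,outcome `snp_assoc` tables; the exposure defines the
#'   instrument set and the output ordering.
#' @param policy Palindromic-SNP handling: `"keep_flag"` keeps them and
#'   records a flag (default, appropriate when both studies are known to
#'   report the forward strand), `"drop"` removes them, `"keep"` keeps them
#'   silently.
#' @param exposure_label,outcome_label Trait labels carried into results.
#' @return A `harmonized_dataset`: parallel vectors of exposure and outcome
#'   effects and standard errors over the common SNPs, plus a `flip_log`
#'   data frame and the rsids dropped.
#' @export
harmonize <- function(exposure, outcome,
                      policy = c("keep_flag", "drop", "keep"),
                      exposure_label = "exposure",
                      outcome_label = "outcome") {
  policy <- match.arg(policy)
  stopifnot(inherits(exposure, "snp_assoc"), inherits(outcome, "snp_assoc"))
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    stop("exposure and outcome tables must be nonempty", call. = FALSE)
  }
  common <- intersect(exposure$rsid, outcome$rsid)
  if (length(common) == 0) {
    stop("no overlapping rsids between exposure and outcome", call. = FALSE)
  }
  n_missing <- sum(!(exposure$rsid %in% common))
  exp_df <- exposure[exposure$rsid %in% common, ]
  out_df <- outcome[match(exp_df$rsid, outcome$rsid), ]

  keep <- logical(nrow(exp_df))
  flipped <- logical(nrow(exp_df))
  flagged <- logical(nrow(exp_df))
  by <- out_df$beta
  for (j in seq_len(nrow(exp_df))) {
    ea_x <- exp_df$effect_allele[j]; oa_x <- exp_df$other_allele[j]
    ea_y <- out_df$effect_allele[j]; oa_y <- out_df$other_allele[j]
    same <- identical(ea_y, ea_x) &&
      (is.na(oa_x) || is.na(oa_y) || identical(oa_y, oa_x))
    swapped <- (!is.na(oa_x) && identical(ea_y, oa_x) &&
                  (is.na(oa_y) || identical(oa_y, ea_x))) ||
      (!is.na(oa_y) && identical(oa_y, ea_x) && !identical(ea_y, ea_x) &&
         is.na(oa_x))
    if (same) {
      keep[j] <- TRUE
    } else if (swapped) {
      keep[j] <- TRUE
      flipped[j] <- TRUE
      by[j] <- -by[j]
    }
    if (keep[j] && is_palindromic(ea_x, oa_x)) {
      if (policy == "drop") keep[j] <- FALSE else flagged[j] <- policy == "keep_flag"
    }
  }
  n_mismatch <- sum(!keep & !is_palindromic(exp_df$effect_allele,
                                            exp_df$other_allele))
  if (any(!keep)) {
    warning(sum(!keep), " SNP(s) dropped during harmonization: ",
            paste(exp_df$rsid[!keep], collapse = ", "), call. = FALSE)
  }
  if (!any(keep)) {
    stop("all overlapping SNPs dropped during harmonization", call. = FALSE)
  }
  flip_log <- data.frame(
    rsid = exp_df$rsid[keep & (flipped | flagged)],
    action = ifelse(flipped[keep & (flipped | flagged)],
                    "allele_flip", "palindromic_flag"),
    stringsAsFactors = FALSE
  )
  harmonized_dataset(
    snps = exp_df$rsid[keep],
    beta_exposure = exp_df$beta[keep],
    se_exposure = exp_df$se[keep],
    beta_outcome = by[keep],
    se_outcome = out_df$se[keep],
    exposure_label = exposure_label,
    outcome_label = outcome_label,
    flip_log = flip_log,
    n_dropped_missing = n_missing,
    n_dropped_mismatch = n_mismatch
  )
}

#' Construct a harmonized two-sample dataset
#'
#' The unit every estimator consumes: per-SNP exposure and outcome effects on
#' a shared effect allele, with strictly positive standard errors.
#'
#' @param snps Character vector of unique rsids.
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric vectors,
#'   same length as `snps`; standard errors must be positive.
#' @param exposure_label,outcome_label Trait labels.
#' @param flip_log Data frame recording harmonization flips/flags.
#' @param n_dropped_missing,n_dropped_mismatch Bookkeeping counts.
#' @return An object of class `harmonized_dataset`.
#' @export
harmonized_dataset <- function(snps, beta_exposure, se_exposure,
                               beta_outcome, se_outcome,
                               exposure_label = "exposure",
                               outcome_label = "outcome",
                               flip_log = data.frame(rsid = character(),
                                                     action = character()),
                               n_dropped_missing = 0L,
                               n_dropped_mismatch = 0L) {
  J <- length(snps)
  if (J < 1) stop("harmonized dataset must contain at least one SNP",
                  call. = FALSE)
  vecs <- list(beta_exposure = beta_exposure, se_exposure = se_exposure,
               beta_outcome = beta_outcome, se_outcome = se_outcome)
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) != J || any(!is.finite(v))) {
      stop(nm, " must be finite and of length ", J, call. = FALSE)
    }
  }
  if (any(se_exposure <= 0) || any(se_outcome <= 0)) {
    stop("standard errors must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(snps)) stop("duplicate snps", call. = FALSE)
  structure(
    list(snps = as.character(snps),
         beta_exposure = as.numeric(beta_exposure),
         se_exposure = as.numeric(se_exposure),
         beta_outcome = as.numeric(beta_outcome),
         se_outcome = as.numeric(se_outcome),
         exposure_label = exposure_label,
         outcome_label = outcome_label,
         flip_log = flip_log,
         n_dropped_missing = as.integer(n_dropped_missing),
         n_dropped_mismatch = as.integer(n_dropped_mismatch)),
    class = "harmonized_dataset"
  )
}

#' @export
print.harmonized_dataset <- function(x, ...) {
  cat("Harmonized two-sample dataset: ", x$exposure_label, " -> ",
      x$outcome_label, "\n", sep = "")
  cat("  SNPs: ", length(x$snps), "; flips/flags: ", nrow(x$flip_log),
      "; dropped (missing/mismatch): ", x$n_dropped_missing, "/",
      x$n_dropped_mismatch, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.harmonized_dataset <- function(x, ...) {
  data.frame(rsid = x$snps,
             beta_exposure = x$beta_exposure,
             se_exposure = x$se_exposure,
             beta_outcome = x$beta_outcome,
             se_outcome = x$se_outcome,
             stringsAsFactors = FALSE)
}

#' Write a harmonized dataset to TSV
#' @param ds `harmonized_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(ds, path) {
  utils::write.table(as.data.frame(ds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subset a harmonized dataset by rsid
#' @param ds `harmonized_dataset`.
#' @param rsids Character vector of rsids to keep (order of `ds` preserved).
#' @return A `harmonized_dataset` restricted to `rsids`.
#' @export
subset_snps <- function(ds, rsids) {
  keep <- ds$snps %in% rsids
  if (!any(keep)) stop("no SNPs left after subsetting", call. = FALSE)
  harmonized_dataset(ds$snps[keep], ds$beta_exposure[keep],
                     ds$se_exposure[keep], ds$beta_outcome[keep],
                     ds$se_outcome[keep], ds$exposure_label,
                     ds$outcome_label, ds$flip_log[ds$flip_log$rsid %in%
                                                     ds$snps[keep], ,
                                                   drop = FALSE])
}

#' Package a log-scale estimate as an effect with confidence interval
#'
#' Converts a log-odds-scale causal estimate and standard error into the
#' odds-ratio-scale reporting convention: exponentiated point estimate,
#' Wald confidence bounds `exp(estimate +/- z * se)` and a two-sided normal
#' p-value.
#'
#' @param estimate_log Causal effect on the log-odds scale per unit exposure.
#' @param se_log Standard error of `estimate_log`; must be positive.
#' @param n_snps Number of instruments behind the estimate.
#' @param method Method label (e.g. `"IVW-random"`).
#' @param alpha Two-sided confidence level complement; default `0.05` gives
#'   a 95% interval with `z = qnorm(0.975)`.
#' @return An object of class `mr_estimate`.
#' @examples
#' to_effect_with_ci(0.2337, 0.1599, 12, "IVW-fixed")
#' @export
to_effect_with_ci <- function(estimate_log, se_log, n_snps, method,
                              alpha = 0.05) {
  if (!is.finite(se_log) || se_log <= 0) {
    stop("se_log must be a positive finite number", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  p <- 2 * stats::pnorm(-abs(estimate_log / se_log))
  p <- max(p, .Machine$double.xmin)  # keep within (0, 1]
  structure(
    list(estimate_log = estimate_log,
         se_log = se_log,
         or_scale = exp(estimate_log),
         ci_low = exp(estimate_log - z * se_log),
         ci_high = exp(estimate_log + z * se_log),
         pvalue = p,
         n_snps = as.integer(n_snps),
         method = method,
         alpha = alpha),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): OR %.3f, %d%% CI %.3f-%.3f, p = %.3g\n",
              x$method, x$n_snps, x$or_scale,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$pvalue))
  invisible(x)
}
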