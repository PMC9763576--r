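# Evaluate an expression under a fixed RNG state, restoring the caller's
# stream afterwards so seeded estimators never perturb user code.
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("a finite integer seed is required", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Packaged homocysteine / liver-disease summary dataset
#'
#' The 12-instrument plasma-homocysteine association table with the three
#' FinnGen binary liver outcomes (NAFLD, NASH, cirrhosis), as shipped in
#' `inst/extdata`. Exposure effects are per-allele homocysteine effects with
#' their GWAS standard errors and p-values; outcome effects are log-odds per
#' allele. All four tables share effect alleles, so harmonization is a
#' no-flip inner join.
#'
#' @return List with elements `exposure` (a `snp_assoc` of 12 SNPs) and
#'   `outcomes`, a named list of `snp_assoc` tables (`NAFLD`, `NASH`,
#'   `Cirrhosis`).
#' @examples
#' d <- hcy_table1()
#' nrow(d$exposure)
#' @export
hcy_table1 <- function() {
  ext <- function(f) system.file("extdata", f, package = "hcymr",
                                 mustWork = TRUE)
  list(
    exposure = read_summary_table(ext("hcy_exposure.tsv")),
    outcomes = list(
      NAFLD = read_summary_table(ext("outcome_nafld.tsv")),
      NASH = read_summary_table(ext("outcome_nash.tsv")),
      Cirrhosis = read_summary_table(ext("outcome_cirrhosis.tsv"))
    )
  )
}

#' Packaged instrument-selection demonstration inputs
#'
#' An 18-candidate homocysteine instrument table together with a synthetic
#' LD r2 matrix and an exclusion list, arranged so that LD pruning at
#' r2 < 0.05 removes three correlated candidates and the exclusion list
#' removes three more, leaving the 12 instruments of [hcy_table1()]. The LD
#' values and one placeholder candidate id (`rs0cand18`) are synthetic: the
#' source GWAS reports which SNPs were pruned, not the pairwise r2 values,
#' and names only 17 of its 18 candidates.
#'
#' @return List with `candidates` (`snp_assoc`, 18 rows), `ld` (`ld_matrix`),
#'   and `info_lacking` (character vector of rsids to exclude).
#' @export
hcy_candidates <- function() {
  ext <- function(f) system.file("extdata", f, package = "hcymr",
                                 mustWork = TRUE)
  list(
    candidates = read_summary_table(ext("hcy_candidates18_synthetic.tsv")),
    ld = read_ld_matrix(ext("ld_matrix18_synthetic.tsv")),
    info_lacking = read_exclusion_list(ext("info_lacking_synthetic.txt"))
  )
}
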