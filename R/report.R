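#' Configuration for a full multi-outcome MR analysis
#'
#' @param exposure_path Path to the exposure summary-statistics table.
#' @param outcome_paths Named character vector of outcome table paths; the
#'   names are the outcome labels used throughout the report.
#' @param p_threshold Genome-wide significance cutoff applied to the
#'   exposure associations (default `5e-8`); `NULL` skips the step (e.g. for
#'   a pre-selected instrument table without p-values).
#' @param ld_matrix_path Optional LD r2 matrix path; when given, instruments
#'   are greedily pruned at `r2_threshold`.
#' @param r2_threshold LD pruning cutoff (default 0.05).
#' @param exclusion_list_path Optional path to an rsid exclusion list.
#' @param ivw_model `"random"` (default) or `"fixed"`.
#' @param n_boot Weighted-median bootstrap replicates (default 1000).
#' @param presso_n_sim PRESSO simulations (default 1000); `0` disables
#'   PRESSO.
#' @param seed Integer seed for all stochastic stages (required).
#' @param alpha Confidence level complement (default 0.05).
#' @param output_dir Directory for report files; created if needed.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(exposure_path, outcome_paths,
                            p_threshold = 5e-8,
                            ld_matrix_path = NULL, r2_threshold = 0.05,
                            exclusion_list_path = NULL,
                            ivw_model = c("random", "fixed"),
                            n_boot = 1000, presso_n_sim = 1000,
                            seed, alpha = 0.05, output_dir = ".") {
  ivw_model <- match.arg(ivw_model)
  if (length(outcome_paths) < 1) {
    stop("at least one outcome is required", call. = FALSE)
  }
  if (is.null(names(outcome_paths)) || any(!nzchar(names(outcome_paths)))) {
    stop("outcome_paths must be a named vector (labels -> paths)",
         call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required (weighted median and PRESSO are stochastic)",
         call. = FALSE)
  }
  for (p in c(exposure_path, unname(outcome_paths), ld_matrix_path,
              exclusion_list_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(
    list(exposure_path = exposure_path, outcome_paths = outcome_paths,
         p_threshold = p_threshold, ld_matrix_path = ld_matrix_path,
         r2_threshold = r2_threshold,
         exclusion_list_path = exclusion_list_path,
         ivw_model = ivw_model, n_boot = n_boot,
         presso_n_sim = presso_n_sim, seed = as.integer(seed),
         alpha = alpha, output_dir = output_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Keys match the arguments of [analysis_config()]; `outcome_paths` is a
#' mapping of outcome label to file path. Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  y$exposure_path <- fix(y$exposure_path)
  y$outcome_paths <- vapply(y$outcome_paths, fix, character(1))
  y$ld_matrix_path <- fix(y$ld_matrix_path)
  y$exclusion_list_path <- fix(y$exclusion_list_path)
  do.call(analysis_config, y)
}

#' Run the full multi-outcome MR analysis
#'
#' Reads the exposure table, applies instrument selection (significance
#' threshold, optional LD pruning, optional exclusion list), then for every
#' outcome: harmonizes, computes IVW, weighted-median and MR-Egger
#' estimates, runs MR-PRESSO, and writes per-outcome TSVs plus a combined
#' cross-outcome results table and a run log. All stochastic stages run
#' under the configured seed, so two runs with the same configuration
#' produce byte-identical files.
#'
#' @param config An `analysis_config`.
#' @return Invisibly, a list with `instruments` (the final `snp_assoc`),
#'   `per_outcome` (per-label list of harmonized dataset, estimates and
#'   PRESSO result) and `combined` (the cross-outcome results data frame).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("ivw_model: %s", config$ivw_model))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  exposure <- read_summary_table(config$exposure_path)
  note("exposure: %s (%d SNPs)", config$exposure_path, nrow(exposure))
  if (!is.null(config$p_threshold)) {
    exposure <- select_by_pvalue(exposure, config$p_threshold)
    note("after p < %g: %d SNPs", config$p_threshold, nrow(exposure))
  }
  if (!is.null(config$ld_matrix_path)) {
    ld <- read_ld_matrix(config$ld_matrix_path)
    exposure <- ld_prune(exposure, ld, config$r2_threshold)
    note("after LD pruning at r2 < %g: %d SNPs", config$r2_threshold,
         nrow(exposure))
  }
  if (!is.null(config$exclusion_list_path)) {
    excl <- read_exclusion_list(config$exclusion_list_path)
    exposure <- exclude_rsids(exposure, excl, reason = "exclusion list")
    note("after excluding %d listed rsids: %d SNPs", length(excl),
         nrow(exposure))
  }

  per_outcome <- list()
  combined <- NULL
  for (label in names(config$outcome_paths)) {
    outcome <- read_summary_table(config$outcome_paths[[label]])
    ds <- harmonize(exposure, outcome, exposure_label = "exposure",
                    outcome_label = label)
    note("%s: harmonized %d SNPs (%d flips/flags, %d dropped)", label,
         length(ds$snps), nrow(ds$flip_log),
         ds$n_dropped_missing + ds$n_dropped_mismatch)
    estimates <- list(
      mr_ivw(ds, model = config$ivw_model, alpha = config$alpha),
      mr_weighted_median(ds, n_boot = config$n_boot, seed = config$seed,
                         alpha = config$alpha),
      mr_egger(ds, alpha = config$alpha))
    presso <- NULL
    if (config$presso_n_sim > 0 && length(ds$snps) >= 4) {
      presso <- mr_presso(ds, n_sim = config$presso_n_sim,
                          seed = config$seed, model = config$ivw_model)
    }
    tab <- mr_results_table(estimates, outcome = label)
    slug <- gsub("[^A-Za-z0-9]+", "_", tolower(label))
    out <- function(f) file.path(config$output_dir, f)
    write_harmonized(ds, out(paste0(slug, "_harmonized.tsv")))
    utils::write.table(wald_ratios(ds),
                       out(paste0(slug, "_wald_ratios.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tab, out(paste0(slug, "_results.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(presso)) write_presso(presso, out(paste0(slug,
                                                          "_presso.tsv")))
    per_outcome[[label]] <- list(dataset = ds, estimates = estimates,
                                 presso = presso)
    combined <- rbind(combined, tab)
  }
  utils::write.table(combined, file.path(config$output_dir,
                                         "combined_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(list(instruments = exposure, per_outcome = per_outcome,
                 combined = combined))
}
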