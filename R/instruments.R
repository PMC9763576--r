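#' Read a square LD (r-squared) matrix
#'
#' Expects a delimited file whose first column holds rsids and whose header
#' names the same rsids, i.e. a labelled square matrix of pairwise r2 values.
#'
#' @param path TSV/CSV file path.
#' @return An `ld_matrix`: list with `rsids` and the numeric matrix `r2`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("LD matrix file not found: ", path,
                               call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  rsids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- rsids
  storage.mode(m) <- "double"
  ld_matrix(rsids, m)
}

#' Construct and validate an LD matrix
#'
#' @param rsids Character vector of variant ids.
#' @param r2 Square numeric matrix of pairwise r2 values: symmetric, unit
#'   diagonal, entries in `[0, 1]`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(rsids, r2) {
  r2 <- as.matrix(r2)
  n <- length(rsids)
  if (!all(dim(r2) == c(n, n))) {
    stop("LD matrix must be ", n, " x ", n, call. = FALSE)
  }
  if (anyDuplicated(rsids)) stop("duplicate rsids in LD matrix", call. = FALSE)
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("LD r2 entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    stop("LD matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = as.character(rsids), r2 = r2), class = "ld_matrix")
}

#' Keep associations reaching a significance threshold
#'
#' @param assocs `snp_assoc` table; every record needs a p-value.
#' @param threshold Significance level; the conventional genome-wide cutoff
#'   is `5e-8`. Records with `pvalue < threshold` are kept, input order
#'   preserved.
#' @return Filtered `snp_assoc` table.
#' @export
select_by_pvalue <- function(assocs, threshold = 5e-8) {
  stopifnot(inherits(assocs, "snp_assoc"))
  if (any(is.na(assocs$pvalue))) {
    stop("records lack p-values: ",
         paste(assocs$rsid[is.na(assocs$pvalue)], collapse = ", "),
         call. = FALSE)
  }
  out <- assocs[assocs$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(assocs)
  out
}

#' Prune correlated instruments against an LD matrix
#'
#' Greedy clumping: candidates are visited in order of ascending exposure
#' p-value (rsid lexicographic tie-break) and accepted only if their r2 with
#' every already-accepted SNP is below `r2_threshold`. The accepted set is
#' returned in the original input order, so the operation only ever removes
#' rows.
#'
#' @param assocs `snp_assoc` table with p-values.
#' @param ld `ld_matrix` covering every rsid in `assocs`.
#' @param r2_threshold Pairwise independence cutoff in `[0, 1]`; default
#'   `0.05`, a strict near-independence requirement. A threshold of 1
#'   disables pruning (r2 values never exceed 1).
#' @return Pruned `snp_assoc` table whose retained pairs all satisfy
#'   `r2 < r2_threshold`.
#' @export
ld_prune <- function(assocs, ld, r2_threshold = 0.05) {
  stopifnot(inherits(assocs, "snp_assoc"), inherits(ld, "ld_matrix"))
  stopifnot(r2_threshold >= 0, r2_threshold <= 1)
  missing <- setdiff(assocs$rsid, ld$rsids)
  if (length(missing) > 0) {
    stop("rsids absent from LD matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(assocs$pvalue))) {
    stop("LD pruning requires p-values for every record", call. = FALSE)
  }
  if (r2_threshold >= 1) return(assocs)
  visit <- order(assocs$pvalue, assocs$rsid)
  accepted <- character(0)
  for (i in visit) {
    rs <- assocs$rsid[i]
    if (length(accepted) == 0 ||
        all(ld$r2[rs, accepted] < r2_threshold)) {
      accepted <- c(accepted, rs)
    }
  }
  out <- assocs[assocs$rsid %in% accepted, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(assocs)
  out
}

#' Remove named rsids from an association table
#'
#' Used for explicit exclusions the analyst has decided on, e.g. variants
#' lacking outcome-GWAS information or flagged as confounder-associated.
#' Excluding an rsid not present in the table is a no-op with a warning.
#'
#' @param assocs `snp_assoc` table.
#' @param excluded Character vector of rsids to remove.
#' @param reason Free-text label recorded in the `exclusions` attribute.
#' @return Filtered `snp_assoc` table; attribute `exclusions` records the
#'   removed rsids and the reason.
#' @export
exclude_rsids <- function(assocs, excluded, reason = "excluded") {
  stopifnot(inherits(assocs, "snp_assoc"))
  excluded <- unique(as.character(excluded))
  absent <- setdiff(excluded, assocs$rsid)
  if (length(absent) > 0) {
    warning("rsids not present, nothing to exclude: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  removed <- intersect(excluded, assocs$rsid)
  out <- assocs[!(assocs$rsid %in% excluded), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(assocs)
  log <- rbind(attr(assocs, "exclusions"),
               if (length(removed) > 0)
                 data.frame(rsid = removed, reason = reason,
                            stringsAsFactors = FALSE))
  attr(out, "exclusions") <- log
  out
}

#' Read an rsid exclusion list
#'
#' One rsid per line; blank lines and `#` comments are ignored.
#'
#' @param path Text file path.
#' @return Character vector of rsids.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("exclusion list not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
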