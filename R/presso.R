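# Leave-one-out residual machinery shared by the PRESSO tests.
#
# For each SNP j the causal effect is re-estimated by fixed-effect IVW on the
# remaining J-1 instruments; the observed statistic is the weighted residual
# sum of squares sum_j (by_j - thetahat_{-j} * bx_j)^2 / sy_j^2. The null
# reference distribution comes from parametric simulation: outcome effects
# are redrawn around their leave-one-out predictions at the reported SEs
# (optionally redrawing exposure effects too), and the whole leave-one-out
# statistic is recomputed per simulated dataset.
presso_core <- function(ds, n_sim, seed, simulate_exposure = FALSE) {
  J <- length(ds$snps)
  if (J < 4) stop("PRESSO requires at least 4 SNPs", call. = FALSE)
  if (n_sim < 10) stop("n_sim must be at least 10", call. = FALSE)
  if (n_sim < 100) warning("n_sim below 100 gives coarse empirical p-values",
                           call. = FALSE)
  bx <- ds$beta_exposure; by <- ds$beta_outcome
  sx <- ds$se_exposure; sy <- ds$se_outcome

  loo_wres <- function(Bx, By) {
    # Bx, By: J x n matrices (or vectors); returns J x n weighted sq residuals
    Bx <- as.matrix(Bx); By <- as.matrix(By)
    n <- ncol(Bx)
    W <- Bx^2 / sy^2
    Th <- By / Bx
    SwT <- matrix(colSums(W * Th), J, n, byrow = TRUE)
    Wt <- matrix(colSums(W), J, n, byrow = TRUE)
    Thloo <- (SwT - W * Th) / (Wt - W)
    (By - Thloo * Bx)^2 / sy^2
  }

  wres_obs <- loo_wres(bx, by)[, 1]
  rss_obs <- sum(wres_obs)

  # leave-one-out predictions for the simulation means
  w <- bx^2 / sy^2; th <- by / bx
  thloo <- (sum(w * th) - w * th) / (sum(w) - w)
  mu_y <- thloo * bx

  sim <- with_seed(seed, {
    Bx <- if (simulate_exposure) {
      matrix(stats::rnorm(J * n_sim, bx, sx), nrow = J)
    } else matrix(bx, J, n_sim)
    By <- matrix(stats::rnorm(J * n_sim, mu_y, sy), nrow = J)
    loo_wres(Bx, By)
  })
  list(wres_obs = wres_obs, rss_obs = rss_obs,
       wres_sim = sim, rss_sim = colSums(sim), n_sim = n_sim, seed = seed)
}

new_presso_result <- function(ds, core, global_pvalue = NULL,
                              snp_pvalues = NULL, outliers = NULL,
                              corrected = NULL, distortion_pvalue = NULL,
                              distortion = NULL, too_few_remaining = FALSE,
                              sig_threshold = NA_real_) {
  structure(
    list(snps = ds$snps, rss_observed = core$rss_obs,
         global_pvalue = global_pvalue, snp_pvalues = snp_pvalues,
         outliers = outliers, corrected = corrected,
         distortion = distortion, distortion_pvalue = distortion_pvalue,
         too_few_remaining = too_few_remaining,
         sig_threshold = sig_threshold,
         n_sim = core$n_sim, seed = core$seed),
    class = "presso_result"
  )
}

#' PRESSO global heterogeneity test
#'
#' Tests whether the observed leave-one-out weighted residual sum of squares
#' is larger than expected under a model with no pleiotropic outliers, by
#' comparing it to its parametric-simulation distribution. The empirical
#' p-value uses the add-one correction `(count + 1) / (n_sim + 1)` and so is
#' never exactly zero.
#'
#' @param ds `harmonized_dataset` with at least 4 SNPs.
#' @param n_sim Number of simulated datasets (default 1000).
#' @param seed Integer seed (required).
#' @param simulate_exposure Also redraw exposure effects at their SEs;
#'   default `FALSE` (outcome-only simulation).
#' @return A `presso_result` with `rss_observed` and `global_pvalue` filled.
#' @export
presso_global <- function(ds, n_sim = 1000, seed, simulate_exposure = FALSE) {
  core <- presso_core(ds, n_sim, seed, simulate_exposure)
  p <- (sum(core$rss_sim >= core$rss_obs) + 1) / (n_sim + 1)
  new_presso_result(ds, core, global_pvalue = p)
}

#' PRESSO per-SNP outlier test with outlier-corrected estimate
#'
#' Each SNP's observed weighted squared leave-one-out residual is compared to
#' its own simulated null distribution; SNPs whose empirical p-value falls
#' below the Bonferroni-adjusted threshold `sig_threshold / J` are flagged as
#' pleiotropic outliers. When outliers are found and at least 3 instruments
#' remain, the causal effect is re-estimated by IVW on the remaining SNPs.
#'
#' @inheritParams presso_global
#' @param sig_threshold Familywise level for outlier flagging (default 0.05,
#'   Bonferroni-divided by the number of SNPs).
#' @param model IVW model used for the outlier-corrected estimate.
#' @return A `presso_result` with `snp_pvalues`, `outliers` and (when
#'   outliers exist and enough SNPs remain) `corrected` filled;
#'   `too_few_remaining` flags the guard case.
#' @export
presso_outlier <- function(ds, n_sim = 1000, seed, sig_threshold = 0.05,
                           simulate_exposure = FALSE,
                           model = c("random", "fixed")) {
  model <- match.arg(model)
  core <- presso_core(ds, n_sim, seed, simulate_exposure)
  J <- length(ds$snps)
  pj <- (rowSums(core$wres_sim >= core$wres_obs) + 1) / (n_sim + 1)
  names(pj) <- ds$snps
  outliers <- ds$snps[pj < sig_threshold / J]
  corrected <- NULL
  too_few <- FALSE
  if (length(outliers) > 0) {
    remaining <- setdiff(ds$snps, outliers)
    if (length(remaining) >= 3) {
      corrected <- mr_ivw(subset_snps(ds, remaining), model = model)
    } else {
      too_few <- TRUE
    }
  }
  gp <- (sum(core$rss_sim >= core$rss_obs) + 1) / (n_sim + 1)
  new_presso_result(ds, core, global_pvalue = gp, snp_pvalues = pj,
                    outliers = outliers, corrected = corrected,
                    too_few_remaining = too_few,
                    sig_threshold = sig_threshold)
}

#' PRESSO distortion test
#'
#' Quantifies how much removing a flagged outlier set shifts the IVW point
#' estimate, relative to the all-SNP estimate, and compares the shift to the
#' distribution obtained by removing random SNP sets of the same size.
#'
#' @param ds `harmonized_dataset`.
#' @param outliers Nonempty character vector of flagged rsids, a strict
#'   subset of `ds$snps` leaving at least 3 SNPs.
#' @param n_sim Number of random sets drawn (default 1000).
#' @param seed Integer seed (required).
#' @return List with `distortion` (relative shift of the point estimate),
#'   `distortion_pvalue`, and `corrected` (`mr_estimate` on the non-outliers).
#' @export
presso_distortion <- function(ds, outliers, n_sim = 1000, seed) {
  stopifnot(inherits(ds, "harmonized_dataset"))
  outliers <- as.character(outliers)
  if (length(outliers) == 0 || !all(outliers %in% ds$snps)) {
    stop("outliers must be a nonempty subset of the dataset's snps",
         call. = FALSE)
  }
  remaining <- setdiff(ds$snps, outliers)
  if (length(remaining) < 3) {
    stop("removing the outlier set must leave at least 3 SNPs",
         call. = FALSE)
  }
  point <- function(rsids) {
    keep <- ds$snps %in% rsids
    w <- ds$beta_exposure[keep]^2 / ds$se_outcome[keep]^2
    th <- ds$beta_outcome[keep] / ds$beta_exposure[keep]
    sum(w * th) / sum(w)
  }
  est_all <- point(ds$snps)
  est_corr <- point(remaining)
  d_obs <- (est_corr - est_all) / abs(est_all)
  k <- length(outliers)
  d_sim <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      drop <- sample(ds$snps, k)
      (point(setdiff(ds$snps, drop)) - est_all) / abs(est_all)
    }, numeric(1))
  })
  p <- (sum(abs(d_sim) >= abs(d_obs)) + 1) / (n_sim + 1)
  list(distortion = d_obs, distortion_pvalue = p,
       corrected = mr_ivw(subset_snps(ds, remaining)))
}

#' Full MR-PRESSO analysis
#'
#' Runs the global heterogeneity test, the per-SNP outlier test, and — when
#' outliers are flagged and enough instruments remain — the distortion test
#' with an outlier-corrected IVW estimate, all under one seed. The distortion
#' resampling uses `seed + 1` so its draws do not alias the outlier
#' simulation.
#'
#' @inheritParams presso_outlier
#' @return A complete `presso_result`.
#' @export
mr_presso <- function(ds, n_sim = 1000, seed, sig_threshold = 0.05,
                      simulate_exposure = FALSE,
                      model = c("random", "fixed")) {
  model <- match.arg(model)
  res <- presso_outlier(ds, n_sim = n_sim, seed = seed,
                        sig_threshold = sig_threshold,
                        simulate_exposure = simulate_exposure, model = model)
  if (length(res$outliers) > 0 && !res$too_few_remaining) {
    dist <- presso_distortion(ds, res$outliers, n_sim = n_sim,
                              seed = seed + 1)
    res$distortion <- dist$distortion
    res$distortion_pvalue <- dist$distortion_pvalue
  }
  res
}

#' @export
print.presso_result <- function(x, ...) {
  cat("MR-PRESSO (", length(x$snps), " SNPs, ", x$n_sim, " simulations)\n",
      sep = "")
  cat(sprintf("  global RSS %.3f, p = %.4g\n", x$rss_observed,
              x$global_pvalue))
  if (!is.null(x$outliers)) {
    if (length(x$outliers) == 0) cat("  no outliers flagged\n")
    else cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  }
  if (!is.null(x$distortion_pvalue)) {
    cat(sprintf("  distortion %.3f, p = %.4g\n", x$distortion,
                x$distortion_pvalue))
  }
  invisible(x)
}

#' Serialize a PRESSO result to TSV
#'
#' Writes a global row followed by one row per SNP (empirical outlier
#' p-values and flags) in a single long-format table.
#'
#' @param x `presso_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_presso <- function(x, path) {
  rows <- data.frame(record = "global", rsid = NA_character_,
                     statistic = x$rss_observed, pvalue = x$global_pvalue,
                     outlier = NA, stringsAsFactors = FALSE)
  if (!is.null(x$snp_pvalues)) {
    rows <- rbind(rows, data.frame(
      record = "snp", rsid = names(x$snp_pvalues),
      statistic = NA_real_, pvalue = unname(x$snp_pvalues),
      outlier = names(x$snp_pvalues) %in% x$outliers,
      stringsAsFactors = FALSE))
  }
  if (!is.null(x$distortion_pvalue)) {
    rows <- rbind(rows, data.frame(record = "distortion", rsid = NA_character_,
                                   statistic = x$distortion,
                                   pvalue = x$distortion_pvalue,
                                   outlier = NA, stringsAsFactors = FALSE))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
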