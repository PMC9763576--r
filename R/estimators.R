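#' Per-SNP Wald ratios and inverse-variance weights
#'
#' The Wald ratio for SNP j is the outcome effect divided by the exposure
#' effect, its first-order standard error is `se_outcome / |beta_exposure|`,
#' and the inverse-variance weight is `beta_exposure^2 / se_outcome^2`.
#' Exposure-side uncertainty can be folded in with `second_order = TRUE`
#' (delta-method second term), which widens the ratio SEs but leaves the
#' ratios themselves untouched.
#'
#' @param ds `harmonized_dataset`; no exposure beta may be exactly zero.
#' @param second_order Include the exposure-uncertainty term in the ratio SE.
#' @return Data frame of class `wald_ratio_set` with columns `rsid`, `ratio`,
#'   `se_ratio`, `weight`.
#' @export
wald_ratios <- function(ds, second_order = FALSE) {
  stopifnot(inherits(ds, "harmonized_dataset"))
  zero <- ds$beta_exposure == 0
  if (any(zero)) {
    stop("zero exposure beta, Wald ratio undefined for: ",
         paste(ds$snps[zero], collapse = ", "), call. = FALSE)
  }
  ratio <- ds$beta_outcome / ds$beta_exposure
  se1 <- ds$se_outcome / abs(ds$beta_exposure)
  se_ratio <- if (second_order) {
    sqrt(se1^2 + ds$beta_outcome^2 * ds$se_exposure^2 / ds$beta_exposure^4)
  } else se1
  out <- data.frame(rsid = ds$snps, ratio = ratio, se_ratio = se_ratio,
                    weight = 1 / se_ratio^2, stringsAsFactors = FALSE)
  class(out) <- c("wald_ratio_set", "data.frame")
  out
}

#' Inverse-variance weighted causal estimate
#'
#' Combines per-SNP Wald ratios by inverse-variance weighting, the standard
#' meta-analytic MR estimator; algebraically identical to weighted least
#' squares of outcome on exposure effects through the origin with weights
#' `1/se_outcome^2`. The multiplicative random-effects model (default)
#' inflates the fixed-effect standard error by `max(1, sqrt(Q/(J-1)))`, where
#' `Q` is Cochran's heterogeneity statistic, so it coincides with the
#' fixed-effect model when the instruments are homogeneous and is never
#' narrower.
#'
#' @param ds `harmonized_dataset` with `J >= 1` SNPs.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @param alpha Confidence level complement for the reported interval.
#' @return An `mr_estimate`; also carries fields `Q` (heterogeneity
#'   statistic) and `dispersion` (the SE inflation factor applied).
#' @examples
#' d <- hcy_table1()
#' ds <- harmonize(d$exposure, d$outcomes$NAFLD, outcome_label = "NAFLD")
#' mr_ivw(ds)
#' @export
mr_ivw <- function(ds, model = c("random", "fixed"), alpha = 0.05) {
  model <- match.arg(model)
  wr <- wald_ratios(ds)
  J <- nrow(wr)
  est <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  se_fixed <- 1 / sqrt(sum(wr$weight))
  Q <- sum(wr$weight * (wr$ratio - est)^2)
  dispersion <- 1
  if (model == "random") {
    if (J < 2) {
      warning("single instrument: falling back to fixed-effect IVW",
              call. = FALSE)
      model <- "fixed"
    } else {
      dispersion <- max(1, sqrt(Q / (J - 1)))
    }
  }
  res <- to_effect_with_ci(est, se_fixed * dispersion, J,
                           method = paste0("IVW-", model), alpha = alpha)
  res$Q <- Q
  res$dispersion <- dispersion
  res
}

# Midpoint-convention weighted median of ratios: order ratios ascending,
# place each at its cumulative normalized weight minus half its own weight,
# and linearly interpolate at 0.5 (clamped to the extremes).
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The 50%-cumulative-weight point of the ordered per-SNP Wald ratios, a
#' consistent estimator when at least half the total instrument weight comes
#' from valid instruments. The standard error comes from a parametric
#' bootstrap: exposure and outcome effects are resampled from normal
#' distributions centred on the observed values with the reported standard
#' errors, and the estimate recomputed per replicate.
#'
#' @param ds `harmonized_dataset` with at least 3 SNPs.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @param alpha Confidence level complement.
#' @return An `mr_estimate` (method `"weighted-median"`).
#' @export
mr_weighted_median <- function(ds, n_boot = 1000, seed, alpha = 0.05) {
  wr <- wald_ratios(ds)
  J <- nrow(wr)
  if (J < 3) stop("weighted median requires at least 3 SNPs", call. = FALSE)
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  est <- weighted_median_point(wr$ratio, wr$weight)
  boots <- with_seed(seed, {
    bx <- matrix(stats::rnorm(J * n_boot, ds$beta_exposure, ds$se_exposure),
                 nrow = J)
    by <- matrix(stats::rnorm(J * n_boot, ds$beta_outcome, ds$se_outcome),
                 nrow = J)
    vapply(seq_len(n_boot), function(i) {
      weighted_median_point(by[, i] / bx[, i], bx[, i]^2 / ds$se_outcome^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  to_effect_with_ci(est, se, J, method = "weighted-median", alpha = alpha)
}

#' MR-Egger regression with pleiotropy intercept test
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept, weights `1/se_outcome^2`, after orienting every SNP to a
#' positive exposure effect (negating both betas where needed, which leaves
#' all ratio-based quantities invariant). The slope is the pleiotropy-robust
#' causal estimate; the intercept estimates the average directional
#' pleiotropic effect per SNP, and its two-sided normal test is the standard
#' check of the exclusion-restriction assumption. Standard errors use a
#' multiplicative overdispersion factor `max(1, sqrt(RSS/(J-2)))`.
#'
#' @param ds `harmonized_dataset` with at least 3 SNPs.
#' @param alpha Confidence level complement for the slope interval.
#' @return An `egger_result`: the slope as fields of an `mr_estimate`
#'   (method `"MR-Egger"`), plus `intercept`, `se_intercept`,
#'   `intercept_pvalue` and `dispersion`.
#' @export
mr_egger <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "harmonized_dataset"))
  J <- length(ds$snps)
  if (J < 3) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  if (any(ds$beta_exposure == 0)) {
    stop("zero exposure beta; orientation undefined", call. = FALSE)
  }
  s <- sign(ds$beta_exposure)
  bx <- abs(ds$beta_exposure)
  by <- ds$beta_outcome * s
  w <- 1 / ds$se_outcome^2
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  det <- sw * swx2 - swx^2
  if (det <= .Machine$double.eps * sw * swx2) {
    stop("singular design: oriented exposure effects have no spread",
         call. = FALSE)
  }
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  intercept <- (swx2 * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  rss <- sum(w * (by - intercept - slope * bx)^2)
  dispersion <- max(1, sqrt(rss / (J - 2)))
  se_intercept <- sqrt(swx2 / det) * dispersion
  se_slope <- sqrt(sw / det) * dispersion
  res <- to_effect_with_ci(slope, se_slope, J, method = "MR-Egger",
                           alpha = alpha)
  res$intercept <- intercept
  res$se_intercept <- se_intercept
  res$intercept_pvalue <- max(2 * stats::pnorm(-abs(intercept / se_intercept)),
                              .Machine$double.xmin)
  res$dispersion <- dispersion
  class(res) <- c("egger_result", class(res))
  res
}

#' @export
print.egger_result <- function(x, ...) {
  NextMethod()
  cat(sprintf("  intercept %.4f (SE %.4f), p = %.3f\n",
              x$intercept, x$se_intercept, x$intercept_pvalue))
  invisible(x)
}

#' Flatten MR estimates into a results table
#'
#' @param estimates List of `mr_estimate` objects.
#' @param outcome Outcome label recycled across rows.
#' @return Data frame with one row per estimate: method, outcome, n_snps,
#'   log-scale estimate and SE, odds ratio, CI bounds and p-value.
#' @export
mr_results_table <- function(estimates, outcome = "outcome") {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method, outcome = outcome, n_snps = e$n_snps,
               estimate_log = e$estimate_log, se_log = e$se_log,
               or = e$or_scale, ci_low = e$ci_low, ci_high = e$ci_high,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  }))
}
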