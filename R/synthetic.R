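#' Configuration for the two-sample summary-statistics generator
#'
#' Defines a linear causal model on summary scale: true exposure effects
#' `bx_j`, per-SNP pleiotropic effects `alpha_j`, true outcome effects
#' `theta * bx_j + alpha_j`, and independently observed noisy versions of
#' each in the two (non-overlapping) GWAS samples. Defaults mimic the scale
#' of the packaged homocysteine dataset: exposure effect magnitudes around
#' 0.04-0.16, exposure SEs 0.007-0.013, outcome SEs 0.037-0.063 (the NAFLD
#' column's range).
#'
#' @param n_snps Number of instruments J (default 12).
#' @param theta True causal effect, log-odds per unit exposure (default 0).
#' @param beta_x_mean,beta_x_sd Mean and SD of the normal draw for exposure
#'   effect magnitudes (defaults 0.08 and 0.04).
#' @param beta_x_min Magnitude floor keeping instruments relevant
#'   (default 0.02); draws below it are clipped up.
#' @param sign_random Randomize exposure effect signs (default `TRUE`).
#' @param se_x_range,se_y_range Uniform ranges for exposure/outcome SEs.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero alpha) or
#'   `"directional"` (mean `pleio_mu`).
#' @param pleio_mu Mean pleiotropic effect under `"directional"`.
#' @param pleio_tau SD of pleiotropic effects under `"balanced"` or
#'   `"directional"`.
#' @param inside_rho Correlation between pleiotropic effect and instrument
#'   strength, violating the InSIDE condition when nonzero (default 0).
#' @param outlier_index Optional index of a SNP whose observed outcome effect
#'   is shifted by `outlier_shift` outcome SEs after generation.
#' @param outlier_shift Shift size in units of that SNP's outcome SE.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_snps = 12, theta = 0,
                             beta_x_mean = 0.08, beta_x_sd = 0.04,
                             beta_x_min = 0.02, sign_random = TRUE,
                             se_x_range = c(0.007, 0.013),
                             se_y_range = c(0.037, 0.063),
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional"),
                             pleio_mu = 0, pleio_tau = 0,
                             inside_rho = 0,
                             outlier_index = NULL, outlier_shift = 0,
                             seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, beta_x_min > 0, pleio_tau >= 0,
            length(se_x_range) == 2, length(se_y_range) == 2,
            all(se_x_range > 0), all(se_y_range > 0),
            abs(inside_rho) <= 1)
  if (!is.null(outlier_index)) {
    stopifnot(outlier_index >= 1, outlier_index <= n_snps)
  }
  structure(
    list(n_snps = as.integer(n_snps), theta = theta,
         beta_x_mean = beta_x_mean, beta_x_sd = beta_x_sd,
         beta_x_min = beta_x_min, sign_random = sign_random,
         se_x_range = sort(se_x_range), se_y_range = sort(se_y_range),
         pleiotropy_mode = pleiotropy_mode, pleio_mu = pleio_mu,
         pleio_tau = pleio_tau, inside_rho = inside_rho,
         outlier_index = outlier_index, outlier_shift = outlier_shift,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Read a synthetic-generator configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(synthetic_config, yaml::read_yaml(path))
}

#' Generate a synthetic harmonized two-sample dataset
#'
#' Draws true exposure effects, adds per-SNP pleiotropy per the configured
#' regime (expressed relative to the exposure-increasing allele), forms true
#' outcome effects `theta * bx + sign(bx) * alpha`, then observes
#' both with independent normal noise at the configured SEs — the two-sample
#' design's independence between exposure and outcome estimation error. Any
#' planted outlier shift is applied last, to the observed outcome effect.
#' The generative truth (true effects, pleiotropy, theta) is attached as
#' attribute `"truth"`.
#'
#' @param config A `synthetic_config`.
#' @return A `harmonized_dataset` of `config$n_snps` SNPs.
#' @examples
#' ds <- generate_dataset(synthetic_config(theta = 0.234, seed = 7))
#' mr_ivw(ds)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  J <- config$n_snps
  with_seed(config$seed, {
    mag <- pmax(config$beta_x_min,
                abs(stats::rnorm(J, config$beta_x_mean, config$beta_x_sd)))
    sgn <- if (config$sign_random) sample(c(-1, 1), J, replace = TRUE)
           else rep(1, J)
    bx_true <- sgn * mag
    se_x <- stats::runif(J, config$se_x_range[1], config$se_x_range[2])
    se_y <- stats::runif(J, config$se_y_range[1], config$se_y_range[2])
    alpha <- switch(config$pleiotropy_mode,
      none = rep(0, J),
      balanced = stats::rnorm(J, 0, config$pleio_tau),
      directional = stats::rnorm(J, config$pleio_mu, config$pleio_tau))
    if (config$inside_rho != 0 && config$pleiotropy_mode != "none" &&
        config$pleio_tau > 0) {
      # re-express alpha with the requested correlation to |bx|
      z_str <- as.numeric(scale(mag))
      eps <- stats::rnorm(J)
      mu0 <- if (config$pleiotropy_mode == "directional") config$pleio_mu else 0
      alpha <- mu0 + config$pleio_tau *
        (config$inside_rho * z_str + sqrt(1 - config$inside_rho^2) * eps)
    }
    # Pleiotropic effects act on the exposure-increasing allele, so that
    # "directional" keeps its meaning when instrument signs are randomized:
    # in the un-oriented frame the contribution is sign(bx) * alpha.
    by_true <- config$theta * bx_true + sgn * alpha
    bx_obs <- bx_true + stats::rnorm(J, 0, 1) * se_x
    by_obs <- by_true + stats::rnorm(J, 0, 1) * se_y
    if (!is.null(config$outlier_index)) {
      i <- config$outlier_index
      by_obs[i] <- by_obs[i] + config$outlier_shift * se_y[i]
    }
    ds <- harmonized_dataset(
      snps = sprintf("snp%03d", seq_len(J)),
      beta_exposure = bx_obs, se_exposure = se_x,
      beta_outcome = by_obs, se_outcome = se_y,
      exposure_label = "synthetic exposure",
      outcome_label = "synthetic outcome")
    attr(ds, "truth") <- list(theta = config$theta, beta_x_true = bx_true,
                              beta_y_true = by_true, alpha = alpha)
    ds
  })
}

#' Repeated-generation recovery experiment
#'
#' Generates `n_reps` datasets from a base configuration (varying only the
#' seed) and summarizes each requested estimator's bias, empirical spread,
#' confidence-interval coverage of the true `theta`, and rejection rate of
#' the null at the estimate's alpha.
#'
#' @param config Base `synthetic_config`; replicate r uses seed
#'   `config$seed + r`.
#' @param n_reps Number of replicates (at least 2).
#' @param estimators Subset of `"ivw_fixed"`, `"ivw_random"`,
#'   `"weighted_median"`, `"egger"`.
#' @param n_boot Bootstrap replicates for the weighted median (default 200,
#'   kept modest because it runs `n_reps` times).
#' @return Data frame with one row per estimator: `mean_bias`,
#'   `empirical_sd`, `mean_se`, `coverage`, `rejection_rate`, `n_reps`.
#' @export
recovery_experiment <- function(config, n_reps,
                                estimators = c("ivw_fixed"),
                                n_boot = 200) {
  stopifnot(inherits(config, "synthetic_config"), n_reps >= 2)
  known <- c("ivw_fixed", "ivw_random", "weighted_median", "egger")
  estimators <- match.arg(estimators, known, several.ok = TRUE)
  fit_one <- function(ds, est, seed) {
    switch(est,
      ivw_fixed = mr_ivw(ds, model = "fixed"),
      ivw_random = mr_ivw(ds, model = "random"),
      weighted_median = mr_weighted_median(ds, n_boot = n_boot, seed = seed),
      egger = mr_egger(ds))
  }
  z <- stats::qnorm(0.975)
  res <- array(NA_real_, dim = c(n_reps, length(estimators), 2),
               dimnames = list(NULL, estimators, c("est", "se")))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    ds <- generate_dataset(cfg)
    for (e in estimators) {
      fit <- fit_one(ds, e, seed = cfg$seed)
      res[r, e, "est"] <- fit$estimate_log
      res[r, e, "se"] <- fit$se_log
    }
  }
  out <- do.call(rbind, lapply(estimators, function(e) {
    est <- res[, e, "est"]; se <- res[, e, "se"]
    data.frame(
      estimator = e,
      n_reps = n_reps,
      mean_bias = mean(est) - config$theta,
      empirical_sd = stats::sd(est),
      mean_se = mean(se),
      coverage = mean(abs(est - config$theta) <= z * se),
      rejection_rate = mean(abs(est / se) > z),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
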