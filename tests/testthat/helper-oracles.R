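# Independent oracles and small dataset builders used across the suite.

# IVW should equal weighted least squares of outcome on exposure effects
# through the origin, weights 1/se_outcome^2 (point estimate only).
wls_origin_oracle <- function(ds) {
  fit <- stats::lm(ds$beta_outcome ~ 0 + ds$beta_exposure,
                   weights = 1 / ds$se_outcome^2)
  unname(stats::coef(fit)[1])
}

# Egger regression oracle: orient to positive exposure effects, then plain
# weighted lm with a free intercept.
egger_lm_oracle <- function(ds) {
  s <- sign(ds$beta_exposure)
  bx <- abs(ds$beta_exposure)
  by <- ds$beta_outcome * s
  fit <- stats::lm(by ~ bx, weights = 1 / ds$se_outcome^2)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       sigma = summary(fit)$sigma,
       se_unit = summary(fit)$coefficients[, "Std. Error"] /
         summary(fit)$sigma)
}

# Build a harmonized dataset directly from vectors (no file round trip).
make_ds <- function(bx, by, sx = rep(0.01, length(bx)),
                    sy = rep(0.05, length(bx)),
                    snps = sprintf("rs%d", seq_along(bx))) {
  harmonized_dataset(snps = snps, beta_exposure = bx, se_exposure = sx,
                     beta_outcome = by, se_outcome = sy)
}

# Build a dataset with prescribed Wald ratios and normalized IVW weights:
# unit exposure betas make ratio = beta_outcome and weight = 1/se_outcome^2.
make_ratio_ds <- function(ratios, weights) {
  make_ds(bx = rep(1, length(ratios)), by = ratios,
          sy = 1 / sqrt(weights / sum(weights)))
}

table1_nafld <- function() {
  d <- hcy_table1()
  harmonize(d$exposure, d$outcomes$NAFLD, outcome_label = "NAFLD")
}

# Write a snp_assoc-shaped data frame to a temp TSV and return the path.
write_tmp_table <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}
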