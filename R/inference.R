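#' Scale a log-odds effect and convert to an odds ratio
#'
#' Rescales a per-unit log-odds effect by a unit multiplier (e.g. 10 for a
#' 10-mm Hg blood-pressure increase when effects are per mm Hg), then
#' exponentiates to an odds ratio with a 95% normal CI.
#'
#' @param beta effect on the log-odds scale per exposure unit.
#' @param se standard error of `beta` (> 0).
#' @param unit_multiplier positive scalar applied to both `beta` and `se`
#'   before exponentiation.
#' @return data.frame with `b_scaled`, `se_scaled`, `or_`, `or_lo`, `or_hi`.
#' @examples
#' scale_and_convert(0.02, 0.005, 10)  # OR per 10-unit increase
#' @export
scale_and_convert <- function(beta, se, unit_multiplier = 1) {
  if (any(unit_multiplier <= 0)) stop("unit_multiplier must be positive")
  if (any(se <= 0)) stop("se must be positive")
  b <- beta * unit_multiplier
  s <- se * unit_multiplier
  data.frame(b_scaled = b, se_scaled = s, or_ = exp(b),
             or_lo = exp(b - Z95 * s), or_hi = exp(b + Z95 * s))
}

#' Benjamini-Hochberg FDR within method groups
#'
#' Step-up false-discovery-rate adjustment applied independently within each
#' group (one group per MR method, as multiple exposures are tested per
#' method); groups are never pooled. Delegates to
#' `stats::p.adjust(method = "BH")` per group.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param group optional grouping vector (same length); `NULL` treats all
#'   p-values as one group.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvals, group = NULL) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (is.null(group)) return(stats::p.adjust(pvals, method = "BH"))
  stopifnot(length(group) == length(pvals))
  unsplit(lapply(split(pvals, group), stats::p.adjust, method = "BH"), group)
}

#' Variance in the exposure explained by one instrument
#'
#' The standard single-variant approximation for a trait in SD units:
#' `beta^2 * 2 * MAF * (1 - MAF)`. Per-instrument values sum to the
#' instrument set's total R-squared. Frequencies above 0.5 are folded to the
#' minor allele with a warning.
#'
#' @param beta per-allele effect in SD units of the exposure.
#' @param maf minor allele frequency in \[0, 0.5\].
#' @return proportion of variance explained (vectorized).
#' @export
variance_explained <- function(beta, maf) {
  if (any(maf < 0 | maf > 1)) stop("maf must lie in [0, 1]")
  if (any(maf > 0.5)) {
    warning("allele frequency > 0.5 folded to the minor allele")
    maf <- pmin(maf, 1 - maf)
  }
  beta^2 * 2 * maf * (1 - maf)
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Standard noncentrality approximation: the IVW estimate of a log-odds
#' effect `b` has approximate standard error `1 / sqrt(N * R2 * phi * (1 -
#' phi))` with `N` the total outcome sample size, `phi` the case fraction and
#' `R2` the variance in the exposure explained by the instruments, so the
#' two-sided power at level `alpha` is
#' `pnorm(ncp - z) + pnorm(-ncp - z)` with `ncp = sqrt(N * R2 * phi *
#' (1 - phi)) * |b|` and `z` the upper `alpha/2` normal quantile.
#'
#' @param b hypothesized causal effect on the log-odds scale per exposure
#'   unit (vectorized).
#' @param n_case,n_control outcome case and control counts.
#' @param r2 instrument variance explained, in (0, 1].
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @seealso [min_detectable_effect()]
#' @export
mr_power <- function(b, n_case, n_control, r2, alpha = 0.05) {
  stopifnot(n_case > 0, n_control > 0)
  if (any(r2 <= 0)) stop("r2 must be positive")
  n <- n_case + n_control
  phi <- n_case / n
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- sqrt(n * r2 * phi * (1 - phi)) * abs(b)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Minimum detectable effect of a two-sample MR analysis
#'
#' Numerically inverts [mr_power()] for the smallest absolute log-odds effect
#' reaching `target_power`, reported as a percent change in log odds
#' (`100 * |b|`). Monotone decreasing in both `r2` and sample size. With
#' several `r2` values (one per exposure), the per-exposure curve is returned
#' and the study-level minimum detectable change is the smallest entry —
#' attained at the largest variance explained.
#'
#' @param n_case,n_control outcome case and control counts.
#' @param r2 instrument variance explained (vectorized over exposures).
#' @param alpha two-sided significance level.
#' @param target_power required power, in (0, 1).
#' @return data.frame with columns `r2`, `b_min` (log-odds scale) and
#'   `pct_change` (`100 * b_min`).
#' @examples
#' min_detectable_effect(39106, 401577, r2 = 0.19)
#' @export
min_detectable_effect <- function(n_case, n_control, r2, alpha = 0.05,
                                  target_power = 0.8) {
  stopifnot(target_power > 0, target_power < 1)
  if (any(r2 <= 0)) stop("r2 must be positive: the detectable effect is undefined at r2 = 0")
  b_min <- vapply(r2, function(r) {
    stats::uniroot(function(b) mr_power(b, n_case, n_control, r, alpha) - target_power,
                   interval = c(1e-10, 100), tol = 1e-12)$root
  }, numeric(1))
  data.frame(r2 = r2, b_min = b_min, pct_change = 100 * b_min)
}

#' Tidy results table with odds ratios and per-method FDR
#'
#' Combines per-analysis estimates into the long results format (one row per
#' exposure x outcome x method), applies per-exposure unit scaling and OR
#' conversion, and computes Benjamini-Hochberg q-values within each
#' (method, outcome) stratum across exposures.
#'
#' @param estimates data.frame with at least `exposure`, `outcome`, `method`,
#'   `nsnp`, `b`, `se`, `pval` (as produced by [as.data.frame.mr_fit()]).
#' @param scaling named vector of per-exposure unit multipliers (default 1).
#' @return the input with `or_`, `or_lo`, `or_hi` and `qval` columns added.
#' @export
results_table <- function(estimates, scaling = NULL) {
  stopifnot(all(c("exposure", "outcome", "method", "b", "se", "pval") %in%
                names(estimates)))
  mult <- rep(1, nrow(estimates))
  if (!is.null(scaling)) {
    hit <- match(estimates$exposure, names(scaling))
    mult[!is.na(hit)] <- scaling[hit[!is.na(hit)]]
  }
  conv <- scale_and_convert(estimates$b, estimates$se, 1)
  conv$b_scaled <- estimates$b * mult
  conv$se_scaled <- estimates$se * mult
  conv$or_ <- exp(conv$b_scaled)
  conv$or_lo <- exp(conv$b_scaled - Z95 * conv$se_scaled)
  conv$or_hi <- exp(conv$b_scaled + Z95 * conv$se_scaled)
  out <- cbind(estimates, conv[c("or_", "or_lo", "or_hi")])
  out$qval <- NA_real_
  ok <- is.finite(out$pval)
  out$qval[ok] <- bh_fdr(out$pval[ok],
                         group = interaction(out$method[ok], out$outcome[ok],
                                             drop = TRUE))
  out
}
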