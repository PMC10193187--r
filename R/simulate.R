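#' Configuration of a synthetic two-sample MR scenario
#'
#' Describes a complete generative model for paired GWAS summary statistics:
#' instrument count, true causal effect, per-allele exposure-effect
#' distribution, allele-frequency range, the three sample sizes, a
#' pleiotropy model, planted outliers, optional LD blocks and a mandatory
#' seed. Defaults mirror a large-biobank exposure GWAS (400,000
#' participants, 50 instruments with per-allele effects of SD 0.02,
#' explaining roughly 6% of an SD-scaled trait) against a case-control
#' outcome of 39,106 cases and 401,577 controls.
#'
#' Pleiotropy modes (`pleiotropy$mode`):
#' * `"none"` — all instruments valid;
#' * `"balanced"` — zero-mean direct effects of SD `sd` on the invalid
#'   fraction;
#' * `"directional"` — direct effects with nonzero `mean`, planted in the
#'   frame of the exposure-increasing allele (so the mean is estimable by
#'   MR-Egger after its orientation step);
#' * `"inside_violating"` — directional effects whose magnitude scales with
#'   instrument strength, violating the InSIDE assumption.
#'
#' @param n_snv number of instruments.
#' @param theta true causal effect, log odds of the outcome per exposure SD.
#' @param beta_exp_mean,beta_exp_sd normal distribution of true per-allele
#'   exposure effects (SD units).
#' @param maf_range range of allele frequencies, strictly inside (0, 1).
#' @param n_exp exposure GWAS sample size.
#' @param n_out_case,n_out_control outcome case/control counts.
#' @param pleiotropy list with `mode`, `mean`, `sd`, `invalid_fraction`.
#' @param outliers list of planted outliers, each a list with `ratio` (the
#'   variant's Wald ratio), `se` (its outcome SE) and optionally `beta_exp`
#'   (default 0.03).
#' @param ld_blocks optional list with `n_blocks` and `within_r2`; emits a
#'   block-structured r-squared matrix in the truth record for exercising
#'   [clump()].
#' @param seed mandatory RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_snv = 50, theta = 0,
                       beta_exp_mean = 0, beta_exp_sd = 0.02,
                       maf_range = c(0.05, 0.5),
                       n_exp = 4e5, n_out_case = 39106, n_out_control = 401577,
                       pleiotropy = list(mode = "none", mean = 0, sd = 0.001,
                                         invalid_fraction = 1),
                       outliers = list(), ld_blocks = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  pl <- utils::modifyList(list(mode = "none", mean = 0, sd = 0.001,
                               invalid_fraction = 1), pleiotropy)
  pl$mode <- match.arg(pl$mode, c("none", "balanced", "directional", "inside_violating"))
  stopifnot(n_snv >= 1, n_exp > 0, n_out_case > 0, n_out_control > 0,
            pl$invalid_fraction >= 0, pl$invalid_fraction <= 1,
            maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2])
  structure(list(n_snv = as.integer(n_snv), theta = theta,
                 beta_exp_mean = beta_exp_mean, beta_exp_sd = beta_exp_sd,
                 maf_range = maf_range, n_exp = n_exp,
                 n_out_case = n_out_case, n_out_control = n_out_control,
                 pleiotropy = pl, outliers = outliers, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## two-sided normal p-value, floored so extreme z-scores never underflow to 0
## (record invariant requires pval in (0, 1])
p_from_z <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

## analytic SEs used throughout: SD-scaled quantitative trait and
## log-odds-scale case-control trait
se_quantitative <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))
se_binary <- function(n_case, n_control, maf) {
  n <- n_case + n_control
  phi <- n_case / n
  1 / sqrt(n * phi * (1 - phi) * 2 * maf * (1 - maf))
}

## non-palindromic allele pairs used for simulated variants
NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                 "G", "A", "C", "A", "G", "T", "C", "T"),
                               ncol = 2, byrow = TRUE)

sim_variant_frame <- function(n_snv, maf, prefix = "rs") {
  pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), n_snv,
                                          replace = TRUE), , drop = FALSE]
  data.frame(variant_id = sprintf("%s%05d", prefix, seq_len(n_snv)),
             chrom = as.character(sample.int(22, n_snv, replace = TRUE)),
             effect_allele = pair[, 1], other_allele = pair[, 2],
             eaf = maf, stringsAsFactors = FALSE)
}

draw_pleiotropy <- function(cfg, beta_true) {
  pl <- cfg$pleiotropy
  n <- length(beta_true)
  pleio <- numeric(n)
  if (pl$mode == "none" || pl$invalid_fraction == 0)
    return(list(pleio = pleio, invalid = logical(n)))
  n_invalid <- round(pl$invalid_fraction * n)
  invalid <- logical(n)
  invalid[sample.int(n, n_invalid)] <- TRUE
  z <- stats::rnorm(n_invalid)
  sgn <- sign(beta_true[invalid])
  sgn[sgn == 0] <- 1
  pleio[invalid] <- switch(pl$mode,
    balanced = pl$sd * z,
    ## planted relative to the exposure-increasing allele
    directional = sgn * (pl$mean + pl$sd * z),
    inside_violating = {
      strength <- abs(beta_true[invalid]) / mean(abs(beta_true))
      sgn * (pl$mean * strength + pl$sd * z)
    })
  list(pleio = pleio, invalid = invalid)
}

#' Simulate a two-sample MR data set
#'
#' Draws true per-allele exposure effects, adds exposure-GWAS sampling noise
#' with the analytic SE `1 / sqrt(2 * N_exp * maf * (1 - maf))` (SD-scaled
#' trait), and builds outcome effects as `theta * beta_true + pleiotropy +
#' noise` with the log-odds-scale SE `1 / sqrt(N * phi * (1 - phi) * 2 * maf
#' * (1 - maf))`. Planted outliers are appended with fixed Wald ratio and
#' outcome SE. Pure function of the config (including its seed): identical
#' configs give bit-identical tables.
#'
#' @param config a [sim_config()].
#' @return list with `exposure` and `outcome` [summary_table()] objects and a
#'   `truth` record carrying every latent quantity (`beta_true`, `pleio`,
#'   `invalid`, `maf`, `theta`, per-table SEs, the planted-outlier ids and,
#'   when `ld_blocks` is set, the block `ld` matrix).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_snv
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    if (any(maf <= 0 | maf >= 1)) stop("degenerate maf drawn")
    beta_true <- stats::rnorm(n, config$beta_exp_mean, config$beta_exp_sd)
    se_exp <- se_quantitative(config$n_exp, maf)
    beta_exp_hat <- beta_true + stats::rnorm(n, 0, se_exp)
    pl <- draw_pleiotropy(config, beta_true)
    se_out <- se_binary(config$n_out_case, config$n_out_control, maf)
    beta_out_hat <- config$theta * beta_true + pl$pleio +
      stats::rnorm(n, 0, se_out)
    vf <- sim_variant_frame(n, maf)

    outlier_ids <- character(0)
    if (length(config$outliers)) {
      for (k in seq_along(config$outliers)) {
        ob <- config$outliers[[k]]
        bx <- ob$beta_exp %||% 0.03
        omaf <- 0.25
        vf <- rbind(vf, data.frame(variant_id = sprintf("outlier%02d", k),
                                   chrom = as.character(sample.int(22, 1)),
                                   effect_allele = "A", other_allele = "G",
                                   eaf = omaf, stringsAsFactors = FALSE))
        maf <- c(maf, omaf)
        beta_true <- c(beta_true, bx)
        se_exp <- c(se_exp, se_quantitative(config$n_exp, omaf))
        beta_exp_hat <- c(beta_exp_hat, bx)
        pl$pleio <- c(pl$pleio, NA_real_)
        pl$invalid <- c(pl$invalid, TRUE)
        se_out <- c(se_out, ob$se)
        beta_out_hat <- c(beta_out_hat, ob$ratio * bx)
        outlier_ids <- c(outlier_ids, sprintf("outlier%02d", k))
      }
    }

    exposure <- summary_table(
      cbind(vf, data.frame(beta = beta_exp_hat, se = se_exp,
                           pval = p_from_z(beta_exp_hat / se_exp),
                           n = config$n_exp)),
      trait_name = "exposure", trait_type = "continuous", unit = "SD")
    outcome <- summary_table(
      cbind(vf, data.frame(beta = beta_out_hat, se = se_out,
                           pval = p_from_z(beta_out_hat / se_out),
                           n = config$n_out_case + config$n_out_control)),
      trait_name = "outcome", trait_type = "binary", unit = "log odds")

    truth <- list(theta = config$theta, beta_true = beta_true, maf = maf,
                  pleio = pl$pleio, invalid = pl$invalid,
                  se_exp = se_exp, se_out = se_out,
                  outlier_ids = outlier_ids, seed = config$seed)
    if (!is.null(config$ld_blocks)) {
      nb <- config$ld_blocks$n_blocks
      r2 <- config$ld_blocks$within_r2
      block <- rep_len(seq_len(nb), nrow(vf))
      ld <- outer(block, block, function(a, b) ifelse(a == b, r2, 0))
      diag(ld) <- 1
      dimnames(ld) <- list(vf$variant_id, vf$variant_id)
      truth$ld <- ld
      truth$block <- block
    }
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate correlated exposures for multivariable MR
#'
#' Per-variant true effect vectors for `n_exposures` traits are drawn jointly
#' normal with pairwise correlation `cross_effect_correlation`; the outcome
#' is built from the direct effects only (`beta_out = B %*% direct_effects +
#' noise`), so a univariable analysis of an exposure with zero direct effect
#' is biased by the correlated co-exposure while multivariable MR is not.
#'
#' @param config a [sim_config()]; `theta` is ignored in favour of
#'   `direct_effects`.
#' @param n_exposures number of exposures (>= 1).
#' @param direct_effects numeric vector of length `n_exposures`.
#' @param cross_effect_correlation pairwise correlation of true effects,
#'   with absolute value below 1.
#' @return list with `exposures` (list of [summary_table()]), `outcome`, and
#'   `truth` (including the true effect matrix `B`).
#' @export
simulate_mv_exposures <- function(config, n_exposures, direct_effects,
                                  cross_effect_correlation = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (length(direct_effects) != n_exposures)
    stop("direct_effects must have length n_exposures")
  if (abs(cross_effect_correlation) >= 1)
    stop("|cross_effect_correlation| must be below 1")
  if (n_exposures == 1) {
    cfg1 <- config
    cfg1$theta <- direct_effects[1]
    sim <- simulate_two_sample(cfg1)
    return(list(exposures = list(sim$exposure), outcome = sim$outcome,
                truth = sim$truth))
  }
  with_seed(config$seed, {
    n <- config$n_snv
    k <- n_exposures
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    ## equicorrelated effect vectors via Cholesky
    R <- matrix(cross_effect_correlation, k, k); diag(R) <- 1
    L <- chol(R)
    Z <- matrix(stats::rnorm(n * k), n, k)
    B <- config$beta_exp_mean + config$beta_exp_sd * (Z %*% L)
    colnames(B) <- paste0("exposure", seq_len(k))
    se_exp <- se_quantitative(config$n_exp, maf)
    se_out <- se_binary(config$n_out_case, config$n_out_control, maf)
    y_true <- drop(B %*% direct_effects)
    pl <- draw_pleiotropy(config, y_true)
    beta_out_hat <- y_true + pl$pleio + stats::rnorm(n, 0, se_out)
    vf <- sim_variant_frame(n, maf)
    exposures <- lapply(seq_len(k), function(j) {
      bhat <- B[, j] + stats::rnorm(n, 0, se_exp)
      summary_table(
        cbind(vf, data.frame(beta = bhat, se = se_exp,
                             pval = p_from_z(bhat / se_exp),
                             n = config$n_exp)),
        trait_name = colnames(B)[j], trait_type = "continuous", unit = "SD")
    })
    outcome <- summary_table(
      cbind(vf, data.frame(beta = beta_out_hat, se = se_out,
                           pval = p_from_z(beta_out_hat / se_out),
                           n = config$n_out_case + config$n_out_control)),
      trait_name = "outcome", trait_type = "binary", unit = "log odds")
    list(exposures = exposures, outcome = outcome,
         truth = list(B = B, direct_effects = direct_effects, maf = maf,
                      cross_effect_correlation = cross_effect_correlation,
                      se_exp = se_exp, se_out = se_out,
                      pleio = pl$pleio, invalid = pl$invalid,
                      seed = config$seed))
  })
}
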