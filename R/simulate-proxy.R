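#' Configuration of a diagnosed-vs-proxy outcome simulation
#'
#' Extends [sim_config()] with the generative pieces of a GWAS-by-proxy
#' outcome: offspring in a biobank report whether a parent had the disease,
#' and that report — not a clinical diagnosis of the respondent — defines
#' case status. Two channels link offspring genotype to the proxy phenotype:
#'
#' 1. **Dilution channel.** The parent carries the offspring's instrument
#'    alleles with correlation `transmission` (0.5 for true parent-offspring
#'    pairs), so a real causal effect of the exposure on parental disease
#'    reappears attenuated by roughly that factor.
#' 2. **Reporting channel.** The offspring's own exposure (e.g. education)
#'    shifts the probability that parental disease is recognized and
#'    reported, with log-odds coefficient `reporting_effect`. Because the
#'    instruments drive the offspring exposure directly, a positive
#'    `reporting_effect` induces a positive instrument-proxy association that
#'    is independent of the true causal effect — violating the MR
#'    independence assumption and able to attenuate or sign-flip the
#'    proxy-based estimate.
#'
#' Defaults are calibrated (derivation in the package vignette) so that with
#' a protective true effect `theta = -0.18` per exposure SD the reporting
#' channel is about twice the diluted protective channel, reproducing a
#' sign flip between the diagnosed-outcome and proxy-outcome analyses.
#'
#' @inheritParams sim_config
#' @param n_snv,theta,maf_range,n_exp,n_out_case,n_out_control,seed as in
#'   [sim_config()].
#' @param n_families number of respondent-parent pairs in the proxy GWAS.
#' @param r2_exposure variance in the exposure explained by the instruments;
#'   true per-allele effects are rescaled to hit it exactly.
#' @param prevalence parental disease prevalence.
#' @param transmission offspring-parent genotype correlation in \[0, 0.5\].
#' @param reporting_effect log-odds effect of offspring exposure (per SD) on
#'   the probability a diseased parent is reported.
#' @param reporting_baseline baseline probability a diseased parent is
#'   reported.
#' @return a `proxy_sim_config`.
#' @export
proxy_sim_config <- function(n_snv = 30, theta = -0.18,
                             maf_range = c(0.1, 0.5),
                             n_exp = 4e5, n_out_case = 39106,
                             n_out_control = 401577,
                             n_families = 20000, r2_exposure = 0.12,
                             prevalence = 0.15, transmission = 0.5,
                             reporting_effect = 0.5,
                             reporting_baseline = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(prevalence > 0, prevalence < 1,
            reporting_baseline > 0, reporting_baseline < 1,
            transmission >= 0, transmission <= 0.5,
            r2_exposure > 0, r2_exposure < 1, n_families > 1)
  structure(list(n_snv = as.integer(n_snv), theta = theta,
                 maf_range = maf_range, n_exp = n_exp,
                 n_out_case = n_out_case, n_out_control = n_out_control,
                 n_families = as.integer(n_families),
                 r2_exposure = r2_exposure, prevalence = prevalence,
                 transmission = transmission,
                 reporting_effect = reporting_effect,
                 reporting_baseline = reporting_baseline,
                 seed = as.integer(seed)),
            class = "proxy_sim_config")
}

#' Simulate a diagnosed and a proxy outcome from one exposure
#'
#' Builds three summary tables over a shared variant panel:
#'
#' * the **exposure** table, summary-level with analytic SEs;
#' * the **diagnosed** outcome table, summary-level with the true causal
#'   effect `theta` (clinically ascertained cases, as in
#'   [simulate_two_sample()]); and
#' * the **proxy** outcome table, computed from an individual-level
#'   respondent-parent model: parent genotypes are drawn at the panel
#'   frequencies, one allele is transmitted to the respondent (genotype
#'   correlation `transmission`), parental disease follows a logistic model
#'   in the parental exposure with effect `theta`, the report indicator
#'   follows a logistic model in the respondent's exposure with effect
#'   `reporting_effect`, and the proxy case is a reported diseased parent.
#'   Per-variant log-odds associations use the logistic score approximation
#'   `cov(g, y) / (var(g) * p * (1 - p))` with SE
#'   `1 / sqrt(n * var(g) * p * (1 - p))`.
#'
#' @param config a [proxy_sim_config()].
#' @return list with `exposure`, `diagnosed`, `proxy` [summary_table()]
#'   objects and a `truth` record (true effects, genotype frequencies,
#'   channel parameters, realized proxy case fraction).
#' @export
simulate_proxy_pair <- function(config) {
  stopifnot(inherits(config, "proxy_sim_config"))
  with_seed(config$seed, {
    n <- config$n_snv
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    b_raw <- stats::rnorm(n)
    ## rescale true per-allele effects to the requested variance explained
    b <- b_raw * sqrt(config$r2_exposure / sum(b_raw^2 * 2 * maf * (1 - maf)))
    vf <- sim_variant_frame(n, maf)

    se_exp <- se_quantitative(config$n_exp, maf)
    bx_hat <- b + stats::rnorm(n, 0, se_exp)
    exposure <- summary_table(
      cbind(vf, data.frame(beta = bx_hat, se = se_exp,
                           pval = p_from_z(bx_hat / se_exp),
                           n = config$n_exp)),
      trait_name = "exposure", trait_type = "continuous", unit = "SD")

    se_diag <- se_binary(config$n_out_case, config$n_out_control, maf)
    by_diag <- config$theta * b + stats::rnorm(n, 0, se_diag)
    diagnosed <- summary_table(
      cbind(vf, data.frame(beta = by_diag, se = se_diag,
                           pval = p_from_z(by_diag / se_diag),
                           n = config$n_out_case + config$n_out_control)),
      trait_name = "diagnosed", trait_type = "binary", unit = "log odds")

    ## individual-level respondent-parent model
    nf <- config$n_families
    Gp <- matrix(stats::rbinom(nf * n, 2, rep(maf, each = nf)), nf, n)
    ## respondent allele 1: transmitted with the requested genotype correlation
    p1 <- rep(maf, each = nf) + config$transmission *
      (Gp - 2 * rep(maf, each = nf))
    p1 <- pmin(pmax(p1, 0), 1)
    Go <- matrix(stats::rbinom(nf * n, 1, p1), nf, n) +
      matrix(stats::rbinom(nf * n, 1, rep(maf, each = nf)), nf, n)
    env_sd <- sqrt(max(0, 1 - config$r2_exposure))
    Xp <- drop(sweep(Gp, 2, 2 * maf) %*% b) + stats::rnorm(nf, 0, env_sd)
    Xo <- drop(sweep(Go, 2, 2 * maf) %*% b) + stats::rnorm(nf, 0, env_sd)
    Dp <- stats::rbinom(nf, 1, stats::plogis(stats::qlogis(config$prevalence) +
                                             config$theta * Xp))
    Rp <- stats::rbinom(nf, 1, stats::plogis(stats::qlogis(config$reporting_baseline) +
                                             config$reporting_effect * Xo))
    y <- Dp * Rp
    pbar <- mean(y)
    if (pbar == 0 || pbar == 1) stop("degenerate proxy phenotype (all cases or all controls)")
    gbar <- colMeans(Go)
    gvar <- colMeans(Go^2) - gbar^2
    covgy <- drop(crossprod(Go, y - pbar)) / nf
    beta_proxy <- covgy / (gvar * pbar * (1 - pbar))
    se_proxy <- 1 / sqrt(nf * gvar * pbar * (1 - pbar))
    proxy <- summary_table(
      cbind(vf, data.frame(beta = beta_proxy, se = se_proxy,
                           pval = p_from_z(beta_proxy / se_proxy),
                           n = nf)),
      trait_name = "proxy", trait_type = "binary", unit = "log odds")

    list(exposure = exposure, diagnosed = diagnosed, proxy = proxy,
         truth = list(theta = config$theta, beta_true = b, maf = maf,
                      transmission = config$transmission,
                      reporting_effect = config$reporting_effect,
                      prevalence = config$prevalence,
                      proxy_case_fraction = pbar,
                      parent_disease_fraction = mean(Dp),
                      seed = config$seed))
  })
}
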