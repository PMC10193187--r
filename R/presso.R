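#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Residual-sum-of-squares based detection and correction of horizontal
#' pleiotropy:
#'
#' 1. **Global test.** The observed statistic is the leave-one-out weighted
#'    residual sum of squares `RSS = sum_j (beta_out_j - theta(-j) *
#'    beta_exp_j)^2 / se_out_j^2`, where `theta(-j)` is the IVW estimate
#'    excluding variant `j`. Its null distribution is built from `n_sim`
#'    parametric replicates with `beta_out*_j ~ N(theta(-j) * beta_exp_j,
#'    se_out_j)` and `beta_exp*_j ~ N(beta_exp_j, se_exp_j)`, each scored by
#'    the same statistic; the empirical p-value uses the add-one rule, so its
#'    floor is `1 / (n_sim + 1)`.
#' 2. **Outlier test.** Each variant's observed squared weighted residual is
#'    compared with the simulated distribution of the same variant's
#'    residual; the empirical p-value is Bonferroni-multiplied by the number
#'    of variants and compared with `outlier_alpha`. P-values at the
#'    attainable floor are flagged (`at_floor`) and should be reported as
#'    "< 1/(n_sim+1)". Note the adjusted floor `n_snv / (n_sim + 1)` must lie
#'    below `outlier_alpha` for any variant to be flaggable; with the
#'    defaults that requires `n_sim >= 20 * n_snv`.
#' 3. **Corrected estimate.** IVW recomputed on the non-outlying variants.
#' 4. **Distortion test.** The observed relative difference
#'    `(corrected - raw) / |raw|` is compared two-sidedly with its empirical
#'    distribution when random pseudo-outlier sets of the same size are
#'    removed instead.
#'
#' The whole procedure is a pure function of the inputs and `seed`.
#'
#' @inheritParams mr_ivw
#' @param n_sim number of parametric replicates (>= 100; default 1000).
#' @param seed RNG seed (required).
#' @param outlier_alpha significance level applied to the
#'   Bonferroni-adjusted per-variant empirical p-values.
#' @param model IVW model used for the raw and corrected estimates.
#' @return an object of class `mr_presso`: a list with `rss_obs`,
#'   `global_pval`, `outlier_pvals` (data.frame: variant_id, pval,
#'   pval_bonferroni, at_floor, flagged), `outliers`, `raw_estimate`,
#'   `corrected_estimate` (`NULL` with `all_flagged = TRUE` if every variant
#'   is an outlier), `distortion_pval`, `n_sim`, `seed`.
#' @export
mr_presso <- function(set, n_sim = 1000, seed, outlier_alpha = 0.05,
                      model = c("mre", "fe")) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is required")
  v <- hs_vectors(set)
  n <- length(v$x)
  if (n < 4) stop("MR-PRESSO needs at least 4 instruments")
  if (n_sim < 100) stop("n_sim must be at least 100")

  ## leave-one-out IVW slopes via sum updates
  a_terms <- v$x * v$y / v$sy^2
  b_terms <- v$x^2 / v$sy^2
  theta_loo <- (sum(a_terms) - a_terms) / (sum(b_terms) - b_terms)
  res_obs <- (v$y - theta_loo * v$x)^2 / v$sy^2
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    ## n_sim x n matrices of parametric replicates
    Xs <- matrix(stats::rnorm(n_sim * n, mean = rep(v$x, each = n_sim),
                              sd = rep(v$sx, each = n_sim)), n_sim, n)
    Ys <- matrix(stats::rnorm(n_sim * n, mean = rep(theta_loo * v$x, each = n_sim),
                              sd = rep(v$sy, each = n_sim)), n_sim, n)
    W <- matrix(rep(1 / v$sy^2, each = n_sim), n_sim, n)
    A <- Xs * Ys * W
    B <- Xs * Xs * W
    Tloo <- (rowSums(A) - A) / (rowSums(B) - B)
    Rs <- (Ys - Tloo * Xs)^2 * W
    list(rss = rowSums(Rs), res = Rs)
  })

  global_pval <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  out_p <- (1 + colSums(sims$res >= rep(res_obs, each = n_sim))) / (n_sim + 1)
  floor_p <- 1 / (n_sim + 1)
  out_p_bonf <- pmin(1, out_p * n)
  flagged <- out_p_bonf < outlier_alpha
  outlier_tab <- data.frame(variant_id = if (is.null(v$id)) as.character(seq_len(n)) else v$id,
                            pval = out_p, pval_bonferroni = out_p_bonf,
                            at_floor = out_p <= floor_p, flagged = flagged,
                            stringsAsFactors = FALSE)

  raw <- mr_ivw(set, model = model)
  outliers <- outlier_tab$variant_id[flagged]
  corrected <- NULL
  all_flagged <- all(flagged)
  distortion_pval <- NA_real_
  if (!all_flagged && any(flagged)) {
    corrected <- mr_ivw(set[!flagged, , drop = FALSE], model = model)
    d_obs <- (corrected$beta - raw$beta) / abs(raw$beta)
    k <- sum(flagged)
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(n, k)
        est <- mr_ivw(set[-drop_idx, , drop = FALSE], model = model)
        (est$beta - raw$beta) / abs(raw$beta)
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  } else if (!any(flagged)) {
    corrected <- raw
  }

  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 outlier_pvals = outlier_tab, outliers = outliers,
                 raw_estimate = raw, corrected_estimate = corrected,
                 all_flagged = all_flagged,
                 distortion_pval = distortion_pval,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO\n")
  gp <- if (x$global_pval <= 1 / (x$n_sim + 1))
    sprintf("< %.4g", 1 / (x$n_sim + 1)) else sprintf("%.4g", x$global_pval)
  cat(sprintf("  global test: RSS = %.3f, p %s (%d simulations)\n",
              x$rss_obs, gp, x$n_sim))
  cat(sprintf("  outliers: %d of %d variants",
              length(x$outliers), nrow(x$outlier_pvals)))
  if (length(x$outliers))
    cat(" (", paste(x$outliers, collapse = ", "), ")", sep = "")
  cat("\n")
  cat("  raw:       "); print(x$raw_estimate)
  if (x$all_flagged) {
    cat("  corrected estimate undefined: every variant flagged\n")
  } else {
    cat("  corrected: "); print(x$corrected_estimate)
  }
  if (!is.na(x$distortion_pval))
    cat(sprintf("  distortion test p = %.4g\n", x$distortion_pval))
  invisible(x)
}
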