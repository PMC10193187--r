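Z95 <- 1.959964

new_mr_estimate <- function(method, beta, se, pval = NULL, n_snv,
                            q_stat = NA_real_, q_df = NA_real_, ...) {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  q_pval <- if (is.na(q_stat) || is.na(q_df) || q_df < 1) NA_real_
            else stats::pchisq(q_stat, df = q_df, lower.tail = FALSE)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                 pval = pval, n_snv = n_snv,
                 q_stat = q_stat, q_df = q_df, q_pval = q_pval, ...),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s]: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, nSNV = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snv))
  if (!is.na(x$q_stat))
    cat(sprintf("  Cochran's Q = %.2f on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_pval))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.5f (SE %.5f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snv, b = x$beta, se = x$se,
             lo95 = x$ci_low, up95 = x$ci_high, pval = x$pval,
             q = x$q_stat, q_pval = x$q_pval,
             intercept = if (is.null(x$intercept)) NA_real_ else x$intercept,
             intercept_se = if (is.null(x$intercept_se)) NA_real_ else x$intercept_se,
             intercept_pval = if (is.null(x$intercept_pval)) NA_real_ else x$intercept_pval,
             stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#'
#' The per-variant causal estimate: the variant-outcome effect divided by the
#' variant-exposure effect. The default standard error is the first-order
#' delta-method `se_out / |beta_exp|`; `second_order = TRUE` adds the
#' exposure-side term `beta_out^2 * se_exp^2 / beta_exp^4` under the root.
#'
#' @param beta_exp,se_exp variant-exposure effect and SE.
#' @param beta_out,se_out variant-outcome effect and SE.
#' @param second_order use the second-order delta-method SE.
#' @return an `mr_estimate` with method `"wald"`.
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                          second_order = FALSE) {
  if (beta_exp == 0) stop("Wald ratio undefined: beta_exp is zero")
  beta <- beta_out / beta_exp
  var1 <- se_out^2 / beta_exp^2
  se <- if (second_order)
    sqrt(var1 + beta_out^2 * se_exp^2 / beta_exp^4)
  else sqrt(var1)
  new_mr_estimate("wald", beta, se, n_snv = 1L)
}

## pull instrument vectors out of any harmonized-set-like object
hs_vectors <- function(set) {
  stopifnot(is.data.frame(set))
  list(x = set$beta_exp, sx = set$se_exp, y = set$beta_out, sy = set$se_out,
       id = set$variant_id)
}

#' Inverse-variance weighted estimate
#'
#' Combines per-variant Wald ratios with weights
#' `beta_exp^2 / se_out^2` — algebraically identical to the zero-intercept
#' weighted regression of outcome effects on exposure effects with weights
#' `1 / se_out^2`. This is the primary analysis method. The fixed-effect SE is
#' `(sum w)^(-1/2)`; the default multiplicative random-effects model scales it
#' by `sqrt(max(1, Q / (n - 1)))`, so it is never narrower than fixed.
#' A single instrument degenerates to the first-order Wald ratio.
#'
#' @param set a `harmonized_set` (or any data.frame with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`).
#' @param model `"mre"` (multiplicative random effects, default) or `"fe"`.
#' @return an `mr_estimate` with method `"ivw_mre"` or `"ivw_fe"`,
#'   Cochran's Q in `q_stat`.
#' @export
mr_ivw <- function(set, model = c("mre", "fe")) {
  model <- match.arg(model)
  v <- hs_vectors(set)
  n <- length(v$x)
  if (n == 0) stop("empty instrument set")
  if (any(v$x == 0)) stop("beta_exp of zero is not a usable instrument")
  w <- v$x^2 / v$sy^2
  theta <- v$y / v$x
  beta <- sum(w * theta) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - beta)^2)
  se <- if (model == "mre" && n >= 2) se_fe * sqrt(max(1, q / (n - 1))) else se_fe
  new_mr_estimate(paste0("ivw_", model), beta, se, n_snv = n,
                  q_stat = if (n >= 2) q else NA_real_, q_df = n - 1)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept and weights `1 / se_out^2`. The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect and is reported with its own test. Before
#' fitting, every instrument is oriented so `beta_exp >= 0` (flipping the
#' allele coding of both effects), which makes the intercept interpretable
#' and the slope invariant to allele coding. Standard errors carry the
#' multiplicative overdispersion factor `sqrt(max(1, RSS / (n - 2)))`.
#'
#' @inheritParams mr_ivw
#' @return an `mr_estimate` with method `"egger"` and fields `intercept`,
#'   `intercept_se`, `intercept_pval`; `q_stat` holds the weighted RSS
#'   (Rucker's Q) on `n - 2` df.
#' @export
mr_egger <- function(set) {
  v <- hs_vectors(set)
  n <- length(v$x)
  if (n < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(v$x)
  flip[flip == 0] <- 1
  x <- v$x * flip
  y <- v$y * flip
  w <- 1 / v$sy^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  denom <- sw * swxx - swx^2
  if (denom <= 0 || abs(denom) < 1e-12 * sw * swxx)
    stop("degenerate design: exposure effects have no spread after orientation")
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swxx * swy - swx * swxy) / denom
  rss <- sum(w * (y - intercept - slope * x)^2)
  scale2 <- max(1, rss / (n - 2))
  se_slope <- sqrt(sw / denom * scale2)
  se_int <- sqrt(swxx / denom * scale2)
  new_mr_estimate("egger", slope, se_slope, n_snv = n,
                  q_stat = rss, q_df = n - 2,
                  intercept = intercept, intercept_se = se_int,
                  intercept_pval = 2 * stats::pnorm(-abs(intercept / se_int)))
}

## Weighted-median point estimate: linear interpolation of the order
## statistics of the ratio estimates at standardized cumulative weight 1/2.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Consistent when instruments contributing at least half the weight are
#' valid. Ratio estimates are sorted and the estimate is the linear
#' interpolation of the order statistics at standardized cumulative weight
#' one half, with first-order inverse-variance weights
#' `beta_exp^2 / se_out^2`. The SE comes from a parametric bootstrap:
#' exposure and outcome effects are redrawn from their normal sampling
#' distributions `n_boot` times and the estimator recomputed.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap draws for the SE (default 1000); `n_boot = 0`
#'   returns the point estimate with `NA` SE (useful in simulation loops).
#' @param seed RNG seed for the bootstrap; required when `n_boot > 0`.
#' @return an `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = NULL) {
  v <- hs_vectors(set)
  n <- length(v$x)
  if (n < 3) stop("weighted median needs at least 3 instruments")
  theta <- v$y / v$x
  w <- v$x^2 / v$sy^2
  beta <- weighted_median_point(theta, w)
  se <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed is required for the bootstrap SE")
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        xb <- stats::rnorm(n, v$x, v$sx)
        yb <- stats::rnorm(n, v$y, v$sy)
        weighted_median_point(yb / xb, xb^2 / v$sy^2)
      }, numeric(1))
    })
    se <- stats::sd(boot)
  }
  pv <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", beta, se, pval = pv, n_snv = n)
}

#' Multivariable MR
#'
#' Zero-intercept weighted multiple regression of outcome effects on the
#' exposure-effect matrix (weights `1 / se_out^2`), giving each exposure's
#' direct effect conditional on the others. Standard errors are scaled by
#' `sqrt(max(1, RSS / (n - k)))`. A rank-deficient exposure matrix
#' (collinear exposures, e.g. apoB with LDL) is an error naming the most
#' correlated pair — this is the multicollinearity that motivates restricting
#' adjustment sets.
#'
#' @param set an `mv_harmonized_set` from [merge_multivariable()], or a list
#'   with elements `beta_exp` (n x k matrix with column names), `beta_out`,
#'   `se_out`.
#' @return an `mvmr_result`: one row per exposure with direct effect, SE,
#'   CI and p; attributes `n_snv`, `q_stat`, `q_df`, `conditioning`.
#' @export
mr_mvmr <- function(set) {
  if (inherits(set, "mv_harmonized_set")) {
    X <- mv_beta_matrix(set)
    y <- set$beta_out
    sy <- set$se_out
  } else {
    X <- as.matrix(set$beta_exp)
    y <- set$beta_out
    sy <- set$se_out
  }
  n <- nrow(X); k <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(k))
  if (n < k + 1) stop("multivariable MR needs at least n_exposures + 1 instruments")
  w <- 1 / sy^2
  Xw <- X * sqrt(w)
  yw <- y * sqrt(w)
  qrX <- qr(Xw)
  if (qrX$rank < k) {
    cm <- abs(stats::cor(X))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop(sprintf("rank-deficient exposure matrix (collinear exposures: %s, %s)",
                 colnames(X)[worst[1]], colnames(X)[worst[2]]))
  }
  xtx <- crossprod(Xw)
  bhat <- solve(xtx, crossprod(Xw, yw))
  rss <- sum((yw - Xw %*% bhat)^2)
  scale2 <- max(1, rss / (n - k))
  vc <- solve(xtx) * scale2
  se <- sqrt(diag(vc))
  b <- drop(bhat)
  res <- data.frame(exposure = colnames(X), b = b, se = se,
                    lo95 = b - Z95 * se, up95 = b + Z95 * se,
                    pval = 2 * stats::pnorm(-abs(b / se)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, n_snv = n, q_stat = rss, q_df = n - k,
            q_pval = stats::pchisq(rss, n - k, lower.tail = FALSE),
            conditioning = colnames(X),
            class = c("mvmr_result", "data.frame"))
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR (%d instruments, conditioning on: %s)\n",
              attr(x, "n_snv"), paste(attr(x, "conditioning"), collapse = ", ")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

## evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
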