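#' Fit the two-sample MR estimator suite
#'
#' The central fitting function: applies the requested causal-effect
#' estimators to a harmonized instrument set and returns them as one classed
#' object with the usual accessor methods. Available methods:
#'
#' * `"ivw"` — inverse-variance weighted (the primary analysis); fixed or
#'   multiplicative-random-effects per `ivw_model`;
#' * `"egger"` — MR-Egger regression (slope + pleiotropy intercept);
#' * `"weighted_median"` — weighted median with parametric-bootstrap SE;
#' * `"presso"` — MR-PRESSO raw and outlier-corrected estimates;
#' * `"wald"` — per-variant Wald ratios (returned in `$wald` rather than the
#'   estimate table when more than one instrument is present).
#'
#' @param set a `harmonized_set` from [harmonize()].
#' @param methods character vector of methods to fit.
#' @param ivw_model `"mre"` or `"fe"`.
#' @param n_boot bootstrap draws for the weighted-median SE.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed seed driving the weighted-median bootstrap and MR-PRESSO.
#' @param outlier_alpha MR-PRESSO outlier threshold.
#' @return an object of class `mr_fit` with components `estimates` (list of
#'   `mr_estimate`), `presso` (an `mr_presso` or `NULL`), `set`, and the call;
#'   methods: `print`, `summary`, `coef`, `confint`, `as.data.frame`, `plot`.
#' @examples
#' sim <- simulate_two_sample(sim_config(n_snv = 30, theta = 0.1, seed = 7))
#' hs <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(hs, methods = c("ivw", "egger"), seed = 1)
#' coef(fit)
#' @export
mr_fit <- function(set, methods = c("ivw", "egger", "weighted_median", "presso"),
                   ivw_model = c("mre", "fe"), n_boot = 1000, n_sim = 1000,
                   seed = 1, outlier_alpha = 0.05) {
  stopifnot(is.data.frame(set))
  ivw_model <- match.arg(ivw_model)
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median", "presso", "wald"),
                       several.ok = TRUE)
  est <- list()
  presso <- NULL
  wald <- NULL
  for (m in methods) {
    switch(m,
      ivw = { est$ivw <- mr_ivw(set, model = ivw_model) },
      egger = { est$egger <- mr_egger(set) },
      weighted_median = {
        est$weighted_median <- mr_weighted_median(set, n_boot = n_boot, seed = seed)
      },
      presso = {
        presso <- mr_presso(set, n_sim = n_sim, seed = seed,
                            outlier_alpha = outlier_alpha)
        est$mr_presso_raw <- presso$raw_estimate
        est$mr_presso_raw$method <- "mr_presso_raw"
        if (!presso$all_flagged) {
          est$mr_presso_corrected <- presso$corrected_estimate
          est$mr_presso_corrected$method <- "mr_presso_corrected"
        }
      },
      wald = {
        wald <- do.call(rbind, lapply(seq_len(nrow(set)), function(j) {
          wr <- mr_wald_ratio(set$beta_exp[j], set$se_exp[j],
                              set$beta_out[j], set$se_out[j])
          data.frame(variant_id = set$variant_id[j], b = wr$beta, se = wr$se,
                     pval = wr$pval, stringsAsFactors = FALSE)
        }))
        if (nrow(set) == 1)
          est$wald <- mr_wald_ratio(set$beta_exp, set$se_exp,
                                    set$beta_out, set$se_out)
      })
  }
  structure(list(estimates = est, presso = presso, wald = wald, set = set,
                 exposure = attr(set, "exposure_name"),
                 outcome = attr(set, "outcome_name"),
                 call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instruments)\n",
              x$exposure %||% "exposure", x$outcome %||% "outcome", nrow(x$set)))
  for (e in x$estimates) print(e)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Two-sample MR: %s -> %s\n", object$exposure %||% "exposure",
              object$outcome %||% "outcome"))
  print(df, digits = 4, row.names = FALSE)
  if (!is.null(object$presso)) {
    cat("\n")
    print(object$presso)
  }
  invisible(df)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- t(vapply(object$estimates,
                function(e) c(e$beta - z * e$se, e$beta + z * e$se),
                numeric(2)))
  colnames(m) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  m
}

#' Tidy one-row-per-method estimate table
#'
#' @param x an `mr_fit`.
#' @param ... unused.
#' @return data.frame with columns `exposure`, `outcome`, `method`, `nsnp`,
#'   `b`, `se`, `lo95`, `up95`, `pval`, `q`, `q_pval` and Egger intercept
#'   fields.
#' @export
as.data.frame.mr_fit <- function(x, ...) {
  df <- do.call(rbind, lapply(x$estimates, as.data.frame))
  rownames(df) <- NULL
  cbind(data.frame(exposure = x$exposure %||% NA_character_,
                   outcome = x$outcome %||% NA_character_,
                   stringsAsFactors = FALSE),
        df)
}

#' Scatter plot of a fitted MR analysis
#'
#' Instrument-level outcome effects against exposure effects (oriented so
#' exposure effects are nonnegative) with one fitted line per estimator.
#'
#' @param x an `mr_fit`.
#' @param ... passed to `plot()`.
#' @export
plot.mr_fit <- function(x, ...) {
  s <- sign(x$set$beta_exp); s[s == 0] <- 1
  bx <- x$set$beta_exp * s
  by <- x$set$beta_out * s
  graphics::plot(bx, by, xlab = "variant-exposure effect",
                 ylab = "variant-outcome effect",
                 main = sprintf("%s -> %s", x$exposure %||% "exposure",
                                x$outcome %||% "outcome"), ...)
  graphics::segments(bx, by - Z95 * x$set$se_out, bx, by + Z95 * x$set$se_out,
                     col = "grey70")
  cols <- c(ivw = "black", egger = "firebrick", weighted_median = "dodgerblue",
            mr_presso_corrected = "darkgreen")
  shown <- character(0)
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    col <- cols[nm]
    if (is.na(col)) next
    if (nm == "egger") graphics::abline(e$intercept, e$beta, col = col)
    else graphics::abline(0, e$beta, col = col, lty = 2)
    shown <- c(shown, nm)
  }
  if (length(shown))
    graphics::legend("topleft", legend = shown, col = cols[shown], lty = 1,
                     bty = "n", cex = 0.8)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
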