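# Independent oracles: stats::lm weighted fits (QR-based) against the
# closed-form implementations.

lm_ivw_oracle <- function(hs) {
  w <- 1 / hs$se_out^2
  fit <- lm(beta_out ~ 0 + beta_exp, data = hs, weights = w)
  s <- summary(fit)$sigma
  se_lm <- summary(fit)$coefficients[1, 2]
  n <- nrow(hs)
  list(beta = unname(coef(fit)), se_fe = se_lm / s,
       se_mre = se_lm / s * sqrt(max(1, s^2)),
       q = sum(w * resid(fit)^2))
}

lm_egger_oracle <- function(hs) {
  flip <- ifelse(hs$beta_exp < 0, -1, 1)
  x <- hs$beta_exp * flip
  y <- hs$beta_out * flip
  w <- 1 / hs$se_out^2
  fit <- lm(y ~ x, weights = w)
  s <- summary(fit)$sigma
  co <- summary(fit)$coefficients
  list(intercept = co[1, 1], slope = co[2, 1],
       se_int = co[1, 2] / s * sqrt(max(1, s^2)),
       se_slope = co[2, 2] / s * sqrt(max(1, s^2)))
}

# dense inversion of the interpolated weighted CDF (independent route: the
# implementation interpolates s -> theta, the oracle root-finds theta -> s)
grid_median_oracle <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  s <- cumsum(w[ord] / sum(w)) - w[ord] / sum(w) / 2
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  uniroot(function(m) approx(th, s, xout = m, ties = "ordered")$y - 0.5,
          range(th), tol = 1e-12)$root
}

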