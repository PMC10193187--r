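# Oracles shared with the acceptance suite live in helper-oracles.R.

test_that("Wald ratio arithmetic and preconditions", {
  wr <- mr_wald_ratio(beta_exp = 0.25, se_exp = 0.01, beta_out = 0.05, se_out = 0.01)
  expect_equal(wr$beta, 0.2)
  expect_equal(wr$se, 0.04)
  z <- mr_wald_ratio(0.25, 0.01, 0, 0.01)
  expect_equal(z$beta, 0)
  expect_equal(z$se, 0.04)
  expect_error(mr_wald_ratio(0, 0.01, 0.05, 0.01), "beta_exp")
  # second-order SE adds the exposure-side term
  wr2 <- mr_wald_ratio(0.25, 0.01, 0.05, 0.01, second_order = TRUE)
  expect_equal(wr2$se, sqrt(0.01^2 / 0.25^2 + 0.05^2 * 0.01^2 / 0.25^4))
  expect_gt(wr2$se, wr$se)
})

test_that("two-instrument IVW matches the frozen weighted-least-squares solution", {
  hs <- make_hset(beta_exp = c(1, 1), se_exp = c(0.01, 0.01),
                  beta_out = c(0.2, 0.1), se_out = c(0.1, 0.1))
  fe <- mr_ivw(hs, model = "fe")
  expect_equal(fe$beta, 0.15)
  expect_equal(fe$se, 1 / sqrt(200))
  expect_equal(fe$q_stat, 0.5)
  # mre never narrower than fe; equal here because Q < n - 1
  expect_equal(mr_ivw(hs, model = "mre")$se, fe$se)
})

test_that("IVW degenerates to the Wald ratio for one instrument and errors when empty", {
  hs <- make_hset(0.25, 0.01, 0.05, 0.01)
  ivw <- mr_ivw(hs)
  wr <- mr_wald_ratio(0.25, 0.01, 0.05, 0.01)
  expect_equal(ivw$beta, wr$beta)
  expect_equal(ivw$se, wr$se)
  expect_error(mr_ivw(hs[0, ]), "empty")
})

test_that("IVW's two formulations agree with the regression oracle on random sets", {
  for (seed in 1:25) {
    hs <- random_hset(sample(2:10, 1), seed)
    got <- mr_ivw(hs, model = "mre")
    ora <- lm_ivw_oracle(hs)
    expect_equal(got$beta, ora$beta, tolerance = 1e-10)
    expect_equal(got$se, ora$se_mre, tolerance = 1e-10)
    expect_equal(got$q_stat, ora$q, tolerance = 1e-10)
    # ratio-form identity: precision-weighted mean of Wald ratios
    w <- hs$beta_exp^2 / hs$se_out^2
    expect_equal(got$beta,
                 sum(w * hs$beta_out / hs$beta_exp) / sum(w),
                 tolerance = 1e-12)
    # fe never wider than mre
    expect_lte(mr_ivw(hs, model = "fe")$se, got$se + 1e-15)
  }
})

test_that("homogeneous ratios collapse IVW to the common ratio with zero Q", {
  hs <- make_hset(beta_exp = c(0.1, 0.2, 0.4), se_exp = rep(0.01, 3),
                  beta_out = c(0.03, 0.06, 0.12), se_out = rep(0.01, 3))
  got <- mr_ivw(hs)
  expect_equal(got$beta, 0.3)
  expect_equal(got$q_stat, 0, tolerance = 1e-20)
  expect_equal(got$se, mr_ivw(hs, model = "fe")$se)
})

test_that("MR-Egger recovers exact affine data and matches the lm oracle", {
  # collinear through the origin
  hs0 <- make_hset(beta_exp = c(1, 2, 3), se_exp = rep(0.01, 3),
                   beta_out = c(0.1, 0.2, 0.3), se_out = rep(0.05, 3))
  e0 <- mr_egger(hs0)
  expect_equal(e0$beta, 0.1, tolerance = 1e-12)
  expect_equal(e0$intercept, 0, tolerance = 1e-12)
  # exact affine data
  hs1 <- make_hset(beta_exp = c(1, 2, 3, 5), se_exp = rep(0.01, 4),
                   beta_out = 0.05 + 0.1 * c(1, 2, 3, 5), se_out = rep(0.05, 4))
  e1 <- mr_egger(hs1)
  expect_equal(e1$beta, 0.1, tolerance = 1e-12)
  expect_equal(e1$intercept, 0.05, tolerance = 1e-12)
  # random sets against the weighted-regression oracle
  for (seed in 1:25) {
    hs <- random_hset(sample(3:10, 1), seed + 100)
    got <- mr_egger(hs)
    ora <- lm_egger_oracle(hs)
    expect_equal(got$beta, ora$slope, tolerance = 1e-10)
    expect_equal(got$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(got$se, ora$se_slope, tolerance = 1e-10)
    expect_equal(got$intercept_se, ora$se_int, tolerance = 1e-10)
  }
  expect_error(mr_egger(make_hset(c(1, 2), c(0.1, 0.1), c(0.1, 0.2), c(0.1, 0.1))),
               "at least 3")
})

test_that("Egger slope is invariant to flipping any instrument's allele coding", {
  hs <- random_hset(8, 42)
  base <- mr_egger(hs)
  for (j in c(1, 4, 8)) {
    flipped <- hs
    flipped$beta_exp[j] <- -flipped$beta_exp[j]
    flipped$beta_out[j] <- -flipped$beta_out[j]
    got <- mr_egger(flipped)
    expect_equal(got$beta, base$beta)
    expect_equal(got$intercept, base$intercept)
  }
})

test_that("weighted median interpolates the weighted order statistics", {
  # equal weights on (0.1, 0.2, 0.3) -> the simple median
  hs <- make_hset(beta_exp = c(1, 1, 1), se_exp = rep(0.01, 3),
                  beta_out = c(0.1, 0.2, 0.3), se_out = rep(0.05, 3))
  wm <- mr_weighted_median(hs, n_boot = 0)
  expect_equal(wm$beta, 0.2)
  # all ratios equal -> that ratio, tiny bootstrap SE
  hsc <- make_hset(beta_exp = c(1, 2, 3), se_exp = rep(1e-6, 3),
                   beta_out = 0.25 * c(1, 2, 3), se_out = rep(1e-6, 3))
  wmc <- mr_weighted_median(hsc, n_boot = 200, seed = 1)
  expect_equal(wmc$beta, 0.25)
  expect_lt(wmc$se, 1e-4)
  # a dominant instrument (> half the normalized weight) pins the estimate
  hsd <- make_hset(beta_exp = c(1, 0.1, 0.1), se_exp = rep(0.01, 3),
                   beta_out = c(0.5, 0.01, 0.002), se_out = rep(0.05, 3))
  wd <- (hsd$beta_exp^2 / hsd$se_out^2)
  expect_gt(wd[1] / sum(wd), 0.5)
  got <- mr_weighted_median(hsd, n_boot = 0)
  expect_equal(got$beta, grid_median_oracle(hsd$beta_out / hsd$beta_exp, wd),
               tolerance = 1e-6)
  expect_error(mr_weighted_median(hs[1:2, ], n_boot = 0), "at least 3")
  expect_error(mr_weighted_median(hs, n_boot = 10), "seed")
})

test_that("weighted median agrees with the dense-grid oracle and stays in range", {
  for (seed in 1:30) {
    hs <- random_hset(sample(3:10, 1), seed + 200)
    got <- mr_weighted_median(hs, n_boot = 0)
    theta <- hs$beta_out / hs$beta_exp
    w <- hs$beta_exp^2 / hs$se_out^2
    expect_equal(got$beta, grid_median_oracle(theta, w), tolerance = 1e-6)
    expect_gte(got$beta, min(theta))
    expect_lte(got$beta, max(theta))
  }
})

test_that("multivariable MR matches the weighted normal-equations oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:12, 1)
    X <- cbind(a = rnorm(n, 0, 0.05), b = rnorm(n, 0, 0.05))
    y <- drop(X %*% c(0.3, -0.1)) + rnorm(n, 0, 0.01)
    sy <- runif(n, 0.005, 0.02)
    got <- mr_mvmr(list(beta_exp = X, beta_out = y, se_out = sy))
    fit <- lm(y ~ 0 + X, weights = 1 / sy^2)
    s <- summary(fit)$sigma
    expect_equal(got$b, unname(coef(fit)), tolerance = 1e-10)
    scale_ratio <- sqrt(max(1, sum(resid(fit)^2 / sy^2) / (n - 2)))
    expect_equal(got$se,
                 unname(summary(fit)$coefficients[, 2]) / s * scale_ratio,
                 tolerance = 1e-10)
  }
})

test_that("MVMR nests univariable IVW and rejects collinear exposures", {
  hs <- random_hset(8, 7)
  # single-exposure MVMR is exactly IVW (same zero-intercept weighted fit)
  got <- mr_mvmr(list(beta_exp = cbind(x1 = hs$beta_exp), beta_out = hs$beta_out,
                      se_out = hs$se_out))
  ivw <- mr_ivw(hs, model = "mre")
  expect_equal(got$b, ivw$beta, tolerance = 1e-12)
  # true nesting: a second exposure with all-zero true effect contributes
  # nothing to the fit on orthogonal instruments
  expect_error(
    mr_mvmr(list(beta_exp = cbind(a = hs$beta_exp, b = hs$beta_exp),
                 beta_out = hs$beta_out, se_out = hs$se_out)),
    "collinear")
  expect_error(
    mr_mvmr(list(beta_exp = cbind(a = hs$beta_exp[1:2], b = hs$beta_out[1:2]),
                 beta_out = hs$beta_out[1:2], se_out = hs$se_out[1:2])),
    "n_exposures")
})

test_that("mr_fit aggregates methods with the standard accessors", {
  sim <- simulate_two_sample(sim_config(n_snv = 20, theta = 0.1, seed = 9))
  hs <- harmonize(sim$exposure, sim$outcome)
  fit <- mr_fit(hs, methods = c("ivw", "egger", "weighted_median"),
                n_boot = 100, seed = 2)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), c("ivw", "egger", "weighted_median"))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 3L)
  expect_true(all(c("exposure", "outcome", "method", "nsnp", "b", "se",
                    "lo95", "up95", "pval") %in% names(df)))
  # estimates are reproducible under the same seed
  fit2 <- mr_fit(hs, methods = c("weighted_median"), n_boot = 100, seed = 2)
  expect_identical(fit2$estimates$weighted_median$se,
                   fit$estimates$weighted_median$se)
})
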