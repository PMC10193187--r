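# harmonization_fixture() lives in helper-fixtures.R (shared with acceptance).

test_that("the alignment fixture yields exactly the expected partition", {
  fx <- harmonization_fixture()
  hs <- harmonize(fx$exposure, fx$outcome)
  # v01 direct; v02 swap; v03 strand flip (A/G vs T/C); v04 strand flip + swap;
  # v05/v07 palindromic A/T; v06/v08 palindromic C/G; v09/v10 mismatches;
  # v11 not in outcome; v12 C/T vs C/A mismatch
  expect_equal(hs$variant_id, c("v01", "v02", "v03", "v04"))
  expect_equal(hs$beta_out, c(0.05, 0.05, 0.05, 0.05))
  ex <- exclusions(hs)
  expect_equal(ex$reason[match(c("v05", "v06", "v07", "v08"), ex$variant_id)],
               rep("palindromic", 4))
  expect_equal(ex$reason[match(c("v09", "v10", "v12"), ex$variant_id)],
               rep("allele_mismatch", 3))
  expect_equal(ex$reason[ex$variant_id == "v11"], "not_in_outcome")
  # bookkeeping: every exposure variant is an instrument or an exclusion
  expect_equal(nrow(hs) + nrow(ex), nrow(fx$exposure))
  expect_length(intersect(hs$variant_id, ex$variant_id), 0)
})

test_that("allele swap flips the outcome effect sign and frequency", {
  exp1 <- summary_table(data.frame(
    variant_id = "rs1", chrom = "1", effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.10, se = 0.01, pval = 1e-9, n = 1e5),
    trait_name = "x")
  out_sw <- summary_table(data.frame(
    variant_id = "rs1", chrom = "1", effect_allele = "G", other_allele = "A",
    eaf = 0.7, beta = -0.05, se = 0.01, pval = 0.01, n = 1e5),
    trait_name = "y")
  hs <- harmonize(exp1, out_sw)
  expect_equal(hs$beta_out, 0.05)
  expect_equal(hs$eaf_out, 0.3)
})

test_that("harmonization is involution-safe on already-aligned tables", {
  sim <- simulate_two_sample(sim_config(n_snv = 25, theta = 0.1, seed = 11))
  hs1 <- harmonize(sim$exposure, sim$outcome)
  expect_equal(hs1$beta_out, sim$outcome$beta)
  expect_equal(nrow(exclusions(hs1)), 0L)
})

test_that("flipping a variant's exposure coding leaves the Wald ratio unchanged", {
  sim <- simulate_two_sample(sim_config(n_snv = 10, theta = 0.2, seed = 3))
  expo <- sim$exposure
  ratio_before <- with(suppressWarnings(harmonize(expo, sim$outcome)),
                       beta_out[1] / beta_exp[1])
  flipped <- as.data.frame(expo)
  tmp <- flipped$effect_allele[1]
  flipped$effect_allele[1] <- flipped$other_allele[1]
  flipped$other_allele[1] <- tmp
  flipped$beta[1] <- -flipped$beta[1]
  flipped$eaf[1] <- 1 - flipped$eaf[1]
  expo2 <- summary_table(flipped, trait_name = "exposure")
  ratio_after <- with(suppressWarnings(harmonize(expo2, sim$outcome)),
                      beta_out[1] / beta_exp[1])
  expect_equal(ratio_after, ratio_before)
})

test_that("palindrome rescue keeps only frequency-decisive variants when enabled", {
  pal <- function(eaf_exp, eaf_out) {
    e <- summary_table(data.frame(
      variant_id = "rs1", chrom = "1", effect_allele = "A", other_allele = "T",
      eaf = eaf_exp, beta = 0.1, se = 0.01, pval = 1e-9, n = 1e5), "x")
    o <- summary_table(data.frame(
      variant_id = "rs1", chrom = "1", effect_allele = "A", other_allele = "T",
      eaf = eaf_out, beta = 0.05, se = 0.01, pval = 0.01, n = 1e5), "y")
    list(e = e, o = o)
  }
  # default: excluded regardless of frequency
  fx <- pal(0.1, 0.1)
  expect_equal(exclusions(harmonize(fx$e, fx$o))$reason, "palindromic")
  # rescue: concordant decisive frequencies keep the variant as-is
  hs <- harmonize(fx$e, fx$o, palindrome_rescue = TRUE)
  expect_equal(hs$beta_out, 0.05)
  # rescue: opposite decisive frequencies imply the other allele - sign flips
  fx2 <- pal(0.1, 0.9)
  hs2 <- harmonize(fx2$e, fx2$o, palindrome_rescue = TRUE)
  expect_equal(hs2$beta_out, -0.05)
  # intermediate frequency stays excluded even with rescue on
  fx3 <- pal(0.45, 0.45)
  expect_equal(nrow(harmonize(fx3$e, fx3$o, palindrome_rescue = TRUE)), 0L)
})

test_that("frequency discordance warns but does not exclude", {
  e <- summary_table(data.frame(
    variant_id = "rs1", chrom = "1", effect_allele = "A", other_allele = "G",
    eaf = 0.1, beta = 0.1, se = 0.01, pval = 1e-9, n = 1e5), "x")
  o <- summary_table(data.frame(
    variant_id = "rs1", chrom = "1", effect_allele = "A", other_allele = "G",
    eaf = 0.6, beta = 0.05, se = 0.01, pval = 0.01, n = 1e5), "y")
  expect_warning(hs <- harmonize(e, o), "discordance")
  expect_equal(nrow(hs), 1L)
})

test_that("multivariable merge takes the significant union across exposures", {
  sim <- simulate_mv_exposures(sim_config(n_snv = 10, seed = 5), 2, c(0.2, 0), 0.3)
  mv <- merge_multivariable(sim$exposures, sim$outcome, p_threshold = 1)
  expect_s3_class(mv, "mv_harmonized_set")
  expect_equal(nrow(mv), 10L)
  B <- mrpipe:::mv_beta_matrix(mv)
  expect_equal(dim(B), c(10L, 2L))
  expect_equal(unname(B[, 1]), sim$exposures[[1]]$beta)

  # a variant absent from one exposure table is excluded with a reason
  e2 <- sim$exposures[[2]]
  e2short <- mrpipe:::keep_rows(e2, -1)
  mv2 <- merge_multivariable(list(sim$exposures[[1]], e2short), sim$outcome,
                             p_threshold = 1)
  expect_equal(nrow(mv2), 9L)
  ex <- exclusions(mv2)
  expect_equal(ex$reason[ex$variant_id == e2$variant_id[1]], "not_in_exposure")
  expect_error(merge_multivariable(list(sim$exposures[[1]]), sim$outcome),
               "at least 2")
})
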