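# Fixture builders shared across test files.

# minimal well-formed summary table
make_table <- function(n = 3, trait = "trait", pvals = NULL, chrom = NULL,
                       beta = NULL, unit = "SD") {
  summary_table(
    data.frame(variant_id = sprintf("rs%03d", seq_len(n)),
               chrom = chrom %||% rep("1", n),
               effect_allele = rep("A", n), other_allele = rep("G", n),
               eaf = seq(0.1, 0.4, length.out = n),
               beta = beta %||% seq(0.02, 0.05, length.out = n),
               se = rep(0.004, n),
               pval = pvals %||% rep(1e-10, n),
               n = rep(4e5, n)),
    trait_name = trait, unit = unit)
}

# harmonized set straight from vectors (bypasses allele bookkeeping)
make_hset <- function(beta_exp, se_exp, beta_out, se_out,
                      exposure = "exposure", outcome = "outcome") {
  n <- length(beta_exp)
  structure(data.frame(variant_id = sprintf("rs%03d", seq_len(n)),
                       chrom = rep("1", n),
                       beta_exp = beta_exp, se_exp = se_exp,
                       beta_out = beta_out, se_out = se_out,
                       eaf_exp = rep(0.3, n), eaf_out = rep(0.3, n),
                       stringsAsFactors = FALSE),
            exposure_name = exposure, outcome_name = outcome,
            exclusions = data.frame(variant_id = character(0),
                                    reason = character(0)),
            class = c("harmonized_set", "data.frame"))
}

# random instrument set for oracle-equivalence checks
random_hset <- function(n, seed) {
  set.seed(seed)
  make_hset(beta_exp = rnorm(n, 0, 0.05) + 0.02 * sample(c(-1, 1), n, TRUE),
            se_exp = runif(n, 0.002, 0.01),
            beta_out = rnorm(n, 0, 0.02),
            se_out = runif(n, 0.005, 0.02))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 12-variant harmonization fixture covering every alignment case:
# direct match, swapped alleles, strand flip, strand flip + swap,
# palindromes, mismatches and a variant missing from the outcome.
harmonization_fixture <- function() {
  exposure <- summary_table(data.frame(
    variant_id = sprintf("v%02d", 1:12),
    chrom = rep("2", 12),
    effect_allele = c("A", "A", "A", "A", "A", "C", "A", "C", "A", "G", "A", "C"),
    other_allele  = c("G", "G", "G", "G", "T", "G", "T", "G", "C", "T", "G", "T"),
    eaf = rep(0.2, 12),
    beta = rep(0.10, 12), se = rep(0.01, 12),
    pval = rep(1e-10, 12), n = rep(1e5, 12)),
    trait_name = "exposure")
  outcome <- summary_table(data.frame(
    variant_id = sprintf("v%02d", c(1:10, 12)),   # v11 missing
    chrom = rep("2", 11),
    effect_allele = c("A", "G", "T", "C", "A", "C", "T", "G", "A", "C", "C"),
    other_allele  = c("G", "A", "C", "T", "T", "G", "A", "C", "G", "G", "A"),
    eaf = c(0.2, 0.8, 0.2, 0.8, rep(0.2, 7)),
    beta = c(0.05, -0.05, 0.05, -0.05, 0.05, 0.05, 0.04, 0.06, 0.03, 0.05, 0.05),
    se = rep(0.012, 11), pval = rep(0.01, 11), n = rep(2e5, 11)),
    trait_name = "outcome", trait_type = "binary", unit = "log odds")
  list(exposure = exposure, outcome = outcome)
}

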