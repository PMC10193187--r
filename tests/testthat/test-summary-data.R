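test_that("well-formed files round-trip losslessly through read/write", {
  tab <- make_table(3, pvals = c(1e-12, 4.9e-8, 0.2), beta = c(0.021, -0.013, 0.002))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary(tab, f1)
  back <- read_summary(f1, trait_name = "trait", unit = "SD")
  expect_identical(nrow(attr(back, "rejected")), 0L)
  attr(back, "rejected") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # second write is byte-identical
  write_summary(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gzip-compressed input and column remapping are accepted", {
  tab <- make_table(4)
  raw <- as.data.frame(tab)
  names(raw) <- c("SNP", "CHR", "EA", "OA", "FREQ", "effect", "stderr", "p", "N")
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(f, "w")
  write.table(raw, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  got <- read_summary(f, column_map = c(variant_id = "SNP", chrom = "CHR",
                                        effect_allele = "EA", other_allele = "OA",
                                        eaf = "FREQ", beta = "effect",
                                        se = "stderr", pval = "p", n = "N"),
                      trait_name = "trait")
  attr(got, "rejected") <- NULL
  expect_equal(as.data.frame(got), as.data.frame(tab))
  expect_error(read_summary(f, trait_name = "trait"), "column_map")
})

test_that("invalid rows are rejected with row-numbered reasons", {
  raw <- as.data.frame(make_table(5))
  raw$se[2] <- 0
  raw$effect_allele[4] <- "I"
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(raw, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_summary(f, trait_name = "trait")
  expect_equal(nrow(got), 3L)
  rej <- attr(got, "rejected")
  expect_equal(rej$row, c(2L, 4L))
  expect_equal(rej$reason, c("nonpositive SE", "non-SNV allele"))
})

test_that("significance filtering is strict and idempotent", {
  tab <- make_table(3, pvals = c(1e-9, 1e-7, 4.9e-8))
  kept <- filter_significant(tab, 5e-8)
  expect_equal(kept$variant_id, c("rs001", "rs003"))
  # exactly-at-threshold p is dropped (strict <)
  at <- make_table(1, pvals = 5e-8)
  expect_equal(nrow(filter_significant(at, 5e-8)), 0L)
  # idempotence and the identity threshold
  expect_equal(as.data.frame(filter_significant(kept, 5e-8)),
               as.data.frame(kept))
  expect_equal(nrow(filter_significant(tab, 1)), 3L)
  expect_equal(nrow(filter_significant(make_table(0), 5e-8)), 0L)
})

test_that("greedy clumping keeps the independent best-p variants", {
  tab <- make_table(3, pvals = c(1e-10, 1e-9, 1e-8))
  ld <- diag(3)
  ld[1, 2] <- ld[2, 1] <- 0.5
  dimnames(ld) <- list(tab$variant_id, tab$variant_id)
  got <- clump(tab, ld, r2_threshold = 0.1)
  # exhaustive oracle: replay the greedy rule by hand over all orderings
  expect_equal(got$variant_id, c("rs001", "rs003"))
  # no retained pair exceeds the threshold
  expect_true(all(ld[got$variant_id, got$variant_id][upper.tri(diag(2))] <= 0.1))
})

test_that("clumping degenerates correctly at the r2 extremes", {
  tab <- make_table(4, pvals = c(1e-8, 1e-10, 1e-9, 1e-7))
  ld0 <- diag(4); dimnames(ld0) <- list(tab$variant_id, tab$variant_id)
  expect_equal(as.data.frame(clump(tab, ld0, 0.1)), as.data.frame(tab))
  ld1 <- matrix(1, 4, 4); dimnames(ld1) <- dimnames(ld0)
  expect_equal(clump(tab, ld1, 0.999)$variant_id, "rs002")
  # unknown variant is a named error
  expect_error(clump(tab, ld0[1:3, 1:3], 0.1), "rs004")
})

test_that("clump output is mutually independent on random LD structures", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 12
    tab <- make_table(n, pvals = runif(n, 1e-12, 1e-6))
    m <- matrix(runif(n * n), n, n)
    ld <- (m + t(m)) / 2
    diag(ld) <- 1
    dimnames(ld) <- list(tab$variant_id, tab$variant_id)
    thr <- runif(1, 0.05, 0.6)
    got <- clump(tab, ld, thr)
    sub <- ld[got$variant_id, got$variant_id, drop = FALSE]
    expect_true(all(sub[upper.tri(sub)] <= thr))
    # the top variant always survives
    expect_true(tab$variant_id[which.min(tab$pval)] %in% got$variant_id)
  }
})

test_that("chromosome exclusion removes matching records and reports the count", {
  tab <- make_table(5, chrom = c("1", "19", "2", "19", "3"))
  expect_message(got <- exclude_chromosome(tab, "19"), "2 variant")
  expect_equal(got$chrom, c("1", "2", "3"))
  expect_silent(none <- exclude_chromosome(tab, "22"))
  expect_equal(as.data.frame(none), as.data.frame(tab))
  expect_equal(nrow(exclude_chromosome(make_table(0), "19")), 0L)
})

test_that("summary_table enforces its invariants at construction", {
  rec <- as.data.frame(make_table(2))
  rec$variant_id[2] <- rec$variant_id[1]
  expect_error(summary_table(rec, "t"), "duplicate")
  rec2 <- as.data.frame(make_table(1))
  rec2$other_allele <- "A"
  expect_error(summary_table(rec2, "t"), "identical alleles")
  expect_error(summary_table(as.data.frame(make_table(1))[-3], "t"), "missing columns")
})
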