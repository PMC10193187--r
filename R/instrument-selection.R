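#' Filter variants at a significance threshold
#'
#' Keeps exactly the records with `pval` strictly below the threshold
#' (genome-wide significance, P < 5e-8, by default), preserving order.
#'
#' @param table a [summary_table()].
#' @param p_threshold significance threshold in (0, 1].
#' @return the filtered `summary_table`.
#' @export
filter_significant <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "summary_table"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be a single value in (0, 1]")
  keep_rows(table, table$pval < p_threshold)
}

#' Greedy LD clumping against a supplied r-squared matrix
#'
#' Selects an approximately independent instrument set: repeatedly keep the
#' remaining variant with the smallest p-value (ties broken by variant id)
#' and drop every remaining variant whose squared correlation with it exceeds
#' `r2_threshold`. LD is supplied by the caller as a symmetric r-squared
#' matrix with unit diagonal, keyed by variant id — reference-panel handling
#' is outside this package, and source-GWAS thresholds (0.001 / 0.1 / 0.05)
#' are passed straight through.
#'
#' @param table a [summary_table()].
#' @param ld symmetric variant-by-variant r-squared matrix with dimnames
#'   covering every variant in `table`.
#' @param r2_threshold LD pruning threshold in (0, 1].
#' @return the clumped `summary_table`; no retained pair has r-squared above
#'   the threshold.
#' @export
clump <- function(table, ld, r2_threshold = 0.001) {
  stopifnot(inherits(table, "summary_table"))
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]")
  if (nrow(table) == 0) return(table)
  ids <- table$variant_id
  if (is.null(dimnames(ld)) || is.null(rownames(ld)))
    stop("ld matrix must have variant_id dimnames")
  absent <- setdiff(ids, rownames(ld))
  if (length(absent))
    stop("variant(s) absent from ld matrix: ", paste(absent, collapse = ", "))
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)))
    stop("ld matrix must be symmetric")
  ld <- ld[ids, ids, drop = FALSE]
  remaining <- seq_along(ids)
  kept <- integer(0)
  while (length(remaining)) {
    ord <- order(table$pval[remaining], ids[remaining])
    best <- remaining[ord[1]]
    kept <- c(kept, best)
    drop <- remaining[ld[best, remaining] > r2_threshold]
    remaining <- setdiff(remaining, union(best, drop))
  }
  keep_rows(table, sort(kept))
}

#' Exclude all variants on a chromosome
#'
#' Sensitivity filter removing every variant on the given chromosome — used
#' to address strong single-locus signals (e.g. dropping chromosome 19 to
#' remove the APOE region for Alzheimer disease outcomes). The number of
#' removed variants is reported via `message()`.
#'
#' @param table a [summary_table()].
#' @param chrom chromosome label to remove (matched against the `chrom`
#'   column as a string).
#' @return the filtered `summary_table`.
#' @export
exclude_chromosome <- function(table, chrom = "19") {
  stopifnot(inherits(table, "summary_table"))
  hit <- table$chrom == as.character(chrom)
  if (any(hit))
    message(sum(hit), " variant(s) removed on chromosome ", chrom)
  keep_rows(table, !hit)
}

## subset rows of a summary_table preserving attributes
keep_rows <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_name = attr(table, "trait_name"),
            trait_type = attr(table, "trait_type"),
            unit = attr(table, "unit"),
            class = c("summary_table", "data.frame"))
}
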