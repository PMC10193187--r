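#' GWAS summary-statistics table
#'
#' A `summary_table` holds per-variant association statistics for one trait:
#' variant identifier, chromosome, effect and other allele, effect-allele
#' frequency, effect estimate (log-odds per allele for binary traits, trait
#' units per allele otherwise), its standard error, p-value and sample size.
#' It is a plain `data.frame` with trait metadata stored as attributes, so all
#' the usual data-frame idioms apply.
#'
#' @param records data.frame with columns `variant_id`, `chrom`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_name name of the trait (e.g. `"HDL"`).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param unit unit of the per-allele effect (e.g. `"SD"`, `"10 mm Hg"`,
#'   `"log odds"`); must be non-empty.
#' @return an object of class `summary_table`.
#' @examples
#' tab <- summary_table(
#'   data.frame(variant_id = "rs1", chrom = "1",
#'              effect_allele = "A", other_allele = "G",
#'              eaf = 0.3, beta = 0.02, se = 0.003, pval = 1e-11, n = 4e5),
#'   trait_name = "HDL", trait_type = "continuous", unit = "SD")
#' @export
summary_table <- function(records, trait_name, trait_type = c("continuous", "binary"),
                          unit = "SD") {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_name), nzchar(trait_name))
  if (!nzchar(unit)) stop("unit must be a non-empty string")
  req <- c("variant_id", "chrom", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[req]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  if (anyDuplicated(records$variant_id))
    stop("duplicate variant_id: ",
         paste(unique(records$variant_id[duplicated(records$variant_id)]),
               collapse = ", "))
  bad <- validate_records(records)
  if (nrow(bad))
    stop("invalid records: ",
         paste(sprintf("%s (%s)", bad$variant_id, bad$reason), collapse = "; "))
  structure(records,
            trait_name = trait_name, trait_type = trait_type, unit = unit,
            class = c("summary_table", "data.frame"))
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s, unit: %s)\n",
              attr(x, "trait_name"), attr(x, "trait_type"), attr(x, "unit")))
  cat(sprintf("  %d variants", nrow(x)))
  if (nrow(x)) cat(sprintf(", min p = %.3g", min(x$pval)))
  cat("\n")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  %d rows rejected at parse time\n", nrow(rej)))
  invisible(x)
}

trait_name <- function(x) attr(x, "trait_name")

## Row-level invariant checks shared by the constructor and the reader.
## Returns a data.frame (row, variant_id, reason); zero rows when clean.
validate_records <- function(records) {
  reasons <- character(nrow(records))
  nt <- c("A", "C", "G", "T")
  bad_allele <- !(records$effect_allele %in% nt) | !(records$other_allele %in% nt)
  same_allele <- !bad_allele & records$effect_allele == records$other_allele
  bad_se <- !is.finite(records$se) | records$se <= 0
  bad_eaf <- !is.finite(records$eaf) | records$eaf < 0 | records$eaf > 1
  bad_p <- !is.finite(records$pval) | records$pval <= 0 | records$pval > 1
  bad_n <- !is.finite(records$n) | records$n <= 0
  bad_beta <- !is.finite(records$beta)
  reasons[bad_beta]    <- "non-finite effect"
  reasons[bad_n]       <- "nonpositive sample size"
  reasons[bad_p]       <- "p-value outside (0,1]"
  reasons[bad_eaf]     <- "allele frequency outside [0,1]"
  reasons[bad_se]      <- "nonpositive SE"
  reasons[same_allele] <- "identical alleles"
  reasons[bad_allele]  <- "non-SNV allele"
  keep <- nzchar(reasons)
  data.frame(row = which(keep),
             variant_id = records$variant_id[keep],
             reason = reasons[keep],
             stringsAsFactors = FALSE)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-delimited file with a header row into a [summary_table()].
#' Column names can be remapped through `column_map`, so common dialects
#' (`effect`/`stderr`/`p` vs `beta`/`se`/`pval`) are ingested without editing
#' the file. Gzip-compressed files are read transparently. Rows violating the
#' record invariants (non-ACGT alleles, nonpositive SE, out-of-range
#' frequency or p-value) are rejected, not fatal: the returned table carries a
#' machine-readable audit of rejected rows in `attr(, "rejected")` with the
#' 1-based data row number, variant id and reason.
#'
#' @param path path to a tab-delimited file (optionally `.gz`).
#' @param column_map named character vector mapping canonical names
#'   (`variant_id`, `chrom`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`) to the column names present in the file. Canonical
#'   names absent from the map are looked up verbatim.
#' @param trait_name,trait_type,unit trait metadata, see [summary_table()].
#' @return a `summary_table`; rejected rows in `attr(, "rejected")`.
#' @seealso [write_summary()]
#' @export
read_summary <- function(path, column_map = NULL, trait_name = basename(path),
                         trait_type = c("continuous", "binary"), unit = "SD") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("variant_id", "chrom", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
  src <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) src[names(column_map)] <- column_map
  absent <- src[!(src %in% names(raw))]
  if (length(absent))
    stop("column(s) not found in ", path, ": ", paste(absent, collapse = ", "),
         " (check column_map)")
  records <- stats::setNames(raw[src], canonical)
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  for (col in c("eaf", "beta", "se", "pval", "n"))
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  bad <- validate_records(records)
  dup <- duplicated(records$variant_id)
  if (any(dup)) {
    bad <- rbind(bad, data.frame(row = which(dup),
                                 variant_id = records$variant_id[dup],
                                 reason = "duplicate variant_id",
                                 stringsAsFactors = FALSE))
    bad <- bad[order(bad$row), , drop = FALSE]
  }
  keep <- setdiff(seq_len(nrow(records)), bad$row)
  tab <- summary_table(records[keep, , drop = FALSE], trait_name = trait_name,
                       trait_type = trait_type, unit = unit)
  rownames(tab) <- NULL
  attr(tab, "rejected") <- bad
  tab
}

#' Write a summary table to a tab-delimited file
#'
#' Writes the canonical nine columns with a header row; [read_summary()] on
#' the result round-trips the data losslessly (numbers are written with full
#' precision).
#'
#' @param table a [summary_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(table, path) {
  stopifnot(inherits(table, "summary_table"))
  out <- as.data.frame(table)
  for (col in c("eaf", "beta", "se", "pval"))
    out[[col]] <- format(out[[col]], digits = 17, trim = TRUE, scientific = NA)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
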