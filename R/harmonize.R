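COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1]) == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome records to the exposure's effect allele, variant by
#' variant, so that both effects refer to the same allele before any causal
#' estimation:
#'
#' * alleles matching directly are kept as-is;
#' * swapped alleles (outcome effect allele equals the exposure's other
#'   allele) flip the sign of the outcome effect and complement its
#'   frequency;
#' * alleles matching only after strand complement (A<->T, C<->G applied to
#'   both outcome alleles) are complemented first, then the direct/swap rule
#'   applies;
#' * palindromic variants (A/T or C/G pairs), whose strand cannot be resolved
#'   from the alleles, are excluded outright by default; and
#' * irreconcilable allele pairs are excluded as mismatches.
#'
#' Candidate instruments are the variants of the exposure table; candidates
#' missing from the outcome are excluded with reason `not_in_outcome`. No
#' LD-proxy lookup is attempted. Exclusions are returned as a machine-readable
#' audit in `attr(, "exclusions")` with reasons drawn from the fixed set
#' `palindromic`, `not_in_outcome`, `not_in_exposure`, `allele_mismatch`.
#' A post-alignment effect-allele-frequency discordance beyond `eaf_warn`
#' raises a warning (never an exclusion).
#'
#' @param exposure,outcome [summary_table()] objects; the exposure table is
#'   the candidate instrument list (typically already significance-filtered
#'   and clumped).
#' @param palindrome_rescue if `TRUE`, palindromic variants whose effect
#'   allele frequency is decisive on both sides (both below `rescue_maf` or
#'   both above `1 - rescue_maf`, after inferring orientation) are kept
#'   instead of excluded; the default keeps the unconditional exclusion.
#' @param rescue_maf frequency window for the rescue (default 0.3).
#' @param eaf_warn absolute post-alignment frequency discordance that
#'   triggers a warning.
#' @return a `harmonized_set`: a data.frame of instruments with columns
#'   `variant_id`, `chrom`, `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#'   `eaf_exp`, `eaf_out`, plus attributes `exposure_name`, `outcome_name`,
#'   `exclusions`.
#' @export
harmonize <- function(exposure, outcome, palindrome_rescue = FALSE,
                      rescue_maf = 0.3, eaf_warn = 0.2) {
  stopifnot(inherits(exposure, "summary_table"), inherits(outcome, "summary_table"))
  om <- match(exposure$variant_id, outcome$variant_id)
  excl <- list()
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    vid <- exposure$variant_id[i]
    if (is.na(om[i])) {
      excl[[length(excl) + 1L]] <- c(vid, "not_in_outcome")
      next
    }
    e <- exposure[i, ]
    o <- outcome[om[i], ]
    if (is_palindromic(e$effect_allele, e$other_allele)) {
      rescued <- FALSE
      if (palindrome_rescue) {
        ## orientation inferable when both frequencies are away from 0.5;
        ## keep only when the inferred orientation is a direct match
        fe <- e$eaf; fo <- o$eaf
        if (!is.na(fe) && !is.na(fo) &&
            (fe < rescue_maf || fe > 1 - rescue_maf) &&
            (fo < rescue_maf || fo > 1 - rescue_maf)) {
          if ((fe < 0.5) != (fo < 0.5)) { # frequencies point to opposite alleles
            o$beta <- -o$beta
            o$eaf <- 1 - o$eaf
          }
          rescued <- TRUE
        }
      }
      if (!rescued) {
        excl[[length(excl) + 1L]] <- c(vid, "palindromic")
        next
      }
      rows[[i]] <- data.frame(variant_id = vid, chrom = e$chrom,
                              beta_exp = e$beta, se_exp = e$se,
                              beta_out = o$beta, se_out = o$se,
                              eaf_exp = e$eaf, eaf_out = o$eaf,
                              stringsAsFactors = FALSE)
      next
    }
    al <- align_alleles(e$effect_allele, e$other_allele,
                        o$effect_allele, o$other_allele)
    if (is.na(al)) {
      excl[[length(excl) + 1L]] <- c(vid, "allele_mismatch")
      next
    }
    beta_out <- if (al == "swap") -o$beta else o$beta
    eaf_out <- if (al == "swap") 1 - o$eaf else o$eaf
    rows[[i]] <- data.frame(variant_id = vid, chrom = e$chrom,
                            beta_exp = e$beta, se_exp = e$se,
                            beta_out = beta_out, se_out = o$se,
                            eaf_exp = e$eaf, eaf_out = eaf_out,
                            stringsAsFactors = FALSE)
  }
  inst <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(inst))
    inst <- data.frame(variant_id = character(0), chrom = character(0),
                       beta_exp = numeric(0), se_exp = numeric(0),
                       beta_out = numeric(0), se_out = numeric(0),
                       eaf_exp = numeric(0), eaf_out = numeric(0),
                       stringsAsFactors = FALSE)
  rownames(inst) <- NULL
  disc <- abs(inst$eaf_exp - inst$eaf_out) > eaf_warn
  if (any(disc, na.rm = TRUE))
    warning("effect-allele frequency discordance > ", eaf_warn, " for: ",
            paste(inst$variant_id[which(disc)], collapse = ", "))
  new_harmonized_set(inst, excl,
                     exposure_name = attr(exposure, "trait_name"),
                     outcome_name = attr(outcome, "trait_name"))
}

## How do outcome alleles relate to the exposure's?  "direct", "swap" or NA.
## Strand complement is tried when the same-strand codings do not match.
align_alleles <- function(ea_exp, oa_exp, ea_out, oa_out) {
  if (ea_out == ea_exp && oa_out == oa_exp) return("direct")
  if (ea_out == oa_exp && oa_out == ea_exp) return("swap")
  ea_c <- unname(COMPLEMENT[ea_out]); oa_c <- unname(COMPLEMENT[oa_out])
  if (ea_c == ea_exp && oa_c == oa_exp) return("direct")
  if (ea_c == oa_exp && oa_c == ea_exp) return("swap")
  NA_character_
}

new_harmonized_set <- function(instruments, exclusions, exposure_name, outcome_name) {
  excl_df <- if (length(exclusions)) {
    m <- do.call(rbind, exclusions)
    data.frame(variant_id = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  structure(instruments,
            exposure_name = exposure_name, outcome_name = outcome_name,
            exclusions = excl_df,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %s -> %s\n",
              attr(x, "exposure_name"), attr(x, "outcome_name")))
  cat(sprintf("  %d instruments, %d excluded\n",
              nrow(x), nrow(attr(x, "exclusions"))))
  ex <- attr(x, "exclusions")
  if (nrow(ex)) {
    tab <- table(ex$reason)
    cat("  exclusions:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exclusion audit of a harmonized set
#'
#' @param set a `harmonized_set` from [harmonize()] or [merge_multivariable()].
#' @return data.frame with columns `variant_id`, `reason`.
#' @export
exclusions <- function(set) attr(set, "exclusions")

#' Harmonize several exposures and one outcome for multivariable MR
#'
#' Builds the multivariable instrument set as the union of variants reaching
#' `p_threshold` in at least one exposure, harmonized to a common effect
#' allele (the first exposure's orientation) across all tables. Variants
#' missing a record in any exposure table or in the outcome are excluded with
#' reason `not_in_exposure` / `not_in_outcome`; palindromic variants are
#' excluded as in [harmonize()].
#'
#' @param exposures list of at least two [summary_table()] objects.
#' @param outcome [summary_table()].
#' @param p_threshold instrument-selection threshold applied per exposure.
#' @return an `mv_harmonized_set`: data.frame with matrix columns unrolled as
#'   `beta_exp.<trait>` / `se_exp.<trait>` per exposure plus `beta_out`,
#'   `se_out`; attributes `exposure_names`, `outcome_name`, `exclusions`.
#' @export
merge_multivariable <- function(exposures, outcome, p_threshold = 5e-8) {
  if (!is.list(exposures) || length(exposures) < 2)
    stop("multivariable MR needs at least 2 exposure tables")
  lapply(exposures, function(x) stopifnot(inherits(x, "summary_table")))
  stopifnot(inherits(outcome, "summary_table"))
  enames <- vapply(exposures, function(x) attr(x, "trait_name"), character(1))
  if (anyDuplicated(enames)) stop("exposure trait names must be unique")
  sig <- lapply(exposures, function(x) x$variant_id[x$pval < p_threshold])
  ids <- sort(unique(unlist(sig)))
  excl <- list()
  rows <- list()
  ref <- exposures[[1]]
  for (vid in ids) {
    recs <- lapply(exposures, function(x) x[match(vid, x$variant_id), ])
    miss_exp <- vapply(recs, function(r) is.na(r$variant_id), logical(1))
    if (any(miss_exp)) {
      excl[[length(excl) + 1L]] <- c(vid, "not_in_exposure")
      next
    }
    orec <- outcome[match(vid, outcome$variant_id), ]
    if (is.na(orec$variant_id)) {
      excl[[length(excl) + 1L]] <- c(vid, "not_in_outcome")
      next
    }
    r1 <- recs[[1]]
    if (is_palindromic(r1$effect_allele, r1$other_allele)) {
      excl[[length(excl) + 1L]] <- c(vid, "palindromic")
      next
    }
    ok <- TRUE
    bexp <- sexp <- numeric(length(recs))
    for (k in seq_along(recs)) {
      al <- align_alleles(r1$effect_allele, r1$other_allele,
                          recs[[k]]$effect_allele, recs[[k]]$other_allele)
      if (is.na(al)) { ok <- FALSE; break }
      bexp[k] <- if (al == "swap") -recs[[k]]$beta else recs[[k]]$beta
      sexp[k] <- recs[[k]]$se
    }
    if (!ok) {
      excl[[length(excl) + 1L]] <- c(vid, "allele_mismatch")
      next
    }
    al_o <- align_alleles(r1$effect_allele, r1$other_allele,
                          orec$effect_allele, orec$other_allele)
    if (is.na(al_o)) {
      excl[[length(excl) + 1L]] <- c(vid, "allele_mismatch")
      next
    }
    beta_out <- if (al_o == "swap") -orec$beta else orec$beta
    row <- data.frame(variant_id = vid, chrom = r1$chrom,
                      stringsAsFactors = FALSE)
    for (k in seq_along(enames)) {
      row[[paste0("beta_exp.", enames[k])]] <- bexp[k]
      row[[paste0("se_exp.", enames[k])]] <- sexp[k]
    }
    row$beta_out <- beta_out
    row$se_out <- orec$se
    rows[[length(rows) + 1L]] <- row
  }
  inst <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(inst)) {
    inst <- data.frame(variant_id = character(0), chrom = character(0),
                       stringsAsFactors = FALSE)
    for (k in seq_along(enames)) {
      inst[[paste0("beta_exp.", enames[k])]] <- numeric(0)
      inst[[paste0("se_exp.", enames[k])]] <- numeric(0)
    }
    inst$beta_out <- numeric(0)
    inst$se_out <- numeric(0)
  }
  rownames(inst) <- NULL
  out <- new_harmonized_set(inst, excl,
                            exposure_name = paste(enames, collapse = " + "),
                            outcome_name = attr(outcome, "trait_name"))
  attr(out, "exposure_names") <- enames
  class(out) <- c("mv_harmonized_set", class(out))
  out
}

## exposure-effect matrix (n x k) of an mv_harmonized_set
mv_beta_matrix <- function(set, what = "beta_exp") {
  enames <- attr(set, "exposure_names")
  m <- as.matrix(as.data.frame(set)[paste0(what, ".", enames)])
  colnames(m) <- enames
  m
}
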