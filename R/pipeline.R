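#' Run a full two-sample MR analysis grid
#'
#' Orchestrates the study design over every exposure x outcome pair: filter
#' to genome-wide significance, clump against the supplied r-squared matrix
#' (if any), optionally drop chromosome 19, harmonize, fit the requested
#' estimators (including MR-PRESSO), convert to odds ratios with per-exposure
#' unit scaling, then compute Benjamini-Hochberg q-values within each
#' (method, outcome) stratum across exposures. Multivariable MR groups and a
#' reverse-direction pass (outcome trait as exposure) are run the same way.
#' Every random component is seeded deterministically from `config$seed`, so
#' a rerun reproduces the results byte for byte. A failing cell is recorded
#' (column `error`) and the grid continues.
#'
#' @param config a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{exposures}{list of exposure specs: `name`, and either `table` (a
#'     [summary_table()]) or `path` (+ optional `column_map`, `unit`,
#'     `trait_type`); optional `unit_multiplier` (default 1), `p_threshold`
#'     (default 5e-8), `r2_threshold` and `ld` matrix for clumping.}
#'   \item{outcomes}{list of outcome specs: `name`, `table` or `path`.}
#'   \item{methods}{subset of `c("ivw", "egger", "weighted_median",
#'     "presso")` (default all).}
#'   \item{mvmr_groups}{optional named list; each entry a character vector of
#'     exposure names analysed jointly.}
#'   \item{sensitivity}{optional flags: `exclude_chrom_19`,
#'     `fixed_effect_ivw`.}
#'   \item{reverse_direction}{if `TRUE`, additionally instrument each outcome
#'     trait (significance-filtered) against each exposure trait.}
#'   \item{seed}{integer master seed.}
#'   \item{output_dir}{optional; results and audit tables are written there
#'     as tab-delimited files.}
#' }
#' @return an object of class `mr_analysis`: list with `results` (tidy
#'   data.frame: exposure, outcome, direction, method, nsnp, b, se, lo95,
#'   up95, pval, q, q_pval, intercept fields, or_, or_lo, or_hi, qval,
#'   error), `mvmr` (per-group [mr_mvmr()] tables), `audits` (per-cell
#'   harmonization exclusions and PRESSO outlier tables), `n_failed`.
#' @export
run_mr_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), length(config$exposures) >= 1,
            length(config$outcomes) >= 1)
  methods <- config$methods %||% c("ivw", "egger", "weighted_median", "presso")
  seed <- config$seed %||% 1L
  sens <- utils::modifyList(list(exclude_chrom_19 = FALSE,
                                 fixed_effect_ivw = FALSE),
                            config$sensitivity %||% list())
  ivw_model <- if (isTRUE(sens$fixed_effect_ivw)) "fe" else "mre"

  load_spec <- function(spec, default_type = "continuous") {
    if (!is.null(spec$table)) return(spec$table)
    read_summary(spec$path, column_map = spec$column_map,
                 trait_name = spec$name,
                 trait_type = spec$trait_type %||% default_type,
                 unit = spec$unit %||% "SD")
  }
  prepare_exposure <- function(spec, tab) {
    tab <- filter_significant(tab, spec$p_threshold %||% 5e-8)
    if (!is.null(spec$ld))
      tab <- clump(tab, spec$ld, spec$r2_threshold %||% 0.001)
    if (isTRUE(sens$exclude_chrom_19))
      tab <- suppressMessages(exclude_chromosome(tab, "19"))
    tab
  }

  exp_tabs <- lapply(config$exposures, load_spec)
  names(exp_tabs) <- vapply(config$exposures, `[[`, character(1), "name")
  out_tabs <- lapply(config$outcomes, function(s) load_spec(s, "binary"))
  names(out_tabs) <- vapply(config$outcomes, `[[`, character(1), "name")
  scaling <- vapply(config$exposures,
                    function(s) s$unit_multiplier %||% 1, numeric(1))
  names(scaling) <- names(exp_tabs)

  rows <- list()
  audits <- list()
  n_failed <- 0L
  cell_idx <- 0L
  run_cell <- function(ename, etab_prepared, oname, otab, direction) {
    cell_idx <<- cell_idx + 1L
    cell_seed <- seed + cell_idx
    res <- tryCatch({
      hs <- harmonize(etab_prepared, otab)
      attr(hs, "exposure_name") <- ename
      attr(hs, "outcome_name") <- oname
      if (nrow(hs) == 0) stop("no instruments after harmonization")
      fit <- mr_fit(hs, methods = methods, ivw_model = ivw_model,
                    seed = cell_seed)
      df <- as.data.frame(fit)
      df$exposure <- ename
      df$outcome <- oname
      audits[[sprintf("%s|%s|%s", direction, ename, oname)]] <<-
        list(exclusions = exclusions(hs),
             presso_outliers = if (!is.null(fit$presso))
               fit$presso$outlier_pvals else NULL)
      df$error <- NA_character_
      df$direction <- direction
      df
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      data.frame(exposure = ename, outcome = oname, method = NA_character_,
                 nsnp = NA_integer_, b = NA_real_, se = NA_real_,
                 lo95 = NA_real_, up95 = NA_real_, pval = NA_real_,
                 q = NA_real_, q_pval = NA_real_, intercept = NA_real_,
                 intercept_se = NA_real_, intercept_pval = NA_real_,
                 error = conditionMessage(e), direction = direction,
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <<- res
  }

  for (ei in seq_along(exp_tabs)) {
    etab <- prepare_exposure(config$exposures[[ei]], exp_tabs[[ei]])
    for (oi in seq_along(out_tabs))
      run_cell(names(exp_tabs)[ei], etab, names(out_tabs)[oi],
               out_tabs[[oi]], "forward")
  }
  if (isTRUE(config$reverse_direction)) {
    for (oi in seq_along(out_tabs)) {
      rtab <- filter_significant(out_tabs[[oi]], 5e-8)
      for (ei in seq_along(exp_tabs))
        run_cell(names(out_tabs)[oi], rtab, names(exp_tabs)[ei],
                 exp_tabs[[ei]], "reverse")
    }
  }

  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ## OR scaling and per-(method, outcome, direction) FDR over exposures
  ok <- !is.na(results$method)
  scaled <- results_table(results[ok, , drop = FALSE], scaling = scaling)
  scaled$qval <- NA_real_
  fin <- is.finite(scaled$pval)
  scaled$qval[fin] <- bh_fdr(scaled$pval[fin],
                             group = interaction(scaled$method[fin],
                                                 scaled$outcome[fin],
                                                 scaled$direction[fin],
                                                 drop = TRUE))
  for (col in setdiff(names(scaled), names(results))) results[[col]] <- NA_real_
  results[ok, names(scaled)] <- scaled
  ord <- order(results$direction, results$outcome, results$exposure, results$method)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL

  mvmr_res <- list()
  for (gname in names(config$mvmr_groups %||% list())) {
    members <- config$mvmr_groups[[gname]]
    if (!all(members %in% names(exp_tabs)))
      stop("mvmr group ", gname, " references undeclared exposures")
    for (oi in seq_along(out_tabs)) {
      key <- sprintf("%s|%s", gname, names(out_tabs)[oi])
      mvmr_res[[key]] <- tryCatch({
        mvset <- merge_multivariable(unname(exp_tabs[members]), out_tabs[[oi]])
        mr_mvmr(mvset)
      }, error = function(e) {
        n_failed <<- n_failed + 1L
        structure(conditionMessage(e), class = "mr_cell_error")
      })
    }
  }

  out <- structure(list(results = results, mvmr = mvmr_res, audits = audits,
                        scaling = scaling, seed = seed, n_failed = n_failed),
                   class = "mr_analysis")
  if (!is.null(config$output_dir)) write_mr_analysis(out, config$output_dir)
  out
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("MR analysis grid: %d result rows, %d MVMR groups, %d failed cell(s)\n",
              nrow(x$results), length(x$mvmr), x$n_failed))
  utils::head(x$results)
  invisible(x)
}

#' Write analysis outputs as tab-delimited files
#'
#' Writes `results.tsv` (the tidy grid), one `mvmr_<group>.tsv` per
#' multivariable group, and per-cell `exclusions_*.tsv` /
#' `presso_outliers_*.tsv` audit tables.
#'
#' @param analysis an `mr_analysis` from [run_mr_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mr_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) utils::write.table(df, file.path(dir, file),
                                              sep = "\t", quote = FALSE,
                                              row.names = FALSE)
  wt(analysis$results, "results.tsv")
  for (key in names(analysis$mvmr)) {
    m <- analysis$mvmr[[key]]
    if (inherits(m, "mr_cell_error")) next
    wt(as.data.frame(m), paste0("mvmr_", gsub("[^A-Za-z0-9_.-]", "_", key), ".tsv"))
  }
  for (key in names(analysis$audits)) {
    a <- analysis$audits[[key]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    if (!is.null(a$exclusions) && nrow(a$exclusions))
      wt(a$exclusions, paste0("exclusions_", safe, ".tsv"))
    if (!is.null(a$presso_outliers))
      wt(a$presso_outliers, paste0("presso_outliers_", safe, ".tsv"))
  }
  invisible(dir)
}
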