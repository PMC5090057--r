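#' Pipeline configuration
#'
#' Bundles the analysis constants: the family inclusion threshold (at least
#' 6 species with members), the Monte-Carlo budget (10000 permutations for
#' the null of the mean correlation; 1000 resamples for enrichment), the
#' minimum background families per retained term (200), the developmental
#' cutoff (13 years), and the FDR gate (0.05).
#'
#' @param target Phenotype under test (default `"nr"`).
#' @param covariates Confound traits for the corrected stage.
#' @param n_perm Permutation replicates for the null distribution.
#' @param n_samples Random samples for the enrichment null.
#' @param min_species Family inclusion threshold.
#' @param min_families Term retention threshold.
#' @param cutoff_years Developmental split.
#' @param fdr_alpha FDR significance gate in (0, 1).
#' @param absent_policy Species-without-members policy for associations.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(target = "nr",
                            covariates = setdiff(c("nr", "ei", "mlsp"),
                                                 target),
                            n_perm = 10000L, n_samples = 1000L,
                            min_species = 6L, min_families = 200L,
                            cutoff_years = 13, fdr_alpha = 0.05,
                            absent_policy = "zero") {
  if (fdr_alpha <= 0 || fdr_alpha >= 1)
    stop("fdr_alpha must lie in (0, 1)", call. = FALSE)
  structure(list(target = target, covariates = covariates,
                 n_perm = .assert_scalar_count(n_perm, "n_perm"),
                 n_samples = .assert_scalar_count(n_samples, "n_samples"),
                 min_species = .assert_scalar_count(min_species,
                                                    "min_species"),
                 min_families = .assert_scalar_count(min_families,
                                                     "min_families"),
                 cutoff_years = cutoff_years, fdr_alpha = fdr_alpha,
                 absent_policy = absent_policy),
            class = "pipeline_config")
}

#' Run the full association pipeline
#'
#' Composes the stages in order: family filtering, per-family associations
#' with the permutation-null shift test and sign chi-square, the
#' confound-plus-phylogeny corrected associations, density-adjusted
#' enrichment over the corrected FDR-significant positively associated
#' families, and (when expression data with a gene-to-family map are
#' supplied) the developmental expression contrast on genes of those
#' families. Per-stage tables are written as TSV; a machine-readable
#' `summary.json` collects the headline statistics. Reruns with the same
#' inputs and seed are byte-identical.
#'
#' @param gfs GFS matrix (families x species) or path to its TSV.
#' @param phenotypes A `phenotype_table` or path to its CSV.
#' @param tree An [ape::phylo] tree or path to a Newick file.
#' @param annotations Optional annotation data.frame or TSV path.
#' @param expression Optional `expression_dataset` (needs `gene_families`).
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param seed Integer master seed; stochastic stages use documented
#'   offsets (permutation null: `seed`; enrichment null: `seed + 1`).
#' @return The summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(gfs, phenotypes, tree, annotations = NULL,
                         expression = NULL, out_dir, config =
                           pipeline_config(), seed = 1L) {
  if (is.character(gfs)) gfs <- read_gfs(gfs)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("seed=%d", seed),
                 sprintf("config: target=%s covariates=%s n_perm=%d n_samples=%d",
                         config$target,
                         paste(config$covariates, collapse = "+"),
                         config$n_perm, config$n_samples))

  flt <- .stage("filter", filter_families(gfs, config$min_species))
  jsonlite::write_json(flt$report, file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE)
  M <- flt$matrix

  pheno <- trait_vector(phenotypes, config$target,
                        gsub(" ", "_", colnames(M)))
  assoc <- .stage("associate",
                  family_associations(M, pheno, config$absent_policy))
  .write_stage_tsv(assoc, file.path(out_dir, "associations.tsv"))
  mean_r <- mean(assoc$r, na.rm = TRUE)
  null <- .stage("permutation_null",
                 permutation_null(M, pheno, n_replicates = config$n_perm,
                                  scheme = "joint", seed = seed))
  shift <- zscore_shift_test(mean_r, null)
  chisq <- sign_chisq(assoc)
  log_lines <- c(log_lines, sprintf("permutation_null seed=%d", seed))

  corrected <- .stage("correct",
                      corrected_association(M, phenotypes, tree,
                                            target = config$target,
                                            covariates = config$covariates))
  .write_stage_tsv(corrected, file.path(out_dir, "corrected.tsv"))
  sig <- corrected$family_id[!is.na(corrected$q) &
                               corrected$q < config$fdr_alpha &
                               corrected$r > 0]

  summary <- list(
    n_families_input = flt$report$n_input,
    n_families_kept = flt$report$n_nonzero_variance,
    target = config$target,
    mean_r = mean_r,
    z = shift$z,
    p_one_tailed = shift$p_one_tailed,
    p_empirical = shift$p_empirical,
    chi2 = chisq$chi2,
    chi2_p = chisq$p,
    n_pos = chisq$n_pos,
    n_neg = chisq$n_neg,
    n_fdr_uncorrected = sum(!is.na(assoc$q) & assoc$q < config$fdr_alpha &
                              assoc$r > 0),
    n_fdr_corrected = length(sig)
  )

  if (!is.null(annotations) && length(sig) > 0L) {
    map <- build_term_map(annotations, rownames(M), config$min_families)
    enr <- .stage("enrich",
                  enrichment_test(sig, rownames(M), map,
                                  n_samples = config$n_samples,
                                  seed = seed + 1L))
    .write_stage_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    summary$n_terms_tested <- nrow(enr)
    summary$n_terms_enriched <- sum(enr$q < config$fdr_alpha)
    summary$enriched_terms <- enr$term[enr$q < config$fdr_alpha]
    log_lines <- c(log_lines, sprintf("enrichment seed=%d", seed + 1L))
  }

  if (!is.null(expression)) {
    if (is.null(expression$gene_families))
      stop("expression stage needs a gene_families map on the dataset",
           call. = FALSE)
    genes <- names(expression$gene_families)[
      expression$gene_families %in% sig]
    if (length(genes) >= 6L) {
      norm <- .stage("expression", normalize_samples(expression))
      wm <- window_means(norm, cutoff_years = config$cutoff_years,
                         gene_subset = genes)
      .write_stage_tsv(wm, file.path(out_dir, "expression_windows.tsv"))
      wilc <- paired_wilcoxon(wm, alternative = "greater")
      summary$expression <- list(statistic = wilc$statistic, p = wilc$p,
                                 n_genes = wilc$n_used)
    } else {
      summary$expression <- list(statistic = NA, p = NA,
                                 n_genes = length(genes))
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

.write_stage_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
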