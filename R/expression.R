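#' Normalize expression against total expression per sample
#'
#' Divides every sample (column) by its column total, so columns sum to one.
#' Idempotent and invariant to per-sample rescaling.
#'
#' @param dataset An `expression_dataset` (see [read_expression()]).
#' @return The dataset with normalized `values`.
#' @export
normalize_samples <- function(dataset) {
  totals <- colSums(dataset$values)
  zero <- which(totals == 0)
  if (length(zero) > 0L)
    stop("sample(s) with zero total expression: ",
         paste(colnames(dataset$values)[zero], collapse = ", "),
         call. = FALSE)
  dataset$values <- sweep(dataset$values, 2L, totals, "/")
  dataset
}

#' Per-gene means in the developmental windows around cortical maturation
#'
#' Splits samples at `cutoff_years` (samples exactly at the cutoff belong to
#' the "before" window, full cortical thickness having just been reached)
#' and averages each gene over the samples of each window.
#'
#' @param dataset An `expression_dataset`; `meta$age_years` must cover every
#'   sample (prenatal ages negative).
#' @param cutoff_years Age split in years (default 13, approximate age of
#'   full cortical-thickness maturation in humans).
#' @param gene_subset Optional character vector restricting the genes.
#' @param cell_means If `TRUE`, average within each (age, region) cell
#'   first, then across cells of the window; default is a plain mean over
#'   all window samples.
#' @return A data.frame with columns `gene_id`, `mean_before`, `mean_after`,
#'   `n_before`, `n_after`.
#' @export
window_means <- function(dataset, cutoff_years = 13, gene_subset = NULL,
                         cell_means = FALSE) {
  age <- dataset$meta$age_years
  if (anyNA(age)) stop("every sample needs an age", call. = FALSE)
  before <- age <= cutoff_years
  if (!any(before) || all(before))
    stop("both developmental windows must contain samples", call. = FALSE)
  values <- dataset$values
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(values))
    if (length(missing) > 0L)
      stop("gene(s) absent from matrix: ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
    values <- values[gene_subset, , drop = FALSE]
  }
  win_mean <- function(cols) {
    if (!cell_means)
      return(rowMeans(values[, cols, drop = FALSE]))
    cell <- interaction(dataset$meta$age_years[cols],
                        dataset$meta$region[cols], drop = TRUE)
    sub <- values[, cols, drop = FALSE]
    cellmeans <- vapply(levels(cell),
                        function(l) rowMeans(sub[, cell == l, drop = FALSE]),
                        numeric(nrow(sub)))
    rowMeans(matrix(cellmeans, nrow = nrow(sub)))
  }
  data.frame(gene_id = rownames(values),
             mean_before = win_mean(which(before)),
             mean_after = win_mean(which(!before)),
             n_before = sum(before),
             n_after = sum(!before),
             stringsAsFactors = FALSE)
}

#' Paired Wilcoxon signed-rank test between developmental windows
#'
#' Tests the per-gene differences `mean_before - mean_after` with the
#' Wilcoxon signed-rank test: exact null distribution for at most 25
#' non-zero pairs, normal approximation with continuity correction above.
#' Zero differences are dropped.
#'
#' @param summaries Output of [window_means()].
#' @param alternative `"greater"` (before > after, the default) or
#'   `"two.sided"`.
#' @param exact_max Largest number of non-zero pairs for which the exact
#'   distribution is used (default 25). Ties force the approximation.
#' @return A list with `statistic` (V, sum of positive ranks), `p`,
#'   `n_used` (non-zero pairs), `alternative`.
#' @export
paired_wilcoxon <- function(summaries, alternative = c("greater",
                                                       "two.sided"),
                            exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- summaries$mean_before - summaries$mean_after
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all differences are zero", call. = FALSE)
  if (length(d) < 6L)
    stop("need at least 6 non-zero paired differences", call. = FALSE)
  ties <- any(duplicated(abs(d)))
  use_exact <- length(d) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(d, mu = 0, alternative = alternative,
                exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_used = length(d), alternative = alternative)
}
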