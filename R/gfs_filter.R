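#' Family inclusion filters for a gene-family-size matrix
#'
#' Keeps gene families whose members are present (size >= 1) in at least
#' `min_species` of the species, and which show non-zero size variance
#' across all species columns (zeros included). Families failing either
#' criterion carry no usable comparative signal.
#'
#' @param matrix Integer GFS matrix, rows = families, columns = species.
#' @param min_species Minimum number of species with at least one member
#'   (default 6).
#' @return A list with elements `matrix` (the filtered matrix) and `report`,
#'   a list with stage-wise counts: `n_input`, `n_present_ge_min`,
#'   `n_nonzero_variance` (families passing both stages) and `kept_ids`.
#' @export
filter_families <- function(matrix, min_species = 6L) {
  min_species <- .assert_scalar_count(min_species, "min_species")
  if (min_species > ncol(matrix))
    stop("min_species exceeds the number of species columns", call. = FALSE)
  n_present <- rowSums(matrix > 0)
  pass_presence <- n_present >= min_species
  vars <- apply(matrix, 1L, var)
  pass_both <- pass_presence & vars > 0
  kept <- matrix[pass_both, , drop = FALSE]
  report <- list(
    n_input = nrow(matrix),
    n_present_ge_min = sum(pass_presence),
    n_nonzero_variance = sum(pass_both),
    kept_ids = rownames(kept)
  )
  list(matrix = kept, report = report)
}
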