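#' Read a species phenotype table
#'
#' Reads a CSV of per-species brain phenotypes: total brain volume, neocortex
#' volume, neocortex ratio `nr` (recomputed from the volumes when the column
#' is absent), encephalization index `ei` and maximum lifespan `mlsp`.
#'
#' @param path Path to a CSV file with header columns `species`,
#'   `brain_volume`, `neocortex_volume`, `ei`, `mlsp` and optionally `nr`.
#'   Extra columns are preserved.
#' @return A `data.frame` of class `phenotype_table`, one row per species,
#'   in file order.
#' @seealso [mammal_phenotypes()] for the packaged 28-species compilation.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("species", "brain_volume", "neocortex_volume", "ei", "mlsp")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("phenotype table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("brain_volume", "neocortex_volume", "ei", "mlsp", "nr")) {
    if (!col %in% names(df)) next
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                   col, bad[1L], df[[col]][bad[1L]]), call. = FALSE)
    df[[col]] <- vals
  }
  if (anyDuplicated(df$species))
    stop("duplicate species in phenotype table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "),
         call. = FALSE)
  if (!"nr" %in% names(df))
    df$nr <- compute_nr(df$brain_volume, df$neocortex_volume)
  validate_phenotypes(df)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

validate_phenotypes <- function(df) {
  if (any(!is.finite(df$brain_volume)) || any(df$brain_volume <= 0))
    stop("brain_volume must be finite and > 0", call. = FALSE)
  if (any(!is.finite(df$neocortex_volume)) || any(df$neocortex_volume <= 0))
    stop("neocortex_volume must be finite and > 0", call. = FALSE)
  bad <- which(df$neocortex_volume >= df$brain_volume)
  if (length(bad) > 0L)
    stop("neocortex_volume must be smaller than brain_volume for: ",
         paste(df$species[bad], collapse = ", "), call. = FALSE)
  for (col in c("nr", "ei", "mlsp"))
    if (any(!is.finite(df[[col]])))
      stop(sprintf("column '%s' contains non-finite values", col),
           call. = FALSE)
  if (any(df$nr <= 0) || any(df$mlsp <= 0))
    stop("nr and mlsp must be > 0", call. = FALSE)
  invisible(df)
}

#' Packaged mammalian brain phenotype compilation
#'
#' Loads the packaged literature compilation of brain volume, neocortex
#' volume, neocortex ratio, encephalization index and maximum lifespan for
#' 28 mammalian species with fully sequenced genomes. The `nr_source` column
#' records whether the tabulated neocortex ratio is reproducible from the
#' stored volumes (`"volumes"`) or is carried as printed in the source
#' compilation (`"printed"`; the mouse row only).
#'
#' @return A `phenotype_table` with 28 rows.
#' @export
mammal_phenotypes <- function() {
  read_phenotypes(system.file("extdata", "mammal_brain_phenotypes.csv",
                              package = "neogfs", mustWork = TRUE))
}

#' Write a phenotype table to CSV
#'
#' @param table A `phenotype_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], signif, digits = 6L)
  .write_csv(out, path)
  invisible(path)
}

.write_csv <- function(df, path) {
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Read a gene-family-size matrix
#'
#' Reads a TSV whose first column is `family_id` and remaining columns are
#' species, cells holding the number of member genes of that family in that
#' species. Empty cells are zero; sizes must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return An integer matrix, rows = families (rownames = family ids),
#'   columns = species.
#' @export
read_gfs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L)
    stop("GFS table needs a family_id column plus at least one species",
         call. = FALSE)
  fam <- df[[1L]]
  if (anyDuplicated(fam))
    stop("duplicate family ids: ",
         paste(unique(fam[duplicated(fam)]), collapse = ", "), call. = FALSE)
  cells <- as.matrix(df[, -1L, drop = FALSE])
  cells[cells == ""] <- "0"
  num <- suppressWarnings(as.numeric(cells))
  if (anyNA(num))
    stop("non-numeric gene family size cell: '",
         cells[which(is.na(num))[1L]], "'", call. = FALSE)
  if (any(num < 0))
    stop("gene family sizes must be non-negative", call. = FALSE)
  if (any(num != round(num)))
    stop("gene family sizes must be integers (counts); found '",
         cells[which(num != round(num))[1L]], "'", call. = FALSE)
  m <- matrix(as.integer(num), nrow = nrow(df),
              dimnames = list(fam, colnames(df)[-1L]))
  m
}

#' Write a gene-family-size matrix to TSV
#'
#' @param matrix Integer matrix with family rownames and species colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gfs <- function(matrix, path) {
  df <- data.frame(family_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper around [ape::read.tree()] that enforces the presence of
#' branch lengths (independent contrasts require them).
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparsable Newick in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree))
    stop("unparsable Newick in '", path, "'", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths; contrasts require them",
         call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree", call. = FALSE)
  tree
}

#' Write a phylogeny to Newick
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Check a tree for ultrametricity
#'
#' @param tree An [ape::phylo] object.
#' @param tol Relative tolerance on root-to-tip path differences.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  ape::is.ultrametric(tree, tol = tol)
}

#' Read a family-to-term annotation map
#'
#' Reads a two-column TSV (`family_id`, `term_id`). A family may carry any
#' number of terms including none (it simply does not appear).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `family_id`, `term_id`; duplicate
#'   pairs are dropped with a warning.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (!all(c("family_id", "term_id") %in% names(df)))
    stop("annotation file needs columns family_id, term_id", call. = FALSE)
  df <- df[, c("family_id", "term_id")]
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sum(dup), " duplicate (family, term) pair(s) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a family-to-term annotation map to TSV
#' @param annotations `data.frame` with columns `family_id`, `term_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations[, c("family_id", "term_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' @param matrix_path TSV, first column `gene_id`, remaining columns one per
#'   sample, non-negative expression values (RPKM-like).
#' @param meta_path CSV with columns `sample_id`, `age_years`, `region`.
#'   Prenatal ages are negative years relative to birth
#'   (post-conception week w maps to (w - 40) / 52).
#' @return A list of class `expression_dataset` with elements `values`
#'   (genes x samples matrix), `meta` (data.frame aligned to the columns),
#'   and optionally `gene_families` (named character vector) when the matrix
#'   was produced by [simulate_expression()].
#' @export
read_expression <- function(matrix_path, meta_path) {
  df <- read.delim(matrix_path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1L]]
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age_years", "region") %in% names(meta)))
    stop("metadata needs columns sample_id, age_years, region", call. = FALSE)
  unmatched <- setdiff(colnames(values), meta$sample_id)
  if (length(unmatched) > 0L)
    stop("sample(s) in matrix absent from metadata: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  structure(list(values = values, meta = meta), class = "expression_dataset")
}

#' Write an expression dataset (matrix TSV + metadata CSV)
#' @param dataset An `expression_dataset`.
#' @param matrix_path,meta_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, meta_path) {
  vals <- signif(dataset$values, 6L)
  df <- data.frame(gene_id = rownames(vals), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_csv(dataset$meta[, c("sample_id", "age_years", "region")],
                  meta_path)
  invisible(matrix_path)
}
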