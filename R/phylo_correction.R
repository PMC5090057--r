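#' Residuals from an ordinary least-squares fit with intercept
#'
#' @param response Numeric response vector.
#' @param covariates Numeric matrix or data.frame of covariates (an
#'   intercept column is added internally).
#' @return Residual vector: response minus the least-squares fit. Residuals
#'   sum to zero and are orthogonal to every covariate column.
#' @export
ols_residuals <- function(response, covariates) {
  X <- .design_matrix(covariates, n = length(response))
  if (length(response) <= ncol(X))
    stop("need more observations than fitted coefficients", call. = FALSE)
  qr.resid(.checked_qr(X), response)
}

.design_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1L,
                                         dimnames = list(NULL, "(Intercept)")))
  X <- as.matrix(covariates)
  if (nrow(X) != n)
    stop("covariates and response have different lengths", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cbind("(Intercept)" = 1, X)
}

.checked_qr <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  qx
}

# ensure binary topology and strictly usable branch lengths for pruning;
# eps kept tiny so a star tree still reproduces the ordinary correlation
.prep_tree <- function(tree, eps_frac = 1e-12) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (any(tree$edge.length == 0)) {
    height <- max(ape::node.depth.edgelength(tree))
    tree$edge.length[tree$edge.length == 0] <- eps_frac * height
  }
  tree
}

.match_tips <- function(tree, values_names) {
  tips <- gsub(" ", "_", tree$tip.label)
  vals <- gsub(" ", "_", values_names)
  idx <- match(tips, vals)
  if (anyNA(idx))
    stop("tip(s) without trait value: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Felsenstein's phylogenetically independent contrasts
#'
#' Standardized contrasts by the pruning algorithm: at each internal node
#' joining children with values x1, x2 on (adjusted) branch lengths v1, v2,
#' the contrast is `(x1 - x2) / sqrt(v1 + v2)`, the ancestral value is the
#' precision-weighted mean, and the parent branch is lengthened by
#' `v1 * v2 / (v1 + v2)`. Multifurcations are resolved to bifurcations with
#' near-zero internal branches first. Computation delegates to
#' [ape::pic()].
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param trait Numeric vector named by species (tip labels).
#' @return A list of class `contrast_set`: `contrasts` (one per internal
#'   node, named by node id), `node_ids`, `df` (= number of contrasts).
#' @export
independent_contrasts <- function(tree, trait) {
  tree <- .prep_tree(tree)
  if (is.null(names(trait)))
    stop("trait must be named by species", call. = FALSE)
  x <- trait[.match_tips(tree, names(trait))]
  if (any(!is.finite(x)))
    stop("trait has non-finite values", call. = FALSE)
  pics <- ape::pic(unname(x), tree, scaled = TRUE)
  structure(list(contrasts = pics, node_ids = as.integer(names(pics)),
                 df = length(pics)),
            class = "contrast_set")
}

# contrasts are linear in tip values: build the (ntip-1) x ntip operator once
# so thousands of traits reduce to one matrix product
.pic_operator <- function(tree) {
  tree <- .prep_tree(tree)
  n <- length(tree$tip.label)
  L <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    ape::pic(e, tree, scaled = TRUE)
  }, numeric(n - 1L))
  colnames(L) <- tree$tip.label
  L
}

#' Pearson correlation forced through the origin
#'
#' Uncentered correlation appropriate for independent contrasts (whose
#' expectation is zero by construction):
#' `r = sum(u * v) / sqrt(sum(u^2) * sum(v^2))`, with a two-sided p-value
#' from the t transform on `length(u) - 1` degrees of freedom (one slope
#' estimated, no intercept).
#'
#' @param u,v Numeric contrast vectors (or `contrast_set` objects) of equal
#'   length >= 2, in the same node order.
#' @return A list with `r`, `p`, `df`.
#' @export
corr_through_origin <- function(u, v) {
  if (inherits(u, "contrast_set")) u <- u$contrasts
  if (inherits(v, "contrast_set")) v <- v$contrasts
  if (length(u) != length(v))
    stop("contrast vectors must have equal length", call. = FALSE)
  if (length(u) < 2L) stop("need at least 2 contrasts", call. = FALSE)
  su <- sum(u^2); sv <- sum(v^2)
  if (su == 0 || sv == 0)
    stop("undefined correlation: all-zero contrast vector", call. = FALSE)
  r <- sum(u * v) / sqrt(su * sv)
  df <- length(u) - 1L
  list(r = r, p = .r_to_p(r, df), df = df)
}

#' Confound- and phylogeny-corrected family associations
#'
#' The full correction pipeline: (1) residualize the target phenotype and
#' every family's sizes against the same covariates by multivariate OLS
#' across species; (2) transform both residual vectors into independent
#' contrasts on the tree; (3) correlate the contrasts through the origin,
#' per family, with BH adjustment across families. The residualization comes
#' first, then the contrasts — the order is part of the method.
#'
#' @param matrix GFS matrix (families x species).
#' @param table A `phenotype_table` covering the same species.
#' @param tree An [ape::phylo] tree whose tips are the same species.
#' @param target Trait to test (`"nr"`, `"ei"` or `"mlsp"`).
#' @param covariates Character vector of confound traits (default the two
#'   traits other than `target`).
#' @return A data.frame with columns `family_id`, `r`, `p`, `q`, `n`
#'   (number of contrasts). Families whose residuals are identically zero
#'   (no size variance) are `NA`.
#' @export
corrected_association <- function(matrix, table, tree, target = "nr",
                                  covariates = setdiff(c("nr", "ei", "mlsp"),
                                                       target)) {
  if (target %in% covariates)
    stop("target '", target, "' cannot be one of its own covariates",
         call. = FALSE)
  species <- gsub(" ", "_", tree$tip.label)
  msp <- gsub(" ", "_", colnames(matrix))
  tsp <- gsub(" ", "_", table$species)
  if (!setequal(species, msp) || !setequal(species, tsp))
    stop("species sets of matrix, phenotype table and tree differ",
         call. = FALSE)
  M <- matrix[, match(species, msp), drop = FALSE]
  tab <- table[match(species, tsp), , drop = FALSE]
  y <- tab[[target]]
  X <- as.matrix(tab[, covariates, drop = FALSE])
  qx <- .checked_qr(.design_matrix(X, n = length(y)))
  y_res <- qr.resid(qx, y)
  G_res <- qr.resid(qx, t(M))          # species x families
  L <- .pic_operator(tree)
  u <- as.vector(L %*% y_res)
  V <- L %*% G_res                     # contrasts x families
  su <- sum(u^2)
  if (su == 0)
    stop("target residuals carry no variation", call. = FALSE)
  sv <- colSums(V^2)
  ok <- sv > 0
  r <- rep(NA_real_, ncol(V))
  r[ok] <- as.vector(crossprod(u, V[, ok, drop = FALSE])) /
    sqrt(su * sv[ok])
  df <- nrow(V) - 1L
  p <- ifelse(is.na(r), NA_real_, .r_to_p(r, df))
  data.frame(family_id = rownames(matrix), r = r, p = p, q = bh_fdr(p),
             n = rep(nrow(V), length(r)), stringsAsFactors = FALSE)
}
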