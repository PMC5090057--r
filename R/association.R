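#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with positive
#'   variance.
#' @return A list with elements `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  r <- cor(x, y)
  list(r = r, p = .r_to_p(r, n - 2L), n = n)
}

# two-sided p from the t transform of r at the given df
.r_to_p <- function(r, df) {
  r2 <- pmin(r * r, 1)
  tstat <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tstat, df, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  pmin(p, 1)
}

#' Per-family correlations between gene family size and a phenotype
#'
#' Computes the Pearson correlation of each family's size vector with a
#' species-aligned phenotype, with two-sided t-based p-values and BH-adjusted
#' q-values over all families jointly.
#'
#' @param matrix Integer GFS matrix (rows = families, columns = species),
#'   ideally pre-filtered with [filter_families()].
#' @param phenotype Numeric vector named by species, aligned to (or
#'   alignable with) the matrix columns.
#' @param absent_policy `"zero"` (default) scores species without members as
#'   size 0; `"drop"` restricts each family to species with size > 0, so `n`
#'   varies by family. Families left with fewer than 3 species or zero
#'   variance under `"drop"` are reported as `NA` (with a warning) and are
#'   excluded from the joint BH correction.
#' @return A data.frame with columns `family_id`, `r`, `p`, `q`, `n`.
#' @export
family_associations <- function(matrix, phenotype,
                                absent_policy = c("zero", "drop")) {
  absent_policy <- match.arg(absent_policy)
  phenotype <- .align_phenotype(matrix, phenotype)
  if (var(phenotype) == 0)
    stop("undefined correlation: constant phenotype", call. = FALSE)
  n_sp <- ncol(matrix)
  fam <- rownames(matrix)
  if (absent_policy == "zero") {
    r <- .cor_rows(matrix, phenotype)
    n <- rep(n_sp, nrow(matrix))
    p <- ifelse(is.na(r), NA_real_, .r_to_p(r, n_sp - 2L))
  } else {
    r <- p <- rep(NA_real_, nrow(matrix))
    n <- integer(nrow(matrix))
    for (i in seq_len(nrow(matrix))) {
      keep <- matrix[i, ] > 0
      n[i] <- sum(keep)
      if (n[i] < 3L) next
      x <- matrix[i, keep]
      y <- phenotype[keep]
      if (var(x) == 0 || var(y) == 0) next
      r[i] <- cor(x, y)
      p[i] <- .r_to_p(r[i], n[i] - 2L)
    }
    if (anyNA(r))
      warning(sum(is.na(r)),
              " famil(ies) with undefined correlation under 'drop' policy",
              " reported as NA")
  }
  data.frame(family_id = fam, r = r, p = p, q = bh_fdr(p), n = n,
             stringsAsFactors = FALSE)
}

.align_phenotype <- function(matrix, phenotype) {
  if (!is.null(names(phenotype))) {
    missing <- setdiff(colnames(matrix), names(phenotype))
    if (length(missing) > 0L)
      stop("phenotype missing species: ", paste(missing, collapse = ", "),
           call. = FALSE)
    phenotype <- phenotype[colnames(matrix)]
  } else if (length(phenotype) != ncol(matrix)) {
    stop("phenotype length does not match the number of species",
         call. = FALSE)
  }
  if (any(!is.finite(phenotype)))
    stop("phenotype must be finite", call. = FALSE)
  unname(phenotype)
}

# row-wise Pearson r of a matrix against one vector; NA for zero-variance rows
.cor_rows <- function(matrix, y) {
  keep <- apply(matrix, 1L, var) > 0
  r <- rep(NA_real_, nrow(matrix))
  if (any(keep))
    r[keep] <- as.vector(cor(y, t(matrix[keep, , drop = FALSE])))
  r
}

#' Monte-Carlo permutation null for the mean correlation coefficient
#'
#' Builds the null distribution of the mean per-family Pearson correlation
#' under random reassignment of species. Under the default `"joint"` scheme
#' one species permutation is applied to every family per replicate
#' (equivalently, the phenotype is permuted), preserving the inter-family
#' covariance that the distribution-shift Z test relies on; `"per_family"`
#' shuffles every family independently and is provided for sensitivity
#' analysis.
#'
#' @param matrix GFS matrix (families x species).
#' @param phenotype Species-aligned phenotype vector.
#' @param n_replicates Number of Monte-Carlo replicates (default 10000).
#' @param scheme `"joint"` or `"per_family"`.
#' @param seed Integer seed; the same seed reproduces the null exactly.
#' @param exhaustive If `TRUE` (joint scheme, at most 8 species), enumerate
#'   all `n!` species permutations instead of sampling.
#' @return A list of class `null_distribution` with `replicate_means`,
#'   `n_replicates`, `seed`, `scheme`.
#' @export
permutation_null <- function(matrix, phenotype, n_replicates = 10000L,
                             scheme = c("joint", "per_family"), seed = 1L,
                             exhaustive = FALSE) {
  scheme <- match.arg(scheme)
  phenotype <- .align_phenotype(matrix, phenotype)
  if (var(phenotype) == 0)
    stop("undefined correlation: constant phenotype", call. = FALSE)
  usable <- apply(matrix, 1L, var) > 0
  if (!any(usable))
    stop("no family with non-zero size variance", call. = FALSE)
  M <- t(matrix[usable, , drop = FALSE])  # species x families
  n_sp <- nrow(M)
  if (exhaustive) {
    if (scheme != "joint")
      stop("exhaustive enumeration applies to the joint scheme", call. = FALSE)
    if (n_sp > 8L)
      stop("exhaustive enumeration supported for at most 8 species",
           call. = FALSE)
    perms <- .all_permutations(n_sp)
    P <- vapply(perms, function(idx) phenotype[idx], numeric(n_sp))
    means <- rowMeans(cor(P, M))
    return(structure(list(replicate_means = means,
                          n_replicates = length(perms),
                          seed = NA_integer_, scheme = scheme),
                     class = "null_distribution"))
  }
  n_replicates <- .assert_scalar_count(n_replicates, "n_replicates")
  if (n_replicates < 100L)
    warning("fewer than 100 replicates gives an unstable null")
  set.seed(seed)
  means <- numeric(n_replicates)
  if (scheme == "joint") {
    chunk <- 2000L
    done <- 0L
    while (done < n_replicates) {
      k <- min(chunk, n_replicates - done)
      P <- vapply(seq_len(k), function(i) phenotype[sample.int(n_sp)],
                  numeric(n_sp))
      means[done + seq_len(k)] <- rowMeans(cor(P, M))
      done <- done + k
    }
  } else {
    R <- matrix(NA_real_, n_replicates, ncol(M))
    for (j in seq_len(ncol(M))) {
      X <- vapply(seq_len(n_replicates), function(i) M[sample.int(n_sp), j],
                  numeric(n_sp))
      R[, j] <- as.vector(cor(phenotype, X))
    }
    means <- rowMeans(R)
  }
  structure(list(replicate_means = means, n_replicates = n_replicates,
                 seed = seed, scheme = scheme),
            class = "null_distribution")
}

.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' Z-score test for a shift of the correlation distribution
#'
#' Standardizes the observed mean correlation against the permutation null
#' and reports the one-tailed (upper) normal probability together with the
#' empirical rank p-value `(1 + #\{null >= observed\}) / (1 + n_replicates)`.
#'
#' @param observed_mean_r Observed mean of per-family correlations.
#' @param null A `null_distribution` from [permutation_null()].
#' @return A list with `z`, `p_one_tailed`, `p_empirical`.
#' @export
zscore_shift_test <- function(observed_mean_r, null) {
  means <- null$replicate_means
  s <- sd(means)
  if (!is.finite(s) || s == 0)
    stop("degenerate null: zero standard deviation", call. = FALSE)
  z <- (observed_mean_r - mean(means)) / s
  list(z = z,
       p_one_tailed = z_tail_p(z),
       p_empirical = (1 + sum(means >= observed_mean_r)) /
         (1 + length(means)))
}

#' One-tailed upper normal tail probability
#'
#' The p-value convention used by [zscore_shift_test()]: the probability
#' that a standard normal exceeds `z`.
#'
#' @param z Z statistic (vectorized).
#' @return `P(N(0,1) > z)`.
#' @examples
#' z_tail_p(2.225819868)  # ~0.013
#' @export
z_tail_p <- function(z) pnorm(z, lower.tail = FALSE)

#' Sign chi-square for the balance of positive and negative correlations
#'
#' Pearson chi-square (df = 1, no continuity correction) of the observed
#' counts of positive and negative per-family correlations against equal
#' expected counts. Correlations exactly zero are excluded from both counts;
#' `NA` correlations are ignored.
#'
#' @param r Numeric vector of correlations, or a data.frame with an `r`
#'   column as returned by [family_associations()].
#' @return A list with `chi2`, `p`, `n_pos`, `n_neg`.
#' @export
sign_chisq <- function(r) {
  if (is.data.frame(r)) r <- r$r
  r <- r[!is.na(r)]
  n_pos <- sum(r > 0)
  n_neg <- sum(r < 0)
  if (n_pos + n_neg == 0L)
    stop("no non-zero correlations", call. = FALSE)
  ct <- suppressWarnings(chisq.test(c(n_pos, n_neg), p = c(0.5, 0.5),
                                    correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       n_pos = n_pos, n_neg = n_neg)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH false-discovery-rate adjustment, preserving input order.
#' `NA` entries stay `NA` and do not count towards the number of tests.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Vector of adjusted values (q-values) of the same length.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}
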