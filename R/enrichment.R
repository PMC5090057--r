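#' Build a term map with small-term and unannotated buckets
#'
#' Terms linked to at least `min_families` background families are retained
#' as-is. Smaller terms are merged into a single `SMALL_BP` bucket; families
#' with no annotation at all form the `NOT_ANNOTATED` bucket. Each bucket
#' counts as one annotation for its families, so every background family
#' carries at least one annotation after bucketing. The size threshold is
#' applied to the background, not to any test set.
#'
#' @param annotations data.frame with columns `family_id`, `term_id`.
#' @param background Character vector of family ids forming the population.
#'   Annotations of families outside the background are ignored.
#' @param min_families Minimum background families per retained term
#'   (default 200).
#' @return A list of class `term_map`: `term_families` (named list of family
#'   id vectors for retained terms plus buckets), `ann_count` (named integer
#'   vector of annotations per background family), `background`,
#'   `min_families`.
#' @export
build_term_map <- function(annotations, background, min_families = 200L) {
  min_families <- .assert_scalar_count(min_families, "min_families")
  if (length(background) == 0L)
    stop("background must be non-empty", call. = FALSE)
  background <- unique(as.character(background))
  ann <- annotations[annotations$family_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("family_id", "term_id")])
  term_families <- split(ann$family_id, ann$term_id)
  sizes <- lengths(term_families)
  retained <- term_families[sizes >= min_families]
  small <- unique(unlist(term_families[sizes < min_families],
                         use.names = FALSE))
  annotated <- unique(ann$family_id)
  not_annotated <- setdiff(background, annotated)
  if (length(small) > 0L) retained$SMALL_BP <- small
  if (length(not_annotated) > 0L) retained$NOT_ANNOTATED <- not_annotated
  ann_count <- setNames(integer(length(background)), background)
  for (fams in retained) {
    ann_count[fams] <- ann_count[fams] + 1L
  }
  structure(list(term_families = retained, ann_count = ann_count,
                 background = background, min_families = min_families),
            class = "term_map")
}

#' Annotation-density-adjusted family count for a term
#'
#' The number of families of `sample` carrying `term`, divided by the
#' sample's mean number of annotations per family. The adjustment stops
#' samples rich in heavily annotated families from looking enriched for
#' everything.
#'
#' @param sample Character vector of family ids (subset of the map's
#'   background).
#' @param term A retained term id or bucket name present in `map`.
#' @param map A `term_map` from [build_term_map()].
#' @return Non-negative real.
#' @export
adjusted_count <- function(sample, term, map) {
  if (length(sample) == 0L) stop("empty sample", call. = FALSE)
  if (!all(sample %in% map$background))
    stop("sample contains families outside the background", call. = FALSE)
  if (!term %in% names(map$term_families))
    stop("unknown term '", term, "'", call. = FALSE)
  raw <- sum(sample %in% map$term_families[[term]])
  raw / mean(map$ann_count[sample])
}

#' Resampling enrichment test with annotation-density adjustment
#'
#' For every retained term and bucket, compares the density-adjusted family
#' count in `test_set` with its distribution over `n_samples` equally sized
#' random samples drawn without replacement from the background. The
#' empirical one-sided p-value uses the add-one correction
#' `(1 + #\{null >= observed\}) / (1 + n_samples)` (non-strict inequality),
#' so it can never be zero; BH adjustment is applied across all reported
#' terms including the buckets.
#'
#' @param test_set Character vector of family ids, subset of the background.
#' @param background Character vector of family ids; must match the map's
#'   background.
#' @param map A `term_map` from [build_term_map()].
#' @param n_samples Number of random samples (default 1000).
#' @param seed Integer seed.
#' @return A data.frame with columns `term`, `n_background`,
#'   `observed_adjusted`, `null_mean`, `p`, `q`.
#' @export
enrichment_test <- function(test_set, background, map, n_samples = 1000L,
                            seed = 1L) {
  n_samples <- .assert_scalar_count(n_samples, "n_samples")
  test_set <- unique(as.character(test_set))
  if (length(test_set) == 0L) stop("empty test set", call. = FALSE)
  if (!setequal(background, map$background))
    stop("background does not match the term map", call. = FALSE)
  background <- map$background
  if (!all(test_set %in% background))
    stop("test set contains families outside the background", call. = FALSE)
  if (length(test_set) > length(background))
    stop("test set larger than background", call. = FALSE)
  terms <- names(map$term_families)
  n_bg <- length(background)
  k <- length(test_set)
  # terms x families incidence
  Tm <- vapply(map$term_families,
               function(f) as.numeric(background %in% f),
               numeric(n_bg))                 # families x terms
  a <- as.numeric(map$ann_count[background])
  obs_ind <- as.numeric(background %in% test_set)
  observed <- as.vector(crossprod(Tm, obs_ind)) / (sum(a * obs_ind) / k)
  set.seed(seed)
  S <- matrix(0, n_bg, n_samples)
  for (i in seq_len(n_samples)) S[sample.int(n_bg, k), i] <- 1
  counts <- crossprod(Tm, S)                  # terms x samples
  dens <- as.vector(crossprod(a, S)) / k      # mean annotations per sample
  null_adj <- sweep(counts, 2L, dens, "/")
  p <- (1 + rowSums(null_adj >= observed)) / (1 + n_samples)
  data.frame(term = terms,
             n_background = as.integer(colSums(Tm)),
             observed_adjusted = observed,
             null_mean = rowMeans(null_adj),
             p = p,
             q = bh_fdr(p),
             stringsAsFactors = FALSE)
}

#' Jaccard index of two sets
#'
#' @param a,b Vectors treated as sets; their union must be non-empty.
#' @return `|a intersect b| / |a union b|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("both sets are empty", call. = FALSE)
  length(intersect(a, b)) / u
}
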