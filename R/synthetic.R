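#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule (pure-birth) tree rescaled to unit height, tips labelled
#' `sp1 ... spN`. Being a realized birth process scaled to a common depth,
#' the tree is ultrametric, as required by the contrast machinery.
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer seed; the same seed reproduces the tree.
#' @return An [ape::phylo] tree of unit height.
#' @export
simulate_tree <- function(n_tips, seed = 1L) {
  n_tips <- .assert_scalar_count(n_tips, "n_tips", min = 3L)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- paste0("sp", seq_len(n_tips))
  tree
}

#' Default Brownian covariance of the three latent brain traits
#'
#' Per-unit-height Brownian (co)variances for (latent log neocortex ratio,
#' encephalization index, log maximum lifespan). Standard deviations
#' (0.5, 0.8, 0.5) give realistic spreads across a unit-height tree
#' (neocortex ratios roughly 0.2-5, encephalization indices roughly -4-0),
#' and the positive correlations (0.6 between ratio and encephalization,
#' 0.4 elsewhere) reproduce the identifiability challenge the correction
#' stage is designed for: encephalization tracks the neocortex ratio without
#' causing the planted family effects.
#'
#' @return A 3x3 positive-definite matrix with dimnames
#'   `(nr_latent, ei, mlsp_log)`.
#' @export
default_trait_covariance <- function() {
  sds <- c(nr_latent = 0.5, ei = 0.8, mlsp_log = 0.5)
  corr <- matrix(c(1, 0.6, 0.4,
                   0.6, 1, 0.4,
                   0.4, 0.4, 1), 3L, 3L)
  cov <- corr * tcrossprod(sds)
  dimnames(cov) <- list(names(sds), names(sds))
  cov
}

#' Simulate correlated Brownian brain phenotypes on a tree
#'
#' Draws (latent log neocortex ratio, encephalization index, log maximum
#' lifespan) as correlated Brownian motion along the branches, then maps
#' the ratio and lifespan through `exp()` to their positive scales. Brain
#' and neocortex volumes are back-computed from the ratio, so
#' [compute_nr()] on the volumes returns the simulated ratio exactly.
#'
#' @param tree An [ape::phylo] tree (tips become the species).
#' @param covariance 3x3 symmetric positive-definite Brownian covariance of
#'   (nr_latent, ei, mlsp_log) per unit branch length.
#' @param root Root states of the three latent traits.
#' @param seed Integer seed.
#' @return A `phenotype_table` with one row per tip.
#' @export
simulate_traits <- function(tree, covariance = default_trait_covariance(),
                            root = c(nr_latent = 0.3, ei = -2,
                                     mlsp_log = 3),
                            seed = 1L) {
  if (!isSymmetric(unname(covariance)))
    stop("covariance must be symmetric", call. = FALSE)
  ch <- tryCatch(chol(covariance),
                 error = function(e) stop("covariance must be positive",
                                          " definite", call. = FALSE))
  set.seed(seed)
  C <- ape::vcv(tree)
  n <- nrow(C)
  Z <- matrix(rnorm(n * 3L), n, 3L)
  X <- t(chol(C)) %*% Z %*% ch
  X <- sweep(X, 2L, root[c("nr_latent", "ei", "mlsp_log")], "+")
  nr <- exp(X[, 1L])
  brain <- 50 * exp(X[, 1L] / 2)      # volumes loosely track the ratio
  neo <- brain * nr / (1 + nr)
  df <- data.frame(species = rownames(C),
                   brain_volume = brain,
                   neocortex_volume = neo,
                   nr = nr,
                   ei = X[, 2L],
                   mlsp = exp(X[, 3L]),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  validate_phenotypes(df)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Simulate a gene-family-size matrix with planted phenotype effects
#'
#' Family sizes are Poisson (optionally negative-binomial) counts with
#' log-mean `a_j + beta_j * z(Nr_i) + eps_ij`: `a_j` is a per-family
#' baseline, `z(Nr)` the across-species standardization of the neocortex
#' ratio, `beta_j = beta` for a planted fraction of families and 0
#' otherwise, and `eps` Brownian noise on the tree, which makes even
#' unplanted families phylogenetically autocorrelated.
#'
#' @param table A `phenotype_table` (provides the neocortex ratio).
#' @param tree The generating tree (same species).
#' @param n_families Number of families (>= 10).
#' @param frac_planted Fraction of families given the planted effect.
#' @param beta Planted effect size on the log scale (>= 0).
#' @param baseline_log_mean Mean of per-family baselines (default `log(5)`).
#' @param baseline_sd Spread of per-family baselines (default 0.3).
#' @param phylo_noise_sd Brownian noise scale per unit height (default 0.5).
#' @param overdispersion Negative-binomial size parameter; `NULL` (default)
#'   keeps pure Poisson counts.
#' @param seed Integer seed.
#' @return A list with `matrix` (integer GFS matrix) and `truth`, a
#'   `synthetic_truth` list holding `planted_family_ids`, `beta`, `seeds`.
#' @export
simulate_gfs <- function(table, tree, n_families = 1000L,
                         frac_planted = 0.1, beta = 1.5,
                         baseline_log_mean = log(5), baseline_sd = 0.3,
                         phylo_noise_sd = 0.5, overdispersion = NULL,
                         seed = 1L) {
  n_families <- .assert_scalar_count(n_families, "n_families", min = 10L)
  .assert_prob(frac_planted, "frac_planted")
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  species <- gsub(" ", "_", tree$tip.label)
  nr <- trait_vector(table, "nr", species)
  z <- as.vector(scale(nr))
  set.seed(seed)
  fam_ids <- sprintf("F%05d", seq_len(n_families))
  n_planted <- round(frac_planted * n_families)
  planted <- sort(sample(fam_ids, n_planted))
  beta_j <- setNames(numeric(n_families), fam_ids)
  beta_j[planted] <- beta
  a_j <- rnorm(n_families, baseline_log_mean, baseline_sd)
  n_sp <- length(species)
  Lc <- t(chol(ape::vcv(tree)))
  eps <- Lc %*% matrix(rnorm(n_sp * n_families), n_sp) * phylo_noise_sd
  log_mu <- outer(z, beta_j) + eps            # species x families
  log_mu <- sweep(log_mu, 2L, a_j, "+")
  mu <- exp(log_mu)
  draw <- if (is.null(overdispersion)) {
    rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), mu = mu, size = overdispersion)
  }
  sizes <- matrix(as.integer(draw), n_sp, n_families,
                  dimnames = list(species, fam_ids))
  truth <- structure(list(planted_family_ids = planted, beta = beta,
                          planted_terms = character(0),
                          expression_effect = NA_real_,
                          seeds = list(gfs = seed)),
                     class = "synthetic_truth")
  list(matrix = t(sizes), truth = truth)
}

#' Simulate GO-style annotations with planted over-representation
#'
#' Assigns each term a random set of families; planted terms oversample
#' planted families by the factor `planted_bias`, and a fraction of
#' families is left unannotated (they end in the `NOT_ANNOTATED` bucket of
#' [build_term_map()]).
#'
#' @param matrix GFS matrix whose rownames are the family population.
#' @param truth A `synthetic_truth` (provides planted family ids).
#' @param n_terms Number of terms.
#' @param term_size_range Two-element range of families per term.
#' @param n_planted_terms Number of terms biased towards planted families.
#' @param planted_bias Sampling weight multiplier (> 1 plants signal; 1
#'   means no bias).
#' @param unannotated_frac Fraction of families left without any term.
#' @param seed Integer seed.
#' @return A list with `annotations` (data.frame `family_id`, `term_id`)
#'   and the updated `truth` (field `planted_terms`).
#' @export
simulate_annotations <- function(matrix, truth, n_terms = 25L,
                                 term_size_range = c(200L, 350L),
                                 n_planted_terms = 3L, planted_bias = 4,
                                 unannotated_frac = 0.1, seed = 1L) {
  n_terms <- .assert_scalar_count(n_terms, "n_terms")
  n_planted_terms <- .assert_scalar_count(n_planted_terms,
                                          "n_planted_terms", min = 0L)
  if (n_planted_terms > n_terms)
    stop("n_planted_terms exceeds n_terms", call. = FALSE)
  if (planted_bias <= 0) stop("planted_bias must be > 0", call. = FALSE)
  .assert_prob(unannotated_frac, "unannotated_frac")
  families <- rownames(matrix)
  set.seed(seed)
  n_unann <- round(unannotated_frac * length(families))
  unannotated <- sample(families, n_unann)
  annotatable <- setdiff(families, unannotated)
  if (max(term_size_range) > length(annotatable))
    stop("term_size_range exceeds the number of annotatable families",
         call. = FALSE)
  term_ids <- sprintf("GO:%07d", seq_len(n_terms))
  planted_terms <- term_ids[seq_len(n_planted_terms)]
  w <- ifelse(annotatable %in% truth$planted_family_ids, planted_bias, 1)
  pairs <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    s <- sample(seq.int(term_size_range[1L], term_size_range[2L]), 1L)
    prob <- if (term_ids[t] %in% planted_terms) w else NULL
    fams <- sample(annotatable, s, prob = prob)
    pairs[[t]] <- data.frame(family_id = fams, term_id = term_ids[t],
                             stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, pairs)
  rownames(annotations) <- NULL
  truth$planted_terms <- planted_terms
  truth$seeds$annotations <- seed
  list(annotations = annotations, truth = truth)
}

#' Developmental stages emulating a cortical transcriptome atlas
#'
#' Thirteen ages (three prenatal, expressed as negative years relative to
#' birth via `(pcw - 40) / 52`, and ten postnatal) and eleven cortical
#' regions; their product gives the 143-sample layout of the atlas the
#' expression contrast is designed for.
#' @return List with `ages` (years) and `regions`.
#' @export
atlas_design <- function() {
  list(ages = c((c(16, 24, 37) - 40) / 52, 4 / 12,
                1, 3, 8, 13, 19, 21, 30, 36, 37),
       regions = c("A1C", "DFC", "IPC", "ITC", "M1C", "MFC",
                   "OFC", "S1C", "STC", "V1C", "VFC"))
}

#' Simulate developmental cortical expression with a planted early boost
#'
#' One sample per (age, region) pair; per-gene log-normal baselines with
#' log-normal sample noise. Genes belong to planted families
#' (`n_genes_per_family` each, plus optional background families), and all
#' genes of planted families are multiplied by `early_multiplier` in
#' samples at or before 13 years of age.
#'
#' @param truth A `synthetic_truth` (provides planted family ids).
#' @param n_genes_per_family Genes simulated per family.
#' @param ages Sample ages in years; must span both sides of 13.
#' @param regions Region labels.
#' @param early_multiplier Expression multiplier (>= 1) applied to planted
#'   genes in the early window; 1 plants no signal.
#' @param background_families Optional extra (unplanted) family ids to
#'   simulate unboosted genes for.
#' @param noise_sd Log-scale sample noise (default 0.4).
#' @param seed Integer seed.
#' @return An `expression_dataset` with an extra element `gene_families`
#'   (named character vector mapping gene id to family id).
#' @export
simulate_expression <- function(truth, n_genes_per_family = 2L,
                                ages = atlas_design()$ages,
                                regions = atlas_design()$regions,
                                early_multiplier = 1.5,
                                background_families = NULL,
                                noise_sd = 0.4, seed = 1L) {
  if (early_multiplier < 1)
    stop("early_multiplier must be >= 1", call. = FALSE)
  if (length(unique(ages)) < 2L || !any(ages <= 13) || !any(ages > 13))
    stop("ages must span both sides of the 13-year cutoff", call. = FALSE)
  n_genes_per_family <- .assert_scalar_count(n_genes_per_family,
                                             "n_genes_per_family")
  fams <- c(truth$planted_family_ids, background_families)
  planted_gene <- rep(fams %in% truth$planted_family_ids,
                      each = n_genes_per_family)
  gene_fam <- rep(fams, each = n_genes_per_family)
  gene_ids <- paste0(gene_fam, "_g",
                     sequence(rep(n_genes_per_family, length(fams))))
  design <- expand.grid(region = regions, age = ages,
                        stringsAsFactors = FALSE)
  sample_ids <- sprintf("%s_a%03d", design$region,
                        seq_along(design$age))
  set.seed(seed)
  n_g <- length(gene_ids)
  n_s <- nrow(design)
  baseline <- exp(rnorm(n_g, 2, 1))
  values <- baseline * exp(matrix(rnorm(n_g * n_s, 0, noise_sd), n_g, n_s))
  early <- design$age <= 13
  values[planted_gene, early] <- values[planted_gene, early] *
    early_multiplier
  dimnames(values) <- list(gene_ids, sample_ids)
  meta <- data.frame(sample_id = sample_ids, age_years = design$age,
                     region = design$region, stringsAsFactors = FALSE)
  structure(list(values = values, meta = meta,
                 gene_families = setNames(gene_fam, gene_ids)),
            class = "expression_dataset")
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper producing every pipeline input with known ground
#' truth at the package's documented default conditions ("paperlike"
#' preset: 28 species, 1000 families of which 10% carry a planted
#' neocortex-ratio effect of 1.5 on the log scale, 25 annotation terms of
#' which 3 are biased towards planted families, and a 1.5-fold early
#' developmental expression boost). Component seeds are derived from `seed`
#' by fixed small offsets so any stage can be regenerated in isolation.
#'
#' @param seed Integer master seed.
#' @param n_tips,n_families,frac_planted,beta,early_multiplier Override the
#'   preset conditions.
#' @param ... Passed on to [simulate_gfs()].
#' @return A list with `tree`, `phenotypes`, `gfs`, `annotations`,
#'   `expression`, `truth`.
#' @export
simulate_bundle <- function(seed = 1L, n_tips = 28L, n_families = 1000L,
                            frac_planted = 0.1, beta = 1.5,
                            early_multiplier = 1.5, ...) {
  tree <- simulate_tree(n_tips, seed = seed + 1L)
  phenotypes <- simulate_traits(tree, seed = seed + 2L)
  gfs <- simulate_gfs(phenotypes, tree, n_families = n_families,
                      frac_planted = frac_planted, beta = beta,
                      seed = seed + 3L, ...)
  # term sizes scale with the family count (20-35% of families per term,
  # i.e. 200-350 at the 1000-family preset)
  size_range <- pmax(2L, round(c(0.2, 0.35) * n_families))
  ann <- simulate_annotations(gfs$matrix, gfs$truth,
                              term_size_range = size_range,
                              seed = seed + 4L)
  n_bg <- min(length(ann$truth$planted_family_ids),
              n_families - length(ann$truth$planted_family_ids))
  bg_fams <- head(setdiff(rownames(gfs$matrix),
                          ann$truth$planted_family_ids), n_bg)
  expr <- simulate_expression(ann$truth,
                              early_multiplier = early_multiplier,
                              background_families = bg_fams,
                              seed = seed + 5L)
  truth <- ann$truth
  truth$expression_effect <- early_multiplier
  truth$seeds <- list(master = seed, tree = seed + 1L, traits = seed + 2L,
                      gfs = seed + 3L, annotations = seed + 4L,
                      expression = seed + 5L)
  list(tree = tree, phenotypes = phenotypes, gfs = gfs$matrix,
       annotations = ann$annotations, expression = expr, truth = truth)
}
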