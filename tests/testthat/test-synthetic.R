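test_that("simulated trees are ultrametric, unit height and seeded", {
  tree <- simulate_tree(28, seed = 4)
  expect_equal(ape::Ntip(tree), 28L)
  expect_true(is_ultrametric(tree))
  expect_equal(max(ape::node.depth.edgelength(tree)), 1)
  expect_identical(ape::write.tree(tree),
                   ape::write.tree(simulate_tree(28, seed = 4)))
  expect_false(identical(ape::write.tree(tree),
                         ape::write.tree(simulate_tree(28, seed = 5))))
  expect_equal(simulate_tree(3, seed = 1)$Nnode, 2L)
  expect_error(simulate_tree(2), ">= 3")
})

test_that("trait simulation respects the Brownian covariance scaling", {
  tree <- simulate_tree(12, seed = 8)
  t1 <- simulate_traits(tree, seed = 3)
  expect_identical(t1, simulate_traits(tree, seed = 3))
  # volumes are consistent with the simulated ratio by construction
  expect_equal(compute_nr(t1$brain_volume, t1$neocortex_volume), t1$nr,
               tolerance = 1e-12)
  # scaling the covariance by c scales the latent deviations by sqrt(c)
  t4 <- simulate_traits(tree, covariance = 4 * default_trait_covariance(),
                        seed = 3)
  root <- c(nr_latent = 0.3, ei = -2, mlsp_log = 3)
  expect_equal(log(t4$nr) - root["nr_latent"],
               2 * (log(t1$nr) - root["nr_latent"]),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(simulate_traits(tree, covariance = matrix(1, 3, 3)),
               "positive")
})

test_that("independent traits give contrasts uncorrelated across traits", {
  tree <- simulate_tree(20, seed = 11)
  L <- neogfs:::.pic_operator(tree)
  cov0 <- diag(c(0.25, 0.64, 0.25))
  dimnames(cov0) <- list(c("nr_latent", "ei", "mlsp_log"),
                         c("nr_latent", "ei", "mlsp_log"))
  cors <- vapply(1:200, function(i) {
    tt <- simulate_traits(tree, covariance = cov0, seed = 5000 + i)
    cor(L %*% log(tt$nr), L %*% tt$ei)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(200))
})

test_that("GFS simulation plants effects only where declared", {
  tree <- simulate_tree(28, seed = 14)
  ph <- simulate_traits(tree, seed = 15)
  g <- simulate_gfs(ph, tree, n_families = 400, frac_planted = 0.1,
                    beta = 1.5, seed = 16)
  expect_identical(g$matrix,
                   simulate_gfs(ph, tree, n_families = 400,
                                frac_planted = 0.1, beta = 1.5,
                                seed = 16)$matrix)
  expect_equal(length(g$truth$planted_family_ids), 40L)
  expect_true(all(g$truth$planted_family_ids %in% rownames(g$matrix)))
  res <- family_associations(g$matrix,
                             trait_vector(ph, "nr", colnames(g$matrix)))
  planted <- res$family_id %in% g$truth$planted_family_ids
  expect_gt(mean(res$r[planted]), mean(res$r[!planted]))
})

test_that("beta = 0 exchangeable families have sign-balanced correlations", {
  tree <- simulate_tree(28, seed = 24)
  ph <- simulate_traits(tree, seed = 25)
  g <- simulate_gfs(ph, tree, n_families = 600, frac_planted = 0,
                    beta = 0, phylo_noise_sd = 0, seed = 26)
  res <- family_associations(filter_families(g$matrix)$matrix,
                             trait_vector(ph, "nr", colnames(g$matrix)))
  frac_pos <- mean(res$r > 0, na.rm = TRUE)
  expect_lt(abs(frac_pos - 0.5), 3 * sqrt(0.25 / sum(!is.na(res$r))))
})

test_that("annotation simulation biases planted terms as configured", {
  tree <- simulate_tree(28, seed = 34)
  ph <- simulate_traits(tree, seed = 35)
  g <- simulate_gfs(ph, tree, n_families = 500, seed = 36)
  a <- simulate_annotations(g$matrix, g$truth, n_terms = 10,
                            term_size_range = c(80, 120),
                            n_planted_terms = 2, planted_bias = 5,
                            seed = 37)
  expect_identical(a$annotations,
                   simulate_annotations(g$matrix, g$truth, n_terms = 10,
                                        term_size_range = c(80, 120),
                                        n_planted_terms = 2,
                                        planted_bias = 5,
                                        seed = 37)$annotations)
  expect_equal(length(a$truth$planted_terms), 2L)
  planted_fams <- g$truth$planted_family_ids
  freq <- function(term) {
    fams <- a$annotations$family_id[a$annotations$term_id == term]
    mean(fams %in% planted_fams)
  }
  planted_freq <- mean(vapply(a$truth$planted_terms, freq, numeric(1)))
  other <- setdiff(unique(a$annotations$term_id), a$truth$planted_terms)
  other_freq <- mean(vapply(other, freq, numeric(1)))
  expect_gt(planted_freq, other_freq)
  # no bias, no signal
  a1 <- simulate_annotations(g$matrix, g$truth, n_terms = 10,
                             term_size_range = c(80, 120),
                             n_planted_terms = 2, planted_bias = 1,
                             seed = 38)
  fams1 <- a1$annotations$family_id[a1$annotations$term_id %in%
                                      a1$truth$planted_terms]
  expect_lt(abs(mean(fams1 %in% planted_fams) - 0.1), 0.08)
})

test_that("expression simulation reproduces the atlas sample layout", {
  truth <- structure(list(planted_family_ids = c("F1", "F2")),
                     class = "synthetic_truth")
  ds <- simulate_expression(truth, seed = 41)
  expect_equal(ncol(ds$values), 143L)  # 13 ages x 11 regions
  expect_equal(nrow(ds$meta), 143L)
  expect_equal(length(unique(ds$meta$age_years)), 13L)
  expect_equal(length(unique(ds$meta$region)), 11L)
  expect_identical(ds$values, simulate_expression(truth, seed = 41)$values)
  expect_error(simulate_expression(truth, ages = c(1, 2, 3)), "span")
})

test_that("the bundled preset carries a coherent ground truth", {
  b <- simulate_bundle(seed = 6, n_tips = 10, n_families = 30)
  expect_setequal(colnames(b$gfs), b$tree$tip.label)
  expect_setequal(b$phenotypes$species, b$tree$tip.label)
  expect_true(all(b$truth$planted_family_ids %in% rownames(b$gfs)))
  expect_true(all(b$truth$planted_terms %in% b$annotations$term_id))
  expect_true(all(b$expression$gene_families %in% rownames(b$gfs)))
  expect_identical(b$gfs, simulate_bundle(seed = 6, n_tips = 10,
                                          n_families = 30)$gfs)
})
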