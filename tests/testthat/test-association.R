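test_that("pearson_r matches worked examples and the t-transform", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2))$r, -1)
  res <- pearson_r(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$p, 0.104, tolerance = 5e-3)
  # independent route: stats::cor.test on random data
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    ct <- cor.test(x, y)
    res <- pearson_r(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("family associations recover a family equal to the phenotype", {
  m <- tiny_gfs(n_fam = 5, n_sp = 10)
  pheno <- setNames(as.numeric(m[1, ]), colnames(m))
  res <- family_associations(m, pheno)
  expect_equal(res$r[1], 1)
  expect_lt(res$p[1], 0.001)
  expect_true(all(res$n == 10L))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("drop policy reports degenerate families as NA", {
  m <- rbind(F1 = c(5L, 5L, 5L, 0L, 0L, 0L),  # constant once zeros dropped
             F2 = c(1L, 2L, 3L, 4L, 5L, 6L))
  colnames(m) <- paste0("sp", 1:6)
  pheno <- setNames(c(1, 2, 3, 4, 5, 6), colnames(m))
  expect_warning(res <- family_associations(m, pheno, "drop"), "NA")
  expect_true(is.na(res$r[1]))
  expect_equal(res$n[1], 3L)
  expect_equal(res$r[2], 1)
  expect_false(is.na(res$q[2]))
})

test_that("p-values are calibrated on exchangeable null families", {
  set.seed(17)
  n_fam <- 400L
  m <- matrix(rpois(n_fam * 28L, 5), n_fam, 28L,
              dimnames = list(sprintf("F%03d", 1:n_fam), paste0("sp", 1:28)))
  pheno <- setNames(rnorm(28), colnames(m))
  res <- family_associations(filter_families(m)$matrix, pheno)
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / sum(!is.na(res$p)))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("joint permutation null matches exhaustive enumeration", {
  m <- tiny_gfs(n_fam = 3, n_sp = 4)
  pheno <- setNames(c(0.4, 1.1, 2.0, 3.5), colnames(m))
  null <- permutation_null(m, pheno, scheme = "joint", exhaustive = TRUE)
  expect_equal(null$n_replicates, 24L)
  # oracle: enumerate the 24 species permutations directly
  oracle <- vapply(enumerate_perms(4L), function(idx) {
    mean(apply(m, 1L, function(row) cor(row, unname(pheno)[idx])))
  }, numeric(1))
  expect_equal(sort(null$replicate_means), sort(oracle), tolerance = 1e-12)
})

test_that("single-family joint null equals the exact permutation distribution", {
  m <- tiny_gfs(n_fam = 1, n_sp = 5, seed = 8)
  pheno <- setNames(c(2, 5, 1, 4, 3), colnames(m))
  null <- permutation_null(m, pheno, exhaustive = TRUE)
  oracle <- vapply(enumerate_perms(5L),
                   function(idx) cor(m[1, ], unname(pheno)[idx]), numeric(1))
  expect_equal(sort(null$replicate_means), sort(oracle), tolerance = 1e-12)
})

test_that("permutation null is a pure function of its seed", {
  m <- tiny_gfs(n_fam = 4, n_sp = 8)
  pheno <- setNames(rnorm(8), colnames(m))
  n1 <- permutation_null(m, pheno, n_replicates = 300, seed = 10)
  n2 <- permutation_null(m, pheno, n_replicates = 300, seed = 10)
  expect_identical(n1$replicate_means, n2$replicate_means)
  n3 <- permutation_null(m, pheno, n_replicates = 300, seed = 11)
  expect_false(identical(n1$replicate_means, n3$replicate_means))
  expect_error(permutation_null(m, setNames(rep(1, 8), colnames(m)),
                                n_replicates = 300),
               "constant phenotype")
  expect_warning(permutation_null(m, pheno, n_replicates = 99), "unstable")
})

test_that("per-family scheme breaks inter-family covariance but keeps the mean", {
  m <- tiny_gfs(n_fam = 6, n_sp = 10, seed = 2)
  pheno <- setNames(rnorm(10), colnames(m))
  nj <- permutation_null(m, pheno, n_replicates = 2000, seed = 4,
                         scheme = "joint")
  npf <- permutation_null(m, pheno, n_replicates = 2000, seed = 4,
                          scheme = "per_family")
  expect_equal(mean(nj$replicate_means), mean(npf$replicate_means),
               tolerance = 0.05)
  # independent shuffles average away covariance: narrower null of the mean
  expect_lt(sd(npf$replicate_means), sd(nj$replicate_means) + 0.05)
})

test_that("z-score shift test standardizes against the null", {
  null <- structure(list(replicate_means = c(-0.2, -0.1, 0, 0.1, 0.2),
                         n_replicates = 5L, seed = 1L, scheme = "joint"),
                    class = "null_distribution")
  res <- zscore_shift_test(0, null)
  expect_equal(res$z, 0)
  expect_equal(res$p_one_tailed, 0.5)
  expect_equal(res$p_empirical, 4 / 6)
  res2 <- zscore_shift_test(0.3, null)
  expect_equal(res2$z, 0.3 / sd(null$replicate_means))
  expect_equal(res2$p_empirical, 1 / 6)
  degenerate <- null
  degenerate$replicate_means <- rep(0.1, 5)
  expect_error(zscore_shift_test(0.2, degenerate), "zero standard deviation")
})

test_that("sign chi-square counts signs, excludes zeros, ignores order", {
  even <- sign_chisq(c(rep(0.5, 50), rep(-0.5, 50)))
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  lop <- sign_chisq(c(rep(-0.1, 10)))
  expect_equal(lop$chi2, 10)
  expect_equal(lop$p, 2 * pnorm(-sqrt(10)), tolerance = 1e-10)
  r <- c(runif(30, 0.01, 1), runif(12, -1, -0.01), 0, NA)
  a <- sign_chisq(r)
  b <- sign_chisq(sample(r))
  expect_equal(a, b)
  expect_equal(a$n_pos + a$n_neg, 42L)
  expect_error(sign_chisq(c(0, 0, NA)), "non-zero")
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  set.seed(30)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
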