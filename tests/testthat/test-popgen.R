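## Independent Weir-Cockerham oracle: the 1984 variance components
## written out literally for one locus and two populations.
wc_oracle_two_pop <- function(geno1, geno2) {
  n <- c(length(geno1), length(geno2))
  p <- c(mean(geno1) / 2, mean(geno2) / 2)
  h <- c(mean(geno1 == 1), mean(geno2 == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

test_that("pairwise Fst equals the hand-computed Weir-Cockerham value", {
  pop1 <- c(2L, 2L, 2L, 0L)
  pop2 <- c(0L, 0L, 0L, 0L)
  g <- genotype_matrix(matrix(c(pop1, pop2), ncol = 1),
                       data.frame(chrom = "c", pos = 1L),
                       groups = rep(c("p1", "p2"), each = 4))
  expect_equal(pairwise_fst(g)[1, 2], wc_oracle_two_pop(pop1, pop2),
               tolerance = 1e-12)
})

test_that("Fst hits 1 for fixed opposite alleles and <= 0 for identical groups", {
  gfix <- genotype_matrix(rbind(matrix(2L, 5, 10), matrix(0L, 5, 10)),
                          data.frame(chrom = "c", pos = 1:10 * 5L),
                          groups = rep(c("p1", "p2"), each = 5))
  expect_equal(unname(pairwise_fst(gfix)[1, 2]), 1)
  set.seed(3)
  base <- matrix(rbinom(80, 2, 0.4), 8, 10)
  gdup <- genotype_matrix(rbind(base, base),
                          data.frame(chrom = "c", pos = 1:10 * 5L),
                          groups = rep(c("p1", "p2"), each = 8))
  expect_lte(pairwise_fst(gdup)[1, 2], 1e-12)
})

test_that("Fst is invariant to sample order and to allele-label swap", {
  set.seed(5)
  geno <- matrix(rbinom(200, 2, runif(20, 0.2, 0.8)), 10, 20, byrow = TRUE)
  groups <- rep(c("a", "b"), each = 5)
  g <- genotype_matrix(geno, data.frame(chrom = "c", pos = 1:20),
                       groups = groups)
  perm <- sample(10)
  gp <- genotype_matrix(geno[perm, ], data.frame(chrom = "c", pos = 1:20),
                        groups = groups[perm])
  expect_equal(pairwise_fst(g)["a", "b"], pairwise_fst(gp)["a", "b"],
               tolerance = 1e-12)
  gs <- genotype_matrix(2L - geno, data.frame(chrom = "c", pos = 1:20),
                        groups = groups)
  expect_equal(pairwise_fst(g)["a", "b"], pairwise_fst(gs)["a", "b"],
               tolerance = 1e-12)
})

test_that("VanRaden kinship equals the hand example and is PSD", {
  g <- genotype_matrix(matrix(c(0L, 2L), 2, 1),
                       data.frame(chrom = "c", pos = 1L))
  G <- vanraden_kinship(g)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  set.seed(6)
  geno <- matrix(rbinom(600, 2, 0.3), 20, 30)
  geno[sample(600, 30)] <- NA
  g2 <- genotype_matrix(geno, data.frame(chrom = "c", pos = 1:30))
  G2 <- vanraden_kinship(g2)
  expect_equal(G2, t(G2))
  expect_gte(min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  ## duplicated individuals have identical rows and G(i,j) = G(i,i)
  g3 <- genotype_matrix(geno[c(1, 1, 2:20), ],
                        data.frame(chrom = "c", pos = 1:30))
  G3 <- vanraden_kinship(g3)
  expect_equal(G3[1, 2], G3[1, 1], tolerance = 1e-12)
})

test_that("p_distance counts differences over shared loci", {
  g <- toy_genotypes()
  d <- p_distance(g)
  expect_equal(unname(diag(d)), rep(0, 4))
  ## S1 vs S2: loci 1,2,4,5 shared; one difference (locus 5: 1 vs 2)
  expect_equal(d["S1", "S2"], 1 / 4)
  ## identical and fully different constructed pairs
  geno <- rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L), c = c(2L, 0L, 1L))
  g2 <- genotype_matrix(geno, data.frame(chrom = "c", pos = 1:3))
  d2 <- p_distance(g2)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
})

test_that("NJ reproduces the 3-taxon closed form and additive 4-taxon trees", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  ## closed form: v_x = (d_xy + d_xz - d_yz) / 2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["x"]], (5 + 9 - 10) / 2)
  expect_equal(bl[["y"]], (5 + 10 - 9) / 2)
  expect_equal(bl[["z"]], (9 + 10 - 5) / 2)
  ## additive matrix from a known 4-taxon tree
  tree4 <- ape::read.tree(text = "((a:2,b:3):1,(c:4,d:1):2);")
  d4 <- cophenetic(tree4)
  rec <- nj_tree(d4)
  expect_equal(ape::dist.topo(ape::unroot(tree4), ape::unroot(rec)), 0,
               ignore_attr = TRUE)
  expect_equal(sum(rec$edge.length), sum(tree4$edge.length), tolerance = 1e-10)
})

test_that("NJ recovers random additive trees (property over 50 trees)", {
  set.seed(12)
  for (r in 1:50) {
    nt <- sample(4:8, 1)
    tr <- ape::rtree(nt, br = function(n) runif(n, 0.5, 2))
    rec <- nj_tree(cophenetic(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap gives full support to an exactly duplicated taxon pair", {
  set.seed(13)
  geno <- matrix(rbinom(5 * 40, 2, 0.5), 5, 40)
  geno <- rbind(geno, geno[1, ])           # taxon 6 duplicates taxon 1
  g <- genotype_matrix(geno, data.frame(chrom = "c", pos = 1:40))
  d <- p_distance(g)
  expect_equal(d[1, 6], 0)
  tr <- nj_tree(d, boot_geno = g, n_boot = 50, seed = 2)
  pair_node <- ape::getMRCA(tr, c("S1", "S6"))
  expect_equal(tr$node.label[pair_node - ape::Ntip(tr)], 1)
})

test_that("genotype PCA matches an svd oracle and separates the clades", {
  b <- default_bundle()
  bf <- filter_loci(b$geno)
  sc <- genotype_pca(bf, 4)
  m <- bf$geno
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  sv <- svd(sweep(m, 2, mu))
  for (k in 1:4)
    expect_equal(abs(cor(sc[, k], sv$u[, k])), 1, tolerance = 1e-8)
  clade <- rep(rep(1:2, length.out = 9), each = 10)
  sil <- cluster::silhouette(clade, dist(sc[, 1]))
  expect_gt(mean(sil[, "sil_width"]), 0.8)
  expect_error(genotype_pca(bf, nrow(bf$geno)), "n_pcs")
})

test_that("cluster assignment recovers planted clusters and selects k by silhouette", {
  set.seed(14)
  ang <- 2 * pi * (1:5) / 5
  centers <- 15 * cbind(cos(ang), sin(ang))
  truth <- rep(1:5, each = 12)
  scores <- centers[truth, ] + matrix(rnorm(120), 60, 2)
  hits <- 0
  for (rep in 1:10) {
    lab <- assign_clusters(scores, k = 2:8, seed = rep)
    if (attr(lab, "k") == 5) hits <- hits + 1
  }
  expect_gte(hits, 8)
  lab5 <- assign_clusters(scores, k = 5, seed = 1)
  tab <- table(lab5, truth)
  expect_equal(sum(apply(tab, 2, max)), 60)  # perfect up to label permutation
  expect_equal(unname(assign_clusters(scores, k = 1, seed = 1)),
               rep(1L, 60), ignore_attr = TRUE)
  expect_error(assign_clusters(scores, k = 100), "k exceeds")
})
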