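## Shared fixtures. Bundles are generated once per session and cached;
## all randomness is seeded so the suite is deterministic.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## the default-world bundle at desk scale
default_bundle <- function() cached("default_bundle", {
  simulate_dataset(sim_config(n_loci = 1000, n_eas = 10, n_outliers = 10,
                              n_pa_regions = 50, seed = 101))
})

## small genotype matrix fixture built by hand
toy_genotypes <- function() {
  geno <- rbind(S1 = c(0L, 1L, 2L, 0L, 1L),
                S2 = c(0L, 1L, NA, 0L, 2L),
                S3 = c(1L, 0L, 2L, NA, 2L),
                S4 = c(2L, 2L, 0L, 0L, 1L))
  genotype_matrix(geno,
                  data.frame(chrom = "chr1", pos = c(100L, 200L, 350L, 400L, 900L),
                             ref = "A", alt = "T",
                             id = paste0("snp", 1:5)),
                  groups = c("g1", "g1", "g2", "g2"))
}

## island-model allele counts with optionally planted fixed-opposite loci
island_counts <- function(n_loci, n_groups, fst, n_planted = 0,
                          n_per_group = 20, seed = 1) {
  set.seed(seed)
  p0 <- runif(n_loci, 0.1, 0.9)
  pg <- sapply(seq_len(n_groups), function(j) {
    if (fst <= 0) return(p0)
    rbeta(n_loci, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
  })
  if (n_planted > 0)
    for (i in seq_len(n_planted))
      pg[i, ] <- rep(c(0.001, 0.999), length.out = n_groups)
  tot <- matrix(2L * n_per_group, n_loci, n_groups)
  alt <- matrix(rbinom(n_loci * n_groups, 2L * n_per_group, pg),
                n_loci, n_groups)
  ids <- sprintf("L%04d", seq_len(n_loci))
  rownames(alt) <- rownames(tot) <- ids
  list(alt = alt, total = tot, planted = ids[seq_len(n_planted)])
}

## diploid genotypes from explicit haplotype pairs (for LD fixtures)
genotypes_from_haplotypes <- function(hapA1, hapA2, hapB1, hapB2) {
  g <- cbind(hapA1 + hapA2, hapB1 + hapB2)
  genotype_matrix(g, data.frame(chrom = "chr1", pos = c(1L, 2L)))
}

## genotype matrix with planted perfect-LD blocks: each block shares one
## haplotype indicator per sample; blocks are separated by independent draws
planted_block_genotypes <- function(block_sizes, n_samples = 60, seed = 1) {
  set.seed(seed)
  cols <- list()
  for (b in seq_along(block_sizes)) {
    p <- runif(1, 0.3, 0.7)
    h1 <- rbinom(n_samples, 1, p)
    h2 <- rbinom(n_samples, 1, p)
    for (k in seq_len(block_sizes[b])) cols[[length(cols) + 1]] <- h1 + h2
  }
  geno <- do.call(cbind, cols)
  L <- ncol(geno)
  genotype_matrix(geno, data.frame(chrom = "chr1", pos = seq_len(L) * 100L))
}
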