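test_that("perfectly coupled loci give D' = 1 with a high lower bound", {
  set.seed(21)
  h1 <- rbinom(40, 1, 0.5); h2 <- rbinom(40, 1, 0.5)
  g <- genotypes_from_haplotypes(h1, h2, h1, h2)   # only AB / ab haplotypes
  st <- dprime_ci(g$geno[, 1], g$geno[, 2])
  expect_equal(st$dprime, 1, tolerance = 1e-6)
  expect_gt(st$lower, 0.7)
  expect_gt(st$upper, 0.98)
})

test_that("independent equifrequent loci give D' near 0", {
  set.seed(22)
  gA <- rbinom(400, 1, 0.5) + rbinom(400, 1, 0.5)
  gB <- rbinom(400, 1, 0.5) + rbinom(400, 1, 0.5)
  st <- dprime_ci(gA, gB)
  expect_lt(st$dprime, 0.15)
  expect_false(dprime_ci(rep(0L, 30), gB[1:30])$informative)
})

test_that("EM haplotype frequencies match a brute-force likelihood grid search", {
  ## For unphased data the allele frequencies are fixed by the margins,
  ## so the likelihood is one-dimensional in f11: grid-search it.
  set.seed(23)
  for (r in 1:4) {
    hA1 <- rbinom(20, 1, 0.5); hB1 <- ifelse(runif(20) < 0.7, hA1, rbinom(20, 1, 0.5))
    hA2 <- rbinom(20, 1, 0.5); hB2 <- ifelse(runif(20) < 0.7, hA2, rbinom(20, 1, 0.5))
    gA <- hA1 + hA2; gB <- hB1 + hB2
    st <- dprime_ci(gA, gB)
    pA <- mean(gA) / 2; pB <- mean(gB) / 2
    n <- table(factor(gA, 0:2), factor(gB, 0:2))
    grid <- seq(max(0, pA + pB - 1), min(pA, pB), by = 1e-4)
    ll <- vapply(grid, function(f11) {
      f10 <- pA - f11; f01 <- pB - f11; f00 <- 1 - pA - pB + f11
      f <- pmax(c(f00, f01, f10, f11), 1e-12)
      probs <- matrix(c(f[1]^2, 2 * f[1] * f[2], f[2]^2,
                        2 * f[1] * f[3], 2 * (f[1] * f[4] + f[2] * f[3]),
                        2 * f[2] * f[4],
                        f[3]^2, 2 * f[3] * f[4], f[4]^2), 3, byrow = TRUE)
      sum(n * log(probs))
    }, 0)
    f11_grid <- grid[which.max(ll)]
    ## the engine reports the D-positive orientation (allele labels at
    ## the second locus swapped when D < 0): undo the flip if needed
    f11_em <- unname(st$hap_freq["f11"])
    if (f11_grid - pA * pB < 0) f11_em <- pA - f11_em
    expect_lt(abs(f11_em - f11_grid), 2e-3)
  }
})

test_that("gabriel_blocks handles the all-strong and all-recombinant limits", {
  g_strong <- planted_block_genotypes(5, n_samples = 80, seed = 31)
  part <- gabriel_blocks(g_strong, window = 10)
  expect_equal(nrow(part$blocks), 1)
  expect_equal(part$blocks$size, 5)
  expect_equal(part$n_independent_tests, 1)
  set.seed(32)
  g_free <- genotype_matrix(matrix(rbinom(80 * 6, 1, 0.5) +
                                     rbinom(80 * 6, 1, 0.5), 80, 6),
                            data.frame(chrom = "c", pos = 1:6 * 50L))
  part2 <- gabriel_blocks(g_free, window = 10)
  expect_equal(nrow(part2$blocks), 0)
  expect_equal(sort(part2$singletons), 1:6)
  expect_error(gabriel_blocks(g_free, window = 1), "window")
})

test_that("planted 12-locus partition equals the exhaustive max-coverage search", {
  ## two perfect blocks (loci 1-5 and 9-12) separated by free loci
  g <- planted_block_genotypes(c(5, 1, 1, 1, 4), n_samples = 80, seed = 33)
  part <- gabriel_blocks(g, window = 12)
  ## oracle: candidate predicate computed pair-by-pair through the
  ## exported single-pair interface, then exhaustive search over all
  ## families of disjoint candidates maximizing covered loci
  L <- 12
  strong <- matrix(FALSE, L, L); informative <- matrix(FALSE, L, L)
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    st <- dprime_ci(g$geno[, i], g$geno[, j])
    informative[i, j] <- st$informative
    strong[i, j] <- st$informative && st$upper > 0.98 && st$lower > 0.7
  }
  cands <- list()
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    pr <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    inside <- pr[pr[, 1] >= i & pr[, 2] <= j, , drop = FALSE]
    n_inf <- sum(informative[inside])
    n_str <- sum(strong[inside])
    if (strong[i, j] && n_inf > 0 && n_str / n_inf >= 0.95)
      cands[[length(cands) + 1]] <- i:j
  }
  best <- 0
  n_c <- length(cands)
  for (mask in 0:(2^n_c - 1)) {
    sel <- cands[bitwAnd(mask, 2^(seq_len(n_c) - 1)) > 0]
    loci <- unlist(sel)
    if (!anyDuplicated(loci)) best <- max(best, length(loci))
  }
  covered <- sum(part$blocks$size)
  expect_equal(covered, best)
  expect_equal(part$blocks$first, c(1, 9))
  expect_equal(part$blocks$last, c(5, 12))
})

test_that("every locus lands in exactly one block or singleton (40 random fixtures)", {
  set.seed(34)
  for (r in 1:40) {
    sizes <- sample(1:4, sample(2:4, 1), replace = TRUE)
    g <- planted_block_genotypes(sizes, n_samples = 40, seed = 100 + r)
    part <- gabriel_blocks(g, window = 8)
    covered <- unlist(mapply(seq, part$blocks$first, part$blocks$last,
                             SIMPLIFY = FALSE))
    expect_equal(sort(c(covered, part$singletons)), seq_len(ncol(g$geno)))
    expect_equal(part$n_independent_tests,
                 nrow(part$blocks) + length(part$singletons))
  }
})

test_that("raising min_strong_fraction never increases block coverage", {
  g <- simulate_dataset(sim_config(n_loci = 60, n_eas = 0, n_outliers = 0,
                                   missing_rate = 0, seed = 35))$geno
  cov <- sapply(c(0.5, 0.8, 0.95, 1), function(ms)
    sum(gabriel_blocks(g, window = 20, min_strong_fraction = ms)$blocks$size))
  expect_true(all(diff(cov) <= 0))
})

test_that("planted block boundaries are recovered", {
  hits <- 0; total <- 0
  for (r in 1:5) {
    sizes <- c(4, 1, 3, 1, 5)
    g <- planted_block_genotypes(sizes, n_samples = 80, seed = 200 + r)
    part <- gabriel_blocks(g, window = 14)
    bounds <- cumsum(sizes)
    starts <- c(1, head(bounds, -1) + 1)
    planted <- cbind(starts[sizes >= 2], bounds[sizes >= 2])
    for (k in seq_len(nrow(planted))) {
      total <- total + 1
      ok <- any(abs(part$blocks$first - planted[k, 1]) <= 1 &
                  abs(part$blocks$last - planted[k, 2]) <= 1)
      if (ok) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("the LD-corrected Bonferroni threshold divides alpha by the test count", {
  fake <- structure(list(blocks = data.frame(first = 1, last = 2, size = 2),
                         singletons = 3:7, n_independent_tests = 6),
                    class = "ld_block_partition")
  expect_equal(ld_bonferroni(fake, 0.1), 0.1 / 6)
  expect_equal(ld_bonferroni(654 + 80, 0.1), 0.1 / 734)
  expect_equal(ld_bonferroni(1, 0.1), 0.1)
  expect_equal(ld_bonferroni(15, 0.1), 0.1 / 15)
})
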