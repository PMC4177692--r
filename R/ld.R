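## Pairwise D' with likelihood-profile confidence bounds from unphased
## genotypes, Gabriel-method LD blocks, and the LD-corrected Bonferroni
## threshold.

## Vectorized two-locus EM + CI engine. `pairs` is a 2-column matrix of
## locus indices into g$geno. Returns one row per pair. The confidence
## interval of |D'| comes from the normalized likelihood profile over a
## |D'| grid with allele frequencies held at their EM estimates
## (Gabriel/Haploview convention, 90% interval = 5% in each tail).
pair_ld_stats <- function(g, pairs, confidence = 0.90, grid_step = 0.005,
                          maf_min = 0.05, min_joint = 20) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  K <- nrow(pairs)
  GA <- g$geno[, pairs[, 1], drop = FALSE]
  GB <- g$geno[, pairs[, 2], drop = FALSE]
  joint <- !is.na(GA) & !is.na(GB)
  GA[!joint] <- -1L; GB[!joint] <- -1L
  n <- list()
  for (a in 0:2) for (b in 0:2)
    n[[paste0(a, b)]] <- colSums(GA == a & GB == b)
  N <- colSums(joint)
  ## EM for haplotype frequencies f00 f01 f10 f11 (allele = alt count)
  f00 <- f01 <- f10 <- f11 <- rep(0.25, K)
  base00 <- 2 * n[["00"]] + n[["01"]] + n[["10"]]
  base01 <- 2 * n[["02"]] + n[["01"]] + n[["12"]]
  base10 <- 2 * n[["20"]] + n[["10"]] + n[["21"]]
  base11 <- 2 * n[["22"]] + n[["21"]] + n[["12"]]
  nhh <- n[["11"]]
  tot <- pmax(2 * N, 1)
  for (it in 1:100) {
    den <- f00 * f11 + f01 * f10
    pc <- ifelse(den > 0, f00 * f11 / den, 0.5)
    f00 <- (base00 + nhh * pc) / tot
    f01 <- (base01 + nhh * (1 - pc)) / tot
    f10 <- (base10 + nhh * (1 - pc)) / tot
    f11 <- (base11 + nhh * pc) / tot
  }
  pA <- f10 + f11
  pB <- f01 + f11
  D <- f11 - pA * pB
  ## orient so D >= 0 (swap allele labels at locus B)
  neg <- D < 0
  if (any(neg)) {
    tmp <- f00[neg]; f00[neg] <- f01[neg]; f01[neg] <- tmp
    tmp <- f10[neg]; f10[neg] <- f11[neg]; f11[neg] <- tmp
    pB[neg] <- 1 - pB[neg]
    nb <- n
    for (a in 0:2) {
      t0 <- nb[[paste0(a, 0)]][neg]
      nb[[paste0(a, 0)]][neg] <- nb[[paste0(a, 2)]][neg]
      nb[[paste0(a, 2)]][neg] <- t0
    }
    n <- nb
    D[neg] <- -D[neg]
  }
  dmax <- pmin(pA * (1 - pB), (1 - pA) * pB)
  dprime <- ifelse(dmax > 0, pmin(D / dmax, 1), 0)
  mafA <- pmin(pA, 1 - pA)
  mafB <- pmin(pB, 1 - pB)
  informative <- N >= min_joint & mafA >= maf_min & mafB >= maf_min
  ## likelihood profile over |D'|
  grid <- seq(0, 1, by = grid_step)
  ll <- matrix(-Inf, K, length(grid))
  eps <- 1e-12
  for (gi in seq_along(grid)) {
    h11 <- grid[gi] * dmax + pA * pB
    h10 <- pA - h11; h01 <- pB - h11; h00 <- 1 - pA - pB + h11
    h00 <- pmax(h00, eps); h01 <- pmax(h01, eps)
    h10 <- pmax(h10, eps); h11 <- pmax(h11, eps)
    ll[, gi] <- n[["00"]] * (2 * log(h00)) +
      n[["01"]] * log(2 * h00 * h01) + n[["02"]] * (2 * log(h01)) +
      n[["10"]] * log(2 * h00 * h10) +
      n[["11"]] * log(2 * (h00 * h11 + h01 * h10)) +
      n[["12"]] * log(2 * h01 * h11) + n[["20"]] * (2 * log(h10)) +
      n[["21"]] * log(2 * h10 * h11) + n[["22"]] * (2 * log(h11))
  }
  w <- exp(ll - apply(ll, 1, max))
  cum <- t(apply(w, 1, cumsum)) / rowSums(w)
  tail_p <- (1 - confidence) / 2
  lower <- grid[max.col(cum > tail_p, ties.method = "first")]
  upper <- grid[max.col(cum >= 1 - tail_p, ties.method = "first")]
  lower <- pmin(lower, dprime)
  upper <- pmax(upper, dprime)
  data.frame(i = pairs[, 1], j = pairs[, 2], dprime = dprime,
             lower = lower, upper = upper, informative = informative,
             n_joint = N, f00 = f00, f01 = f01, f10 = f10, f11 = f11)
}

#' D' with confidence bounds for one locus pair
#'
#' Two-locus EM over unphased genotypes resolves double-heterozygote
#' phase; D' = D / Dmax from the EM haplotype frequencies, and the
#' confidence bounds of |D'| come from the normalized profile of the
#' two-locus multinomial likelihood over a |D'| grid.
#'
#' @param gA,gB genotype vectors (0/1/2/NA) over shared samples.
#' @param confidence two-sided interval level (default 0.90, i.e. 5%
#'   in each tail, the Gabriel convention).
#' @return list: `dprime`, `lower`, `upper`, `informative`, and the EM
#'   haplotype frequencies `hap_freq` (f00, f01, f10, f11 on the
#'   D-positive orientation).
#' @export
dprime_ci <- function(gA, gB, confidence = 0.90) {
  stopifnot(length(gA) == length(gB))
  g <- genotype_matrix(cbind(gA, gB),
                       data.frame(chrom = "x", pos = 1:2))
  mono <- function(v) length(unique(v[!is.na(v)])) < 2
  st <- pair_ld_stats(g, cbind(1L, 2L), confidence = confidence)
  if (mono(gA) || mono(gB)) st$informative <- FALSE
  list(dprime = st$dprime, lower = st$lower, upper = st$upper,
       informative = st$informative,
       hap_freq = c(f00 = st$f00, f01 = st$f01, f10 = st$f10, f11 = st$f11))
}

#' Gabriel-method LD block partition
#'
#' Pairwise D' confidence bounds are computed for locus pairs within a
#' sliding window of `window` markers on the same chromosome. A
#' candidate block is a contiguous run whose outermost pair shows
#' strong LD (lower bound > `strong[2]`, upper bound > `strong[1]`) and
#' in which at least `min_strong_fraction` of the informative pairs are
#' strong. Overlapping candidates are resolved greedily, largest first
#' (ties to the leftmost). Remaining loci are singletons.
#'
#' @param g a [genotype_matrix] with loci sorted by position.
#' @param window sliding-window width in markers (default 500).
#' @param strong `c(upper_cut, lower_cut)`: strong LD requires CI upper
#'   > `strong[1]` (default 0.98) and CI lower > `strong[2]` (0.7).
#' @param recomb_upper pairs with CI upper below this (default 0.9)
#'   show strong evidence of recombination.
#' @param min_strong_fraction minimum fraction of informative pairs in
#'   a block that must be strong (default 0.95).
#' @param maf_min,min_joint informativeness cutoffs for a pair.
#' @return list of class `ld_block_partition`: `blocks` (data.frame
#'   first/last locus index and size), `singletons` (locus indices),
#'   `n_independent_tests` = #blocks + #singletons, `pair_stats`.
#' @export
gabriel_blocks <- function(g, window = 500, strong = c(0.98, 0.7),
                           recomb_upper = 0.9, min_strong_fraction = 0.95,
                           maf_min = 0.05, min_joint = 20) {
  if (window < 2) stop("window must be at least 2 markers")
  L <- ncol(g$geno)
  chrom <- g$loci$chrom
  pairs <- which(outer(seq_len(L), seq_len(L),
                       function(i, j) j > i & j - i < window &
                         chrom[i] == chrom[j]),
                 arr.ind = TRUE)
  if (!nrow(pairs)) {
    part <- list(blocks = data.frame(first = integer(0), last = integer(0),
                                     size = integer(0)),
                 singletons = seq_len(L), n_independent_tests = L,
                 pair_stats = NULL)
    class(part) <- "ld_block_partition"
    return(part)
  }
  st <- pair_ld_stats(g, pairs[, c(1, 2)], maf_min = maf_min,
                      min_joint = min_joint)
  is_strong <- matrix(FALSE, L, L)
  is_inf <- matrix(FALSE, L, L)
  idx <- cbind(st$i, st$j)
  is_inf[idx] <- st$informative
  is_strong[idx] <- st$informative & st$upper > strong[1] & st$lower > strong[2]
  ## candidate blocks
  cand <- list()
  for (i in seq_len(L - 1)) {
    n_inf <- 0; n_str <- 0
    jmax <- min(L, i + window - 1)
    for (j in (i + 1):jmax) {
      if (chrom[j] != chrom[i]) break
      rng <- i:(j - 1)
      n_inf <- n_inf + sum(is_inf[rng, j])
      n_str <- n_str + sum(is_strong[rng, j])
      if (is_strong[i, j] && n_inf > 0 && n_str / n_inf >= min_strong_fraction)
        cand[[length(cand) + 1]] <- c(i, j)
    }
  }
  covered <- rep(FALSE, L)
  blocks <- data.frame(first = integer(0), last = integer(0), size = integer(0))
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    sz <- cm[, 2] - cm[, 1] + 1
    ord <- order(-sz, cm[, 1])
    for (k in ord) {
      rng <- cm[k, 1]:cm[k, 2]
      if (!any(covered[rng])) {
        covered[rng] <- TRUE
        blocks <- rbind(blocks, data.frame(first = cm[k, 1], last = cm[k, 2],
                                           size = length(rng)))
      }
    }
    blocks <- blocks[order(blocks$first), ]
    rownames(blocks) <- NULL
  }
  singles <- which(!covered)
  part <- list(blocks = blocks, singletons = singles,
               n_independent_tests = nrow(blocks) + length(singles),
               pair_stats = st)
  class(part) <- "ld_block_partition"
  part
}

#' @export
print.ld_block_partition <- function(x, ...) {
  cat("ld_block_partition:", nrow(x$blocks), "blocks,",
      length(x$singletons), "singletons ->",
      x$n_independent_tests, "independent tests\n")
  invisible(x)
}

#' LD-corrected Bonferroni threshold
#'
#' The per-test significance threshold is the target number of false
#' associations (default 0.1, one in ten) divided by the number of
#' independent tests, i.e. blocks plus singleton loci.
#'
#' @param partition an `ld_block_partition` (or a bare count of
#'   independent tests).
#' @param alpha_target tolerated expected false associations.
#' @return per-test p-value threshold.
#' @export
ld_bonferroni <- function(partition, alpha_target = 0.1) {
  n <- if (inherits(partition, "ld_block_partition"))
    partition$n_independent_tests else as.numeric(partition)
  stopifnot(n >= 1)
  alpha_target / n
}
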