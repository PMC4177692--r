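## Core population-genetic statistics: Weir-Cockerham Fst, VanRaden
## kinship, uncorrected-P distances, NJ trees with bootstrap, genotype
## PCA and k-means cluster assignment.

## Weir-Cockerham (1984) per-locus variance components for the samples
## of the populations listed in `groups`. Returns a 3 x n_loci matrix of
## (a, b, c). Loci where fewer than two populations have >= 2 non-missing
## calls get zero components (they contribute nothing to the ratio of
## sums).
wc_components <- function(geno, group_of) {
  pops <- unique(group_of)
  r_all <- length(pops)
  n <- sapply(pops, function(g) colSums(!is.na(geno[group_of == g, , drop = FALSE])))
  p <- sapply(pops, function(g)
    colMeans(geno[group_of == g, , drop = FALSE], na.rm = TRUE) / 2)
  h <- sapply(pops, function(g)
    colMeans(geno[group_of == g, , drop = FALSE] == 1L, na.rm = TRUE))
  n <- matrix(n, ncol = r_all); p <- matrix(p, ncol = r_all)
  h <- matrix(h, ncol = r_all)
  p[is.nan(p)] <- 0; h[is.nan(h)] <- 0
  use <- n >= 2
  r <- rowSums(use)
  nsum <- rowSums(n * use)
  nbar <- nsum / pmax(r, 1)
  ok <- r >= 2 & nbar > 1
  a <- b <- cc <- numeric(nrow(n))
  if (any(ok)) {
    nu <- n * use; pu <- p * use; hu <- h * use
    n2 <- rowSums(nu^2)
    nc <- (nsum - n2 / nsum) / (r - 1)
    pbar <- rowSums(nu * pu) / nsum
    s2 <- rowSums(nu * (pu - pbar)^2 * use) / ((r - 1) * nbar)
    hbar <- rowSums(nu * hu) / nsum
    a_ <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_ <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_ <- hbar / 2
    a[ok] <- a_[ok]; b[ok] <- b_[ok]; cc[ok] <- c_[ok]
  }
  rbind(a = a, b = b, c = cc)
}

#' Multilocus Weir-Cockerham Fst
#'
#' Pairwise (or overall) Weir-Cockerham theta combined across loci as a
#' ratio of sums, theta = sum(a) / sum(a + b + c), with missing calls
#' excluded per locus. Raw values are reported, so slight negatives are
#' possible (and expected for undifferentiated pairs). A pair that is
#' monomorphic at every usable locus yields `NA`.
#'
#' @param g a [genotype_matrix] with group labels.
#' @param overall if `TRUE` also return the single multi-population
#'   estimate over all groups.
#' @return symmetric matrix of pairwise theta (diagonal 0); when
#'   `overall = TRUE`, the matrix carries the all-populations estimate
#'   in attribute `"overall"`.
#' @export
pairwise_fst <- function(g, overall = FALSE) {
  pops <- unique(g$groups)
  if (length(pops) < 2) stop("need at least two groups")
  np <- length(pops)
  th <- matrix(0, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    sel <- g$groups %in% pops[c(i, j)]
    comp <- wc_components(g$geno[sel, , drop = FALSE], g$groups[sel])
    denom <- sum(comp)
    th[i, j] <- th[j, i] <- if (denom == 0) NA_real_ else sum(comp["a", ]) / denom
  }
  if (overall) {
    comp <- wc_components(g$geno, g$groups)
    attr(th, "overall") <- sum(comp["a", ]) / sum(comp)
  }
  th
}

#' VanRaden genomic relationship matrix
#'
#' G = Z Z' / (2 sum_k p_k (1 - p_k)) with Z = M - 2p, where M is the
#' dosage matrix and p the observed alternate-allele frequencies.
#' Monomorphic loci are dropped; missing dosages are replaced by 2p
#' (mean imputation) for this computation only.
#'
#' @param g a [genotype_matrix].
#' @return symmetric positive semi-definite samples x samples matrix.
#' @export
vanraden_kinship <- function(g) {
  p <- allele_freq(g)
  keep <- !is.nan(p) & p > 0 & p < 1
  if (!any(keep)) stop("all loci are monomorphic; kinship undefined")
  m <- g$geno[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(m, 2, 2 * p)
  z[is.na(z)] <- 0          # missing dosage -> 2p, i.e. centered 0
  gmat <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(gmat) <- list(g$samples, g$samples)
  gmat
}

#' Uncorrected-P distance matrix
#'
#' d(i, j) = number of differing genotype codes / number of loci
#' non-missing in both samples. Pairs sharing no loci get `NA`.
#'
#' @param g a [genotype_matrix].
#' @return symmetric samples x samples matrix in \[0, 1\].
#' @export
p_distance <- function(g) {
  m <- g$geno
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(g$samples, g$samples))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      shared <- !is.na(xi) & !is.na(m[j, ])
      ns <- sum(shared)
      d[i, j] <- d[j, i] <-
        if (ns == 0) NA_real_ else sum(xi[shared] != m[j, shared]) / ns
    }
  }
  d
}

#' Neighbour-joining tree with optional locus bootstrap
#'
#' Canonical Saitou-Nei neighbour joining (via \pkg{ape}). When a
#' genotype matrix is supplied, loci are resampled with replacement
#' `n_boot` times, the distance and topology recomputed, and per-split
#' support fractions attached as `node.label`.
#'
#' @param dist complete symmetric distance matrix (>= 3 taxa).
#' @param boot_geno optional [genotype_matrix] whose samples match the
#'   taxa of `dist`, used for bootstrapping.
#' @param n_boot bootstrap replicates (0 = none).
#' @param seed RNG seed for resampling.
#' @param dist_fun distance recomputed on each resample (default
#'   [p_distance()]).
#' @return an \pkg{ape} `phylo`; with bootstrap, internal `node.label`
#'   holds support fractions in \[0, 1\].
#' @export
nj_tree <- function(dist, boot_geno = NULL, n_boot = 0, seed = 1L,
                    dist_fun = p_distance) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3) stop("need at least three taxa")
  if (anyNA(dist)) stop("distance matrix has missing entries; impute before NJ")
  tree <- ape::nj(stats::as.dist(dist))
  if (n_boot > 0) {
    stopifnot(!is.null(boot_geno))
    set.seed(seed)
    reps <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(boot_geno$geno), replace = TRUE)
      ## bypass the constructor: resampling duplicates loci on purpose
      resampled <- boot_geno
      resampled$geno <- boot_geno$geno[, idx, drop = FALSE]
      resampled$loci <- boot_geno$loci[idx, , drop = FALSE]
      reps[[b]] <- ape::nj(stats::as.dist(dist_fun(resampled)))
    }
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- counts / n_boot
  }
  tree
}

#' Leading principal components of the genotype matrix
#'
#' Dosages are mean-imputed per locus and centered; components come
#' from the singular value decomposition. Scores are the usual Q
#' covariates for structure-aware association.
#'
#' @param g a [genotype_matrix].
#' @param n_pcs number of components (must be < min(samples, loci)).
#' @param standardize divide each locus by its sd after centering.
#' @return samples x n_pcs score matrix with attribute `"var_frac"`.
#' @export
genotype_pca <- function(g, n_pcs = 5, standardize = FALSE) {
  if (n_pcs >= min(dim(g$geno))) stop("n_pcs must be < min(samples, loci)")
  m <- g$geno
  mu <- colMeans(m, na.rm = TRUE)
  for (j in which(colSums(is.na(m)) > 0)) m[is.na(m[, j]), j] <- mu[j]
  m <- sweep(m, 2, mu)
  if (standardize) {
    s <- apply(m, 2, stats::sd)
    m <- sweep(m, 2, pmax(s, 1e-12), `/`)
  }
  sv <- svd(m, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(scores) <- list(g$samples, paste0("PC", seq_len(n_pcs)))
  attr(scores, "var_frac") <- (sv$d^2 / sum(sv$d^2))[seq_len(n_pcs)]
  scores
}

#' k-means cluster assignment on PCA scores
#'
#' Replaces admixture-model Bayesian clustering as the cryptic-cluster
#' engine: k-means on genotype PC scores with multiple restarts and a
#' fixed seed. When `k` is a vector, the value maximizing the mean
#' silhouette width is selected.
#'
#' @param scores samples x components score matrix.
#' @param k cluster count, or a vector of candidate counts (default 2:8
#'   scanning around the expected five clusters).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return integer labels with attributes `"k"` and `"silhouette"`
#'   (mean width per candidate k, `NA` for k = 1).
#' @export
assign_clusters <- function(scores, k = 5, seed = 1L, nstart = 25) {
  scores <- as.matrix(scores)
  if (max(k) > nrow(scores)) stop("k exceeds the number of samples")
  set.seed(seed)
  sil <- stats::setNames(rep(NA_real_, length(k)), k)
  fits <- vector("list", length(k))
  for (i in seq_along(k)) {
    if (k[i] == 1) {
      fits[[i]] <- list(cluster = rep(1L, nrow(scores)))
    } else {
      fits[[i]] <- stats::kmeans(scores, centers = k[i], nstart = nstart)
      sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster,
                                         stats::dist(scores))[, "sil_width"])
    }
  }
  best <- if (length(k) == 1) 1 else which.max(sil)
  labels <- fits[[best]]$cluster
  names(labels) <- rownames(scores)
  attr(labels, "k") <- k[best]
  attr(labels, "silhouette") <- sil
  labels
}
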