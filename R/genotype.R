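#' Genotype matrix container
#'
#' Holds a samples x loci matrix of biallelic genotype dosages coded
#' 0/1/2 (copies of the alternate allele) with `NA` for missing calls,
#' together with per-locus coordinates (1-based) and per-sample group
#' labels. Loci are kept sorted by (chrom, pos); duplicated positions
#' are rejected.
#'
#' @param geno integer matrix, samples in rows, loci in columns; values
#'   in \{0, 1, 2, NA\}.
#' @param loci data.frame with columns `chrom`, `pos`, and optionally
#'   `ref`, `alt`, `id`.
#' @param samples character vector of sample identifiers (row names).
#' @param groups group label per sample (coerced to character).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, loci, samples = rownames(geno), groups = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno)))
  if (is.null(groups)) groups <- rep("all", nrow(geno))
  stopifnot(nrow(loci) == ncol(geno), length(samples) == nrow(geno),
            length(groups) == nrow(geno))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(loci)))
    stop("loci must have columns 'chrom' and 'pos'")
  if (is.null(loci$ref)) loci$ref <- "A"
  if (is.null(loci$alt)) loci$alt <- "T"
  if (is.null(loci$id)) loci$id <- paste0(loci$chrom, "_", loci$pos)
  loci$chrom <- as.character(loci$chrom)
  loci$ref <- as.character(loci$ref)
  loci$alt <- as.character(loci$alt)
  loci$id <- as.character(loci$id)
  loci <- loci[, c("chrom", "pos", "ref", "alt", "id",
                   setdiff(names(loci), c("chrom", "pos", "ref", "alt", "id")))]
  ord <- order(loci$chrom, loci$pos)
  if (is.unsorted(ord)) {
    warning("loci were not sorted by (chrom, pos); sorting")
    loci <- loci[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
  }
  if (anyDuplicated(paste(loci$chrom, loci$pos)))
    stop("duplicate (chrom, pos) among loci: ",
         paste(loci$chrom, loci$pos)[anyDuplicated(paste(loci$chrom, loci$pos))])
  rownames(geno) <- samples
  colnames(geno) <- loci$id
  rownames(loci) <- NULL
  structure(list(geno = geno, loci = loci,
                 samples = as.character(samples),
                 groups = as.character(groups)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "loci;",
      length(unique(x$groups)), "groups;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (logical/integer); `j` locus index.
#' @param j locus index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  genotype_matrix(x$geno[i, j, drop = FALSE], x$loci[j, , drop = FALSE],
                  samples = x$samples[i], groups = x$groups[i])
}

#' Per-locus alternate-allele frequency over non-missing calls
#' @param g a `genotype_matrix`.
#' @return numeric vector, one entry per locus (NaN when fully missing).
#' @export
allele_freq <- function(g) colMeans(g$geno, na.rm = TRUE) / 2

#' Per-locus minor allele frequency
#' @inheritParams allele_freq
#' @export
maf <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

#' Filter loci by minor allele frequency and call rate
#'
#' Retains loci with a non-missing fraction of at least `call_rate_min`
#' and a minor allele frequency (over non-missing calls) of at least
#' `maf_min`. Both cutoffs are inclusive, so a 10-sample locus carrying
#' exactly one copy of the minor allele (MAF 0.05) survives `maf_min =
#' 0.05`. Locus order is preserved.
#'
#' @param g a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency in \[0, 0.5\].
#' @param call_rate_min minimum non-missing fraction.
#' @return The filtered `genotype_matrix`. An empty result warns, it is
#'   not an error.
#' @export
filter_loci <- function(g, maf_min = 0.05, call_rate_min = 0.80) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, call_rate_min >= 0, call_rate_min <= 1)
  call_rate <- colMeans(!is.na(g$geno))
  keep <- call_rate >= call_rate_min & maf(g) >= maf_min & !is.nan(maf(g))
  if (!any(keep)) warning("no loci pass the filters")
  g[, keep]
}
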