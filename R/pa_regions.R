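## Presence/absence coverage regions: calling, merging, Jaccard
## distances, TE enrichment, and the group-level NJ tree.

#' Call presence/absence bins from binned coverage
#'
#' A bin is P/A iff (a) every sample of each absent group has exactly
#' zero reads, and (b) at least one other group has a mean per-sample
#' count of at least `min_presence_mean`. Bins absent in all groups or
#' present in all groups are not P/A.
#'
#' @param cov a `bin_coverage`.
#' @param groups group label per coverage sample column.
#' @param min_presence_mean mean reads/sample required of at least one
#'   presence group (default 1; see the methods vignette for why the
#'   much larger depth rule sometimes quoted for GBS is exposed as a
#' parameter rather than hard-coded).
#' @return list: `pa` logical per bin, `presence` bins x groups 0/1
#'   matrix (1 = reads present in that group), `bins` the bin table.
#' @export
call_pa_bins <- function(cov, groups, min_presence_mean = 1) {
  stopifnot(length(groups) == ncol(cov$counts))
  glev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  if (any(!glev %in% groups))
    stop("group with zero samples: ", paste(setdiff(glev, groups), collapse = ", "))
  gsum0 <- sapply(glev, function(g)
    rowSums(cov$counts[, groups == g, drop = FALSE] == 0L))
  gmean <- sapply(glev, function(g)
    rowMeans(cov$counts[, groups == g, drop = FALSE]))
  nsamp <- table(groups)[glev]
  absent <- sweep(gsum0, 2, as.numeric(nsamp), `==`)     # all-zero group
  qualified <- !absent & gmean >= min_presence_mean      # presence with depth
  n_abs <- rowSums(absent)
  pa <- n_abs >= 1 & n_abs <= length(glev) - 1 & rowSums(qualified) >= 1
  presence <- 1L - absent
  colnames(presence) <- glev
  list(pa = pa, presence = presence, bins = cov$bins)
}

#' Merge adjacent P/A bins into regions
#'
#' Adjacent P/A bins on the same chromosome with identical
#' group-presence patterns merge into one region; a change of pattern
#' starts a new region.
#'
#' @param pa_bins output of [call_pa_bins()].
#' @return list of class `pa_region_set`: `regions` (chrom, start, end,
#'   0-based half-open), `group_presence` (groups x regions 0/1),
#'   `summary` (count, mean length, length sd).
#' @export
merge_pa_regions <- function(pa_bins) {
  idx <- which(pa_bins$pa)
  if (!length(idx)) {
    return(structure(list(regions = data.frame(chrom = character(0),
                                               start = integer(0), end = integer(0)),
                          group_presence = matrix(0L, ncol(pa_bins$presence), 0,
                                                  dimnames = list(colnames(pa_bins$presence), NULL)),
                          summary = c(n = 0, mean_length = NA, sd_length = NA)),
                     class = "pa_region_set"))
  }
  b <- pa_bins$bins[idx, , drop = FALSE]
  pat <- apply(pa_bins$presence[idx, , drop = FALSE], 1, paste, collapse = "")
  new_run <- c(TRUE, !(b$chrom[-1] == b$chrom[-nrow(b)] &
                         b$start[-1] == b$end[-nrow(b)] &
                         pat[-1] == pat[-length(pat)]))
  run <- cumsum(new_run)
  run <- factor(run, levels = unique(run))  # keep genomic order, not lexicographic
  regions <- data.frame(chrom = as.vector(tapply(b$chrom, run, `[`, 1)),
                        start = as.integer(tapply(b$start, run, min)),
                        end = as.integer(tapply(b$end, run, max)),
                        stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  pres <- t(pa_bins$presence[idx[!duplicated(run)], , drop = FALSE])
  colnames(pres) <- NULL
  len <- regions$end - regions$start
  structure(list(regions = regions, group_presence = pres,
                 summary = c(n = nrow(regions), mean_length = mean(len),
                             sd_length = stats::sd(len))),
            class = "pa_region_set")
}

#' Jaccard distance between binary presence profiles
#'
#' d(i, j) = 1 - |intersection| / |union| over regions, ignoring joint
#' absences (shared-states-only logic). Two all-zero rows have an empty
#' union; their distance is defined as 0 with a warning.
#'
#' @param group_presence groups x regions binary matrix.
#' @return symmetric groups x groups distance matrix.
#' @export
jaccard_distance <- function(group_presence) {
  m <- as.matrix(group_presence)
  stopifnot(all(m %in% c(0, 1)))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- sum(m[i, ] & m[j, ])
    uni <- sum(m[i, ] | m[j, ])
    if (uni == 0) {
      warning("two all-zero presence rows; distance set to 0")
      d[i, j] <- d[j, i] <- 0
    } else d[i, j] <- d[j, i] <- 1 - inter / uni
  }
  d
}

#' TE-masked fraction of the genome, of P/A bins, and of matched controls
#'
#' Computes masked bp / total bp for (i) all genome bins, (ii) the bins
#' inside P/A regions, and (iii) an equally sized control set of non-P/A
#' bins sampled uniformly without replacement with the given seed.
#'
#' @param pa a `pa_region_set`.
#' @param mask GRanges of merged TE intervals (see [read_te_mask()]).
#' @param genome_bins data.frame chrom/start/end of all bins (0-based
#'   half-open).
#' @param seed RNG seed for the control draw.
#' @return named numeric: `genome`, `pa`, `control` masked fractions.
#' @export
te_enrichment <- function(pa, mask, genome_bins, seed = 1L) {
  gr_bins <- GenomicRanges::GRanges(genome_bins$chrom,
                                    IRanges::IRanges(genome_bins$start + 1L,
                                                     genome_bins$end))
  masked_frac <- function(gr) {
    if (length(gr) == 0) return(0)
    hits <- GenomicRanges::intersect(gr, mask, ignore.strand = TRUE)
    sum(GenomicRanges::width(hits)) / sum(GenomicRanges::width(gr))
  }
  if (length(mask) == 0)
    return(c(genome = 0, pa = 0, control = 0))
  if (nrow(pa$regions) == 0) {
    return(c(genome = masked_frac(GenomicRanges::reduce(gr_bins)), pa = 0,
             control = 0))
  }
  gr_pa <- GenomicRanges::GRanges(pa$regions$chrom,
                                  IRanges::IRanges(pa$regions$start + 1L,
                                                   pa$regions$end))
  in_pa <- IRanges::overlapsAny(gr_bins, gr_pa)
  n_pa_bins <- sum(in_pa)
  if (sum(!in_pa) < n_pa_bins) stop("fewer non-P/A bins than P/A bins")
  set.seed(seed)
  ctrl <- sample(which(!in_pa), n_pa_bins)
  c(genome = masked_frac(GenomicRanges::reduce(gr_bins)),
    pa = masked_frac(GenomicRanges::reduce(gr_bins[in_pa])),
    control = masked_frac(GenomicRanges::reduce(gr_bins[ctrl])))
}

#' NJ tree over groups from P/A presence profiles
#'
#' Neighbour joining on the [jaccard_distance()] matrix, with bootstrap
#' over regions (columns resampled with replacement).
#'
#' @param group_presence groups x regions binary matrix (>= 3 groups).
#' @param n_boot bootstrap replicates (0 = none).
#' @param seed RNG seed.
#' @return an \pkg{ape} `phylo`; with bootstrap, `node.label` holds
#'   support fractions.
#' @export
nj_from_pa <- function(group_presence, n_boot = 0, seed = 1L) {
  m <- as.matrix(group_presence)
  if (nrow(m) < 3) stop("need at least three groups")
  tree <- ape::nj(stats::as.dist(jaccard_distance(m)))
  if (n_boot > 0) {
    set.seed(seed)
    reps <- lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(ncol(m), replace = TRUE)
      ape::nj(stats::as.dist(jaccard_distance(m[, idx, drop = FALSE])))
    })
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- counts / n_boot
  }
  tree
}
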