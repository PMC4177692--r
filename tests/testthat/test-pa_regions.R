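## A tiny hand-built coverage fixture: 3 groups x 2 samples, 6 bins.
toy_coverage <- function() {
  bins <- data.frame(chrom = "chr1", start = 0:5 * 1000L, end = 1:6 * 1000L)
  counts <- rbind(
    c(0L, 0L, 12L, 14L, 9L, 11L),   # bin 1: absent in A, present B, C
    c(0L, 0L, 10L, 12L, 8L, 15L),   # bin 2: same pattern -> merges with 1
    c(0L, 0L, 11L, 9L, 0L, 0L),     # bin 3: absent in A and C
    c(3L, 2L, 4L, 6L, 5L, 2L),      # bin 4: present everywhere
    c(0L, 0L, 0L, 0L, 0L, 0L),      # bin 5: absent everywhere
    c(0L, 1L, 7L, 8L, 6L, 4L))      # bin 6: A has a read -> not all-zero
  bin_coverage(bins, counts)        # rows are bins, columns samples
}
toy_groups <- c("A", "A", "B", "B", "C", "C")

test_that("the P/A bin rule is applied literally", {
  cov <- toy_coverage()
  pb <- call_pa_bins(cov, toy_groups, min_presence_mean = 1)
  expect_equal(pb$pa, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(pb$presence[1, ]), c(0L, 1L, 1L))
  expect_equal(unname(pb$presence[3, ]), c(0L, 1L, 0L))
  expect_error(call_pa_bins(cov, factor(toy_groups, levels = c("A", "B", "C", "D"))),
               "zero samples")
})

test_that("adjacent bins merge only on identical group-presence patterns", {
  pb <- call_pa_bins(toy_coverage(), toy_groups)
  pa <- merge_pa_regions(pb)
  ## bins 1-2 share a pattern -> one region [0, 2000); bin 3 differs
  expect_equal(pa$regions$start, c(0L, 2000L))
  expect_equal(pa$regions$end, c(2000L, 3000L))
  expect_equal(unname(pa$summary["n"]), 2)
  expect_equal(ncol(pa$group_presence), 2)
  ## mean of lengths {1000, 1000, 3000} after a three-region merge
  expect_equal(mean(c(1000, 1000, 3000)), 1666.67, tolerance = 1e-4)
})

test_that("region calling on the synthetic bundle recovers the truth exactly", {
  b <- default_bundle()
  groups <- b$geno$groups[match(colnames(b$coverage$counts), b$geno$samples)]
  pb <- call_pa_bins(b$coverage, groups)
  pa <- merge_pa_regions(pb)
  tr <- b$truth$pa_regions
  expect_equal(nrow(pa$regions), nrow(tr))
  expect_equal(pa$regions$start, tr$start)
  expect_equal(pa$regions$end, tr$end)
  glev <- colnames(pb$presence)
  for (k in seq_len(nrow(tr))) {
    absent <- strsplit(tr$absent_groups[k], ",")[[1]]
    expect_equal(glev[pa$group_presence[, k] == 0], absent)
  }
})

test_that("region -> bin round trip reproduces the per-bin flags", {
  b <- default_bundle()
  groups <- b$geno$groups[match(colnames(b$coverage$counts), b$geno$samples)]
  pb <- call_pa_bins(b$coverage, groups)
  pa <- merge_pa_regions(pb)
  flags <- rep(FALSE, nrow(b$coverage$bins))
  for (k in seq_len(nrow(pa$regions)))
    flags <- flags | (b$coverage$bins$start >= pa$regions$start[k] &
                        b$coverage$bins$end <= pa$regions$end[k])
  expect_equal(flags, pb$pa)
})

test_that("jaccard_distance ignores joint absences", {
  m <- rbind(a = c(1, 1, 0, 1), b = c(1, 0, 0, 1), c = c(0, 0, 0, 0),
             d = c(1, 1, 0, 1))
  expect_warning(d <- jaccard_distance(rbind(c = m[3, ], c2 = m[3, ])),
                 "all-zero")
  d <- jaccard_distance(m[c(1, 2, 4), ])
  expect_equal(d["a", "b"], 1 - 2 / 3, tolerance = 1e-12)
  expect_equal(d["a", "d"], 0)
  disj <- jaccard_distance(rbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1)))
  expect_equal(disj["x", "y"], 1)
})

test_that("te_enrichment handles degenerate masks and a toy genome", {
  bins <- data.frame(chrom = "chr1", start = 0:9 * 1000L, end = 1:10 * 1000L)
  pa <- structure(list(regions = data.frame(chrom = "chr1", start = 0L,
                                            end = 1000L),
                       group_presence = matrix(1, 2, 1)),
                  class = "pa_region_set")
  full_mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  expect_equal(unname(te_enrichment(pa, full_mask, bins, seed = 1)),
               c(1, 1, 1))
  empty <- GenomicRanges::GRanges()
  expect_equal(unname(te_enrichment(pa, empty, bins, seed = 1)), c(0, 0, 0))
  ## mask covers bins 1-2 (bp 1..2000); P/A = bin 1
  mask12 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
  enr <- te_enrichment(pa, mask12, bins, seed = 1)
  expect_equal(unname(enr["pa"]), 1)
  expect_equal(unname(enr["genome"]), 0.2)
  expect_identical(te_enrichment(pa, mask12, bins, seed = 7),
                   te_enrichment(pa, mask12, bins, seed = 7))
})

test_that("synthetic TE densification reproduces the enrichment ordering", {
  b <- default_bundle()
  groups <- b$geno$groups[match(colnames(b$coverage$counts), b$geno$samples)]
  pa <- merge_pa_regions(call_pa_bins(b$coverage, groups))
  enr <- te_enrichment(pa, b$te_mask, b$coverage$bins, seed = 2)
  expect_gt(enr["pa"], enr["genome"])
  expect_gt(enr["genome"], enr["control"])
})

test_that("control masked fraction converges to the non-P/A mean over seeds", {
  b <- default_bundle()
  groups <- b$geno$groups[match(colnames(b$coverage$counts), b$geno$samples)]
  pa <- merge_pa_regions(call_pa_bins(b$coverage, groups))
  ctrl <- vapply(1:100, function(s)
    te_enrichment(pa, b$te_mask, b$coverage$bins, seed = s)["control"], 0)
  ## expected value: masked fraction of all non-P/A bins
  gr_bins <- GenomicRanges::GRanges(b$coverage$bins$chrom,
                                    IRanges::IRanges(b$coverage$bins$start + 1L,
                                                     b$coverage$bins$end))
  gr_pa <- GenomicRanges::GRanges(pa$regions$chrom,
                                  IRanges::IRanges(pa$regions$start + 1L,
                                                   pa$regions$end))
  nonpa <- gr_bins[!IRanges::overlapsAny(gr_bins, gr_pa)]
  hit <- GenomicRanges::intersect(GenomicRanges::reduce(nonpa), b$te_mask)
  target <- sum(GenomicRanges::width(hit)) / sum(GenomicRanges::width(nonpa))
  se <- sd(ctrl) / sqrt(length(ctrl))
  expect_lt(abs(mean(ctrl) - target), 2 * se + 1e-3)
})

test_that("nj_from_pa reproduces the closed form and flags identical groups", {
  pres <- rbind(A = c(1, 1, 1, 0, 0, 1, 0, 1),
                B = c(1, 0, 1, 0, 1, 1, 0, 1),
                C = c(0, 1, 0, 1, 0, 0, 1, 0))
  d <- jaccard_distance(pres)
  tr <- nj_from_pa(pres)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], (d["A", "B"] + d["A", "C"] - d["B", "C"]) / 2)
  pres2 <- rbind(pres, A2 = pres["A", ])
  tr2 <- nj_from_pa(pres2, n_boot = 30, seed = 1)
  d2 <- jaccard_distance(pres2)
  expect_equal(d2["A", "A2"], 0)
  expect_error(nj_from_pa(pres[1:2, ]), "three")
})
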