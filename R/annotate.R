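## Positional classification of significant loci against gene models.

#' Classify loci relative to gene models
#'
#' Each locus gets exactly one class: `genic` if it falls inside any
#' gene (1-based closed span); otherwise `upstream5kb` if it lies
#' within `upstream_bp` of the 5' end of at least one gene on that
#' gene's coding strand (before the start for `+` genes, after the end
#' for `-` genes, excluding the gene body); otherwise `distal`. A locus
#' that is genic for one gene and upstream of another is genic only,
#' and only the genes it is inside are listed; an upstream locus lists
#' every gene whose window contains it.
#'
#' @param loci data.frame with `chrom` and `pos` (1-based).
#' @param genes gene models (id, chrom, start, end, strand), e.g. from
#'   [read_gene_models()].
#' @param upstream_bp width of the upstream window (default 5000, the
#'   usual cis-regulatory reach).
#' @return data.frame: chrom, pos, class, genes (comma-separated ids,
#'   empty for distal).
#' @export
classify_positions <- function(loci, genes, upstream_bp = 5000) {
  stopifnot(all(c("chrom", "pos") %in% names(loci)),
            all(genes$start < genes$end), all(genes$strand %in% c("+", "-")))
  gr_loci <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$pos, width = 1))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end))
  up_start <- ifelse(genes$strand == "+",
                     pmax(1L, genes$start - upstream_bp), genes$end + 1L)
  up_end <- ifelse(genes$strand == "+",
                   genes$start - 1L, genes$end + upstream_bp)
  has_up <- up_end >= up_start
  gr_up <- GenomicRanges::GRanges(genes$chrom[has_up],
                                  IRanges::IRanges(up_start[has_up],
                                                   up_end[has_up]))
  hit_g <- GenomicRanges::findOverlaps(gr_loci, gr_genes)
  hit_u <- GenomicRanges::findOverlaps(gr_loci, gr_up)
  cls <- rep("distal", nrow(loci))
  gene_list <- rep("", nrow(loci))
  up_ids <- genes$id[has_up]
  if (length(hit_u)) {
    qi <- S4Vectors::queryHits(hit_u)
    ids <- tapply(up_ids[S4Vectors::subjectHits(hit_u)], qi,
                  function(x) paste(sort(unique(x)), collapse = ","))
    cls[as.integer(names(ids))] <- "upstream5kb"
    gene_list[as.integer(names(ids))] <- as.vector(ids)
  }
  if (length(hit_g)) {     # genic wins over upstream ("once and genic only")
    qi <- S4Vectors::queryHits(hit_g)
    ids <- tapply(genes$id[S4Vectors::subjectHits(hit_g)], qi,
                  function(x) paste(sort(unique(x)), collapse = ","))
    cls[as.integer(names(ids))] <- "genic"
    gene_list[as.integer(names(ids))] <- as.vector(ids)
  }
  data.frame(chrom = loci$chrom, pos = loci$pos, class = cls,
             genes = gene_list, stringsAsFactors = FALSE)
}

#' Positional summary row (counts and percentages)
#'
#' @param classes character vector of classes from
#'   [classify_positions()], or a named count vector with entries
#'   `distal`, `upstream5kb`, `genic`.
#' @param digits decimals for the percentages (default 0, i.e. the
#'   usual integer table percentages).
#' @return data.frame with one row: counts and percentages per class
#'   plus the total.
#' @export
position_summary <- function(classes, digits = 0) {
  lev <- c("distal", "upstream5kb", "genic")
  cnt <- if (is.character(classes)) {
    as.numeric(table(factor(classes, levels = lev)))
  } else as.numeric(classes[lev])
  total <- sum(cnt)
  if (total == 0)
    return(data.frame(distal = 0, upstream5kb = 0, genic = 0, total = 0,
                      distal_pct = NA, upstream5kb_pct = NA, genic_pct = NA))
  pct <- round(100 * cnt / total, digits)
  data.frame(distal = cnt[1], upstream5kb = cnt[2], genic = cnt[3],
             total = total,
             distal_pct = pct[1], upstream5kb_pct = pct[2], genic_pct = pct[3])
}

#' Per-method gene lists and their cross-method intersections
#'
#' @param loci_by_method named list of loci data.frames (chrom, pos),
#'   one per method (e.g. the two association engines and the outlier
#'   scan).
#' @param genes gene models.
#' @param upstream_bp upstream window width.
#' @return list: `per_method` (named list of unique gene-id vectors),
#'   `classifications` (named list of the per-locus tables), and
#'   `intersections` (data.frame of gene ids shared by each method
#'   pair).
#' @export
gene_lists <- function(loci_by_method, genes, upstream_bp = 5000) {
  cls <- lapply(loci_by_method, classify_positions, genes = genes,
                upstream_bp = upstream_bp)
  per_method <- lapply(cls, function(x) {
    ids <- unlist(strsplit(x$genes[x$genes != ""], ","))
    sort(unique(ids))
  })
  meths <- names(loci_by_method)
  inter <- data.frame()
  if (length(meths) >= 2) {
    pairs <- utils::combn(meths, 2)
    inter <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      shared <- intersect(per_method[[pairs[1, k]]], per_method[[pairs[2, k]]])
      if (!length(shared)) return(NULL)
      data.frame(method_a = pairs[1, k], method_b = pairs[2, k],
                 gene = shared, stringsAsFactors = FALSE)
    }))
    if (is.null(inter)) inter <- data.frame()
  }
  list(per_method = per_method, classifications = cls, intersections = inter)
}
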