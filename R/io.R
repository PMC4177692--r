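## Readers and writers for the plain-text interchange formats used by the
## pipeline. Coordinate dialects: VCF and GFF3 are 1-based closed, BED and
## the binned-coverage table are 0-based half-open. All internal interval
## logic is 0-based half-open; conversion happens here, at the boundary.

#' Read a genotype matrix from VCF or TSV
#'
#' Accepts either a plain-text VCF (biallelic SNPs, GT field first in
#' FORMAT) or the package's tabular encoding (columns `chrom`, `pos`,
#' `ref`, `alt`, `id`, then one 0/1/2/NA column per sample). Loci are
#' sorted by (chrom, pos) with a warning if the input was unsorted;
#' multi-allelic records and duplicated positions are errors.
#'
#' @param path input file; format is sniffed from the `##fileformat=VCF`
#'   header line.
#' @param groups optional named vector mapping sample id to group label.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, groups = NULL) {
  first <- readLines(path, n = 1L)
  g <- if (startsWith(first, "##fileformat=VCF")) read_genotypes_vcf(path)
       else read_genotypes_tsv(path)
  if (!is.null(groups)) g$groups <- unname(as.character(groups[g$samples]))
  g
}

read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  samples <- hdr[-(1:9)]
  if (!length(body)) stop("VCF contains no records")
  fields <- do.call(rbind, body)
  if (any(grepl(",", fields[, 5], fixed = TRUE)))
    stop("multi-allelic record at ", fields[grepl(",", fields[, 5]), 1][1], ":",
         fields[grepl(",", fields[, 5]), 2][1])
  gt <- fields[, -(1:9), drop = FALSE]
  ## keep the GT subfield only, tolerate phased separators
  gt <- sub(":.*$", "", gt)
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  geno <- t(apply(gt, 1, code))            # loci x samples -> transpose below
  if (length(samples) == 1L) geno <- matrix(geno, ncol = 1L)
  genotype_matrix(t(geno),
                  data.frame(chrom = fields[, 1], pos = as.integer(fields[, 2]),
                             id = fields[, 3], ref = fields[, 4], alt = fields[, 5],
                             stringsAsFactors = FALSE),
                  samples = samples)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character",
                                          id = "character"))
  meta <- c("chrom", "pos", "ref", "alt", "id")
  stopifnot(all(c("chrom", "pos") %in% names(tab)))
  samp_cols <- setdiff(names(tab), meta)
  genotype_matrix(t(as.matrix(tab[, samp_cols, drop = FALSE])),
                  tab[, intersect(meta, names(tab)), drop = FALSE],
                  samples = samp_cols)
}

#' Write a genotype matrix as VCF
#' @param g a [genotype_matrix].
#' @param path output path (plain text).
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$geno))) {
    calls <- g$geno[, j]
    s <- ifelse(is.na(calls), "./.", gt_str[calls + 1L])
    writeLines(paste(c(g$loci$chrom[j], g$loci$pos[j], g$loci$id[j],
                       g$loci$ref[j], g$loci$alt[j], ".", "PASS", ".", "GT", s),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a genotype matrix as TSV
#' @inheritParams write_genotypes_vcf
#' @export
write_genotypes_tsv <- function(g, path) {
  tab <- cbind(g$loci[, c("chrom", "pos", "ref", "alt", "id")],
               as.data.frame(t(g$geno)))
  names(tab) <- c("chrom", "pos", "ref", "alt", "id", g$samples)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet (sample, group, lat, lon, altitude)
#' @param path TSV path.
#' @return data.frame with the five columns, coordinates validated.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group", "lat", "lon") %in% names(tab)))
  if (any(tab$lat < -90 | tab$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(tab$lon < -180 | tab$lon > 180)) stop("longitude outside [-180, 180]")
  if (anyDuplicated(tab$sample)) stop("duplicated sample ids in sample sheet")
  tab
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the binned coverage table
#'
#' Plain TSV with columns `chrom`, `start`, `end` (0-based half-open,
#' fixed bin width) followed by one read-count column per sample.
#' @param path TSV path.
#' @return list with `bins` (data.frame chrom/start/end) and `counts`
#'   (integer matrix bins x samples), class `bin_coverage`.
#' @export
read_coverage <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  bins <- tab[, c("chrom", "start", "end")]
  counts <- as.matrix(tab[, setdiff(names(tab), c("chrom", "start", "end")),
                          drop = FALSE])
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("negative read counts")
  bin_coverage(bins, counts)
}

#' @rdname read_coverage
#' @param cov a `bin_coverage` object.
#' @export
write_coverage <- function(cov, path) {
  utils::write.table(cbind(cov$bins, as.data.frame(cov$counts)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binned coverage constructor
#' @param bins data.frame chrom/start/end tiling each chromosome.
#' @param counts non-negative integer matrix, bins x samples.
#' @export
bin_coverage <- function(bins, counts) {
  stopifnot(nrow(bins) == nrow(counts), all(bins$end > bins$start))
  ord <- order(bins$chrom, bins$start)
  bins <- bins[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  rownames(bins) <- NULL
  structure(list(bins = bins, counts = counts), class = "bin_coverage")
}

#' Read a TE mask from BED (0-based half-open); intervals are merged
#' @param path BED path.
#' @return GRanges of merged repeat intervals.
#' @export
read_te_mask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(gr)
}

#' Read gene models from GFF3 (gene-level records)
#' @param path GFF3 path.
#' @return data.frame (id, chrom, start, end, strand), 1-based closed.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  data.frame(id = if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read an environment table (locations x variables)
#' @param path TSV with a `location` column and numeric variables.
#' @return numeric matrix with location row names.
#' @export
read_env_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("location" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "location"), drop = FALSE])
  rownames(m) <- tab$location
  if (anyNA(m)) stop("environment table contains missing values")
  m
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(stats::setNames(data.frame(rownames(x)), rownames_as),
               as.data.frame(x))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
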