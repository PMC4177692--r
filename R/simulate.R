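#' Simulation configuration
#'
#' Parameters of the synthetic study design: a selfing annual grass
#' sampled in `n_groups` local groups along a linear environmental
#' transect, with two deep genetic clades that do not follow geography,
#' injected environment-associated loci (allele-frequency clines in
#' environmental PC1), injected high-Fst outlier loci, linkage blocks,
#' and group-consistent zero-coverage bins enriched for TE intervals.
#'
#' Neutral allele frequencies evolve hierarchically (ancestral -> clade
#' -> group) as Balding-Nichols beta draws, which makes the clade- and
#' group-level differentiation directly tunable. Coverage in covered
#' bins is negative-binomial; absence bins are exactly zero.
#'
#' @param n_groups number of local groups (default 9).
#' @param samples_per_group samples per group (default 10).
#' @param n_loci number of biallelic loci.
#' @param selfing_rate selfing probability; controls homozygosity via
#'   the equilibrium inbreeding coefficient s/(2-s).
#' @param n_clades number of deep clades (default 2), assigned to groups
#'   alternating along the transect so clade membership is orthogonal to
#'   the environmental gradient.
#' @param fst_between_clades Balding-Nichols F at the clade level.
#' @param fst_within_group Balding-Nichols F at the group level (local
#'   drift on top of the clade frequency).
#' @param transect_length_km length of the sampling transect.
#' @param env_noise_sd per-variable noise s.d. around the latent
#'   gradient (variables are generated on a unit-variance scale).
#' @param n_eas number of injected environment-associated loci.
#' @param eas_effect logistic slope of allele frequency on standardized
#'   environmental PC1.
#' @param n_outliers number of injected high-Fst loci.
#' @param outlier_fst Balding-Nichols F of injected outliers (near 1
#'   gives per-group fixation).
#' @param genome_length_bp genome length (single chromosome).
#' @param bin_size_bp coverage bin width (default 1000).
#' @param n_pa_regions number of injected presence/absence regions.
#' @param pa_te_enrichment multiplier of TE density inside injected P/A
#'   regions.
#' @param pa_env_effect logistic slope of per-group absence probability
#'   on the environmental gradient; 0 (default) gives gradient-free
#'   absence patterns.
#' @param te_base_density genome-wide TE masked fraction outside P/A
#'   regions.
#' @param mean_depth negative-binomial mean reads per covered bin per
#'   sample.
#' @param nb_dispersion negative-binomial size parameter.
#' @param ld_block_mean_loci mean loci per linkage block (geometric);
#'   loci in a block copy a shared haplotype pattern.
#' @param ld_decay per-locus probability of escaping its block pattern.
#' @param missing_rate genotype missingness rate.
#' @param n_env_vars number of environmental variables (default 20:
#'   19 BioClim-like plus altitude).
#' @param n_genes number of gene models drawn on the genome.
#' @param seed integer RNG seed; identical configs (seed included) give
#'   byte-identical bundles.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_groups = 9, samples_per_group = 10, n_loci = 2000,
                       selfing_rate = 0.99, n_clades = 2,
                       fst_between_clades = 0.5, fst_within_group = 0.1,
                       transect_length_km = 740, env_noise_sd = 0.3,
                       n_eas = 20, eas_effect = 3,
                       n_outliers = 10, outlier_fst = 0.9,
                       genome_length_bp = 1e6, bin_size_bp = 1000,
                       n_pa_regions = 50, pa_te_enrichment = 3,
                       pa_env_effect = 0, te_base_density = 0.15,
                       mean_depth = 30, nb_dispersion = 5,
                       ld_block_mean_loci = 3, ld_decay = 0.05,
                       missing_rate = 0.05, n_env_vars = 20, n_genes = 300,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_groups", "samples_per_group", "n_loci", "n_clades", "n_eas",
              "n_outliers", "n_pa_regions", "n_env_vars", "n_genes")
  for (f in counts)
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop("invalid config field '", f, "': must be a non-negative count")
  fracs <- c("selfing_rate", "fst_between_clades", "fst_within_group",
             "outlier_fst", "te_base_density", "missing_rate", "ld_decay")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid config field '", f, "': must be a fraction in [0, 1]")
  if (cfg$n_eas + cfg$n_outliers > cfg$n_loci)
    stop("invalid config field 'n_eas': n_eas + n_outliers must not exceed n_loci")
  if (cfg$n_clades > cfg$n_groups)
    stop("invalid config field 'n_clades': more clades than groups")
  n_bins <- floor(cfg$genome_length_bp / cfg$bin_size_bp)
  if (cfg$n_pa_regions * 4 > n_bins)
    stop("invalid config field 'n_pa_regions': too many regions for the genome")
  class(cfg) <- "sim_config"
  cfg
}

## Balding-Nichols draw: beta around p with variance F p (1 - p)
rbn <- function(n, p, f) {
  if (f <= 0) return(rep(p, length.out = n))
  if (f >= 1) return(stats::rbinom(n, 1, p))
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  stats::rbeta(n, a, b)
}

## genotype draws for one locus given per-sample allele freq and
## equilibrium inbreeding coefficient
draw_genos <- function(p_sample, f_is) {
  n <- length(p_sample)
  selfed <- stats::runif(n) < f_is
  g <- stats::rbinom(n, 2, p_sample)
  g[selfed] <- 2L * stats::rbinom(sum(selfed), 1, p_sample[selfed])
  g
}

#' Simulate a complete input bundle
#'
#' Draws the sample sheet, environment table, genotype matrix, binned
#' coverage, TE mask and gene models described by a [sim_config], plus
#' truth tables recording every injected environment-associated locus,
#' Fst-outlier locus and presence/absence region.
#'
#' @param config a [sim_config].
#' @return list of class `dataset_bundle` with elements `config`,
#'   `sheet`, `env`, `geno`, `coverage`, `te_mask`, `genes`, `truth`
#'   (list `eas`, `outliers`, `pa_regions`) and `group_gradient` (the
#'   latent standardized transect position per group).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  n_samp <- cfg$n_groups * cfg$samples_per_group
  groups <- LETTERS[seq_len(cfg$n_groups)]
  grp_of <- rep(groups, each = cfg$samples_per_group)
  samples <- paste0(grp_of, rep(seq_len(cfg$samples_per_group), cfg$n_groups))

  ## transect geometry: groups evenly spaced west -> east; gradient z is
  ## the standardized transect position and plays the role of env PC1
  frac <- seq(0, 1, length.out = cfg$n_groups)
  z <- as.numeric(scale(frac))
  lon0 <- 26.5
  lat0 <- 40.0
  lon <- lon0 + frac * cfg$transect_length_km / (111.32 * cos(lat0 * pi / 180))
  lat <- rep(lat0, cfg$n_groups) - frac * 1.2
  altitude <- round(100 + 900 * frac + stats::rnorm(cfg$n_groups, 0, 30))
  sheet <- data.frame(sample = samples, group = grp_of,
                      lat = lat[match(grp_of, groups)],
                      lon = lon[match(grp_of, groups)],
                      altitude = altitude[match(grp_of, groups)],
                      stringsAsFactors = FALSE)

  ## environment: each variable loads on the gradient with random sign
  ## and magnitude, plus noise; column 20 is altitude (rescaled)
  loadings <- stats::runif(cfg$n_env_vars, 0.6, 1) *
    sample(c(-1, 1), cfg$n_env_vars, replace = TRUE)
  env <- sapply(seq_len(cfg$n_env_vars), function(v)
    loadings[v] * z + stats::rnorm(cfg$n_groups, 0, cfg$env_noise_sd))
  colnames(env) <- c(paste0("bio", seq_len(cfg$n_env_vars - 1)), "altitude")
  env[, cfg$n_env_vars] <- altitude
  rownames(env) <- groups

  ## clades alternate along the transect (structure != geography)
  clade_of_group <- rep(seq_len(cfg$n_clades), length.out = cfg$n_groups)

  ## locus roles and positions
  n_loci <- cfg$n_loci
  pos <- sort(sample.int(cfg$genome_length_bp - 1L, n_loci)) + 1L
  roles <- rep("neutral", n_loci)
  special <- sample.int(n_loci, cfg$n_eas + cfg$n_outliers)
  eas_idx <- special[seq_len(cfg$n_eas)]
  out_idx <- setdiff(special, eas_idx)
  roles[eas_idx] <- "eas"
  roles[out_idx] <- "outlier"

  ## linkage blocks over neutral loci: geometric run lengths; loci in a
  ## block share one group-frequency pattern and one haplotype draw
  block_id <- integer(n_loci)
  b <- 0L
  i <- 1L
  while (i <= n_loci) {
    b <- b + 1L
    len <- 1L + stats::rgeom(1, 1 / cfg$ld_block_mean_loci)
    j <- min(n_loci, i + len - 1L)
    block_id[i:j] <- b
    i <- j + 1L
  }
  block_id[roles != "neutral"] <- -seq_along(which(roles != "neutral")) # singletons

  f_is <- cfg$selfing_rate / (2 - cfg$selfing_rate)
  geno <- matrix(NA_integer_, n_samp, n_loci)
  grp_index <- match(grp_of, groups)

  ## per-block shared pattern for neutral loci
  blocks <- split(seq_len(n_loci), block_id)
  for (loci_in_block in blocks) {
    lead <- loci_in_block[1]
    role <- roles[lead]
    p0 <- stats::runif(1, 0.05, 0.95)
    p_group <- switch(role,
      neutral = {
        p_clade <- rbn(cfg$n_clades, p0, cfg$fst_between_clades)
        vapply(seq_len(cfg$n_groups), function(gi)
          rbn(1, p_clade[clade_of_group[gi]], cfg$fst_within_group), 0)
      },
      eas = stats::plogis(stats::qlogis(stats::runif(1, 0.3, 0.7)) +
                            cfg$eas_effect * z),
      outlier = rbn(cfg$n_groups, p0, cfg$outlier_fst))
    p_group <- pmin(pmax(p_group, 1e-6), 1 - 1e-6)
    g_block <- draw_genos(p_group[grp_index], f_is)
    for (l in loci_in_block) {
      g <- g_block
      escape <- stats::runif(n_samp) < cfg$ld_decay
      if (any(escape)) g[escape] <- draw_genos(p_group[grp_index][escape], f_is)
      geno[, l] <- g
    }
  }
  if (cfg$missing_rate > 0)
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_

  gm <- genotype_matrix(geno,
                        data.frame(chrom = "chr1", pos = pos,
                                   ref = "A", alt = "T",
                                   id = sprintf("L%05d", seq_len(n_loci)),
                                   stringsAsFactors = FALSE),
                        samples = samples, groups = grp_of)

  ## coverage: tile the genome in bins; choose P/A regions of 1-4 bins
  n_bins <- floor(cfg$genome_length_bp / cfg$bin_size_bp)
  bins <- data.frame(chrom = "chr1",
                     start = (seq_len(n_bins) - 1L) * cfg$bin_size_bp,
                     end = seq_len(n_bins) * cfg$bin_size_bp)
  counts <- matrix(stats::rnbinom(n_bins * n_samp, mu = cfg$mean_depth,
                                  size = cfg$nb_dispersion),
                   n_bins, n_samp)
  colnames(counts) <- samples

  pa_truth <- data.frame()
  pa_bin_flag <- rep(FALSE, n_bins)
  if (cfg$n_pa_regions > 0) {
    lens <- sample(1:4, cfg$n_pa_regions, replace = TRUE,
                   prob = c(0.5, 0.25, 0.15, 0.1))
    starts <- integer(0)
    taken <- rep(FALSE, n_bins)
    for (k in seq_len(cfg$n_pa_regions)) {
      repeat {
        s <- sample.int(n_bins - lens[k] + 1L, 1)
        idx <- s:(s + lens[k] - 1L)
        ## keep a free bin on each side so regions never merge
        guard <- max(1L, s - 1L):min(n_bins, s + lens[k])
        if (!any(taken[guard])) { taken[idx] <- TRUE; starts[k] <- s; break }
      }
    }
    absent_list <- lapply(seq_len(cfg$n_pa_regions), function(k) {
      if (cfg$pa_env_effect != 0) {
        ## absence probability logistic in the gradient, random sign
        sgn <- sample(c(-1, 1), 1)
        pr <- stats::plogis(sgn * cfg$pa_env_effect * z)
        ab <- which(stats::runif(cfg$n_groups) < pr)
        if (length(ab) == 0) ab <- which.max(pr)
        if (length(ab) == cfg$n_groups) ab <- ab[-which.min(pr)]
        ab
      } else {
        n_ab <- sample.int(cfg$n_groups - 1L, 1)
        sort(sample.int(cfg$n_groups, n_ab))
      }
    })
    for (k in seq_len(cfg$n_pa_regions)) {
      idx <- starts[k]:(starts[k] + lens[k] - 1L)
      pa_bin_flag[idx] <- TRUE
      ab_samples <- grp_index %in% absent_list[[k]]
      counts[idx, ab_samples] <- 0L
    }
    pa_truth <- data.frame(chrom = "chr1",
                           start = (starts - 1L) * cfg$bin_size_bp,
                           end = (starts + lens - 1L) * cfg$bin_size_bp,
                           absent_groups = vapply(absent_list, function(a)
                             paste(groups[a], collapse = ","), ""),
                           stringsAsFactors = FALSE)
    pa_truth <- pa_truth[order(pa_truth$start), ]
    rownames(pa_truth) <- NULL
  }
  cov <- bin_coverage(bins, counts)

  ## TE mask: one interval per masked bin, masked length binomial around
  ## the target density (densified inside P/A regions)
  dens <- ifelse(pa_bin_flag,
                 pmin(0.95, cfg$te_base_density * cfg$pa_te_enrichment),
                 cfg$te_base_density)
  mlen <- stats::rbinom(n_bins, cfg$bin_size_bp, dens)
  has <- mlen > 0
  off <- integer(n_bins)
  off[has] <- vapply(which(has), function(i)
    sample.int(cfg$bin_size_bp - mlen[i] + 1L, 1) - 1L, 0L)
  te <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = bins$start[has] + off[has] + 1L,
                             width = mlen[has])))

  ## gene models: non-overlapping, random strand, 1-based closed
  glen <- pmax(300L, round(stats::rnorm(cfg$n_genes, 1500, 500)))
  slot <- sort(sample.int(cfg$genome_length_bp - max(glen) - 1L, cfg$n_genes))
  gstart <- slot
  ok <- c(TRUE, diff(gstart) > glen[-cfg$n_genes] + 100L)
  genes <- data.frame(id = sprintf("gene%04d", seq_len(sum(ok))),
                      chrom = "chr1", start = gstart[ok] + 1L,
                      end = gstart[ok] + glen[ok],
                      strand = sample(c("+", "-"), sum(ok), replace = TRUE),
                      stringsAsFactors = FALSE)

  truth <- list(
    eas = data.frame(id = gm$loci$id[eas_idx],
                     chrom = rep("chr1", length(eas_idx)),
                     pos = pos[eas_idx],
                     effect = rep(cfg$eas_effect, length(eas_idx)),
                     stringsAsFactors = FALSE)[order(pos[eas_idx]), ],
    outliers = data.frame(id = gm$loci$id[out_idx],
                          chrom = rep("chr1", length(out_idx)),
                          pos = pos[out_idx],
                          target_fst = rep(cfg$outlier_fst, length(out_idx)),
                          stringsAsFactors = FALSE)[order(pos[out_idx]), ],
    pa_regions = pa_truth)
  rownames(truth$eas) <- rownames(truth$outliers) <- NULL

  structure(list(config = cfg, sheet = sheet, env = env, geno = gm,
                 coverage = cov, te_mask = te, genes = genes, truth = truth,
                 group_gradient = stats::setNames(z, groups)),
            class = "dataset_bundle")
}

#' Write a simulated bundle to disk as plain-text files
#'
#' Emits the sample sheet, environment table, genotypes (VCF and TSV),
#' coverage TSV, TE mask BED (0-based half-open), gene models GFF3
#' (1-based closed) and the three truth TSVs.
#'
#' @param bundle a `dataset_bundle` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_sample_sheet(bundle$sheet, p("sample_sheet.tsv"))
  write_tsv(bundle$env, p("environment.tsv"), rownames_as = "location")
  write_genotypes_vcf(bundle$geno, p("genotypes.vcf"))
  write_genotypes_tsv(bundle$geno, p("genotypes.tsv"))
  write_coverage(bundle$coverage, p("coverage.tsv"))
  te <- bundle$te_mask
  utils::write.table(data.frame(chrom = as.character(GenomicRanges::seqnames(te)),
                                start = GenomicRanges::start(te) - 1L,
                                end = GenomicRanges::end(te)),
                     p("te_mask.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gf <- bundle$genes
  gff <- data.frame(gf$chrom, "landgen_sim", "gene", gf$start, gf$end, ".",
                    gf$strand, ".", paste0("ID=", gf$id))
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")), p("genes.gff3"))
  write_tsv(bundle$truth$eas, p("truth_eas.tsv"))
  write_tsv(bundle$truth$outliers, p("truth_outliers.tsv"))
  write_tsv(bundle$truth$pa_regions, p("truth_pa_regions.tsv"))
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, p("sim_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
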