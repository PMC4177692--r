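## Run configuration and the stage-chaining driver. Every tunable
## defaults to the reference analysis value: MAF 0.05, call rate 0.80,
## 1000-bp bins, 500-marker LD windows, D' bounds 0.98/0.7/0.9, an
## alpha target of one false association in ten (0.1), a 5% outlier
## FDR, 999 CCA permutations, and 1,000 burn-in + 10,000 sampling
## sweeps for the outlier MCMC.

#' Pipeline run configuration
#'
#' @param input_dir directory holding the input bundle (as written by
#'   [write_dataset_bundle()]); individual paths may be overridden.
#' @param out_dir output directory.
#' @param genotypes,sample_sheet,env_table,coverage,te_mask,gene_models
#'   input paths (default: conventional names under `input_dir`).
#' @param stages character vector of stages to run, in order, from
#'   `c("filter", "envpca", "pascan", "popgen", "ldblocks", "assoc",
#'   "outliers", "annotate", "cca", "report")`.
#' @param maf_min,call_rate_min locus filters.
#' @param n_env_pcs environmental PCs used as responses (default 3).
#' @param min_presence_mean P/A presence-depth rule (reads/sample).
#' @param ld_window,ld_strong,ld_recomb_upper,min_strong_fraction
#'   Gabriel-block parameters.
#' @param alpha_target numerator of the LD-corrected Bonferroni.
#' @param n_geno_pcs genotype PCs used as Q covariates (default 5).
#' @param n_latent_factors latent factors for the second engine.
#' @param mcmc_burn,mcmc_iter,mcmc_thin outlier-scan chain lengths.
#' @param outlier_fdr outlier q-value threshold.
#' @param upstream_bp annotation window.
#' @param n_perm CCA (and Mantel) permutation count.
#' @param n_boot NJ bootstrap replicates (0 disables).
#' @param seed master seed; stage seeds are derived by fixed offsets.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir = file.path(input_dir, "results"),
                       genotypes = file.path(input_dir, "genotypes.vcf"),
                       sample_sheet = file.path(input_dir, "sample_sheet.tsv"),
                       env_table = file.path(input_dir, "environment.tsv"),
                       coverage = file.path(input_dir, "coverage.tsv"),
                       te_mask = file.path(input_dir, "te_mask.bed"),
                       gene_models = file.path(input_dir, "genes.gff3"),
                       stages = c("filter", "envpca", "pascan", "popgen",
                                  "ldblocks", "assoc", "outliers", "annotate",
                                  "cca", "report"),
                       maf_min = 0.05, call_rate_min = 0.80, n_env_pcs = 3,
                       min_presence_mean = 1,
                       ld_window = 500, ld_strong = c(0.98, 0.7),
                       ld_recomb_upper = 0.9, min_strong_fraction = 0.95,
                       alpha_target = 0.1, n_geno_pcs = 5,
                       n_latent_factors = 5,
                       mcmc_burn = 1000, mcmc_iter = 10000, mcmc_thin = 10,
                       outlier_fdr = 0.05, upstream_bp = 5000,
                       n_perm = 999, n_boot = 0, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(cfg, offset) (cfg$seed + 1009L * offset) %% .Machine$integer.max

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Chains the enabled stages on the configured inputs, writing each
#' stage's tables under `out_dir`, the fully resolved configuration as
#' `run_config.json`, and a markdown `report.md` with the summary
#' tables. A stage whose prerequisites were disabled is skipped with a
#' warning.
#'
#' @param cfg a [run_config].
#' @return named list of stage results, invisibly; also written to
#'   disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  echo <- unclass(cfg)
  jsonlite::write_json(echo, file.path(cfg$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res <- list()
  on <- function(s) s %in% cfg$stages
  need <- function(s, what) {
    if (is.null(res[[s]])) {
      warning("stage '", what, "' skipped: requires disabled stage '", s, "'")
      FALSE
    } else TRUE
  }
  sheet <- read_sample_sheet(cfg$sample_sheet)
  grp_of <- stats::setNames(sheet$group, sheet$sample)

  log_stage("load", "reading genotypes from ", cfg$genotypes)
  geno <- read_genotypes(cfg$genotypes, groups = grp_of)

  if (on("filter")) {
    geno <- filter_loci(geno, cfg$maf_min, cfg$call_rate_min)
    log_stage("filter", ncol(geno$geno), " loci retained")
    write_genotypes_tsv(geno, file.path(cfg$out_dir, "genotypes_filtered.tsv"))
    res$filter <- geno
  }
  if (on("envpca")) {
    env <- read_env_table(cfg$env_table)
    pcs <- env_pca(env, k = cfg$n_env_pcs)
    log_stage("envpca", "variance fractions: ",
              paste(sprintf("%.3f", pcs$var_frac), collapse = " "))
    write_tsv(pcs$scores, file.path(cfg$out_dir, "env_pc_scores.tsv"),
              rownames_as = "location")
    write_tsv(pcs$loadings, file.path(cfg$out_dir, "env_pc_loadings.tsv"),
              rownames_as = "variable")
    res$envpca <- pcs
  }
  if (on("pascan")) {
    cov <- read_coverage(cfg$coverage)
    cov_groups <- grp_of[colnames(cov$counts)]
    bins <- call_pa_bins(cov, cov_groups, cfg$min_presence_mean)
    pa <- merge_pa_regions(bins)
    log_stage("pascan", sum(bins$pa), " P/A bins -> ", nrow(pa$regions),
              " regions")
    write_tsv(cbind(pa$regions,
                    t(pa$group_presence)),
              file.path(cfg$out_dir, "pa_regions.tsv"))
    enr <- tryCatch(
      te_enrichment(pa, read_te_mask(cfg$te_mask), cov$bins,
                    seed = stage_seed(cfg, 3L)),
      error = function(e) { warning("te_enrichment failed: ", conditionMessage(e)); NULL })
    if (!is.null(enr))
      write_tsv(data.frame(set = names(enr), masked_fraction = enr),
                file.path(cfg$out_dir, "te_enrichment.tsv"))
    res$pascan <- list(bins = bins, regions = pa, te = enr)
  }
  if (on("popgen")) {
    fst <- pairwise_fst(geno, overall = TRUE)
    kin <- vanraden_kinship(geno)
    pdist <- p_distance(geno)
    tree <- nj_tree(pdist, boot_geno = if (cfg$n_boot > 0) geno else NULL,
                    n_boot = cfg$n_boot, seed = stage_seed(cfg, 4L))
    scores <- genotype_pca(geno, n_pcs = cfg$n_geno_pcs)
    clusters <- assign_clusters(scores, k = 2:8, seed = stage_seed(cfg, 5L))
    log_stage("popgen", "overall Fst ", sprintf("%.3f", attr(fst, "overall")),
              "; k = ", attr(clusters, "k"))
    write_tsv(fst, file.path(cfg$out_dir, "fst_pairwise.tsv"),
              rownames_as = "group")
    write_tsv(kin, file.path(cfg$out_dir, "kinship.tsv"),
              rownames_as = "sample")
    ape::write.tree(tree, file.path(cfg$out_dir, "nj_tree.nwk"))
    write_tsv(data.frame(sample = names(clusters), cluster = as.integer(clusters)),
              file.path(cfg$out_dir, "clusters.tsv"))
    res$popgen <- list(fst = fst, kinship = kin, tree = tree,
                       scores = scores, clusters = clusters)
    ## geographic vs genetic distance (Mantel-style, group level)
    gd <- geodesic_matrix(sheet)
    gfst <- fst[rownames(gd), rownames(gd)]
    mant <- matrix_spearman(gfst, gd, n_perm = cfg$n_perm,
                            seed = stage_seed(cfg, 6L))
    res$popgen$mantel <- mant
    write_tsv(gd, file.path(cfg$out_dir, "geodesic_km.tsv"),
              rownames_as = "group")
  }
  if (on("ldblocks")) {
    part <- gabriel_blocks(geno, window = cfg$ld_window, strong = cfg$ld_strong,
                           recomb_upper = cfg$ld_recomb_upper,
                           min_strong_fraction = cfg$min_strong_fraction,
                           maf_min = cfg$maf_min)
    thr <- ld_bonferroni(part, cfg$alpha_target)
    log_stage("ldblocks", nrow(part$blocks), " blocks + ",
              length(part$singletons), " singletons; threshold ",
              format(thr, digits = 4))
    write_tsv(part$blocks, file.path(cfg$out_dir, "ld_blocks.tsv"))
    res$ldblocks <- list(partition = part, threshold = thr)
  }
  if (on("assoc")) {
    if (!need("envpca", "assoc") || !need("popgen", "assoc")) {
    } else {
      env_scores <- res$envpca$scores[geno$groups, , drop = FALSE]
      thr <- if (!is.null(res$ldblocks)) res$ldblocks$threshold else {
        warning("association thresholded without LD correction (ldblocks disabled)")
        cfg$alpha_target / ncol(geno$geno)
      }
      mlm <- select_eas(mlm_assoc(geno, env_scores, K = res$popgen$kinship,
                                  Q = res$popgen$scores), thr)
      lf <- select_eas(lfmm_assoc(geno, env_scores,
                                  n_factors = cfg$n_latent_factors), thr)
      both <- intersect_methods(mlm, lf)
      log_stage("assoc", sum(mlm$significant), " mlm / ",
                sum(lf$significant), " lfmm EAS records; ",
                nrow(both$pooled), " pooled joint loci")
      write_tsv(mlm, file.path(cfg$out_dir, "assoc_mlm.tsv"))
      write_tsv(lf, file.path(cfg$out_dir, "assoc_lfmm.tsv"))
      write_tsv(both$pooled, file.path(cfg$out_dir, "assoc_joint.tsv"))
      res$assoc <- list(mlm = mlm, lfmm = lf, joint = both, threshold = thr)
    }
  }
  if (on("outliers")) {
    counts <- allele_counts(geno)
    scan <- bayes_fst_scan(counts, n_burn = cfg$mcmc_burn,
                           n_iter = cfg$mcmc_iter, thin = cfg$mcmc_thin,
                           fdr = cfg$outlier_fdr, seed = stage_seed(cfg, 7L))
    summ <- summarize_scan(scan)
    log_stage("outliers", summ$n_outliers, " outliers (", summ$percent, "%)")
    write_tsv(scan, file.path(cfg$out_dir, "outliers.tsv"))
    res$outliers <- list(scan = scan, summary = summ)
  }
  if (on("annotate")) {
    genes <- read_gene_models(cfg$gene_models)
    sets <- list()
    if (!is.null(res$assoc)) {
      sets$mlm <- unique(res$assoc$mlm[res$assoc$mlm$significant,
                                       c("chrom", "pos")])
      sets$lfmm <- unique(res$assoc$lfmm[res$assoc$lfmm$significant,
                                         c("chrom", "pos")])
    }
    if (!is.null(res$outliers)) {
      out_ids <- res$outliers$scan$id[res$outliers$scan$outlier]
      sets$outliers <- geno$loci[geno$loci$id %in% out_ids, c("chrom", "pos")]
    }
    sets <- Filter(function(x) nrow(x) > 0, sets)
    if (!length(sets)) {
      warning("stage 'annotate' skipped: no significant loci to classify")
    } else {
      gl <- gene_lists(sets, genes, upstream_bp = cfg$upstream_bp)
      summ <- do.call(rbind, lapply(names(gl$classifications), function(m)
        cbind(method = m, position_summary(gl$classifications[[m]]$class))))
      log_stage("annotate", paste(names(sets), collapse = ", "), " classified")
      write_tsv(summ, file.path(cfg$out_dir, "position_summary.tsv"))
      res$annotate <- list(lists = gl, summary = summ)
    }
  }
  if (on("cca")) {
    if (!need("pascan", "cca") || !need("envpca", "cca")) {
    } else if (nrow(res$pascan$regions$regions) < 2) {
      warning("stage 'cca' skipped: fewer than two P/A regions")
    } else {
      pres <- res$pascan$regions$group_presence
      constr <- res$envpca$scores[rownames(pres), , drop = FALSE]
      fit <- cca_fit(pres, constr)
      perm <- cca_permutation(pres, constr, n_perm = cfg$n_perm,
                              seed = stage_seed(cfg, 8L))
      log_stage("cca", sprintf("constrained fraction %.3f, p = %.4g",
                               fit$constrained_fraction, perm$p))
      jsonlite::write_json(list(total_inertia = fit$total_inertia,
                                constrained_fraction = fit$constrained_fraction,
                                eig_constrained = fit$eig_constrained,
                                p = perm$p),
                           file.path(cfg$out_dir, "cca_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      res$cca <- list(fit = fit, permutation = perm)
    }
  }
  if (on("report")) write_report(res, cfg)
  invisible(res)
}

fmt_tab <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
}

write_report <- function(res, cfg) {
  lines <- c("# Landscape genomics run report", "")
  if (!is.null(res$popgen)) {
    lines <- c(lines, "## Pairwise Fst (lower) / geodesic km", "",
               fmt_tab(cbind(group = rownames(res$popgen$fst),
                             as.data.frame(res$popgen$fst))), "",
               sprintf("Mantel-style Spearman rho = %.4f, p = %.4g",
                       res$popgen$mantel$rho, res$popgen$mantel$p), "")
  }
  if (!is.null(res$pascan)) {
    s <- res$pascan$regions$summary
    lines <- c(lines, "## Presence/absence regions", "",
               sprintf("%d P/A bins merged into %d regions (mean length %.1f bp, sd %.1f).",
                       sum(res$pascan$bins$pa), s["n"], s["mean_length"],
                       s["sd_length"]), "")
    if (!is.null(res$pascan$te))
      lines <- c(lines, "## TE enrichment (masked fraction)", "",
                 fmt_tab(data.frame(set = names(res$pascan$te),
                                    masked_fraction = res$pascan$te)), "")
  }
  if (!is.null(res$ldblocks))
    lines <- c(lines, "## LD blocks", "",
               sprintf("%d blocks + %d singletons = %d independent tests; threshold %.4g.",
                       nrow(res$ldblocks$partition$blocks),
                       length(res$ldblocks$partition$singletons),
                       res$ldblocks$partition$n_independent_tests,
                       res$ldblocks$threshold), "")
  if (!is.null(res$assoc))
    lines <- c(lines, "## Environment-associated SNPs", "",
               sprintf("mlm: %d significant records; lfmm: %d; joint pooled loci: %d.",
                       sum(res$assoc$mlm$significant),
                       sum(res$assoc$lfmm$significant),
                       nrow(res$assoc$joint$pooled)), "")
  if (!is.null(res$outliers))
    lines <- c(lines, "## Fst outliers", "",
               sprintf("%d outliers of %d loci (%.1f%%).",
                       res$outliers$summary$n_outliers,
                       res$outliers$summary$n_total,
                       res$outliers$summary$percent), "")
  if (!is.null(res$annotate))
    lines <- c(lines, "## Positional classification", "",
               fmt_tab(res$annotate$summary), "")
  if (!is.null(res$cca))
    lines <- c(lines, "## CCA of P/A regions on environmental PCs", "",
               sprintf("Constrained axes account for %.1f%% of total inertia (%.4g); permutation p = %.4g.",
                       100 * res$cca$fit$constrained_fraction,
                       res$cca$fit$total_inertia, res$cca$permutation$p), "")
  writeLines(lines, file.path(cfg$out_dir, "report.md"))
  invisible(lines)
}
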