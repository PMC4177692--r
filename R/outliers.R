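## Bayesian Fst-outlier scan: the per-locus/per-population Fst
## coefficient is decomposed on the logit scale into a locus-specific
## selection effect alpha_i (shared by all populations) and a
## population-specific effect beta_j (shared by all loci). alpha_i
## carries a spike-and-slab indicator; loci whose posterior supports a
## non-zero alpha are selection candidates, ranked by q-value.

#' Per-locus, per-group allele counts
#'
#' @param g a [genotype_matrix] with group labels.
#' @param groups optional explicit group vector overriding `g$groups`.
#' @return list: `alt` (loci x groups alternate-allele counts) and
#'   `total` (2 x non-missing samples); counts come from non-missing
#'   diploid calls only.
#' @export
allele_counts <- function(g, groups = NULL) {
  grp <- if (is.null(groups)) g$groups else as.character(groups)
  glev <- unique(grp)
  alt <- sapply(glev, function(gl)
    colSums(g$geno[grp == gl, , drop = FALSE], na.rm = TRUE))
  tot <- sapply(glev, function(gl)
    2L * colSums(!is.na(g$geno[grp == gl, , drop = FALSE])))
  alt <- matrix(alt, ncol = length(glev), dimnames = list(g$loci$id, glev))
  tot <- matrix(tot, ncol = length(glev), dimnames = list(g$loci$id, glev))
  list(alt = alt, total = tot)
}

## beta-binomial loglik of counts given ancestral freq p (length L) and
## theta (L x J); constant binomial coefficient omitted.
bb_ll <- function(alt, tot, p, theta) {
  A <- theta * p
  B <- theta * (1 - p)
  lbeta(alt + A, tot - alt + B) - lbeta(A, B)
}

#' Bayesian Fst decomposition outlier scan
#'
#' Metropolis-within-Gibbs sampler for the multinomial-Dirichlet
#' (beta-binomial for two alleles) likelihood of per-group allele
#' counts with logit(Fst_ij) = alpha_i + beta_j. The locus effect
#' alpha_i has a spike-and-slab prior: included with prior odds
#' `1:prior_odds` and a N(0, 1) slab; beta_j has a diffuse N(-1, 1.8)
#' prior; ancestral frequencies are uniform. Proposal standard
#' deviations are tuned adaptively during burn-in (target 25-45%
#' acceptance) and then frozen. The q-value of a locus is the mean of
#' (1 - inclusion probability) over all loci with inclusion
#' probability at least as high.
#'
#' @param counts output of [allele_counts()].
#' @param n_burn burn-in sweeps (default 1000).
#' @param n_iter post-burn-in sweeps (default 10000).
#' @param thin keep every `thin`-th sweep (default 10).
#' @param prior_odds prior odds against inclusion of alpha (default 10).
#' @param fdr flagging threshold on the q-value (default 0.05).
#' @param seed RNG seed; identical seeds give identical chains.
#' @return data.frame of class `outlier_result`: id, post_alpha
#'   (posterior mean of alpha), incl_prob, qvalue, outlier flag
#'   (qvalue <= fdr). Attributes: `"beta"` (posterior means),
#'   `"fdr"`, `"converged"` (split-chain beta agreement).
#' @export
bayes_fst_scan <- function(counts, n_burn = 1000, n_iter = 10000, thin = 10,
                           prior_odds = 10, fdr = 0.05, seed = 1L) {
  alt <- counts$alt
  tot <- counts$total
  L <- nrow(alt); J <- ncol(alt)
  stopifnot(J >= 2)
  set.seed(seed)
  pi_incl <- 1 / (1 + prior_odds)
  ## state
  p <- (rowSums(alt) + 0.5) / (rowSums(tot) + 1)
  x <- stats::qlogis(pmin(pmax(p, 1e-4), 1 - 1e-4))   # logit ancestral freq
  alpha <- rep(0, L)
  delta <- rep(FALSE, L)
  beta <- rep(-1, J)
  s_p <- rep(0.5, L); s_a <- rep(0.5, L); s_b <- rep(0.3, J)
  theta_of <- function(alpha, beta) exp(-outer(alpha, beta, `+`))
  ll_rows <- function(alpha, beta, p)
    rowSums(bb_ll(alt, tot, p, theta_of(alpha, beta)))
  ll <- ll_rows(alpha, beta, p)
  acc_p <- acc_a <- rep(0, L); acc_b <- rep(0, J); n_a <- rep(0, L)
  n_keep <- floor(n_iter / thin)
  sum_alpha <- rep(0, L); sum_delta <- rep(0, L)
  beta_draws <- matrix(0, n_keep, J)
  kept <- 0L
  total_sweeps <- n_burn + n_iter
  for (sw in seq_len(total_sweeps)) {
    ## ancestral frequencies (logit RW, uniform prior on p)
    x_new <- x + stats::rnorm(L, 0, s_p)
    p_new <- stats::plogis(x_new)
    ll_new <- ll_rows(alpha, beta, p_new)
    lacc <- ll_new - ll + log(p_new * (1 - p_new)) - log(p * (1 - p))
    take <- log(stats::runif(L)) < lacc
    x[take] <- x_new[take]; p[take] <- p_new[take]; ll[take] <- ll_new[take]
    acc_p <- acc_p + take
    ## alpha random walk for included loci
    if (any(delta)) {
      a_new <- alpha
      a_new[delta] <- alpha[delta] + stats::rnorm(sum(delta), 0, s_a[delta])
      ll_new <- ll_rows(a_new, beta, p)
      lacc <- ll_new - ll + stats::dnorm(a_new, 0, 1, log = TRUE) -
        stats::dnorm(alpha, 0, 1, log = TRUE)
      take <- delta & log(stats::runif(L)) < lacc
      alpha[take] <- a_new[take]; ll[take] <- ll_new[take]
      acc_a <- acc_a + take; n_a <- n_a + delta
    }
    ## spike-and-slab jump: off->on draws alpha* from the N(0,1) slab
    ## (prior == proposal, so only the likelihood and prior odds remain)
    a_prop <- ifelse(delta, 0, stats::rnorm(L, 0, 1))
    ll_new <- ll_rows(a_prop, beta, p)
    lacc <- ll_new - ll + ifelse(delta,
                                 log((1 - pi_incl) / pi_incl),
                                 log(pi_incl / (1 - pi_incl)))
    take <- log(stats::runif(L)) < lacc
    alpha[take] <- a_prop[take]; delta[take] <- !delta[take]
    ll[take] <- ll_new[take]
    ## population effects
    for (j in seq_len(J)) {
      b_new <- beta; b_new[j] <- beta[j] + stats::rnorm(1, 0, s_b[j])
      th_col <- exp(-(alpha + b_new[j]))
      ll_col_new <- bb_ll(alt[, j], tot[, j], p, th_col)
      th_old <- exp(-(alpha + beta[j]))
      ll_col_old <- bb_ll(alt[, j], tot[, j], p, th_old)
      lacc <- sum(ll_col_new - ll_col_old) +
        stats::dnorm(b_new[j], -1, 1.8, log = TRUE) -
        stats::dnorm(beta[j], -1, 1.8, log = TRUE)
      if (log(stats::runif(1)) < lacc) {
        beta[j] <- b_new[j]
        ll <- ll + (ll_col_new - ll_col_old)
        acc_b[j] <- acc_b[j] + 1
      }
    }
    ## adaptive tuning during burn-in
    if (sw <= n_burn && sw %% 50 == 0) {
      rate_p <- acc_p / 50
      s_p <- s_p * ifelse(rate_p > 0.45, 1.3, ifelse(rate_p < 0.25, 0.75, 1))
      rate_a <- ifelse(n_a > 0, acc_a / n_a, 0.35)
      s_a <- s_a * ifelse(rate_a > 0.45, 1.3, ifelse(rate_a < 0.25, 0.75, 1))
      rate_b <- acc_b / 50
      s_b <- s_b * ifelse(rate_b > 0.45, 1.3, ifelse(rate_b < 0.25, 0.75, 1))
      acc_p[] <- 0; acc_a[] <- 0; acc_b[] <- 0; n_a[] <- 0
    }
    if (sw > n_burn && (sw - n_burn) %% thin == 0) {
      kept <- kept + 1L
      sum_alpha <- sum_alpha + alpha
      sum_delta <- sum_delta + delta
      beta_draws[kept, ] <- beta
    }
  }
  incl <- sum_delta / kept
  post_alpha <- sum_alpha / kept
  ord <- order(incl, decreasing = TRUE)
  qv <- numeric(L)
  qv[ord] <- cummean_(1 - incl[ord])
  half <- floor(kept / 2)
  bdiff <- abs(colMeans(beta_draws[seq_len(half), , drop = FALSE]) -
                 colMeans(beta_draws[(half + 1):kept, , drop = FALSE]))
  converged <- all(bdiff < 0.5)
  if (!converged)
    warning("split-chain disagreement in beta beyond tolerance; ",
            "consider longer chains")
  res <- data.frame(id = rownames(alt), post_alpha = post_alpha,
                    incl_prob = incl, qvalue = qv,
                    outlier = qv <= fdr, stringsAsFactors = FALSE)
  attr(res, "beta") <- colMeans(beta_draws[seq_len(kept), , drop = FALSE])
  attr(res, "fdr") <- fdr
  attr(res, "converged") <- converged
  class(res) <- c("outlier_result", "data.frame")
  res
}

cummean_ <- function(x) cumsum(x) / seq_along(x)

#' Summarize an outlier scan
#'
#' @param result an `outlier_result`.
#' @param n_total_loci denominator for the percentage (defaults to the
#'   number of loci scanned).
#' @return list: `n_outliers`, `n_total`, `percent` (one decimal),
#'   `outlier_ids`.
#' @export
summarize_scan <- function(result, n_total_loci = nrow(result)) {
  n_out <- if (is.data.frame(result)) sum(result$outlier) else as.numeric(result)
  list(n_outliers = n_out, n_total = n_total_loci,
       percent = round(100 * n_out / n_total_loci, 1),
       outlier_ids = if (is.data.frame(result)) result$id[result$outlier]
                     else character(0))
}
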