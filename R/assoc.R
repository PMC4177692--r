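## Two genotype-environment association engines: an EMMA-style single
## variance component mixed model (kinship + genotype-PC covariates)
## and a latent-factor ridge regression with genomic-control
## recalibration. Both return per-locus, per-environmental-PC tables.

## mean-impute missing dosages per locus
impute_dosage <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas)) m[nas] <- mu[nas[, 2]]
  m
}

## exact REML log-likelihood (up to a constant) for V = sigma_g^2 (K + delta I),
## on the eigenbasis of K. lam: eigenvalues; ystar, Wstar: rotated data.
reml_ll <- function(log_delta, lam, ystar, Wstar) {
  delta <- exp(log_delta)
  w <- 1 / (lam + delta)
  WtW <- crossprod(Wstar, Wstar * w)
  beta <- solve(WtW, crossprod(Wstar, ystar * w))
  r <- ystar - Wstar %*% beta
  rss <- sum(w * r^2)
  nq <- length(ystar) - ncol(Wstar)
  -0.5 * (nq * log(rss) + sum(log(lam + delta)) +
            determinant(WtW, logarithm = TRUE)$modulus)
}

#' Mixed-model association scan (EMMA-style)
#'
#' Fits Y = X beta + Z u + e per locus, with u carrying covariance
#' proportional to the kinship matrix K. The variance ratio
#' delta = sigma_e^2 / sigma_g^2 is estimated once by REML on the null
#' model (intercept + Q) through the spectral decomposition of K; each
#' SNP is then tested by generalized least squares with a Wald t test
#' on its dosage coefficient. Missing dosages are mean-imputed per
#' locus. When K is the identity and Q is empty the procedure reduces
#' exactly to ordinary least squares.
#'
#' @param g a [genotype_matrix].
#' @param env_pc response vector per sample (an environmental PC
#'   score), or a matrix with one column per PC.
#' @param K kinship matrix (see [vanraden_kinship()]); identity if
#'   omitted.
#' @param Q structure covariates, samples x q (default: none). The
#'   usual choice is the first five genotype PCs.
#' @return data.frame of class `assoc_result`: id, chrom, pos, pc,
#'   beta, stat (t), p, method = "mlm". Collinear SNPs get `NA` p.
#' @export
mlm_assoc <- function(g, env_pc, K = NULL, Q = NULL) {
  n <- nrow(g$geno)
  env_pc <- as.matrix(env_pc)
  stopifnot(nrow(env_pc) == n)
  if (is.null(K)) K <- diag(n)
  W <- cbind(`(Intercept)` = rep(1, n), Q)
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  M <- impute_dosage(g$geno)
  Mstar <- crossprod(U, M)
  Wstar <- crossprod(U, W)
  out <- vector("list", ncol(env_pc))
  for (e in seq_len(ncol(env_pc))) {
    y <- env_pc[, e]
    ystar <- crossprod(U, y)
    opt <- stats::optimize(reml_ll, c(-10, 10), lam = lam, ystar = ystar,
                           Wstar = Wstar, maximum = TRUE)
    delta <- exp(opt$maximum)
    w <- 1 / (lam + delta)
    q <- ncol(W) + 1
    beta <- stat <- pval <- rep(NA_real_, ncol(M))
    for (j in seq_len(ncol(M))) {
      X <- cbind(Wstar, snp = Mstar[, j])
      XtX <- crossprod(X, X * w)
      ok <- tryCatch({
        R <- chol(XtX)
        TRUE
      }, error = function(err) FALSE)
      if (!ok) next                         # SNP collinear with covariates
      b <- backsolve(R, backsolve(R, crossprod(X, ystar * w), transpose = TRUE))
      r <- ystar - X %*% b
      s2 <- sum(w * r^2) / (n - q)
      xtxinv_snp <- sum(backsolve(R, diag(q)[, q], transpose = TRUE)^2)
      se <- sqrt(s2 * xtxinv_snp)
      beta[j] <- b[q]
      stat[j] <- b[q] / se
      pval[j] <- 2 * stats::pt(-abs(stat[j]), df = n - q)
    }
    out[[e]] <- data.frame(id = g$loci$id, chrom = g$loci$chrom,
                           pos = g$loci$pos, pc = colnames(env_pc)[e] %||%
                             paste0("PC", e),
                           beta = beta, stat = stat, p = pval,
                           method = "mlm", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "delta") <- NULL
  class(res) <- c("assoc_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Latent-factor association scan
#'
#' Latent factors are the leading left singular vectors of the
#' centered (mean-imputed) genotype matrix; each locus is regressed on
#' the environmental variable given the factors, and the resulting
#' z-scores are recalibrated by a median-based genomic-inflation
#' factor before conversion to p-values. This is the deterministic
#' least-squares formulation of the latent factor mixed model; with
#' `n_factors = 0` it is plain per-locus linear regression.
#'
#' @param g a [genotype_matrix].
#' @param env_pc response per sample (vector or matrix, one column per
#'   environmental PC).
#' @param n_factors number of latent factors (default 5, the number of
#'   cryptic clusters in the emulated design); must be < samples.
#' @param gif_floor lower clamp for the inflation factor.
#' @return data.frame of class `assoc_result` (method = "lfmm") with
#'   attribute `"gif"`, the per-PC inflation factor before rescaling.
#' @export
lfmm_assoc <- function(g, env_pc, n_factors = 5, gif_floor = 0.05) {
  n <- nrow(g$geno)
  if (n_factors >= n) stop("n_factors must be smaller than the sample count")
  env_pc <- as.matrix(env_pc)
  stopifnot(nrow(env_pc) == n)
  M <- impute_dosage(g$geno)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  gif <- numeric(ncol(env_pc))
  out <- vector("list", ncol(env_pc))
  for (e in seq_len(ncol(env_pc))) {
    ## factors from the genotype matrix with the environmental
    ## direction partialled out first (the least-squares latent-factor
    ## solution estimates U jointly with the X effect; equivalently U
    ## spans structure orthogonal to X), so structure correction does
    ## not swallow the tested environmental axis itself
    Fac <- NULL
    if (n_factors > 0) {
      xe <- cbind(1, env_pc[, e])
      Mr <- Mc - xe %*% solve(crossprod(xe), crossprod(xe, Mc))
      Fac <- svd(Mr, nu = n_factors, nv = 0)$u
    }
    W <- cbind(1, env_pc[, e], Fac)
    k <- ncol(W)
    WtWi <- solve(crossprod(W))
    B <- WtWi %*% crossprod(W, Mc)
    R <- Mc - W %*% B
    s2 <- colSums(R^2) / (n - k)
    se <- sqrt(s2 * WtWi[2, 2])
    z <- ifelse(se > 0, B[2, ] / se, NA_real_)
    lam <- stats::median(z^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
    lam <- max(lam, gif_floor)
    gif[e] <- lam
    pval <- stats::pchisq(z^2 / lam, df = 1, lower.tail = FALSE)
    out[[e]] <- data.frame(id = g$loci$id, chrom = g$loci$chrom,
                           pos = g$loci$pos,
                           pc = colnames(env_pc)[e] %||% paste0("PC", e),
                           beta = B[2, ], stat = z, p = pval,
                           method = "lfmm", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "gif") <- gif
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Flag environment-associated SNPs at a threshold
#'
#' @param results an `assoc_result`.
#' @param threshold per-test p-value cutoff, normally from
#'   [ld_bonferroni()]; significance is strict (`p < threshold`).
#' @return the input with a logical `significant` column.
#' @export
select_eas <- function(results, threshold) {
  results$significant <- !is.na(results$p) & results$p < threshold
  results
}

#' Intersect the significant loci of two association engines
#'
#' Returns loci flagged by both methods, both per environmental PC
#' (same PC in both) and pooled over PCs (significant for any PC in
#' each method).
#'
#' @param a,b `assoc_result` tables carrying a `significant` column
#'   (see [select_eas()]).
#' @return list: `per_pc` data.frame (id, chrom, pos, pc), `pooled`
#'   data.frame (id, chrom, pos) of loci in the pooled intersection.
#' @export
intersect_methods <- function(a, b) {
  stopifnot(!is.null(a$significant), !is.null(b$significant))
  key <- function(x) paste(x$id, x$pc)
  sa <- a[a$significant, , drop = FALSE]
  sb <- b[b$significant, , drop = FALSE]
  per_pc <- sa[key(sa) %in% key(sb), c("id", "chrom", "pos", "pc")]
  ua <- unique(sa[, c("id", "chrom", "pos")])
  ub <- unique(sb$id)
  pooled <- ua[ua$id %in% ub, , drop = FALSE]
  rownames(per_pc) <- rownames(pooled) <- NULL
  list(per_pc = per_pc, pooled = pooled)
}
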