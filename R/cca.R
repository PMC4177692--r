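## Canonical correspondence analysis of the group x P/A-region
## presence matrix constrained by environmental PCs, with a
## permutation test on the constrained-inertia fraction.

#' Fit a CCA of presence profiles on environmental constraints
#'
#' ter Braak's algorithm via \pkg{vegan}: the binary presence matrix
#' is treated as a 0/1 abundance contingency table, the constraints
#' are regressed in by weighted least squares, and the fitted part is
#' decomposed. Total inertia equals the scaled chi-square statistic of
#' the table; the constrained fraction is the share of that inertia
#' captured by the constrained axes. All-zero rows or columns are
#' dropped with a warning.
#'
#' @param presence groups x regions binary matrix.
#' @param constraints numeric matrix of per-group explanatory
#'   variables (rows aligned with `presence`), typically environmental
#'   PC scores.
#' @return list of class `cca_result`: `eig_constrained`,
#'   `eig_unconstrained`, `total_inertia`, `constrained_fraction`,
#'   `site_scores`, `object_scores`, `constraint_vectors` (biplot
#'   arrows), and the underlying \pkg{vegan} fit in `fit`.
#' @export
cca_fit <- function(presence, constraints) {
  presence <- as.matrix(presence)
  constraints <- as.matrix(constraints)
  stopifnot(nrow(presence) == nrow(constraints))
  if (ncol(constraints) >= nrow(presence))
    stop("saturated model: need fewer constraints than groups")
  zr <- rowSums(presence) == 0
  zc <- colSums(presence) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ", sum(zc),
            " all-zero column(s)")
    presence <- presence[!zr, !zc, drop = FALSE]
    constraints <- constraints[!zr, , drop = FALSE]
  }
  fit <- vegan::cca(presence ~ ., data = as.data.frame(constraints))
  eig_c <- unname(fit$CCA$eig)
  eig_u <- unname(fit$CA$eig)
  tot <- fit$tot.chi
  structure(list(eig_constrained = eig_c, eig_unconstrained = eig_u,
                 total_inertia = tot,
                 constrained_fraction = sum(eig_c) / tot,
                 site_scores = vegan::scores(fit, display = "lc",
                                             choices = seq_along(eig_c)),
                 object_scores = vegan::scores(fit, display = "sp",
                                               choices = seq_along(eig_c)),
                 constraint_vectors = vegan::scores(fit, display = "bp",
                                                    choices = seq_along(eig_c)),
                 fit = fit),
            class = "cca_result")
}

#' Permutation test of the constrained-inertia fraction
#'
#' Rows of the constraint matrix (group labels) are permuted, the CCA
#' refit, and p = (1 + #\{fraction_perm >= fraction_obs\}) /
#' (n_perm + 1).
#'
#' @inheritParams cca_fit
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param exhaustive if `TRUE`, enumerate all row permutations instead
#'   of sampling (small group counts only).
#' @return list: `p`, `observed` fraction, `perm_fractions`.
#' @export
cca_permutation <- function(presence, constraints, n_perm = 999, seed = 1L,
                            exhaustive = FALSE) {
  stopifnot(n_perm >= 1 || exhaustive)
  obs <- cca_fit(presence, constraints)$constrained_fraction
  n <- nrow(as.matrix(presence))
  perms <- if (exhaustive) {
    all_permutations(n)
  } else {
    set.seed(seed)
    lapply(seq_len(n_perm), function(i) sample.int(n))
  }
  frac <- vapply(perms, function(pr)
    cca_fit(presence, as.matrix(constraints)[pr, , drop = FALSE])$constrained_fraction,
    0)
  list(p = (1 + sum(frac >= obs - 1e-12)) / (length(perms) + 1),
       observed = obs, perm_fractions = frac)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (s in sub) for (k in seq_len(n))
    out[[length(out) + 1L]] <- append(s, n, after = k - 1L)
  out
}
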