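## Geodesic distances, environmental PCA, and Mantel-style matrix
## correlation.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6378.137 km (the WGS84
#' equatorial radius). The radius was chosen by back-calculation against
#' the reference pairwise distances between the sampling sites
#' shipped in inst/extdata, which match
#' 6378.137 and not the volumetric mean 6371.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees (vectorized).
#' @return distance(s) in km, symmetric and non-negative.
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * 6378.137 * asin(pmin(1, sqrt(a)))
}

#' Pairwise geodesic distance matrix from a sample sheet
#'
#' One row/column per group; group coordinates are the mean of its
#' samples' coordinates (identical within a group in the usual design).
#'
#' @param sheet a sample sheet (see [read_sample_sheet()]) or any
#'   data.frame with `group`, `lat`, `lon`.
#' @return symmetric matrix of km distances with group dimnames.
#' @export
geodesic_matrix <- function(sheet) {
  agg <- stats::aggregate(sheet[, c("lat", "lon")], list(group = sheet$group), mean)
  n <- nrow(agg)
  d <- matrix(0, n, n, dimnames = list(agg$group, agg$group))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- geodesic_km(agg$lat[i], agg$lon[i], agg$lat[j], agg$lon[j])
  d
}

#' Principal components of the normalized environment table
#'
#' Each variable is z-normalized (mean 0, sd 1) before the
#' decomposition, so the result is invariant to per-variable affine
#' rescaling. Zero-variance variables are dropped with a warning. Each
#' component is oriented so that its largest-magnitude loading is
#' positive (signs are otherwise arbitrary).
#'
#' @param env numeric matrix, locations x variables, no missing values.
#' @param k number of components to keep (default 3).
#' @return list of class `env_pcs`: `scores` (locations x k, zero mean
#'   per component), `loadings` (variables x k), `var_frac` (variance
#'   fraction of each of the `k` components), `var_frac_all` (all
#'   components; sums to 1).
#' @export
env_pca <- function(env, k = 3) {
  env <- as.matrix(env)
  if (anyNA(env)) stop("environment table contains missing values")
  if (nrow(env) < k + 1) stop("need at least k + 1 locations")
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(env)[sds == 0], collapse = ", "))
    env <- env[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_frac = frac[seq_len(k)], var_frac_all = frac),
            class = "env_pcs")
}

#' Spearman matrix correlation with Mantel permutation p-value
#'
#' Correlates the upper triangles of two symmetric matrices; the
#' p-value permutes row/column labels of the second matrix jointly
#' (Mantel scheme), two-sided by absolute rho:
#' p = (1 + #\{|rho_perm| >= |rho_obs|\}) / (n_perm + 1).
#'
#' @param dist_a,dist_b symmetric matrices of equal dimension.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list `rho`, `p`. A constant matrix yields `rho = NA` and
#'   `p = NA` (undefined correlation).
#' @export
matrix_spearman <- function(dist_a, dist_b, n_perm = 999, seed = 1L) {
  stopifnot(all(dim(dist_a) == dim(dist_b)), nrow(dist_a) == ncol(dist_a))
  n <- nrow(dist_a)
  ut <- upper.tri(dist_a)
  if (stats::sd(dist_a[ut]) == 0 || stats::sd(dist_b[ut]) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho_obs <- stats::cor(dist_a[ut], dist_b[ut], method = "spearman")
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    rho_p <- stats::cor(dist_a[ut], dist_b[perm, perm][ut], method = "spearman")
    if (abs(rho_p) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
  }
  list(rho = rho_obs, p = (1 + hits) / (n_perm + 1))
}
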