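#' Distance thresholds for nested neighbor shells on a checkered lattice
#'
#' On a checkered lattice with unit cell spacing (occupied cells are those
#' with even coordinate sum), the first shell consists of the four diagonal
#' neighbors at distance `sqrt(2)` and the cumulative second shell of the
#' twelve nearest and second-nearest occupied cells. The thresholds
#' `delta_s = s * sqrt(2) * (1 + 1e-6)` reproduce exactly L = 4 at s = 1
#' and L = 12 at s = 2 for interior individuals; the small inflation keeps
#' boundary distances float-safe.
#'
#' @param map A [spatial_map()] whose `"lattice"` attribute has
#'   `checkered = TRUE`.
#' @param s_max Largest spatial scale.
#' @return Numeric vector `delta_1 < ... < delta_{s_max}`.
#' @export
lattice_thresholds <- function(map, s_max) {
  lat <- attr(map, "lattice")
  if (is.null(lat) || !isTRUE(lat$checkered))
    stop("map has no checkered-lattice metadata; supply explicit deltas to build_neighbor_index()")
  stopifnot(s_max >= 1L)
  seq_len(s_max) * sqrt(2) * (1 + 1e-6)
}

#' Identify neighbors at nested spatial scales
#'
#' Individual `j` belongs to shell `s` of individual `i` iff
#' `delta_{s-1} < d(i, j) <= delta_s` (Euclidean distance, `delta_0 = 0`),
#' so shells are disjoint and their unions nested across scales. The
#' relation is symmetric by construction.
#'
#' @param map A [spatial_map()].
#' @param deltas Strictly increasing distance thresholds, one per scale.
#' @return An object of class `"neighbor_index"`: list with `adjacency`
#'   (one `n x n` 0/1 matrix per shell), `L` (`n x s_max` matrix of
#'   cumulative neighbor counts), `deltas`, and `n`.
#' @export
build_neighbor_index <- function(map, deltas) {
  stopifnot(inherits(map, "spatial_map"))
  deltas <- as.numeric(deltas)
  if (any(diff(deltas) <= 0) || any(deltas <= 0))
    stop("deltas must be positive and strictly increasing")
  n <- nrow(map)
  d <- as.matrix(stats::dist(cbind(map$x, map$y)))
  s_max <- length(deltas)
  adjacency <- vector("list", s_max)
  lower <- 0
  for (s in seq_len(s_max)) {
    A <- (d > lower & d <= deltas[s]) * 1
    diag(A) <- 0
    adjacency[[s]] <- A
    lower <- deltas[s]
  }
  L <- vapply(seq_len(s_max),
              function(s) rowSums(Reduce(`+`, adjacency[seq_len(s)])),
              numeric(n))
  L <- matrix(L, nrow = n, dimnames = list(map$id, paste0("s", seq_len(s_max))))
  if (all(L[, 1L] == 0))
    stop("no individual has a neighbor at scale 1; delta_1 = ", deltas[1L],
         " is too small")
  structure(list(adjacency = adjacency, L = L, deltas = deltas, n = n),
            class = "neighbor_index")
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat("Neighbor index:", x$n, "individuals,", length(x$deltas), "scale(s)\n")
  cat("  deltas:", paste(format(x$deltas, digits = 4), collapse = ", "), "\n")
  cat("  median cumulative L:",
      paste(apply(x$L, 2L, stats::median), collapse = ", "), "\n")
  invisible(x)
}

#' Exponential distance-decay weight
#'
#' `w(s, alpha) = exp(-alpha * (s - 1))`: shell 1 always has weight 1 and
#' farther shells are down-weighted by the decay coefficient `alpha`.
#'
#' @param s Shell index (>= 1).
#' @param alpha Decay coefficient (>= 0).
#' @return Numeric weight in `(0, 1]`.
#' @export
decay_weight <- function(s, alpha) {
  if (any(s < 1)) stop("shell index s must be >= 1")
  if (any(alpha < 0)) stop("alpha must be >= 0")
  exp(-alpha * (s - 1))
}

#' Neighbor genotypic-identity covariates
#'
#' Builds, for each individual `i` and marker `k`, the scaled sum of
#' allele products with its neighbors:
#' `X2[i, k] = (1/L_i) * sum_{t <= s} sum_{j in shell t} w_t * x_i[k] * x_j[k]`,
#' with `w_t = 1` (unweighted, the fitting model) or
#' `w_t = decay_weight(t, alpha)` (the generative model), and `L_i` the
#' cumulative neighbor count within scale `s`. `X2` entries lie in
#' `[-1, +1]`: +1 when all neighbors carry the focal allele, -1 when all
#' differ, 0 when identical and different alleles balance. The asymmetric
#' covariate is the elementwise product `X12 = X1 * X2`. Individuals with
#' no neighbors get zero rows (with a warning) rather than being dropped.
#'
#' @param G A [genotype_table()] or a plain numeric matrix (individuals x
#'   markers, e.g. column-standardized genotypes).
#' @param idx A [build_neighbor_index()] covering scales `1..s`.
#' @param s Spatial scale (number of cumulative shells to use).
#' @param weighted Apply the distance-decay weights? Default `FALSE`.
#' @param alpha Decay coefficient used when `weighted = TRUE`.
#' @return List of class `"neighbor_covariates"` with `X1`, `X2`, `X12`
#'   (`n x q` matrices), and `L` (cumulative counts at scale `s`).
#' @export
neighbor_covariate <- function(G, idx, s = 1L, weighted = FALSE, alpha = 0) {
  stopifnot(inherits(idx, "neighbor_index"))
  X1 <- if (inherits(G, "genotype_table")) G$values else as.matrix(G)
  if (nrow(X1) != idx$n) stop("genotypes and neighbor index disagree on n")
  if (s < 1L || s > length(idx$deltas))
    stop("neighbor index does not cover scale ", s)
  acc <- matrix(0, nrow(X1), ncol(X1))
  for (t in seq_len(s)) {
    w <- if (weighted) decay_weight(t, alpha) else 1
    acc <- acc + w * (idx$adjacency[[t]] %*% X1)
  }
  L <- idx$L[, s]
  if (any(L == 0))
    warning(sum(L == 0), " individual(s) with no neighbors at scale ", s,
            "; their neighbor covariates are set to 0")
  Linv <- ifelse(L > 0, 1 / L, 0)
  X2 <- X1 * (Linv * acc)
  dimnames(X2) <- dimnames(X1)
  structure(list(X1 = X1, X2 = X2, X12 = X1 * X2, L = L),
            class = "neighbor_covariates")
}

#' Per-marker collinearity between self and neighbor covariates
#'
#' The self genotype `x_i` and the neighbor identity covariate become
#' correlated when the minor allele is rare or the neighborhood spans the
#' whole field (where `X2` degenerates to `x_i * mean(x_j)`); this
#' diagnostic reports the per-marker Pearson correlation and its
#' quantiles. Markers with zero variance in either covariate give `NA`.
#'
#' @param C A [neighbor_covariate()] result.
#' @return List of class `"collinearity_diagnostics"` with `r` (per-marker
#'   correlation) and `summary` (quantiles of `|r|`).
#' @export
collinearity_diagnostics <- function(C) {
  stopifnot(inherits(C, "neighbor_covariates"))
  if (nrow(C$X1) < 3L) stop("need at least 3 individuals")
  r <- vapply(seq_len(ncol(C$X1)), function(k) {
    x <- C$X1[, k]; z <- C$X2[, k]
    if (stats::sd(x) == 0 || stats::sd(z) == 0) return(NA_real_)
    stats::cor(x, z)
  }, numeric(1))
  names(r) <- colnames(C$X1)
  qs <- stats::quantile(abs(r), c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  structure(list(r = r, summary = qs), class = "collinearity_diagnostics")
}

#' @export
print.collinearity_diagnostics <- function(x, ...) {
  cat("Self vs neighbor covariate collinearity (|r| quantiles):\n")
  print(round(x$summary, 3))
  cat(sum(is.na(x$r)), "marker(s) with undefined correlation\n")
  invisible(x)
}
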