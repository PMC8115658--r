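#' Simulation configuration
#'
#' Bundles the parameters of the generative phenotype model: the distance
#' decay `alpha` of neighbor effects, the variance budget (`pve_beta` for
#' major-effect genes, `pve_total = pve_beta + pve_u` adding the polygenic
#' variance components; the residual takes `1 - pve_total`), the relative
#' contribution of the self, neighbor, and self-by-neighbor variance
#' components (`ratio`, applied to `sigma_1^2 : sigma_2^2 : sigma_12^2`),
#' the number of causal markers, and the maximum shell `s_max` over which
#' the decay-weighted covariates are accumulated.
#'
#' @param alpha Distance-decay coefficient (>= 0); 3 gives a narrow,
#'   0.01 a broad effective range.
#' @param pve_beta Variance fraction of the causal fixed effects, in (0, 1).
#' @param pve_total Fixed plus random genetic variance fraction; must
#'   satisfy `pve_beta <= pve_total < 1`.
#' @param ratio Length-3 non-negative vector: self, neighbor,
#'   self-by-neighbor variance-component weights.
#' @param n_causal Number of causal markers.
#' @param s_max Maximum neighbor shell of the generative model.
#' @param seed Optional integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(alpha = 1, pve_beta = 0.3, pve_total = 0.4,
                       ratio = c(8, 1, 1), n_causal = 50, s_max = 3L,
                       seed = NULL) {
  stopifnot(alpha >= 0, pve_beta > 0, pve_beta <= pve_total, pve_total < 1,
            length(ratio) == 3L, all(ratio >= 0), sum(ratio) > 0,
            n_causal >= 1, s_max >= 1)
  structure(list(alpha = alpha, pve_beta = pve_beta, pve_total = pve_total,
                 ratio = ratio, n_causal = as.integer(n_causal),
                 s_max = as.integer(s_max), seed = seed),
            class = "sim_config")
}

#' Generate structured synthetic genotypes
#'
#' Balding-Nichols-style draw for inbred individuals: each marker gets an
#' ancestral alternate-allele frequency uniform on
#' `(maf_min, 1 - maf_min)`; each of `n_subpop` subpopulations perturbs it
#' by a Beta draw with concentration `(1 - fst) / fst`; individuals
#' (split evenly across subpopulations) are drawn as homozygous -1/+1.
#' Markers whose realized MAF falls below `maf_min` are redrawn, so all
#' realized MAFs are at least `maf_min`.
#'
#' @param n,q Numbers of individuals and markers.
#' @param n_subpop Number of subpopulations (1 disables structure).
#' @param fst Wright's fixation index in `[0, 1)`; 0 disables the
#'   subpopulation perturbation.
#' @param maf_min Minimum (ancestral and realized) minor allele frequency.
#' @param seed Optional integer seed.
#' @return A [genotype_table()] with a `"subpop"` attribute giving the
#'   subpopulation label of each individual.
#' @export
generate_genotypes <- function(n, q, n_subpop = 3L, fst = 0.3,
                               maf_min = 0.1, seed = NULL) {
  stopifnot(n >= 2, q >= 2, fst >= 0, fst < 1)
  if (maf_min >= 0.5) stop("maf_min must be < 0.5")
  if (!is.null(seed)) set.seed(seed)
  pop <- rep(seq_len(n_subpop), length.out = n)
  draw <- function(qk) {
    p_anc <- stats::runif(qk, maf_min, 1 - maf_min)
    X <- matrix(0, n, qk)
    for (s in seq_len(n_subpop)) {
      rows <- which(pop == s)
      p_s <- if (fst > 0) {
        stats::rbeta(qk, p_anc * (1 - fst) / fst,
                     (1 - p_anc) * (1 - fst) / fst)
      } else p_anc
      X[rows, ] <- ifelse(matrix(stats::runif(length(rows) * qk),
                                 length(rows)) <
                            matrix(p_s, length(rows), qk, byrow = TRUE),
                          1, -1)
    }
    X
  }
  X <- draw(q)
  for (it in 1:1000) {
    maf <- compute_maf(X)
    bad <- which(maf < maf_min)
    if (length(bad) == 0L) break
    X[, bad] <- draw(length(bad))
  }
  if (length(bad <- which(compute_maf(X) < maf_min)) > 0L)
    stop("could not satisfy maf_min = ", maf_min, " after redrawing")
  dimnames(X) <- list(paste0("ind_", seq_len(n)), paste0("m", seq_len(q)))
  G <- genotype_table(X)
  attr(G, "subpop") <- pop
  G
}

#' Place individuals on a (checkered) lattice
#'
#' Assigns `n` individuals at random, without replacement, to the occupied
#' cells of a `rows x cols` lattice with unit spacing. On a checkered
#' lattice the occupied cells are exactly those with even coordinate sum,
#' mimicking alternating planting positions; the occupancy set is fixed
#' and only the assignment is randomized.
#'
#' @param n Number of individuals.
#' @param rows,cols Lattice dimensions.
#' @param checkered Occupy only even-coordinate-sum cells (default `TRUE`).
#' @param ids Individual ids (default `ind_1..ind_n`, matching
#'   [generate_genotypes()]).
#' @param seed Optional integer seed.
#' @return A [spatial_map()] with lattice metadata.
#' @export
place_on_grid <- function(n, rows, cols, checkered = TRUE, ids = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(y = seq_len(rows), x = seq_len(cols))
  if (checkered) cells <- cells[(cells$x + cells$y) %% 2 == 0, ]
  if (nrow(cells) < n)
    stop("only ", nrow(cells), " occupied cells for ", n, " individuals")
  if (is.null(ids)) ids <- paste0("ind_", seq_len(n))
  pick <- cells[sample.int(nrow(cells), n), ]
  spatial_map(ids, pick$x, pick$y,
              lattice = list(rows = rows, cols = cols,
                             checkered = checkered))
}

# Largest-remainder apportionment, ties to the earlier-listed class.
largest_remainder <- function(n, props) {
  quota <- n * props
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), seq_along(props))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Assign causal markers to effect classes
#'
#' Samples `n_causal` marker indices without replacement and partitions
#' them into four classes at 15% (self + neighbor + asymmetric), 15%
#' (self + neighbor, no asymmetry), 35% (self only), and 35% (neighbor
#' only), using largest-remainder rounding with ties resolved toward the
#' earlier-listed class. Each non-zero coefficient independently receives
#' a -1 or +1 sign.
#'
#' @param q Total number of markers.
#' @param n_causal Number of causal markers (<= q).
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `"causal_set"` with columns `index`,
#'   `class` (one of `"self+nei+asym"`, `"self+nei"`, `"self"`, `"nei"`),
#'   and the sign columns `b1`, `b2`, `b12` (0 where the class has no such
#'   effect).
#' @export
assign_causal <- function(q, n_causal, seed = NULL) {
  if (n_causal > q) stop("n_causal exceeds the number of markers")
  if (!is.null(seed)) set.seed(seed)
  sizes <- largest_remainder(n_causal, c(0.15, 0.15, 0.35, 0.35))
  classes <- rep(c("self+nei+asym", "self+nei", "self", "nei"), sizes)
  idx <- sample.int(q, n_causal)
  rsign <- function(k) ifelse(stats::runif(k) < 0.5, -1, 1)
  has1 <- classes != "nei"
  has2 <- classes != "self"
  has12 <- classes == "self+nei+asym"
  out <- data.frame(index = idx, class = classes,
                    b1 = ifelse(has1, rsign(n_causal), 0),
                    b2 = ifelse(has2, rsign(n_causal), 0),
                    b12 = ifelse(has12, rsign(n_causal), 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("causal_set", "data.frame")
  out
}

standardize_markers <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  scale(X, center = mu, scale = sdv)
}

#' Simulate phenotypes under the generative neighbor-effects model
#'
#' Builds the phenotype
#' `y_i = b1 x_i + (b2/L) sum w(s, alpha) x_i x_j + b12 (x_i/L) sum
#' w(s, alpha) x_i x_j + u_i + e_i`
#' from causal self, neighbor, and asymmetric effects with exponential
#' distance decay, a polygenic random effect
#' `u ~ N(0, s1 K1 + s2 K2 + s12 K12)` with component variances
#' proportional to `cfg$ratio`, and i.i.d. Gaussian residuals. Marker
#' columns are standardized (mean 0, variance 1) before effect
#' construction. Two scalar gains — one for the fixed block, one for the
#' random block — are calibrated by alternating 1-D optimization so the
#' realized variance fractions hit `pve_beta` and
#' `pve_total - pve_beta`; the returned phenotype is standardized to mean
#' 0 and variance 1.
#'
#' @param G A [genotype_table()].
#' @param map A [spatial_map()] (lattice metadata required unless `idx`
#'   is supplied).
#' @param causal A [assign_causal()] result.
#' @param cfg A [sim_config()].
#' @param idx Optional pre-built [build_neighbor_index()] covering
#'   `1..cfg$s_max`.
#' @return A list of class `"sim_phenotype"`: `y` (standardized), `truth`
#'   (the causal set with calibrated coefficients `beta1`, `beta2`,
#'   `beta12` on the raw-phenotype scale), `true_pve`
#'   (realized `beta`, `u`, and `total` fractions), `sd_raw`
#'   (standard deviation of the non-standardized phenotype; multiplying
#'   estimated coefficients by it recovers the truth scale), and the
#'   component vectors.
#' @export
simulate_phenotype <- function(G, map, causal, cfg, idx = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(causal, "causal_set"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  Z <- standardize_markers(G$values)
  if (is.null(idx))
    idx <- build_neighbor_index(map, lattice_thresholds(map, cfg$s_max))
  C <- neighbor_covariate(Z, idx, s = cfg$s_max, weighted = TRUE,
                          alpha = cfg$alpha)
  n <- nrow(Z); q <- ncol(Z)

  sel <- causal$index
  r <- cfg$ratio / sum(cfg$ratio)
  # The ratio governs the relative importance of the self, neighbor, and
  # self-by-neighbor effects in both the fixed and the random blocks:
  # each fixed sub-block is normalized to unit variance and reweighted so
  # the realized block variances are proportional to the ratio.
  parts <- list(as.numeric(Z[, sel, drop = FALSE] %*% causal$b1),
                as.numeric(C$X2[, sel, drop = FALSE] %*% causal$b2),
                as.numeric(C$X12[, sel, drop = FALSE] %*% causal$b12))
  gains <- vapply(1:3, function(i) {
    v <- stats::var(parts[[i]])
    if (r[i] > 0 && v > 0) sqrt(r[i] / v) else 0
  }, numeric(1))
  f <- gains[1] * parts[[1]] + gains[2] * parts[[2]] + gains[3] * parts[[3]]
  Sigma <- matrix(0, n, n)
  if (r[1] > 0) Sigma <- Sigma + r[1] * tcrossprod(Z) / (q - 1)
  if (r[2] > 0) Sigma <- Sigma + r[2] * tcrossprod(C$X2) / (q - 1)
  if (r[3] > 0) Sigma <- Sigma + r[3] * tcrossprod(C$X12) / (q - 1)
  jitter <- 1e-8 * mean(diag(Sigma))
  u <- as.numeric(t(chol(Sigma + diag(jitter + 1e-12, n))) %*%
                    stats::rnorm(n))
  e <- stats::rnorm(n)
  # The random draw lies partly along the fixed block (both are built from
  # the same genotype covariates), which would make the realized variance
  # fractions non-identifiable; decorrelate the blocks so the budget is
  # exact: u is residualized on f, and e on both.
  if (stats::var(f) > 0) {
    u <- stats::residuals(stats::lm(u ~ f))
    e <- stats::residuals(stats::lm(e ~ f + u))
  }

  pve_u <- cfg$pve_total - cfg$pve_beta
  pve_e <- 1 - cfg$pve_total
  vf <- stats::var(f); vu <- stats::var(u); ve <- stats::var(e)
  if (vf <= 0) stop("fixed part has zero variance; no causal effect realized")
  a <- sqrt(cfg$pve_beta / pve_e * ve / vf)
  b <- if (pve_u > 0 && vu > 0) sqrt(pve_u / pve_e * ve / vu) else 0
  frac <- function(a, b, which) {
    tot <- stats::var(a * f + b * u + e)
    if (which == 1L) a^2 * vf / tot else b^2 * vu / tot
  }
  for (round in 1:4) {
    a <- stats::optimize(function(s) (frac(s, b, 1L) - cfg$pve_beta)^2,
                         interval = c(0, max(a * 10, 1)))$minimum
    if (pve_u > 0 && vu > 0)
      b <- stats::optimize(function(s) (frac(a, s, 2L) - pve_u)^2,
                           interval = c(0, max(b * 10, 1)))$minimum
  }
  # record the raw phenotype on the scale where the fixed coefficients
  # equal the block gains (dividing by the fixed-block calibration gain
  # changes nothing after standardization), so true coefficients are
  # recovered as beta_hat * sd(raw phenotype)
  y_raw <- f + (b / a) * u + e / a
  sd_raw <- stats::sd(y_raw)
  y <- as.numeric((y_raw - mean(y_raw)) / sd_raw)

  truth <- causal
  truth$beta1 <- gains[1] * causal$b1
  truth$beta2 <- gains[2] * causal$b2
  truth$beta12 <- gains[3] * causal$b12
  structure(list(y = y, truth = truth,
                 true_pve = list(beta = frac(a, b, 1L), u = frac(a, b, 2L),
                                 total = frac(a, b, 1L) + frac(a, b, 2L)),
                 sd_raw = sd_raw, fixed = a * f, random = b * u, resid = e,
                 cfg = cfg),
            class = "sim_phenotype")
}

#' @export
print.sim_phenotype <- function(x, ...) {
  cat("Simulated phenotype: n =", length(x$y), "\n")
  cat("  realized PVE_beta =", round(x$true_pve$beta, 3),
      " PVE_u =", round(x$true_pve$u, 3),
      " total =", round(x$true_pve$total, 3), "\n")
  cat("  causal markers:", nrow(x$truth), "(",
      paste(table(x$truth$class)[unique(x$truth$class)], collapse = "/"),
      ")\n")
  invisible(x)
}
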