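#' Neighbor GWAS: fit self and neighbor genetic effects
#'
#' The main fitting function. For each marker `k` and focal individual
#' `i`, the model extends the standard kinship mixed model with the
#' neighbor genotypic-identity covariate (the mean allele product with
#' the `L_i` neighbors within spatial scale `s`):
#'
#' `y_i = b0 + b1 x_i + (b2 / L_i) * sum_{j in N_s(i)} x_i x_j + u_i + e_i`
#'
#' with `u ~ N(0, s1^2 K1 + s2^2 K2)` and `e ~ N(0, se^2 I)` — the inverse
#' problem of a two-dimensional Ising model in which `b2` plays the role
#' of the interaction energy and `b1` of the external field. The function
#'
#' 1. builds nested neighbor shells from the spatial map,
#' 2. partitions phenotypic variance across the requested scales
#'    ([pve_partition()]) and estimates the effective scale `s_hat` by the
#'    argmax of the Delta PVE_nei profile,
#' 3. runs the forward-selection association scan ([assoc_scan()]) at
#'    `s` (default: `s_hat`).
#'
#' @param formula Model formula for the phenotype and fixed covariates,
#'   e.g. `damage ~ size + bolting`, evaluated in `data`; or `NULL`, in
#'   which case `data` itself is taken as the phenotype vector and the
#'   design is intercept-only.
#' @param data A data.frame in genotype individual order (see
#'   [load_table()]), or a numeric phenotype vector when `formula` is
#'   `NULL`.
#' @param geno A [genotype_table()].
#' @param smap A [spatial_map()].
#' @param scales Integer vector of spatial scales for the PVE profile
#'   (default `1:2`).
#' @param s Scale for the association scan; default the estimated
#'   effective scale.
#' @param deltas Explicit distance thresholds (one per scale); default
#'   [lattice_thresholds()] from the map's lattice metadata.
#' @param asym Also test asymmetric neighbor effects (default `FALSE`).
#' @param scan Run the per-marker scan (default `TRUE`; `FALSE` stops
#'   after variance partitioning).
#' @return Object of class `"nbgwas"` with components `pve`
#'   ([pve_partition()] result), `scan` ([assoc_scan()] result or
#'   `NULL`), `s` (scale scanned), `vc` (plug-in variance components at
#'   `s`), `tau` (fixed-covariate GLS coefficients), and the call.
#' @seealso [simulate_phenotype()] to generate test data, [anneal()] for
#'   arrangement optimization from fitted coefficients.
#' @examples
#' G <- generate_genotypes(100, 300, seed = 1)
#' map <- place_on_grid(100, 10, 20, seed = 1)
#' cs <- assign_causal(300, 10, seed = 1)
#' sim <- simulate_phenotype(G, map, cs,
#'                           sim_config(alpha = 3, pve_beta = 0.6,
#'                                      pve_total = 0.8, seed = 1))
#' fit <- neighbor_gwas(data = sim$y, geno = G, smap = map, scales = 1:2)
#' fit
#' @export
neighbor_gwas <- function(formula = NULL, data, geno, smap, scales = 1:2,
                          s = NULL, deltas = NULL, asym = FALSE,
                          scan = TRUE) {
  cl <- match.call()
  stopifnot(inherits(geno, "genotype_table"), inherits(smap, "spatial_map"))
  if (is.null(formula)) {
    y <- as.numeric(data)
    W <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    mf <- stats::model.frame(formula, data)
    y <- stats::model.response(mf)
    W <- stats::model.matrix(formula, mf)
  }
  if (length(y) != nrow(geno$values))
    stop("phenotype length does not match the genotype table")
  if (nrow(smap) != nrow(geno$values))
    stop("spatial map does not match the genotype table")
  scales <- sort(unique(as.integer(scales)))
  if (is.null(deltas)) deltas <- lattice_thresholds(smap, max(scales))
  idx <- build_neighbor_index(smap, deltas)
  K1 <- make_kinship(geno, "self")
  covs <- lapply(scales, function(sc) neighbor_covariate(geno, idx, s = sc))
  K2s <- stats::setNames(lapply(covs, function(C)
    make_kinship(C$X2, "neighbor")), scales)
  pve <- pve_partition(y, W, K1, K2s)
  s_scan <- if (is.null(s)) pve$s_hat else as.integer(s)
  scan_res <- vc <- tau <- NULL
  if (scan) {
    i <- match(s_scan, scales)
    if (is.na(i)) stop("scan scale ", s_scan, " not among the fitted scales")
    scan_res <- assoc_scan(y, W, geno, X2 = covs[[i]]$X2, K1 = K1,
                           K2 = K2s[[i]],
                           X12 = if (asym) covs[[i]]$X12,
                           test_asym = asym)
    vc <- attr(scan_res, "vc2")
    st <- mm_setup(y, W, list(K1, K2s[[i]]), vc)
    tau <- st$null$coef
  }
  structure(list(call = cl, y = y, W = W, pve = pve, scan = scan_res,
                 s = s_scan, vc = vc, tau = tau, scales = scales,
                 n = length(y), q = ncol(geno$values)),
            class = "nbgwas")
}

#' @export
print.nbgwas <- function(x, ...) {
  cat("Neighbor GWAS fit: n =", x$n, " markers =", x$q, "\n")
  cat("Scales profiled:", paste(x$scales, collapse = ", "),
      " scan at s =", x$s, "\n\n")
  print(x$pve)
  if (!is.null(x$scan)) {
    thr <- attr(x$scan, "bonferroni")
    cat("\nAssociation scan:", sum(x$scan$p_self <= thr, na.rm = TRUE),
        "self and",
        if (!is.null(x$scan$p_nei))
          sum(x$scan$p_nei <= thr, na.rm = TRUE) else 0,
        "neighbor marker(s) below the Bonferroni threshold",
        format(thr, digits = 3), "\n")
  }
  invisible(x)
}

#' @export
summary.nbgwas <- function(object, n_top = 5L, ...) {
  out <- list(fit = object, n_top = n_top)
  if (!is.null(object$scan)) {
    sc <- as.data.frame(object$scan)
    out$top_self <- utils::head(sc[order(sc$p_self), ], n_top)
    if (!is.null(sc$p_nei))
      out$top_nei <- utils::head(sc[order(sc$p_nei), ], n_top)
  }
  class(out) <- "summary.nbgwas"
  out
}

#' @export
print.summary.nbgwas <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$top_self)) {
    cat("\nTop self-effect markers:\n")
    print(x$top_self, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$top_nei)) {
    cat("\nTop neighbor-effect markers:\n")
    print(x$top_nei, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.nbgwas <- function(object, ...) {
  if (is.null(object$scan)) return(object$tau)
  cols <- intersect(c("marker_id", "beta1_hat", "beta2_hat", "beta12_hat"),
                    names(object$scan))
  as.data.frame(object$scan)[, cols]
}

#' @export
residuals.nbgwas <- function(object, ...) {
  # marginal residuals about the fixed covariates under the two-component
  # GLS fit (markers not included)
  if (is.null(object$tau)) return(object$y - mean(object$y))
  as.numeric(object$y - object$W %*% object$tau)
}

#' Manhattan plot of a neighbor GWAS scan
#'
#' One panel per tested effect (self, neighbor, and asymmetric when
#' present), with the Bonferroni threshold `0.05/q` as a dashed line.
#'
#' @param x An `"nbgwas"` object with a scan component.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nbgwas <- function(x, ...) {
  if (is.null(x$scan)) stop("no scan component to plot")
  sc <- as.data.frame(x$scan)
  effects <- c(self = "p_self",
               neighbor = if ("p_nei" %in% names(sc)) "p_nei",
               asymmetric = if ("p_asym" %in% names(sc)) "p_asym")
  thr <- attr(x$scan, "bonferroni")
  old <- graphics::par(mfrow = c(length(effects), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  chrf <- factor(sc$chrom, levels = unique(sc$chrom))
  xpos <- seq_len(nrow(sc))
  for (i in seq_along(effects)) {
    p <- sc[[effects[i]]]
    graphics::plot(xpos, -log10(p), pch = 20, cex = 0.6,
                   col = c("grey30", "steelblue")[(as.integer(chrf) %% 2) + 1],
                   xlab = "marker", ylab = expression(-log[10](p)),
                   main = paste(names(effects)[i], "effects"), ...)
    graphics::abline(h = -log10(thr), lty = 2, col = "red")
  }
  invisible(x)
}
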