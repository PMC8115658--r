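#' Variance partitioning into self and neighbor components
#'
#' Fits, by [reml_fit()], (a) the fixed-effects-only null, (b) the
#' self-kinship-only model, (c) the neighbor-kinship-only model per scale,
#' and (d) the joint two-component model per scale, and derives the PVE
#' (proportion of phenotypic variance explained) metrics:
#'
#' * single PVE_self `= s1/(s1 + se)` from (b); single PVE_nei analogously
#'   from (c) — known to overstate either component under collinearity;
#' * partial PVE_self `= s1/(s1 + s2 + se)` and partial PVE_nei
#'   `= s2/(s1 + s2 + se)` from (d);
#' * net PVE_nei `= (partial self + partial nei) - single self`, the
#'   conservative gain over the standard (self-only) model;
#' * Delta PVE_nei between successive scales, whose argmax estimates the
#'   effective spatial scale of the neighbor effects (at the first scale
#'   the increment is taken from 0, since no neighbor model exists at
#'   s = 0; partial PVE_self at s = 0 equals single PVE_self).
#'
#' Likelihood-ratio tests compare (b) vs (a) for single PVE_self, (c) vs
#' (a) for single PVE_nei, (d) vs (b) for partial PVE_nei, and (d) vs (c)
#' for partial PVE_self, each on 1 df.
#'
#' @param y Phenotype vector.
#' @param W Fixed-covariate design (default intercept only).
#' @param K1 Self kinship ([make_kinship()] with `kind = "self"`).
#' @param K2_by_scale Named list of neighbor kinship matrices, one per
#'   spatial scale (names parsed as the scale index; unnamed lists are
#'   taken as scales `1..length`).
#' @param boundary Use the 50:50 boundary mixture in the variance LRTs
#'   (default `FALSE`, plain chi-squared on 1 df).
#' @param ... Passed to [reml_fit()].
#' @return Object of class `"nbgwas_pve"` with per-scale vectors of the
#'   metrics, LRT p-values, `s_hat` (from [effective_scale()]), and a
#'   `converged` flag (`FALSE` marks the metrics unreliable).
#' @export
pve_partition <- function(y, W = NULL, K1, K2_by_scale, boundary = FALSE,
                          ...) {
  if (inherits(K2_by_scale, "kinship_matrix") || is.matrix(K2_by_scale))
    K2_by_scale <- list(K2_by_scale)
  scales <- names(K2_by_scale)
  scales <- if (is.null(scales)) seq_along(K2_by_scale) else
    as.integer(gsub("[^0-9]", "", scales))
  ns <- length(K2_by_scale)

  fit_a <- reml_fit(y, W, list(), ...)
  fit_b <- reml_fit(y, W, list(K1), ...)
  frac <- function(f, i) {
    s <- f$sigma2
    unname(s[i] / sum(s))
  }
  single_self <- frac(fit_b, 1L)
  p_single_self <- lrt_pvalue(fit_b$loglik_reml, fit_a$loglik_reml,
                              boundary = boundary)

  single_nei <- partial_self <- partial_nei <- net_nei <-
    p_single_nei <- p_partial_nei <- p_partial_self <- numeric(ns)
  lrt_partial_nei <- numeric(ns)
  conv <- fit_a$converged && fit_b$converged
  for (i in seq_len(ns)) {
    fit_c <- reml_fit(y, W, list(K2_by_scale[[i]]), ...)
    fit_d <- reml_fit(y, W, list(K1, K2_by_scale[[i]]), ...)
    conv <- conv && fit_c$converged && fit_d$converged
    single_nei[i] <- frac(fit_c, 1L)
    partial_self[i] <- frac(fit_d, 1L)
    partial_nei[i] <- frac(fit_d, 2L)
    net_nei[i] <- partial_self[i] + partial_nei[i] - single_self
    p_single_nei[i] <- lrt_pvalue(fit_c$loglik_reml, fit_a$loglik_reml,
                                  boundary = boundary)
    lrt_partial_nei[i] <- max(0, 2 * (fit_d$loglik_reml - fit_b$loglik_reml))
    p_partial_nei[i] <- lrt_pvalue(fit_d$loglik_reml, fit_b$loglik_reml,
                                   boundary = boundary)
    p_partial_self[i] <- lrt_pvalue(fit_d$loglik_reml, fit_c$loglik_reml,
                                    boundary = boundary)
  }
  delta <- c(partial_nei[1L], diff(partial_nei))
  out <- structure(list(scales = scales,
                        single_pve_self = single_self,
                        p_single_self = p_single_self,
                        single_pve_nei = stats::setNames(single_nei, scales),
                        p_single_nei = p_single_nei,
                        partial_pve_self = stats::setNames(partial_self, scales),
                        partial_pve_nei = stats::setNames(partial_nei, scales),
                        net_pve_nei = stats::setNames(net_nei, scales),
                        delta_pve_nei = stats::setNames(delta, scales),
                        lrt_partial_nei = lrt_partial_nei,
                        p_partial_nei = p_partial_nei,
                        p_partial_self = p_partial_self,
                        converged = conv),
                   class = "nbgwas_pve")
  if (!conv) warning("REML did not converge in at least one sub-model; PVE metrics unreliable")
  out$s_hat <- effective_scale(out)
  out
}

#' Effective spatial scale from the Delta PVE profile
#'
#' Returns `arg max_s Delta PVE_nei(s)`, where
#' `Delta PVE_nei(s) = partial PVE_nei(s) - partial PVE_nei(s - 1)` and the
#' neighbor PVE at s = 0 is 0. Ties are broken toward the smallest scale.
#'
#' @param P A [pve_partition()] result.
#' @return The estimated effective scale (one of `P$scales`).
#' @export
effective_scale <- function(P) {
  stopifnot(inherits(P, "nbgwas_pve"))
  if (length(P$scales) < 2L)
    warning("only one spatial scale available; returning it")
  P$scales[which.max(P$delta_pve_nei)]
}

#' @export
print.nbgwas_pve <- function(x, digits = 3, ...) {
  cat("Variance partitioning (PVE)\n")
  cat("  single PVE_self = ", round(x$single_pve_self, digits),
      " (p = ", format.pval(x$p_single_self, digits = 3), ")\n", sep = "")
  tab <- data.frame(s = x$scales,
                    single_nei = round(x$single_pve_nei, digits),
                    partial_self = round(x$partial_pve_self, digits),
                    partial_nei = round(x$partial_pve_nei, digits),
                    net_nei = round(x$net_pve_nei, digits),
                    delta_nei = round(x$delta_pve_nei, digits),
                    p_partial_nei = format.pval(x$p_partial_nei, digits = 3))
  print(tab, row.names = FALSE)
  cat("  effective scale s_hat =", x$s_hat, "\n")
  invisible(x)
}

#' Forward-selection association scan for self and neighbor effects
#'
#' Per-marker tests following the forward-selection order that keeps the
#' neighbor test conservative under self-neighbor collinearity:
#'
#' 1. the null likelihood uses the self-kinship-only covariance
#'    (`sigma_2^2 = 0`) with no marker;
#' 2. the self effect `beta_1` is tested by LRT against that null;
#' 3. the self-likelihood is recomputed under the two-component covariance
#'    with the self marker included;
#' 4. the neighbor effect `beta_2` is tested by LRT against the
#'    self-likelihood (and optionally the asymmetric effect `beta_12` as a
#'    third step on top).
#'
#' Variance components are estimated once on the no-marker model and held
#' fixed across markers (plug-in scan); `reestimate = TRUE` re-fits them
#' per marker (validation only, much slower). With `X2 = NULL` the scan
#' reduces exactly to a standard single-kinship GWAS of the self effects.
#'
#' @param y Phenotype vector.
#' @param W Fixed-covariate design (default intercept only).
#' @param G [genotype_table()] (or plain -1/+1 matrix) of self genotypes.
#' @param X2 Neighbor covariate matrix at the chosen scale (from
#'   [neighbor_covariate()]), or `NULL` for a standard GWAS.
#' @param K1 Self kinship matrix.
#' @param K2 Neighbor kinship matrix at the same scale as `X2`.
#' @param X12 Asymmetric covariate matrix (required if `test_asym`).
#' @param test_asym Also test the asymmetric effect (default `FALSE`).
#' @param reestimate Re-estimate variance components per marker.
#' @return A `data.frame` of class `"nbgwas_scan"` with one row per
#'   marker: `marker_id`, `chrom`, `pos`, `maf`, `beta1_hat`, `p_self`,
#'   and (when applicable) `beta2_hat`, `p_nei`, `beta12_hat`, `p_asym`,
#'   plus a `flag` column marking monomorphic or collinear markers.
#'   Attributes carry the variance-component fits and the Bonferroni
#'   threshold `0.05 / q`.
#' @export
assoc_scan <- function(y, W = NULL, G, X2 = NULL, K1, K2 = NULL,
                       X12 = NULL, test_asym = FALSE, reestimate = FALSE) {
  y <- as.numeric(y)
  Gv <- if (inherits(G, "genotype_table")) G$values else as.matrix(G)
  q <- ncol(Gv)
  n <- nrow(Gv)
  marker_id <- colnames(Gv)
  if (is.null(marker_id)) marker_id <- paste0("m", seq_len(q))
  chrom <- if (inherits(G, "genotype_table")) G$chrom else rep("1", q)
  pos <- if (inherits(G, "genotype_table")) G$pos else seq_len(q)
  maf <- if (inherits(G, "genotype_table")) G$maf else compute_maf(Gv)
  if (test_asym && is.null(X12))
    stop("test_asym = TRUE requires X12")
  do_nei <- !is.null(X2)
  if (do_nei && is.null(K2)) stop("X2 given without K2")

  vc1 <- reml_fit(y, W, list(K1))
  setup1 <- mm_setup(y, W, list(K1), vc1)
  Gt1 <- crossprod(setup1$U, Gv)
  if (do_nei) {
    vc2 <- reml_fit(y, W, list(K1, K2))
    setup2 <- mm_setup(y, W, list(K1, K2), vc2)
    Gt2 <- crossprod(setup2$U, Gv)
    X2t2 <- crossprod(setup2$U, X2)
    if (test_asym) X12t2 <- crossprod(setup2$U, X12)
  }

  beta1 <- beta2 <- beta12 <- rep(NA_real_, q)
  p_self <- p_nei <- p_asym <- rep(NA_real_, q)
  flag <- character(q)
  sd0 <- apply(Gv, 2L, stats::sd)
  sdX2 <- if (do_nei) apply(X2, 2L, stats::sd) else NULL

  for (k in seq_len(q)) {
    if (sd0[k] == 0) {
      p_self[k] <- 1
      if (do_nei) p_nei[k] <- 1
      if (test_asym) p_asym[k] <- 1
      flag[k] <- "monomorphic"
      next
    }
    if (reestimate) {
      vck <- reml_fit(y, cbind(if (is.null(W)) matrix(1, n, 1) else W,
                               Gv[, k]), list(K1))
      ft <- fixed_effect_test(y, W, Gv[, k, drop = FALSE], list(K1), vck)
      beta1[k] <- unname(utils::tail(ft$beta_hat, 1L))
      p_self[k] <- ft$p
      if (ft$collinear) flag[k] <- "self_collinear"
    } else {
      fs <- mm_profile(setup1$ytil,
                       cbind(setup1$Wtil, Gt1[, k]), setup1)
      if (any(is.na(fs$coef))) {
        p_self[k] <- 1
        flag[k] <- "self_collinear"
      } else {
        beta1[k] <- unname(utils::tail(fs$coef, 1L))
        p_self[k] <- lrt_pvalue(fs$ll, setup1$null$ll)
      }
    }
    if (!do_nei) next
    fself2 <- mm_profile(setup2$ytil,
                         cbind(setup2$Wtil, Gt2[, k]), setup2)
    if (sdX2[k] == 0) {
      p_nei[k] <- 1
      flag[k] <- paste0(flag[k], if (nzchar(flag[k])) ";", "x2_constant")
      if (test_asym) p_asym[k] <- 1
      next
    }
    fnei <- mm_profile(setup2$ytil,
                       cbind(setup2$Wtil, Gt2[, k], X2t2[, k]), setup2)
    if (any(is.na(fnei$coef))) {
      p_nei[k] <- 1
      flag[k] <- paste0(flag[k], if (nzchar(flag[k])) ";", "nei_collinear")
    } else {
      beta2[k] <- unname(utils::tail(fnei$coef, 1L))
      p_nei[k] <- lrt_pvalue(fnei$ll, fself2$ll)
    }
    if (test_asym) {
      fasym <- mm_profile(setup2$ytil,
                          cbind(setup2$Wtil, Gt2[, k], X2t2[, k],
                                X12t2[, k]), setup2)
      if (any(is.na(fasym$coef))) {
        p_asym[k] <- 1
      } else {
        beta12[k] <- unname(utils::tail(fasym$coef, 1L))
        p_asym[k] <- lrt_pvalue(fasym$ll, fnei$ll)
      }
    }
  }

  out <- data.frame(marker_id = marker_id, chrom = chrom, pos = pos,
                    maf = maf, beta1_hat = beta1, p_self = p_self,
                    stringsAsFactors = FALSE)
  if (do_nei) {
    out$beta2_hat <- beta2
    out$p_nei <- p_nei
  }
  if (test_asym) {
    out$beta12_hat <- beta12
    out$p_asym <- p_asym
  }
  out$flag <- flag
  rownames(out) <- NULL
  attr(out, "vc1") <- vc1
  if (do_nei) attr(out, "vc2") <- vc2
  attr(out, "bonferroni") <- 0.05 / q
  class(out) <- c("nbgwas_scan", "data.frame")
  out
}

#' Write scan results as TSV
#'
#' @param scan A [assoc_scan()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
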