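#' Marker-based kinship / similarity matrices
#'
#' Computes the `n x n` similarity `K = M %*% t(M) / (q - 1)` among
#' individuals from an `n x q` covariate matrix. For `kind = "self"` the
#' input must be -1/+1 genotype codes and the result is additionally
#' rescaled entrywise to `(k + 1) / 2`, so entries approximate the
#' proportion of shared marker loci (diagonal `(q/(q-1) + 1)/2`, about 1).
#' Neighbor (`X2`) and asymmetric (`X12`) similarities are left on the
#' cross-product scale.
#'
#' @param M Numeric matrix, individuals x markers.
#' @param kind `"self"`, `"neighbor"`, or `"asym"`.
#' @return An object of class `"kinship_matrix"`: list with `values`
#'   (symmetric PSD `n x n` matrix), `kind`, and `q_used`.
#' @export
make_kinship <- function(M, kind = c("self", "neighbor", "asym")) {
  kind <- match.arg(kind)
  M <- if (inherits(M, "genotype_table")) M$values else as.matrix(M)
  q <- ncol(M)
  if (q < 2L) stop("need at least 2 markers (q - 1 in the denominator)")
  if (kind == "self" && !all(M == -1 | M == 1))
    stop("self kinship requires -1/+1 genotype codes")
  K <- tcrossprod(M) / (q - 1)
  if (kind == "self") K <- (K + 1) / 2
  K <- (K + t(K)) / 2
  structure(list(values = K, kind = kind, q_used = q),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("Kinship matrix (", x$kind, "): ", nrow(x$values), " x ",
      ncol(x$values), ", from ", x$q_used, " markers\n", sep = "")
  cat("  diagonal mean:", format(mean(diag(x$values)), digits = 4),
      " off-diagonal mean:",
      format(mean(x$values[lower.tri(x$values)]), digits = 4), "\n")
  invisible(x)
}

kin_values <- function(K) {
  if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
}

# Restricted log-likelihood of y ~ N(W tau, sum theta_i K_i + theta_e I),
# together with the quantities AI-REML needs. K_list excludes the residual.
restricted_ll <- function(y, W, K_list, theta, need_derivs = TRUE) {
  n <- length(y)
  c_ <- ncol(W)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(K_list)) V <- V + theta[i] * K_list[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  WtVinv <- crossprod(W, Vinv)
  A <- WtVinv %*% W
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) stop("fixed-effect design is singular")
  P <- Vinv - crossprod(WtVinv, chol2inv(chA) %*% WtVinv)
  Py <- P %*% y
  ll <- -0.5 * ((n - c_) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                  2 * sum(log(diag(chA))) + sum(y * Py))
  out <- list(ll = as.numeric(ll), P = P, Py = Py)
  if (need_derivs) {
    m <- length(K_list)
    KPy <- vector("list", m + 1L)
    trPK <- numeric(m + 1L)
    for (i in seq_len(m)) {
      KPy[[i]] <- K_list[[i]] %*% Py
      trPK[i] <- sum(P * K_list[[i]])   # tr(P K), K symmetric
    }
    KPy[[m + 1L]] <- Py
    trPK[m + 1L] <- sum(diag(P))
    out$KPy <- KPy
    out$trPK <- trPK
  }
  out
}

#' Variance-component estimation by AI-REML
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(W tau, sum_m sigma_m^2 K_m + sigma_e^2 I)` over non-negative
#' variances by average-information REML. Starting from an equal split of
#' the ordinary-least-squares residual variance, each iteration proposes
#' an AI (quasi-Newton) step, falls back to step-halving and then to an
#' EM-REML update when the step leaves the parameter space or fails to
#' improve the restricted likelihood, and box-constrains variances at 0.
#' Convergence is declared when the restricted log-likelihood changes by
#' less than `tol`.
#'
#' With an empty `K_list` the closed-form fixed-effects-only restricted
#' likelihood is returned (useful as the null in variance-component
#' likelihood-ratio tests).
#'
#' @param y Phenotype vector.
#' @param W Fixed-covariate design matrix (default: intercept only).
#' @param K_list List of [make_kinship()] objects or plain `n x n`
#'   matrices (excluding the residual identity).
#' @param max_iter,tol Iteration cap (default 100) and restricted
#'   log-likelihood convergence tolerance (default 1e-6).
#' @return Object of class `"nbgwas_vc"`: `sigma2` (named vector of
#'   variance components, residual last), `loglik_reml`, `converged`,
#'   `n_iter`, and the model dimensions.
#' @export
reml_fit <- function(y, W = NULL, K_list = list(), max_iter = 100L,
                     tol = 1e-6) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  W <- as.matrix(W)
  K_list <- lapply(K_list, kin_values)
  m <- length(K_list)
  if (n < ncol(W) + 2L) stop("too few observations for the design")
  nm <- c(if (m > 0L) paste0("sigma2_", seq_len(m)), "sigma2_e")

  ols <- stats::lm.fit(W, y)
  vp <- sum(ols$residuals^2) / max(n - ncol(W), 1L)

  if (m == 0L) {
    cur <- restricted_ll(y, W, K_list, vp, need_derivs = FALSE)
    # profile sigma_e^2 in closed form: sigma2_e = RSS / (n - c)
    sig <- stats::setNames(vp, nm)
    return(structure(list(sigma2 = sig, loglik_reml = cur$ll,
                          converged = TRUE, n_iter = 0L, n = n,
                          n_fixed = ncol(W)),
                     class = "nbgwas_vc"))
  }

  theta <- rep(vp / (m + 1L), m + 1L)
  floor_ <- 0
  cur <- restricted_ll(y, W, K_list, theta)
  if (is.null(cur)) stop("initial covariance matrix is not positive definite")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    score <- vapply(seq_len(m + 1L), function(i)
      -0.5 * (cur$trPK[i] - sum(cur$Py * cur$KPy[[i]])), numeric(1))
    AI <- matrix(0, m + 1L, m + 1L)
    PKPy <- lapply(cur$KPy, function(k) cur$P %*% k)
    for (i in seq_len(m + 1L))
      for (j in i:(m + 1L))
        AI[i, j] <- AI[j, i] <- 0.5 * sum(cur$KPy[[i]] * PKPy[[j]])
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)

    nxt <- NULL
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:8) {
        cand <- pmax(theta + step * delta, floor_)
        trial <- restricted_ll(y, W, K_list, cand)
        if (!is.null(trial) && trial$ll >= cur$ll - 1e-10) {
          nxt <- trial; theta_new <- cand; break
        }
        step <- step / 2
      }
    }
    if (is.null(nxt)) {
      # EM-REML update: sigma_i^2 <- sigma_i^2 + sigma_i^4/n (y'PK_iPy - tr(PK_i))
      cand <- vapply(seq_len(m + 1L), function(i)
        theta[i] + theta[i]^2 / n *
          (sum(cur$Py * cur$KPy[[i]]) - cur$trPK[i]),
        numeric(1))
      cand <- pmax(cand, floor_)
      trial <- restricted_ll(y, W, K_list, cand)
      if (is.null(trial)) break
      nxt <- trial; theta_new <- cand
    }
    dll <- nxt$ll - cur$ll
    theta <- theta_new
    cur <- nxt
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  structure(list(sigma2 = stats::setNames(theta, nm), loglik_reml = cur$ll,
                 converged = converged, n_iter = iter, n = n,
                 n_fixed = ncol(W)),
            class = "nbgwas_vc")
}

#' @export
print.nbgwas_vc <- function(x, ...) {
  cat("Variance components (AI-REML", if (!x$converged) ", NOT converged",
      "):\n", sep = "")
  print(round(x$sigma2, 5))
  cat("restricted log-likelihood:", format(x$loglik_reml, digits = 8),
      " iterations:", x$n_iter, "\n")
  invisible(x)
}

#' Chi-squared p-value for a likelihood-ratio test
#'
#' Upper-tail probability of `2 * (ll_full - ll_null)` under the
#' chi-squared distribution with `df` degrees of freedom. Negative
#' statistics within numerical noise are clamped at 0 (p = 1). For
#' variance components tested on the boundary, `boundary = TRUE` applies
#' the 50:50 mixture of a point mass and chi-squared (off by default;
#' plain chi-squared matches the reporting convention used here).
#'
#' @param ll_full,ll_null Log-likelihoods of the nested models.
#' @param df Degrees of freedom (>= 1).
#' @param boundary Use the 50:50 boundary mixture (default `FALSE`).
#' @return p-value in `(0, 1]`.
#' @export
lrt_pvalue <- function(ll_full, ll_null, df = 1L, boundary = FALSE) {
  if (df < 1L) stop("df must be >= 1")
  stat <- max(0, 2 * (ll_full - ll_null))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (boundary) p <- if (stat == 0) 1 else 0.5 * p
  min(p, 1)
}

# Eigendecomposition plug-in machinery: with variance components held
# fixed (EMMAX-style), V = sigma_e^2 (M + I) with M = sum sigma_m^2 K_m /
# sigma_e^2. Rotating by the eigenvectors of M diagonalizes V, so each
# marker model is a weighted least-squares fit; the overall scale is
# profiled by maximum likelihood.
mm_setup <- function(y, W, K_list, vc) {
  K_list <- lapply(K_list, kin_values)
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  sig <- vc$sigma2
  se <- sig[length(sig)]
  if (se <= 0) se <- 1e-8 * sum(sig)
  M <- matrix(0, n, n)
  for (i in seq_along(K_list)) M <- M + sig[i] * K_list[[i]]
  M <- M / se
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, 0) + 1
  U <- eig$vectors
  setup <- list(U = U, lam = lam, wts = 1 / lam,
                ytil = crossprod(U, y), Wtil = crossprod(U, W), n = n)
  setup$null <- mm_profile(setup$ytil, setup$Wtil, setup)
  setup
}

# ML profile likelihood of the rotated weighted regression.
mm_profile <- function(ytil, Xtil, setup) {
  fit <- stats::lm.wfit(Xtil, ytil, setup$wts)
  aliased <- is.na(fit$coefficients)
  rss <- sum(setup$wts * fit$residuals^2)
  s2 <- rss / setup$n
  ll <- -0.5 * (setup$n * log(2 * pi * s2) + sum(log(setup$lam)) + setup$n)
  list(coef = fit$coefficients, ll = ll, aliased = aliased)
}

#' Test fixed effects with plug-in variance components
#'
#' Adds candidate column(s) to the fixed-effect design under a covariance
#' structure fixed at the supplied variance-component estimates
#' (the genome-wide plug-in scheme: components are estimated once on the
#' null model and reused across markers). The model is rotated by the
#' eigenvectors of the combined genetic covariance, the residual scale is
#' profiled by maximum likelihood, and the test is a likelihood ratio
#' against the design without the candidate columns.
#'
#' @param y Phenotype vector.
#' @param W Null fixed-effect design (default intercept).
#' @param x_test Candidate column(s) (vector or matrix).
#' @param K_list List of kinship matrices defining the covariance.
#' @param vc Variance components from [reml_fit()] on the null model;
#'   estimated internally when `NULL`.
#' @return Object of class `"nbgwas_fit"`: `beta_hat` (all coefficients,
#'   tested columns last), `loglik`, `loglik_null`, `lrt`, `df`, `p`, and
#'   `collinear` (`TRUE` when the candidate is aliased with `W`, in which
#'   case `p = 1`).
#' @export
fixed_effect_test <- function(y, W = NULL, x_test, K_list, vc = NULL) {
  y <- as.numeric(y)
  if (is.null(vc)) vc <- reml_fit(y, W, K_list)
  setup <- mm_setup(y, W, K_list, vc)
  x_test <- as.matrix(x_test)
  if (is.null(colnames(x_test)))
    colnames(x_test) <- paste0("x_test", seq_len(ncol(x_test)))
  Xtil <- cbind(setup$Wtil, crossprod(setup$U, x_test))
  full <- mm_profile(setup$ytil, Xtil, setup)
  p_test <- ncol(x_test)
  tested_alias <- utils::tail(full$aliased, p_test)
  if (any(tested_alias)) {
    return(structure(list(beta_hat = full$coef, loglik = setup$null$ll,
                          loglik_null = setup$null$ll, lrt = 0, df = p_test,
                          p = 1, collinear = TRUE),
                     class = "nbgwas_fit"))
  }
  lrt <- max(0, 2 * (full$ll - setup$null$ll))
  structure(list(beta_hat = full$coef, loglik = full$ll,
                 loglik_null = setup$null$ll, lrt = lrt, df = p_test,
                 p = lrt_pvalue(full$ll, setup$null$ll, df = p_test),
                 collinear = FALSE),
            class = "nbgwas_fit")
}

#' @export
print.nbgwas_fit <- function(x, ...) {
  cat("Mixed-model fixed-effect test (plug-in covariance)\n")
  cat("  coefficients:\n")
  print(round(x$beta_hat, 5))
  cat("  LRT =", format(x$lrt, digits = 5), " df =", x$df,
      " p =", format.pval(x$p, digits = 4),
      if (x$collinear) " [collinear]", "\n")
  invisible(x)
}
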