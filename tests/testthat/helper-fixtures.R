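# Small fixture builders shared across test files. Everything is generated
# in code; no binary fixtures.

# genotype table from an explicit matrix of -1/+1
gt <- function(M, ...) {
  M <- as.matrix(M)
  if (is.null(colnames(M)) || anyDuplicated(colnames(M)))
    colnames(M) <- paste0("m", seq_len(ncol(M)))
  if (is.null(rownames(M))) rownames(M) <- paste0("ind_", seq_len(nrow(M)))
  genotype_table(M, ...)
}

# random -1/+1 matrix with independent columns
rand_geno <- function(n, q, seed = 1) {
  set.seed(seed)
  matrix(sample(c(-1, 1), n * q, replace = TRUE), n, q,
         dimnames = list(paste0("ind_", seq_len(n)), paste0("m", seq_len(q))))
}

# fully occupied checkered map covering a rows x cols lattice (n = number
# of occupied cells), deterministic placement
full_checkered_map <- function(rows, cols) {
  cells <- expand.grid(y = seq_len(rows), x = seq_len(cols))
  cells <- cells[(cells$x + cells$y) %% 2 == 0, ]
  spatial_map(paste0("ind_", seq_len(nrow(cells))), cells$x, cells$y,
              lattice = list(rows = rows, cols = cols, checkered = TRUE))
}

# independent restricted log-likelihood oracle: direct dense evaluation of
# the closed form for y ~ N(W tau, theta1 * K + theta_e * I)
rll_oracle <- function(y, W, K, theta1, theta_e) {
  n <- length(y)
  V <- theta1 * K + diag(theta_e, n)
  Vi <- solve(V)
  A <- t(W) %*% Vi %*% W
  P <- Vi - Vi %*% W %*% solve(A) %*% t(W) %*% Vi
  -0.5 * ((n - ncol(W)) * log(2 * pi) + determinant(V)$modulus +
            determinant(A)$modulus + drop(t(y) %*% P %*% y))
}

# dense GLS maximum-likelihood oracle with profiled scale: V-shape fixed,
# overall scale profiled, as in the plug-in scan
gls_ml_oracle <- function(y, X, Vshape) {
  n <- length(y)
  Vi <- solve(Vshape)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / n
  ll <- -0.5 * (n * log(2 * pi * s2) + determinant(Vshape)$modulus + n)
  list(beta = drop(beta), ll = as.numeric(ll))
}

# brute-force AUC by pair enumeration (midranks for ties)
auc_pairs <- function(scores, truth) {
  truth <- as.logical(truth)
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
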