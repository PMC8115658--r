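test_that("with s = 0 and sigma2^2 = 0 the scan reduces to a standard single-kinship GWAS", {
  set.seed(31)
  n <- 120; q <- 150
  G <- generate_genotypes(n, q, n_subpop = 3, fst = 0.2, seed = 31)
  K1 <- make_kinship(G, "self")
  ch <- t(chol(K1$values + diag(1e-8, n)))
  y <- as.numeric(ch %*% rnorm(n)) + G$values[, 10] * 0.5 + rnorm(n)

  scan <- assoc_scan(y, NULL, G, X2 = NULL, K1 = K1)

  # independent reference: dense GLS per marker under V = s1 K1 + se I
  vc <- reml_fit(y, NULL, list(K1))
  Vshape <- vc$sigma2[1] * K1$values / vc$sigma2[2] + diag(n)
  W <- matrix(1, n, 1)
  null_ll <- gls_ml_oracle(y, W, Vshape)$ll
  p_ref <- vapply(seq_len(q), function(k) {
    full <- gls_ml_oracle(y, cbind(W, G$values[, k]), Vshape)$ll
    pchisq(max(0, 2 * (full - null_ll)), 1, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(scan$p_self, p_ref, tolerance = 1e-6)
})

test_that("small worked instance: scan LRT statistics equal dense-GLS brute force", {
  set.seed(32)
  n <- 12
  G <- gt(rand_geno(n, 8, seed = 32))
  map <- spatial_map(rownames(G$values), seq_len(n), rep(1, n))
  idx <- build_neighbor_index(map, 1.1)
  C <- neighbor_covariate(G, idx, 1)
  K1 <- make_kinship(G, "self"); K2 <- make_kinship(C$X2, "neighbor")
  y <- rnorm(n) + 0.8 * G$values[, 3]
  scan <- assoc_scan(y, NULL, G, X2 = C$X2, K1 = K1, K2 = K2)

  vc1 <- reml_fit(y, NULL, list(K1))
  vc2 <- reml_fit(y, NULL, list(K1, K2))
  V1 <- vc1$sigma2[1] * K1$values / vc1$sigma2[2] + diag(n)
  V2 <- (vc2$sigma2[1] * K1$values + vc2$sigma2[2] * K2$values) /
    vc2$sigma2[3] + diag(n)
  W <- matrix(1, n, 1)
  for (k in c(1, 3, 5)) {
    ll0 <- gls_ml_oracle(y, W, V1)$ll
    lls <- gls_ml_oracle(y, cbind(W, G$values[, k]), V1)$ll
    expect_equal(-log10(scan$p_self[k]),
                 -log10(pchisq(max(0, 2 * (lls - ll0)), 1, lower.tail = FALSE)),
                 tolerance = 1e-8)
    lls2 <- gls_ml_oracle(y, cbind(W, G$values[, k]), V2)$ll
    lln2 <- gls_ml_oracle(y, cbind(W, G$values[, k], C$X2[, k]), V2)$ll
    expect_equal(-log10(scan$p_nei[k]),
                 -log10(pchisq(max(0, 2 * (lln2 - lls2)), 1, lower.tail = FALSE)),
                 tolerance = 1e-8)
  }
})

test_that("null p-values are approximately uniform (KS < 0.1)", {
  n <- 200; q <- 500
  G <- generate_genotypes(n, q, seed = 33)
  map <- place_on_grid(n, 10, 40, seed = 34)
  set.seed(35)
  y <- rnorm(n)
  idx <- build_neighbor_index(map, lattice_thresholds(map, 1))
  C <- neighbor_covariate(G, idx, 1)
  scan <- assoc_scan(y, NULL, G, X2 = C$X2, K1 = make_kinship(G, "self"),
                     K2 = make_kinship(C$X2, "neighbor"))
  expect_lt(suppressWarnings(ks.test(scan$p_self, "punif")$statistic), 0.1)
  expect_lt(suppressWarnings(ks.test(scan$p_nei, "punif")$statistic), 0.1)
})

test_that("a planted neighbor-only signal attains the genome-wide minimum p_nei", {
  hits <- vapply(1:10, function(r) {
    seed <- 360 + r * 7
    n <- 200; q <- 300
    G <- generate_genotypes(n, q, seed = seed)
    map <- place_on_grid(n, 10, 40, seed = seed + 1)
    idx <- build_neighbor_index(map, lattice_thresholds(map, 1))
    # one neighbor-only causal marker (beta2 != 0, beta1 = 0), PVE ~ 0.6
    causal <- structure(data.frame(index = 17L, class = "nei", b1 = 0,
                                   b2 = 1, b12 = 0),
                        class = c("causal_set", "data.frame"))
    cfg <- sim_config(alpha = 3, pve_beta = 0.6, pve_total = 0.61,
                      ratio = c(0, 1, 0), n_causal = 1, s_max = 1,
                      seed = seed + 2)
    sim <- simulate_phenotype(G, map, causal, cfg, idx = idx)
    C <- neighbor_covariate(G, idx, 1)
    scan <- assoc_scan(sim$y, NULL, G, X2 = C$X2,
                       K1 = make_kinship(G, "self"),
                       K2 = make_kinship(C$X2, "neighbor"))
    which.min(scan$p_nei) == 17L
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("self-only signals do not leak into small neighbor p-values", {
  seed <- 41
  n <- 200; q <- 300
  G <- generate_genotypes(n, q, seed = seed)
  map <- place_on_grid(n, 10, 40, seed = seed + 1)
  idx <- build_neighbor_index(map, lattice_thresholds(map, 1))
  causal <- structure(data.frame(index = c(11L, 99L, 222L), class = "self",
                                 b1 = c(1, -1, 1), b2 = 0, b12 = 0),
                      class = c("causal_set", "data.frame"))
  cfg <- sim_config(alpha = 1, pve_beta = 0.5, pve_total = 0.51,
                    ratio = c(1, 0, 0), n_causal = 3, s_max = 1,
                    seed = seed + 2)
  sim <- simulate_phenotype(G, map, causal, cfg, idx = idx)
  C <- neighbor_covariate(G, idx, 1)
  scan <- assoc_scan(sim$y, NULL, G, X2 = C$X2,
                     K1 = make_kinship(G, "self"),
                     K2 = make_kinship(C$X2, "neighbor"))
  expect_true(all(scan$p_self[causal$index] < 1e-4))
  expect_gt(median(scan$p_nei[causal$index]), 0.1)
})

test_that("plug-in scan and exact per-marker REML scan agree on the top marker", {
  n <- 100; q <- 200
  G <- generate_genotypes(n, q, seed = 42)
  set.seed(43)
  K1 <- make_kinship(G, "self")
  y <- as.numeric(t(chol(K1$values + diag(1e-8, n))) %*% rnorm(n)) * 0.5 +
    1.2 * G$values[, 77] + rnorm(n)
  scan <- assoc_scan(y, NULL, G, X2 = NULL, K1 = K1)
  top_plugin <- which.min(scan$p_self)

  exact_lrt <- vapply(seq_len(q), function(k) {
    W <- cbind(1, G$values[, k])
    if (qr(W)$rank < 2) return(0)
    vck <- reml_fit(y, W, list(K1))
    ft <- fixed_effect_test(y, matrix(1, n, 1), G$values[, k], list(K1), vck)
    ft$lrt
  }, numeric(1))
  expect_equal(top_plugin, which.max(exact_lrt))
  expect_equal(top_plugin, 77L)
})

test_that("monomorphic markers and constant neighbor covariates are flagged with p = 1", {
  n <- 30
  M <- rand_geno(n, 5, seed = 44)
  M[, 2] <- 1
  G <- suppressWarnings(gt(M))
  map <- spatial_map(rownames(M), seq_len(n), rep(0, n))
  idx <- build_neighbor_index(map, 1.1)
  C <- suppressWarnings(neighbor_covariate(G, idx, 1))
  set.seed(44)
  y <- rnorm(n)
  scan <- assoc_scan(y, NULL, G, X2 = C$X2, K1 = make_kinship(G, "self"),
                     K2 = make_kinship(C$X2, "neighbor"))
  expect_equal(scan$p_self[2], 1)
  expect_equal(scan$p_nei[2], 1)
  expect_match(scan$flag[2], "monomorphic")
  expect_true(all(scan$p_self > 0 & scan$p_self <= 1))
})
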