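test_that("synthetic genotypes respect the MAF floor and carry subpop structure", {
  G <- generate_genotypes(120, 300, n_subpop = 3, fst = 0.3, maf_min = 0.1,
                          seed = 61)
  expect_true(all(G$maf >= 0.1))
  expect_true(all(G$values %in% c(-1, 1)))

  # structure oracle via label permutation: within-subpop similarity
  # exceeds between-subpop similarity
  K <- make_kinship(G, "self")$values
  pop <- attr(G, "subpop")
  same <- outer(pop, pop, "==") & upper.tri(K)
  diff_ <- (!outer(pop, pop, "==")) & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff_]))
  set.seed(62)
  perm_gap <- replicate(20, {
    pp <- sample(pop)
    s <- outer(pp, pp, "==") & upper.tri(K)
    mean(K[s]) - mean(K[(!outer(pp, pp, "==")) & upper.tri(K)])
  })
  expect_gt(mean(K[same]) - mean(K[diff_]), max(perm_gap))

  expect_error(generate_genotypes(10, 10, maf_min = 0.5), "maf_min")
})

test_that("without structure the mean kinship matches the analytic expectation", {
  # fst = 0: E[x_i x_j] = (2p - 1)^2 with p ~ U(m, 1 - m), so the expected
  # mean off-diagonal of the (k+1)/2-scaled kinship is ((1-2m)^2/3 + 1)/2
  m <- 0.1
  G <- generate_genotypes(60, 2000, n_subpop = 1, fst = 0, maf_min = m,
                          seed = 63)
  K <- make_kinship(G, "self")$values
  expected <- ((1 - 2 * m)^2 / 3 + 1) / 2
  expect_equal(mean(K[lower.tri(K)]), expected, tolerance = 0.02)
})

test_that("grid placement fills the checkered occupancy exactly", {
  map <- place_on_grid(1296, 36, 72, checkered = TRUE, seed = 64)
  expect_equal(nrow(map), 1296)
  expect_false(anyDuplicated(map[, c("x", "y")]) > 0)
  expect_true(all((map$x + map$y) %% 2 == 0))

  # different seeds: same occupancy set, different assignment
  m1 <- place_on_grid(50, 10, 10, seed = 65)
  m2 <- place_on_grid(50, 10, 10, seed = 66)
  key <- function(m) sort(paste(m$x, m$y))
  expect_identical(key(m1), key(m2))
  expect_false(identical(paste(m1$x, m1$y), paste(m2$x, m2$y)))

  expect_error(place_on_grid(51, 10, 10), "occupied cells")
})

test_that("causal classes follow the 15/15/35/35 largest-remainder split with +-1 signs", {
  cs20 <- assign_causal(1000, 20, seed = 67)
  tab20 <- table(factor(cs20$class,
                        c("self+nei+asym", "self+nei", "self", "nei")))
  expect_equal(unname(as.vector(tab20)), c(3, 3, 7, 7))
  cs10 <- assign_causal(1000, 10, seed = 68)
  tab <- table(factor(cs10$class, c("self+nei+asym", "self+nei", "self", "nei")))
  expect_equal(unname(as.vector(tab)), c(2, 2, 3, 3))

  expect_true(all(cs10$b1[cs10$class != "nei"] %in% c(-1, 1)))
  expect_true(all(cs10$b1[cs10$class == "nei"] == 0))
  expect_true(all(cs10$b2[cs10$class != "self"] %in% c(-1, 1)))
  expect_true(all(cs10$b12[cs10$class == "self+nei+asym"] %in% c(-1, 1)))
  expect_true(all(cs10$b12[cs10$class != "self+nei+asym"] == 0))
  expect_false(anyDuplicated(cs10$index) > 0)
  expect_error(assign_causal(5, 10), "exceeds")
})

test_that("simulated phenotypes are standardized and hit the PVE targets", {
  G <- generate_genotypes(200, 400, seed = 69)
  map <- place_on_grid(200, 10, 40, seed = 70)
  for (seed in c(71, 72, 73)) {
    cs <- assign_causal(400, 20, seed = seed)
    cfg <- sim_config(alpha = 1, pve_beta = 0.3, pve_total = 0.4,
                      ratio = c(8, 1, 1), n_causal = 20, seed = seed)
    sim <- simulate_phenotype(G, map, cs, cfg)
    expect_equal(mean(sim$y), 0, tolerance = 1e-6)
    expect_equal(var(sim$y), 1, tolerance = 1e-6)
    expect_equal(sim$true_pve$beta, 0.3, tolerance = 0.02)
    expect_equal(sim$true_pve$total, 0.4, tolerance = 0.04)
  }
})

test_that("identical seeds reproduce phenotypes bit for bit; sign flips keep the variance split", {
  G <- generate_genotypes(120, 200, seed = 74)
  map <- place_on_grid(120, 10, 24, seed = 75)
  cs <- assign_causal(200, 10, seed = 76)
  cfg <- sim_config(alpha = 1, pve_beta = 0.3, pve_total = 0.5, seed = 77,
                    n_causal = 10)
  s1 <- simulate_phenotype(G, map, cs, cfg)
  s2 <- simulate_phenotype(G, map, cs, cfg)
  expect_identical(s1$y, s2$y)

  # flipping every causal sign mirrors the fixed part exactly (the block
  # variances, and hence the calibrated gains, are sign-invariant) and the
  # realized fixed-effect fraction stays at the calibrated target
  flipped <- cs
  flipped$b1 <- -flipped$b1; flipped$b2 <- -flipped$b2
  flipped$b12 <- -flipped$b12
  s3 <- simulate_phenotype(G, map, flipped, cfg)
  expect_equal(cor(s1$fixed, s3$fixed), -1, tolerance = 1e-10)
  expect_equal(s3$true_pve$beta, s1$true_pve$beta, tolerance = 0.05)
})

test_that("ratio 1:0:0 leaves no neighbor contribution in the phenotype", {
  G <- generate_genotypes(200, 400, seed = 78)
  map <- place_on_grid(200, 10, 40, seed = 79)
  idx <- build_neighbor_index(map, lattice_thresholds(map, 1))
  K1 <- make_kinship(G, "self")
  K2 <- make_kinship(neighbor_covariate(G, idx, 1)$X2, "neighbor")
  nets <- vapply(1:6, function(r) {
    cs <- assign_causal(400, 20, seed = 80 + r)
    cfg <- sim_config(alpha = 1, pve_beta = 0.3, pve_total = 0.4,
                      ratio = c(1, 0, 0), n_causal = 20, seed = 90 + r)
    sim <- simulate_phenotype(G, map, cs, cfg)
    stopifnot(all(sim$truth$beta2 == 0))
    p <- suppressWarnings(pve_partition(sim$y, NULL, K1, list(`1` = K2)))
    unname(p$net_pve_nei[1])
  }, numeric(1))
  expect_lt(median(abs(nets)), 0.05)
})

test_that("as alpha grows the weighted covariate converges to the unweighted s = 1 covariate", {
  map <- full_checkered_map(8, 16)
  idx <- build_neighbor_index(map, lattice_thresholds(map, 3))
  M <- rand_geno(nrow(map), 30, seed = 82)
  C1 <- neighbor_covariate(gt(M), idx, 1)
  Cw <- neighbor_covariate(gt(M), idx, 3, weighted = TRUE, alpha = 50)
  # weighted sum over 3 shells at alpha = 50 keeps only shell 1, but is
  # scaled by the cumulative L at s = 3
  expect_equal(Cw$X2 * idx$L[, 3], C1$X2 * idx$L[, 1], tolerance = 1e-12)
})
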