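test_that("checkered-lattice thresholds give L = 4 at s = 1 and L = 12 at s = 2", {
  map <- full_checkered_map(10, 40)
  idx <- build_neighbor_index(map, lattice_thresholds(map, 2))
  interior <- which(map$x > 2 & map$x < 39 & map$y > 2 & map$y < 9)
  expect_true(length(interior) > 50)
  expect_true(all(idx$L[interior, 1] == 4))
  expect_true(all(idx$L[interior, 2] == 12))

  # corner cell: brute-force distance enumeration gives a single neighbor
  corner <- which(map$x + map$y == min(map$x + map$y))[1]
  d <- sqrt((map$x - map$x[corner])^2 + (map$y - map$y[corner])^2)
  expect_equal(sum(d > 0 & d <= sqrt(2) * (1 + 1e-6)), 1)
  expect_equal(unname(idx$L[corner, 1]), 1)

  expect_error(lattice_thresholds(spatial_map("a", 1, 1), 2), "lattice")
})

test_that("neighbor shells match a brute-force all-pairs oracle and are nested", {
  set.seed(11)
  map <- spatial_map(paste0("p", 1:100), runif(100, 0, 10), runif(100, 0, 10))
  deltas <- c(1, 2, 3)
  idx <- build_neighbor_index(map, deltas)
  D <- as.matrix(dist(cbind(map$x, map$y)))
  for (s in 1:3) {
    lower <- if (s == 1) 0 else deltas[s - 1]
    A_oracle <- (D > lower & D <= deltas[s]) * 1
    diag(A_oracle) <- 0
    expect_equal(unname(idx$adjacency[[s]]), unname(A_oracle))
    # symmetry
    expect_identical(idx$adjacency[[s]], t(idx$adjacency[[s]]))
  }
  # cumulative counts and nestedness
  expect_true(all(idx$L[, 1] <= idx$L[, 2]))
  expect_true(all(idx$L[, 2] <= idx$L[, 3]))
  expect_equal(unname(idx$L[, 3]), unname(rowSums(D > 0 & D <= 3)))

  expect_error(build_neighbor_index(map, c(2, 1)), "strictly increasing")
  expect_error(build_neighbor_index(map, 1e-6), "too small")
})

test_that("decay weights follow exp(-alpha (s - 1))", {
  expect_equal(decay_weight(1, 0), 1)
  expect_equal(decay_weight(1, 99), 1)
  expect_equal(decay_weight(2, 3), exp(-3))
  expect_equal(round(decay_weight(2, 3), 6), 0.049787)
  expect_equal(round(decay_weight(3, 0.01), 6), 0.980199)
  expect_error(decay_weight(0, 1), ">= 1")
  expect_error(decay_weight(1, -1), ">= 0")
})

test_that("neighbor covariate takes hand-computed values on planted neighborhoods", {
  # 3 x 3 full grid, focal at center with 4 rook neighbors
  cells <- expand.grid(y = 1:3, x = 1:3)
  map <- spatial_map(paste0("p", 1:9), cells$x, cells$y)
  idx <- build_neighbor_index(map, c(1.001, 1.5))
  center <- which(map$x == 2 & map$y == 2)
  ring1 <- which(abs(map$x - 2) + abs(map$y - 2) == 1)
  ring2 <- setdiff(seq_len(9), c(center, ring1))

  # all four first-shell neighbors share the focal +1 allele -> X2 = +1
  x <- rep(-1, 9); x[c(center, ring1)] <- 1
  C <- neighbor_covariate(gt(cbind(x, x)), idx, s = 1)
  expect_equal(C$X2[center, 1], 1)

  # two share, two differ -> contributions cancel -> X2 = 0
  x2 <- x; x2[ring1[1:2]] <- -1
  C2 <- neighbor_covariate(gt(cbind(x2, x2)), idx, s = 1)
  expect_equal(C2$X2[center, 1], 0)

  # weighted with strong decay: 4 same-allele at shell 1, 4 different at
  # shell 2, cumulative L = 8 -> entry -> 4/8 = 0.5 as alpha -> infinity
  x3 <- rep(-1, 9); x3[c(center, ring1)] <- 1; x3[ring2] <- -1
  C3 <- neighbor_covariate(gt(cbind(x3, x3)), idx, s = 2, weighted = TRUE,
                           alpha = 50)
  expect_equal(C3$X2[center, 1], 0.5, tolerance = 1e-10)
  expect_equal(C3$X12[center, 1], C3$X1[center, 1] * C3$X2[center, 1])
})

test_that("X2 is bounded, sign-equivariant, and nested in s", {
  map <- full_checkered_map(8, 16)
  n <- nrow(map)
  idx <- build_neighbor_index(map, lattice_thresholds(map, 3))
  M <- rand_geno(n, 40, seed = 12)
  C <- neighbor_covariate(gt(M), idx, s = 3)
  expect_true(all(C$X2 >= -1 - 1e-12 & C$X2 <= 1 + 1e-12))
  expect_equal(C$X12, C$X1 * C$X2)

  # flipping the sign of one marker leaves its X2 column unchanged
  M2 <- M; M2[, 5] <- -M2[, 5]
  C2 <- neighbor_covariate(gt(M2), idx, s = 3)
  expect_equal(C2$X2[, 5], C$X2[, 5])

  # increasing s only changes X2 through newly added shells: recompute the
  # s = 2 covariate from the s = 1 accumulation plus shell 2
  Cc <- neighbor_covariate(gt(M), idx, s = 2)
  manual <- M * ((idx$adjacency[[1]] %*% M) + (idx$adjacency[[2]] %*% M)) /
    idx$L[, 2]
  expect_equal(unname(Cc$X2), unname(manual))
})

test_that("isolated individuals get zero covariates with a warning", {
  map <- spatial_map(c("a", "b", "c"), c(0, 1, 50), c(0, 0, 0))
  idx <- build_neighbor_index(map, 1.5)
  M <- cbind(c(1, -1, 1), c(-1, -1, 1))
  expect_warning(C <- neighbor_covariate(gt(M), idx, 1), "no neighbors")
  expect_equal(unname(C$X2[3, ]), c(0, 0))
  expect_equal(unname(C$X2[1, ]), unname(M[1, ] * M[2, ]))
})

test_that("collinearity with the self genotype grows as the neighborhood spans the field", {
  set.seed(13)
  map <- full_checkered_map(6, 12)
  n <- nrow(map)
  M <- rand_geno(n, 50, seed = 13)
  idx_all <- build_neighbor_index(map, 100)  # whole field in one shell
  C_all <- neighbor_covariate(gt(M), idx_all, 1)
  d_all <- collinearity_diagnostics(C_all)
  expect_true(all(abs(d_all$r) > 0.99, na.rm = TRUE))

  idx1 <- build_neighbor_index(map, lattice_thresholds(map, 1))
  d1 <- collinearity_diagnostics(neighbor_covariate(gt(M), idx1, 1))
  expect_lt(median(abs(d1$r), na.rm = TRUE), 0.5)

  # monomorphic marker -> NA
  M[, 1] <- 1
  dmono <- collinearity_diagnostics(
    suppressWarnings(neighbor_covariate(gt(M), idx1, 1)))
  expect_true(is.na(dmono$r[1]))

  # low MAF shifts |r| upward relative to maf ~ 0.5
  Mlow <- matrix(ifelse(matrix(runif(n * 50), n) < 0.9, -1, 1), n)
  dlow <- collinearity_diagnostics(
    suppressWarnings(neighbor_covariate(gt(Mlow), idx1, 1)))
  expect_gt(median(abs(dlow$r), na.rm = TRUE),
            median(abs(d1$r), na.rm = TRUE))
})
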