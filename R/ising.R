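#' Lattice geometry for the forward Ising machinery
#'
#' Builds the first-shell neighbor structure of a `rows x cols` lattice.
#' On a full lattice the first shell is the 4-neighborhood (distance 1);
#' on a checkered lattice (occupied cells with even coordinate sum) it is
#' the 4 diagonal neighbors (distance `sqrt(2)`), consistent with the
#' neighbor-covariate definitions. Both graphs are bipartite, which the
#' annealer exploits for exact two-color sweeps.
#'
#' @param rows,cols Lattice dimensions.
#' @param checkered Use the checkered occupancy (default `FALSE`).
#' @return List of class `"ising_grid"`: `coords` (data.frame `r`, `c`),
#'   `nbr` (list of neighbor index vectors), `color` (0/1 bipartition),
#'   `n`, and `n_pairs`.
#' @export
ising_grid <- function(rows, cols, checkered = FALSE) {
  stopifnot(rows >= 1, cols >= 1)
  cells <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  if (checkered) cells <- cells[(cells$r + cells$c) %% 2 == 0, , drop = FALSE]
  rownames(cells) <- NULL
  n <- nrow(cells)
  key <- function(r, c) paste(r, c)
  lut <- stats::setNames(seq_len(n), key(cells$r, cells$c))
  offs <- if (checkered) cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)) else
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nbr <- lapply(seq_len(n), function(i) {
    rr <- cells$r[i] + offs[, 1L]; cc <- cells$c[i] + offs[, 2L]
    ok <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
    unname(lut[key(rr[ok], cc[ok])])
  })
  nbr <- lapply(nbr, function(v) v[!is.na(v)])
  color <- if (checkered) cells$r %% 2 else (cells$r + cells$c) %% 2
  structure(list(coords = cells, nbr = nbr, color = color, n = n,
                 n_pairs = sum(lengths(nbr)) / 2),
            class = "ising_grid")
}

neighbor_field <- function(spins, grid) {
  pad <- c(spins, 0)
  deg <- lengths(grid$nbr)
  idx <- t(vapply(grid$nbr, function(v) c(v, rep(grid$n + 1L, 4 - length(v))),
                  integer(4)))
  rowSums(matrix(pad[idx], nrow = grid$n))
}

#' Population phenotype sum of an allele arrangement
#'
#' Sums the basic Ising-form phenotype over all individuals:
#' `sum(y) = beta1 * sum(x_i) + beta2 * sum_i x_i h_i`, where `h_i` is the
#' sum of neighboring spins — equivalently each unordered neighbor pair
#' contributes `2 * beta2 * x_i * x_j`, since the pair is counted from
#' both of its members. Under the mapping to a ferromagnet, `-beta2` is
#' the interaction energy coefficient and `-beta1` the external field.
#'
#' @param spins Vector of -1/+1 spins on the occupied cells.
#' @param grid An [ising_grid()].
#' @param beta1,beta2 Self and neighbor coefficients.
#' @return The population sum `sum(y_i)`.
#' @export
population_sum <- function(spins, grid, beta1, beta2) {
  stopifnot(length(spins) == grid$n, all(spins == -1 | spins == 1))
  h <- neighbor_field(spins, grid)
  beta1 * sum(spins) + beta2 * sum(spins * h)
}

#' Fraction of neighbor pairs sharing the same allele
#'
#' @inheritParams population_sum
#' @return Agreement fraction in `[0, 1]`; 0.5 for a random arrangement.
#' @export
neighbor_agreement <- function(spins, grid) {
  h <- neighbor_field(spins, grid)
  agree <- sum(spins * h)  # = (# agreeing) - (# disagreeing), pairs x2
  tot <- 2 * grid$n_pairs
  (agree / tot + 1) / 2
}

#' Simulated annealing of allele arrangements
#'
#' Searches for the spin configuration minimizing (or maximizing) the
#' population phenotype sum by Metropolis single-spin-flip annealing from
#' a uniform random start, with geometric cooling from `t_init` to
#' `t_final` over `n_iter` sweeps (one sweep proposes a flip at every
#' site, updated color-by-color over the bipartition so simultaneous
#' flips never interact). The best-visited state is returned; its
#' best-so-far objective is non-increasing across sweeps. With
#' `dynamics = "swap"` a sweep instead proposes `n` exchanges of two
#' opposite spins, conserving allele counts.
#'
#' @param grid An [ising_grid()].
#' @param beta1,beta2 Self and neighbor coefficients (e.g. taken from a
#'   scan's effect estimates).
#' @param n_iter Number of sweeps (default 1000).
#' @param t_init,t_final Temperature schedule endpoints (default 10 and
#'   0.01, geometric cooling).
#' @param direction `"minimize"` (default) or `"maximize"`.
#' @param dynamics `"flip"` (default) or `"swap"` (allele-conserving).
#' @param seed Optional integer seed.
#' @return List of class `"ising_state"`: `spins` and `energy` (the
#'   best-visited arrangement and its population sum), `final_spins`,
#'   `trace` (best-so-far per sweep), `grid`, and the configuration.
#' @export
anneal <- function(grid, beta1, beta2, n_iter = 1000L, t_init = 10,
                   t_final = 0.01, direction = c("minimize", "maximize"),
                   dynamics = c("flip", "swap"), seed = NULL) {
  direction <- match.arg(direction)
  dynamics <- match.arg(dynamics)
  stopifnot(n_iter >= 1, t_init > 0, t_final > 0, t_final <= t_init)
  if (!is.null(seed)) set.seed(seed)
  sgn <- if (direction == "minimize") 1 else -1
  x <- ifelse(stats::runif(grid$n) < 0.5, -1, 1)
  temps <- if (n_iter == 1L) t_init else
    t_init * (t_final / t_init)^((seq_len(n_iter) - 1) / (n_iter - 1))
  best <- x
  best_e <- population_sum(x, grid, beta1, beta2)
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    Temp <- temps[it]
    if (dynamics == "flip") {
      for (col in c(0, 1)) {
        sites <- which(grid$color == col)
        h <- neighbor_field(x, grid)
        # flipping x_i changes sum(y) by -2 x_i (beta1 + 2 beta2 h_i)
        dE <- sgn * (-2 * x[sites] * (beta1 + 2 * beta2 * h[sites]))
        # zero-gain flips are taken with probability 1/2: accepting them
        # deterministically makes simultaneous color updates cycle
        p_acc <- ifelse(dE == 0, 0.5, exp(-pmax(dE, 0) / Temp))
        acc <- dE < 0 | stats::runif(length(sites)) < p_acc
        x[sites[acc]] <- -x[sites[acc]]
      }
    } else {
      for (rep_ in seq_len(grid$n)) {
        up <- which(x == 1); dn <- which(x == -1)
        if (length(up) == 0L || length(dn) == 0L) break
        i <- up[sample.int(length(up), 1L)]
        j <- dn[sample.int(length(dn), 1L)]
        e0 <- population_sum(x, grid, beta1, beta2)
        x2 <- x; x2[i] <- -1; x2[j] <- 1
        dE <- sgn * (population_sum(x2, grid, beta1, beta2) - e0)
        if (dE <= 0 || stats::runif(1) < exp(-dE / Temp)) x <- x2
      }
    }
    e <- population_sum(x, grid, beta1, beta2)
    if (sgn * e < sgn * best_e) { best_e <- e; best <- x }
    trace[it] <- best_e
  }
  structure(list(spins = best, energy = best_e, final_spins = x,
                 trace = trace, grid = grid, beta1 = beta1, beta2 = beta2,
                 direction = direction, dynamics = dynamics,
                 n_iter = n_iter),
            class = "ising_state")
}

#' @export
print.ising_state <- function(x, ...) {
  cat("Annealed arrangement (", x$direction, ", ", x$dynamics, "): ",
      x$grid$n, " sites, ", x$n_iter, " sweeps\n", sep = "")
  cat("  best population sum:", format(x$energy, digits = 6), "\n")
  cat("  neighbor agreement:",
      round(neighbor_agreement(x$spins, x$grid), 3), "\n")
  invisible(x)
}

#' @export
plot.ising_state <- function(x, ...) {
  co <- x$grid$coords
  graphics::plot(co$c, co$r, pch = 15,
                 col = ifelse(x$spins > 0, "black", "grey80"),
                 xlab = "column", ylab = "row", asp = 1,
                 main = sprintf("population sum = %.2f", x$energy), ...)
  invisible(x)
}
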