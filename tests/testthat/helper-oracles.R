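# Independent oracles, deliberately built on different primitives than the
# package (stats::dbinom rather than the package's likelihood kernel).

# binomial log-likelihood kernel via dbinom, dropping the binomial coefficient
oracle_loglik <- function(k, n, p) {
  if (p <= 0 || p >= 1) {
    # boundary: only defined when the data sit on the boundary too
    if ((p <= 0 && k == 0) || (p >= 1 && k == n)) return(0)
    return(-Inf)
  }
  dbinom(k, n, p, log = TRUE) - lchoose(n, k)
}

# iterative-refinement 1-D grid maximization over (0, 1)
oracle_grid_max1 <- function(f, tol = 1e-7, points = 61) {
  lo <- 0; hi <- 1
  for (r in 1:6) {
    g <- seq(lo, hi, length.out = points)
    g <- pmin(pmax(g, 1e-12), 1 - 1e-12)
    v <- vapply(g, f, numeric(1))
    i <- which.max(v)
    step <- (hi - lo) / (points - 1)
    lo <- max(0, g[i] - step); hi <- min(1, g[i] + step)
  }
  g[i]
}

# iterative-refinement 2-D grid maximization over (0, 1)^2; returns the
# maximized value and arguments
oracle_grid_max2 <- function(f, points = 41, rounds = 6) {
  lo <- c(0, 0); hi <- c(1, 1)
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    g1 <- pmin(pmax(seq(lo[1], hi[1], length.out = points), 1e-12), 1 - 1e-12)
    g2 <- pmin(pmax(seq(lo[2], hi[2], length.out = points), 1e-12), 1 - 1e-12)
    v <- outer(g1, g2, Vectorize(f))
    ij <- arrayInd(which.max(v), dim(v))
    best <- c(g1[ij[1]], g2[ij[2]])
    s1 <- (hi[1] - lo[1]) / (points - 1); s2 <- (hi[2] - lo[2]) / (points - 1)
    lo <- pmax(0, best - c(s1, s2)); hi <- pmin(1, best + c(s1, s2))
  }
  list(par = best, value = f(best[1], best[2]))
}

# random three-group count tables (allele totals even, all groups non-empty)
random_count_tables <- function(n_tables, seed, max_m = 100) {
  set.seed(seed)
  tibble::tibble(
    m_with = sample(2:max_m, n_tables, replace = TRUE),
    m_without = sample(2:max_m, n_tables, replace = TRUE),
    m_ctrl = sample(2:max_m, n_tables, replace = TRUE),
    p = runif(n_tables, 0.05, 0.95)
  ) |>
    dplyr::mutate(
      n_with = 2L * m_with, n_without = 2L * m_without, n_ctrl = 2L * m_ctrl,
      k_with = rbinom(n_tables, n_with, p),
      k_without = rbinom(n_tables, n_without, p),
      k_ctrl = rbinom(n_tables, n_ctrl, p)
    )
}

toy1_counts <- function() {
  list(k_with = 50, n_with = 100, k_without = 40, n_without = 100,
       k_ctrl = 80, n_ctrl = 200)
}
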