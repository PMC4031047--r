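make_effect_pairs <- function(snp_id, beta_with, se_with, beta_without,
                              se_without) {
  chars <- migraine_characteristics()
  tibble::tibble(
    snp_id = snp_id,
    characteristic = rep(chars, 2),
    stratum = rep(c("with", "without"), each = length(chars)),
    beta = c(beta_with, beta_without),
    se = c(se_with, se_without),
    p = 0.5, n_cases = 100, n_controls = 100, converged = TRUE
  )
}

test_that("t-vectors implement the normalized beta difference", {
  eff <- make_effect_pairs("rs1",
                           beta_with = rep(0.3, 10), se_with = rep(0.04, 10),
                           beta_without = rep(0.1, 10), se_without = rep(0.03, 10))
  ts <- build_tstat_vectors(eff)
  expect_equal(nrow(ts), 10)
  expect_equal(ts$t, rep(0.2 / 0.05, 10)) # sqrt(0.0016 + 0.0009) = 0.05
  # equal betas -> zero vector
  eff0 <- make_effect_pairs("rs1", rep(0.2, 10), rep(0.05, 10),
                            rep(0.2, 10), rep(0.05, 10))
  expect_equal(build_tstat_vectors(eff0)$t, rep(0, 10))
  # doubling both SEs halves every entry
  eff2 <- make_effect_pairs("rs1", rep(0.3, 10), rep(0.08, 10),
                            rep(0.1, 10), rep(0.06, 10))
  expect_equal(build_tstat_vectors(eff2)$t, ts$t / 2)
  # missing characteristic is an error
  expect_error(estimate_null_covariance(build_tstat_vectors(eff[-c(1, 11), ])),
               "missing characteristic")
})

random_tstats <- function(n_snps, seed, sd = 1) {
  set.seed(seed)
  chars <- migraine_characteristics()
  tibble::tibble(
    snp_id = rep(sprintf("n%04d", seq_len(n_snps)), each = length(chars)),
    characteristic = rep(chars, n_snps),
    t = rnorm(n_snps * length(chars), sd = sd)
  )
}

test_that("null covariance of i.i.d. standard-normal vectors is the identity", {
  ts <- random_tstats(5000, seed = 51)
  sg <- estimate_null_covariance(ts)
  expect_equal(sg$n_null_snps, 5000)
  expect_true(all(abs(sg$sigma - diag(10)) < 0.05))
  # permuting SNP order leaves sigma unchanged
  set.seed(52)
  ids <- unique(ts$snp_id)
  ts_shuffled <- ts[order(match(ts$snp_id, sample(ids))), ]
  sg2 <- estimate_null_covariance(ts_shuffled)
  expect_equal(sg$sigma, sg2$sigma)
  # guard
  expect_error(estimate_null_covariance(random_tstats(10, seed = 5)), ">= 30")
  # duplicated single vector -> degenerate, flagged
  one <- random_tstats(1, seed = 53)
  dup <- purrr::map_dfr(1:40, function(i) {
    dplyr::mutate(one, snp_id = sprintf("d%02d", i))
  })
  expect_warning(sgd <- estimate_null_covariance(dup), "degenerate")
  expect_true(all(abs(sgd$sigma) < 1e-12))
})

test_that("Mahalanobis distance matches its closed form and metric axioms", {
  expect_equal(mahalanobis_distance(1:10, 1:10, diag(10)), 0)
  x <- c(1, 2); y <- c(0, 0)
  expect_equal(mahalanobis_distance(x, y, diag(2)), sqrt(5)) # Euclidean
  expect_equal(mahalanobis_distance(x, y, diag(c(1, 4))), sqrt(2),
               tolerance = 1e-12)
  expect_error(mahalanobis_distance(1:3, 1:2, diag(2)), "dimension")

  set.seed(54)
  A <- matrix(rnorm(100), 10)
  sigma <- crossprod(A) + diag(10) * 0.5
  for (r in 1:20) {
    u <- rnorm(10); v <- rnorm(10)
    duv <- mahalanobis_distance(u, v, sigma)
    expect_equal(duv, mahalanobis_distance(v, u, sigma)) # symmetry
    expect_gt(mahalanobis_distance(u, u + 1e-3, sigma), 0)
    # whitening-equivalence oracle: Euclidean distance after multiplying by
    # the inverse of the Cholesky factor of sigma
    L <- t(chol(sigma))
    wu <- solve(L, u); wv <- solve(L, v)
    expect_equal(duv, sqrt(sum((wu - wv)^2)), tolerance = 1e-10)
  }

  # singular covariance falls back to the pseudo-inverse with a warning
  sing <- tcrossprod(c(1, 2)) # rank 1
  expect_warning(d <- mahalanobis_distance(c(1, 0), c(0, 0), sing),
                 "pseudo-inverse")
  expect_true(is.finite(d))
})

test_that("hierarchical clustering reproduces hand-worked agglomerations", {
  # two well-separated pairs of identical vectors merge at height 0 first
  chars <- migraine_characteristics()
  base <- rbind(rep(0, 10), rep(0, 10), rep(5, 10), rep(5, 10))
  ts <- tibble::tibble(
    snp_id = rep(c("a1", "a2", "b1", "b2"), each = 10),
    characteristic = rep(chars, 4),
    t = as.vector(t(base))
  )
  cl <- cluster_selectivity(ts, diag(10))
  hts <- sort(cl$hclust$height)
  expect_equal(hts[1:2], c(0, 0))
  grp <- cutree(cl$hclust, k = 2)
  expect_equal(grp[["a1"]], grp[["a2"]])
  expect_equal(grp[["b1"]], grp[["b2"]])
  expect_false(grp[["a1"]] == grp[["b1"]])

  # 3 points: d(A,B) = 1, d(A,C) = d(B,C) = 10 -> A,B first at 1, then C at 10
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl3 <- cluster_selectivity(stats::as.dist(d))
  expect_equal(cl3$hclust$height, c(1, 10))
  expect_equal(sort(cl3$hclust$merge[1, ]), c(-2, -1)) # A,B merge first

  # single SNP: single-leaf tree
  one <- cluster_selectivity(tibble::tibble(
    snp_id = "solo", characteristic = chars, t = rnorm(10)
  ), diag(10))
  expect_equal(one$order, "solo")
  expect_match(one$newick, "solo")

  # NaN distances are rejected
  dbad <- stats::as.dist(matrix(c(0, NaN, NaN, 0), 2))
  expect_error(cluster_selectivity(dbad), "NaN|NA")
})

test_that("leaf order is invariant to uniform distance scaling", {
  ts <- random_tstats(8, seed = 55)
  d <- selectivity_distances(ts, diag(10))
  o1 <- cluster_selectivity(d)$order
  o2 <- cluster_selectivity(d * 7.3)$order
  expect_identical(o1, o2)
})

test_that("the dendrogram exports as parseable Newick with merge heights", {
  ts <- random_tstats(6, seed = 56)
  cl <- cluster_selectivity(ts, diag(10))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, unique(ts$snp_id))
})
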