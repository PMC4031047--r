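#' Normalized with/without selectivity vectors
#'
#' For each SNP, the difference of the with- and without-stratum logistic
#' betas for each characteristic, normalized by the square root of the sum
#' of the squared standard errors — i.e. a t-statistic per characteristic:
#' t_c = (beta_with - beta_without) / sqrt(se_with^2 + se_without^2).
#'
#' @param effects Output of [estimate_stratified_effects()] (rows with
#'   strata `"with"` and `"without"`; `"overall"` rows are ignored).
#' @return Tibble of class `migselect_tstat`, one row per SNP x
#'   characteristic with column `t`.
#' @export
build_tstat_vectors <- function(effects) {
  eff <- dplyr::filter(as_tibble(effects), .data$stratum %in% c("with", "without"))
  if (any(is.na(eff$se) | eff$se <= 0)) {
    bad <- eff$snp_id[is.na(eff$se) | eff$se <= 0][1]
    abort(paste0("non-positive or missing SE, cannot normalize: SNP ", bad))
  }
  wide <- tidyr::pivot_wider(
    eff[, c("snp_id", "characteristic", "stratum", "beta", "se")],
    names_from = "stratum", values_from = c("beta", "se")
  )
  if (anyNA(wide$beta_with) || anyNA(wide$beta_without)) {
    abort("each SNP x characteristic needs both a with- and a without-stratum estimate")
  }
  out <- tibble(
    snp_id = wide$snp_id,
    characteristic = wide$characteristic,
    t = (wide$beta_with - wide$beta_without) /
        sqrt(wide$se_with^2 + wide$se_without^2)
  )
  class(out) <- c("migselect_tstat", class(out))
  out
}

# long t tibble -> matrix snps x characteristics (column order fixed)
.tstat_matrix <- function(tstats,
                          characteristics = migraine_characteristics()) {
  wide <- tidyr::pivot_wider(as_tibble(tstats), names_from = "characteristic",
                             values_from = "t")
  miss <- setdiff(characteristics, colnames(wide))
  if (length(miss)) {
    abort(paste0("missing characteristic(s) in t-vectors: ",
                 paste(miss, collapse = ", ")))
  }
  m <- as.matrix(wide[, characteristics])
  rownames(m) <- wide$snp_id
  if (any(!is.finite(m))) abort("non-finite t-statistic entries")
  m
}

#' Null covariance of the selectivity vectors
#'
#' Sample covariance of the per-characteristic t-statistics across a panel
#' of SNPs with no migraine association, capturing the correlation induced
#' by overlap of the characteristic strata. In this package the null panel
#' is simulated (see [simulate_null_tstats()]), standing in for an external
#' catalog of non-associated SNPs.
#'
#' @param null_tstats Output of [build_tstat_vectors()] for the null SNPs.
#' @param min_snps Guard on the number of null SNPs (default 30).
#' @return Object of class `null_covariance`: list with `sigma` (10 x 10)
#'   and `n_null_snps`.
#' @export
estimate_null_covariance <- function(null_tstats, min_snps = 30) {
  m <- .tstat_matrix(null_tstats)
  if (nrow(m) < min_snps) {
    abort(paste0("need >= ", min_snps, " null SNPs to estimate the covariance; got ",
                 nrow(m)))
  }
  sigma <- cov(m)
  if (all(abs(sigma) < 1e-12)) {
    warn("degenerate null covariance (all entries ~0); input vectors may be identical")
  }
  structure(list(sigma = sigma, n_null_snps = nrow(m)),
            class = "null_covariance")
}

#' Mahalanobis distance between two selectivity vectors
#'
#' sqrt((x - y)' Sigma^-1 (x - y)); Euclidean distance after whitening by
#' the null covariance. A singular covariance falls back to the
#' Moore-Penrose pseudo-inverse with a warning.
#'
#' @param x,y Numeric vectors of equal length (or one-SNP rows of
#'   [build_tstat_vectors()] output pivoted wide).
#' @param sigma A `null_covariance` object or a covariance matrix.
#' @return Non-negative scalar distance.
#' @export
mahalanobis_distance <- function(x, y, sigma) {
  if (inherits(sigma, "null_covariance")) sigma <- sigma$sigma
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || nrow(sigma) != length(x) ||
      ncol(sigma) != length(x)) {
    abort("dimension mismatch between vectors and covariance")
  }
  d <- x - y
  inv <- .safe_inverse(sigma)
  sqrt(max(0, drop(t(d) %*% inv %*% d)))
}

.safe_inverse <- function(sigma) {
  tryCatch(solve(sigma), error = function(e) {
    warn("singular covariance; using Moore-Penrose pseudo-inverse")
    MASS::ginv(sigma)
  })
}

#' Pairwise Mahalanobis distances between SNP selectivity vectors
#'
#' @param tstats Output of [build_tstat_vectors()].
#' @param sigma A `null_covariance` object or covariance matrix.
#' @return A `dist` object over SNPs.
#' @export
selectivity_distances <- function(tstats, sigma) {
  if (inherits(sigma, "null_covariance")) sigma <- sigma$sigma
  m <- .tstat_matrix(tstats)
  inv <- .safe_inverse(sigma)
  # whiten with the Cholesky factor of the inverse, then Euclidean distance
  ch <- tryCatch(chol(inv), error = function(e) {
    ei <- eigen(inv, symmetric = TRUE)
    diag(sqrt(pmax(ei$values, 0))) %*% t(ei$vectors)
  })
  stats::dist(m %*% t(ch))
}

#' Hierarchically cluster SNPs by selectivity profile
#'
#' Agglomerative clustering of the pairwise Mahalanobis distances between
#' SNP selectivity vectors (complete linkage by default). The leaf order is
#' used to sort SNPs in the effect-matrix report; the dendrogram can be
#' exported as Newick with merge heights as branch lengths.
#'
#' @param tstats Output of [build_tstat_vectors()], or a precomputed `dist`.
#' @param sigma A `null_covariance` (required when `tstats` is not a
#'   `dist`).
#' @param linkage `"complete"` (default), `"average"`, or `"single"`.
#' @return Object of class `selectivity_clust`: list with the `hclust` fit,
#'   `order` (leaf order as SNP ids), and `newick` string.
#' @export
cluster_selectivity <- function(tstats, sigma = NULL,
                                linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (inherits(tstats, "dist")) {
    d <- tstats
  } else {
    if (is.null(sigma)) abort("`sigma` is required unless `tstats` is a dist")
    d <- selectivity_distances(tstats, sigma)
  }
  if (anyNA(d)) abort("NaN/NA distances cannot be clustered")
  n <- attr(d, "Size")
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (n == 1) {
    return(structure(list(hclust = NULL, order = labels,
                          newick = paste0(labels, ";")),
                     class = "selectivity_clust"))
  }
  hc <- hclust(d, method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, order = hc$labels[hc$order], newick = newick),
            class = "selectivity_clust")
}

#' @export
print.selectivity_clust <- function(x, ...) {
  cat("Selectivity clustering of", length(x$order), "SNPs\n")
  cat("leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname cluster_selectivity
#' @param x A `selectivity_clust` object.
#' @param ... Unused.
#' @method tidy selectivity_clust
#' @export
tidy.selectivity_clust <- function(x, ...) {
  if (is.null(x$hclust)) {
    return(tibble(merge1 = integer(0), merge2 = integer(0), height = numeric(0)))
  }
  tibble(merge1 = x$hclust$merge[, 1], merge2 = x$hclust$merge[, 2],
         height = x$hclust$height)
}

#' @rdname cluster_selectivity
#' @method glance selectivity_clust
#' @export
glance.selectivity_clust <- function(x, ...) {
  tibble(n_snps = length(x$order),
         linkage = if (is.null(x$hclust)) NA_character_ else x$hclust$method,
         max_height = if (is.null(x$hclust)) 0 else max(x$hclust$height))
}

#' Write the dendrogram as Newick
#'
#' @param clust A `selectivity_clust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clust, path) {
  writeLines(clust$newick, path)
  invisible(path)
}
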