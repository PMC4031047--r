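#' Permute genotype assignments across individuals
#'
#' Randomly reassigns genotypes to individuals with a single permutation of
#' individual labels applied jointly to every SNP, so the per-SNP genotype
#' multiset and the between-SNP correlation structure are preserved while
#' all genotype-phenotype association is broken.
#'
#' @param geno A `migselect_geno` tibble.
#' @param seed Optional integer seed for reproducibility.
#' @return A `migselect_geno` tibble with doses permuted across individuals.
#' @export
permute_genotypes <- function(geno, seed = NULL) {
  gm <- .geno_matrix(geno)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(length(gm$ids))
  dose <- gm$dose[, perm, drop = FALSE]
  colnames(dose) <- gm$ids
  new_genotypes(gm$snps, dose)
}

#' Empirical significance of one SNP x characteristic cell
#'
#' Given the observed model selection for a cell and the selections from
#' permuted genotypes, computes (i) the fraction of permutations selecting a
#' non-null model and (ii) the empirical p-value: the fraction of permuted
#' analytic LLR p-values at or below the observed one. Permutations that
#' select the null model contribute an analytic p of exactly 1 (pooled
#' convention); set `condition_on_nonnull = TRUE` to instead restrict the
#' comparison to non-null-selecting permutations.
#'
#' @param observed One-row data frame with `selected` and `llr_p_analytic`
#'   (e.g. `glance()` of [select_inheritance_model()]).
#' @param permuted Data frame of the same columns, one row per permutation.
#' @param convention `"plain"` (default), the fraction r/B, or `"add_one"`
#'   for (r + 1)/(B + 1).
#' @param condition_on_nonnull Restrict the empirical comparison to
#'   permutations with a non-null selected model (default `FALSE`).
#' @param ties `"upper"` (default) counts every tied permutation as at or
#'   below the observed value — the conservative reading of "fraction <=
#'   observed", which leaves a point mass at 1 from null-selected
#'   replicates; `"random"` places the observed value uniformly at random
#'   within its tied block, giving an empirical p that is exactly discrete
#'   uniform under exchangeability (the usual randomized-p device for
#'   discrete permutation tests).
#' @return One-row tibble with `frac_nonnull` and `empirical_p`.
#' @export
empirical_cell_significance <- function(observed, permuted,
                                        convention = c("plain", "add_one"),
                                        condition_on_nonnull = FALSE,
                                        ties = c("upper", "random")) {
  convention <- match.arg(convention)
  ties <- match.arg(ties)
  B <- nrow(permuted)
  if (is.null(B) || B == 0) abort("no permutation results supplied")
  perm_p <- ifelse(permuted$selected == "null", 1, permuted$llr_p_analytic)
  obs_p <- if (observed$selected == "null") 1 else observed$llr_p_analytic
  frac_nonnull <- .emp_frac(sum(permuted$selected != "null"), B, convention)
  if (condition_on_nonnull) {
    keep <- permuted$selected != "null"
    perm_p <- perm_p[keep]
    B <- sum(keep)
    if (B == 0) {
      return(tibble(frac_nonnull = frac_nonnull, empirical_p = 1))
    }
  }
  empirical_p <- .emp_frac(.tie_count(obs_p, perm_p, ties), B, convention)
  tibble(frac_nonnull = frac_nonnull, empirical_p = empirical_p)
}

# number of permuted values counted at or below the observed one
.tie_count <- function(obs, perm, ties) {
  if (ties == "upper") return(sum(perm <= obs))
  n_less <- sum(perm < obs)
  n_tied <- sum(perm == obs)
  n_less + sample.int(n_tied + 1L, 1L) - 1L
}

.emp_frac <- function(r, B, convention) {
  if (convention == "add_one") (r + 1) / (B + 1) else r / B
}

#' Per-SNP rank-statistic correction across characteristics
#'
#' Stage-1 multiple-testing correction: for rank r = 1..10, the observed
#' r-th smallest analytic LLR p-value across the ten characteristics is
#' compared with the distribution of r-th smallest values across
#' permutations; the adjusted value is the fraction of permutations whose
#' r-th order statistic is at or below the observed one. Adjusted values are
#' returned in the original characteristic order.
#'
#' @param observed_ps Numeric vector of analytic p-values for one SNP, one
#'   per characteristic.
#' @param permuted_ps Matrix (permutations x characteristics) of analytic
#'   p-values from the same cells under permutation.
#' @param convention `"plain"` or `"add_one"`, as in
#'   [empirical_cell_significance()].
#' @return Numeric vector of adjusted p-values, aligned with `observed_ps`.
#' @export
rank_adjust <- function(observed_ps, permuted_ps,
                        convention = c("plain", "add_one")) {
  convention <- match.arg(convention)
  permuted_ps <- as.matrix(permuted_ps)
  if (ncol(permuted_ps) != length(observed_ps)) {
    abort("permuted_ps must have one column per observed p-value")
  }
  B <- nrow(permuted_ps)
  if (B == 0) abort("no permutation results supplied")
  ord <- order(observed_ps)            # ranks of the observed values
  obs_sorted <- observed_ps[ord]
  perm_sorted <- t(apply(permuted_ps, 1, sort)) # row-wise order statistics
  adj_sorted <- vapply(seq_along(obs_sorted), function(r) {
    .emp_frac(sum(perm_sorted[, r] <= obs_sorted[r]), B, convention)
  }, numeric(1))
  adj <- numeric(length(observed_ps))
  adj[ord] <- adj_sorted
  adj
}

#' Sidak correction for independent tests
#'
#' Family-wise adjustment `1 - (1 - p)^m` for `m` independent tests
#' (default 12, one per candidate SNP).
#'
#' @param p Probability (vectorized) in \[0, 1\].
#' @param m Positive integer number of tests.
#' @return Adjusted probabilities.
#' @export
#' @examples
#' sidak_correct(0.05, 12) # ~0.4596
sidak_correct <- function(p, m = 12) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1]")
  if (length(m) != 1 || m < 1 || m != floor(m)) {
    abort("`m` must be a positive integer")
  }
  1 - (1 - p)^m
}

#' Permutation-based empirical significance for the whole panel
#'
#' Repeats the entire model-selection procedure under `n_permutations`
#' random reassignments of genotypes to individuals (one individual-level
#' permutation per replicate, shared across SNPs and characteristics) and
#' summarizes, per SNP x characteristic cell: the fraction of non-null
#' selections, the empirical LLR p-value, the per-SNP rank-adjusted p-value
#' across the ten characteristics (stage 1), and the Sidak-corrected p-value
#' across SNPs (stage 2).
#'
#' @inheritParams analyze_selection
#' @param n_permutations Number of genotype-reassignment replicates
#'   (default 10,000).
#' @param seed Master seed; deterministically spawns one seed per replicate.
#' @param criterion `"bic"` or `"aic"`.
#' @param m_sidak Number of independent SNPs assumed by the stage-2 Sidak
#'   correction; defaults to the number of SNPs in `geno`.
#' @inheritParams empirical_cell_significance
#' @return Tibble of class `migselect_perm`, one row per SNP x
#'   characteristic: observed `selected` and `llr_p_analytic`, then
#'   `frac_nonnull`, `empirical_p`, `rank_adjusted_p`, `sidak_p`.
#' @export
permutation_significance <- function(geno, cohort,
                                     characteristics = migraine_characteristics(),
                                     n_permutations = 10000,
                                     seed = NULL,
                                     criterion = c("bic", "aic"),
                                     m_sidak = NULL,
                                     convention = c("plain", "add_one"),
                                     condition_on_nonnull = FALSE,
                                     ties = c("upper", "random"),
                                     case_universe = c("active", "ever"),
                                     bic_n = c("individuals", "alleles"),
                                     modifier_weight = c("size", "equal")) {
  criterion <- match.arg(criterion)
  convention <- match.arg(convention)
  ties <- match.arg(ties)
  case_universe <- match.arg(case_universe)
  bic_n <- match.arg(bic_n)
  modifier_weight <- match.arg(modifier_weight)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")

  gm <- .geno_matrix(geno)
  memb <- .membership_matrix(cohort, gm$ids, characteristics, case_universe)
  d0 <- gm$dose; d0[is.na(d0)] <- 0L
  present <- !is.na(gm$dose)
  snp_ids <- gm$snps$snp_id
  n_snp <- length(snp_ids); n_char <- length(characteristics)
  m_sidak <- m_sidak %||% n_snp

  observed <- .select_cells(
    .tabulate_all(gm$dose, snp_ids, memb), criterion, bic_n, modifier_weight
  )

  seeds <- spawn_seeds(seed, n_permutations + 1L)
  n_ind <- ncol(gm$dose)
  perm_p <- matrix(NA_real_, n_permutations, n_snp * n_char)
  perm_nonnull <- matrix(NA, n_permutations, n_snp * n_char)
  for (b in seq_len(n_permutations)) {
    set.seed(seeds[b])
    perm <- sample.int(n_ind)
    cells <- .tabulate_all_perm(d0, present, perm, snp_ids, memb)
    sel <- .select_cells(cells, criterion, bic_n, modifier_weight)
    perm_nonnull[b, ] <- sel$selected != "null"
    perm_p[b, ] <- ifelse(sel$selected == "null", 1, sel$llr_p_analytic)
  }

  obs_p <- ifelse(observed$selected == "null", 1, observed$llr_p_analytic)
  frac_nonnull <- numeric(length(obs_p))
  empirical_p <- numeric(length(obs_p))
  set.seed(seeds[n_permutations + 1L]) # randomized tie-breaking, if requested
  for (j in seq_along(obs_p)) {
    cell <- empirical_cell_significance(
      tibble(selected = observed$selected[j], llr_p_analytic = obs_p[j]),
      tibble(selected = ifelse(perm_nonnull[, j], "nonnull", "null"),
             llr_p_analytic = perm_p[, j]),
      convention = convention, condition_on_nonnull = condition_on_nonnull,
      ties = ties
    )
    frac_nonnull[j] <- cell$frac_nonnull
    empirical_p[j] <- cell$empirical_p
  }

  # stage 1: per-SNP rank correction across characteristics
  rank_adjusted <- numeric(length(obs_p))
  for (s in seq_len(n_snp)) {
    cols <- which(observed$snp_id == snp_ids[s])
    rank_adjusted[cols] <- rank_adjust(obs_p[cols],
                                       perm_p[, cols, drop = FALSE],
                                       convention = convention)
  }

  out <- observed[, c("snp_id", "characteristic", "criterion", "selected",
                      "llr_stat", "llr_p_analytic")]
  out$frac_nonnull <- frac_nonnull
  out$empirical_p <- empirical_p
  out$rank_adjusted_p <- rank_adjusted
  out$sidak_p <- sidak_correct(rank_adjusted, m_sidak)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "m_sidak") <- m_sidak
  class(out) <- c("migselect_perm", class(out))
  out
}

# counts for a permutation replicate: permute individuals (columns), then the
# same two matrix products as .tabulate_all
.tabulate_all_perm <- function(d0, present, perm, snp_ids, memb) {
  Zp <- memb$Z[perm, , drop = FALSE] # permuting Z rows == permuting genotypes
  K <- d0 %*% Zp
  M <- present %*% Zp
  n_char <- length(memb$characteristics)
  idx_w <- 3L * (seq_len(n_char) - 1L) + 1L
  ord <- cbind(rep(seq_along(snp_ids), each = n_char),
               rep(seq_len(n_char), length(snp_ids)))
  tibble(
    snp_id = rep(snp_ids, each = n_char),
    characteristic = rep(memb$characteristics, length(snp_ids)),
    k_with = K[cbind(ord[, 1], idx_w[ord[, 2]])],
    k_without = K[cbind(ord[, 1], idx_w[ord[, 2]] + 1L)],
    k_ctrl = K[cbind(ord[, 1], idx_w[ord[, 2]] + 2L)],
    n_with = 2L * M[cbind(ord[, 1], idx_w[ord[, 2]])],
    n_without = 2L * M[cbind(ord[, 1], idx_w[ord[, 2]] + 1L)],
    n_ctrl = 2L * M[cbind(ord[, 1], idx_w[ord[, 2]] + 2L)]
  )
}
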