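#' Model selection across every SNP x characteristic cell
#'
#' Runs the full likelihood model selection for each SNP against each
#' migraine characteristic (and optionally the active-vs-former partition),
#' returning one row per SNP x characteristic x criterion.
#'
#' @inheritParams tabulate_trigroup
#' @inheritParams fit_inheritance_model
#' @param characteristics Character vector of characteristics to analyze;
#'   defaults to all ten of [migraine_characteristics()].
#' @param criteria One or both of `"bic"`, `"aic"`.
#' @return Tibble of class `migselect_selection_tbl`: `snp_id`,
#'   `characteristic`, `criterion`, `selected`, fitted frequencies,
#'   `llr_stat`, `llr_df`, `llr_p_analytic`, and the underlying counts.
#' @export
analyze_selection <- function(geno, cohort,
                              characteristics = migraine_characteristics(),
                              criteria = c("bic", "aic"),
                              case_universe = c("active", "ever"),
                              bic_n = c("individuals", "alleles"),
                              modifier_weight = c("size", "equal")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  case_universe <- match.arg(case_universe)
  bic_n <- match.arg(bic_n)
  modifier_weight <- match.arg(modifier_weight)
  for (ch in characteristics) .check_characteristic(ch)

  gm <- .geno_matrix(geno)
  memb <- .membership_matrix(cohort, gm$ids, characteristics, case_universe)
  cells <- .tabulate_all(gm$dose, gm$snps$snp_id, memb)
  out <- .select_cells(cells, criteria, bic_n, modifier_weight)
  class(out) <- c("migselect_selection_tbl", class(out))
  out
}

# cells: tibble with count columns (one row per cell); returns selection rows
.select_cells <- function(cells, criteria, bic_n = "individuals",
                          modifier_weight = "size") {
  fits <- .fit_models_cells(cells, bic_n = bic_n,
                            modifier_weight = modifier_weight)
  model_order <- inheritance_models()$model
  ncell <- nrow(cells)
  ll <- matrix(fits$loglik, nrow = ncell)   # cells x models (fit order)
  fw <- matrix(fits$freq_with, nrow = ncell)
  fo <- matrix(fits$freq_without, nrow = ncell)
  fc <- matrix(fits$freq_ctrl, nrow = ncell)
  dfs <- inheritance_models()$df

  out <- vector("list", length(criteria))
  for (j in seq_along(criteria)) {
    crit <- criteria[j]
    score <- matrix(fits[[crit]], nrow = ncell)
    sel <- max.col(-score, ties.method = "first") # tie-break order = fit order
    idx <- cbind(seq_len(ncell), sel)
    stat <- pmax(0, 2 * (ll[idx] - ll[, 1]))
    is_null <- sel == 1L
    df <- dfs[sel] - 1L
    res <- cells[, intersect(c("snp_id", "characteristic",
                               "k_with", "n_with", "k_without", "n_without",
                               "k_ctrl", "n_ctrl"), colnames(cells))]
    res$criterion <- crit
    res$selected <- model_order[sel]
    res$freq_with <- fw[idx]; res$freq_without <- fo[idx]; res$freq_ctrl <- fc[idx]
    res$llr_stat <- ifelse(is_null, 0, stat)
    res$llr_df <- ifelse(is_null, NA_integer_, df)
    res$llr_p_analytic <- ifelse(is_null, 1,
                                 pchisq(stat, pmax(df, 1L), lower.tail = FALSE))
    out[[j]] <- res
  }
  dplyr::bind_rows(out)
}

#' Reshape selection results to the model matrix report
#'
#' Pivots [analyze_selection()] output for one criterion to the wide
#' SNP-by-characteristic matrix with the report vocabulary (`-` for null,
#' `basic`, `sub.`, `inv. sub.`, `modifier`, `general`), optionally starring
#' cells whose fully corrected permutation p-value falls below `alpha`.
#'
#' @param selection Output of [analyze_selection()] (rows of one criterion).
#' @param perm Optional output of [permutation_significance()] providing
#'   `sidak_p` per cell.
#' @param alpha Significance level for the stars (default 0.05).
#' @return Wide tibble, one row per SNP.
#' @export
selection_model_matrix <- function(selection, perm = NULL, alpha = 0.05) {
  if (length(unique(selection$criterion)) != 1) {
    abort("pass selection rows for a single criterion")
  }
  lab <- c(null = "-", basic = "basic", subset = "sub.",
           inverse_subset = "inv. sub.", modifier = "modifier",
           general = "general")
  x <- selection
  x$entry <- unname(lab[x$selected])
  if (!is.null(perm)) {
    x <- dplyr::left_join(
      x, as_tibble(perm)[, c("snp_id", "characteristic", "sidak_p")],
      by = c("snp_id", "characteristic")
    )
    star <- !is.na(x$sidak_p) & x$sidak_p < alpha & x$selected != "null"
    x$entry <- ifelse(star, paste0(x$entry, "*"), x$entry)
  }
  tidyr::pivot_wider(x[, c("snp_id", "characteristic", "entry")],
                     names_from = "characteristic", values_from = "entry")
}
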