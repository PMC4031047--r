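#' Choose the coded allele per SNP
#'
#' Orients each SNP so that the coded allele is the one associated with
#' increased probability of *any* report of migraine (active or former
#' migraineurs versus never-migraineurs): the minor allele if the logistic
#' log-odds of any migraine per minor-allele copy is >= 0, otherwise the
#' major allele. All downstream stratified betas are re-signed accordingly.
#'
#' @inheritParams tabulate_trigroup
#' @return Tibble with one row per SNP: `snp_id`, `beta_any` (log-odds of
#'   any migraine per minor allele), `coded_allele` (`"minor"`/`"major"`),
#'   `coded_label` (the nucleotide when known), and `sign` (+1/-1 applied to
#'   minor-allele effects).
#' @export
choose_coded_allele <- function(geno, cohort) {
  gm <- .geno_matrix(geno)
  cohort <- as_tibble(cohort)[match(gm$ids, cohort$individual_id), ]
  if (anyNA(cohort$individual_id)) {
    abort("genotyped individual(s) absent from the cohort table")
  }
  is_case <- cohort$migraine_status %in% c("active", "former")
  is_ctrl <- cohort$migraine_status == "never"
  counts <- .dose_level_counts(gm$dose, cbind(case = is_case, ctrl = is_ctrl))
  out <- vector("list", nrow(gm$snps))
  for (i in seq_len(nrow(gm$snps))) {
    k_case <- counts[i, , "case"]; k_ctrl <- counts[i, , "ctrl"]
    if (sum((k_case + k_ctrl)[c(2, 3)]) == 0 ||
        sum((k_case + k_ctrl)[c(1, 2)]) == 0) {
      abort(paste0("monomorphic SNP, coded allele undefined: ",
                   gm$snps$snp_id[i]))
    }
    fit <- .logit_dose_fit(k_case, k_ctrl)
    minor_coded <- fit$beta >= 0
    out[[i]] <- tibble(
      snp_id = gm$snps$snp_id[i],
      beta_any = fit$beta,
      coded_allele = if (minor_coded) "minor" else "major",
      coded_label = if (minor_coded) gm$snps$allele_minor[i]
                    else gm$snps$allele_major[i],
      sign = if (minor_coded) 1 else -1
    )
  }
  dplyr::bind_rows(out)
}

#' Stratified logistic effect estimate for one SNP
#'
#' Unadjusted logistic regression of case status on coded-allele count
#' (additive 0/1/2 coding) for one of three strata: active cases *with* the
#' characteristic vs never-migraineurs, active cases *without* it vs
#' never-migraineurs, or all active cases vs never-migraineurs
#' (`"overall"`). Former migraineurs are excluded throughout. Inference is
#' Wald (two-sided).
#'
#' @inheritParams tabulate_trigroup
#' @param stratum `"with"`, `"without"`, or `"overall"`.
#' @param orientation Optional output of [choose_coded_allele()]; computed
#'   from the data when omitted. Effects are reported per coded allele.
#' @param min_cases,min_controls Guard on the stratum design (default 10
#'   each); smaller designs raise an error.
#' @return One-row tibble: `snp_id`, `characteristic`, `stratum`, `beta`,
#'   `se`, `p`, `n_cases`, `n_controls`, `converged`.
#' @export
stratum_effect <- function(geno, cohort, snp_id, characteristic,
                           stratum = c("with", "without", "overall"),
                           orientation = NULL,
                           min_cases = 10, min_controls = 10) {
  stratum <- match.arg(stratum)
  if (stratum != "overall") .check_characteristic(characteristic,
                                                  allow_partition = FALSE)
  eff <- estimate_stratified_effects(
    geno, cohort,
    characteristics = if (stratum == "overall") character(0) else characteristic,
    orientation = orientation, include_overall = (stratum == "overall"),
    min_cases = min_cases, min_controls = min_controls
  )
  out <- dplyr::filter(eff, .data$snp_id == !!snp_id, .data$stratum == !!stratum)
  if (nrow(out) == 0) abort(paste0("SNP not found: ", snp_id))
  out
}

#' Stratified logistic effects for the whole panel
#'
#' Computes [stratum_effect()]-style estimates for every SNP x
#' characteristic x stratum (with/without), plus the per-SNP overall
#' active-migraine effect, all against never-migraineur controls and on the
#' coded-allele orientation.
#'
#' @inheritParams stratum_effect
#' @inheritParams analyze_selection
#' @param include_overall Also estimate the overall active-vs-never effect
#'   per SNP (default `TRUE`).
#' @return Tibble of class `migselect_effects`, one row per SNP x
#'   characteristic x stratum (characteristic is `NA` for `"overall"` rows).
#' @export
estimate_stratified_effects <- function(geno, cohort,
                                        characteristics = migraine_characteristics(),
                                        orientation = NULL,
                                        include_overall = TRUE,
                                        min_cases = 10, min_controls = 10) {
  gm <- .geno_matrix(geno)
  cohort <- as_tibble(cohort)[match(gm$ids, cohort$individual_id), ]
  if (anyNA(cohort$individual_id)) {
    abort("genotyped individual(s) absent from the cohort table")
  }
  if (is.null(orientation)) {
    orientation <- choose_coded_allele(geno, cohort)
  }
  sgn <- orientation$sign[match(gm$snps$snp_id, orientation$snp_id)]
  if (anyNA(sgn)) abort("orientation table does not cover every SNP")

  status <- cohort$migraine_status
  groups <- list(ctrl = status == "never")
  labels <- list()
  for (ch in characteristics) {
    flag <- cohort[[ch]]
    groups[[paste0(ch, "|with")]] <- status == "active" & !is.na(flag) & flag == 1
    groups[[paste0(ch, "|without")]] <- status == "active" & !is.na(flag) & flag == 0
  }
  if (include_overall) groups[["overall|overall"]] <- status == "active"
  memb <- do.call(cbind, groups)
  counts <- .dose_level_counts(gm$dose, memb)

  cells <- setdiff(colnames(memb), "ctrl")
  out <- vector("list", nrow(gm$snps) * length(cells))
  r <- 0L
  for (i in seq_len(nrow(gm$snps))) {
    k_ctrl <- counts[i, , "ctrl"]
    for (cell in cells) {
      k_case <- counts[i, , cell]
      parts <- strsplit(cell, "|", fixed = TRUE)[[1]]
      n_cases <- sum(k_case); n_controls <- sum(k_ctrl)
      if (n_cases < min_cases || n_controls < min_controls) {
        abort(sprintf(
          "stratum '%s' of %s has %d cases / %d controls (guard: >= %d / %d)",
          cell, gm$snps$snp_id[i], n_cases, n_controls, min_cases, min_controls))
      }
      fit <- .logit_dose_fit(k_case, k_ctrl, flip = sgn[i] < 0)
      r <- r + 1L
      out[[r]] <- tibble(
        snp_id = gm$snps$snp_id[i],
        characteristic = if (parts[1] == "overall") NA_character_ else parts[1],
        stratum = parts[2],
        beta = fit$beta, se = fit$se, p = fit$p,
        n_cases = n_cases, n_controls = n_controls,
        converged = fit$converged
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (any(!res$converged)) {
    warn(paste0("logistic fit flagged (separation or non-convergence) for: ",
                paste(unique(res$snp_id[!res$converged]), collapse = ", ")))
  }
  class(res) <- c("migselect_effects", class(res))
  res
}

# counts[snp, dose level 0:2, group] of non-missing genotypes
.dose_level_counts <- function(dose, memb) {
  storage.mode(memb) <- "integer"
  out <- array(0L, dim = c(nrow(dose), 3L, ncol(memb)),
               dimnames = list(NULL, c("d0", "d1", "d2"), colnames(memb)))
  for (d in 0:2) {
    ind <- !is.na(dose) & dose == d
    storage.mode(ind) <- "integer"
    out[, d + 1L, ] <- ind %*% memb
  }
  out
}

# Logistic regression of case status on allele dose from aggregated counts.
# k_case, k_ctrl: length-3 counts of individuals with dose 0/1/2.
# flip = TRUE recodes dose d -> 2 - d (coded allele = major).
.logit_dose_fit <- function(k_case, k_ctrl, flip = FALSE) {
  if (flip) { k_case <- rev(k_case); k_ctrl <- rev(k_ctrl) }
  tot <- k_case + k_ctrl
  keep <- tot > 0
  x <- cbind(1, 0:2)[keep, , drop = FALSE]
  if (nrow(x) < 2 || length(unique(x[, 2])) < 2) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE))
  }
  y <- (k_case / tot)[keep]
  fit <- suppressWarnings(
    stats::glm.fit(x, y, weights = tot[keep], family = binomial())
  )
  beta <- fit$coefficients[2]
  R <- qr.R(fit$qr)
  se <- tryCatch(sqrt(diag(chol2inv(R)))[2], error = function(e) NA_real_)
  converged <- isTRUE(fit$converged) && is.finite(beta) && abs(beta) < 15 &&
    is.finite(se)
  z <- beta / se
  list(beta = unname(beta), se = unname(se),
       p = unname(2 * stats::pnorm(-abs(z))),
       converged = converged)
}
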