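#' Cohort summary table (active vs never migraineurs)
#'
#' Per covariate: median (IQR) for continuous variables with a two-sided
#' t-test (pooled variance by default), or N (%) per level for categorical
#' variables with a Pearson chi-square test on the r x 2 table *without*
#' continuity correction. Former migraineurs are excluded from the
#' comparison, matching the reference cohort's demographic table.
#'
#' @param cohort A `migselect_cohort`.
#' @param covariates Named character vector mapping covariate column names
#'   to `"continuous"` or `"categorical"`.
#' @param var_equal Pooled-variance t-test (default `TRUE`); set `FALSE`
#'   for Welch.
#' @return Tibble: `variable`, `level`, formatted `active` and `never`
#'   summaries, `test`, `statistic`, `p`, `note`.
#' @export
#' @examples
#' sc <- simulation_scenario(n_active = 100, n_former = 30, n_never = 300)
#' coh <- simulate_phenotypes(sc, seed = 1)
#' summarize_cohort(coh, c(age = "continuous", ever_smoke = "categorical"))
summarize_cohort <- function(cohort, covariates, var_equal = TRUE) {
  cohort <- as_tibble(cohort)
  if (is.null(names(covariates)) ||
      !all(covariates %in% c("continuous", "categorical"))) {
    abort("`covariates` must be a named vector of 'continuous'/'categorical'")
  }
  act <- cohort[cohort$migraine_status == "active", ]
  nev <- cohort[cohort$migraine_status == "never", ]
  rows <- list(tibble(
    variable = "N", level = NA_character_,
    active = format(nrow(act), big.mark = ","),
    never = format(nrow(nev), big.mark = ","),
    test = NA_character_, statistic = NA_real_, p = NA_real_,
    note = NA_character_
  ))
  for (v in names(covariates)) {
    if (!v %in% colnames(cohort)) abort(paste0("covariate not found: ", v))
    if (covariates[[v]] == "continuous") {
      tt <- t.test(act[[v]], nev[[v]], var.equal = var_equal)
      rows[[length(rows) + 1]] <- tibble(
        variable = v, level = NA_character_,
        active = .fmt_median_iqr(act[[v]]), never = .fmt_median_iqr(nev[[v]]),
        test = "t", statistic = unname(tt$statistic), p = tt$p.value,
        note = NA_character_
      )
    } else {
      lv <- sort(unique(c(act[[v]], nev[[v]])))
      ka <- vapply(lv, function(l) sum(act[[v]] == l, na.rm = TRUE), numeric(1))
      kn <- vapply(lv, function(l) sum(nev[[v]] == l, na.rm = TRUE), numeric(1))
      if (length(lv) < 2) {
        rows[[length(rows) + 1]] <- tibble(
          variable = v, level = as.character(lv[1]),
          active = .fmt_count_pct(ka[1], nrow(act)),
          never = .fmt_count_pct(kn[1], nrow(nev)),
          test = NA_character_, statistic = NA_real_, p = NA_real_,
          note = "single level; chi-square skipped"
        )
        next
      }
      ct <- chisq_rx2(ka, kn)
      binary01 <- setequal(lv, c(0, 1))
      show_lv <- if (binary01) 2L else seq_along(lv) # binary: the "yes" row
      first <- TRUE
      for (j in show_lv) {
        rows[[length(rows) + 1]] <- tibble(
          variable = v,
          level = if (binary01) NA_character_ else as.character(lv[j]),
          active = .fmt_count_pct(ka[j], nrow(act)),
          never = .fmt_count_pct(kn[j], nrow(nev)),
          test = if (first) "chisq" else NA_character_,
          statistic = if (first) ct$statistic else NA_real_,
          p = if (first) ct$p else NA_real_,
          note = NA_character_
        )
        first <- FALSE
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Pearson chi-square on an r x 2 count table, no continuity correction
#'
#' @param k_active,k_never Count vectors over the r levels in the two
#'   comparison groups.
#' @return List with `statistic`, `df`, `p`.
#' @export
#' @examples
#' chisq_rx2(c(1375, 3003 - 1375), c(8953, 18108 - 8953))$p # ~2e-4
chisq_rx2 <- function(k_active, k_never) {
  tab <- cbind(active = k_active, never = k_never)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Characteristic prevalence table among active migraineurs
#'
#' Counts and fractions (to two decimals) of active migraineurs with and
#' without each of the ten characteristics.
#'
#' @param cohort A `migselect_cohort`.
#' @return Tibble: `characteristic`, `n_yes`, `fr_yes`, `n_no`, `fr_no`.
#' @export
characteristic_table <- function(cohort) {
  cohort <- as_tibble(cohort)
  act <- cohort[cohort$migraine_status == "active", ]
  if (nrow(act) == 0) abort("no active migraineurs in the cohort")
  purrr::map_dfr(migraine_characteristics(), function(ch) {
    yes <- sum(act[[ch]] == 1)
    no <- sum(act[[ch]] == 0)
    tibble(characteristic = ch, n_yes = yes,
           fr_yes = round(yes / nrow(act), 2),
           n_no = no, fr_no = round(no / nrow(act), 2))
  })
}
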