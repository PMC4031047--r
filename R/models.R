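#' The six inheritance models
#'
#' Constraints on the minor-allele frequencies (p_with, p_without, p_ctrl)
#' of the three analysis groups, with free-parameter counts:
#'
#' * `null` (1 df): one common frequency in all three groups.
#' * `basic` (2 df): one frequency for all cases, another for non-cases.
#' * `subset` (2 df): free frequency in cases *with* the characteristic;
#'   cases without and non-cases share a second frequency.
#' * `inverse_subset` (2 df): the mirror image — free frequency in cases
#'   *without* the characteristic.
#' * `modifier` (2 df): free frequencies in the two case sub-groups, with the
#'   non-case frequency constrained to their weighted mean (association with
#'   the characteristic conditional on having migraine).
#' * `general` (3 df): all three frequencies free.
#'
#' The order returned is the tie-break order of model selection: fewer
#' degrees of freedom first, then this fixed order.
#'
#' @return Tibble with columns `model` and `df`.
#' @export
inheritance_models <- function() {
  tibble(
    model = c("null", "basic", "subset", "inverse_subset", "modifier", "general"),
    df = c(1L, 2L, 2L, 2L, 2L, 3L)
  )
}

.model_df <- function(model) {
  m <- inheritance_models()
  m$df[match(model, m$model)]
}

.check_counts <- function(counts) {
  need <- c("k_with", "n_with", "k_without", "n_without", "k_ctrl", "n_ctrl")
  miss <- setdiff(need, names(counts))
  if (length(miss)) abort(paste0("counts are missing field(s): ",
                                 paste(miss, collapse = ", ")))
  for (nm in need) .assert_scalar_count(counts[[nm]], nm)
  with(counts, {
    if (k_with > n_with || k_without > n_without || k_ctrl > n_ctrl) {
      abort("allele count k exceeds allele total n in some group")
    }
    if (n_with + n_without + n_ctrl == 0) abort("all groups empty")
    if (n_with == 0 || n_without == 0 || n_ctrl == 0) {
      abort("empty group: all three groups need a positive allele total")
    }
  })
  invisible(counts)
}

#' Fit one inheritance model to three-group allele counts
#'
#' The likelihood is a product of independent binomials on allele counts
#' (2 Bernoulli alleles per individual, i.e. Hardy-Weinberg within group).
#' All models except `modifier` have closed-form maximum-likelihood
#' frequencies (pooled sample frequencies over the groups each parameter
#' spans); the `modifier` constraint p_ctrl = w * p_with + (1 - w) * p_without
#' is maximized numerically on the logit scale with analytic gradients.
#' Log-likelihoods omit the binomial coefficient, which is identical across
#' models and cancels in all comparisons.
#'
#' @param counts One-row data frame or list with `k_with`, `n_with`,
#'   `k_without`, `n_without`, `k_ctrl`, `n_ctrl` (see [tabulate_trigroup()]).
#' @param model Model name, see [inheritance_models()].
#' @param bic_n Sample-size convention for the BIC penalty:
#'   `"individuals"` (default; allele totals / 2) or `"alleles"`.
#' @param modifier_weight Weighting of the modifier constraint: `"size"`
#'   (default; w = n_with / (n_with + n_without), the allele-total share of
#'   the with-group) or `"equal"` (w = 1/2).
#' @return One-row tibble: `model`, `df`, `freq_with`, `freq_without`,
#'   `freq_ctrl`, `loglik`, `aic`, `bic`.
#' @export
#' @examples
#' toy <- list(k_with = 50, n_with = 100, k_without = 40, n_without = 100,
#'             k_ctrl = 80, n_ctrl = 200)
#' fit_inheritance_model(toy, "subset")
fit_inheritance_model <- function(counts, model,
                                  bic_n = c("individuals", "alleles"),
                                  modifier_weight = c("size", "equal")) {
  bic_n <- match.arg(bic_n)
  modifier_weight <- match.arg(modifier_weight)
  model <- match.arg(model, inheritance_models()$model)
  .check_counts(counts)
  fits <- .fit_models_cells(
    tibble(k_with = counts$k_with, n_with = counts$n_with,
           k_without = counts$k_without, n_without = counts$n_without,
           k_ctrl = counts$k_ctrl, n_ctrl = counts$n_ctrl),
    models = model, bic_n = bic_n, modifier_weight = modifier_weight
  )
  fits[, c("model", "df", "freq_with", "freq_without", "freq_ctrl",
           "loglik", "aic", "bic")]
}

#' Fit all six inheritance models
#'
#' @inheritParams fit_inheritance_model
#' @return Six-row tibble in tie-break order, columns as in
#'   [fit_inheritance_model()].
#' @export
fit_all_models <- function(counts, bic_n = c("individuals", "alleles"),
                           modifier_weight = c("size", "equal")) {
  bic_n <- match.arg(bic_n)
  modifier_weight <- match.arg(modifier_weight)
  .check_counts(counts)
  fits <- .fit_models_cells(
    tibble(k_with = counts$k_with, n_with = counts$n_with,
           k_without = counts$k_without, n_without = counts$n_without,
           k_ctrl = counts$k_ctrl, n_ctrl = counts$n_ctrl),
    models = inheritance_models()$model,
    bic_n = bic_n, modifier_weight = modifier_weight
  )
  fits[, c("model", "df", "freq_with", "freq_without", "freq_ctrl",
           "loglik", "aic", "bic")]
}

# Vectorized fitting over many count cells. `cells` is a tibble with the six
# count columns; returns one row per cell x model with cell = row index.
.fit_models_cells <- function(cells, models = inheritance_models()$model,
                              bic_n = "individuals",
                              modifier_weight = "size") {
  kw <- cells$k_with; nw <- cells$n_with
  ko <- cells$k_without; no <- cells$n_without
  kc <- cells$k_ctrl; nc <- cells$n_ctrl
  n_ind <- if (bic_n == "alleles") nw + no + nc else (nw + no + nc) / 2

  rows <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[i]
    est <- switch(m,
      null = {
        p <- (kw + ko + kc) / (nw + no + nc)
        list(pw = p, po = p, pc = p,
             ll = binom_loglik(kw + ko + kc, nw + no + nc, p))
      },
      basic = {
        pcase <- (kw + ko) / (nw + no); pc <- kc / nc
        list(pw = pcase, po = pcase, pc = pc,
             ll = binom_loglik(kw + ko, nw + no, pcase) +
                  binom_loglik(kc, nc, pc))
      },
      subset = {
        pw <- kw / nw; prest <- (ko + kc) / (no + nc)
        list(pw = pw, po = prest, pc = prest,
             ll = binom_loglik(kw, nw, pw) +
                  binom_loglik(ko + kc, no + nc, prest))
      },
      inverse_subset = {
        po <- ko / no; prest <- (kw + kc) / (nw + nc)
        list(pw = prest, po = po, pc = prest,
             ll = binom_loglik(ko, no, po) +
                  binom_loglik(kw + kc, nw + nc, prest))
      },
      general = {
        pw <- kw / nw; po <- ko / no; pc <- kc / nc
        list(pw = pw, po = po, pc = pc,
             ll = binom_loglik(kw, nw, pw) + binom_loglik(ko, no, po) +
                  binom_loglik(kc, nc, pc))
      },
      modifier = .fit_modifier_vec(kw, nw, ko, no, kc, nc, modifier_weight)
    )
    df <- .model_df(m)
    rows[[i]] <- tibble(
      cell = seq_along(kw), model = m, df = df,
      freq_with = est$pw, freq_without = est$po, freq_ctrl = est$pc,
      loglik = est$ll,
      aic = -2 * est$ll + 2 * df,
      bic = -2 * est$ll + df * log(n_ind)
    )
  }
  dplyr::bind_rows(rows)
}

# Modifier model MLE for vectors of cells. Concave in (p_with, p_without);
# optimized per cell by BFGS on the logit scale with analytic gradient.
.fit_modifier_vec <- function(kw, nw, ko, no, kc, nc, modifier_weight) {
  m <- length(kw)
  pw <- numeric(m); po <- numeric(m); pc <- numeric(m); ll <- numeric(m)
  for (i in seq_len(m)) {
    fit <- .fit_modifier_one(kw[i], nw[i], ko[i], no[i], kc[i], nc[i],
                             modifier_weight)
    pw[i] <- fit$pw; po[i] <- fit$po; pc[i] <- fit$pc; ll[i] <- fit$ll
  }
  list(pw = pw, po = po, pc = pc, ll = ll)
}

.fit_modifier_one <- function(kw, nw, ko, no, kc, nc, modifier_weight) {
  w <- if (modifier_weight == "equal") 0.5 else nw / (nw + no)
  eps <- 1e-9
  ll_at <- function(pw, po) {
    q <- w * pw + (1 - w) * po
    binom_loglik(kw, nw, pw) + binom_loglik(ko, no, po) + binom_loglik(kc, nc, q)
  }
  # when the unconstrained case frequencies already satisfy the constraint,
  # the unconstrained optimum is the constrained optimum
  pw0 <- kw / nw; po0 <- ko / no
  if (abs(w * pw0 + (1 - w) * po0 - kc / nc) < 1e-12) {
    return(list(pw = pw0, po = po0, pc = kc / nc, ll = ll_at(pw0, po0)))
  }
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  nll <- function(th) {
    pw <- stats::plogis(th[1]); po <- stats::plogis(th[2])
    -ll_at(clamp(pw), clamp(po))
  }
  grad <- function(th) {
    pw <- clamp(stats::plogis(th[1])); po <- clamp(stats::plogis(th[2]))
    q <- clamp(w * pw + (1 - w) * po)
    dq <- kc / q - (nc - kc) / (1 - q)
    dpw <- kw / pw - (nw - kw) / (1 - pw) + w * dq
    dpo <- ko / po - (no - ko) / (1 - po) + (1 - w) * dq
    -c(dpw * pw * (1 - pw), dpo * po * (1 - po))
  }
  start <- stats::qlogis(clamp(c(pw0, po0)))
  opt <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  if (opt$convergence != 0) {
    abort(paste0("modifier model fit did not converge (optim code ",
                 opt$convergence, ", counts ",
                 paste(c(kw, nw, ko, no, kc, nc), collapse = "/"), ")"))
  }
  pw <- clamp(stats::plogis(opt$par[1])); po <- clamp(stats::plogis(opt$par[2]))
  list(pw = pw, po = po, pc = w * pw + (1 - w) * po, ll = -opt$value)
}

#' Analytic p-value of the log-likelihood-ratio test
#'
#' Upper-tail chi-square probability for the LLR statistic of a selected
#' model against the null, with degrees of freedom equal to the difference
#' in free parameters. The analytic p is used as a ranking device for the
#' permutation machinery; it returns exactly 1 for a zero statistic.
#'
#' @param llr_stat Non-negative LLR statistic, 2 * (loglik_alt - loglik_null).
#' @param llr_df Positive integer degrees of freedom.
#' @return Probability in (0, 1].
#' @export
#' @examples
#' llr_pvalue(3.841, 1) # ~0.05
llr_pvalue <- function(llr_stat, llr_df) {
  if (any(llr_df <= 0) || any(llr_df != floor(llr_df))) {
    abort("`llr_df` must be a positive integer")
  }
  if (any(llr_stat < 0)) abort("`llr_stat` must be non-negative")
  ifelse(llr_stat == 0, 1, pchisq(llr_stat, df = llr_df, lower.tail = FALSE))
}

#' Select the inheritance model by penalized likelihood
#'
#' Fits all six models and picks the one minimizing the chosen criterion
#' (BIC by default). Ties go to the model with fewer degrees of freedom and
#' then to the fixed order null, basic, subset, inverse_subset, modifier,
#' general. The LLR statistic, df, and analytic chi-square p of the selected
#' model against the null are attached; a null selection has statistic 0 and
#' p exactly 1.
#'
#' @inheritParams fit_inheritance_model
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return Object of class `migselect_selection`: use [glance()] for the
#'   one-row selection summary and [tidy()] for the six per-model fits.
#' @export
#' @examples
#' toy <- list(k_with = 50, n_with = 100, k_without = 40, n_without = 100,
#'             k_ctrl = 80, n_ctrl = 200)
#' glance(select_inheritance_model(toy, criterion = "aic"))
select_inheritance_model <- function(counts, criterion = c("bic", "aic"),
                                     bic_n = c("individuals", "alleles"),
                                     modifier_weight = c("size", "equal")) {
  criterion <- match.arg(criterion)
  fits <- fit_all_models(counts, bic_n = match.arg(bic_n),
                         modifier_weight = match.arg(modifier_weight))
  sel <- .select_from_fits(fits, criterion)
  structure(
    list(fits = fits, selection = sel, criterion = criterion, counts = counts),
    class = "migselect_selection"
  )
}

# fits: tibble in tie-break order for one cell
.select_from_fits <- function(fits, criterion) {
  score <- fits[[criterion]]
  i <- which.min(score) # first minimum = fewest df, then fixed order
  ll0 <- fits$loglik[fits$model == "null"]
  stat <- max(0, 2 * (fits$loglik[i] - ll0))
  df <- fits$df[i] - 1L
  tibble(
    criterion = criterion,
    selected = fits$model[i],
    freq_with = fits$freq_with[i],
    freq_without = fits$freq_without[i],
    freq_ctrl = fits$freq_ctrl[i],
    llr_stat = if (fits$model[i] == "null") 0 else stat,
    llr_df = if (fits$model[i] == "null") NA_integer_ else df,
    llr_p_analytic = if (fits$model[i] == "null") 1 else llr_pvalue(stat, df)
  )
}

#' @export
print.migselect_selection <- function(x, ...) {
  cat("Inheritance model selection (", toupper(x$criterion), ")\n", sep = "")
  cat("  selected:", x$selection$selected,
      "| LLR =", signif(x$selection$llr_stat, 4),
      "| analytic p =", signif(x$selection$llr_p_analytic, 4), "\n")
  invisible(x)
}

#' @rdname select_inheritance_model
#' @param x A `migselect_selection` object.
#' @param ... Unused.
#' @method tidy migselect_selection
#' @export
tidy.migselect_selection <- function(x, ...) x$fits

#' @rdname select_inheritance_model
#' @method glance migselect_selection
#' @export
glance.migselect_selection <- function(x, ...) x$selection
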