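test_that("closed-form MLEs match the pooled sample frequencies on the toy table", {
  toy <- toy1_counts()
  fits <- fit_all_models(toy)

  null <- fits[fits$model == "null", ]
  expect_equal(null$freq_with, 0.425)
  expect_equal(null$freq_ctrl, 0.425)

  sub <- fits[fits$model == "subset", ]
  expect_equal(sub$freq_with, 0.5)
  expect_equal(sub$freq_without, 0.4)
  expect_equal(sub$freq_ctrl, 0.4)

  gen <- fits[fits$model == "general", ]
  expect_equal(c(gen$freq_with, gen$freq_without, gen$freq_ctrl),
               c(0.5, 0.4, 0.4))
})

test_that("log-likelihoods at the closed-form MLEs match direct evaluation", {
  toy <- toy1_counts()
  fits <- fit_all_models(toy)

  ll_null <- oracle_loglik(toy$k_with + toy$k_without + toy$k_ctrl,
                           toy$n_with + toy$n_without + toy$n_ctrl, 0.425)
  ll_subset <- oracle_loglik(toy$k_with, toy$n_with, 0.5) +
    oracle_loglik(toy$k_without + toy$k_ctrl, toy$n_without + toy$n_ctrl, 0.4)

  expect_equal(fits$loglik[fits$model == "null"], ll_null, tolerance = 1e-10)
  expect_equal(fits$loglik[fits$model == "subset"], ll_subset, tolerance = 1e-10)
  # spot values: ~ -272.74 and -271.22 on this table
  expect_equal(fits$loglik[fits$model == "null"], -272.7418, tolerance = 1e-4)
  expect_equal(fits$loglik[fits$model == "subset"], -271.2182, tolerance = 1e-4)
  # p_without-hat equals p_ctrl-hat here, so general collapses onto subset
  expect_equal(fits$loglik[fits$model == "general"],
               fits$loglik[fits$model == "subset"], tolerance = 1e-10)
})

test_that("degrees of freedom and penalty formulas are consistent", {
  m <- inheritance_models()
  expect_equal(m$df[match(c("null", "basic", "subset", "inverse_subset",
                            "modifier", "general"), m$model)],
               c(1L, 2L, 2L, 2L, 2L, 3L))
  fits <- fit_all_models(toy1_counts())
  n_ind <- (100 + 100 + 200) / 2
  expect_equal(fits$aic, -2 * fits$loglik + 2 * fits$df)
  expect_equal(fits$bic, -2 * fits$loglik + fits$df * log(n_ind))
  # allele-count convention switch
  fits2 <- fit_all_models(toy1_counts(), bic_n = "alleles")
  expect_equal(fits2$bic, -2 * fits2$loglik + fits2$df * log(400))
})

test_that("identical group frequencies collapse every model onto the null", {
  cts <- list(k_with = 30, n_with = 100, k_without = 60, n_without = 200,
              k_ctrl = 90, n_ctrl = 300) # all sample freqs exactly 0.3
  fits <- fit_all_models(cts)
  expect_true(all(abs(fits$loglik - fits$loglik[1]) < 1e-8))
  expect_equal(fits$freq_with[fits$model == "modifier"], 0.3, tolerance = 1e-7)
  expect_equal(fits$freq_without[fits$model == "modifier"], 0.3, tolerance = 1e-7)
  for (crit in c("bic", "aic")) {
    sel <- glance(select_inheritance_model(cts, crit))
    expect_identical(sel$selected, "null")
    expect_equal(sel$llr_stat, 0)
    expect_equal(sel$llr_p_analytic, 1)
  }
})

test_that("modifier constraint is honoured and its fit is concave-optimal", {
  toy <- toy1_counts()
  fit <- fit_inheritance_model(toy, "modifier")
  w <- toy$n_with / (toy$n_with + toy$n_without)
  expect_equal(fit$freq_ctrl, w * fit$freq_with + (1 - w) * fit$freq_without,
               tolerance = 1e-9)
  # independent 2-D grid maximization of the constrained likelihood
  f <- function(pw, po) {
    q <- w * pw + (1 - w) * po
    oracle_loglik(toy$k_with, toy$n_with, pw) +
      oracle_loglik(toy$k_without, toy$n_without, po) +
      oracle_loglik(toy$k_ctrl, toy$n_ctrl, q)
  }
  grid <- oracle_grid_max2(f)
  expect_equal(fit$loglik, grid$value, tolerance = 1e-6)
  expect_equal(fit$freq_with, grid$par[1], tolerance = 1e-4)
  # equal-weight option changes the constraint
  fit_eq <- fit_inheritance_model(toy, "modifier", modifier_weight = "equal")
  expect_equal(fit_eq$freq_ctrl,
               0.5 * fit_eq$freq_with + 0.5 * fit_eq$freq_without,
               tolerance = 1e-9)
})

test_that("closed-form MLEs equal grid-search maxima on random tables", {
  tabs <- random_count_tables(20, seed = 71)
  for (i in seq_len(nrow(tabs))) {
    cts <- as.list(tabs[i, c("k_with", "n_with", "k_without", "n_without",
                             "k_ctrl", "n_ctrl")])
    fits <- fit_all_models(cts)
    # null: pooled frequency
    p_null <- oracle_grid_max1(function(p) {
      oracle_loglik(cts$k_with + cts$k_without + cts$k_ctrl,
                    cts$n_with + cts$n_without + cts$n_ctrl, p)
    })
    expect_equal(fits$freq_with[fits$model == "null"], p_null,
                 tolerance = 1e-6)
    # subset: the two parameters factorize into independent 1-D problems
    p_free <- oracle_grid_max1(function(p) oracle_loglik(cts$k_with, cts$n_with, p))
    p_shared <- oracle_grid_max1(function(p) {
      oracle_loglik(cts$k_without + cts$k_ctrl, cts$n_without + cts$n_ctrl, p)
    })
    expect_equal(fits$freq_with[fits$model == "subset"], p_free,
                 tolerance = 1e-6)
    expect_equal(fits$freq_ctrl[fits$model == "subset"], p_shared,
                 tolerance = 1e-6)
    # general: three independent 1-D problems
    expect_equal(fits$freq_ctrl[fits$model == "general"],
                 oracle_grid_max1(function(p) oracle_loglik(cts$k_ctrl, cts$n_ctrl, p)),
                 tolerance = 1e-6)
  }
})

test_that("log-likelihood nesting inequalities hold on random tables", {
  tabs <- random_count_tables(1000, seed = 72)
  fits <- purrr::map_dfr(seq_len(nrow(tabs)), function(i) {
    f <- fit_all_models(as.list(tabs[i, ]))
    tibble::tibble(
      null = f$loglik[f$model == "null"],
      basic = f$loglik[f$model == "basic"],
      subset = f$loglik[f$model == "subset"],
      inv = f$loglik[f$model == "inverse_subset"],
      modifier = f$loglik[f$model == "modifier"],
      general = f$loglik[f$model == "general"]
    )
  })
  tol <- 1e-8
  expect_true(all(fits$general >= fits$basic - tol))
  expect_true(all(fits$general >= fits$subset - tol))
  expect_true(all(fits$general >= fits$inv - tol))
  expect_true(all(fits$general >= fits$modifier - tol))
  expect_true(all(fits$general >= fits$null - tol))
  expect_true(all(fits$basic >= fits$null - tol))
  expect_true(all(fits$subset >= fits$null - tol))
  expect_true(all(fits$inv >= fits$null - tol))
  expect_true(all(fits$modifier >= fits$null - tol))
})

test_that("toy-table selection: BIC keeps the null, AIC prefers subset", {
  toy <- toy1_counts()
  fits <- fit_all_models(toy)
  # oracle: explicit enumeration of the penalized criteria
  expect_identical(fits$model[which.min(fits$bic)], "null")
  expect_identical(fits$model[which.min(fits$aic)], "subset")

  bic <- glance(select_inheritance_model(toy, "bic"))
  expect_identical(bic$selected, "null")
  aic <- glance(select_inheritance_model(toy, "aic"))
  expect_identical(aic$selected, "subset")
  expect_equal(aic$llr_stat, 3.05, tolerance = 0.005)
  expect_equal(aic$llr_df, 1L)
  expect_equal(aic$llr_p_analytic,
               pchisq(aic$llr_stat, 1, lower.tail = FALSE))
})

test_that("BIC-non-null implies AIC-non-null whenever n > 7 individuals", {
  tabs <- random_count_tables(300, seed = 73, max_m = 60)
  for (i in seq_len(nrow(tabs))) {
    cts <- as.list(tabs[i, ])
    n_ind <- (cts$n_with + cts$n_without + cts$n_ctrl) / 2
    if (n_ind <= 7) next
    bic_sel <- glance(select_inheritance_model(cts, "bic"))$selected
    if (bic_sel != "null") {
      aic_sel <- glance(select_inheritance_model(cts, "aic"))$selected
      expect_true(aic_sel != "null")
    }
  }
})

test_that("analytic LLR p-values follow the chi-square tail", {
  expect_equal(llr_pvalue(0, 1), 1)
  expect_equal(llr_pvalue(3.841, 1), 0.05, tolerance = 1e-3)
  expect_equal(llr_pvalue(4, 2), exp(-2), tolerance = 1e-12)
  expect_error(llr_pvalue(1, 0), "positive integer")
  expect_error(llr_pvalue(-1, 1), "non-negative")
})

test_that("forced general-vs-null analytic p is uniform under the null", {
  # calibration of the analytic reference at large group sizes
  counts <- simulate_trigroup_counts(600, 700, 2000, 0.3, 0.3, 0.3,
                                     n_reps = 5000, seed = 74)
  p <- purrr::map_dbl(seq_len(nrow(counts)), function(i) {
    cts <- as.list(counts[i, ])
    ll_gen <- fit_inheritance_model(cts, "general")$loglik
    ll_null <- fit_inheritance_model(cts, "null")$loglik
    llr_pvalue(max(2 * (ll_gen - ll_null), 1e-12), 2)
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("count validation rejects impossible tables", {
  expect_error(fit_all_models(list(k_with = 5, n_with = 4, k_without = 1,
                                   n_without = 2, k_ctrl = 1, n_ctrl = 2)),
               "exceeds")
  expect_error(fit_all_models(list(k_with = 0, n_with = 0, k_without = 0,
                                   n_without = 0, k_ctrl = 0, n_ctrl = 0)))
  expect_error(fit_all_models(list(k_with = 1, n_with = 2, k_without = 1,
                                   n_without = 2, k_ctrl = 0, n_ctrl = 0)),
               "empty group")
})
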