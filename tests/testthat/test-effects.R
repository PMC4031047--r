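test_that("coded allele follows the any-migraine enrichment sign rule", {
  # minor allele enriched among ever-migraineurs -> coded = minor
  status <- c(rep("active", 30), rep("former", 10), rep("never", 60))
  coh <- make_cohort(status, aura = c(rep(1L, 15), rep(0L, 15), rep(NA, 70)))
  set.seed(41)
  dose_cases <- rbinom(40, 2, 0.45)
  dose_ctrl <- rbinom(60, 2, 0.2)
  g <- make_geno(matrix(c(dose_cases, dose_ctrl), nrow = 1))
  ori <- choose_coded_allele(g, coh)
  expect_identical(ori$coded_allele, "minor")
  expect_identical(ori$coded_label, "A")
  expect_gt(ori$beta_any, 0)

  # minor allele depleted -> coded = major, and betas flip sign downstream
  g2 <- make_geno(matrix(c(2L - dose_cases, 2L - dose_ctrl), nrow = 1))
  ori2 <- choose_coded_allele(g2, coh)
  expect_identical(ori2$coded_allele, "major")
  expect_identical(ori2$coded_label, "G")
  eff1 <- stratum_effect(g, coh, "rs1", "aura", "with", orientation = ori)
  eff2 <- stratum_effect(g2, coh, "rs1", "aura", "with", orientation = ori2)
  expect_equal(eff1$beta, eff2$beta, tolerance = 1e-8)
  expect_equal(eff1$se, eff2$se, tolerance = 1e-8)

  # monomorphic SNP: orientation undefined
  g3 <- make_geno(matrix(0L, nrow = 1, ncol = 100))
  expect_error(choose_coded_allele(g3, coh), "monomorphic")
})

test_that("orientation makes the overall any-migraine beta non-negative", {
  sc <- small_scenario(
    dplyr::bind_rows(
      scenario_snp("rs_up", "basic", p_case = 0.35, p_ctrl = 0.28),
      scenario_snp("rs_down", "basic", p_case = 0.22, p_ctrl = 0.30),
      scenario_snp("rs_flat", "null", maf = 0.25)
    ),
    n_active = 400, n_former = 100, n_never = 900
  )
  dat <- simulate_cohort(sc, seed = 42)
  ori <- choose_coded_allele(dat$genotypes, dat$phenotypes)
  expect_true(all(ori$beta_any * ori$sign >= 0))
  expect_identical(ori$coded_allele[ori$snp_id == "rs_down"], "major")
})

test_that("stratified logistic fit recovers the generating log odds ratio", {
  # basic-model data at OR 1.2 per allele: control MAF 0.3, case frequency
  # chosen so the allelic odds ratio is exactly 1.2
  odds0 <- 0.3 / 0.7
  p_case <- 1.2 * odds0 / (1 + 1.2 * odds0)
  sc <- simulation_scenario(
    n_active = 3000, n_former = 0, n_never = 17000,
    snps = scenario_snp("rs1", "basic", p_case = p_case, p_ctrl = 0.3)
  )
  dat <- simulate_cohort(sc, seed = 43)
  eff <- stratum_effect(dat$genotypes, dat$phenotypes, "rs1", NULL, "overall")
  expect_true(eff$converged)
  expect_lt(abs(eff$beta - log(1.2)), 3 * eff$se)
  expect_equal(eff$n_cases, 3000)
  expect_equal(eff$n_controls, 17000)
})

test_that("null data give a null effect and strata partition the cases", {
  sc <- small_scenario(scenario_snp("rs1", "null", maf = 0.3),
                       n_active = 600, n_former = 100, n_never = 2000)
  dat <- simulate_cohort(sc, seed = 44)
  eff <- estimate_stratified_effects(dat$genotypes, dat$phenotypes)
  overall <- eff[eff$stratum == "overall", ]
  expect_lt(abs(overall$beta), 3 * overall$se + abs(overall$beta) * 0)
  # with + without case counts reconstruct the active case count, per cell
  by_char <- dplyr::summarise(
    dplyr::group_by(eff[eff$stratum != "overall", ], .data$characteristic),
    total = sum(.data$n_cases)
  )
  expect_true(all(by_char$total == overall$n_cases))
  expect_true(all(eff$n_controls == 2000))
})

test_that("mean stratified beta tracks the generating log odds across replicates", {
  # general-model data; allelic log odds-ratios implied by the frequencies
  pw <- 0.36; po <- 0.26; pc <- 0.30
  lor <- function(p1, p0) log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  sc <- simulation_scenario(
    n_active = 500, n_former = 0, n_never = 1500,
    snps = scenario_snp("rs1", "general", p_with = pw, p_without = po,
                        p_ctrl = pc)
  )
  # pin the orientation to the minor allele: the overall case and control
  # frequencies are nearly equal here, so the data-driven sign rule would
  # flip between replicates and shrink the mean toward zero by design
  ori <- tibble::tibble(snp_id = "rs1", beta_any = NA_real_,
                        coded_allele = "minor", coded_label = "A", sign = 1)
  reps <- purrr::map_dfr(1:100, function(r) {
    dat <- simulate_cohort(sc, seed = 4400 + r)
    eff <- estimate_stratified_effects(dat$genotypes, dat$phenotypes,
                                       characteristics = "aura",
                                       orientation = ori,
                                       include_overall = FALSE)
    tibble::tibble(stratum = eff$stratum, beta = eff$beta)
  })
  means <- tapply(reps$beta, reps$stratum, mean)
  mc_se <- tapply(reps$beta, reps$stratum, function(x) sd(x) / sqrt(length(x)))
  expect_lt(abs(means["with"] - lor(pw, pc)), 4 * mc_se["with"])
  expect_lt(abs(means["without"] - lor(po, pc)), 4 * mc_se["without"])
})

test_that("design guards and degenerate strata are reported", {
  status <- c(rep("active", 12), rep("never", 30))
  coh <- make_cohort(status, aura = c(rep(1L, 11), 0L, rep(NA, 30)))
  set.seed(45)
  g <- make_geno(matrix(rbinom(42, 2, 0.4), nrow = 1))
  # only one case without aura: below the guard
  expect_error(
    stratum_effect(g, coh, "rs1", "aura", "without"),
    "guard"
  )
  # a one-case stratum fits but may be flagged rather than silently NaN
  eff <- suppressWarnings(stratum_effect(g, coh, "rs1", "aura", "without",
                                         min_cases = 1))
  expect_s3_class(eff, "tbl_df")
  expect_true(is.logical(eff$converged))
})
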