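#' Define a synthetic cohort scenario
#'
#' Describes the cohort the simulator emulates: group sizes (defaults are
#' the reference cohort margins of 3,003 active, 2,119 former and 18,108
#' never migraineurs), the marginal prevalence of each characteristic among
#' active migraineurs ([default_characteristic_prevalences()]), an optional
#' exchangeable correlation among characteristics, and a SNP panel whose
#' per-group minor-allele frequencies follow one of the six inheritance
#' models (see [scenario_snp()]).
#'
#' @param n_active,n_former,n_never Group sizes.
#' @param prevalences Named vector of the ten characteristic prevalences in
#'   (0, 1).
#' @param rho Exchangeable correlation among the latent normals driving the
#'   characteristic indicators (default 0 = independent draws).
#' @param snps Tibble of SNP settings, usually built with [scenario_snp()];
#'   default is a single null SNP at MAF 0.3.
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @param covariates Include demographic covariates (age, BMI, smoking,
#'   diabetes) in the phenotype table for cohort-summary testing
#'   (default `TRUE`).
#' @return Object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_active = 3003, n_former = 2119,
                                n_never = 18108,
                                prevalences = default_characteristic_prevalences(),
                                rho = 0,
                                snps = scenario_snp("snp1", "null", maf = 0.3),
                                missing_rate = 0,
                                covariates = TRUE) {
  chars <- migraine_characteristics()
  if (!all(chars %in% names(prevalences))) {
    abort("prevalences must be named with all ten characteristics")
  }
  prevalences <- prevalences[chars]
  if (any(prevalences <= 0 | prevalences >= 1)) {
    abort("prevalences must lie strictly in (0, 1)")
  }
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must lie in [0, 1)")
  snps <- .validate_scenario_snps(as_tibble(snps))
  structure(
    list(n_active = n_active, n_former = n_former, n_never = n_never,
         prevalences = prevalences, rho = rho, snps = snps,
         missing_rate = missing_rate, covariates = covariates),
    class = "simulation_scenario"
  )
}

#' Specify one simulated SNP
#'
#' Builds a one-row SNP setting for [simulation_scenario()]. The three
#' per-group minor-allele frequencies must satisfy the generating model's
#' equality constraints exactly; convenience shortcuts fill them in:
#' for `"null"` give `maf` only; for `"basic"` give `p_case` and `p_ctrl`;
#' for `"subset"`/`"inverse_subset"` give the free frequency plus the shared
#' one; for `"modifier"` the control frequency is computed at simulation
#' time as the weighted mean of the realized case sub-group frequencies.
#'
#' @param snp_id SNP identifier.
#' @param model Generating model name, see [inheritance_models()].
#' @param characteristic The characteristic anchoring the grouping
#'   (default `"aura"`).
#' @param maf,p_case,p_with,p_without,p_ctrl Minor-allele frequencies in
#'   (0, 1), interpreted per model as above.
#' @return One-row tibble with columns `snp_id`, `model`, `characteristic`,
#'   `p_with`, `p_without`, `p_ctrl`.
#' @export
#' @examples
#' scenario_snp("rs_sub", "subset", p_with = 0.35, p_ctrl = 0.25)
scenario_snp <- function(snp_id, model, characteristic = "aura",
                         maf = NULL, p_case = NULL,
                         p_with = NULL, p_without = NULL, p_ctrl = NULL) {
  model <- match.arg(model, inheritance_models()$model)
  .check_characteristic(characteristic)
  pw <- p_with; po <- p_without; pc <- p_ctrl
  switch(model,
    null = {
      if (is.null(maf)) abort("null model: give `maf`")
      pw <- po <- pc <- maf
    },
    basic = {
      if (!is.null(p_case)) pw <- po <- p_case
      if (is.null(pw) || is.null(po) || is.null(pc)) {
        abort("basic model: give `p_case` (or p_with = p_without) and `p_ctrl`")
      }
    },
    subset = {
      if (is.null(pc) && !is.null(po)) pc <- po
      if (is.null(po) && !is.null(pc)) po <- pc
      if (is.null(pw) || is.null(po)) {
        abort("subset model: give `p_with` and the shared `p_ctrl`")
      }
    },
    inverse_subset = {
      if (is.null(pc) && !is.null(pw)) pc <- pw
      if (is.null(pw) && !is.null(pc)) pw <- pc
      if (is.null(po) || is.null(pw)) {
        abort("inverse_subset model: give `p_without` and the shared `p_ctrl`")
      }
    },
    modifier = {
      if (is.null(pw) || is.null(po)) {
        abort("modifier model: give `p_with` and `p_without`")
      }
      pc <- NA_real_ # realized weighted mean, set at simulation time
    },
    general = {
      if (is.null(pw) || is.null(po) || is.null(pc)) {
        abort("general model: give all three frequencies")
      }
    }
  )
  tibble(snp_id = snp_id, model = model, characteristic = characteristic,
         p_with = pw, p_without = po, p_ctrl = pc)
}

.validate_scenario_snps <- function(snps) {
  need <- c("snp_id", "model", "characteristic", "p_with", "p_without", "p_ctrl")
  miss <- setdiff(need, colnames(snps))
  if (length(miss)) abort(paste0("scenario snps missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(snps$snp_id)) abort("duplicated snp_id in scenario")
  for (i in seq_len(nrow(snps))) {
    m <- snps$model[i]
    p <- c(snps$p_with[i], snps$p_without[i], snps$p_ctrl[i])
    chk <- !is.na(p) & (p <= 0 | p >= 1)
    if (any(chk)) abort(paste0("frequencies must lie in (0,1): ", snps$snp_id[i]))
    ok <- switch(m,
      null = p[1] == p[2] && p[2] == p[3],
      basic = p[1] == p[2],
      subset = p[2] == p[3],
      inverse_subset = p[1] == p[3],
      modifier = is.na(p[3]),
      general = TRUE
    )
    if (!isTRUE(ok)) {
      abort(paste0("frequencies of ", snps$snp_id[i],
                   " violate the '", m, "' model constraints"))
    }
  }
  snps
}

#' Simulate the phenotype table
#'
#' Assigns migraine status by exact group sizes, then draws the ten binary
#' characteristics for each active migraineur at the scenario prevalences
#' (optionally with exchangeable correlation `rho` via a shared latent
#' normal). Former and never migraineurs carry no characteristic values.
#' Optional covariates (age, BMI, ever-smoking, diabetes) are drawn from
#' fixed marginal distributions for cohort-summary testing.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Optional integer seed.
#' @return A `migselect_cohort` tibble.
#' @export
simulate_phenotypes <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_active + scenario$n_former + scenario$n_never
  ids <- sprintf("I%06d", seq_len(n))
  status <- c(rep("active", scenario$n_active),
              rep("former", scenario$n_former),
              rep("never", scenario$n_never))
  df <- tibble(individual_id = ids, migraine_status = status)

  chars <- migraine_characteristics()
  na_col <- rep(NA_integer_, n)
  for (ch in chars) df[[ch]] <- na_col
  if (scenario$n_active > 0) {
    rho <- scenario$rho
    z_shared <- rnorm(scenario$n_active)
    for (ch in chars) {
      z <- sqrt(rho) * z_shared + sqrt(1 - rho) * rnorm(scenario$n_active)
      df[[ch]][seq_len(scenario$n_active)] <-
        as.integer(z < qnorm(scenario$prevalences[[ch]]))
    }
  }
  if (isTRUE(scenario$covariates)) {
    df$age <- round(rnorm(n, mean = 54, sd = 7), 1)
    df$bmi <- round(exp(rnorm(n, mean = log(25.5), sd = 0.17)), 1)
    df$ever_smoke <- rbinom(n, 1, 0.49)
    df$diabetes <- rbinom(n, 1, 0.026)
  }
  as_cohort(df)
}

#' Simulate genotypes for a cohort
#'
#' Draws each individual's minor-allele count as Binomial(2, p_g) —
#' Hardy-Weinberg within group — where p_g is the scenario frequency of the
#' individual's group under the SNP's anchoring characteristic. SNPs are
#' independent. For `modifier` SNPs the control frequency is set to the
#' weighted mean of the two case sub-group frequencies with weights equal
#' to the realized sub-group allele-total shares. Former migraineurs, who
#' belong to no analysis group for the ten characteristics, draw at the
#' prevalence-weighted mean of the case sub-group frequencies (matching the
#' empirical finding that former and active migraineurs carry similar
#' association); for the `"active_vs_former"` anchoring they are group (b).
#'
#' @param scenario A [simulation_scenario()].
#' @param cohort Phenotypes from [simulate_phenotypes()].
#' @param seed Optional integer seed.
#' @return A `migselect_geno` tibble.
#' @export
simulate_genotypes <- function(scenario, cohort, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  cohort <- as_tibble(cohort)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  snps <- scenario$snps
  dose <- matrix(NA_integer_, nrow(snps), n,
                 dimnames = list(snps$snp_id, cohort$individual_id))
  for (i in seq_len(nrow(snps))) {
    ch <- snps$characteristic[i]
    grp <- .assign_group(cohort, ch, case_universe = "active")
    p <- numeric(n)
    pw <- snps$p_with[i]; po <- snps$p_without[i]; pc <- snps$p_ctrl[i]
    if (snps$model[i] == "modifier") {
      mw <- sum(grp == "with", na.rm = TRUE)
      mo <- sum(grp == "without", na.rm = TRUE)
      w <- mw / (mw + mo)
      pc <- w * pw + (1 - w) * po
    }
    p[!is.na(grp) & grp == "with"] <- pw
    p[!is.na(grp) & grp == "without"] <- po
    p[!is.na(grp) & grp == "ctrl"] <- pc
    unassigned <- is.na(grp)
    if (any(unassigned)) {
      if (ch == .active_vs_former) {
        abort("individual not assignable to a group under active_vs_former")
      }
      # former migraineurs: prevalence-weighted mean of the case frequencies
      prev <- scenario$prevalences[[ch]]
      if (!all(cohort$migraine_status[unassigned] == "former")) {
        abort("individual not assignable to a simulation group")
      }
      p[unassigned] <- prev * pw + (1 - prev) * po
    }
    dose[i, ] <- rbinom(n, 2L, p)
    if (scenario$missing_rate > 0) {
      dose[i, runif(n) < scenario$missing_rate] <- NA_integer_
    }
  }
  alleles <- .synthetic_alleles(nrow(snps))
  new_genotypes(
    tibble(snp_id = snps$snp_id, chrom = "1",
           pos = seq_len(nrow(snps)) * 1000L,
           allele_minor = alleles$minor, allele_major = alleles$major),
    dose
  )
}

.synthetic_alleles <- function(n) {
  list(minor = rep("A", n), major = rep("G", n))
}

#' Simulate a full cohort (phenotypes + genotypes)
#'
#' @inheritParams simulate_phenotypes
#' @return List with elements `phenotypes` (a `migselect_cohort`) and
#'   `genotypes` (a `migselect_geno`); deterministic given `seed`.
#' @export
#' @examples
#' sc <- simulation_scenario(n_active = 60, n_former = 20, n_never = 120)
#' dat <- simulate_cohort(sc, seed = 7)
#' nrow(dat$phenotypes)
simulate_cohort <- function(scenario, seed = NULL) {
  seeds <- spawn_seeds(seed, 2)
  phen <- simulate_phenotypes(scenario, seed = seeds[1])
  geno <- simulate_genotypes(scenario, phen, seed = seeds[2])
  list(phenotypes = phen, genotypes = geno)
}

#' Simulate three-group allele counts directly
#'
#' Count-level shortcut used for calibration and model-recovery studies:
#' draws the sufficient statistics k_g ~ Binomial(n_g, p_g) for each group
#' (equivalent to summing Binomial(2, p_g) genotypes over the group's
#' individuals), skipping individual-level simulation entirely.
#'
#' @param m_with,m_without,m_ctrl Individual counts of the three groups.
#' @param p_with,p_without,p_ctrl Minor-allele frequencies.
#' @param n_reps Number of replicate count tables.
#' @param seed Optional integer seed.
#' @return Tibble with `n_reps` rows of `k_with`, `n_with`, `k_without`,
#'   `n_without`, `k_ctrl`, `n_ctrl`.
#' @export
simulate_trigroup_counts <- function(m_with, m_without, m_ctrl,
                                     p_with, p_without, p_ctrl,
                                     n_reps = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nw <- 2L * m_with; no <- 2L * m_without; nc <- 2L * m_ctrl
  tibble(
    k_with = rbinom(n_reps, nw, p_with), n_with = nw,
    k_without = rbinom(n_reps, no, p_without), n_without = no,
    k_ctrl = rbinom(n_reps, nc, p_ctrl), n_ctrl = nc
  )
}

#' Simulate selectivity vectors for a null SNP panel
#'
#' Generates `n_snps` SNPs with no migraine association (independent MAFs
#' uniform on `maf_range`) against the supplied cohort, estimates the
#' stratified effects, and returns the t-statistic vectors — the package's
#' stand-in for an external panel of non-associated SNPs when estimating
#' the null covariance.
#'
#' @param cohort A `migselect_cohort`.
#' @param n_snps Number of null SNPs (default 1222).
#' @param maf_range Range of simulated MAFs (default c(0.2, 0.4)).
#' @param seed Optional integer seed.
#' @return A `migselect_tstat` tibble.
#' @export
simulate_null_tstats <- function(cohort, n_snps = 1222,
                                 maf_range = c(0.2, 0.4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- as_tibble(cohort)
  n <- nrow(cohort)
  mafs <- runif(n_snps, maf_range[1], maf_range[2])
  dose <- matrix(rbinom(n_snps * n, 2L, rep(mafs, n)), nrow = n_snps,
                 dimnames = list(sprintf("null%04d", seq_len(n_snps)),
                                 cohort$individual_id))
  alleles <- .synthetic_alleles(n_snps)
  geno <- new_genotypes(
    tibble(snp_id = rownames(dose), chrom = "0",
           pos = seq_len(n_snps) * 1000L,
           allele_minor = alleles$minor, allele_major = alleles$major),
    dose
  )
  eff <- estimate_stratified_effects(geno, cohort, include_overall = FALSE)
  build_tstat_vectors(eff)
}
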