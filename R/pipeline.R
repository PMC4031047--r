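#' Assemble a pipeline run configuration
#'
#' Either `scenario` (a [simulation_scenario()]; the cohort is simulated
#' from `seed`) or `genotypes` + `phenotypes` (file paths) must be given.
#'
#' @param scenario Optional [simulation_scenario()].
#' @param genotypes,phenotypes Optional input file paths (VCF/TSV and
#'   phenotype TSV).
#' @param criteria Selection criteria to run (`"bic"`, `"aic"`, or both).
#' @param characteristics Characteristics to analyze.
#' @param n_permutations Permutation replicates per criterion.
#' @param n_null_snps Simulated null SNPs for the clustering covariance
#'   (default 1222).
#' @param linkage Clustering linkage.
#' @param alpha Significance level for starred cells.
#' @param seed Master seed for every random stage.
#' @param active_vs_former Also run the active-vs-former partition
#'   (default `TRUE`).
#' @param covariates Named type vector for [summarize_cohort()] (`NULL` for
#'   the default age/BMI/smoking/diabetes set when present).
#' @return List of class `migselect_config`.
#' @export
run_config <- function(scenario = NULL, genotypes = NULL, phenotypes = NULL,
                       criteria = c("bic", "aic"),
                       characteristics = migraine_characteristics(),
                       n_permutations = 1000,
                       n_null_snps = 1222,
                       linkage = "complete",
                       alpha = 0.05,
                       seed = 1,
                       active_vs_former = TRUE,
                       covariates = NULL) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (is.null(scenario) && (is.null(genotypes) || is.null(phenotypes))) {
    abort("give either `scenario` or both `genotypes` and `phenotypes`")
  }
  structure(
    list(scenario = scenario, genotypes = genotypes, phenotypes = phenotypes,
         criteria = criteria, characteristics = characteristics,
         n_permutations = n_permutations, n_null_snps = n_null_snps,
         linkage = linkage, alpha = alpha, seed = seed,
         active_vs_former = active_vs_former, covariates = covariates),
    class = "migselect_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Understands the keys of [run_config()] plus a `scenario:` block with
#' `n_active`, `n_former`, `n_never`, `rho`, `missing_rate`, optional
#' `prevalences:` (named map) and a `snps:` list whose entries hold
#' `snp_id`, `model`, `characteristic` and frequencies as in
#' [scenario_snp()]. Quote the null model name (`model: "null"`) so YAML
#' does not parse it as a missing value.
#'
#' @param path Path to a YAML file.
#' @return A `migselect_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(y$scenario)) {
    s <- y$scenario
    snps <- if (is.null(s$snps)) {
      scenario_snp("snp1", "null", maf = 0.3)
    } else {
      purrr::map_dfr(s$snps, function(e) {
        do.call(scenario_snp, e)
      })
    }
    prev <- default_characteristic_prevalences()
    if (!is.null(s$prevalences)) prev[names(s$prevalences)] <- unlist(s$prevalences)
    scenario <- simulation_scenario(
      n_active = s$n_active %||% 3003, n_former = s$n_former %||% 2119,
      n_never = s$n_never %||% 18108, prevalences = prev,
      rho = s$rho %||% 0, snps = snps,
      missing_rate = s$missing_rate %||% 0,
      covariates = s$covariates %||% TRUE
    )
  }
  run_config(
    scenario = scenario,
    genotypes = y$inputs$genotypes, phenotypes = y$inputs$phenotypes,
    criteria = unlist(y$criteria) %||% c("bic", "aic"),
    characteristics = unlist(y$characteristics) %||% migraine_characteristics(),
    n_permutations = y$permutations$count %||% 1000,
    n_null_snps = y$clustering$n_null_snps %||% 1222,
    linkage = y$clustering$linkage %||% "complete",
    alpha = y$alpha %||% 0.05,
    seed = y$permutations$seed %||% y$seed %||% 1,
    active_vs_former = y$active_vs_former %||% TRUE
  )
}

#' Run the full selective-association pipeline
#'
#' End-to-end orchestration: load or simulate the cohort; run model
#' selection per criterion; estimate permutation significance with the
#' two-stage correction; estimate stratified logistic effects with the
#' coded-allele rule; build selectivity t-vectors, estimate the null
#' covariance from simulated null SNPs, and cluster; run the
#' active-vs-former partition; and produce cohort summary tables. Every
#' random stage derives its seed from the master seed, so the bundle is a
#' pure function of (inputs, config, seed). When `out_dir` is given the
#' report tables are written as TSV (with a provenance header), the
#' dendrogram as Newick, and a JSON manifest; a failing stage aborts with a
#' stage-named error and removes partial outputs.
#'
#' @param config A `migselect_config` from [run_config()] or
#'   [read_run_config()].
#' @param out_dir Optional output directory.
#' @return List of class `migselect_report` with the tables described
#'   above.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "migselect_config"))
  seeds <- spawn_seeds(config$seed, 4 + length(config$criteria))

  dat <- .stage("load_data", {
    if (!is.null(config$scenario)) {
      simulate_cohort(config$scenario, seed = seeds[1])
    } else {
      list(genotypes = read_genotypes(config$genotypes),
           phenotypes = read_phenotypes(config$phenotypes))
    }
  })
  geno <- dat$genotypes; cohort <- dat$phenotypes

  selection <- .stage("model_selection", {
    analyze_selection(geno, cohort, characteristics = config$characteristics,
                      criteria = config$criteria)
  })

  permutation <- .stage("permutation_significance", {
    res <- list()
    for (i in seq_along(config$criteria)) {
      crit <- config$criteria[i]
      res[[crit]] <- permutation_significance(
        geno, cohort, characteristics = config$characteristics,
        n_permutations = config$n_permutations,
        seed = seeds[4 + i], criterion = crit
      )
    }
    res
  })

  model_matrix <- .stage("model_matrix", {
    res <- list()
    for (crit in config$criteria) {
      res[[crit]] <- selection_model_matrix(
        dplyr::filter(selection, .data$criterion == crit),
        perm = permutation[[crit]], alpha = config$alpha
      )
    }
    res
  })

  orientation <- .stage("coded_allele", choose_coded_allele(geno, cohort))
  effects <- .stage("stratified_effects", {
    estimate_stratified_effects(geno, cohort,
                                characteristics = config$characteristics,
                                orientation = orientation)
  })

  clustering <- .stage("selectivity_clustering", {
    tstats <- build_tstat_vectors(effects)
    null_t <- simulate_null_tstats(cohort, n_snps = config$n_null_snps,
                                   seed = seeds[2])
    sigma <- estimate_null_covariance(null_t)
    clust <- cluster_selectivity(tstats, sigma, linkage = config$linkage)
    list(tstats = tstats, sigma = sigma, clust = clust)
  })

  effects_matrix <- .stage("effects_matrix", {
    .cluster_ordered_effects(effects, clustering$clust$order)
  })

  avf <- NULL
  if (isTRUE(config$active_vs_former)) {
    avf <- .stage("active_vs_former", {
      analyze_selection(geno, cohort, characteristics = .active_vs_former,
                        criteria = config$criteria)
    })
  }

  summaries <- .stage("cohort_summary", {
    cov <- config$covariates
    if (is.null(cov)) {
      candidates <- c(age = "continuous", bmi = "continuous",
                      ever_smoke = "categorical", diabetes = "categorical")
      cov <- candidates[names(candidates) %in% colnames(cohort)]
    }
    list(
      demographics = if (length(cov)) summarize_cohort(cohort, cov) else NULL,
      characteristics = characteristic_table(cohort)
    )
  })

  report <- structure(list(
    selection = selection,
    model_matrix = model_matrix,
    permutation = permutation,
    orientation = orientation,
    effects = effects,
    tstats = clustering$tstats,
    null_covariance = clustering$sigma,
    clustering = clustering$clust,
    effects_matrix = effects_matrix,
    active_vs_former = avf,
    cohort_summary = summaries$demographics,
    characteristic_table = summaries$characteristics,
    manifest = list(
      package = "migselect",
      version = as.character(utils::packageVersion("migselect")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      n_permutations = config$n_permutations,
      criteria = config$criteria
    )
  ), class = "migselect_report")

  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

# effects in Figure-1 layout: SNP rows in cluster order, with/without beta
# columns per characteristic plus the overall column
.cluster_ordered_effects <- function(effects, order) {
  eff <- as_tibble(effects)
  eff$characteristic[is.na(eff$characteristic)] <- "actmig"
  wide <- tidyr::pivot_wider(
    eff[, c("snp_id", "characteristic", "stratum", "beta")],
    names_from = c("characteristic", "stratum"), values_from = "beta",
    names_sep = "."
  )
  wide[match(order, wide$snp_id), ]
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  hdr <- c(
    paste0("# migselect ", report$manifest$version),
    paste0("# seed=", report$manifest$seed,
           " config_hash=", report$manifest$config_hash)
  )
  emit <- function(tab, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    suppressMessages(readr::write_tsv(as_tibble(tab), path, append = TRUE,
                                      col_names = TRUE, progress = FALSE))
    written <<- c(written, path)
    path
  }
  tryCatch({
    for (crit in names(report$model_matrix)) {
      emit(report$model_matrix[[crit]], paste0("model_matrix_", crit, ".tsv"))
      emit(report$permutation[[crit]], paste0("permutation_", crit, ".tsv"))
      emit(dplyr::filter(report$selection, .data$criterion == crit),
           paste0("selection_", crit, ".tsv"))
    }
    emit(report$effects, "effects.tsv")
    emit(report$effects_matrix, "effects_matrix_clustered.tsv")
    emit(tibble(order = seq_along(report$clustering$order),
                snp_id = report$clustering$order), "cluster_order.tsv")
    nwk <- file.path(out_dir, "dendrogram.nwk")
    writeLines(report$clustering$newick, nwk)
    written <- c(written, nwk)
    if (!is.null(report$active_vs_former)) {
      emit(report$active_vs_former, "active_vs_former.tsv")
    }
    if (!is.null(report$cohort_summary)) {
      emit(report$cohort_summary, "cohort_summary.tsv")
    }
    emit(report$characteristic_table, "characteristics_summary.tsv")
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(report$manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    written <- c(written, manifest_path)
  }, error = function(e) {
    unlink(written)
    abort(paste0("pipeline stage 'write_report' failed: ", conditionMessage(e)))
  })
  invisible(out_dir)
}

#' @export
print.migselect_report <- function(x, ...) {
  cat("migselect report (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  criteria:", paste(x$manifest$criteria, collapse = ", "), "\n")
  cat("  SNPs:", length(unique(x$selection$snp_id)),
      "| permutations:", x$manifest$n_permutations, "\n")
  invisible(x)
}
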