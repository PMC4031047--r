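#' Reduce genotypes and phenotypes to three-group allele counts
#'
#' Collapses one SNP x characteristic combination to the sufficient
#' statistics of the likelihood framework: minor-allele counts and allele
#' totals among (a) cases with the characteristic, (b) cases without it,
#' and (c) non-cases. Individuals with a missing genotype at the SNP are
#' excluded from all three groups; former migraineurs are excluded from the
#' ten per-characteristic analyses (they are not sub-classified) but form
#' group (b) of the special `"active_vs_former"` partition, for which
#' group (a) is active migraineurs and (c) never-migraineurs.
#'
#' @param geno A `migselect_geno` tibble (see [read_genotypes()]).
#' @param cohort A `migselect_cohort` tibble (see [read_phenotypes()]).
#' @param snp_id SNP to tabulate.
#' @param characteristic One of [migraine_characteristics()] or
#'   `"active_vs_former"`.
#' @param case_universe `"active"` (default) restricts the case side to
#'   active migraineurs; `"ever"` also admits former migraineurs *if* they
#'   carry a non-missing value of the characteristic (in the standard cohort
#'   they do not, so both settings coincide).
#' @return One-row tibble with columns `snp_id`, `characteristic`, `k_with`,
#'   `n_with`, `k_without`, `n_without`, `k_ctrl`, `n_ctrl` and the retained
#'   individual counts `m_with`, `m_without`, `m_ctrl`; `n_*` are allele
#'   totals (twice the retained individuals).
#' @export
#' @examples
#' sc <- simulation_scenario(n_active = 40, n_former = 10, n_never = 60,
#'                           snps = scenario_snp("rs1", "null", maf = 0.3))
#' dat <- simulate_cohort(sc, seed = 1)
#' tabulate_trigroup(dat$genotypes, dat$phenotypes, "rs1", "aura")
tabulate_trigroup <- function(geno, cohort, snp_id, characteristic,
                              case_universe = c("active", "ever")) {
  case_universe <- match.arg(case_universe)
  .check_characteristic(characteristic)
  g <- dplyr::filter(as_tibble(geno), .data$snp_id == !!snp_id)
  if (nrow(g) == 0) abort(paste0("SNP not found: ", snp_id))
  dat <- dplyr::inner_join(g[, c("snp_id", "individual_id", "dose")],
                           as_tibble(cohort), by = "individual_id")
  dat <- dplyr::filter(dat, !is.na(.data$dose))
  grp <- .assign_group(dat, characteristic, case_universe)
  .counts_from_groups(dat$dose, grp, snp_id, characteristic)
}

# group assignment: returns factor with levels with/without/ctrl (NA = excluded)
.assign_group <- function(dat, characteristic, case_universe) {
  status <- dat$migraine_status
  if (characteristic == .active_vs_former) {
    grp <- dplyr::case_when(
      status == "active" ~ "with",
      status == "former" ~ "without",
      status == "never"  ~ "ctrl"
    )
  } else {
    case_status <- if (case_universe == "ever") c("active", "former") else "active"
    flag <- dat[[characteristic]]
    grp <- dplyr::case_when(
      status %in% case_status & !is.na(flag) & flag == 1 ~ "with",
      status %in% case_status & !is.na(flag) & flag == 0 ~ "without",
      status == "never" ~ "ctrl",
      TRUE ~ NA_character_
    )
  }
  factor(grp, levels = c("with", "without", "ctrl"))
}

.counts_from_groups <- function(dose, grp, snp_id, characteristic) {
  keep <- !is.na(grp)
  dose <- dose[keep]; grp <- grp[keep]
  m <- table(grp)
  if (any(m == 0)) {
    abort(paste0("degenerate design for SNP ", snp_id, " x ", characteristic,
                 ": empty group(s) ",
                 paste(names(m)[m == 0], collapse = ", "),
                 " after exclusions"))
  }
  k <- tapply(dose, grp, sum)
  tibble(
    snp_id = snp_id, characteristic = characteristic,
    k_with = unname(k["with"]), n_with = 2L * unname(m["with"]),
    k_without = unname(k["without"]), n_without = 2L * unname(m["without"]),
    k_ctrl = unname(k["ctrl"]), n_ctrl = 2L * unname(m["ctrl"]),
    m_with = unname(m["with"]), m_without = unname(m["without"]),
    m_ctrl = unname(m["ctrl"])
  )
}

# Fast path used by the drivers and the permutation engine: counts for every
# SNP x characteristic cell at once via two matrix products.
#
# Returns a tibble with one row per SNP x characteristic.
.tabulate_all <- function(dose, snp_ids, membership) {
  d0 <- dose; d0[is.na(d0)] <- 0L
  present <- !is.na(dose)
  K <- d0 %*% membership$Z        # minor-allele counts, snp x (3*nchar)
  M <- present %*% membership$Z   # retained individuals, snp x (3*nchar)
  nchar_ <- length(membership$characteristics)
  idx_w <- 3L * (seq_len(nchar_) - 1L) + 1L
  cells <- tidyr::expand_grid(snp_id = snp_ids,
                              characteristic = membership$characteristics)
  ord <- cbind(rep(seq_along(snp_ids), each = nchar_),
               rep(seq_len(nchar_), length(snp_ids)))
  cells$k_with    <- K[cbind(ord[, 1], idx_w[ord[, 2]])]
  cells$k_without <- K[cbind(ord[, 1], idx_w[ord[, 2]] + 1L)]
  cells$k_ctrl    <- K[cbind(ord[, 1], idx_w[ord[, 2]] + 2L)]
  cells$m_with    <- M[cbind(ord[, 1], idx_w[ord[, 2]])]
  cells$m_without <- M[cbind(ord[, 1], idx_w[ord[, 2]] + 1L)]
  cells$m_ctrl    <- M[cbind(ord[, 1], idx_w[ord[, 2]] + 2L)]
  cells$n_with <- 2L * cells$m_with
  cells$n_without <- 2L * cells$m_without
  cells$n_ctrl <- 2L * cells$m_ctrl
  if (any(cells$m_with == 0 | cells$m_without == 0 | cells$m_ctrl == 0)) {
    bad <- cells[cells$m_with == 0 | cells$m_without == 0 | cells$m_ctrl == 0, ]
    abort(paste0("degenerate design: empty group for ",
                 bad$snp_id[1], " x ", bad$characteristic[1]))
  }
  cells
}

# 0/1 membership matrix: individuals x (with, without, ctrl per characteristic)
.membership_matrix <- function(cohort, ids, characteristics,
                               case_universe = "active") {
  cohort <- as_tibble(cohort)[match(ids, cohort$individual_id), ]
  if (anyNA(cohort$individual_id)) {
    abort("genotyped individual(s) absent from the cohort table")
  }
  n <- length(ids)
  Z <- matrix(0L, n, 3L * length(characteristics))
  for (j in seq_along(characteristics)) {
    dat <- cohort
    grp <- .assign_group(dat, characteristics[j], case_universe)
    Z[, 3L * (j - 1L) + 1L] <- as.integer(!is.na(grp) & grp == "with")
    Z[, 3L * (j - 1L) + 2L] <- as.integer(!is.na(grp) & grp == "without")
    Z[, 3L * (j - 1L) + 3L] <- as.integer(!is.na(grp) & grp == "ctrl")
  }
  list(Z = Z, characteristics = characteristics)
}
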