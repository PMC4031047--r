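#' Read hard-call genotypes into the long dosage table
#'
#' Reads a panel of SNPs into the package's genotype representation: a long
#' tibble with one row per SNP x individual and a `dose` column counting
#' copies of the *minor* allele (0, 1, 2, or `NA` for a missing call).
#'
#' For VCF input the minor allele at each site is the allele with sample
#' frequency <= 0.5 across the whole file; an exact 0.5 tie is broken by
#' taking the alphabetically first allele as minor, so orientation is
#' deterministic. Only biallelic sites with hard GT calls are accepted.
#' For TSV input (header row of individual ids, one row per SNP, first
#' column the SNP id) values are taken verbatim as minor-allele dosages;
#' allele labels are unknown and left `NA`.
#'
#' @param path Path to a VCF (4.x, GT field) or genotype TSV file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return A tibble of class `migselect_geno` with columns `snp_id`,
#'   `chrom`, `pos`, `allele_minor`, `allele_major`, `individual_id`,
#'   `dose`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  switch(format,
    vcf = .read_genotypes_vcf(path),
    tsv = .read_genotypes_tsv(path)
  )
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    site <- paste0(fix$CHROM[multi][1], ":", fix$POS[multi][1],
                   " (", fix$ID[multi][1], ")")
    abort(paste0("multi-allelic site not supported: ", site))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT genotype field")
  gt <- matrix(as.character(gt), nrow = nrow(fix),
               dimnames = list(NULL, colnames(gt)))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) abort("duplicated SNP ids in VCF")

  parse_gt <- function(x, site) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(sub(":.*$", "", x), "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    if (!all(al %in% c("0", "1"))) {
      abort(paste0("multi-allelic genotype call at site ", site, ": GT=", x))
    }
    sum(al == "1")
  }
  alt_dose <- matrix(NA_integer_, nrow(gt), ncol(gt),
                     dimnames = list(ids, colnames(gt)))
  for (i in seq_len(nrow(gt))) {
    site <- paste0(fix$CHROM[i], ":", fix$POS[i])
    alt_dose[i, ] <- vapply(gt[i, ], parse_gt, integer(1), site = site)
  }

  snps <- tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  # orient to the minor allele; ties at 0.5 go to the alphabetically first allele
  dose <- alt_dose
  minor <- character(nrow(snps)); major <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    x <- alt_dose[i, ]
    af <- sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
    alt_is_minor <- if (af < 0.5) TRUE
      else if (af > 0.5) FALSE
      else snps$alt[i] <= snps$ref[i]
    if (alt_is_minor) {
      minor[i] <- snps$alt[i]; major[i] <- snps$ref[i]
    } else {
      minor[i] <- snps$ref[i]; major[i] <- snps$alt[i]
      dose[i, ] <- 2L - x
    }
  }
  new_genotypes(
    tibble(snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
           allele_minor = minor, allele_major = major),
    dose
  )
}

.read_genotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(tab) < 2) abort("genotype TSV needs a SNP id column plus >= 1 individual")
  snp_id <- tab[[1]]
  if (anyDuplicated(snp_id)) abort("duplicated SNP ids in genotype TSV")
  ind <- colnames(tab)[-1]
  if (anyDuplicated(ind)) abort("duplicated individual ids in genotype TSV")
  raw <- as.matrix(tab[, -1, drop = FALSE])
  malformed <- !is.na(raw) & !raw %in% c("0", "1", "2", "NA", ".")
  if (any(malformed)) {
    ij <- which(malformed, arr.ind = TRUE)[1, ]
    abort(sprintf("malformed genotype value '%s' at SNP row %d (%s), column %s",
                  raw[ij[1], ij[2]], ij[1], snp_id[ij[1]], ind[ij[2]]))
  }
  raw[raw %in% c("NA", ".")] <- NA_character_
  dose <- matrix(as.integer(raw), nrow(raw), ncol(raw))
  bad <- which(!is.na(dose) & !dose %in% 0:2, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("genotype TSV value out of {0,1,2,NA} at SNP row %d (%s), column %s",
                  bad[1, 1], snp_id[bad[1, 1]], ind[bad[1, 2]]))
  }
  dimnames(dose) <- list(snp_id, ind)
  new_genotypes(
    tibble(snp_id = snp_id, chrom = NA_character_, pos = NA_integer_,
           allele_minor = NA_character_, allele_major = NA_character_),
    dose
  )
}

#' Construct the long genotype table from SNP metadata and a dosage matrix
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`, `allele_minor`,
#'   `allele_major` (one row per SNP, same order as the matrix rows).
#' @param dose Integer matrix, SNPs x individuals, entries in \{0,1,2,NA\};
#'   column names are the individual ids.
#' @return Long tibble of class `migselect_geno`.
#' @export
new_genotypes <- function(snps, dose) {
  stopifnot(nrow(snps) == nrow(dose))
  if (is.null(colnames(dose))) abort("dose matrix needs individual ids as colnames")
  if (anyDuplicated(colnames(dose))) abort("duplicated individual ids")
  if (anyDuplicated(snps$snp_id)) abort("duplicated SNP ids")
  bad <- !is.na(dose) & !(dose %in% 0:2)
  if (any(bad)) abort("dosage values must be in {0, 1, 2, NA}")
  nonmissing_alleles <- snps$allele_minor[!is.na(snps$allele_minor) &
                                          !is.na(snps$allele_major)]
  if (length(nonmissing_alleles)) {
    same <- snps$allele_minor == snps$allele_major
    if (any(same, na.rm = TRUE)) abort("allele_minor must differ from allele_major")
  }
  if (any(!is.na(snps$pos) & snps$pos <= 0)) abort("positions must be positive")
  out <- tidyr::expand_grid(
    snps[, c("snp_id", "chrom", "pos", "allele_minor", "allele_major")],
    individual_id = colnames(dose)
  )
  # expand_grid is SNP-major, matching the column-major flattening of t(dose)
  out$dose <- as.integer(t(dose))
  class(out) <- c("migselect_geno", class(out))
  out
}

# long tibble -> list(dose matrix [snp x ind], snps tibble, ids)
.geno_matrix <- function(geno) {
  snps <- dplyr::distinct(as_tibble(geno)[, c("snp_id", "chrom", "pos",
                                              "allele_minor", "allele_major")])
  ids <- unique(geno$individual_id)
  dose <- matrix(NA_integer_, nrow(snps), length(ids),
                 dimnames = list(snps$snp_id, ids))
  dose[cbind(match(geno$snp_id, snps$snp_id),
             match(geno$individual_id, ids))] <- geno$dose
  list(dose = dose, snps = snps, ids = ids)
}

#' Write the genotype TSV dialect
#'
#' One row per SNP, first column `snp_id`, remaining columns one per
#' individual holding minor-allele dosages; the exact dialect
#' [read_genotypes()] reads back.
#'
#' @param geno A `migselect_geno` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  gm <- .geno_matrix(geno)
  tab <- as_tibble(gm$dose, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble(snp_id = gm$snps$snp_id), tab)
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  invisible(path)
}
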