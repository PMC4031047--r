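# programmatic fixtures: tiny cohorts, genotype tables and text VCFs

# cohort with explicit status / aura vectors; other characteristics filled
# with zeroes for active rows
make_cohort <- function(status, aura = NULL) {
  n <- length(status)
  df <- tibble::tibble(
    individual_id = sprintf("P%03d", seq_len(n)),
    migraine_status = status
  )
  for (ch in migraine_characteristics()) {
    df[[ch]] <- ifelse(status == "active", 0L, NA_integer_)
  }
  if (!is.null(aura)) df$aura <- ifelse(status == "active", aura, NA_integer_)
  as_cohort(df)
}

make_geno <- function(dose_matrix, snp_ids = NULL, ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%d", seq_len(nrow(dose_matrix)))
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(ncol(dose_matrix)))
  colnames(dose_matrix) <- ids
  new_genotypes(
    tibble::tibble(snp_id = snp_ids, chrom = "1",
                   pos = seq_along(snp_ids) * 100L,
                   allele_minor = "A", allele_major = "G"),
    dose_matrix
  )
}

# minimal VCF 4.2 text file; gts is a matrix of GT strings (snps x samples)
write_test_vcf <- function(path, chrom, pos, id, ref, alt, gts,
                           samples = sprintf("S%02d", seq_len(ncol(gts)))) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# a small balanced cohort scenario used in several tests
small_scenario <- function(snps, n_active = 300, n_former = 60,
                           n_never = 900, ...) {
  simulation_scenario(n_active = n_active, n_former = n_former,
                      n_never = n_never, snps = snps, ...)
}
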