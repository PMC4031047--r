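#' Read and validate the phenotype table
#'
#' Expects a TSV with columns `individual_id`, `migraine_status`
#' (`never`/`former`/`active`), the ten characteristic columns
#' (`aura`, `pulsation`, `unipain`, `sound`, `light`, `longdur`, `nausea`,
#' `aggrphys`, `inhibit`, `freq`), and any further columns treated as
#' covariates. Characteristic values must be strictly binary and non-missing
#' for every `active` row; they are ignored (set to `NA`) for `never` and
#' `former` rows, since only active migraineurs are sub-classified.
#'
#' @param path Path to a phenotype TSV.
#' @return A validated cohort tibble of class `migselect_cohort`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    migraine_status = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  as_cohort(tab)
}

#' Validate an in-memory cohort table
#'
#' Applies the same checks as [read_phenotypes()]: unique individual ids,
#' known status labels, characteristic flags binary and complete for active
#' rows and blanked for others.
#'
#' @param df Data frame with at least `individual_id` and `migraine_status`.
#' @return Tibble of class `migselect_cohort`.
#' @export
as_cohort <- function(df) {
  df <- as_tibble(df)
  req <- c("individual_id", "migraine_status")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) abort(paste0("missing required column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$individual_id)) {
    dup <- df$individual_id[duplicated(df$individual_id)][1]
    abort(paste0("duplicated individual_id: ", dup))
  }
  bad_status <- setdiff(unique(df$migraine_status), c("never", "former", "active"))
  if (length(bad_status)) {
    abort(paste0("unknown migraine_status label(s): ",
                 paste(bad_status, collapse = ", ")))
  }
  chars <- migraine_characteristics()
  active <- df$migraine_status == "active"
  if (any(active)) {
    miss_col <- setdiff(chars, colnames(df))
    if (length(miss_col)) {
      abort(paste0("active rows present but characteristic column(s) missing: ",
                   paste(miss_col, collapse = ", ")))
    }
    for (ch in chars) {
      v <- df[[ch]][active]
      if (anyNA(v)) {
        row <- df$individual_id[active][which(is.na(v))[1]]
        abort(paste0("active individual ", row, " has missing value for '", ch, "'"))
      }
      if (!all(v %in% c(0, 1))) {
        row <- df$individual_id[active][which(!v %in% c(0, 1))[1]]
        abort(paste0("non-binary value of '", ch, "' for active individual ", row))
      }
      df[[ch]] <- as.integer(df[[ch]])
    }
  }
  # characteristics are defined only for active migraineurs
  for (ch in intersect(chars, colnames(df))) {
    df[[ch]][df$migraine_status != "active"] <- NA_integer_
  }
  class(df) <- c("migselect_cohort", setdiff(class(df), "migselect_cohort"))
  df
}

#' Write the phenotype TSV dialect
#'
#' @param cohort A `migselect_cohort` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_tsv <- function(cohort, path) {
  readr::write_tsv(as_tibble(cohort), path, na = "NA", progress = FALSE)
  invisible(path)
}
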