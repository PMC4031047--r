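#' Migraine characteristic vocabulary
#'
#' The ten binary attack features used to sub-classify active migraineurs,
#' in the column order of the phenotype TSV dialect: aura, pulsating pain,
#' unilateral pain, phonophobia (`sound`), photophobia (`light`), duration of
#' 4-72 hours (`longdur`), nausea, aggravation by physical activity
#' (`aggrphys`), inhibition of daily activities (`inhibit`), and attack
#' frequency >= 6/year (`freq`).
#'
#' @return Character vector of the ten characteristic names.
#' @export
#' @examples
#' migraine_characteristics()
migraine_characteristics <- function() {
  c("aura", "pulsation", "unipain", "sound", "light",
    "longdur", "nausea", "aggrphys", "inhibit", "freq")
}

#' Default characteristic prevalences among active migraineurs
#'
#' Fractions of active migraineurs reporting each characteristic, taken from
#' the reference cohort of 3,003 active migraineurs (e.g. 1,177 with aura,
#' 1,976 with photophobia, 2,348 with attacks lasting 4-72 h). These are the
#' default marginal prevalences of the synthetic cohort generator.
#'
#' @return Named numeric vector of length 10, values in (0, 1).
#' @export
#' @examples
#' round(default_characteristic_prevalences(), 2)
default_characteristic_prevalences <- function() {
  counts <- c(
    aura = 1177, pulsation = 1591, unipain = 1791, sound = 1232,
    light = 1976, longdur = 2348, nausea = 1958, aggrphys = 1017,
    inhibit = 1499, freq = 1050
  )
  counts / 3003
}

# special partition label accepted wherever a characteristic is expected
.active_vs_former <- "active_vs_former"

.check_characteristic <- function(characteristic, allow_partition = TRUE) {
  ok <- migraine_characteristics()
  if (allow_partition) ok <- c(ok, .active_vs_former)
  if (!is.character(characteristic) || length(characteristic) != 1 ||
      !characteristic %in% ok) {
    abort(paste0(
      "`characteristic` must be one of: ", paste(ok, collapse = ", ")
    ))
  }
  invisible(characteristic)
}
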