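#' Packaged fishery-audit reference tables
#'
#' Small published summary tables from the 2018-2019 British Columbia
#' Chinook salmon genetics-based assessment program, shipped as plain-text
#' data and used by the worked examples and validation checks:
#'
#' * `chinook_er_totals()` --- 2019 Canadian marine fishery catch and
#'   escapement totals per population, estimated via CWTs (estimated-tag
#'   scale) and via GSI+PBT (fish), for the 13 populations where both
#'   methods were available.
#' * `sog_age_distribution()` --- counts of PBT-identified Chinook salmon
#'   by age and size class (legal/sublegal at the 62-cm limit) in the
#'   Strait of Georgia recreational fisheries, by region.
#' * `cwt_pbt_age_audit()` --- cross-tabulation of CWT-decoded age against
#'   PBT-assigned age for coded-wire-tagged fish from five hatchery
#'   populations (the PBT age-accuracy audit).
#'
#' @return a tibble (see the individual descriptions).
#' @name reference_tables
NULL

ref_table <- function(file) {
  path <- system.file("extdata", file, package = "pbtgsi", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' @rdname reference_tables
#' @export
chinook_er_totals <- function() ref_table("chinook_2019_er_totals.tsv")

#' @rdname reference_tables
#' @export
sog_age_distribution <- function() ref_table("sog_age_distribution.tsv")

#' @rdname reference_tables
#' @export
cwt_pbt_age_audit <- function() ref_table("cwt_pbt_age_audit.tsv")
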