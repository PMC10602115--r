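VALID_STATUS <- c("wild", "uncertain", "cultivated", "breeding_material", "unknown")

# a record's stated origin is usable for geographic summaries only when it
# names a present-day country and the collection site is not a garden or
# institute (material passed through such sites was typically collected
# elsewhere, with the natural origin unrecorded)
passport_reliable <- function(country, site) {
  has_country <- !is.na(country) & country != ""
  former_bloc <- grepl("^former ", country, ignore.case = TRUE)
  garden <- !is.na(site) & grepl("garden|institute|botanic", site, ignore.case = TRUE)
  has_country & !former_bloc & !garden
}

#' Read accession passport records
#'
#' Loads a passport TSV (accession id, PI number, origin country, collection
#' site, elevation, cultivation status, cultivar name, acquisition mode and
#' year), validates the categorical fields, and derives the
#' `location_reliable` flag: a record is location-reliable iff it carries an
#' origin country, the country is a present-day state (not a "Former ..."
#' label), and the collection site is not a garden or institute.
#'
#' @param path passport TSV.
#' @return Data frame of passport records with `location_reliable` added.
#' @export
read_passports <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "origin_country", "status")
  if (!all(need %in% names(df)))
    stop("passport table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$status[is.na(df$status) | df$status == ""] <- "unknown"
  bad <- setdiff(unique(df$status), VALID_STATUS)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!"collection_site" %in% names(df)) df$collection_site <- NA_character_
  if (!"acquisition_mode" %in% names(df)) df$acquisition_mode <- "unknown"
  if (!"acquisition_year" %in% names(df)) df$acquisition_year <- NA_integer_
  if ("elevation_m" %in% names(df)) {
    bad_elev <- !is.na(df$elevation_m) & (df$elevation_m < -500 | df$elevation_m > 6000)
    if (any(bad_elev)) stop("implausible elevation for: ",
                            paste(df$accession_id[bad_elev], collapse = ", "),
                            call. = FALSE)
  }
  df$location_reliable <- passport_reliable(df$origin_country, df$collection_site)
  df
}

#' Geographic origin summary
#'
#' Counts accessions per origin country over location-reliable passport
#' records; accessions with unreliable or missing records are tallied
#' separately, so country counts plus the unreliable count equal the size of
#' the requested set.
#'
#' @param records passport data frame from [read_passports()].
#' @param accessions accession ids to summarise (default: all records).
#' @return List with `countries` (named counts, descending) and
#'   `n_unreliable`.
#' @export
origin_summary <- function(records, accessions = NULL) {
  accessions <- accessions %||% records$accession_id
  idx <- match(accessions, records$accession_id)
  reliable <- !is.na(idx) & records$location_reliable[idx]
  country <- records$origin_country[idx][reliable]
  tab <- table(country)
  if (length(tab)) tab <- tab[order(-as.integer(tab), names(tab))]
  list(countries = stats::setNames(as.integer(tab), names(tab)),
       n_unreliable = sum(!reliable))
}

#' Cultivation-status summary
#'
#' Counts accessions per cultivation status (wild / uncertain / cultivated /
#' breeding material / unknown) and reports how many carry an NPGS PI
#' number.
#'
#' @inheritParams origin_summary
#' @return List with `status` (named counts) and `n_with_pi`.
#' @export
status_summary <- function(records, accessions = NULL) {
  accessions <- accessions %||% records$accession_id
  idx <- match(accessions, records$accession_id)
  status <- ifelse(is.na(idx), "unknown", records$status[idx])
  has_pi <- !is.na(idx) & "pi_number" %in% names(records) &
    !is.na(records$pi_number[idx]) & records$pi_number[idx] != ""
  tab <- table(factor(status, levels = VALID_STATUS))
  list(status = stats::setNames(as.integer(tab), names(tab)),
       n_with_pi = sum(has_pi))
}
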