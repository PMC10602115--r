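#' Germplasm availability filter
#'
#' Restricts candidate founder accessions to those that would have been
#' obtainable from the genebank before a breeding program started:
#' accessions *collected* ex situ strictly after `cutoff_year` are excluded;
#' donated accessions are exempt, and accessions with an unknown acquisition
#' year are retained (exclusion requires positive evidence), with a message
#' noting how many were kept on that basis.
#'
#' @param passports passport data frame (see [read_passports()]) with
#'   `accession_id`, `acquisition_mode`, `acquisition_year`.
#' @param cutoff_year last availability year (default 1990).
#' @return Character vector of retained accession ids.
#' @export
availability_filter <- function(passports, cutoff_year = 1990) {
  stopifnot(all(c("accession_id", "acquisition_mode", "acquisition_year")
                %in% names(passports)))
  mode <- passports$acquisition_mode
  year <- passports$acquisition_year
  excluded <- !is.na(year) & mode == "collected" & year > cutoff_year
  unknown_kept <- sum(is.na(year) & mode == "collected")
  if (unknown_kept > 0)
    message(unknown_kept, " collected accession(s) with unknown year retained")
  passports$accession_id[!excluded]
}

#' Count founder assignments and extract the top-k founder set
#'
#' Tallies best-accession assignments (optionally restricted to an allowed
#' accession set), orders accessions by descending count (ties by id), and
#' reports the top-k founder set together with the fraction of queries it
#' covers and the accessions with at most `singleton_threshold` assignments.
#'
#' @param assignments data frame from [assign_genets()].
#' @param k size of the founder set (default 20; all hit accessions if
#'   fewer). Ties at rank k are all included and noted.
#' @param allowed optional vector of allowed accession ids. Assignments
#'   whose best accession is outside the set are re-assigned to their
#'   second-ranked accession when that is allowed (`outside = "reassign"`,
#'   the default, mirroring restriction of the candidate pool) or dropped
#'   (`outside = "discard"`); queries with neither accession allowed are
#'   dropped either way. For exact handling, restrict the reference
#'   profiles before calling [assign_genets()].
#' @param singleton_threshold count at or below which an accession is
#'   reported as a minor (singleton-like) founder (default 10).
#' @param outside policy for best accessions outside `allowed`.
#' @return A `founder_report`: list with `counts` (named, sorted),
#'   `total_queries`, `top_k_set`, `top_k_fraction`, `n_accessions_hit`,
#'   `singletons`, `n_dropped`.
#' @export
count_founders <- function(assignments, k = 20, allowed = NULL,
                           singleton_threshold = 10,
                           outside = c("reassign", "discard")) {
  outside <- match.arg(outside)
  if (nrow(assignments) == 0L) stop("empty assignment list", call. = FALSE)
  best <- assignments$best_accession
  ok <- !is.na(best)
  n_dropped <- 0L
  if (!is.null(allowed)) {
    out_best <- ok & !(best %in% allowed)
    if (outside == "reassign") {
      second_ok <- assignments$second_accession %in% allowed
      best[out_best & second_ok] <- assignments$second_accession[out_best & second_ok]
      drop <- out_best & !second_ok
    } else drop <- out_best
    n_dropped <- sum(drop)
    ok <- ok & !drop
  }
  best <- best[ok]
  if (length(best) == 0L) stop("no assignments left after filtering", call. = FALSE)
  tab <- table(best)
  counts <- sort(tab, decreasing = TRUE)
  # stable ordering: descending count then accession id
  counts <- tab[order(-as.integer(tab), names(tab))]
  counts <- stats::setNames(as.integer(counts), names(counts))
  k_eff <- min(k, length(counts))
  cut <- counts[k_eff]
  top <- names(counts)[counts > cut]
  tied <- names(counts)[counts == cut]
  overflow <- length(top) + length(tied) - k_eff
  top_k_set <- c(top, tied)
  if (overflow > 0 && length(counts) > k_eff)
    message("count tie at rank ", k_eff, ": founder set extended by ",
            overflow, " accession(s)")
  structure(list(counts = counts,
                 total_queries = length(best),
                 top_k_set = top_k_set,
                 top_k_fraction = sum(counts[top_k_set]) / length(best),
                 n_accessions_hit = length(counts),
                 singletons = names(counts)[counts <= singleton_threshold],
                 n_dropped = n_dropped),
            class = "founder_report")
}

#' @export
print.founder_report <- function(x, ...) {
  cat(sprintf("founder_report: %d queries over %d accessions; top-%d set covers %.1f%%\n",
              x$total_queries, x$n_accessions_hit, length(x$top_k_set),
              100 * x$top_k_fraction))
  cat("top founders:", paste(utils::head(x$top_k_set, 10), collapse = ", "),
      if (length(x$top_k_set) > 10) "..." else "", "\n")
  invisible(x)
}

#' Cross-source (Venn) intersection of founder sets
#'
#' Given two or more named accession sets (e.g. the historical Polycross-1
#' reconstruction and the molecularly inferred founder sets from different
#' germplasm pools), computes every Venn-region cardinality and membership,
#' plus the union and all pairwise intersections.
#'
#' @param sources named list (length >= 2) of character vectors.
#' @return List with `regions` (data frame: region signature, count,
#'   members), `union`, `pairwise` (matrix of intersection sizes), and
#'   `all_sources` (members present in every set).
#' @export
intersect_sources <- function(sources) {
  if (!is.list(sources) || length(sources) < 2L || is.null(names(sources)))
    stop("sources must be a named list of at least 2 sets", call. = FALSE)
  sources <- lapply(sources, unique)
  all_ids <- sort(unique(unlist(sources)))
  member <- vapply(sources, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sources)))
  sig <- apply(member, 1, function(r) paste(names(sources)[r], collapse = "&"))
  regions <- data.frame(region = sort(unique(sig)), stringsAsFactors = FALSE)
  regions$count <- vapply(regions$region, function(s) sum(sig == s), integer(1))
  regions$members <- vapply(regions$region, function(s)
    paste(all_ids[sig == s], collapse = ";"), character(1))
  npair <- length(sources)
  pairwise <- matrix(0L, npair, npair, dimnames = list(names(sources), names(sources)))
  for (i in seq_len(npair)) for (j in seq_len(npair))
    pairwise[i, j] <- length(intersect(sources[[i]], sources[[j]]))
  list(regions = regions,
       union = all_ids,
       pairwise = pairwise,
       all_sources = all_ids[rowSums(member) == length(sources)])
}
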