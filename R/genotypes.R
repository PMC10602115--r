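#' Depth-gated genotype calling
#'
#' Converts raw per-cell allele depths into dosage calls with the rules used
#' for composite-profile GBS data: a heterozygote is called as soon as at
#' least one read of each allele is observed ("two contrasting reads"); a
#' homozygote requires at least `min_hom_depth` reads of a single allele
#' with zero reads of the other; anything else is set to missing. The
#' heterozygote rule takes precedence when both alleles are observed, so
#' e.g. (ref = 4, alt = 1) is called heterozygous.
#'
#' @param depths a [depth_matrix()].
#' @param min_hom_depth minimum identical reads to call a homozygote
#'   (default 4).
#' @return A [dosage_matrix()] of the same shape.
#' @export
call_from_depths <- function(depths, min_hom_depth = 4L) {
  stopifnot(inherits(depths, "depth_matrix"))
  min_hom_depth <- check_count(min_hom_depth, "min_hom_depth")
  ref <- depths$ref; alt <- depths$alt
  if (min(ref) < 0 || min(alt) < 0)
    stop("negative read counts", call. = FALSE)
  dos <- matrix(NA_integer_, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  het <- ref >= 1L & alt >= 1L
  hom_ref <- !het & alt == 0L & ref >= min_hom_depth
  hom_alt <- !het & ref == 0L & alt >= min_hom_depth
  dos[het] <- 1L
  dos[hom_ref] <- 0L
  dos[hom_alt] <- 2L
  dosage_matrix(dos)
}

new_filter_report <- function(stage, n_in, n_out, removed_by) {
  structure(list(stage = stage, n_in = n_in, n_out = n_out,
                 removed_by = removed_by), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s]: %d -> %d\n", x$stage, x$n_in, x$n_out))
  for (nm in names(x$removed_by))
    cat(sprintf("  removed by %s: %d\n", nm, x$removed_by[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(stage = x$stage,
             rule = c("input", names(x$removed_by), "output"),
             count = c(x$n_in, unlist(x$removed_by), x$n_out),
             row.names = NULL)
}

folded_maf <- function(dos) {
  f <- colMeans(dos, na.rm = TRUE) / 2
  pmin(f, 1 - f, na.rm = FALSE)
}

#' Marker filtering
#'
#' Keeps loci that are flagged strictly biallelic, have folded minor allele
#' frequency strictly greater than `maf_min` (computed over non-missing
#' calls), and are called in at least `call_rate_min` of the genets. A locus
#' failing several rules is tallied under the first failed rule in the order
#' non-biallelic, MAF, call rate, so the per-rule tallies sum to the number
#' removed.
#'
#' @param dosages a [dosage_matrix()].
#' @param maf_min exclusive lower bound on folded MAF (default 0.05).
#' @param call_rate_min inclusive lower bound on the fraction of genets with
#'   a call (default 0.30, i.e. up to 70 percent missing).
#' @param biallelic logical vector per locus; loci flagged `FALSE` are
#'   removed (default all `TRUE`, as simulated data are biallelic by
#'   construction).
#' @return List with the filtered `dosage` and a `filter_report` under
#'   `report`.
#' @export
filter_loci <- function(dosages, maf_min = 0.05, call_rate_min = 0.30,
                        biallelic = NULL) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  if (nrow(dosages) == 0L || ncol(dosages) == 0L)
    stop("empty dosage matrix", call. = FALSE)
  maf_min <- check_fraction(maf_min, "maf_min")
  call_rate_min <- check_fraction(call_rate_min, "call_rate_min")
  biallelic <- biallelic %||% rep(TRUE, ncol(dosages))
  stopifnot(length(biallelic) == ncol(dosages))
  call_rate <- colMeans(!is.na(dosages))
  maf <- folded_maf(dosages)
  ok_bi <- as.logical(biallelic)
  ok_maf <- !is.na(maf) & maf > maf_min
  ok_cr <- call_rate >= call_rate_min
  keep <- ok_bi & ok_maf & ok_cr
  removed_by <- c(
    non_biallelic = sum(!ok_bi),
    maf = sum(ok_bi & !ok_maf),
    call_rate = sum(ok_bi & ok_maf & !ok_cr))
  out <- dosage_matrix(unclass(dosages)[, keep, drop = FALSE])
  list(dosage = out,
       report = new_filter_report("loci", ncol(dosages), ncol(out),
                                  as.list(removed_by)))
}

#' Genet filtering on missingness
#'
#' Removes genets whose fraction of missing calls strictly exceeds
#' `max_missing` ("more than 95 percent missing data").
#'
#' @param dosages a [dosage_matrix()].
#' @param max_missing exclusive upper bound on a genet's missing fraction,
#'   in (0, 1\].
#' @return List with the filtered `dosage` and a `report`.
#' @export
filter_genets <- function(dosages, max_missing = 0.95) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  max_missing <- check_fraction(max_missing, "max_missing", lo_open = TRUE)
  miss <- rowMeans(is.na(dosages))
  keep <- miss <= max_missing
  out <- dosage_matrix(unclass(dosages)[keep, , drop = FALSE])
  list(dosage = out,
       report = new_filter_report("genets", nrow(dosages), nrow(out),
                                  list(genet_missingness = sum(!keep))))
}

#' Build composite accession profiles
#'
#' Pools member genets of each accession into a composite genomic profile:
#' per locus, the mean of the non-missing member dosages (missing where no
#' member has a call).
#'
#' @param dosages a [dosage_matrix()] of reference genets.
#' @param membership data frame with columns `genet_id` and `accession_id`
#'   covering every row of `dosages` that is to be pooled.
#' @return An [accession_profiles()] object.
#' @export
pool_accessions <- function(dosages, membership) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  stopifnot(all(c("genet_id", "accession_id") %in% names(membership)))
  acc <- membership$accession_id[match(rownames(dosages), membership$genet_id)]
  if (anyNA(acc))
    stop("every pooled genet must appear in the membership table", call. = FALSE)
  accs <- sort(unique(acc))
  dos <- unclass(dosages)
  called <- !is.na(dos)
  dos0 <- dos; dos0[!called] <- 0L
  # per-accession sums of dosages and of call indicators
  grp <- factor(acc, levels = accs)
  sums <- rowsum(dos0, grp)
  cnts <- rowsum(called + 0L, grp)
  prof <- sums / cnts            # NaN where no member called
  prof[cnts == 0L] <- NA_real_
  n_genets <- as.integer(table(grp))
  if (any(n_genets == 0L))
    stop("accession with zero member genets", call. = FALSE)
  accession_profiles(prof, n_genets)
}
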