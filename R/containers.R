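#' Dosage matrix of biallelic genotype calls
#'
#' A `dosage_matrix` holds alt-allele dosages for genets (rows) at biallelic
#' loci (columns). Entries are 0, 1 or 2 copies of the alternate allele, or
#' `NA` where no call was made.
#'
#' @param dosage integer/numeric matrix with entries in \{0, 1, 2\} or `NA`;
#'   must carry unique row (genet) and column (locus) names.
#' @return A `dosage_matrix` object.
#' @export
dosage_matrix <- function(dosage) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage matrix requires genet (row) and locus (column) names", call. = FALSE)
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage)))
    stop("genet and locus labels must be unique", call. = FALSE)
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  storage.mode(dosage) <- "integer"
  structure(dosage, class = c("dosage_matrix", "matrix", "array"))
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d genets x %d loci (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Paired reference/alternate read-depth matrices
#'
#' Raw GBS observation layer: per genet and locus, the number of reads
#' supporting the reference and the alternate allele.
#'
#' @param ref,alt non-negative integer matrices of identical shape with
#'   matching genet/locus dimnames.
#' @return A `depth_matrix` object (list with elements `ref` and `alt`).
#' @export
depth_matrix <- function(ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt)))
    stop("ref and alt matrices must have identical shape", call. = FALSE)
  if (!identical(dimnames(ref), dimnames(alt)))
    stop("ref and alt matrices must have identical dimnames", call. = FALSE)
  if (is.null(rownames(ref)) || is.null(colnames(ref)))
    stop("depth matrices require genet and locus names", call. = FALSE)
  if (min(ref, na.rm = TRUE) < 0 || min(alt, na.rm = TRUE) < 0)
    stop("read counts must be non-negative", call. = FALSE)
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  structure(list(ref = ref, alt = alt), class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  tot <- x$ref + x$alt
  cat(sprintf("depth_matrix: %d genets x %d loci, mean depth %.2f, %.1f%% zero-depth\n",
              nrow(x$ref), ncol(x$ref), mean(tot), 100 * mean(tot == 0)))
  invisible(x)
}

#' @export
dim.depth_matrix <- function(x) dim(x$ref)

#' Composite accession profiles
#'
#' Per-accession reference vectors of mean alt-allele dosage per locus,
#' formed by pooling the non-missing calls of an accession's member genets.
#' Used as the assignment targets.
#'
#' @param mean_dosage numeric matrix (accessions x loci) with entries in
#'   \[0, 2\] or `NA`.
#' @param n_genets integer vector, member genets per accession.
#' @return An `accession_profiles` object.
#' @export
accession_profiles <- function(mean_dosage, n_genets) {
  mean_dosage <- as.matrix(mean_dosage)
  if (is.null(rownames(mean_dosage)) || is.null(colnames(mean_dosage)))
    stop("profiles require accession and locus names", call. = FALSE)
  rng <- range(mean_dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("mean dosages must lie in [0, 2]", call. = FALSE)
  n_genets <- as.integer(n_genets)
  if (length(n_genets) != nrow(mean_dosage) || any(n_genets < 1L))
    stop("n_genets must give a positive count per accession", call. = FALSE)
  names(n_genets) <- rownames(mean_dosage)
  structure(list(mean_dosage = mean_dosage, n_genets = n_genets),
            class = "accession_profiles")
}

#' @export
print.accession_profiles <- function(x, ...) {
  cat(sprintf("accession_profiles: %d accessions x %d loci (%d-%d genets each)\n",
              nrow(x$mean_dosage), ncol(x$mean_dosage),
              min(x$n_genets), max(x$n_genets)))
  invisible(x)
}
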