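#' Read genotypes (GT) and allele depths (AD) from a VCF
#'
#' Loads a VCF 4.x file via \pkg{vcfR}. Dosages count copies of the first
#' ALT allele; records whose ALT field lists several alleles are flagged
#' non-biallelic (their calls are set missing and they are removed later by
#' [filter_loci()]). When the AD FORMAT field is absent the depth layer is
#' unavailable (`depths = NULL`) and depth-gated re-calling is skipped.
#'
#' @param path VCF file (optionally bgzip/gzip compressed).
#' @return List with `dosage` (a [dosage_matrix()]), `depths` (a
#'   [depth_matrix()] or `NULL`), and `biallelic` (logical per locus).
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  locus_ids <- fix[, "ID"]
  nameless <- is.na(locus_ids) | locus_ids == "."
  locus_ids[nameless] <- paste0(fix[nameless, "CHROM"], ":", fix[nameless, "POS"])
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE) & !is.na(fix[, "ALT"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rownames(gt) <- locus_ids
  alleles <- gsub("\\|", "/", gt)
  dos <- (substr(alleles, 1, 1) == "1") + (substr(alleles, 3, 3) == "1")
  dos[is.na(gt) | !grepl("^[01][/|][01]$", gt)] <- NA_integer_
  dos[!biallelic, ] <- NA_integer_
  dosage <- dosage_matrix(t(dos))
  depths <- NULL
  has_ad <- any(grepl("^##FORMAT=<ID=AD[,>]", vcf@meta))
  if (has_ad) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    rownames(ad) <- locus_ids
    ref <- suppressWarnings(as.integer(sub(",.*", "", ad)))
    alt <- suppressWarnings(as.integer(vapply(strsplit(ad, ","), function(x)
      if (length(x) >= 2) x[2] else NA_character_, character(1))))
    shape <- function(v) {
      m <- matrix(v, nrow = nrow(ad), dimnames = dimnames(ad))
      m[is.na(m)] <- 0L
      t(m)
    }
    depths <- depth_matrix(shape(ref), shape(alt))
  }
  list(dosage = dosage, depths = depths, biallelic = stats::setNames(biallelic, locus_ids))
}

#' Write genotypes (and optionally allele depths) to VCF
#'
#' Emits one sample per genet with GT (and AD when depths are supplied)
#' FORMAT fields, using placeholder A/T alleles for simulated loci. The file
#' is written gzip-compressed (the standard for VCF interchange) via
#' \pkg{vcfR}; [read_genotype_vcf()] round-trips it.
#'
#' @param path output path (a `.vcf.gz` suffix is conventional).
#' @param dosages a [dosage_matrix()].
#' @param depths optional matching [depth_matrix()].
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(path, dosages, depths = NULL) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  dos <- t(unclass(dosages))               # loci x genets
  nL <- nrow(dos)
  meta <- c("##fileformat=VCFv4.2",
            "##source=iwgorigin",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fmt <- "GT"
  gt_str <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow = nL)
  gt_str[is.na(dos)] <- "./."
  if (!is.null(depths)) {
    stopifnot(inherits(depths, "depth_matrix"))
    meta <- c(meta,
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
    fmt <- "GT:AD"
    ad_str <- matrix(paste0(t(depths$ref), ",", t(depths$alt)), nrow = nL)
    gt_str <- matrix(paste0(gt_str, ":", ad_str), nrow = nL)
  }
  gt <- cbind(FORMAT = fmt, gt_str)
  colnames(gt) <- c("FORMAT", colnames(dos))
  fix <- cbind(CHROM = "sim", POS = as.character(seq_len(nL)),
               ID = rownames(dos), REF = "A", ALT = "T",
               QUAL = ".", FILTER = "PASS", INFO = ".")
  vcf <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Dosage-matrix TSV round trip
#'
#' Genets as rows, loci as columns, `NA` for missing calls; first column
#' `genet_id`.
#'
#' @param dosages a [dosage_matrix()].
#' @param path file path.
#' @return `read_dosage_tsv()` returns a [dosage_matrix()];
#'   `write_dosage_tsv()` returns `path` invisibly.
#' @export
write_dosage_tsv <- function(dosages, path) {
  df <- data.frame(genet_id = rownames(dosages), unclass(dosages),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dosage_matrix(m)
}

#' Read a genet-to-accession membership table
#'
#' @param path TSV with columns `genet_id` and `accession_id`.
#' @return Data frame with the two columns.
#' @export
read_membership <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genet_id", "accession_id") %in% names(df)))
    stop("membership table needs genet_id and accession_id columns", call. = FALSE)
  df
}

#' Read a long-format phenotype table
#'
#' @param path TSV with columns `accession_id`, `trait`, `year`, `value`
#'   (`NA` for missing observations).
#' @return Validated data frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "trait", "year", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df[c("accession_id", "trait", "year")]))
    stop("duplicate (accession, trait, year) rows", call. = FALSE)
  df
}

iwg_extdata <- function(name) {
  p <- system.file("extdata", name, package = "iwgorigin", mustWork = FALSE)
  if (p == "") p <- file.path("inst", "extdata", name)  # pre-install fallback
  if (!file.exists(p)) stop("fixture not found: ", name, call. = FALSE)
  p
}

#' Packaged historical evaluation fixtures
#'
#' Transcriptions of the published 1988-1989 Rodale Institute evaluation
#' records and NPGS passport columns for the inferred Polycross-1 parents
#' (`table = 1`), the additional accessions supported only by molecular
#' assignment (`table = 2`), and NPGS accessions never evaluated by Rodale
#' (`table = 3`, passports only). The 1988 yield-per-10-heads column of
#' table 1 is present for only 10 of the 20 accessions, exactly as recorded;
#' table 2's yield column survives only as a single (collapsed) value per
#' accession, stored under 1989.
#'
#' @param table which table to load (1 or 2 for phenotypes; 1, 2 or 3 for
#'   passports).
#' @return `rodale_phenotypes()`: long phenotype data frame;
#'   `rodale_passports()`: passport data frame (see [read_passports()]);
#'   `rodale_source_sets()`: named list of accession-id sets for the
#'   cross-source analysis (joint memberships follow the published record;
#'   single-source placement of accessions whose per-source attribution was
#'   not published is synthetic and fixed).
#' @export
rodale_phenotypes <- function(table = 1) {
  stopifnot(table %in% 1:2)
  read_phenotypes(iwg_extdata(sprintf("table%d_phenotypes.tsv", table)))
}

#' @rdname rodale_phenotypes
#' @export
rodale_passports <- function(table = 1) {
  stopifnot(table %in% 1:3)
  read_passports(iwg_extdata(sprintf("table%d_passports.tsv", table)))
}

#' @rdname rodale_phenotypes
#' @export
rodale_source_sets <- function() {
  df <- utils::read.delim(iwg_extdata("source_sets.tsv"), stringsAsFactors = FALSE)
  split(df$accession_id, df$set_name)
}
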