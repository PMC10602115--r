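#' Parse a flat key: value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric.
#'
#' @param path config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("cannot parse config line: ", lines[bad][1], call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, trimws(keys))
}

default_run_config <- function() {
  list(n_accessions = 30, n_genets_per_accession = 6, n_loci = 500,
       fst = 0.15, mean_depth = 8, missing_rate = 0.3,
       n_founders = 10, n_cycles = 2, n_progeny_per_cycle = 100,
       maf_min = 0.05, call_rate_min = 0.30, max_genet_missing = 0.95,
       k = 20, cutoff_year = 1990, singleton_threshold = 10,
       seed = 1, out_dir = "iwgorigin_run")
}

#' Run the full inference pipeline on synthetic data
#'
#' Orchestrates simulate -> GBS observation -> depth-gated calling ->
#' marker/genet filtering -> composite profiles -> assignment of polycross
#' descendants -> leave-one-out validation -> founder counting, writing
#' every artifact to `out_dir` together with a manifest (parameters, file
#' MD5 hashes, package version). Identical configuration (seed included)
#' reproduces identical artifact hashes.
#'
#' @param config named list (see `read_run_config()`), path to a flat
#'   key: value config file, or `NULL` for the built-in demo configuration.
#' @param out_dir output directory (overrides the config entry).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config %||% list())
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  sim_cfg <- sim_config(
    n_accessions = cfg$n_accessions,
    n_genets_per_accession = cfg$n_genets_per_accession,
    n_loci = cfg$n_loci, fst = cfg$fst,
    mean_depth = cfg$mean_depth, missing_rate = cfg$missing_rate,
    n_cycles = cfg$n_cycles, n_progeny_per_cycle = cfg$n_progeny_per_cycle,
    seed = seed)

  founders <- simulate_founders(sim_cfg)
  genets <- simulate_genets(founders, seed = seed + 1L)
  true_founders <- with_rng(seed + 2L,
    sort(sample(founders$accession_ids, cfg$n_founders)))
  parent_rows <- genets$membership$accession_id %in% true_founders
  poly <- simulate_polycross(unclass(genets$dosage)[parent_rows, , drop = FALSE],
                             cycles = cfg$n_cycles,
                             n_progeny = cfg$n_progeny_per_cycle,
                             seed = seed + 3L)

  truth <- rbind(unclass(genets$dosage), unclass(poly$dosage))
  depths <- simulate_gbs(truth, cfg$mean_depth, cfg$missing_rate, seed = seed + 4L)
  called <- call_from_depths(depths)
  fl <- filter_loci(called, maf_min = cfg$maf_min,
                    call_rate_min = cfg$call_rate_min)
  fg <- filter_genets(fl$dosage, max_missing = cfg$max_genet_missing)
  dos <- fg$dosage

  is_ref <- rownames(dos) %in% genets$membership$genet_id
  refs <- dosage_matrix(unclass(dos)[is_ref, , drop = FALSE])
  queries <- dosage_matrix(unclass(dos)[!is_ref, , drop = FALSE])
  profiles <- pool_accessions(refs, genets$membership)

  allowed <- availability_filter(founders$passports, cfg$cutoff_year)
  allowed_profiles <- accession_profiles(
    profiles$mean_dosage[rownames(profiles$mean_dosage) %in% allowed, , drop = FALSE],
    profiles$n_genets[rownames(profiles$mean_dosage) %in% allowed])
  assignments <- assign_genets(queries, allowed_profiles)
  validation <- loo_validate(refs, genets$membership)
  founder_rep <- count_founders(assignments, k = cfg$k,
                                singleton_threshold = cfg$singleton_threshold)

  paths <- list(
    pedigree = "pedigree.tsv", membership = "membership.tsv",
    passports = "passports.tsv", dosage_references = "dosage_references.tsv",
    dosage_queries = "dosage_queries.tsv", assignments = "assignments.tsv",
    validation = "validation.tsv", founder_counts = "founder_counts.tsv",
    filter_report = "filter_report.tsv", genotypes_vcf = "genotypes.vcf.gz")
  paths <- lapply(paths, function(p) file.path(cfg$out_dir, p))
  wtsv <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE, na = "NA")
  wtsv(rbind(genets$pedigree, poly$pedigree), paths$pedigree)
  wtsv(genets$membership, paths$membership)
  wtsv(founders$passports, paths$passports)
  write_dosage_tsv(refs, paths$dosage_references)
  write_dosage_tsv(queries, paths$dosage_queries)
  wtsv(assignments, paths$assignments)
  wtsv(validation$per_query, paths$validation)
  wtsv(data.frame(accession_id = names(founder_rep$counts),
                  n_assigned = founder_rep$counts,
                  in_top_k = names(founder_rep$counts) %in% founder_rep$top_k_set),
       paths$founder_counts)
  wtsv(rbind(as.data.frame(fl$report), as.data.frame(fg$report)),
       paths$filter_report)
  write_genotype_vcf(paths$genotypes_vcf, dos, depth_matrix(
    depths$ref[rownames(depths$ref) %in% rownames(dos),
               colnames(depths$ref) %in% colnames(dos), drop = FALSE],
    depths$alt[rownames(depths$alt) %in% rownames(dos),
               colnames(depths$alt) %in% colnames(dos), drop = FALSE]))

  tsv_paths <- unlist(paths[names(paths) != "genotypes_vcf"])
  manifest <- list(
    package = "iwgorigin",
    version = as.character(utils::packageVersion("iwgorigin")),
    parameters = cfg,
    true_founders = true_founders,
    loo_accuracy = validation$accuracy,
    top_founders = founder_rep$top_k_set,
    # hashes cover the plain-text artifacts; gzip output embeds an mtime
    files = as.list(stats::setNames(unname(tools::md5sum(tsv_paths)),
                                    names(tsv_paths))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = cfg, founders = founders, genets = genets,
                 polycross = poly, dosage = dos, profiles = profiles,
                 assignments = assignments, validation = validation,
                 founder_report = founder_rep, manifest = manifest,
                 true_founders = true_founders))
}
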