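# small builders shared across tests

make_founders <- function(freqs, fst = 0.15, seed = 1L) {
  freqs <- as.matrix(freqs)
  if (is.null(rownames(freqs)))
    rownames(freqs) <- sprintf("ACC%03d", seq_len(nrow(freqs)))
  if (is.null(colnames(freqs)))
    colnames(freqs) <- sprintf("L%05d", seq_len(ncol(freqs)))
  structure(list(allele_freqs = freqs, accession_ids = rownames(freqs),
                 ancestral_freqs = colMeans(freqs),
                 passports = data.frame(accession_id = rownames(freqs)),
                 config = sim_config(n_accessions = nrow(freqs),
                                     n_loci = ncol(freqs), fst = fst,
                                     seed = seed)),
            class = "founder_set")
}

make_dosage <- function(m, genets = NULL, loci = NULL) {
  m <- as.matrix(m)
  rownames(m) <- genets %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- loci %||% sprintf("L%02d", seq_len(ncol(m)))
  dosage_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent per-pair scaled-distance oracle: explicit loop over shared loci
oracle_dist <- function(x, y, total = length(x)) {
  sh <- !is.na(x) & !is.na(y)
  if (!any(sh)) return(NA_real_)
  sqrt(sum((x[sh] - y[sh])^2) * total / sum(sh))
}

# benchmark scenario: simulate, observe, call, filter
bench_loo <- function(seed, n_accessions = 50, n_genets = 6, n_loci = 2000,
                      fst = 0.15, mean_depth = 8, missing_rate = 0.30) {
  cfg <- sim_config(n_accessions = n_accessions,
                    n_genets_per_accession = n_genets, n_loci = n_loci,
                    fst = fst, mean_depth = mean_depth,
                    missing_rate = missing_rate, seed = seed)
  f <- simulate_founders(cfg)
  g <- simulate_genets(f, seed = seed + 100L)
  d <- simulate_gbs(g$dosage, mean_depth, missing_rate, seed = seed + 200L)
  fl <- filter_loci(call_from_depths(d))
  fg <- filter_genets(fl$dosage)
  loo_validate(fg$dosage, g$membership)
}
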