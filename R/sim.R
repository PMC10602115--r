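#' Simulation configuration for the synthetic polycross/GBS generator
#'
#' Bundles and validates every knob of the synthetic-data module. The
#' defaults describe the benchmark scenario used throughout the package's
#' validation: hierarchically structured accessions under Balding-Nichols
#' divergence, about six genets per accession, and a GBS observation layer
#' with Poisson read depth and extra dropout.
#'
#' @param n_accessions number of founder accessions.
#' @param n_genets_per_accession genets sampled per accession (Hardy-Weinberg
#'   within accession).
#' @param n_loci number of independent biallelic loci.
#' @param fst Balding-Nichols divergence parameter in (0, 1).
#' @param ancestral_maf_range interval in (0, 0.5] from which ancestral minor
#'   allele frequencies are drawn uniformly.
#' @param mean_depth expected reads per genet-locus (Poisson mean).
#' @param missing_rate probability a genet-locus yields zero reads regardless
#'   of depth (library dropout), in \[0, 1).
#' @param n_cycles polycross intermating cycles.
#' @param n_progeny_per_cycle progeny generated per cycle.
#' @param seed integer random seed; identical configs (seed included) give
#'   bit-identical outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accessions = 50L, n_genets_per_accession = 6L,
                       n_loci = 2000L, fst = 0.15,
                       ancestral_maf_range = c(0.05, 0.5),
                       mean_depth = 8, missing_rate = 0.30,
                       n_cycles = 2L, n_progeny_per_cycle = 300L,
                       seed = 1L) {
  cfg <- list(
    n_accessions = check_count(n_accessions, "n_accessions"),
    n_genets_per_accession = check_count(n_genets_per_accession, "n_genets_per_accession"),
    n_loci = check_count(n_loci, "n_loci"),
    fst = check_fraction(fst, "fst", lo_open = TRUE, hi_open = TRUE),
    ancestral_maf_range = ancestral_maf_range,
    mean_depth = mean_depth,
    missing_rate = check_fraction(missing_rate, "missing_rate", hi_open = TRUE),
    n_cycles = check_count(n_cycles, "n_cycles"),
    n_progeny_per_cycle = check_count(n_progeny_per_cycle, "n_progeny_per_cycle"),
    seed = check_count(seed, "seed", min = 0L))
  r <- cfg$ancestral_maf_range
  if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) ||
      r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    stop_config("ancestral_maf_range", "must be an interval within (0, 0.5]")
  if (!is.numeric(cfg$mean_depth) || length(cfg$mean_depth) != 1L ||
      is.na(cfg$mean_depth) || cfg$mean_depth < 0)
    stop_config("mean_depth", "must be a single non-negative number")
  structure(cfg, class = "sim_config")
}

acc_label <- function(i) sprintf("ACC%03d", i)

#' Simulate founder accessions under the Balding-Nichols model
#'
#' Draws an ancestral minor allele frequency per locus uniformly from
#' `ancestral_maf_range`, then each accession's alt-allele frequency from a
#' Beta distribution with mean `p` and variance `fst * p * (1 - p)`
#' (Balding-Nichols). Synthetic passport records (origin, acquisition mode
#' and year) are attached so availability filtering and geographic summaries
#' can be exercised end to end.
#'
#' @param config a [sim_config()].
#' @return A `founder_set`: list with `allele_freqs` (accession x locus
#'   matrix), `accession_ids`, and a `passports` data frame.
#' @export
simulate_founders <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_rng(config$seed, {
    nA <- config$n_accessions; nL <- config$n_loci
    p <- stats::runif(nL, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
    a <- p * (1 - config$fst) / config$fst
    b <- (1 - p) * (1 - config$fst) / config$fst
    freqs <- matrix(stats::rbeta(nA * nL, rep(a, each = nA), rep(b, each = nA)),
                    nrow = nA, ncol = nL,
                    dimnames = list(acc_label(seq_len(nA)),
                                    sprintf("L%05d", seq_len(nL))))
    countries <- c("Russia", "Kazakhstan", "Turkey", "Iran", "Uzbekistan",
                   "Afghanistan", "Former USSR")
    mode <- sample(c("collected", "donated", "unknown"), nA, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))
    year <- ifelse(stats::runif(nA) < 0.1, NA_integer_,
                   sample(1955:1995, nA, replace = TRUE))
    passports <- data.frame(
      accession_id = rownames(freqs),
      pi_number = sprintf("PI %06d", 400000 + seq_len(nA)),
      origin_country = sample(countries, nA, replace = TRUE,
                              prob = c(0.55, 0.1, 0.1, 0.05, 0.05, 0.05, 0.1)),
      collection_site = NA_character_,
      elevation_m = round(stats::runif(nA, 0, 2000)),
      status = sample(c("wild", "uncertain", "cultivated"), nA, replace = TRUE,
                      prob = c(0.7, 0.2, 0.1)),
      cultivar_name = NA_character_,
      acquisition_mode = mode,
      acquisition_year = year,
      stringsAsFactors = FALSE)
    structure(list(allele_freqs = freqs,
                   accession_ids = rownames(freqs),
                   ancestral_freqs = p,
                   passports = passports,
                   config = config),
              class = "founder_set")
  })
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("founder_set: %d accessions x %d loci (fst = %g)\n",
              nrow(x$allele_freqs), ncol(x$allele_freqs), x$config$fst))
  invisible(x)
}

#' Simulate founder genets within accessions
#'
#' Draws `n` genets per accession with dosage ~ Binomial(2, accession allele
#' frequency) independently across loci (Hardy-Weinberg within accession).
#' These are true (pre-observation) dosages; pass them through
#' [simulate_gbs()] to get read-level data.
#'
#' @param founders a `founder_set` from [simulate_founders()].
#' @param n genets per accession (default from the founder config).
#' @param seed integer seed.
#' @return List with `dosage` (a [dosage_matrix()]), `pedigree` (generation-0
#'   records), and `membership` (genet -> accession data frame).
#' @export
simulate_genets <- function(founders, n = NULL, seed = 1L) {
  stopifnot(inherits(founders, "founder_set"))
  n <- check_count(n %||% founders$config$n_genets_per_accession, "n")
  with_rng(seed, {
    fr <- founders$allele_freqs
    nA <- nrow(fr); nL <- ncol(fr)
    # row-block per accession: n genets x nL loci
    probs <- fr[rep(seq_len(nA), each = n), , drop = FALSE]
    dos <- matrix(stats::rbinom(length(probs), 2L, probs), nrow = nA * n,
                  dimnames = list(
                    paste0(rep(rownames(fr), each = n), "_g", rep(seq_len(n), nA)),
                    colnames(fr)))
    membership <- data.frame(
      genet_id = rownames(dos),
      accession_id = rep(rownames(fr), each = n),
      stringsAsFactors = FALSE)
    pedigree <- data.frame(
      genet_id = rownames(dos), generation = 0L,
      parent1 = NA_character_, parent2 = NA_character_,
      source_accession = membership$accession_id,
      stringsAsFactors = FALSE)
    list(dosage = dosage_matrix(dos), pedigree = pedigree, membership = membership)
  })
}

#' Simulate multi-cycle polycross descent
#'
#' Each progeny draws two distinct parents uniformly at random (no selfing)
#' from the current parent pool and one Mendelian gamete per parent per locus
#' (loci independent, no linkage). After each cycle the progeny become the
#' parent pool for the next, mirroring the bulked Syn-0/Syn-1 seed of a
#' recurrent polycross program.
#'
#' @param parents a [dosage_matrix()] (complete, no missing) of the founding
#'   parent pool.
#' @param cycles number of intermating cycles (>= 1).
#' @param n_progeny progeny per cycle.
#' @param seed integer seed.
#' @param start_generation generation index assigned to the first progeny
#'   cycle (founder genets are generation 0).
#' @return List with `dosage` (progeny of the final cycle) and `pedigree`
#'   (records for every cycle).
#' @export
simulate_polycross <- function(parents, cycles = 1L, n_progeny = 300L,
                               seed = 1L, start_generation = 1L) {
  cycles <- check_count(cycles, "cycles")
  n_progeny <- check_count(n_progeny, "n_progeny")
  parents <- as.matrix(parents)
  if (nrow(parents) < 2L) stop("a polycross needs at least 2 parents", call. = FALSE)
  if (anyNA(parents)) stop("parent dosages must be complete", call. = FALSE)
  with_rng(seed, {
    nL <- ncol(parents)
    pool <- parents
    pedigree <- list()
    for (cy in seq_len(cycles)) {
      np <- nrow(pool)
      p1 <- sample.int(np, n_progeny, replace = TRUE)
      # second parent distinct from the first
      p2 <- sample.int(np - 1L, n_progeny, replace = TRUE)
      p2 <- ifelse(p2 >= p1, p2 + 1L, p2)
      gen <- start_generation + cy - 1L
      ids <- sprintf("C%d_p%04d", gen, seq_len(n_progeny))
      g1 <- matrix(stats::rbinom(n_progeny * nL, 1L, pool[p1, , drop = FALSE] / 2),
                   nrow = n_progeny)
      g2 <- matrix(stats::rbinom(n_progeny * nL, 1L, pool[p2, , drop = FALSE] / 2),
                   nrow = n_progeny)
      prog <- g1 + g2
      dimnames(prog) <- list(ids, colnames(parents))
      pedigree[[cy]] <- data.frame(
        genet_id = ids, generation = gen,
        parent1 = rownames(pool)[p1], parent2 = rownames(pool)[p2],
        source_accession = NA_character_, stringsAsFactors = FALSE)
      pool <- prog
    }
    list(dosage = dosage_matrix(pool), pedigree = do.call(rbind, pedigree))
  })
}

#' Simulate the GBS observation layer
#'
#' Per genet-locus, total read depth ~ Poisson(`mean_depth`), set to zero
#' with probability `missing_rate` (independent dropout); alternate-allele
#' reads ~ Binomial(depth, dosage / 2); reference reads make up the rest.
#'
#' @param dosages a complete [dosage_matrix()] of true genotypes.
#' @param mean_depth expected reads per genet-locus (>= 0).
#' @param missing_rate dropout probability in \[0, 1\].
#' @param seed integer seed.
#' @return A [depth_matrix()].
#' @export
simulate_gbs <- function(dosages, mean_depth = 8, missing_rate = 0.3, seed = 1L) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages)) stop("true dosages must be complete", call. = FALSE)
  if (!is.numeric(mean_depth) || mean_depth < 0)
    stop("mean_depth must be non-negative", call. = FALSE)
  missing_rate <- check_fraction(missing_rate, "missing_rate")
  with_rng(seed, {
    n <- length(dosages)
    depth <- stats::rpois(n, mean_depth)
    depth[stats::runif(n) < missing_rate] <- 0L
    alt <- stats::rbinom(n, depth, as.vector(dosages) / 2)
    ref <- depth - alt
    shape <- function(v) matrix(v, nrow = nrow(dosages), dimnames = dimnames(dosages))
    depth_matrix(shape(ref), shape(alt))
  })
}

#' Simulate accession-by-year phenotype records
#'
#' value = trait mean + accession main effect + year effect + accession-by-
#' year interaction + residual noise, each component Gaussian with a
#' configurable standard deviation. A missingness pattern (logical matrix or
#' data frame of cells) can knock out individual accession-trait-year cells,
#' mimicking the incomplete historical records (e.g. a yield column absent
#' for most accessions in a drought year).
#'
#' @param accession_ids character vector of accessions.
#' @param traits character vector of trait names (>= 1).
#' @param years integer vector of years (>= 2).
#' @param effect_config list with elements `trait_means` (named per trait;
#'   default 1), `accession_sd`, `year_sd`, `interaction_sd`, `noise_sd`.
#' @param seed integer seed.
#' @param missing_cells optional data frame (accession_id, trait, year) of
#'   cells to set missing.
#' @return Long data frame (accession_id, trait, year, value).
#' @export
simulate_phenotypes <- function(accession_ids, traits, years,
                                effect_config = list(), seed = 1L,
                                missing_cells = NULL) {
  if (length(traits) < 1L) stop("need at least one trait", call. = FALSE)
  if (length(years) < 2L) stop("need at least two years", call. = FALSE)
  ec <- utils::modifyList(list(accession_sd = 1, year_sd = 1,
                               interaction_sd = 0, noise_sd = 0.1,
                               trait_means = NULL), effect_config)
  means <- ec$trait_means %||% stats::setNames(rep(1, length(traits)), traits)
  with_rng(seed, {
    out <- expand.grid(accession_id = accession_ids, trait = traits,
                       year = years, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    nA <- length(accession_ids); nT <- length(traits); nY <- length(years)
    accfx <- matrix(stats::rnorm(nA * nT, 0, ec$accession_sd), nA, nT,
                    dimnames = list(accession_ids, traits))
    yearfx <- matrix(stats::rnorm(nY * nT, 0, ec$year_sd), nY, nT,
                     dimnames = list(as.character(years), traits))
    interfx <- array(stats::rnorm(nA * nT * nY, 0, ec$interaction_sd),
                     dim = c(nA, nT, nY),
                     dimnames = list(accession_ids, traits, as.character(years)))
    idx <- cbind(match(out$accession_id, accession_ids),
                 match(out$trait, traits),
                 match(out$year, years))
    out$value <- means[out$trait] +
      accfx[idx[, 1:2]] +
      yearfx[cbind(idx[, 3], idx[, 2])] +
      interfx[idx] +
      stats::rnorm(nrow(out), 0, ec$noise_sd)
    if (!is.null(missing_cells)) {
      key <- function(d) paste(d$accession_id, d$trait, d$year, sep = "\r")
      out$value[key(out) %in% key(missing_cells)] <- NA_real_
    }
    rownames(out) <- NULL
    out
  })
}
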