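test_that("simulation is bit-identical under a repeated seed", {
  cfg <- sim_config(n_accessions = 3, n_loci = 100, seed = 1)
  f1 <- simulate_founders(cfg)
  f2 <- simulate_founders(cfg)
  expect_identical(f1$allele_freqs, f2$allele_freqs)
  g1 <- simulate_genets(f1, seed = 5)
  g2 <- simulate_genets(f2, seed = 5)
  expect_identical(g1$dosage, g2$dosage)
  p1 <- simulate_polycross(g1$dosage, cycles = 2, n_progeny = 20, seed = 7)
  p2 <- simulate_polycross(g2$dosage, cycles = 2, n_progeny = 20, seed = 7)
  expect_identical(p1$dosage, p2$dosage)
  d1 <- simulate_gbs(p1$dosage, 5, 0.2, seed = 9)
  d2 <- simulate_gbs(p2$dosage, 5, 0.2, seed = 9)
  expect_identical(d1, d2)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(n_accessions = 0), "n_accessions")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(ancestral_maf_range = c(0, 0.6)), "ancestral_maf_range")
  expect_error(sim_config(mean_depth = -1), "mean_depth")
})

test_that("accession frequencies collapse onto the ancestral values as fst -> 0", {
  cfg <- sim_config(n_accessions = 10, n_loci = 300, fst = 0.001, seed = 2)
  f <- simulate_founders(cfg)
  dev <- sweep(f$allele_freqs, 2, f$ancestral_freqs)
  # sd per cell is sqrt(fst * p(1-p)) <= 0.016; 0.1 is > 6 sd
  expect_lt(max(abs(dev)), 0.1)
})

test_that("accession frequencies match the Balding-Nichols moments", {
  cfg <- sim_config(n_accessions = 200, n_loci = 10000, fst = 0.15,
                    ancestral_maf_range = c(0.05, 0.5), seed = 3)
  f <- simulate_founders(cfg)
  near <- which(abs(f$ancestral_freqs - 0.3) < 0.02)
  expect_gt(length(near), 100)
  v <- mean(apply(f$allele_freqs[, near, drop = FALSE], 2, var))
  m <- mean(f$allele_freqs[, near])
  expect_equal(v, 0.15 * 0.3 * 0.7, tolerance = 0.1)
  expect_equal(m, 0.3, tolerance = 0.05)
})

test_that("genet dosages respect boundary frequencies and the binomial mean", {
  f <- make_founders(rbind(c(0, 1, 0.5)))
  g <- simulate_genets(f, n = 10000, seed = 4)
  dos <- unclass(g$dosage)
  expect_true(all(dos[, 1] == 0))
  expect_true(all(dos[, 2] == 2))
  se <- sqrt(2 * 0.25 / 10000)
  expect_lt(abs(mean(dos[, 3]) - 1), 3 * se)
})

test_that("polycross forces heterozygosity from opposite homozygotes and rejects single parents", {
  par <- make_dosage(matrix(c(0L, 2L), nrow = 2, ncol = 6))
  pc <- simulate_polycross(par, cycles = 1, n_progeny = 50, seed = 5)
  expect_true(all(unclass(pc$dosage) == 1L))
  expect_error(simulate_polycross(make_dosage(matrix(1L, 1, 6)), 1, 10, 1),
               "at least 2 parents")
})

test_that("random mating conserves allele frequencies within sampling error", {
  set.seed(6)
  par <- make_dosage(matrix(rbinom(40 * 200, 2, 0.4), nrow = 40))
  pc <- simulate_polycross(par, cycles = 1, n_progeny = 10000, seed = 6)
  f_par <- colMeans(unclass(par)) / 2
  f_prog <- colMeans(unclass(pc$dosage)) / 2
  se <- sqrt(pmax(f_par * (1 - f_par), 1e-12) / (2 * 10000))
  expect_true(all(abs(f_prog - f_par) <= 4 * se + 1e-12))
})

test_that("pedigree records close over generations and founders carry their accession", {
  f <- make_founders(matrix(0.5, 3, 20))
  g <- simulate_genets(f, n = 4, seed = 7)
  pc <- simulate_polycross(g$dosage, cycles = 3, n_progeny = 30, seed = 8)
  ped <- rbind(g$pedigree, pc$pedigree)
  expect_true(all(is.na(ped$parent1[ped$generation == 0])))
  expect_true(all(!is.na(ped$source_accession[ped$generation == 0])))
  for (gen in 1:3) {
    prev <- ped$genet_id[ped$generation == gen - 1]
    cur <- ped[ped$generation == gen, ]
    expect_true(all(cur$parent1 %in% prev))
    expect_true(all(cur$parent2 %in% prev))
    expect_true(all(cur$parent1 != cur$parent2))  # no selfing
  }
})

test_that("GBS observation layer honours dosage, dropout and the thinned Poisson mean", {
  dos <- make_dosage(matrix(0L, 4, 25))
  d <- simulate_gbs(dos, mean_depth = 6, missing_rate = 0, seed = 9)
  expect_true(all(d$alt == 0L))
  d1 <- simulate_gbs(dos, mean_depth = 6, missing_rate = 1 - 1e-12, seed = 9)
  expect_true(all(d1$ref + d1$alt == 0L))
  big <- make_dosage(matrix(1L, 100, 1000))
  d2 <- simulate_gbs(big, mean_depth = 8, missing_rate = 0.3, seed = 10)
  expect_equal(mean(d2$ref + d2$alt), 8 * 0.7, tolerance = 0.01)
})

test_that("phenotype simulation reproduces no-GxE and strong-GxE regimes", {
  ids <- sprintf("A%03d", 1:500)
  ph0 <- simulate_phenotypes(ids, "yield", c(1988, 1989),
                             effect_config = list(interaction_sd = 0, noise_sd = 0),
                             seed = 11)
  v0 <- reshape(ph0, idvar = "accession_id", timevar = "year",
                direction = "wide", drop = "trait")
  expect_identical(order(v0$value.1988), order(v0$value.1989))
  ph1 <- simulate_phenotypes(ids, "yield", c(1988, 1989),
                             effect_config = list(accession_sd = 0.01,
                                                  interaction_sd = 5, noise_sd = 0),
                             seed = 12)
  v1 <- reshape(ph1, idvar = "accession_id", timevar = "year",
                direction = "wide", drop = "trait")
  rho <- cor(v1$value.1988, v1$value.1989, method = "spearman")
  expect_lt(abs(rho), 0.15)
})

test_that("a configured missingness pattern reproduces the historical record gaps", {
  t1 <- rodale_phenotypes(1)
  gap <- t1[t1$trait == "yield_per_10_heads_g" & t1$year == 1988 & is.na(t1$value),
            c("accession_id", "trait", "year")]
  expect_equal(nrow(gap), 10)  # 1988 yield present for only 10 of 20
  ids <- unique(t1$accession_id)
  ph <- simulate_phenotypes(ids, "yield_per_10_heads_g", c(1988, 1989),
                            seed = 13, missing_cells = gap)
  miss88 <- is.na(ph$value[ph$year == 1988])
  expect_equal(sum(miss88), 10)
  expect_setequal(ph$accession_id[ph$year == 1988][miss88], gap$accession_id)
  expect_false(anyNA(ph$value[ph$year == 1989]))
})
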