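test_that("distances reproduce hand values and equal stats::dist on complete data", {
  x <- make_dosage(rbind(c(0L, 0L, 0L), c(2L, 2L, 2L), c(0L, 0L, 0L)))
  D <- pairwise_distance(x)
  expect_equal(D[1, 2], sqrt(12))
  expect_equal(D[1, 3], 0)
  set.seed(1)
  m <- matrix(sample(0:2, 8 * 30, replace = TRUE), 8, 30,
              dimnames = list(paste0("g", 1:8), paste0("L", 1:30)))
  D2 <- pairwise_distance(dosage_matrix(m))
  expect_equal(unclass(D2), as.matrix(dist(m)), ignore_attr = TRUE)
})

test_that("missing-scaled distances match a brute-force shared-locus oracle", {
  set.seed(2)
  for (rep in 1:5) {
    m <- matrix(sample(c(0:2, NA), 10 * 15, replace = TRUE), 10, 15,
                dimnames = list(paste0("g", 1:10), paste0("L", 1:15)))
    keep <- rowSums(!is.na(m)) > 0
    m <- m[keep, , drop = FALSE]
    D <- suppressWarnings(pairwise_distance(dosage_matrix(m)))
    for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
      if (i == j) expect_equal(D[i, j], 0) else
        expect_equal(D[i, j], oracle_dist(m[i, ], m[j, ], ncol(m)))
    }
    expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
    expect_true(all(D >= 0, na.rm = TRUE))
  }
})

test_that("pairs sharing no loci give a missing distance with a warning", {
  m <- make_dosage(rbind(c(1L, NA), c(NA, 1L)))
  expect_warning(D <- pairwise_distance(m), "no called loci")
  expect_true(is.na(D[1, 2]))
})

test_that("assignment finds exact matches and breaks ties lexicographically", {
  prof <- accession_profiles(
    rbind(B = c(2, 2, 2), A = c(2, 2, 2), C = c(0, 0, 0)) |>
      (\(m) {colnames(m) <- paste0("L", 1:3); m})(),
    n_genets = c(3, 3, 3))
  q <- make_dosage(rbind(c(2L, 2L, 2L)), genets = "q1")
  expect_message(res <- assign_genets(q, prof), "tie")
  expect_equal(res$best_accession, "A")   # tie with B, smaller id wins
  expect_equal(res$best_distance, 0)
  expect_equal(res$second_accession, "B")
  expect_equal(res$n_shared_loci_best, 3L)
  expect_true(res$tie)
})

test_that("assignment equals a brute-force argmin over the full distance table", {
  cfg <- sim_config(n_accessions = 8, n_genets_per_accession = 5, n_loci = 400,
                    fst = 0.15, seed = 3)
  f <- simulate_founders(cfg)
  g <- simulate_genets(f, seed = 4)
  d <- simulate_gbs(g$dosage, 8, 0.3, seed = 5)
  dos <- filter_genets(filter_loci(call_from_depths(d))$dosage)$dosage
  mem <- g$membership[g$membership$genet_id %in% rownames(dos), ]
  prof <- pool_accessions(dos, mem)
  queries <- dosage_matrix(unclass(dos)[1:10, , drop = FALSE])
  res <- assign_genets(queries, prof)
  P <- prof$mean_dosage
  for (i in 1:10) {
    d_all <- vapply(rownames(P), function(a)
      oracle_dist(unclass(queries)[i, ], P[a, ], ncol(P)), numeric(1))
    o <- order(d_all, names(d_all))
    expect_equal(res$best_accession[i], names(d_all)[o[1]])
    expect_equal(res$best_distance[i], unname(d_all[o[1]]))
    expect_equal(res$second_accession[i], names(d_all)[o[2]])
  }
  expect_true(all(res$best_distance <= res$second_distance))
})

test_that("assignment is invariant to locus permutation and reference relabeling", {
  cfg <- sim_config(n_accessions = 5, n_genets_per_accession = 4, n_loci = 200,
                    fst = 0.2, seed = 6)
  f <- simulate_founders(cfg)
  g <- simulate_genets(f, seed = 7)
  prof <- pool_accessions(g$dosage, g$membership)
  q <- dosage_matrix(unclass(g$dosage)[1:5, , drop = FALSE])
  base <- assign_genets(q, prof)
  perm <- sample(ncol(unclass(q)))
  q2 <- dosage_matrix(unclass(q)[, perm, drop = FALSE])
  prof2 <- accession_profiles(prof$mean_dosage[, perm, drop = FALSE], prof$n_genets)
  res2 <- assign_genets(q2, prof2)
  expect_equal(res2$best_accession, base$best_accession)
  expect_equal(res2$best_distance, base$best_distance)
})

test_that("leave-one-out is perfect for maximally diverged accessions", {
  f <- make_founders(rbind(rep(0, 50), rep(1, 50)))
  g <- simulate_genets(f, n = 6, seed = 8)
  v <- loo_validate(g$dosage, g$membership)
  expect_equal(v$accuracy, 1)
  expect_equal(v$n_queries, 12)
  expect_error(loo_validate(g$dosage,
                            transform(g$membership, accession_id = "X")),
               "at least 2 accessions")
})

test_that("leave-one-out accuracy degrades to chance as divergence vanishes", {
  accs <- vapply(1:3, function(s) {
    cfg <- sim_config(n_accessions = 20, n_genets_per_accession = 4,
                      n_loci = 100, fst = 0.002, mean_depth = 8,
                      missing_rate = 0, seed = s)
    f <- simulate_founders(cfg)
    g <- simulate_genets(f, seed = s + 10L)
    loo_validate(g$dosage, g$membership)$accuracy
  }, numeric(1))
  # chance level is 1/20; allow generous sampling noise above it
  expect_lt(mean(accs), 0.25)
})

test_that("leave-one-out accuracy is monotone in divergence and in locus count", {
  acc_at <- function(fst, n_loci) {
    v <- vapply(1:2, function(s) {
      cfg <- sim_config(n_accessions = 15, n_genets_per_accession = 4,
                        n_loci = n_loci, fst = fst, mean_depth = 8,
                        missing_rate = 0.3, seed = s)
      f <- simulate_founders(cfg)
      g <- simulate_genets(f, seed = s + 20L)
      d <- simulate_gbs(g$dosage, 8, 0.3, seed = s + 40L)
      dos <- filter_genets(filter_loci(call_from_depths(d))$dosage)$dosage
      loo_validate(dos, g$membership)$accuracy
    }, numeric(1))
    mean(v)
  }
  by_fst <- vapply(c(0.01, 0.05, 0.15), acc_at, numeric(1), n_loci = 300)
  expect_true(all(diff(by_fst) >= 0))
  by_loci <- vapply(c(50, 300, 1500), function(L) acc_at(0.05, L), numeric(1))
  expect_true(all(diff(by_loci) >= 0))
})

test_that("the per-genet mode reports nearest-member distances as a secondary output", {
  cfg <- sim_config(n_accessions = 6, n_genets_per_accession = 4, n_loci = 300,
                    fst = 0.25, seed = 30)
  f <- simulate_founders(cfg)
  g <- simulate_genets(f, seed = 31)
  prof <- pool_accessions(g$dosage, g$membership)
  q <- dosage_matrix(unclass(g$dosage)[1:6, , drop = FALSE])
  res <- assign_genets(q, prof, per_genet = list(dosage = g$dosage,
                                                 membership = g$membership))
  # each query IS a member genet, so its nearest member is itself at distance 0
  expect_true(all(res$nearest_genet_distance == 0))
  expect_identical(res$nearest_genet_accession,
                   g$membership$accession_id[1:6])
  expect_true(all(res$best_min_genet_distance >= 0))
  # oracle: min over member genets of the assigned accession
  for (i in 1:3) {
    members <- g$membership$genet_id[g$membership$accession_id ==
                                       res$best_accession[i]]
    d <- vapply(members, function(m)
      oracle_dist(unclass(q)[i, ], unclass(g$dosage)[m, ], ncol(unclass(q))),
      numeric(1))
    expect_equal(res$best_min_genet_distance[i], min(d, na.rm = TRUE))
  }
})
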