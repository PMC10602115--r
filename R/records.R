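#' Seed set rating
#'
#' Percent ratio of clean threshed seed weight to unthreshed seed-head
#' weight from a 10-head sample; a seed-head fertility measure.
#'
#' @param clean_seed_g clean seed mass (g), >= 0.
#' @param unthreshed_heads_g unthreshed 10-head mass (g), > 0.
#' @return Seed set rating in percent.
#' @export
seed_set_rating <- function(clean_seed_g, unthreshed_heads_g) {
  if (any(unthreshed_heads_g <= 0))
    stop("unthreshed head weight must be positive", call. = FALSE)
  if (any(clean_seed_g < 0)) stop("clean seed weight cannot be negative", call. = FALSE)
  if (any(clean_seed_g > unthreshed_heads_g))
    stop("clean seed cannot outweigh the unthreshed heads", call. = FALSE)
  100 * clean_seed_g / unthreshed_heads_g
}

#' Hundred-seed weight
#'
#' Mean mass of three random 100-seed samples (dried to 12 percent
#' moisture).
#'
#' @param samples numeric vector of exactly three positive masses (g).
#' @return Mean mass in grams.
#' @export
hundred_seed_weight <- function(samples) {
  if (length(samples) != 3L)
    stop("exactly three 100-seed samples are required", call. = FALSE)
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("sample masses must be positive", call. = FALSE)
  mean(samples)
}

#' Combined-year trait summary
#'
#' Summarises traits over a set of accessions across evaluation years. The
#' default (`method = "year_mean"`) computes each year's mean over the
#' accessions with a non-missing value in that year and then averages the
#' year means with equal weight — the convention that handles trait columns
#' recorded for only part of the panel in one year. `method = "pooled"`
#' instead averages all non-missing accession-year cells directly.
#'
#' @param table long phenotype data frame (see [read_phenotypes()]).
#' @param accessions accession ids to summarise (default: all in `table`).
#' @param traits trait names (default: all in `table`).
#' @param method `"year_mean"` (default) or `"pooled"`.
#' @return Data frame with one row per trait: `trait`, `mean`, `n_cells`,
#'   `n_missing`.
#' @export
trait_summary <- function(table, accessions = NULL, traits = NULL,
                          method = c("year_mean", "pooled")) {
  method <- match.arg(method)
  accessions <- accessions %||% unique(table$accession_id)
  traits <- traits %||% unique(table$trait)
  sub <- table[table$accession_id %in% accessions & table$trait %in% traits, ]
  out <- data.frame(trait = traits, mean = NA_real_,
                    n_cells = NA_integer_, n_missing = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(traits)) {
    tr <- sub[sub$trait == traits[i], ]
    if (sum(!is.na(tr$value)) == 0L)
      stop("trait with zero observations: ", traits[i], call. = FALSE)
    for (a in accessions)
      if (!any(tr$accession_id == a & !is.na(tr$value)))
        stop("accession ", a, " has no observation for trait ", traits[i],
             call. = FALSE)
    if (method == "year_mean") {
      ym <- tapply(tr$value, tr$year, mean, na.rm = TRUE)
      out$mean[i] <- mean(ym[is.finite(ym)])
    } else {
      out$mean[i] <- mean(tr$value, na.rm = TRUE)
    }
    out$n_cells[i] <- sum(!is.na(tr$value))
    out$n_missing[i] <- sum(is.na(tr$value))
  }
  out
}

# per-subset objective machinery: value[accession, year] arrays per trait
pheno_arrays <- function(table, candidates, traits) {
  years <- sort(unique(table$year))
  lapply(stats::setNames(traits, traits), function(tr) {
    m <- matrix(NA_real_, length(candidates), length(years),
                dimnames = list(candidates, as.character(years)))
    sub <- table[table$trait == tr & table$accession_id %in% candidates, ]
    m[cbind(match(sub$accession_id, candidates), match(sub$year, years))] <- sub$value
    m
  })
}

subset_means <- function(arrays, idx) {
  vapply(arrays, function(m) {
    ym <- colMeans(m[idx, , drop = FALSE], na.rm = TRUE)
    mean(ym[is.finite(ym)])
  }, numeric(1))
}

selection_objective <- function(means, targets, weights) {
  sum(weights * ((means - targets) / targets)^2)
}

#' Reconstruct a k-accession selection matching recorded target means
#'
#' Searches for the subset of `k` candidate accessions whose combined-year
#' trait means best match recorded target means, minimising the weighted
#' relative squared deviation
#' `sum_t w_t * ((mean_t(subset) - target_t) / target_t)^2`.
#' All subsets are enumerated when `choose(n, k) <= max_exhaustive`;
#' otherwise a greedy construction followed by pairwise-swap local search
#' with seeded random restarts is used. Locked accessions are always
#' included.
#'
#' @param table long phenotype data frame.
#' @param k subset size.
#' @param targets named numeric vector of per-trait target means (names are
#'   trait names; all finite and positive).
#' @param weights optional named per-trait weights (default equal).
#' @param locked accession ids forced into the subset.
#' @param max_exhaustive largest number of subsets enumerated exhaustively
#'   (default 1e6).
#' @param n_restarts random restarts for the local search (default 10).
#' @param seed seed for the randomized restarts.
#' @return A `subset_solution`: list with `accessions`, `achieved_means`,
#'   `objective`, and a `trace` describing the solver path.
#' @export
reconstruct_selection <- function(table, k, targets, weights = NULL,
                                  locked = character(), max_exhaustive = 1e6,
                                  n_restarts = 10, seed = 1L) {
  traits <- names(targets)
  if (is.null(traits) || any(!is.finite(targets)) || any(targets <= 0))
    stop("targets must be a named vector of finite positive values", call. = FALSE)
  weights <- weights %||% stats::setNames(rep(1, length(targets)), traits)
  weights <- weights[traits]
  candidates <- sort(unique(table$accession_id[table$trait %in% traits]))
  n <- length(candidates)
  if (k > n) stop("k exceeds the number of candidate accessions", call. = FALSE)
  if (!all(locked %in% candidates) || length(locked) > k)
    stop("infeasible locked set", call. = FALSE)
  arrays <- pheno_arrays(table, candidates, traits)
  lock_idx <- match(locked, candidates)
  free <- setdiff(seq_len(n), lock_idx)
  n_free <- k - length(lock_idx)
  obj_of <- function(idx) selection_objective(subset_means(arrays, idx),
                                              targets, weights)
  if (choose(length(free), n_free) <= max_exhaustive) {
    combs <- utils::combn(free, n_free)
    best <- NULL; best_obj <- Inf
    for (j in seq_len(ncol(combs))) {
      idx <- c(lock_idx, combs[, j])
      o <- obj_of(idx)
      if (o < best_obj) { best_obj <- o; best <- idx }
    }
    trace <- list(method = "exhaustive", n_evaluated = ncol(combs), seed = seed)
  } else {
    search_one <- function(start_idx) {
      idx <- start_idx
      repeat {                                       # pairwise swaps to local optimum
        cur <- obj_of(idx)
        improved <- FALSE
        outside <- setdiff(free, idx)
        for (i_in in setdiff(idx, lock_idx)) {
          for (i_out in outside) {
            cand <- c(setdiff(idx, i_in), i_out)
            o <- obj_of(cand)
            if (o < cur - 1e-12) {
              idx <- cand; cur <- o; improved <- TRUE
              outside <- setdiff(free, idx)
              break
            }
          }
          if (improved) break
        }
        if (!improved) return(list(idx = idx, obj = cur))
      }
    }
    # greedy construction
    idx <- lock_idx
    while (length(idx) < k) {
      rest <- setdiff(free, idx)
      objs <- vapply(rest, function(i) obj_of(c(idx, i)), numeric(1))
      idx <- c(idx, rest[which.min(objs)])
    }
    best_run <- search_one(idx)
    iters <- 1L
    with_rng(seed, {
      for (r in seq_len(n_restarts)) {
        start <- c(lock_idx, sample(free, n_free))
        run <- search_one(start)
        iters <- iters + 1L
        if (run$obj < best_run$obj) best_run <- run
      }
    })
    best <- best_run$idx; best_obj <- best_run$obj
    trace <- list(method = "greedy+swap", n_restarts = n_restarts,
                  n_runs = iters, seed = seed)
  }
  chosen <- sort(candidates[best])
  structure(list(accessions = chosen,
                 achieved_means = subset_means(arrays, match(chosen, candidates)),
                 objective = best_obj,
                 targets = targets, weights = weights,
                 trace = trace),
            class = "subset_solution")
}

#' @export
print.subset_solution <- function(x, ...) {
  cat(sprintf("subset_solution: %d accessions, objective %.5g (%s)\n",
              length(x$accessions), x$objective, x$trace$method))
  m <- rbind(target = x$targets, achieved = x$achieved_means)
  print(round(m, 3))
  invisible(x)
}
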