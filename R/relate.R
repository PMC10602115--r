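# Pairwise relationship distances and accession assignment.
#
# Distances are Euclidean over the loci at which both vectors carry a call,
# rescaled by sqrt(total_loci / shared_loci) so sparser pairs are comparable
# with complete ones (the missing-data scaling used by stats::dist). With no
# missing data the scaled distance equals the plain Euclidean distance.

# squared scaled distances between rows of X and rows of Y (may be the same)
cross_dist2 <- function(X, Y, scale_missing = TRUE) {
  MX <- !is.na(X); MY <- !is.na(Y)
  X0 <- X; X0[!MX] <- 0
  Y0 <- Y; Y0[!MY] <- 0
  S <- MX %*% t(MY)                                   # shared locus counts
  D2 <- (X0 * X0) %*% t(MY) + MX %*% t(Y0 * Y0) - 2 * X0 %*% t(Y0)
  D2[D2 < 0] <- 0                                     # numerical noise
  if (scale_missing) D2 <- D2 * ncol(X) / S           # S = 0 -> Inf/NaN
  D2[S == 0] <- NA_real_
  attr(D2, "shared") <- S
  D2
}

#' Pairwise distance (relationship) matrix
#'
#' Euclidean distance computed over the loci where both items are
#' non-missing, scaled by `sqrt(total_loci / shared_loci)`. Item pairs that
#' share no called locus get a missing distance and a warning.
#'
#' @param x matrix of dosage or profile rows (genets and/or composite
#'   accession profiles); `NA` marks missing calls.
#' @param scale_missing apply the missing-data scaling (default `TRUE`;
#'   `FALSE` gives the raw complete-pair Euclidean distance).
#' @return A symmetric `distance_matrix` (square numeric matrix, zero
#'   diagonal) with a `shared` attribute holding shared-locus counts.
#' @export
pairwise_distance <- function(x, scale_missing = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 items", call. = FALSE)
  D2 <- cross_dist2(x, x, scale_missing)
  if (anyNA(D2)) warning("some item pairs share no called loci; distance set to NA")
  D <- sqrt(D2)
  diag(D) <- 0
  D <- (D + t(D)) / 2                                 # exact symmetry
  attr(D, "shared") <- attr(D2, "shared")
  class(D) <- c("distance_matrix", "matrix", "array")
  D
}

#' Assign query genets to their most related accession
#'
#' Ranks the composite accession profiles by ascending scaled Euclidean
#' distance from each query genet and records the first and second most
#' related accessions. Ties are broken lexicographically on accession id
#' (and reported via a message).
#'
#' @param queries a [dosage_matrix()] (or plain matrix) of query genets.
#' @param references an [accession_profiles()] object (or profile matrix)
#'   restricted, if desired, to the allowed candidate accessions.
#' @param per_genet optional list with `dosage` (member-genet
#'   [dosage_matrix()]) and `membership` (genet-to-accession data frame);
#'   when given, the minimum distance over each accession's member genets
#'   is reported as a secondary output (`nearest_genet_accession`,
#'   `nearest_genet_distance`, and `best_min_genet_distance` for the
#'   assigned accession's members).
#' @return Data frame with one row per query: `query_id`, `best_accession`,
#'   `best_distance`, `second_accession`, `second_distance`,
#'   `n_shared_loci_best`, `tie`, `unassigned` (plus the per-genet columns
#'   when requested). Queries sharing no loci with any reference are
#'   flagged `unassigned`.
#' @export
assign_genets <- function(queries, references, per_genet = NULL) {
  Q <- as.matrix(queries)
  P <- if (inherits(references, "accession_profiles")) references$mean_dosage
       else as.matrix(references)
  if (nrow(P) < 1L) stop("need at least one reference profile", call. = FALSE)
  ord_ref <- order(rownames(P))
  P <- P[ord_ref, , drop = FALSE]                     # lexicographic tie-break
  D2 <- cross_dist2(Q, P)
  S <- attr(D2, "shared")
  n <- nrow(Q)
  res <- data.frame(query_id = rownames(Q),
                    best_accession = NA_character_, best_distance = NA_real_,
                    second_accession = NA_character_, second_distance = NA_real_,
                    n_shared_loci_best = NA_integer_,
                    tie = FALSE, unassigned = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- D2[i, ]
    if (all(is.na(d))) { res$unassigned[i] <- TRUE; next }
    o <- order(d, na.last = TRUE)                     # rownames pre-sorted
    res$best_accession[i] <- rownames(P)[o[1]]
    res$best_distance[i] <- sqrt(d[o[1]])
    res$n_shared_loci_best[i] <- S[i, o[1]]
    if (nrow(P) >= 2L && !is.na(d[o[2]])) {
      res$second_accession[i] <- rownames(P)[o[2]]
      res$second_distance[i] <- sqrt(d[o[2]])
      res$tie[i] <- isTRUE(all.equal(unname(d[o[1]]), unname(d[o[2]])))
    }
  }
  if (any(res$tie))
    message(sum(res$tie), " query/queries had tied best distances; ",
            "lexicographically smaller accession chosen")
  if (any(res$unassigned))
    warning(sum(res$unassigned), " query/queries shared no loci with any reference")
  if (!is.null(per_genet)) {
    G <- as.matrix(per_genet$dosage)
    gacc <- per_genet$membership$accession_id[
      match(rownames(G), per_genet$membership$genet_id)]
    if (anyNA(gacc))
      stop("every member genet must appear in the membership table", call. = FALSE)
    D2g <- cross_dist2(Q, G)
    res$nearest_genet_accession <- NA_character_
    res$nearest_genet_distance <- NA_real_
    res$best_min_genet_distance <- NA_real_
    for (i in seq_len(n)) {
      d <- D2g[i, ]
      if (all(is.na(d))) next
      o <- order(d, gacc, na.last = TRUE)
      res$nearest_genet_accession[i] <- gacc[o[1]]
      res$nearest_genet_distance[i] <- sqrt(d[o[1]])
      own <- which(gacc == res$best_accession[i] & !is.na(d))
      if (length(own))
        res$best_min_genet_distance[i] <- sqrt(min(d[own]))
    }
  }
  res
}

#' Leave-one-out masking validation of accession assignment
#'
#' For each reference genet in turn, masks its accession label, recomputes
#' its own accession's composite profile without it, assigns the genet
#' against all composite profiles, and tallies whether the closest profile
#' is the true source accession. Accessions with a single genet cannot serve
#' as queries (their profile would be empty after masking) and are skipped
#' and counted separately.
#'
#' @param dosages a filtered [dosage_matrix()] of reference genets.
#' @param membership genet-to-accession data frame.
#' @return A `validation_result`: list with `n_queries`, `n_correct`,
#'   `accuracy`, `n_skipped_singletons`, and the `per_query` assignment
#'   data frame.
#' @export
loo_validate <- function(dosages, membership) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  acc <- membership$accession_id[match(rownames(dosages), membership$genet_id)]
  if (anyNA(acc)) stop("all genets must have a membership record", call. = FALSE)
  accs <- sort(unique(acc))
  if (length(accs) < 2L) stop("need at least 2 accessions", call. = FALSE)
  dos <- unclass(dosages)
  L <- ncol(dos)
  grp <- factor(acc, levels = accs)
  called <- !is.na(dos)
  dos0 <- dos; dos0[!called] <- 0
  sums <- rowsum(dos0, grp)
  cnts <- rowsum(called + 0L, grp)
  prof <- sums / cnts; prof[cnts == 0L] <- NA_real_
  sizes <- as.integer(table(grp))
  names(sizes) <- accs
  singleton <- sizes[acc] == 1L
  queries <- which(!singleton)
  D2 <- cross_dist2(dos, prof)                        # distances to static profiles
  per_query <- data.frame(query_id = rownames(dos)[queries],
                          true_accession = acc[queries],
                          best_accession = NA_character_,
                          best_distance = NA_real_,
                          correct = NA, stringsAsFactors = FALSE)
  acc_idx <- match(acc, accs)
  for (j in seq_along(queries)) {
    i <- queries[j]
    a <- acc_idx[i]
    q <- dos[i, ]
    qc <- called[i, ]
    # own-accession profile with this genet masked out
    cnt2 <- cnts[a, ] - qc
    p2 <- (sums[a, ] - dos0[i, ]) / cnt2
    p2[cnt2 == 0] <- NA_real_
    sh <- qc & !is.na(p2)
    d2own <- if (any(sh)) sum((q[sh] - p2[sh])^2) * L / sum(sh) else NA_real_
    d <- D2[i, ]
    d[a] <- d2own
    if (all(is.na(d))) next
    o <- order(d, na.last = TRUE)
    per_query$best_accession[j] <- accs[o[1]]
    per_query$best_distance[j] <- sqrt(d[o[1]])
    per_query$correct[j] <- accs[o[1]] == acc[i]
  }
  n_queries <- sum(!is.na(per_query$correct))
  n_correct <- sum(per_query$correct, na.rm = TRUE)
  structure(list(n_queries = n_queries,
                 n_correct = n_correct,
                 accuracy = n_correct / n_queries,
                 n_skipped_singletons = sum(singleton),
                 per_query = per_query),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("leave-one-out validation: %d/%d correct (%.2f%% accuracy), %d singleton genets skipped\n",
              x$n_correct, x$n_queries, 100 * x$accuracy, x$n_skipped_singletons))
  invisible(x)
}
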