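#' Greedy extraction of largest clusters
#'
#' Repeatedly finds the decoy A with the largest surviving neighbor set,
#' records A and its neighbors as the next ranked cluster, then removes those
#' decoys from the pool and from every other neighbor set. Ties on size are
#' broken toward the lowest decoy index so the output is deterministic.
#' Cluster sizes are the counts at extraction time; they need not be
#' non-increasing, since each removal shrinks later sets.
#'
#' @param neighbor_sets list of integer neighbor vectors from
#'   [find_neighbors()] or [neighbors_brute()] (must satisfy the symmetry
#'   invariant: X in N_Y iff Y in N_X).
#' @return An object of class `cluster_ranking`: `rounds`, a list of
#'   `list(rank, representative, members)` with disjoint member sets whose
#'   union is the input pool.
#' @export
extract_clusters <- function(neighbor_sets) {
    n <- length(neighbor_sets)
    if (n == 0L)
        stop("no decoys to rank")
    alive <- rep(TRUE, n)
    nb <- neighbor_sets
    sizes <- lengths(nb)
    rounds <- list()
    rank <- 0L
    while (any(alive)) {
        rank <- rank + 1L
        cand <- which(alive)
        a <- cand[which.max(sizes[cand])]   # which.max takes the first max
        members <- nb[[a]]
        rounds[[rank]] <- list(rank = rank, representative = a,
                               members = members)
        alive[members] <- FALSE
        # remove each Y in N_A from the neighbor set of every Z in N_Y
        for (y in members) {
            for (z in nb[[y]]) {
                if (alive[z]) {
                    nb[[z]] <- nb[[z]][nb[[z]] != y]
                    sizes[z] <- sizes[z] - 1L
                }
            }
        }
    }
    structure(list(rounds = rounds), class = "cluster_ranking")
}

#' @export
print.cluster_ranking <- function(x, ...) {
    cat("Cluster ranking:", length(x$rounds), "rounds\n")
    for (rd in head(x$rounds, 10L))
        cat(sprintf("  rank %d: decoy %d, size %d\n", rd$rank,
                    rd$representative, length(rd$members)))
    if (length(x$rounds) > 10L) cat("  ...\n")
    invisible(x)
}

#' Best decoy only, in linear memory
#'
#' Returns the first-round winner (the decoy with the most neighbors within
#' `d`) using only per-decoy neighbor counts; member lists are never
#' materialized, so memory stays linear in the set size. The winner and count
#' equal round 1 of [extract_clusters()].
#'
#' @param set a [decoy_set()].
#' @param grouping a `decoy_grouping` from [build_groups()].
#' @param metrics a `decoy_metrics` from [precompute_metrics()].
#' @param d threshold distance, Angstrom.
#' @param counters optional `case_counters`.
#' @param use_bounds,use_groups ablation switches (see [find_neighbors()]).
#' @return List with `index` (decoy index, lowest on ties) and `count`.
#' @export
best_decoy_only <- function(set, grouping, metrics, d, counters = NULL,
                            use_bounds = TRUE, use_groups = TRUE) {
    stopifnot(inherits(metrics, "decoy_metrics"))
    n <- metrics$n_decoys
    if (n == 0L)
        stop("no decoys to rank")
    best_i <- 0L
    best_c <- -1L
    for (a in seq_len(n)) {
        cnt <- length(.scan_one(a, grouping, metrics, d, counters,
                                use_bounds, use_groups))
        if (cnt > best_c) {
            best_c <- cnt
            best_i <- a
        }
    }
    list(index = best_i, count = best_c)
}
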