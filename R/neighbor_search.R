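#' Create a case-counter accumulator
#'
#' Tallies, per screening case, how many ordered pair decisions were resolved
#' without an exact RMSD (cases 1-5 of the group cascade; per-pair upper and
#' lower bounds) and how many needed the exact computation (`pair_exact`).
#' The ten decision tallies sum to the total number of ordered pair decisions
#' made. `n_exact_calls` additionally counts exact superpositions performed
#' (including center distances that decide whole groups).
#'
#' @return An environment of class `case_counters`.
#' @export
new_case_counters <- function() {
    e <- new.env(parent = emptyenv())
    for (f in c("case1", "case2_bound", "case2_exact", "case3_bound",
                "case3_exact", "case4", "case5", "pair_upper", "pair_lower",
                "pair_exact", "n_exact_calls"))
        assign(f, 0, envir = e)
    class(e) <- "case_counters"
    e
}

.bump <- function(counters, field, by = 1) {
    if (!is.null(counters))
        assign(field, get(field, envir = counters) + by, envir = counters)
    invisible(NULL)
}

#' Summarize case counters as a table
#'
#' @param counters a `case_counters` from [new_case_counters()].
#' @return A data.frame with columns `case`, `tally`, `percent` (share of all
#'   pair decisions), suitable for a tab-separated dump.
#' @export
counters_table <- function(counters) {
    stopifnot(inherits(counters, "case_counters"))
    fields <- c("case1", "case2_bound", "case2_exact", "case3_bound",
                "case3_exact", "case4", "case5", "pair_upper", "pair_lower",
                "pair_exact")
    tall <- vapply(fields, get, numeric(1), envir = counters)
    total <- sum(tall)
    data.frame(case = fields, tally = tall,
               percent = if (total > 0) 100 * tall / total else 0 * tall,
               row.names = NULL)
}

#' @export
print.case_counters <- function(x, ...) {
    print(counters_table(x))
    invisible(x)
}

# Vectorized per-pair screen of decoy a against decoys idx at threshold d.
# Order: reference upper bounds, rRMSD (accepts), reference lower bounds,
# signature distance (rejects), exact RMSD. Result equals the exact rule.
.pair_screen <- function(metrics, a, idx, d, counters = NULL,
                         use_bounds = TRUE) {
    res <- logical(length(idx))
    und <- seq_along(idx)
    if (use_bounds && length(und) > 0L) {
        ub <- .ref_ub(metrics, a, idx[und])
        acc <- ub <= d
        res[und[acc]] <- TRUE
        .bump(counters, "pair_upper", sum(acc))
        und <- und[!acc]
        if (length(und) > 0L) {
            rr <- .rrmsd_vec(metrics, a, idx[und])
            acc <- rr <= d
            res[und[acc]] <- TRUE
            .bump(counters, "pair_upper", sum(acc))
            und <- und[!acc]
        }
        if (length(und) > 0L) {
            lb <- .ref_lb(metrics, a, idx[und])
            rej <- lb > d
            .bump(counters, "pair_lower", sum(rej))
            und <- und[!rej]
        }
        if (length(und) > 0L) {
            sl <- .sig_lb(metrics, a, idx[und])
            rej <- sl > d
            .bump(counters, "pair_lower", sum(rej))
            und <- und[!rej]
        }
    }
    if (length(und) > 0L) {
        ex <- .rmsd_to(metrics$coords, a, idx[und])
        res[und] <- ex <= d
        .bump(counters, "pair_exact", length(und))
        .bump(counters, "n_exact_calls", length(und))
    }
    res
}

#' Decide whether two decoys are within threshold distance
#'
#' Applies the screening cascade for a single pair: reference-decoy upper
#' bounds, then rRMSD (either can accept), then reference lower bounds, then
#' the signature distance (either can reject); the exact C-alpha RMSD is
#' computed only when every bound is inconclusive. The result always equals
#' the exact comparison `ca_rmsd(x, y) <= d`.
#'
#' @param metrics a `decoy_metrics` from [precompute_metrics()].
#' @param x,y decoy indices.
#' @param d threshold distance, Angstrom (>= 0).
#' @param counters optional `case_counters` to update.
#' @param use_bounds logical; `FALSE` forces the exact computation.
#' @return Logical scalar.
#' @export
within_threshold <- function(metrics, x, y, d, counters = NULL,
                             use_bounds = TRUE) {
    stopifnot(inherits(metrics, "decoy_metrics"), d >= 0)
    .pair_screen(metrics, x, y, d, counters, use_bounds)
}

# Neighbor scan for a single decoy a: the (a)-(g) cascade over groups.
.scan_one <- function(a, grouping, metrics, d, counters, use_bounds,
                      use_groups) {
    if (!use_groups) {
        idx <- seq_len(metrics$n_decoys)
        return(idx[.pair_screen(metrics, a, idx, d, counters, use_bounds)])
    }
    r <- grouping$radius
    case1_ok <- (2 * r) <= d
    own <- grouping$assignment[a]
    out <- integer(0)
    for (g in seq_along(grouping$groups)) {
        grp <- grouping$groups[[g]]
        mem <- grp$members
        nm <- length(mem)
        # (a) A's own group: every member is within 2r <= d of A
        if (g == own && case1_ok) {
            .bump(counters, "case1", nm)
            out <- c(out, mem)
            next
        }
        ctr <- grp$center
        if (use_bounds) {
            # (b) any upper bound of d(A,C) <= d - r admits the whole group
            ub <- min(.ref_ub(metrics, a, ctr), .rrmsd_vec(metrics, a, ctr))
            if (ub <= d - r) {
                .bump(counters, "case2_bound", nm)
                out <- c(out, mem)
                next
            }
            # (c) any lower bound of d(A,C) > d + r rejects the whole group
            lb <- max(.ref_lb(metrics, a, ctr), .sig_lb(metrics, a, ctr))
            if (lb > d + r) {
                .bump(counters, "case3_bound", nm)
                next
            }
        }
        # (d) exact center distance
        dAC <- .rmsd_to(metrics$coords, a, ctr)
        .bump(counters, "n_exact_calls", 1)
        # (e)/(f) exact re-tests of Cases 2 and 3
        if (dAC + r <= d) {
            .bump(counters, "case2_exact", nm)
            out <- c(out, mem)
            next
        }
        if (dAC > d + r) {
            .bump(counters, "case3_exact", nm)
            next
        }
        # (g) per-member cascade using the recorded member-center distances
        in4 <- (dAC + grp$dist) <= d
        .bump(counters, "case4", sum(in4))
        rest <- !in4
        out5 <- rest & (abs(dAC - grp$dist) > d)
        .bump(counters, "case5", sum(out5))
        rest <- rest & !out5
        keep <- mem[in4]
        if (any(rest)) {
            sub <- mem[rest]
            keep <- c(keep, sub[.pair_screen(metrics, a, sub, d, counters,
                                             use_bounds)])
        }
        out <- c(out, keep)
    }
    sort(out)
}

#' Find all neighbor sets at threshold d
#'
#' For each decoy A, computes the neighbor set N_A of all decoys within
#' C-alpha RMSD `d` of A (A inclusive), iterating over auxiliary groups with
#' the five-case triangle-inequality cascade and bound pre-checks. The output
#' is set-equal to the brute-force all-pairs result for every decoy.
#'
#' @param set a [decoy_set()].
#' @param grouping a `decoy_grouping` from [build_groups()] (ignored when
#'   `use_groups = FALSE`).
#' @param metrics a `decoy_metrics` from [precompute_metrics()].
#' @param d threshold distance, Angstrom.
#' @param counters optional `case_counters`.
#' @param use_bounds,use_groups ablation switches for the two screening
#'   strategies; the result is identical either way.
#' @return List of sorted integer vectors, one per decoy, in decoy order.
#' @export
find_neighbors <- function(set, grouping, metrics, d, counters = NULL,
                           use_bounds = TRUE, use_groups = TRUE) {
    stopifnot(inherits(metrics, "decoy_metrics"))
    lapply(seq_len(metrics$n_decoys), .scan_one, grouping = grouping,
           metrics = metrics, d = d, counters = counters,
           use_bounds = use_bounds, use_groups = use_groups)
}

#' Brute-force neighbor sets
#'
#' The all-pairs ablation: computes every pairwise C-alpha RMSD and
#' thresholds. Used as the exactness oracle for [find_neighbors()].
#'
#' @param set a [decoy_set()].
#' @param d threshold distance, Angstrom.
#' @return List of sorted integer vectors, one per decoy.
#' @export
neighbors_brute <- function(set, d) {
    D <- .rmsd_pairwise_cpp(set$coords)
    lapply(seq_len(nrow(D)), function(i) which(D[i, ] <= d))
}
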