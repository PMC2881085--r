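#' Build auxiliary groups by the leader algorithm
#'
#' Partitions the decoys into groups of radius `r`: decoys are scanned in set
#' order; each is assigned to the first existing center (in creation order)
#' whose exact C-alpha RMSD to it is at most `r`, otherwise it becomes a new
#' center. The exact member-to-center distance is recorded for every member
#' (centers belong to their own group at distance 0).
#'
#' Lower-bound screening (signature and reference bounds) is used to skip
#' center candidates that cannot be within `r`; assignments are identical to
#' the unscreened algorithm because only provably-too-far centers are skipped
#' and acceptance always uses the exact distance.
#'
#' @param set a [decoy_set()].
#' @param r group radius, Angstrom (> 0). Use `d/2` so that two members of one
#'   group are guaranteed within `d` of each other.
#' @param metrics a `decoy_metrics` from [precompute_metrics()].
#' @param use_bounds logical; disable to run the naive unscreened scan.
#' @return An object of class `decoy_grouping`: `radius`, `centers` (decoy
#'   indices in creation order), `assignment` (group id per decoy), and
#'   `groups`, a list of `list(center, members, dist)` with `dist` the exact
#'   member-to-center RMSDs aligned with `members`.
#' @export
build_groups <- function(set, r, metrics, use_bounds = TRUE) {
    stopifnot(inherits(set, "decoy_set"), inherits(metrics, "decoy_metrics"))
    if (r <= 0)
        stop("group radius r must be positive")
    N <- set$n_decoys
    centers <- integer(0)
    assignment <- integer(N)
    gdist <- numeric(N)
    for (i in seq_len(N)) {
        assigned <- FALSE
        if (length(centers) > 0L) {
            cand <- centers
            if (use_bounds) {
                lb <- pmax(.sig_lb(metrics, i, cand),
                           .ref_lb(metrics, i, cand))
                cand <- cand[lb <= r]
            }
            for (ctr in cand) {           # creation order preserved
                dd <- .rmsd_to(metrics$coords, i, ctr)
                if (dd <= r) {
                    assignment[i] <- match(ctr, centers)
                    gdist[i] <- dd
                    assigned <- TRUE
                    break
                }
            }
        }
        if (!assigned) {
            centers <- c(centers, i)
            assignment[i] <- length(centers)
            gdist[i] <- 0
        }
    }
    groups <- lapply(seq_along(centers), function(g) {
        mem <- which(assignment == g)
        list(center = centers[g], members = mem, dist = gdist[mem])
    })
    structure(list(radius = r, centers = centers, assignment = assignment,
                   groups = groups),
              class = "decoy_grouping")
}

#' @export
print.decoy_grouping <- function(x, ...) {
    cat("Auxiliary grouping: ", length(x$groups), " groups of radius ",
        format(x$radius, digits = 4), " Angstrom over ",
        length(x$assignment), " decoys\n", sep = "")
    invisible(x)
}
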