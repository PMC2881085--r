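#' Filter outlier decoys before clustering
#'
#' Draws `sample_size` decoys uniformly without replacement (the whole set if
#' smaller) and keeps a decoy X iff some sampled decoy Q has
#' `ca_rmsd(X, Q) <= 2d`. Sampled decoys are always kept (distance 0 to
#' themselves). If every high-ranking decoy has at least 10 percent of the set
#' within d of it, a decoy within d of such a "good" decoy is within 2d of one
#' of its neighbors, and the chance that none of those neighbors lands in the
#' sample is 0.9^sample_size -- so retention exceeds 0.9999 at the default
#' sample size of 100.
#'
#' Signature lower bounds screen the exact computations (a pair whose
#' signature distance exceeds 2d cannot be within 2d), so the result equals
#' the exact rule.
#'
#' When the sample covers the whole set, keeping every sampled decoy would
#' make the filter a no-op; in that degenerate case self-matches are excluded
#' and a decoy is removed iff it is farther than 2d from every other decoy.
#'
#' @param set a [decoy_set()].
#' @param d clustering threshold, Angstrom (> 0).
#' @param sample_size number of sampled decoys (default 100).
#' @param seed optional integer for reproducible sampling.
#' @return List with `kept` and `removed` (decoy indices, increasing) and
#'   `sample` (the sampled indices).
#' @export
filter_outliers <- function(set, d, sample_size = 100L, seed = NULL) {
    stopifnot(inherits(set, "decoy_set"))
    if (d <= 0)
        stop("threshold d must be positive")
    if (!is.null(seed)) set.seed(seed)
    n <- set$n_decoys
    full <- n <= sample_size
    smp <- if (full) seq_len(n) else sample.int(n, sample_size)
    kept <- logical(n)
    if (!full) kept[smp] <- TRUE
    S <- matrix(0, set$n_residues, n)
    for (j in seq_len(n))
        S[, j] <- compute_signature(set$coords[, , j, drop = TRUE])
    lim <- 2 * d
    for (q in smp) {
        und <- which(!kept)
        und <- und[und != q]            # self never witnesses in full mode
        if (length(und) == 0L) next
        lb <- sqrt(colMeans((S[, und, drop = FALSE] - S[, q])^2))
        cand <- und[lb <= lim]
        if (length(cand) > 0L) {
            ex <- .rmsd_to(set$coords, q, cand)
            kept[cand[ex <= lim]] <- TRUE
        }
    }
    list(kept = which(kept), removed = which(!kept), sample = smp)
}
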