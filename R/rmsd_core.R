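#' Optimal rigid-body superposition of two C-alpha traces
#'
#' Finds the proper rotation and translation minimizing the root-mean-square
#' deviation between corresponding C-alpha atoms (Kabsch SVD solution, with
#' determinant sign correction so reflections are excluded). The optimal
#' translation brings the centroids of the two traces into coincidence.
#'
#' @param a,b [ca_trace()] objects (or n x 3 matrices) of equal length.
#' @return An object of class `superposition`: `rmsd` (Angstrom), `rotation`
#'   (3 x 3 proper rotation applied as `x \%*\% rotation`), `translation`
#'   (length-3 vector), such that `a` maps onto `b` via
#'   `a \%*\% rotation + translation`.
#' @export
superpose <- function(a, b) {
    A <- if (inherits(a, "ca_trace")) a$coords else as.matrix(a)
    B <- if (inherits(b, "ca_trace")) b$coords else as.matrix(b)
    if (nrow(A) != nrow(B))
        stop("cannot superpose traces of unequal length (", nrow(A),
             " vs ", nrow(B), ")")
    if (nrow(A) < 3L)
        stop("superposition needs at least 3 points")
    res <- .kabsch_cpp(A, B)
    structure(list(rmsd = res$rmsd, rotation = res$rotation,
                   translation = as.numeric(res$translation)),
              class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
    cat(sprintf("Superposition: RMSD %.4f Angstrom\n", x$rmsd))
    invisible(x)
}

#' C-alpha RMSD between two traces
#'
#' @inheritParams superpose
#' @return Non-negative scalar, Angstrom.
#' @export
ca_rmsd <- function(a, b) superpose(a, b)$rmsd

#' Centroid-distance signature of a trace
#'
#' The signature of a structure is the vector of per-residue distances to the
#' structure's centroid, in residue order (not sorted: the lower-bound proof
#' pairs residue k with residue k). It is invariant under rigid transforms.
#'
#' @param a a [ca_trace()] or n x 3 matrix.
#' @return Numeric vector of length n, Angstrom.
#' @export
compute_signature <- function(a) {
    A <- if (inherits(a, "ca_trace")) a$coords else as.matrix(a)
    cen <- colMeans(A)
    sqrt(rowSums(sweep(A, 2, cen)^2))
}

#' Distance between two signatures
#'
#' `sqrt(mean((v1 - v2)^2))`: the root-mean-square difference of per-residue
#' centroid distances. This is a lower bound of the C-alpha RMSD of the two
#' structures, because after optimal superposition the centroids coincide and
#' each per-residue deviation is at least the difference of the two centroid
#' distances.
#'
#' @param s1,s2 signatures from [compute_signature()], equal length.
#' @return Non-negative scalar, Angstrom.
#' @export
signature_distance <- function(s1, s2) {
    if (length(s1) != length(s2))
        stop("signatures have unequal length")
    sqrt(mean((s1 - s2)^2))
}

# Exact RMSD of decoy i against decoys idx, batched in C++.
.rmsd_to <- function(coords, i, idx) {
    if (length(idx) == 0L) return(numeric(0))
    as.numeric(.rmsd_one_to_many_cpp(coords, as.integer(i), as.integer(idx)))
}

#' All-pairs C-alpha RMSD matrix
#'
#' The brute-force quadratic computation; used by the `--brute-force` ablation
#' and as the exactness oracle for the accelerated pipeline.
#'
#' @param set a [decoy_set()].
#' @return Symmetric n_decoys x n_decoys matrix, Angstrom.
#' @export
pairwise_rmsd <- function(set) {
    stopifnot(inherits(set, "decoy_set"))
    D <- .rmsd_pairwise_cpp(set$coords)
    dimnames(D) <- list(set$names, set$names)
    D
}

#' Precompute per-decoy screening metrics
#'
#' For each decoy: its centroid-distance signature; its exact C-alpha RMSD to
#' each of `m_refs` reference decoys (giving triangle-inequality lower and
#' upper bounds for any pair); and its coordinates after optimal superposition
#' onto a fixed anchor (the first reference), from which the rRMSD upper bound
#' of any pair is a plain Euclidean RMS deviation with no further
#' superposition.
#'
#' References are chosen by a deterministic max-min spread: the first decoy,
#' the decoy farthest from it, then the decoy farthest from that one. Spread
#' references tighten the `|d(X,O) - d(Y,O)|` lower bounds.
#'
#' @param set a [decoy_set()].
#' @param m_refs number of reference decoys (clamped to the set size, with a
#'   warning, when larger).
#' @param seed unused by the default deterministic reference rule; accepted so
#'   callers can thread one seed through the pipeline.
#' @return An object of class `decoy_metrics`.
#' @export
precompute_metrics <- function(set, m_refs = 3L, seed = NULL) {
    stopifnot(inherits(set, "decoy_set"))
    N <- set$n_decoys
    n <- set$n_residues
    if (m_refs > N) {
        warning("m_refs = ", m_refs, " exceeds set size ", N, "; clamped")
        m_refs <- N
    }
    m_refs <- max(1L, as.integer(m_refs))
    coords <- set$coords

    sig <- matrix(0, n, N)
    for (j in seq_len(N))
        sig[, j] <- compute_signature(coords[, , j, drop = TRUE])

    refs <- integer(m_refs)
    refs[1] <- 1L
    ref_dist <- matrix(0, N, m_refs)
    ref_dist[, 1] <- .rmsd_to(coords, 1L, seq_len(N))
    if (m_refs > 1L) {
        for (k in 2:m_refs) {
            cand <- which.max(ref_dist[, k - 1L])
            refs[k] <- cand
            ref_dist[, k] <- .rmsd_to(coords, cand, seq_len(N))
        }
    }

    # Orient every decoy onto the anchor (first reference): center, rotate by
    # the Kabsch rotation, store as stacked 3n-vectors for fast column math.
    anchor <- refs[1]
    anc <- coords[, , anchor, drop = TRUE]
    anc_c <- sweep(anc, 2, colMeans(anc))
    oriented <- matrix(0, 3L * n, N)
    for (j in seq_len(N)) {
        P <- coords[, , j, drop = TRUE]
        Pc <- sweep(P, 2, colMeans(P))
        R <- .kabsch_cpp(Pc, anc_c)$rotation
        oriented[, j] <- as.numeric(Pc %*% R)
    }

    structure(list(coords = coords, signatures = sig, refs = refs,
                   ref_dist = ref_dist, oriented = oriented,
                   n_residues = n, n_decoys = N, names = set$names),
              class = "decoy_metrics")
}

#' @export
print.decoy_metrics <- function(x, ...) {
    cat("Decoy screening metrics: ", x$n_decoys, " decoys, ",
        length(x$refs), " reference decoys (anchor = ", x$refs[1], ")\n",
        sep = "")
    invisible(x)
}

#' rRMSD upper bound between two decoys
#'
#' The plain (no re-superposition) root-mean-square Euclidean deviation
#' between the stored anchor-oriented coordinates of two decoys. Because both
#' were independently superposed onto the same fixed anchor, this is an upper
#' bound of their C-alpha RMSD, and equals it exactly when one of the two is
#' the anchor.
#'
#' @param metrics a `decoy_metrics` object from [precompute_metrics()].
#' @param x,y decoy indices.
#' @return Non-negative scalar, Angstrom.
#' @export
rrmsd <- function(metrics, x, y) {
    stopifnot(inherits(metrics, "decoy_metrics"))
    d <- metrics$oriented[, x] - metrics$oriented[, y]
    sqrt(sum(d * d) / metrics$n_residues)
}

# Vectorized screening bounds of decoy a against decoys idx.
.sig_lb <- function(metrics, a, idx) {
    S <- metrics$signatures
    sqrt(colMeans((S[, idx, drop = FALSE] - S[, a])^2))
}

.ref_lb <- function(metrics, a, idx) {
    D <- metrics$ref_dist
    da <- D[a, ]
    apply(abs(sweep(D[idx, , drop = FALSE], 2, da)), 1, max)
}

.ref_ub <- function(metrics, a, idx) {
    D <- metrics$ref_dist
    da <- D[a, ]
    apply(sweep(D[idx, , drop = FALSE], 2, da, "+"), 1, min)
}

.rrmsd_vec <- function(metrics, a, idx) {
    O <- metrics$oriented
    sqrt(colSums((O[, idx, drop = FALSE] - O[, a])^2) / metrics$n_residues)
}
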