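# Independent oracles and small fixture builders. Everything here is written
# against the definitions, not against the package's code paths.

# Pure-R Kabsch superposition (oracle for the compiled kernel).
r_kabsch_rmsd <- function(A, B) {
    Ac <- sweep(A, 2, colMeans(A))
    Bc <- sweep(B, 2, colMeans(B))
    M <- crossprod(Ac, Bc)
    sv <- svd(M)
    s <- sign(det(sv$u) * det(sv$v))
    R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
    sqrt(mean(rowSums((Ac %*% R - Bc)^2)))
}

# Brute-force rotation-space oracle: minimize RMS deviation over a dense
# random sample of unit quaternions, then refine locally. Centroids are
# aligned, which is optimal for the translation.
.quat_to_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}

quat_grid_rmsd <- function(A, B, n_grid = 4000L, seed = 424242L) {
    Ac <- sweep(A, 2, colMeans(A))
    Bc <- sweep(B, 2, colMeans(B))
    msd <- function(q) mean(rowSums((Ac %*% .quat_to_rot(q) - Bc)^2))
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    qs <- matrix(rnorm(4L * n_grid), n_grid, 4L)
    vals <- apply(qs, 1, msd)
    best <- qs[which.min(vals), ]
    ref <- optim(best, msd, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    sqrt(min(ref$value, min(vals)))
}

# Rigid transform of a coordinate matrix: rotate about z by `angle` (degrees)
# and translate.
rigid_copy <- function(coords, angle = 37, shift = c(5, -2, 1)) {
    th <- angle * pi / 180
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    sweep(coords %*% R, 2, shift, "+")
}

# Naive leader clustering from a precomputed distance matrix.
naive_leader <- function(D, r) {
    n <- nrow(D)
    centers <- integer(0)
    assignment <- integer(n)
    for (i in seq_len(n)) {
        hit <- 0L
        for (g in seq_along(centers)) {
            if (D[i, centers[g]] <= r) { hit <- g; break }
        }
        if (hit == 0L) {
            centers <- c(centers, i)
            hit <- length(centers)
        }
        assignment[i] <- hit
    }
    list(centers = centers, assignment = assignment)
}

# Greedy ranking oracle that recomputes every neighbor count from the full
# pairwise matrix after each removal (no incremental bookkeeping).
naive_ranking <- function(D, d) {
    alive <- rep(TRUE, nrow(D))
    rounds <- list()
    while (any(alive)) {
        idx <- which(alive)
        counts <- vapply(idx, function(a) sum(D[a, idx] <= d), integer(1))
        a <- idx[which.max(counts)]
        members <- idx[D[a, idx] <= d]
        rounds[[length(rounds) + 1L]] <-
            list(representative = a, members = sort(members))
        alive[members] <- FALSE
    }
    rounds
}

# Flatten a cluster_ranking for element-for-element comparison.
ranking_signature <- function(ranking) {
    lapply(ranking$rounds, function(rd)
        list(rep = rd$representative, members = sort(rd$members)))
}

# A fixed, asymmetric 4-point toy pair for superposition tests.
toy_pair <- function() {
    A <- matrix(c(0, 0, 0,
                  3.8, 0, 0,
                  5.1, 3.2, 0.4,
                  7.7, 4.0, 2.9), 4, 3, byrow = TRUE)
    B <- matrix(c(0.2, -0.1, 0.3,
                  3.5, 1.0, -0.2,
                  4.6, 4.1, 1.0,
                  6.9, 5.2, 2.2), 4, 3, byrow = TRUE)
    list(A = A, B = B)
}

# Small random ensemble shared by several tests.
test_ensemble <- function(seed, n_clusters = 3L, members = 15L,
                          outliers = 3L, n_res = 30L, sigma = 0.8,
                          separation = 8) {
    make_ensemble(n_clusters = n_clusters, members_per_cluster = members,
                  n_outliers = outliers, n_residues = n_res,
                  noise_sigma = sigma, separation = separation, seed = seed)
}
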