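test_that("superposition is exact on identical and rigidly moved traces", {
    tr <- random_backbone(25, seed = 11)
    expect_lt(superpose(tr, tr)$rmsd, 1e-9)
    moved <- ca_trace(rigid_copy(tr$coords), "moved")
    expect_lt(ca_rmsd(tr, moved), 1e-8)

    sp <- superpose(tr, moved)
    # proper rotation: orthogonal, det +1
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    # the returned transform maps a onto b
    mapped <- sweep(tr$coords %*% sp$rotation, 2, sp$translation, "+")
    expect_equal(mapped, moved$coords, tolerance = 1e-7)

    expect_error(superpose(tr, random_backbone(24, seed = 1)),
                 "unequal length")
})

test_that("superposition agrees with a rotation-space grid oracle", {
    tp <- toy_pair()
    expect_equal(superpose(tp$A, tp$B)$rmsd, quat_grid_rmsd(tp$A, tp$B),
                 tolerance = 1e-6)
    # and with an independent pure-R Kabsch on random pairs
    set.seed(3)
    for (i in 1:5) {
        a <- random_backbone(15)$coords
        b <- random_backbone(15)$coords
        expect_equal(superpose(a, b)$rmsd, r_kabsch_rmsd(a, b),
                     tolerance = 1e-10)
    }
})

test_that("collinear degenerate input still returns a minimizer", {
    A <- cbind(seq(0, 3.8 * 4, by = 3.8), 0, 0)
    B <- rigid_copy(A, angle = 63, shift = c(1, 2, 3))
    expect_lt(superpose(A, B)$rmsd, 1e-8)
})

test_that("signatures are centroid distances, rigid-invariant, order-kept", {
    sq <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0), 4, 3, byrow = TRUE)
    expect_equal(compute_signature(sq), rep(1, 4), tolerance = 1e-12)

    tr <- random_backbone(18, seed = 21)
    shifted <- tr$coords + matrix(10, 18, 3)
    expect_equal(compute_signature(tr$coords), compute_signature(shifted),
                 tolerance = 1e-9)
    rot <- rigid_copy(tr$coords, angle = 120, shift = c(-3, 7, 0.5))
    expect_equal(compute_signature(tr$coords), compute_signature(rot),
                 tolerance = 1e-9)

    # naive double-loop oracle on a 5-point trace
    pts <- matrix(rnorm(15, sd = 4), 5, 3)
    cen <- colMeans(pts)
    naive <- vapply(1:5, function(i) sqrt(sum((pts[i, ] - cen)^2)),
                    numeric(1))
    expect_equal(compute_signature(pts), naive, tolerance = 1e-12)
})

test_that("signature distance matches its closed form and bounds the RMSD", {
    expect_identical(signature_distance(c(1, 1), c(1, 1)), 0)
    expect_equal(signature_distance(c(1, 1), c(3, 1)), sqrt(2),
                 tolerance = 1e-12)
    expect_error(signature_distance(1:3, 1:4), "unequal")

    # Lemma: signature distance <= exact RMSD, 200 random pairs
    ens <- test_ensemble(41, members = 10L, outliers = 4L, sigma = 1.5)
    set.seed(42)
    n <- ens$set$n_decoys
    for (k in 1:200) {
        ij <- sample.int(n, 2)
        a <- ens$set$decoys[[ij[1]]]
        b <- ens$set$decoys[[ij[2]]]
        sd <- signature_distance(compute_signature(a), compute_signature(b))
        expect_lte(sd, ca_rmsd(a, b) + 1e-9)
    }
})

test_that("C-alpha RMSD behaves as a metric on random triples", {
    ens <- test_ensemble(43, members = 8L, outliers = 4L, sigma = 2)
    D <- pairwise_rmsd(ens$set)
    expect_equal(D, t(D), tolerance = 1e-9)
    set.seed(7)
    n <- nrow(D)
    for (k in 1:200) {
        t3 <- sample.int(n, 3)
        expect_lte(D[t3[1], t3[3]],
                   D[t3[1], t3[2]] + D[t3[2], t3[3]] + 1e-7)
    }
    # invariance under simultaneous rigid transform of both inputs
    a <- ens$set$decoys[[1]]$coords
    b <- ens$set$decoys[[2]]$coords
    r0 <- superpose(a, b)$rmsd
    expect_equal(superpose(rigid_copy(a, 77, c(1, -9, 4)),
                           rigid_copy(b, 77, c(1, -9, 4)))$rmsd,
                 r0, tolerance = 1e-8)
})

test_that("precomputed metrics check out against direct recomputation", {
    ens <- test_ensemble(47, members = 10L, outliers = 2L)
    met <- precompute_metrics(ens$set, m_refs = 3)
    n <- ens$set$n_decoys
    expect_identical(met$refs[1], 1L)

    set.seed(9)
    for (k in sample.int(n, 15)) {
        for (r in seq_along(met$refs)) {
            expect_equal(met$ref_dist[k, r],
                         ca_rmsd(ens$set$decoys[[k]],
                                 ens$set$decoys[[met$refs[r]]]),
                         tolerance = 1e-9)
        }
    }

    # rRMSD: upper bound everywhere, exact against the anchor
    anchor <- met$refs[1]
    for (k in 1:100) {
        ij <- sample.int(n, 2)
        rr <- rrmsd(met, ij[1], ij[2])
        ex <- ca_rmsd(ens$set$decoys[[ij[1]]], ens$set$decoys[[ij[2]]])
        expect_gte(rr, ex - 1e-9)
    }
    for (k in sample.int(n, 10))
        expect_equal(rrmsd(met, k, anchor), met$ref_dist[k, 1],
                     tolerance = 1e-9)
    expect_identical(rrmsd(met, 4, 4), 0)
})

test_that("single-decoy metrics degenerate cleanly", {
    one <- decoy_set(list(random_backbone(12, seed = 3)))
    expect_warning(met <- precompute_metrics(one, m_refs = 3), "clamped")
    expect_identical(dim(met$ref_dist), c(1L, 1L))
    expect_equal(met$ref_dist[1, 1], 0, tolerance = 1e-12)
    centered <- sweep(one$coords[, , 1], 2, colMeans(one$coords[, , 1]))
    expect_equal(matrix(met$oriented[, 1], ncol = 3), centered,
                 tolerance = 1e-8)
})

test_that("bound sandwich holds on random pairs", {
    ens <- test_ensemble(53, members = 12L, outliers = 4L, sigma = 1.2)
    met <- precompute_metrics(ens$set, m_refs = 3)
    n <- ens$set$n_decoys
    set.seed(12)
    for (k in 1:150) {
        ij <- sample.int(n, 2)
        x <- ij[1]; y <- ij[2]
        ex <- ca_rmsd(ens$set$decoys[[x]], ens$set$decoys[[y]])
        sig_lb <- signature_distance(met$signatures[, x], met$signatures[, y])
        ref_lb <- max(abs(met$ref_dist[x, ] - met$ref_dist[y, ]))
        ref_ub <- min(met$ref_dist[x, ] + met$ref_dist[y, ])
        expect_lte(sig_lb, ex + 1e-9)
        expect_lte(ref_lb, ex + 1e-9)
        expect_gte(min(ref_ub, rrmsd(met, x, y)), ex - 1e-9)
    }
})
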