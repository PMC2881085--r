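# Uniform random proper rotation via a normalized quaternion.
.random_rotation <- function() {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}

.runit <- function() {
    repeat {
        v <- rnorm(3)
        nv <- sqrt(sum(v^2))
        if (nv > 1e-12) return(v / nv)
    }
}

#' Generate a protein-like random backbone
#'
#' A self-avoiding random walk with the consecutive C-alpha step length fixed
#' at 3.8 Angstrom and all non-consecutive pairs at least `min_sep` apart.
#' Step directions carry mild persistence (a bias toward the previous
#' direction) so chains extend instead of collapsing, which keeps the
#' self-avoidance rejection rate low.
#'
#' @param n_residues number of residues (>= 3).
#' @param seed optional integer; when given, the trace is reproducible.
#' @param step consecutive C-alpha distance, Angstrom.
#' @param min_sep minimum non-consecutive pair distance, Angstrom.
#' @param name identifier for the trace.
#' @param max_restarts,max_tries retry budget per walk and per step.
#' @return A [ca_trace()].
#' @export
random_backbone <- function(n_residues, seed = NULL, step = 3.8,
                            min_sep = 3.0, name = "backbone",
                            max_restarts = 100L, max_tries = 100L) {
    stopifnot(n_residues >= 3L)
    if (!is.null(seed)) set.seed(seed)
    for (restart in seq_len(max_restarts)) {
        pts <- matrix(0, n_residues, 3L)
        dir <- .runit()
        pts[2L, ] <- pts[1L, ] + step * dir
        ok <- TRUE
        for (i in seq_len(n_residues - 2L) + 2L) {
            placed <- FALSE
            for (try in seq_len(max_tries)) {
                prop <- dir + 0.8 * .runit()   # persistence keeps chains open
                prop <- prop / sqrt(sum(prop^2))
                p <- pts[i - 1L, ] + step * prop
                prev <- pts[seq_len(i - 2L), , drop = FALSE]
                if (min(sqrt(rowSums(sweep(prev, 2, p)^2))) >= min_sep) {
                    pts[i, ] <- p
                    dir <- prop
                    placed <- TRUE
                    break
                }
            }
            if (!placed) { ok <- FALSE; break }
        }
        if (ok) return(ca_trace(pts, name = name))
    }
    stop("random backbone generation failed after ", max_restarts,
         " restarts; relax min_sep or shorten the chain")
}

#' Generate a synthetic decoy ensemble with planted ground truth
#'
#' Emulates what a decoy clustering method sees: a few distinct conformations
#' each sampled many times with small coordinate noise, plus unrelated
#' outliers. `n_clusters` center backbones are drawn so that every pair is
#' farther than `separation` in C-alpha RMSD (rejection sampling); each member
#' perturbs its center with isotropic Gaussian noise (sd `noise_sigma` per
#' coordinate); outliers are independent random backbones, kept farther than
#' `separation` from every center and farther than `separation/2` from each
#' other, so they stay unclustered at thresholds up to a quarter of the
#' separation. Every decoy then
#' receives a random rigid transform (uniform rotation plus translation), so
#' clustering must be invariant to pose. The decoy order is shuffled.
#'
#' Defaults mirror a small but realistic planted-cluster scenario: 3
#' conformations of 30 residues, 30 members each, 0.5 Angstrom noise, 8
#' Angstrom separation.
#'
#' @param n_clusters number of planted clusters.
#' @param members_per_cluster decoys per cluster.
#' @param n_outliers unrelated decoys.
#' @param n_residues chain length.
#' @param noise_sigma per-coordinate Gaussian noise, Angstrom.
#' @param separation minimum center-center and center-outlier RMSD, Angstrom;
#'   must be well above `noise_sigma` for the ground truth to be recoverable.
#'   For 3.8 Angstrom-step random walks the default 8 needs chains of about
#'   30 residues to be reachable by rejection sampling.
#' @param seed optional integer for full reproducibility.
#' @param shuffle logical; permute decoy order (default TRUE).
#' @param max_tries rejection-sampling budget for separated backbones.
#' @return List with `set` (a [decoy_set()]), `labels` (integer vector aligned
#'   with the set: cluster id, or 0 for outliers), and `centers` (the
#'   unperturbed center traces).
#' @export
make_ensemble <- function(n_clusters = 3L, members_per_cluster = 30L,
                          n_outliers = 5L, n_residues = 30L,
                          noise_sigma = 0.5, separation = 8,
                          seed = NULL, shuffle = TRUE, max_tries = 200L) {
    if (!is.null(seed)) set.seed(seed)
    draw_separated <- function(others, minseps, nm) {
        for (try in seq_len(max_tries)) {
            cand <- random_backbone(n_residues, name = nm)
            ok <- all(vapply(seq_along(others), function(i)
                ca_rmsd(cand, others[[i]]) > minseps[i], logical(1)))
            if (ok) return(cand)
        }
        stop("could not draw a backbone farther than separation = ",
             separation, " from the existing ones; lower the separation ",
             "or lengthen the chain")
    }
    centers <- list()
    for (k in seq_len(n_clusters))
        centers[[k]] <- draw_separated(centers,
                                       rep(separation, length(centers)),
                                       sprintf("center%02d", k))

    traces <- list()
    labels <- integer(0)
    for (k in seq_len(n_clusters)) {
        for (m in seq_len(members_per_cluster)) {
            pts <- centers[[k]]$coords +
                matrix(rnorm(3L * n_residues, sd = noise_sigma),
                       n_residues, 3L)
            pts <- pts %*% .random_rotation() +
                matrix(runif(3, -20, 20), n_residues, 3L, byrow = TRUE)
            traces[[length(traces) + 1L]] <-
                ca_trace(pts, sprintf("c%02d_m%03d", k, m))
            labels <- c(labels, k)
        }
    }
    anti <- centers
    anti_sep <- rep(separation, length(centers))
    for (j in seq_len(n_outliers)) {
        out <- draw_separated(anti, anti_sep, sprintf("outlier%02d", j))
        anti[[length(anti) + 1L]] <- out
        anti_sep <- c(anti_sep, separation / 2)
        pts <- out$coords %*% .random_rotation() +
            matrix(runif(3, -20, 20), n_residues, 3L, byrow = TRUE)
        traces[[length(traces) + 1L]] <- ca_trace(pts, out$name)
        labels <- c(labels, 0L)
    }
    if (shuffle) {
        perm <- sample.int(length(traces))
        traces <- traces[perm]
        labels <- labels[perm]
    }
    list(set = decoy_set(traces), labels = labels, centers = centers)
}

#' Write a decoy set as PDB files plus a decoy list
#'
#' One PDB per decoy, a plain-text decoy list (one file name per line) and,
#' when labels are given, a sidecar `labels.json` mapping decoy names to
#' planted cluster ids (never stored in PDB fields).
#'
#' @param set a [decoy_set()].
#' @param dir output directory (created if missing).
#' @param labels optional integer labels aligned with the set.
#' @return List with `list_path`, `pdb_paths` and (if labels given)
#'   `labels_path`.
#' @export
write_decoy_set <- function(set, dir, labels = NULL) {
    stopifnot(inherits(set, "decoy_set"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- paste0(set$names, ".pdb")
    paths <- file.path(dir, files)
    for (j in seq_len(set$n_decoys))
        write_ca_pdb(set$decoys[[j]], paths[j])
    list_path <- file.path(dir, "decoys.list")
    writeLines(files, list_path)
    out <- list(list_path = list_path, pdb_paths = paths)
    if (!is.null(labels)) {
        labels_path <- file.path(dir, "labels.json")
        jsonlite::write_json(as.list(stats::setNames(as.integer(labels),
                                                     set$names)),
                             labels_path, auto_unbox = TRUE)
        out$labels_path <- labels_path
    }
    out
}
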