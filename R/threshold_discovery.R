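#' Default percentile for threshold discovery
#'
#' The heuristic percentile `min(100 * n^(-1/4), 10)`: with more decoys
#' available, a smaller share of pairwise distances suffices to define
#' "significantly related", which also speeds up the clustering. For example
#' the value is 10 at n = 10000 and 5 at n = 160000.
#'
#' @param n decoy count (>= 1).
#' @return Percent value in (0, 10].
#' @export
default_percentile <- function(n) {
    stopifnot(n >= 1)
    min(100 * n^(-1 / 4), 10)
}

# Pairwise RMSDs within one random sample of decoys (lower triangle).
.sample_pair_dists <- function(set, sample_size) {
    n <- set$n_decoys
    idx <- if (n <= sample_size) seq_len(n)
           else sample.int(n, sample_size)
    D <- .rmsd_pairwise_cpp(set$coords[, , idx, drop = FALSE])
    D[lower.tri(D)]
}

#' Percentile-based threshold discovery
#'
#' Estimates the distance d below which `x` percent of all pairwise C-alpha
#' RMSDs fall, from repeated small random samples instead of the full
#' quadratic matrix: each round draws `sample_size` decoys without
#' replacement, computes all within-sample pairwise RMSDs and takes their
#' x-percentile (linear interpolation between order statistics); the round
#' estimates are combined by their median. Around 10 samplings of 100 decoys
#' are enough to make this stable.
#'
#' @param set a [decoy_set()] with at least 2 decoys.
#' @param x percentile in (0, 100]; default [default_percentile()] of the set
#'   size.
#' @param n_rounds number of sampling rounds.
#' @param sample_size decoys per round (whole set if smaller).
#' @param seed optional integer; when given, makes the sampling reproducible.
#' @return Threshold distance, Angstrom.
#' @export
percentile_threshold <- function(set, x = NULL, n_rounds = 10L,
                                 sample_size = 100L, seed = NULL) {
    stopifnot(inherits(set, "decoy_set"))
    if (set$n_decoys < 2L)
        stop("cannot estimate threshold from a single decoy")
    if (is.null(x)) x <- default_percentile(set$n_decoys)
    stopifnot(x > 0, x <= 100)
    if (!is.null(seed)) set.seed(seed)
    est <- vapply(seq_len(n_rounds), function(i) {
        quantile(.sample_pair_dists(set, sample_size), x / 100,
                 names = FALSE, type = 7)
    }, numeric(1))
    median(est)
}

#' Exact percentile threshold (debug)
#'
#' Computes the x-percentile of the full pairwise RMSD matrix. Quadratic in
#' the set size; intended for small sets and for validating
#' [percentile_threshold()].
#'
#' @inheritParams percentile_threshold
#' @return Threshold distance, Angstrom.
#' @export
exact_percentile_threshold <- function(set, x = NULL) {
    stopifnot(inherits(set, "decoy_set"))
    if (set$n_decoys < 2L)
        stop("cannot estimate threshold from a single decoy")
    if (is.null(x)) x <- default_percentile(set$n_decoys)
    D <- .rmsd_pairwise_cpp(set$coords)
    quantile(D[lower.tri(D)], x / 100, names = FALSE, type = 7)
}

#' Mode-based threshold discovery
#'
#' Estimates the most frequently occurring pairwise C-alpha RMSD, f, from
#' sampled pairs (histogram with Freedman-Diaconis bin width; the mode is the
#' center of the densest bin) and returns `d = c * f + b`, where `b` is the
#' minimum pairwise distance seen during sampling. If the pairwise distances
#' are normally distributed, f corresponds to the 50th percentile, so `c`
#' rescales the typical distance down to a neighborhood radius.
#'
#' @inheritParams percentile_threshold
#' @param coef the coefficient c (default 2/3).
#' @return Threshold distance, Angstrom.
#' @export
mostfreq_threshold <- function(set, coef = 2 / 3, n_rounds = 10L,
                               sample_size = 100L, seed = NULL) {
    stopifnot(inherits(set, "decoy_set"))
    if (set$n_decoys < 2L)
        stop("cannot estimate threshold from a single decoy")
    if (!is.null(seed)) set.seed(seed)
    dists <- unlist(lapply(seq_len(n_rounds), function(i)
        .sample_pair_dists(set, sample_size)), use.names = FALSE)
    f <- .hist_mode(dists)
    coef * f + min(dists)
}

# Mode of a sample via a Freedman-Diaconis histogram; degenerate spreads
# (all values equal, or zero IQR) fall back to the median.
.hist_mode <- function(x) {
    rng <- range(x)
    bw <- 2 * IQR(x) / length(x)^(1 / 3)
    if (!is.finite(bw) || bw <= 0 || diff(rng) <= bw * 1e-9)
        return(median(x))
    nb <- max(1L, ceiling(diff(rng) / bw))
    edges <- seq(rng[1], rng[2], length.out = nb + 1L)
    counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                       nbins = nb)
    k <- which.max(counts)
    (edges[k] + edges[k + 1L]) / 2
}
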