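#' Cluster a decoy set and rank representatives by neighbor count
#'
#' Runs the full pipeline: threshold discovery (skipped when `d` is given),
#' outlier filtering, metric precomputation and auxiliary grouping, neighbor
#' search through the triangle-inequality cascade, and greedy extraction of
#' the largest clusters. With `brute_force = TRUE` all three acceleration
#' strategies are bypassed and the full pairwise RMSD matrix is thresholded;
#' the ranking is identical either way.
#'
#' @param input a [decoy_set()] or the path to a decoy list file.
#' @param d clustering threshold in Angstrom; `NULL` to auto-discover.
#' @param threshold_mode how to discover d when not given: `"percentile"`
#'   (default; see [percentile_threshold()]) or `"mostfreq"` (see
#'   [mostfreq_threshold()]).
#' @param percentile percentile x for the percentile mode; default
#'   [default_percentile()] of the set size.
#' @param n_rounds,sample_size sampling effort for threshold discovery, and
#'   `sample_size` also for the outlier filter.
#' @param mode_coef coefficient c of the mode-based rule `d = c f + b`.
#' @param filter logical; apply the outlier pre-filter.
#' @param n_top number of ranked decoys to report (default 3).
#' @param n_references number of reference decoys for the bound screening.
#' @param radius_factor group radius as a fraction of d (default 0.5; the
#'   whole-group self-acceptance of a decoy's own group is only sound at
#'   factors <= 0.5 and is disabled above).
#' @param brute_force logical; all-pairs ablation.
#' @param use_bounds,use_groups strategy ablation switches.
#' @param best_only logical; report only the top decoy, from neighbor counts
#'   alone (linear memory, no member lists).
#' @param seed integer seed driving all sampling (threshold discovery and
#'   filtering); same seed and input give byte-identical reports.
#' @param verbose logical; log per-step timing and counts.
#' @return An object of class `decoy_clustering` with fields `names`,
#'   `threshold`, `threshold_mode`, `ranking` (a `cluster_ranking`, `NULL` in
#'   best-only mode), `best` (best-only result or `NULL`), `filtered`
#'   (names of removed decoys), `counters`, `timings` and `n_top`.
#' @export
decoy_cluster <- function(input, d = NULL,
                          threshold_mode = c("percentile", "mostfreq"),
                          percentile = NULL, n_rounds = 10L,
                          sample_size = 100L, mode_coef = 2 / 3,
                          filter = TRUE, n_top = 3L, n_references = 3L,
                          radius_factor = 0.5, brute_force = FALSE,
                          use_bounds = TRUE, use_groups = TRUE,
                          best_only = FALSE, seed = NULL, verbose = FALSE) {
    threshold_mode <- match.arg(threshold_mode)
    set <- if (inherits(input, "decoy_set")) input else load_decoy_set(input)
    if (!is.null(seed)) set.seed(seed)
    say <- function(...) if (verbose) message(sprintf(...))
    tic <- function() proc.time()[["elapsed"]]
    timings <- c()

    # Step 1: threshold
    t0 <- tic()
    if (is.null(d)) {
        d <- switch(threshold_mode,
            percentile = percentile_threshold(set, x = percentile,
                                              n_rounds = n_rounds,
                                              sample_size = sample_size),
            mostfreq = mostfreq_threshold(set, coef = mode_coef,
                                          n_rounds = n_rounds,
                                          sample_size = sample_size))
        say("step 1: threshold d = %.4f A (%s mode)", d, threshold_mode)
    } else {
        threshold_mode <- "fixed"
        say("step 1: threshold d = %.4f A (given)", d)
    }
    timings["threshold"] <- tic() - t0

    # Step 2: outlier filter
    t0 <- tic()
    filtered_names <- character(0)
    if (filter) {
        fl <- filter_outliers(set, d, sample_size = sample_size)
        filtered_names <- set$names[fl$removed]
        say("step 2: filtered %d of %d decoys (%.1f%%)",
            length(fl$removed), set$n_decoys,
            100 * length(fl$removed) / set$n_decoys)
        if (length(fl$removed) > 0L)
            set <- subset_decoy_set(set, fl$kept)
    } else {
        say("step 2: filtering disabled")
    }
    timings["filter"] <- tic() - t0

    # Step 3: precompute metrics and auxiliary groups
    t0 <- tic()
    counters <- new_case_counters()
    metrics <- grouping <- NULL
    if (!brute_force) {
        metrics <- precompute_metrics(set, m_refs = n_references)
        if (use_groups)
            grouping <- build_groups(set, radius_factor * d, metrics,
                                     use_bounds = use_bounds)
        say("step 3: %d reference decoys%s", length(metrics$refs),
            if (use_groups) sprintf(", %d auxiliary groups",
                                    length(grouping$groups)) else "")
    }
    timings["precompute"] <- tic() - t0

    # Steps 4-5: neighbor search and ranking
    t0 <- tic()
    ranking <- NULL
    best <- NULL
    if (best_only && !brute_force) {
        best <- best_decoy_only(set, grouping, metrics, d,
                                counters = counters,
                                use_bounds = use_bounds,
                                use_groups = use_groups)
        say("step 4: best decoy %s with %d neighbors (best-only mode)",
            set$names[best$index], best$count)
    } else {
        nb <- if (brute_force) neighbors_brute(set, d)
              else find_neighbors(set, grouping, metrics, d,
                                  counters = counters,
                                  use_bounds = use_bounds,
                                  use_groups = use_groups)
        timings["neighbors"] <- tic() - t0
        t0 <- tic()
        ranking <- extract_clusters(nb)
        say("step 5: %d clusters extracted", length(ranking$rounds))
    }
    timings["ranking"] <- tic() - t0

    structure(list(names = set$names, threshold = d,
                   threshold_mode = threshold_mode, ranking = ranking,
                   best = best, filtered = filtered_names,
                   counters = counters, timings = timings,
                   n_top = as.integer(n_top)),
              class = "decoy_clustering")
}

#' @export
print.decoy_clustering <- function(x, ...) {
    cat(sprintf("Decoy clustering: %d decoys, threshold %.4f A (%s)\n",
                length(x$names), x$threshold, x$threshold_mode))
    if (length(x$filtered) > 0L)
        cat(sprintf("  %d decoys removed by outlier filter\n",
                    length(x$filtered)))
    if (!is.null(x$best)) {
        cat(sprintf("  best decoy: %s (%d neighbors)\n",
                    x$names[x$best$index], x$best$count))
    } else {
        for (rd in head(x$ranking$rounds, x$n_top))
            cat(sprintf("  rank %d: %s (cluster size %d)\n", rd$rank,
                        x$names[rd$representative], length(rd$members)))
    }
    invisible(x)
}
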