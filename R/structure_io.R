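#' Construct a C-alpha trace
#'
#' A `ca_trace` is the coordinate representation of one decoy: the ordered
#' C-alpha positions of its backbone, in Angstrom.
#'
#' @param coords numeric matrix, n x 3, one row per residue in backbone order.
#' @param name identifier string.
#' @return An object of class `ca_trace` with fields `name` and `coords`.
#' @export
ca_trace <- function(coords, name = "decoy") {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (ncol(coords) != 3L)
        stop("coords must have 3 columns (x, y, z)")
    if (nrow(coords) < 3L)
        stop("a C-alpha trace needs at least 3 residues (superposition is ",
             "underdetermined below 3 points)")
    if (!all(is.finite(coords)))
        stop("non-finite coordinates in trace '", name, "'")
    dimnames(coords) <- NULL
    structure(list(name = as.character(name), coords = coords),
              class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
    cat("C-alpha trace '", x$name, "': ", nrow(x$coords), " residues\n",
        sep = "")
    invisible(x)
}

#' Read a decoy list file
#'
#' One PDB path per line; blank lines and lines starting with `#` are ignored.
#' Relative paths are resolved against the directory of the list file.
#'
#' @param path path to the list file.
#' @return Character vector of file paths, in file order.
#' @export
read_decoy_list <- function(path) {
    if (!file.exists(path))
        stop("decoy list file not found: ", path)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L)
        stop("no decoys: decoy list '", path, "' contains no entries")
    base <- dirname(normalizePath(path))
    ifelse(grepl("^(/|~|[A-Za-z]:)", lines), lines, file.path(base, lines))
}

# PDB v3.3 fixed-width ATOM record fields; whitespace-split fallback when the
# fixed-width coordinate fields do not parse.
.parse_atom_line <- function(line, lineno, path) {
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                         substr(line, 39, 46),
                                         substr(line, 47, 54))))
    if (all(is.finite(xyz)))
        return(xyz)
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(toks))
    cand <- which(is.finite(num))
    # x,y,z are the three consecutive numeric tokens after serial/resseq
    if (length(cand) >= 3L) {
        for (k in cand) {
            if (k + 2L <= length(num) && all(is.finite(num[k:(k + 2L)])) &&
                !all(num[k:(k + 2L)] == round(num[k:(k + 2L)])))
                return(num[k:(k + 2L)])
        }
    }
    stop("unparseable coordinates at line ", lineno, " of ", path)
}

#' Parse the C-alpha trace of a PDB file
#'
#' Extracts one point per residue from ATOM records with atom name `CA`
#' (carbon, not calcium), first model only, alternate location blank or `A`.
#' Reading stops at the first TER of the first chain encountered: a decoy is
#' treated as a single backbone trace, and anything beyond the first chain is
#' ignored with a warning.
#'
#' @param path path to a PDB file.
#' @param name identifier for the trace; defaults to the file name.
#' @return A [ca_trace()].
#' @export
parse_ca_trace <- function(path, name = basename(path)) {
    if (!file.exists(path))
        stop("PDB file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    coords <- matrix(numeric(0), 0L, 3L)
    started <- FALSE
    truncated <- FALSE
    for (i in seq_along(lines)) {
        line <- lines[[i]]
        rec <- substr(line, 1, 6)
        if (rec == "ENDMDL") break                     # first model only
        if (startsWith(rec, "TER") && started) {       # first chain only
            truncated <- any(startsWith(substr(lines[-seq_len(i)], 1, 4),
                                        "ATOM"))
            break
        }
        if (!startsWith(rec, "ATOM")) next
        atom <- trimws(substr(line, 13, 16))
        if (atom != "CA") next
        if (atom == "CA" && trimws(substr(line, 77, 78)) == "CA") next  # calcium
        altloc <- substr(line, 17, 17)
        if (!(altloc %in% c(" ", "A", "")))
            next
        coords <- rbind(coords, .parse_atom_line(line, i, path))
        started <- TRUE
    }
    if (truncated)
        warning("multi-chain PDB '", path, "': only the first chain was read")
    if (nrow(coords) == 0L)
        stop("no CA atoms found in ", path)
    ca_trace(coords, name = name)
}

#' Write a C-alpha trace as a PDB file
#'
#' Emits one ATOM record per residue (atom `CA`, residue `ALA`, chain `A`),
#' 3-decimal coordinates, followed by TER and END.
#'
#' @param trace a [ca_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(trace, path) {
    stopifnot(inherits(trace, "ca_trace"))
    n <- nrow(trace$coords)
    recs <- sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(n), seq_len(n),
        trace$coords[, 1], trace$coords[, 2], trace$coords[, 3])
    writeLines(c(recs, "TER", "END"), path)
    invisible(path)
}

#' Construct a decoy set
#'
#' A named, ordered collection of equal-length C-alpha traces. Duplicate names
#' are disambiguated by appending an ordinal suffix.
#'
#' @param traces list of [ca_trace()] objects, all of the same length.
#' @return An object of class `decoy_set` with fields `decoys` (list of
#'   traces), `names`, `n_residues`, `n_decoys`, and `coords`
#'   (n_residues x 3 x n_decoys array used by the numeric kernels).
#' @export
decoy_set <- function(traces) {
    if (length(traces) == 0L)
        stop("no decoys")
    if (!all(vapply(traces, inherits, logical(1), "ca_trace")))
        stop("all elements must be ca_trace objects")
    n_res <- nrow(traces[[1]]$coords)
    for (tr in traces) {
        if (nrow(tr$coords) != n_res)
            stop("length mismatch: decoy '", traces[[1]]$name, "' has ",
                 n_res, " residues but '", tr$name, "' has ",
                 nrow(tr$coords))
    }
    nms <- vapply(traces, function(t) t$name, character(1))
    dup <- duplicated(nms)
    if (any(dup))
        nms[dup] <- paste0(nms[dup], "_", seq_len(sum(dup)))
    coords <- array(unlist(lapply(traces, function(t) t$coords),
                           use.names = FALSE),
                    dim = c(n_res, 3L, length(traces)))
    # unlist concatenates column-major per matrix, which matches array layout
    structure(list(decoys = traces, names = nms, n_residues = n_res,
                   n_decoys = length(traces), coords = coords),
              class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
    cat("Decoy set: ", x$n_decoys, " decoys x ", x$n_residues,
        " residues\n", sep = "")
    invisible(x)
}

#' Load a decoy set from a decoy list file
#'
#' Reads every PDB referenced by the list (see [read_decoy_list()]) and checks
#' that all traces match the first decoy's length.
#'
#' @param list_path path to the decoy list file.
#' @return A [decoy_set()], in list-file order.
#' @export
load_decoy_set <- function(list_path) {
    paths <- read_decoy_list(list_path)
    traces <- lapply(paths, parse_ca_trace)
    decoy_set(traces)
}

#' Subset a decoy set by index
#'
#' @param set a [decoy_set()].
#' @param idx integer indices of decoys to keep (order preserved).
#' @return A [decoy_set()] containing the selected decoys.
#' @export
subset_decoy_set <- function(set, idx) {
    stopifnot(inherits(set, "decoy_set"))
    decoy_set(set$decoys[idx])
}

#' Write a clustering report
#'
#' One line per ranked cluster: rank, representative decoy name, cluster size
#' and, optionally, the member names.
#'
#' @param result a `decoy_clustering` object from [decoy_cluster()].
#' @param file connection or path, `""` for stdout.
#' @param members logical; include member names.
#' @param n_top number of ranked clusters to report (default from the run).
#' @return Invisibly, the report lines.
#' @export
write_report <- function(result, file = "", members = FALSE, n_top = NULL) {
    stopifnot(inherits(result, "decoy_clustering"))
    rk <- result$ranking
    if (is.null(n_top)) n_top <- result$n_top
    keep <- seq_len(min(n_top, length(rk$rounds)))
    lines <- vapply(keep, function(i) {
        rd <- rk$rounds[[i]]
        ln <- sprintf("%d\t%s\t%d", rd$rank, result$names[rd$representative],
                      length(rd$members))
        if (members)
            ln <- paste0(ln, "\t",
                         paste(result$names[rd$members], collapse = " "))
        ln
    }, character(1))
    if (identical(file, "")) file <- stdout()
    writeLines(lines, file)
    invisible(lines)
}

#' Write a machine-readable clustering report
#'
#' One JSON object per ranked cluster (`rank`, `representative`, `size`,
#' `members`), newline-delimited.
#'
#' @inheritParams write_report
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(result, path, n_top = NULL) {
    stopifnot(inherits(result, "decoy_clustering"))
    rk <- result$ranking
    if (is.null(n_top)) n_top <- result$n_top
    keep <- seq_len(min(n_top, length(rk$rounds)))
    lines <- vapply(keep, function(i) {
        rd <- rk$rounds[[i]]
        jsonlite::toJSON(list(rank = rd$rank,
                              representative = result$names[rd$representative],
                              size = length(rd$members),
                              members = result$names[rd$members]),
                         auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
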