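test_that("decoy list reading keeps order, skips blanks and comments", {
    dir <- withr::local_tempdir()
    pdbs <- file.path(dir, paste0("d", 1:3, ".pdb"))
    file.create(pdbs)
    lst <- file.path(dir, "decoys.list")
    writeLines(c("d1.pdb", "", "# a comment", "d2.pdb", "  ", "d3.pdb"), lst)
    got <- read_decoy_list(lst)
    expect_length(got, 3L)
    expect_equal(basename(got), c("d1.pdb", "d2.pdb", "d3.pdb"))
    # relative paths resolve against the list file's directory
    expect_true(all(dirname(got) == normalizePath(dir)))

    writeLines(c("# only comments", ""), lst)
    expect_error(read_decoy_list(lst), "no decoys")
    expect_error(read_decoy_list(file.path(dir, "absent.list")), "not found")
})

test_that("PDB CA parsing reads back coordinates bit-equal", {
    dir <- withr::local_tempdir()
    pdb <- file.path(dir, "toy.pdb")
    writeLines(c(
        "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
        "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
        "ATOM      3  CA  GLY A   2       2.210   1.333   0.450  1.00  0.00",
        "ATOM      4  CB  GLY A   2       9.999   9.999   9.999  1.00  0.00",
        "ATOM      5  CA  SER A   3      -1.875   2.000  -3.210  1.00  0.00",
        "ATOM      6  CA  LEU A   4       0.125  -4.500   1.750  1.00  0.00",
        "TER", "END"), pdb)
    tr <- parse_ca_trace(pdb)
    expect_s3_class(tr, "ca_trace")
    expect_identical(nrow(tr$coords), 4L)
    expect_identical(tr$coords[1, ], c(1.458, 0, 0))
    expect_identical(tr$coords[3, ], c(-1.875, 2.000, -3.210))
})

test_that("altloc, model and chain conventions are honored", {
    dir <- withr::local_tempdir()
    pdb <- file.path(dir, "alt.pdb")
    writeLines(c(
        "ATOM      1  CA AALA A   1       1.000   0.000   0.000  1.00  0.00",
        "ATOM      2  CA BALA A   1       9.000   9.000   9.000  1.00  0.00",
        "ATOM      3  CA  GLY A   2       2.000   1.000   0.000  1.00  0.00",
        "ATOM      4  CA  SER A   3       3.000   2.000   1.000  1.00  0.00",
        "TER",
        "ATOM      5  CA  ALA B   1       7.000   7.000   7.000  1.00  0.00",
        "END"), pdb)
    expect_warning(tr <- parse_ca_trace(pdb), "first chain")
    expect_identical(nrow(tr$coords), 3L)   # altloc B dropped, chain B ignored
    expect_identical(tr$coords[1, 1], 1.0)

    multi <- file.path(dir, "multi.pdb")
    writeLines(c(
        "MODEL        1",
        "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00",
        "ATOM      2  CA  GLY A   2       2.000   1.000   0.000  1.00  0.00",
        "ATOM      3  CA  SER A   3       3.000   2.000   1.000  1.00  0.00",
        "ENDMDL",
        "MODEL        2",
        "ATOM      4  CA  ALA A   1       5.000   5.000   5.000  1.00  0.00",
        "ENDMDL", "END"), multi)
    expect_identical(nrow(parse_ca_trace(multi)$coords), 3L)

    empty <- file.path(dir, "noca.pdb")
    writeLines("ATOM      1  N   ALA A   1       0.000   0.000   0.000", empty)
    expect_error(parse_ca_trace(empty), "no CA atoms")
})

test_that("write -> parse round-trips at PDB coordinate precision", {
    dir <- withr::local_tempdir()
    tr <- random_backbone(20, seed = 5)
    p <- file.path(dir, "rt.pdb")
    write_ca_pdb(tr, p)
    back <- parse_ca_trace(p)
    expect_equal(back$coords, round(tr$coords, 3), tolerance = 1e-12)
    # idempotent: parse -> write -> parse is exact
    p2 <- file.path(dir, "rt2.pdb")
    write_ca_pdb(back, p2)
    expect_identical(parse_ca_trace(p2)$coords, back$coords)
})

test_that("decoy sets enforce equal lengths, unique names and list order", {
    dir <- withr::local_tempdir()
    ens <- test_ensemble(31, n_clusters = 2L, members = 4L, outliers = 1L)
    paths <- write_decoy_set(ens$set, dir, labels = ens$labels)
    loaded <- load_decoy_set(paths$list_path)
    expect_identical(loaded$n_decoys, ens$set$n_decoys)
    expect_identical(loaded$names, paste0(ens$set$names, ".pdb"))
    expect_identical(loaded$n_residues, ens$set$n_residues)

    # length mismatch is fatal and names both lengths
    short <- random_backbone(19, seed = 2, name = "short")
    write_ca_pdb(short, file.path(dir, "short.pdb"))
    lst <- readLines(paths$list_path)
    writeLines(c(lst, "short.pdb"), paths$list_path)
    expect_error(load_decoy_set(paths$list_path), "19")

    # duplicate names are disambiguated
    t1 <- random_backbone(10, seed = 1, name = "same")
    t2 <- random_backbone(10, seed = 2, name = "same")
    ds <- decoy_set(list(t1, t2))
    expect_identical(anyDuplicated(ds$names), 0L)
})

test_that("trace constructor rejects degenerate input", {
    expect_error(ca_trace(matrix(0, 2, 3)), "at least 3")
    expect_error(ca_trace(matrix(c(1, 2, NA, 4, 5, 6, 7, 8, 9), 3, 3)),
                 "non-finite")
    expect_error(decoy_set(list()), "no decoys")
})
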