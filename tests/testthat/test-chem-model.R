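# Readers/writers and substructure matching.

test_that("SDF round-trip preserves atoms, bonds, charges, properties and coordinates", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  ba <- gen_toy_ligand("benzoic_acid")
  ba$properties$program <- "Glide SP"
  ba$atoms$formal_charge[9L] <- -1L
  graphs <- list(ba, benzene_graph(), gen_toy_ligand("isoindoline_dione"))
  write_sdf(graphs, tmp)
  back <- read_sdf(tmp)
  expect_length(back, 3L)
  for (k in seq_along(graphs)) {
    expect_identical(back[[k]]$atoms$element, graphs[[k]]$atoms$element)
    expect_identical(back[[k]]$atoms$formal_charge,
                     graphs[[k]]$atoms$formal_charge)
    # bond multiset, exactly
    key <- function(g) sort(paste(pmin(g$bonds$i, g$bonds$j),
                                  pmax(g$bonds$i, g$bonds$j), g$bonds$order))
    expect_identical(key(back[[k]]), key(graphs[[k]]))
    expect_lt(max(abs(graph_coords(back[[k]]) - graph_coords(graphs[[k]]))),
              1e-4)
  }
  expect_identical(back[[1L]]$properties$program, "Glide SP")
})

test_that("benzene SDF reads as 6 C, 6 H and 6 aromatic ring bonds", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(benzene_graph(), tmp)
  g <- read_sdf(tmp)[[1L]]
  expect_equal(sum(g$atoms$element == "C"), 6L)
  expect_equal(sum(g$atoms$element == "H"), 6L)
  expect_equal(sum(g$bonds$order == "ar"), 6L)
})

test_that("empty SDF file gives an empty list; malformed counts line names the record", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", tmp)
  expect_length(read_sdf(tmp), 0L)
  writeLines(c("bad", "", "", "  X  3  0  0", "M  END", "$$$$"), tmp)
  expect_error(read_sdf(tmp), "record 1")
})

test_that("PDB reading builds the chain/residue hierarchy with author numbering", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N   ALA A 311      -1.200  -0.800   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A 311       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A 312       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  CYS A 314       7.600   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, tmp)
  p <- read_pdb(tmp)
  expect_s3_class(p, "protein_structure")
  expect_equal(sort(unique(p$atoms$resno)), c(311L, 312L, 314L))
  expect_equal(nrow(residue_atoms(p, "A", 311L)), 2L)
})

test_that("altloc duplicates keep the highest-occupancy copy, with a log message", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, tmp)
  expect_message(p <- read_pdb(tmp), "altloc")
  a1 <- residue_atoms(p, "A", 1L)
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$x, 1.0)
})

test_that("multi-MODEL PDB files map to trajectories and round-trip", {
  rec <- gen_receptor_with_pocket(1, 1, seed = 4)
  lig <- gen_toy_ligand("isoindoline_dione")
  spec <- trajectory_spec(n_frames = 5, sigma = 0.02, seed = 8,
                          planted = list(list(resno = 314L, occupancy = 0.6)))
  traj <- gen_trajectory(spec, rec$protein, lig)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, tmp)
  back <- read_trajectory(tmp, ligand_template = lig)
  expect_equal(n_frames(back), 5L)
  for (k in 1:5)  # PDB fixed columns carry 3 decimals
    expect_lt(max(abs(back$frames[[k]] - traj$frames[[k]])), 1e-3)
})

test_that("TRIPOS MOL2 reads elements, coordinates and aromatic flags", {
  tmp <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "toy", "4 3 1", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    "1 C1 0.0000 0.0000 0.0000 C.2 1 LIG 0.0000",
    "2 O1 1.2290 0.0000 0.0000 O.2 1 LIG 0.0000",
    "3 O2 -0.6150 1.0650 0.0001 O.3 1 LIG 0.0000",
    "4 C2 -0.7000 -1.2124 0.0000 C.ar 1 LIG 0.0000",
    "@<TRIPOS>BOND", "1 1 2 2", "2 1 3 1", "3 1 4 ar"), tmp)
  g <- read_mol2(tmp)
  expect_identical(g$atoms$element, c("C", "O", "O", "C"))
  expect_identical(g$bonds$order, c("2", "1", "ar"))
  expect_equal(g$atoms$x[2L], 1.229)
})

test_that("carboxylic-acid SMARTS finds 1 match in benzoic acid, 0 in benzene, 2 in phthalic acid", {
  patt <- "C(=O)[O;H1,-]"
  expect_length(match_substructure(gen_toy_ligand("benzoic_acid"), patt), 1L)
  expect_length(match_substructure(benzene_graph(), patt), 0L)
  expect_length(match_substructure(phthalic_acid_graph(), patt), 2L)
  expect_error(match_substructure(benzene_graph(), "C(=O"), "invalid SMARTS")
})

test_that("substructure matching equals brute-force enumeration on small graphs", {
  graphs <- list(gen_toy_ligand("benzoic_acid"), benzene_graph(),
                 phthalic_acid_graph(), gen_toy_ligand("isoindoline_dione"))
  patterns <- c("C(=O)[O;H1,-]", "c1ccccc1", "[O,N]", "C=O", "cC", "[O;H1]")
  for (g in graphs) {
    for (p in patterns) {
      got <- match_substructure(g, p)
      want <- brute_match(g, p)
      norm <- function(l) sort(vapply(l, paste, "", collapse = ","))
      expect_identical(norm(got), norm(want),
                       label = sprintf("%s vs %s", g$id, p))
    }
  }
})

test_that("halogen and charge primitives match as specified", {
  at <- data.frame(element = c("C", "Cl", "O", "O"),
                   x = c(0, 1.8, -1, -1.5), y = c(0, 0, 1, -0.8), z = 0,
                   formal_charge = c(0L, 0L, 0L, -1L))
  g <- molecular_graph("frag", at,
                       data.frame(i = c(1, 1, 1), j = c(2, 3, 4),
                                  order = c("1", "2", "1")))
  expect_length(match_substructure(g, "[Cl,Br,I]"), 1L)
  expect_length(match_substructure(g, "[O;-]"), 1L)
  expect_equal(match_substructure(g, "[O;-]")[[1L]], 4L)
})

test_that("graph validation rejects bad bonds and non-finite coordinates", {
  at <- data.frame(element = c("C", "O"), x = c(0, 1), y = 0, z = 0)
  expect_error(molecular_graph("x", at, data.frame(i = 1, j = 3, order = "1")),
               "out of range")
  expect_error(molecular_graph("x", at, data.frame(i = 1, j = 1, order = "1")),
               "self-bond")
  at$x[2] <- Inf
  expect_error(molecular_graph("x", at), "non-finite")
})
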