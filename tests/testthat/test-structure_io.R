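# Topology/Frame data model, PDB parsing and writing, parameter assignment.

test_that("minimal whitespace PDB record parses to a one-atom topology", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("ATOM 1 CA ALA A 1 0.0 0.0 0.0", f)
  parsed <- read_structure(f)
  expect_equal(n_atoms(parsed$topology), 1L)
  expect_equal(parsed$topology$residues$resname, "ALA")
  expect_equal(parsed$topology$residues$resseq, 1L)
  expect_length(parsed$frames, 1L)
  expect_equal(unname(parsed$frames[[1]]$coordinates), matrix(0, 1, 3))
})

test_that("MODEL/ENDMDL blocks become frames over one topology", {
  top <- point_topology(diag(3), resseqs = 1:3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(f, top, list(new_frame(diag(3)), new_frame(diag(3) + 1)))
  parsed <- read_structure(f)
  expect_length(parsed$frames, 2L)
  expect_equal(n_atoms(parsed$topology), 3L)
  expect_equal(parsed$topology$atoms$resseq, 1:3)
  expect_equal(unname(parsed$frames[[2]]$coordinates), diag(3) + 1,
               tolerance = 1e-9)
})

test_that("PDB write/read round trip preserves order, numbering and coords", {
  set.seed(11)
  coords <- matrix(runif(30, -50, 50), ncol = 3)
  top <- point_topology(coords, resnames = rep(c("VAL", "HOH"), each = 5),
                        resseqs = c(501:505, 9001:9005))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(f, top, new_frame(coords, box = c(60, 60, 60)))
  parsed <- read_structure(f)
  expect_equal(parsed$topology$atoms$resseq, top$atoms$resseq)
  expect_equal(parsed$topology$atoms$name, top$atoms$name)
  expect_true(all(parsed$topology$atoms$is_water[6:10]))
  # PDB stores 3 decimals
  expect_equal(unname(parsed$frames[[1]]$coordinates), unname(coords),
               tolerance = 1e-3)
  expect_equal(parsed$frames[[1]]$box, c(60, 60, 60))
})

test_that("malformed and inconsistent PDB input raises informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM 1 CA ALA A 1 0.0 0.0 0.0",
               "ATOM 2 CB ALA A xx 1.0 1.0"), f)
  expect_error(read_structure(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL 1",
               "ATOM 1 CA ALA A 1 0.0 0.0 0.0",
               "ATOM 2 CB ALA A 1 1.0 0.0 0.0",
               "ENDMDL",
               "MODEL 2",
               "ATOM 1 CA ALA A 1 0.0 0.0 0.0",
               "ENDMDL"), f2)
  expect_error(read_structure(f2), "inconsistent atom count")

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("CRYST1   30.000   30.000   30.000  90.00  90.00  60.00 P 1",
               "ATOM 1 CA ALA A 1 0.0 0.0 0.0"), f3)
  expect_error(read_structure(f3), "triclinic")
})

test_that("DCD round trip is bit-faithful within float32 precision", {
  sys <- build_mini_protein()
  gen <- generate_ensemble(sys, synthetic_truth(3, "wt", n_frames = 10,
                                                n_replicates = 1))
  tr <- gen$ensemble$replicates[[1]]
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, f)
  back <- read_trajectory(gen$topology, f)
  expect_equal(n_frames(back), 10L)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-4)
  expect_equal(back$box, tr$box, tolerance = 1e-12)
  expect_equal(back$times, tr$times, tolerance = 1e-6)
})

test_that("multi-model PDB trajectories honor the same Trajectory contract", {
  sys <- build_mini_protein()
  gen <- generate_ensemble(sys, synthetic_truth(3, "wt", n_frames = 4,
                                                n_replicates = 1))
  tr <- gen$ensemble$replicates[[1]]
  fd <- withr::local_tempfile(fileext = ".dcd")
  fp <- withr::local_tempfile(fileext = ".pdb")
  write_dcd(tr, fd)
  frames <- lapply(seq_len(4), function(i) trajectory_frame(tr, i))
  write_structure(fp, gen$topology, frames)
  via_dcd <- read_trajectory(gen$topology, fd)
  via_pdb <- read_trajectory(gen$topology, fp)
  expect_equal(n_frames(via_pdb), n_frames(via_dcd))
  expect_lt(max(abs(via_pdb$coords - via_dcd$coords)), 2e-3)
  expect_equal(via_pdb$box, via_dcd$box, tolerance = 1e-9)
})

test_that("degenerate trajectory input errors instead of passing silently", {
  sys <- build_mini_protein()
  f <- withr::local_tempfile(fileext = ".dcd")
  writeBin(raw(0), f)
  expect_error(read_dcd(sys$topology, f), "not a DCD")

  gen <- generate_ensemble(sys, synthetic_truth(3, "wt", n_frames = 3,
                                                n_replicates = 1))
  tr <- gen$ensemble$replicates[[1]]
  ok <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, ok)
  # atom-count mismatch against a smaller topology
  expect_error(read_dcd(sys$topology, ok), "does not match topology")
  # truncated file: drop the tail
  bytes <- readBin(ok, "raw", file.size(ok))
  trunc <- withr::local_tempfile(fileext = ".dcd")
  writeBin(bytes[seq_len(length(bytes) - 2000L)], trunc)
  expect_error(read_dcd(gen$topology, trunc), "truncated|frames")
})

test_that("assign_parameters fills published constants and unit masses", {
  # glycine with backbone + hydrogens: C2H5NO2
  atoms <- data.frame(
    serial = 1:10,
    name = c("N", "CA", "C", "O", "OXT", "H", "HA1", "HA2", "H2", "H3"),
    element = c("N", "C", "C", "O", "O", "H", "H", "H", "H", "H"),
    resname = "GLY", resseq = 1L, chain = "A", stringsAsFactors = FALSE)
  top <- assign_parameters(new_topology(atoms))
  expect_equal(top$atoms$vdw_radius[top$atoms$element == "C"][1], 1.70)
  hand_total <- 2 * 12.011 + 5 * 1.008 + 14.007 + 2 * 15.999
  expect_equal(sum(top$atoms$mass), hand_total, tolerance = 1e-9)

  top_unit <- assign_parameters(new_topology(atoms), masses = "unit")
  expect_true(all(top_unit$atoms$mass == 1))

  weird <- atoms
  weird$element[2] <- "XX"
  expect_warning(assign_parameters(new_topology(weird)), "fallback")
  expect_error(assign_parameters(new_topology(weird), strict = TRUE), "XX")
})

test_that("topology invariants hold: water flags, heavy flags, residue map", {
  sys <- build_mini_protein()
  gen <- generate_ensemble(sys, synthetic_truth(5, "wt", n_frames = 2,
                                                n_replicates = 1))
  top <- gen$topology
  expect_true(all(top$atoms$is_water == (top$atoms$resname %in%
                                           water_residue_names())))
  expect_true(all(top$atoms$is_heavy == (top$atoms$element != "H")))
  # every atom belongs to exactly one residue
  spans <- unlist(lapply(seq_len(nrow(top$residues)), function(i) {
    seq.int(top$residues$first[i], top$residues$last[i])
  }))
  expect_equal(sort(spans), seq_len(n_atoms(top)))
})
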