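# Neighborhood selection and Shrake-Rupley SASA.

test_that("neighborhood selection applies the closed <= cutoff criterion", {
  # residues at heavy-atom min distances 3, 7.9, 8.1 from the site
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 7.9, 0), c(8.1, 0, 0))
  top <- point_topology(coords, resseqs = c(647L, 10L, 11L, 12L))
  frame <- new_frame(coords)
  sel <- select_neighborhood(top, frame, 647L, cutoff = 8.0)
  expect_equal(sel$members$resseq, c(10L, 11L))
  # boundary value is included (closed interval)
  sel8.1 <- select_neighborhood(top, frame, 647L, cutoff = 8.1)
  expect_true(12L %in% sel8.1$members$resseq)
})

test_that("neighborhood degenerate and monotone behavior", {
  sys <- build_mini_protein()
  frame <- sys$reference
  expect_equal(nrow(select_neighborhood(sys$topology, frame, 647L,
                                        cutoff = 0)$members), 0L)
  expect_error(select_neighborhood(sys$topology, frame, 9999L), "not found")
  cuts <- c(2, 4, 6, 8, 12, 20)
  sizes <- vapply(cuts, function(cc) {
    nrow(select_neighborhood(sys$topology, frame, 647L, cutoff = cc)$members)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # determinism
  a <- select_neighborhood(sys$topology, frame, 647L)
  b <- select_neighborhood(sys$topology, frame, 647L)
  expect_identical(a$members, b$members)
  # the site itself is never a member
  expect_false(647L %in% a$members$resseq)
})

test_that("isolated-atom SASA matches the analytic sphere to 1%", {
  top <- point_topology(matrix(0, 1, 3))
  area <- shrake_rupley_sasa(new_frame(matrix(0, 1, 3)), top)
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(area - exact) / exact, 0.01)
  # convergence: doubling lattice points moves the estimate < 0.5%
  area2 <- shrake_rupley_sasa(new_frame(matrix(0, 1, 3)), top,
                              n_sphere_points = 1920L)
  expect_lt(abs(area2 - area) / exact, 0.005)
})

test_that("two intersecting spheres match the closed form to 2%", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  top <- point_topology(coords, resseqs = 1:2)
  areas <- shrake_rupley_sasa(new_frame(coords), top)
  exact <- two_sphere_sasa(1.7, 1.7, 1.4, 2.0)
  expect_lt(abs(sum(areas) - exact) / exact, 0.02)
})

test_that("a caged atom loses essentially all accessible area", {
  # icosahedral cage of large atoms around one carbon
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  verts <- verts / sqrt(1 + phi^2) * 3.4
  coords <- rbind(c(0, 0, 0), verts)
  top <- point_topology(coords, resseqs = seq_len(nrow(coords)),
                        element = "S")  # larger cage radii
  caged <- shrake_rupley_sasa(new_frame(coords), top, atom_subset = 1L)
  free <- 4 * pi * (1.8 + 1.4)^2
  expect_lt(caged / free, 0.01)
})

test_that("SASA respects the additivity bound on a random cluster", {
  set.seed(41)
  coords <- matrix(rnorm(30, sd = 2.5), ncol = 3)
  top <- point_topology(coords, resseqs = 1:10)
  areas <- shrake_rupley_sasa(new_frame(coords), top)
  expect_true(all(areas >= 0))
  expect_lte(sum(areas), 10 * 4 * pi * (1.7 + 1.4)^2 + 1e-9)
})

test_that("missing radii and empty subsets are errors", {
  atoms <- data.frame(serial = 1L, name = "CA", element = "C",
                      resname = "ALA", resseq = 1L, chain = "A",
                      stringsAsFactors = FALSE)
  top_bare <- new_topology(atoms)  # no assign_parameters
  expect_error(shrake_rupley_sasa(new_frame(matrix(0, 1, 3)), top_bare),
               "radius")
  sys <- build_mini_protein()
  expect_error(shrake_rupley_sasa(sys$reference, sys$topology,
                                  atom_subset = integer(0)), "empty")
})

test_that("per-residue SASA distributions honor the pooling contract", {
  sys <- build_mini_protein()
  gen <- generate_ensemble(sys, synthetic_truth(42, "wt", n_frames = 10,
                                                n_replicates = 2))
  sel <- select_neighborhood(sys$topology,
                             trajectory_frame(gen$ensemble$replicates[[1]], 1),
                             647L)
  dists <- residue_sasa_distributions(gen$ensemble, sel,
                                      n_sphere_points = 240L)
  post_eq <- 2 * (10 - floor(0.4 * 10))
  for (d in dists) expect_equal(d$n, post_eq)
  expect_equal(nrow(attr(dists, "samples")), post_eq * nrow(sel$members))
})

test_that("constant trajectories give zero-spread SASA distributions", {
  sys <- build_mini_protein()
  gen <- generate_ensemble(sys, synthetic_truth(43, "wt", n_frames = 5,
                                                n_replicates = 1,
                                                jitter_sigma = 0))
  sel <- select_neighborhood(sys$topology,
                             trajectory_frame(gen$ensemble$replicates[[1]], 1),
                             647L)
  dists <- residue_sasa_distributions(gen$ensemble, sel,
                                      n_sphere_points = 240L)
  for (d in dists) {
    expect_equal(d$sd, 0)
    expect_equal(d$median, d$samples[1])
    expect_equal(sum(d$histogram$counts), d$n)
  }
})

test_that("planted core opening raises SASA of the planted residues", {
  sys <- build_mini_protein()
  wt <- generate_ensemble(sys, synthetic_truth(44, "wt", n_frames = 40,
                                               n_replicates = 1))
  mut <- generate_ensemble(sys, synthetic_truth(10044, "mutant",
                                                n_frames = 40,
                                                n_replicates = 1))
  sel <- select_neighborhood(sys$topology,
                             trajectory_frame(wt$ensemble$replicates[[1]], 1),
                             647L)
  d_wt <- residue_sasa_distributions(wt$ensemble, sel, n_sphere_points = 240L)
  d_mut <- residue_sasa_distributions(mut$ensemble, sel,
                                      n_sphere_points = 240L)
  for (lab in c("V520", "Y588", "I658")) {
    expect_gt(d_mut[[lab]]$mean, d_wt[[lab]]$mean)
  }
})
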