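# Water RDFs, the cumulative difference statistic, and residue ranking.

make_profile <- function(g, dr = 1, residue = 1L) {
  structure(list(residue = residue, label = paste0("R", residue),
                 site_definition = "test",
                 bin_edges = seq(0, by = dr, length.out = length(g) + 1L),
                 g = g, sd = rep(0, length(g)),
                 g_replicates = matrix(g, ncol = 1), bulk_density = 0.033),
            class = "RDFProfile")
}

test_that("ideal-gas water yields g(r) = 1 within 3 SE beyond 1 A", {
  ens <- ideal_gas_ensemble(seed = 51, n_water = 600, box_edge = 30,
                            n_frames = 150)
  prof <- water_rdf(ens, 1L, r_max = 10, dr = 0.1)
  edges <- prof$bin_edges
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  rho <- 600 / 30^3
  # Poisson SE of the per-bin mean count, propagated to g
  se <- 1 / sqrt(150 * rho * 4 * pi * mids^2 * 0.1)
  keep <- mids > 1
  expect_true(all(abs(prof$g[keep] - 1) <= 3 * se[keep]))
  # normalization invariant: mean of g over [2, r_max] within 3 SE of 1
  win <- mids >= 2
  pooled_se <- sqrt(sum(se[win]^2)) / sum(win)
  expect_lt(abs(mean(prof$g[win]) - 1), 3 * pooled_se)
})

test_that("an empty shell below the placement radius gives exactly zero", {
  set.seed(52)
  n_w <- 300
  box <- 24
  top <- water_box_topology(n_w)
  site <- rep(box / 2, 3)
  # waters uniformly beyond r0 = 4 A from the site
  dirs <- matrix(rnorm(3 * n_w), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  radii <- (runif(n_w, 4^3, 11^3))^(1 / 3)
  coords <- array(NA_real_, dim = c(1 + n_w, 3, 2))
  for (f in 1:2) {
    coords[1, , f] <- site
    coords[-1, , f] <- sweep(dirs * radii, 2, site, `+`)
  }
  tr <- new_trajectory(top, coords, box = rep(box, 3))
  ens <- new_ensemble(list(tr), equilibration_fraction = 0, label = "shell")
  prof <- water_rdf(ens, 1L, r_max = 10, dr = 0.1)
  mids <- (prof$bin_edges[-1] + prof$bin_edges[-length(prof$bin_edges)]) / 2
  expect_true(all(prof$g[mids < 4] == 0))
  expect_gt(sum(prof$g[mids > 4]), 0)
})

test_that("binned counts match a brute-force minimum-image double loop", {
  set.seed(53)
  box <- c(20, 24, 28)
  site <- c(1, 22, 5)  # near a corner so images matter
  pts <- cbind(runif(100, 0, box[1]), runif(100, 0, box[2]),
               runif(100, 0, box[3]))
  counts <- mutsolv:::cpp_rdf_hist(site, pts, box, 9, 0.1)
  expect_identical(counts, bf_min_image_counts(site, pts, box, 9, 0.1))
  expect_equal(sum(counts > 0) > 5, TRUE)

  # and the single-frame g equals the oracle counts under the shared
  # normalization, bin by bin
  n_w <- 100
  top <- water_box_topology(n_w)
  coords <- array(NA_real_, dim = c(1 + n_w, 3, 1))
  coords[1, , 1] <- site
  coords[-1, , 1] <- pts
  tr <- new_trajectory(top, coords, box = box)
  ens <- new_ensemble(list(tr), equilibration_fraction = 0, label = "x")
  prof <- water_rdf(ens, 1L, r_max = 9, dr = 0.1)
  mids <- (prof$bin_edges[-1] + prof$bin_edges[-length(prof$bin_edges)]) / 2
  rho <- n_w / prod(box)
  oracle_g <- bf_min_image_counts(site, pts, box, 9, 0.1) /
    (rho * 4 * pi * mids^2 * 0.1)
  expect_equal(prof$g, oracle_g, tolerance = 1e-12)
})

test_that("RDF preconditions are enforced", {
  ens <- ideal_gas_ensemble(seed = 54, n_water = 50, box_edge = 16,
                            n_frames = 2)
  expect_error(water_rdf(ens, 1L, r_max = 10), "half the smallest box edge")
  top <- point_topology(matrix(0, 1, 3))
  tr <- new_trajectory(top, array(0, c(1, 3, 2)), box = c(20, 20, 20))
  ens2 <- new_ensemble(list(tr), equilibration_fraction = 0, label = "dry")
  expect_error(water_rdf(ens2, 1L), "no water")
})

test_that("cumulative RDF difference obeys its algebraic contract", {
  a <- make_profile(c(1.0, 1.2, 0.8))
  b <- make_profile(c(1.0, 1.0, 1.0))
  # hand sum: 0 + 0.2 - 0.2 = 0
  expect_equal(rdf_difference_accumulation(a, b), 0)
  expect_equal(rdf_difference_accumulation(a, a), 0)

  set.seed(55)
  c1 <- make_profile(runif(40, 0.5, 1.5), dr = 0.25)
  c2 <- make_profile(runif(40, 0.5, 1.5), dr = 0.25)
  s <- rdf_difference_accumulation(c1, c2)
  expect_equal(rdf_difference_accumulation(c2, c1), -s)
  # additivity over disjoint bin ranges
  lo <- rdf_difference_accumulation(c1, c2, range = c(0, 4.99))
  hi <- rdf_difference_accumulation(c1, c2, range = c(5.01, 10))
  expect_equal(lo + hi, s, tolerance = 1e-12)

  expect_error(rdf_difference_accumulation(a, c1), "mismatched")
})

test_that("null contrast ranks degenerate to residue order with zero sums", {
  pair <- small_pair(56, n_frames = 12L)
  wt <- pair$wt$ensemble
  top <- mutsolv:::ensemble_topology(wt)
  sel <- select_neighborhood(top, trajectory_frame(wt$replicates[[1]], 1),
                             647L)
  tab <- rank_residues_by_rdf_shift(wt, wt, sel, top_n = 10)
  expect_true(all(tab$sum_delta_g == 0))
  expect_equal(tab$residue, sort(sel$members$resseq))
  expect_equal(tab$rank, seq_len(nrow(tab)))
  # top_n larger than the selection covers the whole table
  tab_all <- rank_residues_by_rdf_shift(wt, wt, sel, top_n = 99)
  expect_true(all(tab_all$in_top_n))
})

test_that("planted water enrichment is recovered and monotone in strength", {
  pair <- small_pair(57, n_frames = 60L)
  top <- mutsolv:::ensemble_topology(pair$wt$ensemble)
  sel <- select_neighborhood(top,
                             trajectory_frame(pair$wt$ensemble$replicates[[1]], 1),
                             647L)
  tab <- rank_residues_by_rdf_shift(pair$wt$ensemble, pair$mut$ensemble, sel)
  expect_setequal(tab$residue[tab$rank <= 3], c(520L, 588L, 658L))
  # planted residues have higher mutant water density: negative g_wt - g_mut
  expect_true(all(tab$sum_delta_g[tab$rank <= 3] < 0))

  # monotonicity in the enrichment factor at a planted residue
  sys <- pair$system
  strengths <- c(1, 2, 4)
  shift <- vapply(strengths, function(f) {
    mut <- generate_ensemble(sys, synthetic_truth(
      58, "mutant", n_frames = 40, n_replicates = 1,
      enrichment_factor = f, delta_rg = 0))
    wt <- generate_ensemble(sys, synthetic_truth(
      59, "wt", n_frames = 40, n_replicates = 1))
    abs(rdf_difference_accumulation(water_rdf(wt$ensemble, 520L),
                                    water_rdf(mut$ensemble, 520L)))
  }, numeric(1))
  expect_true(all(diff(shift) > 0))
})

test_that("ranking is invariant under replicate relabeling", {
  pair <- small_pair(60, n_frames = 20L)
  wt <- pair$wt$ensemble
  mut <- pair$mut$ensemble
  top <- mutsolv:::ensemble_topology(wt)
  sel <- select_neighborhood(top, trajectory_frame(wt$replicates[[1]], 1),
                             647L)
  tab1 <- rank_residues_by_rdf_shift(wt, mut, sel)
  wt_shuffled <- new_ensemble(wt$replicates[c(3, 1, 2)],
                              equilibration_fraction = wt$equilibration_fraction,
                              label = wt$label)
  tab2 <- rank_residues_by_rdf_shift(wt_shuffled, mut, sel)
  expect_equal(tab1$residue, tab2$residue)
  expect_equal(tab1$sum_delta_g, tab2$sum_delta_g, tolerance = 1e-12)
})
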