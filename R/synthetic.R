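# Synthetic solvated mini-protein ensembles with known planted ground truth.
#
# The generator states a toy version of the WT-vs-mutant contrast: a compact
# mini-protein whose mutation site sits at the center of a packed shell of
# labeled residues (the buried-tryptophan picture), explicit ideal-gas water
# at TIP3P bulk oxygen density, and a mutant mode that plants (a) a rigid
# inflation of the hydrophobic core's radius of gyration and (b) elevated
# water density inside a shell around designated residues. Water carries no
# water-water structure, so analytic expectations (flat g(r), exact planted
# enrichment relative to accessible volume) hold exactly in expectation.

#' Default residue specification for the synthetic mini-protein
#'
#' The mutation-site tryptophan (647) surrounded by the ten neighborhood
#' residues discussed throughout the analyses (author numbering), plus nine
#' distant glycine fillers that must stay outside the 8 A neighborhood.
#'
#' @return data.frame with `resname`, `resseq`, `role`
#'   (site/neighbor/filler)
#' @export
default_residue_spec <- function() {
  data.frame(
    resname = c("TRP",
                "ASP", "VAL", "ILE", "LYS", "TYR", "TYR", "LEU", "THR",
                "PHE", "ILE",
                rep("GLY", 9L)),
    resseq = c(647L,
               517L, 520L, 521L, 582L, 588L, 590L, 616L, 628L, 630L, 658L,
               901:909),
    role = c("site", rep("neighbor", 10L), rep("filler", 9L)),
    stringsAsFactors = FALSE
  )
}

#' Build a deterministic compact mini-protein
#'
#' Site-role residues are placed at the origin; neighbor-role residues on a
#' golden-spiral shell of radius 3.2 A with four pseudo-heavy atoms each
#' (one reaching 1.2 A inward, so that every residue pair - including
#' antipodal ones - has a heavy-atom contact within 4.5 A); filler residues
#' sit on a distant shell (13 A) outside any 8 A neighborhood of the site.
#' Geometry is pure arithmetic: the same spec always yields identical
#' coordinates.
#'
#' @param residue_spec data.frame as [default_residue_spec()]
#' @return list with `topology` (radii/masses assigned) and `reference`
#'   (a `Frame`, no box)
#' @export
build_mini_protein <- function(residue_spec = default_residue_spec()) {
  if (anyDuplicated(residue_spec$resseq)) {
    stop("duplicate residue_seq in residue specification")
  }
  if (is.null(residue_spec$role)) {
    residue_spec$role <- c("site", rep("neighbor", nrow(residue_spec) - 1L))
  }

  unit <- function(v) v / sqrt(sum(v^2))
  atoms <- list()
  coords <- list()
  serial <- 0L
  n_neigh <- sum(residue_spec$role == "neighbor")
  n_fill <- sum(residue_spec$role == "filler")
  neigh_dirs <- if (n_neigh > 0L) fibonacci_sphere(n_neigh)
  fill_dirs <- if (n_fill > 0L) fibonacci_sphere(max(n_fill, 2L))
  i_neigh <- 0L
  i_fill <- 0L

  for (k in seq_len(nrow(residue_spec))) {
    role <- residue_spec$role[k]
    if (role == "site") {
      center <- c(0, 0, 0)
      local <- rbind(c(0.00, 0.00, 0.00),
                     c(0.70, 0.00, 0.00),
                     c(-0.35, 0.61, 0.00),
                     c(-0.35, -0.61, 0.00))
      names4 <- c("CA", "CB", "N", "O")
      el4 <- c("C", "C", "N", "O")
    } else if (role == "neighbor") {
      i_neigh <- i_neigh + 1L
      dir <- neigh_dirs[i_neigh, ]
      center <- 3.2 * dir
      inward <- -dir
      # tangent frame
      t1 <- unit(if (abs(dir[3L]) < 0.9) c(-dir[2L], dir[1L], 0) else c(1, 0, 0))
      t2 <- unit(c(dir[2L] * t1[3L] - dir[3L] * t1[2L],
                   dir[3L] * t1[1L] - dir[1L] * t1[3L],
                   dir[1L] * t1[2L] - dir[2L] * t1[1L]))
      local <- rbind(c(0, 0, 0),
                     1.2 * inward,
                     0.8 * t1,
                     0.8 * t2)
      names4 <- c("CA", "CB", "N", "O")
      el4 <- c("C", "C", "N", "O")
    } else {
      i_fill <- i_fill + 1L
      dir <- fill_dirs[i_fill, ]
      center <- 13.0 * dir
      t1 <- unit(if (abs(dir[3L]) < 0.9) c(-dir[2L], dir[1L], 0) else c(1, 0, 0))
      local <- rbind(c(0, 0, 0), 0.8 * t1, -0.8 * t1)
      names4 <- c("CA", "N", "C")
      el4 <- c("C", "N", "C")
    }
    for (a in seq_len(nrow(local))) {
      serial <- serial + 1L
      atoms[[serial]] <- data.frame(
        serial = serial, name = names4[a], element = el4[a],
        resname = residue_spec$resname[k], resseq = residue_spec$resseq[k],
        chain = "A", stringsAsFactors = FALSE)
      coords[[serial]] <- center + local[a, ]
    }
  }
  topology <- new_topology(do.call(rbind, atoms))
  topology <- assign_parameters(topology)
  list(topology = topology,
       reference = new_frame(do.call(rbind, coords)))
}

#' Ground-truth parameter record for the synthetic generator
#'
#' Defaults state the emulated world at toy scale: 3 replicates of 500
#' frames spanning a nominal 1000 ns with the first 0.4 discarded as
#' equilibration (mirroring the 3 x 1 us / 0.4 us design of the full-scale
#' study), thermal jitter of 0.3 A, TIP3P bulk water-oxygen density 0.0334
#' per cubic Angstrom in a 30 A box, and - in mutant mode - a +0.8 A core
#' Rg inflation (the toy-scale analogue of the full-scale 8.847 -> 9.675 A
#' shift) plus threefold water enrichment within 4 A of residues 520, 588
#' and 658.
#'
#' @param seed integer RNG seed; identical seed + parameters give
#'   bit-identical trajectories
#' @param mode `"wt"` or `"mutant"`
#' @param core_residues residue ids of the hydrophobic core
#' @param delta_rg core Rg inflation in Angstrom applied in mutant mode
#' @param jitter_sigma isotropic per-atom Gaussian jitter SD, Angstrom
#' @param bulk_density bulk water-oxygen number density, Angstrom^-3
#' @param box_edge cubic box edge, Angstrom
#' @param enriched_residues residues receiving planted water enrichment in
#'   mutant mode
#' @param enrichment_factor local/bulk density ratio (>= 1) inside the
#'   enrichment shell
#' @param enrichment_radius shell radius around the residue center, Angstrom
#' @param n_frames frames per replicate
#' @param n_replicates number of replicates
#' @param equilibration_fraction fraction flagged as equilibration
#' @param duration_ns nominal total duration per replicate
#' @return object of class `SyntheticTruth`
#' @export
synthetic_truth <- function(seed, mode = c("wt", "mutant"),
                            core_residues = c(520L, 521L, 588L, 590L,
                                              616L, 630L, 658L),
                            delta_rg = 0.8,
                            jitter_sigma = 0.3,
                            bulk_density = 0.0334,
                            box_edge = 30.0,
                            enriched_residues = c(520L, 588L, 658L),
                            enrichment_factor = 3.0,
                            enrichment_radius = 4.0,
                            n_frames = 500L,
                            n_replicates = 3L,
                            equilibration_fraction = 0.4,
                            duration_ns = 1000) {
  mode <- match.arg(mode)
  if (mode == "wt") {
    enriched_residues <- integer(0)
    enrichment_factor <- 1.0
    delta_rg <- 0.0
  }
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (bulk_density <= 0 || box_edge <= 0) stop("invalid density/box")
  structure(list(seed = as.integer(seed), mode = mode,
                 core_residues = core_residues, delta_rg = delta_rg,
                 jitter_sigma = jitter_sigma, bulk_density = bulk_density,
                 box_edge = box_edge, enriched_residues = enriched_residues,
                 enrichment_factor = enrichment_factor,
                 enrichment_radius = enrichment_radius,
                 n_frames = as.integer(n_frames),
                 n_replicates = as.integer(n_replicates),
                 equilibration_fraction = equilibration_fraction,
                 duration_ns = duration_ns),
            class = "SyntheticTruth")
}

# Uniform points inside a sphere of radius R about `center`.
.runif_sphere <- function(n, center, R) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3L))
  d <- matrix(rnorm(3L * n), ncol = 3L)
  d <- d / sqrt(rowSums(d^2))
  r <- R * runif(n)^(1 / 3)
  sweep(d * r, 2L, center, `+`)
}

# Resample rows of `pts` violating the overlap rule until all are valid.
.reject_overlaps <- function(pts, resampler, protein_xyz, min_dist,
                             max_iter = 200L) {
  bad <- which(cpp_too_close(pts, protein_xyz, min_dist))
  it <- 0L
  while (length(bad) > 0L) {
    it <- it + 1L
    if (it > max_iter) {
      stop("water placement infeasible: density/box leave no room ",
           "outside the ", min_dist, " A exclusion zone")
    }
    pts[bad, ] <- resampler(length(bad))
    bad <- bad[cpp_too_close(pts[bad, , drop = FALSE], protein_xyz, min_dist)]
  }
  pts
}

#' Generate a solvated synthetic ensemble with planted ground truth
#'
#' Per frame: protein coordinates are the reference with the core rigidly
#' scaled about its (mass-weighted) centroid so the pre-jitter core Rg
#' equals the planted target, plus isotropic Gaussian jitter; water oxygens
#' are resampled uniformly in the box at bulk density, with a fixed number
#' of extra waters placed inside the enrichment shell of each enriched
#' residue so that the local density in the *accessible* part of the shell
#' is `enrichment_factor` times bulk (the accessible volume is estimated
#' once by Monte Carlo on the scaled reference). All placements reject
#' positions within 2 A of a protein heavy atom. The protein sits at the
#' box center; water count and atom order are identical in every frame.
#'
#' @param system list with `topology` and `reference` from
#'   [build_mini_protein()]
#' @param truth a [synthetic_truth()] record
#' @return list with `ensemble` (an `Ensemble`, label `"WT"` or `"W647R"`),
#'   `manifest` (truth parameters plus derived quantities: water counts,
#'   accessible shell volumes, scale factor) and `topology` (protein +
#'   water)
#' @export
generate_ensemble <- function(system, truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(truth$seed)
  prot_top <- system$topology
  L <- truth$box_edge
  box <- c(L, L, L)
  ref <- system$reference$coordinates
  ref <- sweep(ref, 2L, L / 2 - colMeans(ref), `+`)  # center in the box
  np <- nrow(ref)
  heavy_local <- select_atoms(prot_top, "protein_heavy")

  # plant the core Rg by rigid scaling about the core centroid
  core_idx <- unlist(lapply(truth$core_residues, function(r) {
    residue_atom_indices(prot_top, r, heavy_only = TRUE)
  }))
  core_w <- prot_top$atoms$mass[core_idx]
  rg_ref <- radius_of_gyration(ref[core_idx, , drop = FALSE], weights = core_w)
  target <- rg_ref + truth$delta_rg
  scale <- target / rg_ref
  centroid <- colSums(ref[core_idx, , drop = FALSE] * (core_w / sum(core_w)))
  scaled <- ref
  scaled[core_idx, ] <- sweep(sweep(ref[core_idx, , drop = FALSE], 2L,
                                    centroid) * scale, 2L, centroid, `+`)

  # water bookkeeping: fixed counts so the topology is frame-invariant
  rho <- truth$bulk_density
  n_bulk <- round(rho * prod(box))
  v_acc <- numeric(length(truth$enriched_residues))
  n_extra <- integer(length(truth$enriched_residues))
  enr_centers <- matrix(NA_real_, nrow = length(truth$enriched_residues),
                        ncol = 3L)
  if (length(truth$enriched_residues) > 0L) {
    for (i in seq_along(truth$enriched_residues)) {
      idx <- residue_atom_indices(prot_top, truth$enriched_residues[i],
                                  heavy_only = TRUE)
      enr_centers[i, ] <- colMeans(scaled[idx, , drop = FALSE])
      mc <- .runif_sphere(20000L, enr_centers[i, ], truth$enrichment_radius)
      frac <- mean(!cpp_too_close(mc, scaled[heavy_local, , drop = FALSE], 2.0))
      v_acc[i] <- frac * 4 / 3 * pi * truth$enrichment_radius^3
      n_extra[i] <- round((truth$enrichment_factor - 1) * rho * v_acc[i])
    }
  }
  n_water <- n_bulk + sum(n_extra)

  water_atoms <- data.frame(
    serial = np + seq_len(n_water),
    name = "O", element = "O", resname = "HOH",
    resseq = max(prot_top$atoms$resseq) + 1000L + seq_len(n_water),
    chain = "W", stringsAsFactors = FALSE)
  full_top <- new_topology(rbind(prot_top$atoms[, c("serial", "name", "element",
                                                    "resname", "resseq", "chain")],
                                 water_atoms))
  full_top <- suppressWarnings(assign_parameters(full_top))

  dt <- truth$duration_ns / truth$n_frames
  replicates <- vector("list", truth$n_replicates)
  for (rep_i in seq_len(truth$n_replicates)) {
    coords <- array(NA_real_, dim = c(np + n_water, 3L, truth$n_frames))
    for (f in seq_len(truth$n_frames)) {
      prot <- scaled + matrix(rnorm(np * 3L, sd = truth$jitter_sigma),
                              ncol = 3L)
      prot_heavy_xyz <- prot[heavy_local, , drop = FALSE]

      bulk <- matrix(runif(n_bulk * 3L, min = 0, max = L), ncol = 3L)
      bulk <- .reject_overlaps(
        bulk, function(n) matrix(runif(n * 3L, min = 0, max = L), ncol = 3L),
        prot_heavy_xyz, 2.0)

      extras <- matrix(numeric(0), ncol = 3L)
      for (i in seq_along(n_extra)) {
        if (n_extra[i] == 0L) next
        cen <- colMeans(prot[residue_atom_indices(prot_top,
                                                  truth$enriched_residues[i],
                                                  heavy_only = TRUE), ,
                             drop = FALSE])
        e <- .runif_sphere(n_extra[i], cen, truth$enrichment_radius)
        e <- .reject_overlaps(
          e, function(n) .runif_sphere(n, cen, truth$enrichment_radius),
          prot_heavy_xyz, 2.0)
        extras <- rbind(extras, e)
      }
      coords[, , f] <- rbind(prot, bulk, extras)
    }
    replicates[[rep_i]] <- new_trajectory(full_top, coords, box = box,
                                          times = (seq_len(truth$n_frames) - 1) * dt)
  }

  label <- if (truth$mode == "wt") "WT" else "W647R"
  ensemble <- new_ensemble(replicates,
                           equilibration_fraction = truth$equilibration_fraction,
                           label = label)
  manifest <- c(unclass(truth),
                list(n_bulk_water = n_bulk, n_extra_water = n_extra,
                     accessible_shell_volume_A3 = v_acc,
                     core_rg_reference_A = rg_ref,
                     core_rg_target_A = target,
                     core_scale_factor = scale,
                     n_protein_atoms = np, n_water_atoms = n_water,
                     package_version = as.character(packageVersion("mutsolv"))))
  list(ensemble = ensemble, manifest = manifest, topology = full_top)
}

#' Convenience wrapper: matched WT/mutant synthetic pair
#'
#' Builds one mini-protein and two ensembles with independent seeds derived
#' from `seed` (wild type: `seed`; mutant: `seed + 10000`).
#'
#' @param seed base seed
#' @param ... overrides forwarded to [synthetic_truth()] for both modes
#' @return list with `system`, `wt`, `mut` (each as [generate_ensemble()])
#' @export
synthetic_comparison <- function(seed, ...) {
  system <- build_mini_protein()
  wt <- generate_ensemble(system, synthetic_truth(seed, mode = "wt", ...))
  mut <- generate_ensemble(system,
                           synthetic_truth(seed + 10000L, mode = "mutant", ...))
  list(system = system, wt = wt, mut = mut)
}

#' Write a generated ensemble to disk (PDB topology + DCD replicates + manifest)
#'
#' @param generated result of [generate_ensemble()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix (default: the ensemble label, lower case)
#' @return named list of written paths, invisibly
#' @export
write_synthetic_ensemble <- function(generated, dir, prefix = NULL) {
  if (is.null(prefix)) prefix <- tolower(generated$ensemble$label)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  top_path <- file.path(dir, paste0(prefix, "_topology.pdb"))
  tr1 <- generated$ensemble$replicates[[1L]]
  write_structure(top_path, generated$topology,
                  new_frame(tr1$coords[, , 1L], box = tr1$box[1L, ]))
  dcd_paths <- vapply(seq_along(generated$ensemble$replicates), function(r) {
    p <- file.path(dir, sprintf("%s_rep%d.dcd", prefix, r))
    write_dcd(generated$ensemble$replicates[[r]], p)
    p
  }, character(1))
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(generated$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(topology = top_path, trajectories = dcd_paths,
                 manifest = manifest_path))
}
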