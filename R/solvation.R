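# Mutation-site neighborhood selection and per-residue SASA distributions.

#' Select the residue neighborhood of a mutation site
#'
#' Member residues are all non-water residues, other than the site itself,
#' with at least one heavy atom within `cutoff` (closed interval, `<=`) of
#' any heavy atom of the site residue in the basis frame. The basis frame
#' should be the shared reference (initial) structure so that wild-type and
#' mutant neighborhoods are comparable; the mutated residue itself differs
#' chemically between the systems and is therefore excluded from the
#' compared set.
#'
#' @param topology a `Topology`
#' @param basis_frame a `Frame` (typically the reference structure)
#' @param site_residue residue id: author `resseq`, or `"chain:resseq"`
#' @param cutoff neighborhood radius in Angstrom (default 8)
#' @param mode distance criterion: `"heavy_min"` (minimum heavy-atom pair
#'   distance, default) or `"calpha"` (CA-CA distance)
#' @return object of class `NeighborhoodSelection` with the site id, the
#'   cutoff, and `members`, a data.frame of `chain`, `resseq`, `resname`,
#'   `min_dist` ordered by `resseq`
#' @export
select_neighborhood <- function(topology, basis_frame, site_residue,
                                cutoff = 8.0,
                                mode = c("heavy_min", "calpha")) {
  mode <- match.arg(mode)
  site_row <- residue_row(topology, site_residue)
  xyz <- basis_frame$coordinates
  res <- topology$residues
  a <- topology$atoms

  group_coords <- function(row) {
    idx <- seq.int(res$first[row], res$last[row])
    if (mode == "heavy_min") {
      idx <- idx[a$is_heavy[idx]]
    } else {
      idx <- idx[trimws(a$name[idx]) == "CA"]
    }
    xyz[idx, , drop = FALSE]
  }
  site_xyz <- group_coords(site_row)
  if (nrow(site_xyz) == 0L) stop("site residue has no atoms under mode ", mode)

  candidate <- which(!(a$is_water[res$first]) & seq_len(nrow(res)) != site_row)
  dists <- vapply(candidate, function(row) {
    g <- group_coords(row)
    if (nrow(g) == 0L) return(Inf)
    cpp_min_group_dist(g, site_xyz)
  }, numeric(1))
  keep <- dists <= cutoff
  members <- data.frame(
    chain = res$chain[candidate[keep]],
    resseq = res$resseq[candidate[keep]],
    resname = res$resname[candidate[keep]],
    min_dist = dists[keep],
    stringsAsFactors = FALSE
  )
  members <- members[order(members$resseq), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(site = list(chain = res$chain[site_row],
                             resseq = res$resseq[site_row]),
                 cutoff = cutoff, mode = mode,
                 members = members, frame_basis = "reference"),
            class = "NeighborhoodSelection")
}

#' @export
print.NeighborhoodSelection <- function(x, ...) {
  cat(sprintf("Neighborhood of residue %d (cutoff %.1f A, %s): %d residues\n",
              x$site$resseq, x$cutoff, x$mode, nrow(x$members)))
  invisible(x)
}

# Deterministic golden-spiral lattice of n points on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by testing a
#' deterministic lattice of points on each atom's expanded sphere against
#' all neighboring solute heavy atoms. Water atoms and hydrogens are never
#' occluders and receive no area; periodic images are ignored (the solute
#' is assumed compact and far from its images).
#'
#' @param frame a `Frame`
#' @param topology a `Topology` with radii assigned ([assign_parameters()])
#' @param atom_subset indices of atoms whose area is wanted (default: all
#'   solute heavy atoms)
#' @param probe_radius probe radius in Angstrom (default 1.4, water-sized)
#' @param n_sphere_points lattice resolution (default 960)
#' @return numeric vector of per-atom areas (Angstrom^2), named by atom index
#' @export
shrake_rupley_sasa <- function(frame, topology, atom_subset = NULL,
                               probe_radius = 1.4, n_sphere_points = 960L) {
  heavy <- select_atoms(topology, "protein_heavy")
  if (is.null(atom_subset)) atom_subset <- heavy
  if (length(atom_subset) == 0L) stop("empty atom subset")
  if (!all(atom_subset %in% heavy)) {
    stop("atom subset must be solute heavy atoms")
  }
  radii <- topology$atoms$vdw_radius[heavy]
  if (anyNA(radii)) {
    bad <- heavy[is.na(radii)]
    stop("missing vdW radius for atom(s) ",
         paste(topology$atoms$name[bad], collapse = ", "),
         "; call assign_parameters() first")
  }
  coords <- frame$coordinates[heavy, , drop = FALSE]
  sub_local <- match(atom_subset, heavy)
  areas <- cpp_sasa(coords, radii, sub_local, fibonacci_sphere(n_sphere_points),
                    probe_radius)
  names(areas) <- atom_subset
  areas
}

#' Per-residue SASA distributions over an ensemble
#'
#' For every post-equilibration frame of every replicate, the per-atom
#' Shrake-Rupley areas of each neighborhood residue (occluded by the whole
#' solute) are summed into one per-residue SASA sample; samples are pooled
#' across replicates into one distribution per residue. Per-replicate
#' summaries are attached as the `"per_replicate"` attribute.
#'
#' @param ensemble an `Ensemble`
#' @param selection a `NeighborhoodSelection`
#' @param probe_radius,n_sphere_points see [shrake_rupley_sasa()]
#' @param nbins histogram bins for the summaries
#' @return named list (residue label, e.g. `"V520"`) of
#'   [summarize_distribution()] objects; attribute `"samples"` holds the
#'   long-format table (residue, replicate, time_ns, sasa_A2)
#' @export
residue_sasa_distributions <- function(ensemble, selection,
                                       probe_radius = 1.4,
                                       n_sphere_points = 960L,
                                       nbins = 30L) {
  topology <- ensemble_topology(ensemble)
  res_ids <- selection$members$resseq
  if (length(res_ids) == 0L) stop("neighborhood selection is empty")
  atom_idx <- lapply(res_ids, function(r) {
    residue_atom_indices(topology, r, heavy_only = TRUE)
  })
  subset <- unlist(atom_idx)
  res_of <- rep(seq_along(res_ids), lengths(atom_idx))
  sphere <- fibonacci_sphere(n_sphere_points)
  heavy <- select_atoms(topology, "protein_heavy")
  radii <- topology$atoms$vdw_radius[heavy]
  if (anyNA(radii)) stop("radii unassigned; call assign_parameters() first")
  sub_local <- match(subset, heavy)

  rows <- list()
  for (r in seq_along(ensemble$replicates)) {
    tr <- ensemble$replicates[[r]]
    frames <- analysis_frame_indices(tr, ensemble$equilibration_fraction)
    per_res <- matrix(NA_real_, nrow = length(frames), ncol = length(res_ids))
    for (k in seq_along(frames)) {
      f <- frames[k]
      areas <- cpp_sasa(tr$coords[heavy, , f], radii, sub_local, sphere,
                        probe_radius)
      per_res[k, ] <- as.numeric(tapply(areas, res_of, sum))
    }
    rows[[r]] <- data.frame(
      residue = rep(res_ids, each = length(frames)),
      replicate = r,
      time_ns = rep(tr$times[frames], times = length(res_ids)),
      sasa_A2 = as.numeric(per_res),
      stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, rows)

  labels <- vapply(res_ids, function(r) residue_label(topology, r), character(1))
  summaries <- setNames(lapply(seq_along(res_ids), function(i) {
    s <- long$sasa_A2[long$residue == res_ids[i]]
    summarize_distribution(s, observable = paste("SASA", labels[i]),
                           nbins = nbins)
  }), labels)
  per_rep <- do.call(rbind, lapply(split(long, list(long$residue, long$replicate)),
    function(d) data.frame(residue = d$residue[1L], replicate = d$replicate[1L],
                           mean = mean(d$sasa_A2), median = median(d$sasa_A2),
                           sd = sd(d$sasa_A2), n = nrow(d))))
  rownames(per_rep) <- NULL
  attr(summaries, "samples") <- long
  attr(summaries, "per_replicate") <- per_rep
  summaries
}
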