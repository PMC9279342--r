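# Hydrophobic classification of ranked residues, core contact check, and
# radius-of-gyration distributions.

#' Filter residues to the hydrophobic subset
#'
#' Order-preserving filter of residue ids by 3-letter residue name
#' membership in the hydrophobic classification set. Idempotent.
#'
#' @param residue_ids integer vector of author residue numbers
#' @param topology a `Topology`
#' @param hydrophobic_set 3-letter codes treated as hydrophobic
#'   (default [default_hydrophobic_set()])
#' @return the hydrophobic subset of `residue_ids`, in input order
#' @export
classify_hydrophobic <- function(residue_ids, topology,
                                 hydrophobic_set = default_hydrophobic_set()) {
  if (length(residue_ids) == 0L) return(integer(0))
  names_of <- vapply(residue_ids, function(r) {
    topology$residues$resname[residue_row(topology, r)]
  }, character(1))
  residue_ids[names_of %in% toupper(hydrophobic_set)]
}

#' Hydrophobic core definition
#'
#' @param residues residue ids forming the core
#' @param classification_set the hydrophobic set used to derive them
#' @param contact_cutoff heavy-atom contact distance in Angstrom
#' @return object of class `HydrophobicCore`
#' @export
hydrophobic_core <- function(residues,
                             classification_set = default_hydrophobic_set(),
                             contact_cutoff = 4.5) {
  structure(list(residues = residues,
                 classification_set = classification_set,
                 contact_cutoff = contact_cutoff),
            class = "HydrophobicCore")
}

#' Residue-residue contact graph
#'
#' Two residues are in contact when any heavy-atom pair distance is within
#' `cutoff` (closed interval). Also reports whether the contact graph forms
#' a single connected component, the qualitative signature of a packed core.
#'
#' @param frame a `Frame`
#' @param topology a `Topology`
#' @param residue_set residue ids
#' @param cutoff contact distance in Angstrom (default 4.5)
#' @return list with `contacts` (logical matrix), `distances` (minimum
#'   heavy-atom distances, Angstrom) and `connected` (logical)
#' @export
contact_graph <- function(frame, topology, residue_set, cutoff = 4.5) {
  n <- length(residue_set)
  if (n == 0L) stop("empty residue set")
  coords <- lapply(residue_set, function(r) {
    frame$coordinates[residue_atom_indices(topology, r, heavy_only = TRUE), ,
                      drop = FALSE]
  })
  d <- matrix(0, n, n, dimnames = list(residue_set, residue_set))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- d[j, i] <- cpp_min_group_dist(coords[[i]], coords[[j]])
    }
  }
  contacts <- d <= cutoff
  # connectivity by breadth-first search over the contact adjacency
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    i <- queue[1L]
    queue <- queue[-1L]
    nbr <- which(contacts[i, ] & !seen)
    seen[nbr] <- TRUE
    queue <- c(queue, nbr)
  }
  list(contacts = contacts, distances = d, connected = all(seen))
}

#' Radius of gyration of an atom selection
#'
#' `Rg = sqrt( sum_i w_i |x_i - xbar_w|^2 / sum_i w_i )` with `xbar_w` the
#' weighted centroid.
#'
#' @param coords N x 3 coordinate matrix (or a `Frame`)
#' @param selection optional atom indices (default: all rows)
#' @param weights per-atom weights over the selection (default uniform)
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(coords, selection = NULL, weights = NULL) {
  if (inherits(coords, "Frame")) coords <- coords$coordinates
  if (!is.null(selection)) coords <- coords[selection, , drop = FALSE]
  n <- nrow(coords)
  if (is.null(n) || n == 0L) stop("empty selection")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  centroid <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2L, centroid)^2)))
}

#' Radius-of-gyration distribution of a hydrophobic core over an ensemble
#'
#' One Rg sample (heavy atoms of the core residues) per post-equilibration
#' frame, pooled across replicates.
#'
#' @param ensemble an `Ensemble`
#' @param core a `HydrophobicCore` or vector of residue ids
#' @param weighting `"mass"` (default) or `"uniform"`
#' @param nbins histogram bins
#' @return a [summarize_distribution()] object; attribute `"samples"` holds
#'   the long table (replicate, time_ns, rg_A)
#' @export
rg_distribution <- function(ensemble, core, weighting = c("mass", "uniform"),
                            nbins = 30L) {
  weighting <- match.arg(weighting)
  topology <- ensemble_topology(ensemble)
  residues <- if (inherits(core, "HydrophobicCore")) core$residues else core
  idx <- unlist(lapply(residues, function(r) {
    residue_atom_indices(topology, r, heavy_only = TRUE)
  }))
  if (length(idx) == 0L) stop("core selection is empty")
  weights <- if (weighting == "mass") {
    m <- topology$atoms$mass[idx]
    if (anyNA(m)) stop("masses unassigned; call assign_parameters() first")
    m
  } else {
    rep(1, length(idx))
  }

  rows <- list()
  for (r in seq_along(ensemble$replicates)) {
    tr <- ensemble$replicates[[r]]
    frames <- analysis_frame_indices(tr, ensemble$equilibration_fraction)
    rg <- vapply(frames, function(f) {
      radius_of_gyration(tr$coords[idx, , f], weights = weights)
    }, numeric(1))
    rows[[r]] <- data.frame(replicate = r, time_ns = tr$times[frames],
                            rg_A = rg)
  }
  long <- do.call(rbind, rows)
  out <- summarize_distribution(long$rg_A,
                                observable = paste0("core Rg (", weighting, ")"),
                                nbins = nbins)
  attr(out, "samples") <- long
  out
}
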