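# Per-residue radial distribution functions of water and the cumulative
# RDF-difference ranking statistic.
#
# The RDF site is the per-frame heavy-atom center of geometry of the
# residue; distances to water oxygens use the orthorhombic minimum-image
# convention. Bin b spanning [r_b - dr/2, r_b + dr/2] is normalized by
# 4*pi*r_b^2*dr times the bulk water-oxygen number density (waters per box
# volume, per frame). g is computed per replicate, then averaged, with the
# per-bin SD taken across replicates.

#' Radial distribution function of water around one residue
#'
#' @param ensemble an `Ensemble` whose frames all carry a box
#' @param residue residue id (author `resseq` or `"chain:resseq"`)
#' @param r_max maximum radius in Angstrom (default 10); must not exceed
#'   half the smallest box edge (minimum-image validity)
#' @param dr bin width in Angstrom (default 0.1)
#' @return object of class `RDFProfile`: `residue`, `label`,
#'   `site_definition`, `bin_edges` (length nbins+1), `g` (mean over
#'   replicates), `sd` (across replicates), `g_replicates` (nbins x n_rep),
#'   `bulk_density` (mean, Angstrom^-3)
#' @export
water_rdf <- function(ensemble, residue, r_max = 10.0, dr = 0.1) {
  topology <- ensemble_topology(ensemble)
  site_idx <- residue_atom_indices(topology, residue, heavy_only = TRUE)
  if (length(site_idx) == 0L) stop("residue has no heavy atoms")
  wox <- select_atoms(topology, "water_oxygen")
  if (length(wox) == 0L) stop("no water oxygens in topology")

  nbins <- as.integer(round(r_max / dr))
  edges <- seq(0, by = dr, length.out = nbins + 1L)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  shell <- 4 * pi * mids^2 * dr

  g_rep <- matrix(NA_real_, nrow = nbins, ncol = length(ensemble$replicates))
  dens <- numeric(0)
  for (r in seq_along(ensemble$replicates)) {
    tr <- ensemble$replicates[[r]]
    if (anyNA(tr$box)) stop("RDF requires a box in every frame")
    frames <- analysis_frame_indices(tr, ensemble$equilibration_fraction)
    acc <- numeric(nbins)
    for (f in frames) {
      box <- tr$box[f, ]
      if (r_max > min(box) / 2) {
        stop(sprintf(
          "r_max (%.2f A) exceeds half the smallest box edge (%.2f A)",
          r_max, min(box) / 2))
      }
      site <- colMeans(tr$coords[site_idx, , f, drop = FALSE])
      counts <- cpp_rdf_hist(site, tr$coords[wox, , f], box, r_max, dr)
      rho <- length(wox) / prod(box)
      dens <- c(dens, rho)
      acc <- acc + counts / (rho * shell)
    }
    g_rep[, r] <- acc / length(frames)
  }
  g <- rowMeans(g_rep)
  sdv <- if (ncol(g_rep) > 1L) apply(g_rep, 1L, sd) else rep(NA_real_, nbins)
  structure(list(residue = topology$residues$resseq[residue_row(topology, residue)],
                 label = residue_label(topology, residue),
                 site_definition = "heavy-atom center of geometry",
                 bin_edges = edges, g = g, sd = sdv, g_replicates = g_rep,
                 bulk_density = mean(dens)),
            class = "RDFProfile")
}

#' @export
print.RDFProfile <- function(x, ...) {
  cat(sprintf("RDF of water around %s: %d bins to %.1f A, bulk %.4g A^-3\n",
              x$label, length(x$g), max(x$bin_edges), x$bulk_density))
  invisible(x)
}

#' Cumulative RDF difference between two profiles
#'
#' The ranking statistic: the sum over all bins of `g_a(r) - g_b(r)`
#' (conventionally wild type minus mutant). Antisymmetric under swapping
#' the arguments. An optional radial sub-range restricts the accumulation.
#'
#' @param profile_a,profile_b `RDFProfile`s on identical bins
#' @param range optional `c(lo, hi)` in Angstrom restricting the summed bins
#'   (a bin is included when its midpoint lies in `[lo, hi]`)
#' @return scalar sum of per-bin g differences (dimensionless)
#' @export
rdf_difference_accumulation <- function(profile_a, profile_b, range = NULL) {
  if (length(profile_a$bin_edges) != length(profile_b$bin_edges) ||
      any(abs(profile_a$bin_edges - profile_b$bin_edges) > 1e-9)) {
    stop("RDF profiles have mismatched binning")
  }
  dg <- profile_a$g - profile_b$g
  if (!is.null(range)) {
    e <- profile_a$bin_edges
    mids <- (e[-1L] + e[-length(e)]) / 2
    dg <- dg[mids >= range[1L] & mids <= range[2L]]
  }
  sum(dg)
}

#' Rank neighborhood residues by their mutation-induced water-RDF shift
#'
#' Computes the water RDF of every neighborhood residue in both systems and
#' the cumulative difference sum(g_wt - g_mut) per residue, then ranks by
#' absolute value (descending; ties broken by residue number ascending).
#' The signed value is always reported alongside the rank.
#'
#' @param ensemble_wt,ensemble_mut `Ensemble`s sharing residue numbering
#'   over the selection
#' @param selection a `NeighborhoodSelection`
#' @param top_n how many residues to flag as the headline set (default 10;
#'   clamped to the selection size)
#' @param r_max,dr see [water_rdf()]
#' @param profiles optional precomputed list (per residue label) of
#'   `list(wt =, mut =)` RDF profiles, to avoid recomputation
#' @return object of class `RankingTable`: data.frame with `residue`,
#'   `label`, `sum_delta_g`, `abs_sum_delta_g`, `rank`, `in_top_n`, ordered
#'   by rank; attribute `"profiles"` carries the per-residue RDF pairs
#' @export
rank_residues_by_rdf_shift <- function(ensemble_wt, ensemble_mut, selection,
                                       top_n = 10L, r_max = 10.0, dr = 0.1,
                                       profiles = NULL) {
  res_ids <- selection$members$resseq
  if (length(res_ids) == 0L) stop("neighborhood selection is empty")
  if (is.null(profiles)) {
    profiles <- lapply(res_ids, function(rid) {
      list(wt = water_rdf(ensemble_wt, rid, r_max = r_max, dr = dr),
           mut = water_rdf(ensemble_mut, rid, r_max = r_max, dr = dr))
    })
    names(profiles) <- vapply(profiles, function(p) p$wt$label, character(1))
  }
  sums <- vapply(profiles, function(p) {
    rdf_difference_accumulation(p$wt, p$mut)
  }, numeric(1))
  tab <- data.frame(
    residue = res_ids,
    label = names(profiles),
    sum_delta_g = unname(sums),
    abs_sum_delta_g = abs(unname(sums)),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$abs_sum_delta_g, tab$residue)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$in_top_n <- tab$rank <= min(top_n, nrow(tab))
  rownames(tab) <- NULL
  structure(tab, class = c("RankingTable", "data.frame"),
            profiles = profiles, direction = "abs(sum g_wt - g_mut) descending")
}
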