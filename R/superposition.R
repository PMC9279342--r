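# Optimal rigid-body superposition (Kabsch, via SVD with reflection
# correction) and per-replicate RMSD time series.

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' between `mobile` and `reference`. Row convention: the fitted coordinates
#' are `mobile %*% rotation + translation`.
#'
#' @param mobile n x 3 matrix
#' @param reference n x 3 matrix
#' @param weights optional non-negative weights of length n (e.g. masses)
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd` (Angstrom)
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n) {
    stop("superposition needs two equal point sets with >= 3 points")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)

  # degenerate geometry: reference points (near-)collinear
  if (svd(Q * sqrt(w))$d[2L] < 1e-8 * max(1, svd(Q * sqrt(w))$d[1L])) {
    stop("degenerate (collinear) reference geometry")
  }

  C <- t(P * w) %*% Q
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  rotation <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  translation <- cr - as.numeric(cm %*% rotation)
  fitted <- P %*% rotation
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  list(rotation = rotation, translation = translation, rmsd = rmsd)
}

#' RMSD time series for every replicate of an ensemble
#'
#' Each frame is optimally superposed (Kabsch) onto the reference before the
#' deviation is measured, so the series is invariant under rigid motion of
#' any frame. By default each replicate is compared against its own initial
#' frame, matching the convention of measuring drift from each run's
#' starting structure. Equilibration frames are included in the series but
#' flagged, so plots can show the full run while statistics exclude them.
#'
#' @param ensemble an `Ensemble`
#' @param reference_frame optional `Frame` shared by all replicates; default
#'   `NULL` uses each replicate's first frame
#' @param selection atom indices or a [select_atoms()] keyword (default
#'   `"protein_heavy"`; use `"calpha"` for a backbone-only series)
#' @param weights optional per-atom weights over the selection
#' @return list of `RMSDSeries` objects, one per replicate, each with
#'   `replicate_id`, `times` (ns), `values` (Angstrom), `selection` and
#'   `equilibration` (logical flag per frame)
#' @export
rmsd_series <- function(ensemble, reference_frame = NULL,
                        selection = "protein_heavy", weights = NULL) {
  topology <- ensemble_topology(ensemble)
  if (is.character(selection)) {
    sel_desc <- selection
    selection <- select_atoms(topology, selection)
  } else {
    sel_desc <- sprintf("%d atoms (custom)", length(selection))
  }
  if (length(selection) == 0L) stop("empty atom selection")

  lapply(seq_along(ensemble$replicates), function(r) {
    tr <- ensemble$replicates[[r]]
    ref <- if (is.null(reference_frame)) {
      tr$coords[selection, , 1L, drop = FALSE][, , 1L]
    } else {
      reference_frame$coordinates[selection, , drop = FALSE]
    }
    nf <- n_frames(tr)
    values <- vapply(seq_len(nf), function(f) {
      kabsch_superpose(tr$coords[selection, , f], ref, weights)$rmsd
    }, numeric(1))
    n_eq <- floor(ensemble$equilibration_fraction * nf)
    structure(list(replicate_id = r, times = tr$times, values = values,
                   selection = sel_desc,
                   equilibration = seq_len(nf) <= n_eq),
              class = "RMSDSeries")
  })
}
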