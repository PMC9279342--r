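# Shared fixtures and independent oracles. Everything here is built in code
# at test time; the oracles deliberately avoid the code paths they check.

# --- tiny topology builders -------------------------------------------------

# Topology with one carbon atom per "residue" at the supplied coordinates.
point_topology <- function(coords, resnames = NULL, resseqs = NULL,
                           element = "C") {
  n <- nrow(coords)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  if (is.null(resseqs)) resseqs <- seq_len(n)
  top <- new_topology(data.frame(
    serial = seq_len(n), name = "CA", element = element,
    resname = resnames, resseq = resseqs, chain = "A",
    stringsAsFactors = FALSE))
  assign_parameters(top)
}

# Solvated single-site system: one carbon "protein" atom plus n_water water
# oxygens with caller-supplied per-frame coordinates.
water_box_topology <- function(n_water) {
  atoms <- rbind(
    data.frame(serial = 1L, name = "CA", element = "C", resname = "ALA",
               resseq = 1L, chain = "A", stringsAsFactors = FALSE),
    data.frame(serial = 1L + seq_len(n_water), name = "O", element = "O",
               resname = "HOH", resseq = 100L + seq_len(n_water),
               chain = "W", stringsAsFactors = FALSE))
  assign_parameters(new_topology(atoms))
}

# Ideal-gas water ensemble: site fixed at the box center, waters uniform in
# the box each frame (no exclusion, no structure). Exact flat-g(r) world.
ideal_gas_ensemble <- function(seed, n_water, box_edge, n_frames,
                               n_replicates = 1L) {
  set.seed(seed)
  top <- water_box_topology(n_water)
  site <- rep(box_edge / 2, 3)
  reps <- lapply(seq_len(n_replicates), function(r) {
    coords <- array(NA_real_, dim = c(1L + n_water, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      coords[1L, , f] <- site
      coords[-1L, , f] <- matrix(runif(3 * n_water, 0, box_edge), ncol = 3)
    }
    new_trajectory(top, coords, box = rep(box_edge, 3))
  })
  new_ensemble(reps, equilibration_fraction = 0, label = "ideal")
}

# A quick matched synthetic pair at reduced frame count for module tests.
small_pair <- function(seed, n_frames = 80L, ...) {
  synthetic_comparison(seed, n_frames = n_frames, ...)
}

# --- independent oracles ----------------------------------------------------

# Brute-force minimum-image histogram (explicit double loop, same rounding
# convention as the kernel: round-half-even via round()).
bf_min_image_counts <- function(site, pts, box, r_max, dr) {
  nb <- as.integer(round(r_max / dr))
  counts <- integer(nb)
  for (i in seq_len(nrow(pts))) {
    d <- pts[i, ] - site
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    if (r < r_max) {
      b <- floor(r / dr) + 1L
      if (b > nb) b <- nb
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# Closed-form solvent-accessible area of two intersecting spheres: each
# expanded sphere loses the spherical cap buried inside the other.
two_sphere_sasa <- function(r1, r2, probe, d) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  stopifnot(d < R1 + R2, d > abs(R1 - R2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Brute-force minimum RMSD over rigid transforms: dense Euler-angle grid
# followed by Nelder-Mead refinement; centroids matched at every rotation.
euler_rotation <- function(a, b, c) {
  Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)
  Rz1 %*% Ry %*% Rz2
}

bf_min_rmsd <- function(mobile, reference, grid_step = pi / 12) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rmsd_at <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% R - Q)^2)))
  }
  best <- Inf
  best_ang <- c(0, 0, 0)
  for (a in seq(0, 2 * pi - grid_step, by = grid_step)) {
    for (b in seq(0, pi, by = grid_step)) {
      for (c in seq(0, 2 * pi - grid_step, by = grid_step)) {
        v <- rmsd_at(c(a, b, c))
        if (v < best) {
          best <- v
          best_ang <- c(a, b, c)
        }
      }
    }
  }
  opt <- stats::optim(best_ang, rmsd_at, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

# Sort-based percentile oracle for the median (matches the convention of
# averaging the two central order statistics at even n).
sort_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Random proper rotation (QR-based, determinant fixed to +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
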