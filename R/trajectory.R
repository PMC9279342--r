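# Trajectory and Ensemble containers, DCD binary I/O, trajectory reading.
#
# A Trajectory holds one replicate: the shared Topology plus an N x 3 x F
# coordinate array (Angstrom), an F x 3 matrix of orthorhombic box edges
# (NA rows when the format carried no box) and frame times in ns. An
# Ensemble is a list of replicate Trajectories over one topology with an
# equilibration fraction and a system label ("WT", "W647R", ...).

#' Construct a Trajectory
#'
#' @param topology a `Topology`
#' @param coords N x 3 x F numeric array, or a list of N x 3 matrices
#' @param box F x 3 matrix of box edges, a single length-3 vector recycled
#'   to all frames, or `NULL` (no box information)
#' @param times frame times in ns (default `0:(F-1)`)
#' @return object of class `Trajectory`
#' @export
new_trajectory <- function(topology, coords, box = NULL, times = NULL) {
  if (is.list(coords)) {
    n <- nrow(coords[[1L]])
    arr <- array(NA_real_, dim = c(n, 3L, length(coords)))
    for (f in seq_along(coords)) arr[, , f] <- as.matrix(coords[[f]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  nf <- dim(coords)[3L]
  if (nf < 1L) stop("trajectory must contain at least one frame")
  if (dim(coords)[1L] != n_atoms(topology)) {
    stop("frame atom count (", dim(coords)[1L],
         ") does not match topology (", n_atoms(topology), ")")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (is.null(box)) {
    box <- matrix(NA_real_, nrow = nf, ncol = 3L)
  } else if (is.null(dim(box))) {
    box <- matrix(rep(as.numeric(box), each = nf), nrow = nf)
  }
  stopifnot(nrow(box) == nf, ncol(box) == 3L)
  if (any(!is.na(box) & box <= 0)) stop("box edges must be positive")
  if (is.null(times)) times <- seq_len(nf) - 1
  stopifnot(length(times) == nf)
  structure(list(topology = topology, coords = coords, box = box,
                 times = as.numeric(times)),
            class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param trajectory a `Trajectory`
#' @return integer frame count
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3L]

#' Extract one frame from a trajectory
#' @param trajectory a `Trajectory`
#' @param i frame index
#' @return a `Frame`
#' @export
trajectory_frame <- function(trajectory, i) {
  stopifnot(i >= 1L, i <= n_frames(trajectory))
  b <- trajectory$box[i, ]
  new_frame(trajectory$coords[, , i, drop = TRUE],
            box = if (anyNA(b)) NULL else b,
            time = trajectory$times[i])
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms x %d frames (%.3g-%.3g ns)%s\n",
              dim(x$coords)[1L], n_frames(x), min(x$times), max(x$times),
              if (anyNA(x$box)) ", no box" else ""))
  invisible(x)
}

#' Construct an Ensemble of replicate trajectories
#'
#' @param replicates list of `Trajectory` objects sharing one topology
#' @param equilibration_fraction fraction of each replicate discarded as
#'   equilibration by the analysis stages, in `[0, 1)`
#' @param label system label, e.g. `"WT"` or `"W647R"`
#' @return object of class `Ensemble`
#' @export
new_ensemble <- function(replicates, equilibration_fraction = 0.4,
                         label = "system") {
  stopifnot(length(replicates) >= 1L)
  if (equilibration_fraction < 0 || equilibration_fraction >= 1) {
    stop("equilibration_fraction must be in [0, 1)")
  }
  n0 <- n_atoms(replicates[[1L]]$topology)
  for (r in seq_along(replicates)) {
    tr <- replicates[[r]]
    if (!inherits(tr, "Trajectory")) stop("replicate ", r, " is not a Trajectory")
    if (n_atoms(tr$topology) != n0) {
      stop("replicate ", r, " topology atom count differs")
    }
    kept <- n_frames(tr) - floor(equilibration_fraction * n_frames(tr))
    if (kept < 1L) {
      stop("replicate ", r, " has no post-equilibration frames")
    }
  }
  structure(list(replicates = replicates,
                 equilibration_fraction = equilibration_fraction,
                 label = label),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble '%s': %d replicates x %d frames, equilibration %.2f\n",
              x$label, length(x$replicates), n_frames(x$replicates[[1L]]),
              x$equilibration_fraction))
  invisible(x)
}

# Topology of an ensemble (shared across replicates).
ensemble_topology <- function(ensemble) ensemble$replicates[[1L]]$topology

# Frame indices retained for analysis in one replicate.
analysis_frame_indices <- function(trajectory, fraction) {
  nf <- n_frames(trajectory)
  drop <- floor(fraction * nf)
  if (drop >= nf) stop("equilibration fraction discards every frame")
  seq.int(drop + 1L, nf)
}

# ---------------------------------------------------------------------------
# DCD I/O (CHARMM-style, Fortran unformatted records, native endianness).
# Layout: header record ("CORD" + 20 int control block, with the unit-cell
# flag at slot 11 and the frame interval, stored here directly in ns, as a
# float in slot 10), a title record, an atom-count record, then per frame a
# 6-double unit-cell record (A, 90, B, 90, 90, C) and three float32 records
# (x, y, z).

.write_record <- function(con, writer) {
  # Fortran unformatted: payload length (int32) brackets the payload.
  raw <- writer()
  writeBin(length(raw), con, size = 4L)
  writeBin(raw, con)
  writeBin(length(raw), con, size = 4L)
}

.read_record <- function(con, what, size, n_expected = NULL) {
  len <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(len) == 0L) return(NULL)
  n <- len / size
  dat <- readBin(con, what, n = n, size = size)
  if (length(dat) < n) stop("truncated DCD record")
  tail <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(tail) == 0L || tail != len) stop("corrupt DCD record framing")
  if (!is.null(n_expected) && n != n_expected) {
    stop("unexpected DCD record length: ", n, " (wanted ", n_expected, ")")
  }
  dat
}

#' Write a trajectory to a DCD file
#'
#' CHARMM-style DCD with a per-frame orthorhombic unit-cell record. Frame
#' times must be uniformly spaced; the spacing is stored in the header.
#' Coordinates are stored as float32 (format precision about 1e-6 relative).
#'
#' @param trajectory a `Trajectory` with box information in every frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dcd <- function(trajectory, path) {
  nf <- n_frames(trajectory)
  na <- dim(trajectory$coords)[1L]
  if (anyNA(trajectory$box)) stop("DCD output requires a box in every frame")
  dt <- if (nf > 1L) diff(trajectory$times)[1L] else 0
  con <- file(path, "wb")
  on.exit(close(con))

  icntrl <- integer(20L)
  icntrl[1L] <- nf          # number of frames
  icntrl[2L] <- 1L          # first step
  icntrl[3L] <- 1L          # save interval
  icntrl[4L] <- nf          # last step
  icntrl[10L] <- packBits(intToBits(0L), "integer")  # replaced below
  icntrl[11L] <- 1L         # unit-cell records present
  icntrl[20L] <- 24L        # CHARMM version tag
  .write_record(con, function() {
    r <- charToRaw("CORD")
    body <- writeBin(icntrl, raw(), size = 4L)
    # splice the frame interval (ns) into control slot 10 as float32 bits
    dtraw <- writeBin(as.numeric(dt), raw(), size = 4L)
    body[37:40] <- dtraw
    c(r, body)
  })
  .write_record(con, function() {
    title <- sprintf("%-80s", "mutsolv trajectory")
    c(writeBin(1L, raw(), size = 4L), charToRaw(title))
  })
  .write_record(con, function() writeBin(na, raw(), size = 4L))

  for (f in seq_len(nf)) {
    b <- trajectory$box[f, ]
    .write_record(con, function() {
      writeBin(as.numeric(c(b[1L], 90, b[2L], 90, 90, b[3L])), raw(), size = 8L)
    })
    for (d in 1:3) {
      .write_record(con, function() {
        writeBin(as.numeric(trajectory$coords[, d, f]), raw(), size = 4L)
      })
    }
  }
  invisible(path)
}

#' Read a DCD trajectory
#'
#' @param topology `Topology` whose atom count must match the file
#' @param path DCD path
#' @return a `Trajectory`
#' @export
read_dcd <- function(topology, path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  hdr_len <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(hdr_len) == 0L || hdr_len != 84L) {
    stop("not a DCD file (bad header length): ", path)
  }
  magic <- rawToChar(readBin(con, "raw", n = 4L))
  if (magic != "CORD") stop("not a DCD file (magic '", magic, "')")
  icntrl_raw <- readBin(con, "raw", n = 80L)
  readBin(con, "integer", n = 1L, size = 4L)
  icntrl <- readBin(icntrl_raw, "integer", n = 20L, size = 4L)
  nf_declared <- icntrl[1L]
  dt <- readBin(icntrl_raw[37:40], "numeric", n = 1L, size = 4L)
  has_cell <- icntrl[11L] != 0L

  .read_record(con, "raw", 1L)  # title block, ignored
  na <- .read_record(con, "integer", 4L, 1L)
  if (na != n_atoms(topology)) {
    stop("DCD atom count (", na, ") does not match topology (",
         n_atoms(topology), ")")
  }

  frames <- list()
  boxes <- list()
  repeat {
    if (has_cell) {
      cell <- tryCatch(.read_record(con, "numeric", 8L, 6L),
                       error = function(e) {
                         stop("truncated DCD at frame ", length(frames) + 1L)
                       })
      if (is.null(cell)) break
      ang <- cell[c(2L, 4L, 5L)]
      if (any(abs(ang - 90) > 1e-3)) {
        stop("triclinic DCD unit cell not supported")
      }
      boxes[[length(boxes) + 1L]] <- cell[c(1L, 3L, 6L)]
    }
    x <- .read_record(con, "numeric", 4L, na)
    if (is.null(x)) {
      if (has_cell) stop("truncated DCD at frame ", length(frames) + 1L)
      break
    }
    y <- .read_record(con, "numeric", 4L, na)
    z <- .read_record(con, "numeric", 4L, na)
    if (is.null(y) || is.null(z)) {
      stop("truncated DCD at frame ", length(frames) + 1L)
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
  }
  nf <- length(frames)
  if (nf == 0L) stop("DCD file contains no frames: ", path)
  if (nf_declared > 0L && nf != nf_declared) {
    stop("truncated DCD: header declares ", nf_declared,
         " frames, read ", nf)
  }
  box <- if (has_cell) do.call(rbind, boxes) else NULL
  new_trajectory(topology, frames, box = box,
                 times = (seq_len(nf) - 1) * ifelse(is.finite(dt), dt, 1))
}

#' Read a trajectory in DCD or multi-model PDB format
#'
#' Both routes return the same `Trajectory` contract: frames ordered by
#' time, per-frame box when the format carries one, atom count checked
#' against `topology`.
#'
#' @param topology a `Topology`
#' @param path trajectory file
#' @param format `"dcd"` or `"pdb"`; default guesses from the extension
#' @return a `Trajectory`
#' @export
read_trajectory <- function(topology, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  format <- match.arg(format, c("dcd", "pdb"))
  if (format == "dcd") return(read_dcd(topology, path))
  parsed <- read_structure(path, water_names = topology$water_names)
  if (n_atoms(parsed$topology) != n_atoms(topology)) {
    stop("PDB trajectory atom count (", n_atoms(parsed$topology),
         ") does not match topology (", n_atoms(topology), ")")
  }
  coords <- lapply(parsed$frames, `[[`, "coordinates")
  boxes <- lapply(parsed$frames, `[[`, "box")
  box <- if (is.null(boxes[[1L]])) NULL else do.call(rbind, boxes)
  new_trajectory(topology, coords, box = box,
                 times = vapply(parsed$frames, `[[`, numeric(1), "time"))
}
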