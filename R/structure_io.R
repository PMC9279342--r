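# Topology / Frame data model and PDB reading and writing.
#
# A Topology is the per-atom bookkeeping shared by every frame of a
# trajectory: names, residues (author numbering, never renumbered), chains,
# masses, vdW radii, and water/heavy flags. A Frame is one coordinate set
# (N x 3, Angstrom) plus an optional orthorhombic box and a time stamp (ns).

#' Construct a Topology from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resseq`, `chain`. Optional columns `mass`, `vdw_radius`.
#' @param water_names residue names treated as water
#'   (default [water_residue_names()]).
#' @return An object of class `Topology`: the atom table (with `is_water`
#'   and `is_heavy` flags) plus a `residues` table giving, for each residue
#'   in file order, its chain, author sequence number, name and atom index
#'   range.
#' @export
new_topology <- function(atoms, water_names = water_residue_names()) {
  required <- c("serial", "name", "element", "resname", "resseq", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$element <- toupper(trimws(atoms$element))
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- .element_from_name(atoms$name[blank])
  atoms$resname <- toupper(trimws(atoms$resname))
  atoms$is_water <- atoms$resname %in% toupper(water_names)
  atoms$is_heavy <- atoms$element != "H" & atoms$element != "D"
  if (is.null(atoms$mass)) atoms$mass <- rep(NA_real_, nrow(atoms))
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- rep(NA_real_, nrow(atoms))

  # Residues are maximal runs of constant (chain, resseq); atom order is the
  # file order and is never changed afterwards.
  key <- paste(atoms$chain, atoms$resseq, sep = "\r")
  change <- c(TRUE, key[-1L] != key[-length(key)])
  first <- which(change)
  last <- c(first[-1L] - 1L, nrow(atoms))
  residues <- data.frame(
    chain = atoms$chain[first],
    resseq = atoms$resseq[first],
    resname = atoms$resname[first],
    first = first,
    last = last,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(paste(residues$chain, residues$resseq))
  if (any(dup)) {
    stop("residue identifiers repeat non-contiguously or are duplicated: ",
         paste(unique(residues$resseq[dup]), collapse = ", "))
  }
  structure(list(atoms = atoms, residues = residues, water_names = water_names),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues (%d water)\n",
              nrow(x$atoms), nrow(x$residues),
              sum(x$atoms$is_water[x$residues$first])))
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology a `Topology`
#' @return integer atom count
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

# Row index into topology$residues for a residue id. `residue` is an author
# sequence number, optionally with chain as "A:647" or list(chain, resseq).
residue_row <- function(topology, residue) {
  res <- topology$residues
  if (is.character(residue) && grepl(":", residue)) {
    parts <- strsplit(residue, ":", fixed = TRUE)[[1L]]
    hit <- which(res$chain == parts[1L] & res$resseq == as.integer(parts[2L]))
  } else if (is.list(residue)) {
    hit <- which(res$chain == residue$chain & res$resseq == residue$resseq)
  } else {
    hit <- which(res$resseq == as.integer(residue))
  }
  if (length(hit) == 0L) {
    stop("residue not found in topology: ", format(residue))
  }
  if (length(hit) > 1L) {
    stop("residue id ", format(residue), " is ambiguous across chains; ",
         "qualify as \"<chain>:<resseq>\"")
  }
  hit
}

# Atom indices of one residue, optionally restricted to heavy atoms.
residue_atom_indices <- function(topology, residue, heavy_only = TRUE) {
  row <- residue_row(topology, residue)
  idx <- seq.int(topology$residues$first[row], topology$residues$last[row])
  if (heavy_only) idx <- idx[topology$atoms$is_heavy[idx]]
  idx
}

# Residue label in the field's "V520" style (one-letter code + author number).
residue_label <- function(topology, resseq) {
  row <- residue_row(topology, resseq)
  code <- .aa_one_letter[topology$residues$resname[row]]
  if (is.na(code)) code <- topology$residues$resname[row]
  paste0(code, topology$residues$resseq[row])
}

#' Select atom indices by role
#'
#' @param topology a `Topology`
#' @param what one of `"protein_heavy"` (heavy non-water atoms; the default
#'   selection for RMSD and SASA), `"heavy"`, `"calpha"`, `"water_oxygen"`,
#'   or `"all"`.
#' @return integer vector of atom indices (1-based, file order)
#' @export
select_atoms <- function(topology,
                         what = c("protein_heavy", "heavy", "calpha",
                                  "water_oxygen", "all")) {
  what <- match.arg(what)
  a <- topology$atoms
  switch(what,
    protein_heavy = which(a$is_heavy & !a$is_water),
    heavy = which(a$is_heavy),
    calpha = which(trimws(a$name) == "CA" & !a$is_water),
    water_oxygen = which(a$is_water & a$element == "O"),
    all = seq_len(nrow(a))
  )
}

#' Construct a Frame
#'
#' @param coordinates N x 3 numeric matrix, Angstrom
#' @param box orthorhombic edge lengths (length-3 numeric, Angstrom) or
#'   `NULL` when the input carries no box
#' @param time time stamp in ns
#' @return object of class `Frame`
#' @export
new_frame <- function(coordinates, box = NULL, time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be N x 3")
  if (!all(is.finite(coordinates))) stop("non-finite coordinates in frame")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive orthorhombic edge lengths")
    }
  }
  structure(list(coordinates = coordinates, box = box, time = time),
            class = "Frame")
}

# ---------------------------------------------------------------------------
# PDB parsing

.parse_pdb_atom_line <- function(line, lineno) {
  # Fixed-column PDB first; fall back to whitespace tokens for minimal
  # hand-written records like "ATOM 1 CA ALA A 1 0.0 0.0 0.0".
  ok_fixed <- nchar(line) >= 54L
  if (ok_fixed) {
    x <- suppressWarnings(as.numeric(substr(line, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(line, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(line, 47, 54)))
    serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
    resseq <- suppressWarnings(as.integer(substr(line, 23, 26)))
    if (!anyNA(c(x, y, z, serial, resseq))) {
      return(list(
        serial = serial,
        name = trimws(substr(line, 13, 16)),
        resname = trimws(substr(line, 18, 20)),
        chain = trimws(substr(line, 22, 22)),
        resseq = resseq,
        x = x, y = y, z = z,
        element = trimws(substr(line, 77, 78))
      ))
    }
  }
  tok <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  if (length(tok) >= 9L) {
    serial <- suppressWarnings(as.integer(tok[2L]))
    resseq <- suppressWarnings(as.integer(tok[6L]))
    xyz <- suppressWarnings(as.numeric(tok[7:9]))
    if (!anyNA(c(serial, resseq, xyz))) {
      return(list(serial = serial, name = tok[3L], resname = tok[4L],
                  chain = tok[5L], resseq = resseq,
                  x = xyz[1L], y = xyz[2L], z = xyz[3L], element = ""))
    }
  }
  stop(sprintf("malformed ATOM/HETATM record at line %d: %s", lineno, line))
}

#' Read a (multi-model) PDB structure
#'
#' Parses ATOM/HETATM records; MODEL/ENDMDL delimit frames (a file without
#' MODEL records yields a single frame); CRYST1 is optional and must be
#' orthorhombic (all angles 90 degrees) when present.
#'
#' @param path path to a PDB file
#' @param format only `"pdb"`
#' @param water_names residue names treated as water
#' @return list with `topology` (a [new_topology()] object) and `frames`
#'   (list of [new_frame()] objects)
#' @export
read_structure <- function(path, format = "pdb",
                           water_names = water_residue_names()) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)

  box <- NULL
  cryst <- grep("^CRYST1", lines)
  if (length(cryst) > 0L) {
    l <- lines[cryst[1L]]
    abc <- suppressWarnings(as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                         substr(l, 25, 33))))
    ang <- suppressWarnings(as.numeric(c(substr(l, 34, 40), substr(l, 41, 47),
                                         substr(l, 48, 54))))
    if (anyNA(abc)) stop("malformed CRYST1 record")
    if (!anyNA(ang) && any(abs(ang - 90) > 1e-3)) {
      stop("triclinic box not supported (CRYST1 angles must be 90 degrees)")
    }
    box <- abc
  }

  is_atom <- grepl("^(ATOM|HETATM)", lines)
  model_open <- grepl("^MODEL", lines)
  has_models <- any(model_open)

  # Assign each atom line to a model by counting MODEL records before it.
  model_id <- cumsum(model_open)
  atom_lineno <- which(is_atom)
  if (length(atom_lineno) == 0L) stop("no ATOM/HETATM records in ", path)
  frame_of <- if (has_models) model_id[atom_lineno] else rep(1L, length(atom_lineno))
  if (has_models && any(frame_of == 0L)) {
    stop("ATOM records appear before the first MODEL record")
  }

  parsed <- lapply(seq_along(atom_lineno), function(i) {
    .parse_pdb_atom_line(lines[atom_lineno[i]], atom_lineno[i])
  })
  n_frames <- max(frame_of)
  per_frame <- split(seq_along(parsed), frame_of)
  counts <- lengths(per_frame)
  if (length(unique(counts)) != 1L) {
    stop("inconsistent atom count across models: ",
         paste(counts, collapse = ", "))
  }

  first <- parsed[per_frame[[1L]]]
  atoms <- data.frame(
    serial = vapply(first, `[[`, integer(1), "serial"),
    name = vapply(first, `[[`, character(1), "name"),
    element = vapply(first, `[[`, character(1), "element"),
    resname = vapply(first, `[[`, character(1), "resname"),
    resseq = vapply(first, `[[`, integer(1), "resseq"),
    chain = vapply(first, `[[`, character(1), "chain"),
    stringsAsFactors = FALSE
  )
  topology <- new_topology(atoms, water_names = water_names)

  frames <- lapply(seq_len(n_frames), function(f) {
    p <- parsed[per_frame[[f]]]
    coords <- cbind(vapply(p, `[[`, numeric(1), "x"),
                    vapply(p, `[[`, numeric(1), "y"),
                    vapply(p, `[[`, numeric(1), "z"))
    new_frame(coords, box = box, time = f - 1)
  })
  list(topology = topology, frames = frames)
}

#' Write a (multi-model) PDB structure
#'
#' @param path output path
#' @param topology a `Topology`
#' @param frames a single `Frame` or list of `Frame`s; more than one frame
#'   produces MODEL/ENDMDL blocks
#' @return `path`, invisibly
#' @export
write_structure <- function(path, topology, frames) {
  if (inherits(frames, "Frame")) frames <- list(frames)
  a <- topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  box <- frames[[1L]]$box
  if (!is.null(box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1L], box[2L], box[3L], 90, 90, 90), con)
  }
  multi <- length(frames) > 1L
  rec <- ifelse(a$is_water, "HETATM", "ATOM  ")
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]$coordinates
    if (nrow(xyz) != nrow(a)) {
      stop("frame ", f, " atom count does not match topology")
    }
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    # PDB atom-name column convention: 1-2 char element names start in col 14
    name4 <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1, 4),
                    sprintf(" %-3s", a$name))
    writeLines(sprintf(
      "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, a$serial %% 100000L, name4, "", a$resname, a$chain,
      a$resseq %% 10000L, "", xyz[, 1L], xyz[, 2L], xyz[, 3L],
      1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Parameter assignment

#' Assign van der Waals radii and masses to a topology
#'
#' Radii are Bondi radii by element; masses are IUPAC standard atomic
#' weights or unit masses. Neither is carried by PDB/DCD input, so this must
#' be called before SASA or mass-weighted geometry.
#'
#' @param topology a `Topology`
#' @param radii `"bondi"`
#' @param masses `"standard"` or `"unit"`
#' @param strict if `TRUE`, unknown elements are an error naming the atoms;
#'   otherwise they receive `fallback_radius` (and the mean known mass) with
#'   a warning
#' @param fallback_radius radius (Angstrom) for unknown elements
#' @return the topology with `vdw_radius` and `mass` populated
#' @export
assign_parameters <- function(topology, radii = "bondi",
                              masses = c("standard", "unit"),
                              strict = FALSE, fallback_radius = 1.5) {
  radii <- match.arg(radii, "bondi")
  masses <- match.arg(masses)
  el <- topology$atoms$element
  unknown <- !(el %in% names(.bondi_radii))
  if (any(unknown)) {
    offenders <- unique(paste0(topology$atoms$name[unknown], " (element '",
                               el[unknown], "')"))
    if (strict) {
      stop("unknown element for atoms: ", paste(offenders, collapse = ", "))
    }
    warning("unknown element(s) assigned fallback radius ", fallback_radius,
            " A: ", paste(offenders, collapse = ", "))
  }
  r <- unname(.bondi_radii[el])
  r[unknown] <- fallback_radius
  topology$atoms$vdw_radius <- r
  if (masses == "unit") {
    topology$atoms$mass <- rep(1, nrow(topology$atoms))
  } else {
    m <- unname(.standard_masses[el])
    m[unknown] <- mean(.standard_masses)
    topology$atoms$mass <- m
  }
  topology
}
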