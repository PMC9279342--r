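# Pipeline orchestration: equilibration handling, the full WT-vs-mutant
# comparison, flat config parsing, and TSV/JSON artifact writing.

#' Discard the equilibration segment of a trajectory
#'
#' Drops the first `floor(fraction * n_frames)` frames, e.g. fraction 0.4 of
#' a 1000-frame replicate leaves exactly 600 frames for analysis.
#'
#' @param trajectory a `Trajectory`
#' @param fraction equilibration fraction in `[0, 1)`
#' @return a `Trajectory` view containing only the analysis frames
#' @export
discard_equilibration <- function(trajectory, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  keep <- analysis_frame_indices(trajectory, fraction)
  new_trajectory(trajectory$topology,
                 trajectory$coords[, , keep, drop = FALSE],
                 box = trajectory$box[keep, , drop = FALSE],
                 times = trajectory$times[keep])
}

.write_tsv <- function(df, path) {
  write.table(format(df, trim = TRUE, digits = 15, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full wild-type vs mutant comparison
#'
#' Executes, in order: RMSD series for both systems; neighborhood selection
#' around the mutation site on the wild-type reference structure;
#' per-residue SASA distributions; per-residue water RDFs; the cumulative
#' RDF-difference ranking; hydrophobic classification of the top-ranked
#' residues and their contact graph; and core radius-of-gyration
#' distributions with medians. All artifacts are written under
#' `output_dir` and the report is returned (and saved as `report.json`).
#' Output is a pure function of the inputs and parameters; rerunning with
#' the same inputs reproduces every TSV byte for byte.
#'
#' @param wt,mut `Ensemble`s sharing residue numbering over the selection
#' @param site_residue mutation-site residue id (author numbering)
#' @param output_dir directory for artifacts (created if needed)
#' @param cutoff neighborhood radius, Angstrom
#' @param r_max,dr RDF range and bin width, Angstrom
#' @param probe_radius,n_sphere_points SASA parameters
#' @param top_n size of the headline ranking set
#' @param hydrophobic_set 3-letter codes treated as hydrophobic
#' @param weighting Rg weighting, `"mass"` or `"uniform"`
#' @param contact_cutoff heavy-atom contact distance, Angstrom
#' @param rmsd_selection selection keyword for the RMSD stage
#' @param nbins histogram bins for distribution summaries
#' @return object of class `ComparisonReport` (also written as
#'   `report.json`): output paths, the ranking table, the core definition,
#'   per-system Rg medians and their difference, and run metadata
#' @export
run_comparison <- function(wt, mut, site_residue, output_dir,
                           cutoff = 8.0, r_max = 10.0, dr = 0.1,
                           probe_radius = 1.4, n_sphere_points = 960L,
                           top_n = 10L,
                           hydrophobic_set = default_hydrophobic_set(),
                           weighting = "mass", contact_cutoff = 4.5,
                           rmsd_selection = "protein_heavy", nbins = 30L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logmsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...)),
               log_con)
  }
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    out <- tryCatch(force(expr), error = function(e) {
      logmsg("stage %s: ERROR %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logmsg("stage %s: done", name)
    out
  }
  paths <- list()
  logmsg("run_comparison: site=%s cutoff=%.2f r_max=%.2f dr=%.3f probe=%.2f
 sphere_points=%d top_n=%d weighting=%s",
         format(site_residue), cutoff, r_max, dr, probe_radius,
         n_sphere_points, top_n, weighting)

  # 1. RMSD
  rmsd_tab <- stage("rmsd", {
    rows <- lapply(list(wt, mut), function(ens) {
      series <- rmsd_series(ens, selection = rmsd_selection)
      do.call(rbind, lapply(series, function(s) {
        data.frame(label = ens$label, replicate = s$replicate_id,
                   time_ns = s$times, rmsd_A = s$values)
      }))
    })
    do.call(rbind, rows)
  })
  paths$rmsd <- .write_tsv(rmsd_tab, file.path(output_dir, "rmsd.tsv"))

  # 2. neighborhood on the wild-type reference structure
  wt_top <- ensemble_topology(wt)
  selection <- stage("neighborhood", {
    select_neighborhood(wt_top, trajectory_frame(wt$replicates[[1L]], 1L),
                        site_residue, cutoff = cutoff)
  })
  logmsg("neighborhood: %d residues (%s)", nrow(selection$members),
         paste(selection$members$resseq, collapse = ", "))

  # 3. SASA distributions in both systems
  sasa <- stage("sasa", {
    lapply(list(wt = wt, mut = mut), function(ens) {
      residue_sasa_distributions(ens, selection, probe_radius = probe_radius,
                                 n_sphere_points = n_sphere_points,
                                 nbins = nbins)
    })
  })
  sasa_long <- do.call(rbind, lapply(names(sasa), function(nm) {
    ens <- if (nm == "wt") wt else mut
    cbind(label = ens$label, attr(sasa[[nm]], "samples"))
  }))
  paths$sasa <- .write_tsv(sasa_long, file.path(output_dir, "sasa.tsv"))
  sasa_summary <- do.call(rbind, lapply(names(sasa), function(nm) {
    ens <- if (nm == "wt") wt else mut
    do.call(rbind, lapply(names(sasa[[nm]]), function(lab) {
      s <- sasa[[nm]][[lab]]
      data.frame(label = ens$label, residue = lab, mean = s$mean,
                 median = s$median, sd = s$sd, n = s$n)
    }))
  }))
  paths$sasa_summary <- .write_tsv(sasa_summary,
                                   file.path(output_dir, "sasa_summary.tsv"))

  # 4. per-residue water RDFs in both systems
  profiles <- stage("rdf", {
    out <- lapply(selection$members$resseq, function(rid) {
      list(wt = water_rdf(wt, rid, r_max = r_max, dr = dr),
           mut = water_rdf(mut, rid, r_max = r_max, dr = dr))
    })
    names(out) <- vapply(out, function(p) p$wt$label, character(1))
    out
  })
  for (lab in names(profiles)) {
    for (side in c("wt", "mut")) {
      p <- profiles[[lab]][[side]]
      e <- p$bin_edges
      df <- data.frame(r_mid_A = (e[-1L] + e[-length(e)]) / 2, g = p$g,
                       sd = p$sd)
      sys_lab <- if (side == "wt") wt$label else mut$label
      f <- file.path(output_dir, sprintf("rdf_%s_%s.tsv", sys_lab, lab))
      paths$rdf <- c(paths$rdf, .write_tsv(df, f))
    }
  }

  # 5. ranking by cumulative RDF difference
  ranking <- stage("ranking", {
    rank_residues_by_rdf_shift(wt, mut, selection, top_n = top_n,
                               r_max = r_max, dr = dr, profiles = profiles)
  })
  paths$ranking <- .write_tsv(as.data.frame(ranking),
                              file.path(output_dir, "ranking.tsv"))

  # 6. hydrophobic classification of the top-ranked residues + contacts
  core <- stage("core", {
    top_ids <- ranking$residue[ranking$in_top_n]
    hydrophobic_core(classify_hydrophobic(top_ids, wt_top, hydrophobic_set),
                     classification_set = hydrophobic_set,
                     contact_cutoff = contact_cutoff)
  })
  contacts <- stage("contacts", {
    contact_graph(trajectory_frame(wt$replicates[[1L]], 1L), wt_top,
                  core$residues, cutoff = contact_cutoff)
  })
  core_json <- file.path(output_dir, "core.json")
  jsonlite::write_json(
    list(residues = core$residues,
         classification_set = core$classification_set,
         contact_cutoff = contact_cutoff,
         contact_matrix = unname(contacts$contacts * 1L),
         connected = contacts$connected),
    core_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$core <- core_json

  # 7. core Rg distributions and medians
  rg <- stage("rg", {
    lapply(list(wt = wt, mut = mut), function(ens) {
      rg_distribution(ens, core, weighting = weighting, nbins = nbins)
    })
  })
  rg_long <- do.call(rbind, lapply(names(rg), function(nm) {
    ens <- if (nm == "wt") wt else mut
    cbind(label = ens$label, attr(rg[[nm]], "samples"))
  }))
  paths$rg <- .write_tsv(rg_long, file.path(output_dir, "rg.tsv"))
  rg_summary <- do.call(rbind, lapply(names(rg), function(nm) {
    ens <- if (nm == "wt") wt else mut
    s <- rg[[nm]]
    data.frame(label = ens$label, mean = s$mean, median = s$median,
               sd = s$sd, n = s$n)
  }))
  paths$rg_summary <- .write_tsv(rg_summary,
                                 file.path(output_dir, "rg_summary.tsv"))
  median_diff <- rg$mut$median - rg$wt$median
  logmsg("core Rg medians: %s %.4f A, %s %.4f A, difference %.4f A",
         wt$label, rg$wt$median, mut$label, rg$mut$median, median_diff)

  report <- structure(list(
    outputs = paths,
    parameters = list(site_residue = site_residue, cutoff = cutoff,
                      r_max = r_max, dr = dr, probe_radius = probe_radius,
                      n_sphere_points = n_sphere_points, top_n = top_n,
                      hydrophobic_set = hydrophobic_set,
                      weighting = weighting, contact_cutoff = contact_cutoff,
                      equilibration_fraction = wt$equilibration_fraction),
    neighborhood = selection$members$resseq,
    ranking = as.data.frame(ranking),
    core = list(residues = core$residues, connected = contacts$connected),
    rg_median = setNames(c(rg$wt$median, rg$mut$median),
                         c(wt$label, mut$label)),
    rg_median_difference = median_diff,
    metadata = list(package = "mutsolv",
                    version = as.character(packageVersion("mutsolv")),
                    labels = c(wt$label, mut$label))
  ), class = "ComparisonReport")
  jsonlite::write_json(
    report[setdiff(names(report), "outputs")],
    file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  report
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("Comparison report\n")
  cat(sprintf("  neighborhood: %d residues around site %s\n",
              length(x$neighborhood), format(x$parameters$site_residue)))
  cat("  top-ranked residues:",
      paste(x$ranking$label[x$ranking$in_top_n], collapse = ", "), "\n")
  cat("  hydrophobic core:", paste(x$core$residues, collapse = ", "), "\n")
  cat(sprintf("  core Rg medians: %s = %.3f A, %s = %.3f A (diff %+.3f A)\n",
              names(x$rg_median)[1L], x$rg_median[1L],
              names(x$rg_median)[2L], x$rg_median[2L],
              x$rg_median_difference))
  invisible(x)
}

#' Parse a flat key-value configuration file
#'
#' A YAML-compatible subset: one `key: value` pair per line, `#` comments,
#' comma-separated lists. Numeric-looking values are converted.
#'
#' @param path config file path
#' @return named list
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl(":", lines)]
  out <- list()
  for (l in lines) {
    key <- trimws(sub(":.*$", "", l))
    val <- trimws(sub("^[^:]*:", "", l))
    if (val == "") next
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}

#' Run the comparison pipeline from a configuration file
#'
#' Expected keys: `wt_topology`, `wt_trajectories` (comma list),
#' `mut_topology`, `mut_trajectories`, `site_residue`, `output_dir`, and
#' optionally `label_wt`, `label_mut`, `equilibration_fraction` plus any
#' [run_comparison()] parameter (`cutoff`, `r_max`, `dr`, `probe_radius`,
#' `n_sphere_points`, `top_n`, `weighting`, `contact_cutoff`).
#'
#' @param config path to a flat key-value config file, or an equivalent list
#' @return a `ComparisonReport`
#' @export
run_comparison_config <- function(config) {
  if (is.character(config)) config <- parse_config(config)
  need <- c("wt_topology", "wt_trajectories", "mut_topology",
            "mut_trajectories", "site_residue", "output_dir")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0L) {
    stop("config lacks keys: ", paste(missing, collapse = ", "))
  }
  eq <- if (is.null(config$equilibration_fraction)) 0.4 else
    config$equilibration_fraction
  load_ens <- function(top_path, traj_paths, label) {
    parsed <- read_structure(top_path)
    topology <- assign_parameters(parsed$topology)
    reps <- lapply(traj_paths, function(p) read_trajectory(topology, p))
    new_ensemble(reps, equilibration_fraction = eq, label = label)
  }
  wt <- load_ens(config$wt_topology, config$wt_trajectories,
                 if (is.null(config$label_wt)) "WT" else config$label_wt)
  mut <- load_ens(config$mut_topology, config$mut_trajectories,
                  if (is.null(config$label_mut)) "MUT" else config$label_mut)
  args <- config[intersect(names(config),
                           c("cutoff", "r_max", "dr", "probe_radius",
                             "n_sphere_points", "top_n", "weighting",
                             "contact_cutoff", "nbins"))]
  do.call(run_comparison,
          c(list(wt = wt, mut = mut, site_residue = config$site_residue,
                 output_dir = config$output_dir), args))
}
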