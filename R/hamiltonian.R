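## Per-frame Hamiltonian construction and trajectory files.
##
## One frame of the one-exciton Hamiltonian: site frequencies on the
## diagonal (electrostatic map + nearest-neighbour shift + class shift),
## couplings off-diagonal, plus transition dipoles, site positions and the
## constant site anharmonicity needed downstream for 2DIR. On disk the
## trajectories use the single-precision binary layout consumed by
## time-domain spectral engines, with a text mirror for interchange.

#' Pipeline configuration defaults
#'
#' @param map_cutoff Electrostatic map cutoff, nm (default 2).
#' @param search_cutoff Neighbor-list cutoff, nm (default 2.5).
#' @param rebuild_interval Neighbor-list rebuild period, frames (default 50).
#' @param anharmonicity Constant site anharmonicity, cm^-1 (default 16).
#' @param timestep Frame spacing when the trajectory carries no time stamps,
#'   fs (default 20).
#' @param preproline_shift,sidechain_shift Class-shift magnitudes, cm^-1
#'   (defaults 27 and 30).
#' @param coupling A [coupling_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(map_cutoff = 2.0, search_cutoff = 2.5,
                            rebuild_interval = 50, anharmonicity = 16,
                            timestep = 20, preproline_shift = 27,
                            sidechain_shift = 30,
                            coupling = coupling_config()) {
  if (search_cutoff < map_cutoff)
    stop("search_cutoff must be >= map_cutoff")
  if (anharmonicity <= 0) stop("anharmonicity must be > 0")
  structure(list(map_cutoff = map_cutoff, search_cutoff = search_cutoff,
                 rebuild_interval = rebuild_interval,
                 anharmonicity = anharmonicity, timestep = timestep,
                 preproline_shift = preproline_shift,
                 sidechain_shift = sidechain_shift, coupling = coupling),
            class = "pipeline_config")
}

#' Build one Hamiltonian frame
#'
#' Site frequencies: class-appropriate map applied to the local-frame
#' electrostatics, plus nearest-neighbour Ramachandran shifts, plus the class
#' shift for units handled by the secondary map. Couplings from
#' [assemble_couplings()]; dipoles and positions from [site_dipole()].
#'
#' @param frame Trajectory frame (`xyz` nm, `box`, `time` fs).
#' @param topology `amide_topology`.
#' @param units `amide_units`.
#' @param maps Either one `electrostatic_map` (used for every class, with
#'   class shifts) or a named list per class
#'   (`secondary`, `tertiary_preproline`, `primary_sidechain`).
#' @param grids Named list of [rama_grid()]s (`shift_prev`, `shift_next`,
#'   `coupling`), or `NULL` to skip nearest-neighbour corrections.
#' @param config [pipeline_config()].
#' @param neighbor_list Optional [build_neighbor_list()] result.
#' @return A `hamiltonian_frame`: `time` (fs), `omega` (cm^-1),
#'   `J` (cm^-1, symmetric), `anharmonicity` (cm^-1), `dipoles` (N x 3, D),
#'   `positions` (N x 3, nm).
#' @export
build_frame <- function(frame, topology, units, maps, grids = NULL,
                        config = pipeline_config(), neighbor_list = NULL) {
  n <- length(units)
  charges <- topology$atoms$charge
  omega <- numeric(n)
  dipoles <- vector("list", n)
  for (i in seq_len(n)) {
    u <- units[[i]]
    map <- map_for_class(maps, u$amide_class)
    direct <- !inherits(maps, "electrostatic_map") &&
      !is.null(maps[[u$amide_class]])
    cand <- if (!is.null(neighbor_list)) neighbor_list$candidates[[i]]
    fs <- field_at_unit(frame, u, charges, config$map_cutoff,
                        exclusions = map_exclusions(map, u, topology, units),
                        candidates = cand)
    xyz <- frame$xyz
    R <- amide_frame(xyz[u$atoms["C"], ], xyz[u$atoms["O"], ],
                     xyz[u$atoms["N"], ])
    w <- site_frequency(map, rotate_field_sample(fs, R))
    if (!is.null(grids) && !u$sidechain)
      w <- w + nn_frequency_shift(u, topology, units, frame, grids)
    if (!direct)
      w <- class_shift(w, u$amide_class, config$preproline_shift,
                       config$sidechain_shift)
    omega[i] <- w
    dipoles[[i]] <- site_dipole(map, u, frame)
  }
  J <- assemble_couplings(frame, topology, units, dipoles, config$coupling,
                          grids, maps)
  structure(list(
    time = if (!is.null(frame$time)) frame$time else NA_real_,
    omega = omega, J = J,
    anharmonicity = rep(config$anharmonicity, n),
    dipoles = t(vapply(dipoles, `[[`, numeric(3), "mu")),
    positions = t(vapply(dipoles, `[[`, numeric(3), "position"))
  ), class = "hamiltonian_frame")
}

map_exclusions <- function(map, unit, topology, units) {
  rule <- if (is.null(map$exclusion)) "nearest_residues" else map$exclusion
  switch(rule,
         none = integer(0),
         own_residue = sort(unique(unlist(
           topology$residues$atoms[unique(c(unit$res_c, unit$res_n))]))),
         nearest_residues = default_exclusions(unit, topology, units),
         stop("unknown exclusion rule: ", rule))
}

#' @export
print.hamiltonian_frame <- function(x, ...) {
  cat("hamiltonian_frame: ", length(x$omega), " sites, t = ", x$time,
      " fs, omega in [", signif(min(x$omega), 6), ", ",
      signif(max(x$omega), 6), "] cm^-1\n", sep = "")
  invisible(x)
}

.upper_tri_rowmajor <- function(M) {
  n <- nrow(M)
  unlist(lapply(seq_len(n), function(i) M[i, i:n]), use.names = FALSE)
}

.frame_matrix <- function(fr) {
  M <- fr$J
  diag(M) <- fr$omega
  M
}

#' Write a Hamiltonian trajectory
#'
#' Binary layout (bit-exact): per frame one 4-byte IEEE-754 single (the time
#' stamp in fs, or the 0-based frame counter when no time is available)
#' followed by the N(N+1)/2 singles of the upper triangle of the matrix with
#' site frequencies on the diagonal and couplings off-diagonal, row-major,
#' cm^-1, little-endian. The text format mirrors this, one frame per line.
#'
#' @param frames List of `hamiltonian_frame`s (constant site count).
#' @param path Output file.
#' @param format `"binary"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_hamiltonian <- function(frames, path, format = c("binary", "text")) {
  format <- match.arg(format)
  if (!length(frames)) stop("no frames to write")
  ns <- vapply(frames, function(f) length(f$omega), 0L)
  if (length(unique(ns)) != 1L)
    stop("inconsistent site count across frames: ",
         paste(unique(ns), collapse = ", "))
  recs <- lapply(seq_along(frames), function(k) {
    f <- frames[[k]]
    tm <- if (is.finite(f$time)) f$time else k - 1
    c(tm, .upper_tri_rowmajor(.frame_matrix(f)))
  })
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    for (r in recs) writeBin(as.numeric(r), con, size = 4L,
                             endian = "little")
  } else {
    writeLines(vapply(recs, function(r)
      paste(sprintf("%.8e", r), collapse = " "), ""), path)
  }
  invisible(path)
}

#' Read a Hamiltonian trajectory written by [write_hamiltonian()]
#'
#' @param path File.
#' @param n_sites Site count N.
#' @param format `"binary"` or `"text"`.
#' @return List of `hamiltonian_frame`s (without dipoles/positions).
#' @export
read_hamiltonian <- function(path, n_sites, format = c("binary", "text")) {
  format <- match.arg(format)
  ntri <- n_sites * (n_sites + 1) / 2
  if (format == "binary") {
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = sz / 4, size = 4L, endian = "little")
  } else {
    vals <- as.numeric(unlist(strsplit(trimws(readLines(path)), "\\s+")))
  }
  if (length(vals) %% (1 + ntri) != 0)
    stop("file length inconsistent with ", n_sites, " sites")
  nf <- length(vals) %/% (1 + ntri)
  lapply(seq_len(nf), function(k) {
    r <- vals[((k - 1) * (1 + ntri) + 1):(k * (1 + ntri))]
    M <- matrix(0, n_sites, n_sites)
    pos <- 2L
    for (i in seq_len(n_sites)) {
      M[i, i:n_sites] <- r[pos:(pos + n_sites - i)]
      pos <- pos + n_sites - i + 1L
    }
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    omega <- diag(M)
    diag(M) <- 0
    structure(list(time = r[1], omega = omega, J = M,
                   anharmonicity = NULL, dipoles = NULL, positions = NULL),
              class = "hamiltonian_frame")
  })
}

#' Write dipole or position trajectories
#'
#' Per frame: one 4-byte single (time stamp or counter) then the N x 3
#' components in component-major order (all x, then all y, then all z).
#'
#' @param frames List of `hamiltonian_frame`s.
#' @param path Output file.
#' @param which `"dipoles"` (Debye) or `"positions"` (nm).
#' @param format `"binary"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(frames, path, which = c("dipoles", "positions"),
                          format = c("binary", "text")) {
  which <- match.arg(which)
  format <- match.arg(format)
  if (!length(frames)) stop("no frames to write")
  ns <- vapply(frames, function(f) nrow(f[[which]]), 0L)
  if (length(unique(ns)) != 1L)
    stop("inconsistent site count across frames")
  recs <- lapply(seq_along(frames), function(k) {
    f <- frames[[k]]
    tm <- if (is.finite(f$time)) f$time else k - 1
    c(tm, as.numeric(f[[which]]))  # column-major = all x, all y, all z
  })
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    for (r in recs) writeBin(as.numeric(r), con, size = 4L, endian = "little")
  } else {
    writeLines(vapply(recs, function(r)
      paste(sprintf("%.8e", r), collapse = " "), ""), path)
  }
  invisible(path)
}

#' Read a vector trajectory written by [write_vectors()]
#'
#' @param path File.
#' @param n_sites Site count.
#' @param format `"binary"` or `"text"`.
#' @return List of per-frame lists with `time` and `xyz` (N x 3).
#' @export
read_vectors <- function(path, n_sites, format = c("binary", "text")) {
  format <- match.arg(format)
  rec <- 1 + 3 * n_sites
  if (format == "binary") {
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = sz / 4, size = 4L, endian = "little")
  } else {
    vals <- as.numeric(unlist(strsplit(trimws(readLines(path)), "\\s+")))
  }
  if (length(vals) %% rec != 0)
    stop("file length inconsistent with ", n_sites, " sites")
  nf <- length(vals) %/% rec
  lapply(seq_len(nf), function(k) {
    r <- vals[((k - 1) * rec + 1):(k * rec)]
    list(time = r[1], xyz = matrix(r[-1], n_sites, 3))
  })
}

#' Run the full pipeline on a topology + trajectory
#'
#' Streams the trajectory frame by frame (constant memory in trajectory
#' length), builds the Hamiltonian for every selected frame, and writes the
#' Hamiltonian, dipole and position trajectories plus a human-readable run
#' report. Deterministic given identical inputs.
#'
#' @param topology_file Topology (PDB or GRO).
#' @param trajectory_file Multi-frame GRO trajectory (defaults to the
#'   topology file itself).
#' @param charge_table Charge-table path or data.frame.
#' @param maps Map or per-class map list (see [build_frame()]).
#' @param grids Nearest-neighbour grids or `NULL`.
#' @param config [pipeline_config()].
#' @param out_prefix Output path prefix; writes `<prefix>_ham.bin`,
#'   `<prefix>_dip.bin`, `<prefix>_pos.bin`, `<prefix>_report.txt`.
#' @param frame_range `NULL` for all frames, else `c(first, last)` (1-based).
#' @param stride Keep every `stride`-th frame (default 1).
#' @param format Output format for the three trajectory files.
#' @return Invisibly, a list with the output paths, the unit table and the
#'   number of frames written.
#' @export
run_pipeline <- function(topology_file, trajectory_file = topology_file,
                         charge_table = NULL, maps, grids = NULL,
                         config = pipeline_config(), out_prefix,
                         frame_range = NULL, stride = 1L,
                         format = "binary") {
  top <- read_topology(topology_file, charge_table)
  units <- detect_amide_units(top)
  if (!length(units)) stop("no amide-I chromophores detected")
  paths <- list(hamiltonian = paste0(out_prefix, "_ham.bin"),
                dipoles = paste0(out_prefix, "_dip.bin"),
                positions = paste0(out_prefix, "_pos.bin"),
                report = paste0(out_prefix, "_report.txt"))
  mode <- if (format == "binary") c("wb", "w") else c("w", "w")
  con_h <- file(paths$hamiltonian, mode[1])
  con_d <- file(paths$dipoles, mode[1])
  con_p <- file(paths$positions, mode[1])
  ok <- FALSE
  on.exit({
    close(con_h); close(con_d); close(con_p)
    if (!ok) unlink(unlist(paths))  # never leave partial outputs behind
  })
  put <- function(con, vals) {
    if (format == "binary")
      writeBin(as.numeric(vals), con, size = 4L, endian = "little")
    else
      writeLines(paste(sprintf("%.8e", vals), collapse = " "), con)
  }
  reader <- gro_frame_reader(trajectory_file)
  nl <- NULL
  k <- 0L; kept <- 0L
  repeat {
    fr <- reader()
    if (is.null(fr)) break
    k <- k + 1L
    if (!is.null(frame_range) && (k < frame_range[1] || k > frame_range[2]))
      next
    first <- if (is.null(frame_range)) 1L else frame_range[1]
    if ((k - first) %% stride != 0) next
    kept <- kept + 1L
    if (is.null(fr$time) || is.na(fr$time))
      fr$time <- (kept - 1L) * config$timestep
    if (is.null(nl) || (k - nl$build_frame_index) >= config$rebuild_interval)
      nl <- build_neighbor_list(fr, units, config$search_cutoff,
                                config$rebuild_interval, config$map_cutoff,
                                frame_index = k)
    hf <- tryCatch(
      build_frame(fr, top, units, maps, grids, config, neighbor_list = nl),
      error = function(e) stop("frame ", k, ": ", conditionMessage(e)))
    tm <- if (is.finite(hf$time)) hf$time else kept - 1L
    put(con_h, c(tm, .upper_tri_rowmajor(.frame_matrix(hf))))
    put(con_d, c(tm, as.numeric(hf$dipoles)))
    put(con_p, c(tm, as.numeric(hf$positions)))
  }
  if (!kept) stop("no frames selected")
  ok <- TRUE
  map_names <- if (inherits(maps, "electrostatic_map")) maps$name else
    paste(vapply(maps, `[[`, "", "name"), collapse = ", ")
  report <- c(
    "amidemap run report",
    sprintf("topology:    %s", topology_file),
    sprintf("trajectory:  %s (%d frames read, %d written, stride %d)",
            trajectory_file, k, kept, stride),
    sprintf("maps:        %s", map_names),
    sprintf("coupling:    %s, epsilon_r = %g, prune < %g cm^-1, NN override %s",
            config$coupling$scheme, config$coupling$epsilon_r,
            config$coupling$prune_threshold, config$coupling$nn_override),
    sprintf("cutoffs:     map %g nm, neighbor search %g nm (rebuild every %d)",
            config$map_cutoff, config$search_cutoff, config$rebuild_interval),
    sprintf("anharmonicity: %g cm^-1 (constant per site)",
            config$anharmonicity),
    sprintf("class shifts: preproline -%g, side chain +%g cm^-1",
            config$preproline_shift, config$sidechain_shift),
    "",
    sprintf("units (%d):", length(units)),
    format(units)
  )
  writeLines(report, paths$report)
  invisible(list(paths = paths, units = units, n_frames = kept,
                 n_sites = length(units)))
}
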