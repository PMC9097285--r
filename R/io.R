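## Topology and trajectory I/O.
##
## GRO files (Gromos87 fixed-width, positions in nm) are parsed directly;
## PDB topologies go through bio3d::read.pdb with coordinates converted from
## Angstrom to nm. Trajectories are concatenated GRO frames, which keeps every
## fixture a plain-text file and exercises the same reader as real input.

#' Read a GRO topology/trajectory file
#'
#' Reads one or all frames of a (possibly concatenated multi-frame) GRO file.
#'
#' @param path File path.
#' @param frames `"all"` or integer vector of 1-based frame numbers.
#' @return A list with `atoms` (data.frame: `serial`, `resno`, `resname`,
#'   `name`, `chain`) and `frames`, a list of frames each holding `xyz`
#'   (n x 3 matrix, nm), `box` (length-3, nm) and `time` (fs, `NA` if the
#'   title carries no time stamp).
#' @export
read_gro <- function(path, frames = "all") {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  nframe <- 0L
  atoms <- NULL
  want <- if (identical(frames, "all")) NULL else as.integer(frames)
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms))
      stop("malformed GRO file at line ", i + 1L, ": expected atom count")
    body <- lines[(i + 2L):(i + 1L + natoms)]
    boxline <- strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]
    nframe <- nframe + 1L
    keep <- is.null(want) || (nframe %in% want)
    if (keep) {
      if (is.null(atoms)) {
        atoms <- data.frame(
          serial  = as.integer(substr(body, 16L, 20L)),
          resno   = as.integer(substr(body, 1L, 5L)),
          resname = trimws(substr(body, 6L, 10L)),
          name    = trimws(substr(body, 11L, 15L)),
          chain   = "A",
          stringsAsFactors = FALSE
        )
      }
      xyz <- cbind(as.numeric(substr(body, 21L, 28L)),
                   as.numeric(substr(body, 29L, 36L)),
                   as.numeric(substr(body, 37L, 44L)))
      tm <- NA_real_
      m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
      if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m)) * 1000  # ps -> fs
      out[[length(out) + 1L]] <- list(
        xyz = xyz,
        box = as.numeric(boxline[1:3]),
        time = tm
      )
    }
    i <- i + 3L + natoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (is.null(atoms)) stop("no frames read from ", path)
  list(atoms = atoms, frames = out)
}

#' Write a GRO topology/trajectory file
#'
#' @param atoms Atom table as returned by [read_gro()].
#' @param frames List of frames (`xyz` in nm, `box`, optional `time` in fs).
#' @param path Output path.
#' @param title Title string prefix; the frame time (ps) is appended.
#' @export
write_gro <- function(atoms, frames, path, title = "amidemap fixture") {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(atoms)
  for (fr in frames) {
    tm <- if (!is.null(fr$time) && !is.na(fr$time)) fr$time / 1000 else 0
    writeLines(sprintf("%s t= %.4f", title, tm), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$resno %% 100000L, atoms$resname, atoms$name,
                       atoms$serial %% 100000L,
                       fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}

#' Read a force-field charge table
#'
#' Plain text, one atom per line: `resname atomname charge`, `#` comments.
#' A `resname` of `*` matches any residue.
#'
#' @param path File path.
#' @return data.frame with `resname`, `name`, `charge`.
#' @export
read_charge_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed charge-table entry at line ", bad[1])
  data.frame(
    resname = vapply(parts, `[`, "", 1L),
    name    = vapply(parts, `[`, "", 2L),
    charge  = as.numeric(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

assign_charges <- function(atoms, charge_table) {
  key <- paste(atoms$resname, atoms$name)
  tab <- stats::setNames(charge_table$charge,
                         paste(charge_table$resname, charge_table$name))
  q <- unname(tab[key])
  wild <- is.na(q)
  if (any(wild)) {
    tabw <- stats::setNames(charge_table$charge[charge_table$resname == "*"],
                            charge_table$name[charge_table$resname == "*"])
    q[wild] <- unname(tabw[atoms$name[wild]])
  }
  q[is.na(q)] <- 0
  q
}

#' Read a topology (PDB or GRO) into an `amide_topology`
#'
#' The reference frame is the first frame of the file. Partial charges are
#' taken from `charge_table` when given (PDB/GRO files carry none), else zero.
#'
#' @param path PDB or GRO file.
#' @param charge_table Optional path to a charge table ([read_charge_table()])
#'   or a data.frame in that layout.
#' @return An `amide_topology`: list with `atoms` (including `charge`),
#'   `frame` (reference frame) and `residues` (per-residue atom index table).
#' @export
read_topology <- function(path, charge_table = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    g <- read_gro(path, frames = 1L)
    atoms <- g$atoms
    frame <- g$frames[[1]]
  } else if (ext %in% c("pdb", "ent")) {
    p <- bio3d::read.pdb(path)
    a <- p$atom
    atoms <- data.frame(
      serial  = a$eleno,
      resno   = a$resno,
      resname = a$resid,
      name    = a$elety,
      chain   = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
      stringsAsFactors = FALSE
    )
    frame <- list(
      xyz = cbind(a$x, a$y, a$z) / 10,  # Angstrom -> nm
      box = NULL, time = NA_real_
    )
  } else {
    stop("unsupported topology format: .", ext, " (use PDB or GRO)")
  }
  if (!is.null(charge_table)) {
    if (is.character(charge_table)) charge_table <- read_charge_table(charge_table)
    atoms$charge <- assign_charges(atoms, charge_table)
  } else {
    atoms$charge <- 0
  }
  structure(
    list(atoms = atoms, frame = frame, residues = residue_table(atoms)),
    class = "amide_topology"
  )
}

## Per-residue grouping: one row per (chain, resno, resname) in file order.
residue_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resname, sep = "\r")
  first <- !duplicated(key)
  idx <- split(seq_len(nrow(atoms)), factor(key, levels = key[first]))
  data.frame(
    chain   = atoms$chain[first],
    resno   = atoms$resno[first],
    resname = atoms$resname[first],
    atoms   = I(unname(idx)),
    stringsAsFactors = FALSE
  )
}

#' Construct an `amide_topology` from in-memory tables
#'
#' Used by the fixture generator and useful for programmatic setups.
#'
#' @param atoms Atom data.frame (`serial`, `resno`, `resname`, `name`,
#'   `chain`, optionally `charge`).
#' @param frame Reference frame (`xyz` nm, `box`).
#' @return An `amide_topology`.
#' @export
as_topology <- function(atoms, frame) {
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$chain)) atoms$chain <- "A"
  structure(
    list(atoms = atoms, frame = frame, residues = residue_table(atoms)),
    class = "amide_topology"
  )
}

#' @export
print.amide_topology <- function(x, ...) {
  cat("amide_topology:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Stream frames of a multi-frame GRO trajectory
#'
#' Returns a closure yielding one frame per call (`NULL` at end of file), so
#' the pipeline's memory use is independent of trajectory length.
#'
#' @param path GRO trajectory.
#' @return Function of no arguments returning a frame or `NULL`.
#' @export
gro_frame_reader <- function(path) {
  con <- file(path, "r")
  done <- FALSE
  function() {
    if (done) return(NULL)
    title <- readLines(con, n = 1L)
    if (!length(title) || !nzchar(trimws(title))) {
      close(con); done <<- TRUE; return(NULL)
    }
    natoms <- as.integer(trimws(readLines(con, n = 1L)))
    body <- readLines(con, n = natoms)
    boxline <- strsplit(trimws(readLines(con, n = 1L)), "\\s+")[[1]]
    xyz <- cbind(as.numeric(substr(body, 21L, 28L)),
                 as.numeric(substr(body, 29L, 36L)),
                 as.numeric(substr(body, 37L, 44L)))
    tm <- NA_real_
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m)) * 1000
    list(xyz = xyz, box = as.numeric(boxline[1:3]), time = tm)
  }
}
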