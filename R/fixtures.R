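## Deterministic synthetic fixtures.
##
## Peptides are built from ideal bond lengths/angles and per-kind
## Ramachandran dihedrals (helix -57/-47, sheet -139/135), optionally
## surrounded by a shell of point charges. Trajectories move the solvent
## charges by an Ornstein-Uhlenbeck process with a sub-100-fs correlation
## time, emulating the fast site-frequency fluctuations behind motional
## narrowing, at 20 fs frame spacing. Everything is seeded and byte-stable;
## fixtures are written in the same standard formats the pipeline reads.

.bb <- list(b_NCa = 0.1458, b_CaC = 0.1525, b_CN = 0.1329, b_CO = 0.1229,
            b_NH = 0.100, a_NCaC = 111.0, a_CaCN = 116.6, a_CNCa = 121.9,
            a_CaCO = 120.5, a_CNH = 119.0, omega = 180)

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Fixture specification
#'
#' The defaults are the study conditions the fixtures emulate: 20 fs frame
#' spacing and solvent-charge motion with a 50 fs correlation time (the
#' sub-100-fs regime responsible for motional narrowing).
#'
#' @param kind One of `"ideal_helix"`, `"ideal_sheet_dimer"`,
#'   `"cyclic_peptide"`, `"dimer_scan"`, `"fluctuating"`.
#' @param n_residues Residues per chain (defaults: 10; cyclic 5; dimer 2).
#' @param residues Optional residue-name vector (e.g. to place `PRO`, `ASN`,
#'   `GLN`); defaults to all-`ALA`.
#' @param seed RNG seed (default 1). Identical specs give byte-identical
#'   fixtures.
#' @param n_frames Number of trajectory frames (default 1).
#' @param timestep Frame spacing, fs (default 20).
#' @param n_charges Solvent point charges (default 0; `"fluctuating"`
#'   defaults to 40).
#' @param charge_magnitude Source charge magnitude, e (default 0.4).
#' @param displacement Solvent OU displacement scale sigma, nm (default
#'   0.02).
#' @param correlation_time Solvent OU correlation time, fs (default 50).
#' @param separation Dimer separation for `"dimer_scan"`, nm (default 3).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("ideal_helix", "ideal_sheet_dimer",
                                  "cyclic_peptide", "dimer_scan",
                                  "fluctuating"),
                         n_residues = NULL, residues = NULL, seed = 1,
                         n_frames = 1, timestep = 20, n_charges = NULL,
                         charge_magnitude = 0.4, displacement = 0.02,
                         correlation_time = 50, separation = 3) {
  kind <- match.arg(kind)
  if (is.null(n_residues))
    n_residues <- switch(kind, cyclic_peptide = 5, dimer_scan = 2, 10)
  if (is.null(n_charges))
    n_charges <- if (kind == "fluctuating") 40 else 0
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (correlation_time <= 0) stop("correlation_time must be > 0")
  structure(list(kind = kind, n_residues = n_residues, residues = residues,
                 seed = seed, n_frames = n_frames, timestep = timestep,
                 n_charges = n_charges, charge_magnitude = charge_magnitude,
                 displacement = displacement,
                 correlation_time = correlation_time,
                 separation = separation),
            class = "fixture_spec")
}

## Minimal side-chain atoms so that detection/classification sees PRO, ASN
## and GLN; geometry is idealized, not force-field quality.
.sidechain_rows <- function(rn, N, CA, C, Cprev) {
  out <- list()
  add <- function(name, xyz) out[[length(out) + 1L]] <<- list(name = name,
                                                              xyz = xyz)
  if (rn %in% c("ALA", "ASN", "GLN", "PRO")) {
    CB <- place_atom(C, N, CA, 0.153, 110.5, -122)
    if (rn != "PRO") add("CB", CB)
  }
  if (rn == "ASN") {
    CG <- place_atom(N, CA, CB, 0.152, 113, -60)
    add("CG", CG)
    OD1 <- place_atom(CA, CB, CG, 0.1229, 121, -60)
    ND2 <- place_atom(CA, CB, CG, 0.1335, 117, 120)
    add("OD1", OD1); add("ND2", ND2)
    add("HD21", place_atom(CB, CG, ND2, 0.1, 119, 180))
    add("HD22", place_atom(CB, CG, ND2, 0.1, 119, 0))
  }
  if (rn == "GLN") {
    CG <- place_atom(N, CA, CB, 0.152, 113, -60)
    add("CG", CG)
    CD <- place_atom(CA, CB, CG, 0.152, 113, 180)
    add("CD", CD)
    OE1 <- place_atom(CB, CG, CD, 0.1229, 121, -60)
    NE2 <- place_atom(CB, CG, CD, 0.1335, 117, 120)
    add("OE1", OE1); add("NE2", NE2)
    add("HE21", place_atom(CG, CD, NE2, 0.1, 119, 180))
    add("HE22", place_atom(CG, CD, NE2, 0.1, 119, 0))
  }
  if (rn == "PRO" && !is.null(Cprev)) {
    add("CD", place_atom(CA, Cprev, N, 0.147, 125, 80))
  }
  out
}

## Linear backbone from ideal internal coordinates (NeRF chain extension).
.build_chain <- function(n, phi, psi, residues, resno_offset = 0L) {
  g <- .bb
  rows <- list()
  addrow <- function(resno, resname, name, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = resno + resno_offset, resname = resname, name = name,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  if (length(phi) == 1) phi <- rep(phi, n)
  if (length(psi) == 1) psi <- rep(psi, n)
  N <- c(0, 0, 0)
  CA <- c(g$b_NCa, 0, 0)
  th <- (180 - g$a_NCaC) * pi / 180
  C <- CA + g$b_CaC * c(cos(th), sin(th), 0)
  Hcur <- NULL; Cprev <- NULL
  for (i in seq_len(n)) {
    rn <- residues[i]
    addrow(i, rn, "N", N)
    if (rn != "PRO") {
      H <- if (is.null(Hcur)) place_atom(C, CA, N, g$b_NH, g$a_CNH, 180)
           else Hcur
      addrow(i, rn, "H", H)
    }
    addrow(i, rn, "CA", CA)
    for (sc in .sidechain_rows(rn, N, CA, C, Cprev))
      addrow(i, rn, sc$name, sc$xyz)
    O <- place_atom(N, CA, C, g$b_CO, g$a_CaCO, psi[i] + 180)
    addrow(i, rn, "C", C)
    addrow(i, rn, "O", O)
    if (i < n) {
      Nn <- place_atom(N, CA, C, g$b_CN, g$a_CaCN, psi[i])
      CAn <- place_atom(CA, C, Nn, g$b_NCa, g$a_CNCa, g$omega)
      Hcur <- place_atom(CA, C, Nn, g$b_NH, g$a_CNH, 0)
      Cn <- place_atom(C, Nn, CAn, g$b_CaC, g$a_NCaC, phi[i + 1])
      Cprev <- C
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  do.call(rbind, rows)
}

## Planar ring: backbone atoms evenly spaced on a circle so every
## consecutive C--N pair (including last -> first) is within bonding range.
.build_ring <- function(n, residues) {
  npts <- 3 * n
  d <- 0.145
  R <- d / (2 * sin(pi / npts))
  ang <- function(k) 2 * pi * k / npts
  out <- list()
  add <- function(resno, resname, name, xyz)
    out[[length(out) + 1L]] <<- data.frame(
      resno = resno, resname = resname, name = name,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    k <- 3 * (i - 1)
    pN <- R * c(cos(ang(k)), sin(ang(k)), 0)
    pCA <- R * c(cos(ang(k + 1)), sin(ang(k + 1)), 0)
    pC <- R * c(cos(ang(k + 2)), sin(ang(k + 2)), 0)
    rn <- residues[i]
    add(i, rn, "N", pN)
    if (rn != "PRO") add(i, rn, "H", pN * (1 - 0.1 / R))
    add(i, rn, "CA", pCA)
    add(i, rn, "C", pC)
    add(i, rn, "O", pC * (1 + 0.123 / R))
  }
  do.call(rbind, out)
}

#' Built-in fixture charge table
#'
#' Small per-atom partial-charge table (e) for the fixture peptides and the
#' solvent point charges (`QP`/`QM`).
#'
#' @param charge_magnitude Magnitude of the solvent charges, e.
#' @return data.frame usable as a charge table.
#' @export
builtin_charge_table <- function(charge_magnitude = 0.4) {
  data.frame(
    resname = c(rep("*", 12), "CHG", "CHG"),
    name = c("N", "H", "CA", "C", "O", "CB", "CG", "CD", "OD1", "ND2",
             "OE1", "NE2", "QP", "QM"),
    charge = c(-0.47, 0.31, 0.07, 0.51, -0.51, 0, 0.1, 0.51, -0.51, -0.47,
               -0.51, -0.47, charge_magnitude, -charge_magnitude),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic peptide fixture
#'
#' Builds the topology and reference frame of the requested kind, plus the
#' requested number of trajectory frames (solvent charges moving by an
#' Ornstein-Uhlenbeck process, peptide rigid; with no solvent all frames are
#' identical).
#'
#' @param spec [fixture_spec()].
#' @return List with `topology` (`amide_topology`, charges assigned from
#'   [builtin_charge_table()]), `frames` (list of frames), and `spec`.
#' @export
make_peptide <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  residues <- spec$residues
  if (is.null(residues)) residues <- rep("ALA", n)
  if (length(residues) != n) stop("residues must have length n_residues")
  at <- switch(
    spec$kind,
    ideal_helix = .build_chain(n, -57, -47, residues),
    fluctuating = .build_chain(n, -57, -47, residues),
    ideal_sheet_dimer = {
      s1 <- .build_chain(n, -139, 135, residues)
      s2 <- .build_chain(n, -139, 135, residues, resno_offset = n)
      s2$y <- s2$y + 1.0   # second strand offset; couplings only, no bonds
      rbind(s1, s2)
    },
    cyclic_peptide = .build_ring(n, residues),
    dimer_scan = {
      s1 <- .build_chain(2, -139, 135, residues[1:2])
      s2 <- .build_chain(2, -139, 135, residues[1:2], resno_offset = 2)
      s2$z <- s2$z + spec$separation
      rbind(s1, s2)
    }
  )
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  if (min(stats::dist(xyz)) < 0.05)
    stop("steric clash in generated fixture geometry (atom pair below ",
         "0.05 nm); adjust the spec")
  xyz <- xyz - matrix(colMeans(xyz), nrow(xyz), 3, byrow = TRUE)
  atoms <- data.frame(serial = seq_len(nrow(at)), resno = at$resno,
                      resname = at$resname, name = at$name, chain = "A",
                      stringsAsFactors = FALSE)
  solvent_home <- NULL
  if (spec$n_charges > 0) {
    solvent_home <- .with_seed(spec$seed, {
      placed <- matrix(NA_real_, 0, 3)
      lo <- apply(xyz, 2, min) - 0.8
      hi <- apply(xyz, 2, max) + 0.8
      tries <- 0
      while (nrow(placed) < spec$n_charges && tries < 20000) {
        tries <- tries + 1
        p <- stats::runif(3, lo, hi)
        dmin <- min(sqrt(rowSums((xyz - matrix(p, nrow(xyz), 3,
                                               byrow = TRUE))^2)))
        dsol <- if (nrow(placed)) min(sqrt(rowSums(
          (placed - matrix(p, nrow(placed), 3, byrow = TRUE))^2))) else Inf
        if (dmin >= 0.3 && dsol >= 0.25) placed <- rbind(placed, p)
      }
      if (nrow(placed) < spec$n_charges)
        stop("could not place the solvent charges without clashes")
      placed
    })
    ns <- spec$n_charges
    atoms <- rbind(atoms, data.frame(
      serial = nrow(at) + seq_len(ns),
      resno = max(at$resno) + seq_len(ns),
      resname = "CHG",
      name = rep(c("QP", "QM"), length.out = ns),
      chain = "A", stringsAsFactors = FALSE))
    xyz <- rbind(xyz, solvent_home)
  }
  span <- apply(xyz, 2, function(v) diff(range(v)))
  box <- ceiling((span + 3) * 10) / 10
  xyz <- xyz + matrix(box / 2, nrow(xyz), 3, byrow = TRUE)
  atoms$charge <- assign_charges(atoms,
                                 builtin_charge_table(spec$charge_magnitude))
  frames <- .make_frames(xyz, box, spec,
                         solvent_idx = if (is.null(solvent_home)) integer(0)
                         else nrow(at) + seq_len(spec$n_charges))
  list(topology = as_topology(atoms, frames[[1]]), frames = frames,
       spec = spec)
}

.make_frames <- function(xyz, box, spec, solvent_idx) {
  nf <- spec$n_frames
  frames <- vector("list", nf)
  if (!length(solvent_idx) || spec$displacement == 0) {
    for (k in seq_len(nf))
      frames[[k]] <- list(xyz = xyz, box = box,
                          time = (k - 1) * spec$timestep)
    return(frames)
  }
  m <- length(solvent_idx)
  home <- xyz[solvent_idx, , drop = FALSE]
  a <- exp(-spec$timestep / spec$correlation_time)
  s_eq <- spec$displacement
  s_step <- s_eq * sqrt(1 - a^2)
  .with_seed(spec$seed + 1L, {
    u <- matrix(stats::rnorm(m * 3, 0, s_eq), m, 3)
    for (k in seq_len(nf)) {
      xk <- xyz
      xk[solvent_idx, ] <- home + u
      frames[[k]] <- list(xyz = xk, box = box,
                          time = (k - 1) * spec$timestep)
      u <- a * u + matrix(stats::rnorm(m * 3, 0, s_step), m, 3)
    }
  })
  frames
}

#' Generate only the frames of a fluctuating fixture
#'
#' Convenience wrapper returning the trajectory frames of [make_peptide()]
#' for a `"fluctuating"`-style spec.
#'
#' @param spec [fixture_spec()].
#' @return List of frames.
#' @export
make_fluctuating_trajectory <- function(spec) make_peptide(spec)$frames

#' Write a fixture to disk
#'
#' Emits `<base>.gro` (topology = first frame), `<base>_traj.gro` (all
#' frames), `<base>_charges.txt` and `<base>_config.yaml`, all plain text in
#' the formats the pipeline reads.
#'
#' @param fix Result of [make_peptide()].
#' @param dir Output directory.
#' @param base File-name base (default the fixture kind).
#' @return Named list of paths, invisibly.
#' @export
write_fixture <- function(fix, dir, base = fix$spec$kind) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(topology = file.path(dir, paste0(base, ".gro")),
                trajectory = file.path(dir, paste0(base, "_traj.gro")),
                charges = file.path(dir, paste0(base, "_charges.txt")),
                config = file.path(dir, paste0(base, "_config.yaml")))
  atoms <- fix$topology$atoms
  write_gro(atoms, fix$frames[1], paths$topology)
  write_gro(atoms, fix$frames, paths$trajectory)
  ct <- builtin_charge_table(fix$spec$charge_magnitude)
  writeLines(c("# amidemap fixture charge table (resname atom charge)",
               sprintf("%-5s %-5s %8.4f", ct$resname, ct$name, ct$charge)),
             paths$charges)
  yaml::write_yaml(list(
    topology = paths$topology, trajectory = paths$trajectory,
    charge_table = paths$charges,
    map_cutoff = 2.0, search_cutoff = 2.5, rebuild_interval = 50,
    epsilon_r = 1, anharmonicity = 16, timestep = fix$spec$timestep,
    coupling_scheme = "TDC", prune_threshold = 0.01
  ), paths$config)
  invisible(paths)
}
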