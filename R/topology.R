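## Amide-I chromophore recognition.
##
## Every backbone peptide bond is one chromophore; glutamine and asparagine
## contribute one primary side-chain amide each. Units preceding proline are
## tertiary amides (no N-H). Connectivity (prev/next along the backbone) is
## established per chain, with chain breaks severing links and head-to-tail
## bonded chains closing into cycles.

.aa_names <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
               "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
               "TYR", "VAL", "HID", "HIE", "HIP", "HSD", "HSE", "HSP", "CYX",
               "CYM", "MSE", "LYN", "ASH", "GLH")

.solvent_names <- c("SOL", "HOH", "WAT", "TIP3", "TIP4", "TIP5", "SPC",
                    "NA", "CL", "NA+", "CL-", "K", "K+", "MG", "ZN", "CA2",
                    "ION", "CHG")

.h_names <- c("H", "HN", "D", "DN", "H1")

#' Read a residue-recognition extension file
#'
#' YAML list of stanzas extending chromophore detection to nonstandard
#' residues. Each stanza has `resname`, `kind` (`"backbone"` to treat the
#' residue as a standard amino acid, `"sidechain"` to declare a side-chain
#' amide), and for side chains a `roles` table mapping `C`, `O`, `N`, `H` to
#' atom names.
#'
#' @param path YAML file.
#' @return List of extension entries.
#' @export
read_residue_extensions <- function(path) {
  ext <- yaml::read_yaml(path)
  ext <- lapply(ext, function(e) {
    e$roles <- .fix_role_names(e$roles)
    e
  })
  for (e in ext) {
    if (is.null(e$resname) || is.null(e$kind) ||
        !e$kind %in% c("backbone", "sidechain"))
      stop("residue extension entries need 'resname' and kind backbone/sidechain")
    if (e$kind == "sidechain" &&
        !all(c("C", "O", "N") %in% names(e$roles)))
      stop("side-chain extension for ", e$resname,
           " must map roles C, O and N to atom names")
  }
  ext
}

.find_atom <- function(atoms, resrow, names_wanted) {
  idx <- resrow$atoms[[1]]
  hit <- idx[match(names_wanted, atoms$name[idx])]
  hit <- hit[!is.na(hit)]
  if (length(hit)) hit[1] else NA_integer_
}

.dist_mi <- function(x, y, box) {
  d <- y - x
  if (!is.null(box) && all(is.finite(box)) && all(box > 0))
    d <- d - box * floor(d / box + 0.5)
  sqrt(sum(d * d))
}

#' Detect all amide-I chromophores in a topology
#'
#' Scans each chain for peptide bonds (consecutive amino-acid residues whose
#' C--N distance in the reference frame is below `bond_cutoff`), appends one
#' primary amide per Gln/Asn side chain, classifies every unit, and links
#' backbone neighbours. A chain whose last residue is bonded back to its first
#' closes into a cycle. Unit ids are 0-based: backbone units ordered by chain
#' then sequence, side-chain units appended after all backbone units.
#'
#' @param topology An `amide_topology`.
#' @param frame Frame used for distance tests (default: the reference frame).
#' @param extensions Optional list from [read_residue_extensions()].
#' @param bond_cutoff C--N bond criterion in nm (default 0.2).
#' @return An `amide_units` object: list of units, each with `unit_id`,
#'   `atoms` (named indices `C`, `O`, `N`, `H`, `CA_prev`, `CA_next`),
#'   `amide_class`, `chain`, `prev_unit`, `next_unit`, `residue_label`.
#' @export
detect_amide_units <- function(topology, frame = topology$frame,
                               extensions = NULL, bond_cutoff = 0.2) {
  atoms <- topology$atoms
  res <- topology$residues
  ext_bb <- character(0)
  ext_sc <- list()
  for (e in extensions) {
    if (e$kind == "backbone") ext_bb <- c(ext_bb, e$resname)
    if (e$kind == "sidechain") ext_sc[[e$resname]] <- e$roles
  }
  aa <- res$resname %in% c(.aa_names, ext_bb)
  unknown <- setdiff(res$resname[!aa], .solvent_names)
  unknown <- setdiff(unknown, names(ext_sc))
  if (length(unknown))
    warning("skipping unrecognized residue name(s): ",
            paste(unique(unknown), collapse = ", "),
            " (declare them in a residue extension file to include them)")

  units <- list()
  add_unit <- function(u) units[[length(units) + 1L]] <<- u

  for (ch in sort(unique(res$chain[aa]))) {
    rows <- which(aa & res$chain == ch)
    rows <- rows[order(res$resno[rows])]
    n <- length(rows)
    if (n < 2L) next
    pairs <- cbind(rows[-n], rows[-1L])
    if (n >= 3L) pairs <- rbind(pairs, c(rows[n], rows[1L]))  # cyclic probe
    chain_units <- integer(0)
    closes <- FALSE
    for (k in seq_len(nrow(pairs))) {
      r <- pairs[k, 1]; s <- pairs[k, 2]
      iC <- .find_atom(atoms, res[r, ], "C")
      iN <- .find_atom(atoms, res[s, ], "N")
      lab <- function(row) paste0(res$resname[row], res$resno[row])
      if (is.na(iC))
        stop("residue ", lab(r), " (chain ", ch, ") lacks a backbone C atom")
      if (is.na(iN))
        stop("residue ", lab(s), " (chain ", ch, ") lacks a backbone N atom")
      if (.dist_mi(frame$xyz[iC, ], frame$xyz[iN, ], frame$box) >= bond_cutoff)
        next
      iO <- .find_atom(atoms, res[r, ], "O")
      if (is.na(iO))
        stop("residue ", lab(r), " (chain ", ch, ") lacks a backbone O atom")
      iH <- .find_atom(atoms, res[s, ], .h_names)
      cls <- if (res$resname[s] == "PRO") "tertiary_preproline" else "secondary"
      if (cls == "tertiary_preproline") iH <- NA_integer_
      u <- list(
        atoms = c(C = iC, O = iO, N = iN, H = iH,
                  CA_prev = .find_atom(atoms, res[r, ], "CA"),
                  CA_next = .find_atom(atoms, res[s, ], "CA")),
        amide_class = cls, chain = ch,
        res_c = r, res_n = s, sidechain = FALSE,
        residue_label = paste0(lab(r), "-", lab(s))
      )
      if (k == n) { closes <- TRUE }  # the wrap-around bond
      add_unit(u)
      chain_units <- c(chain_units, length(units))
    }
    ## link prev/next: consecutive detected bonds share a residue
    m <- length(chain_units)
    for (a in seq_len(m)) {
      b <- if (a < m) a + 1L else if (closes || FALSE) 1L else NA_integer_
      if (is.na(b)) next
      ua <- chain_units[a]; ub <- chain_units[b]
      if (identical(units[[ua]]$res_n, units[[ub]]$res_c)) {
        units[[ua]]$next_unit_pos <- ub
        units[[ub]]$prev_unit_pos <- ua
      }
    }
  }

  ## side-chain amides
  sc_roles <- list(
    GLN = list(C = "CD", O = "OE1", N = "NE2",
               H = c("HE21", "HE22", "1HE2", "2HE2")),
    ASN = list(C = "CG", O = "OD1", N = "ND2",
               H = c("HD21", "HD22", "1HD2", "2HD2"))
  )
  for (nm in names(ext_sc)) sc_roles[[nm]] <- ext_sc[[nm]]
  sc_rows <- which(res$resname %in% names(sc_roles))
  sc_rows <- sc_rows[order(res$chain[sc_rows], res$resno[sc_rows])]
  for (r in sc_rows) {
    roles <- sc_roles[[res$resname[r]]]
    iC <- .find_atom(atoms, res[r, ], roles$C)
    iO <- .find_atom(atoms, res[r, ], roles$O)
    iN <- .find_atom(atoms, res[r, ], roles$N)
    if (any(is.na(c(iC, iO, iN))))
      stop("side-chain amide of ", res$resname[r], res$resno[r],
           " (chain ", res$chain[r], ") is missing a C, O or N atom")
    add_unit(list(
      atoms = c(C = iC, O = iO, N = iN,
                H = .find_atom(atoms, res[r, ], roles$H),
                CA_prev = NA_integer_, CA_next = NA_integer_),
      amide_class = "primary_sidechain", chain = res$chain[r],
      res_c = r, res_n = r, sidechain = TRUE,
      residue_label = paste0(res$resname[r], res$resno[r], "-sidechain")
    ))
  }

  ## assign 0-based ids (list order is already backbone-then-sidechain)
  for (i in seq_along(units)) units[[i]]$unit_id <- i - 1L
  for (i in seq_along(units)) {
    p <- units[[i]]$prev_unit_pos
    nx <- units[[i]]$next_unit_pos
    units[[i]]$prev_unit <- if (is.null(p)) NA_integer_ else units[[p]]$unit_id
    units[[i]]$next_unit <- if (is.null(nx)) NA_integer_ else units[[nx]]$unit_id
    units[[i]]$prev_unit_pos <- NULL
    units[[i]]$next_unit_pos <- NULL
  }
  structure(units, class = "amide_units")
}

#' @export
print.amide_units <- function(x, ...) {
  cls <- vapply(x, `[[`, "", "amide_class")
  cat("amide_units:", length(x), "chromophores (",
      sum(cls == "secondary"), "secondary,",
      sum(cls == "tertiary_preproline"), "preproline,",
      sum(cls == "primary_sidechain"), "side-chain )\n")
  invisible(x)
}

#' @export
format.amide_units <- function(x, ...) {
  vapply(x, function(u)
    sprintf("%3d %-22s %-19s prev=%3s next=%3s", u$unit_id, u$residue_label,
            u$amide_class, format(u$prev_unit), format(u$next_unit)), "")
}

#' Classify one amide unit
#'
#' Total classification: a backbone unit whose nitrogen belongs to a proline
#' is a tertiary (preproline) amide, Gln/Asn side-chain amides are primary,
#' and every other peptide bond is a secondary amide.
#'
#' @param unit One element of an `amide_units` object.
#' @param topology The `amide_topology` the unit was detected in.
#' @return `"secondary"`, `"tertiary_preproline"` or `"primary_sidechain"`.
#' @export
classify_unit <- function(unit, topology) {
  if (isTRUE(unit$sidechain)) return("primary_sidechain")
  if (topology$residues$resname[unit$res_n] == "PRO")
    return("tertiary_preproline")
  "secondary"
}

#' Ramachandran angles governing a unit's nearest-neighbour corrections
#'
#' For a backbone unit, the link to its previous neighbour runs through the
#' residue the two bonds share; that residue's (phi, psi) pair is returned as
#' `prev`, and likewise `next` for the following link. Pairs that need a
#' flanking atom missing at a terminus are `NA` (the nearest-neighbour
#' correction for that link is then skipped).
#'
#' @param unit One amide unit.
#' @param topology The parent `amide_topology`.
#' @param units The full `amide_units` set (for neighbour lookups).
#' @param frame Coordinates to use.
#' @return List with `prev` and `next`, each `c(phi, psi)` in degrees in
#'   `[-180, 180)` or `c(NA, NA)`.
#' @export
ramachandran_angles <- function(unit, topology, units,
                                frame = topology$frame) {
  if (isTRUE(unit$sidechain))
    return(list(prev = c(phi = NA_real_, psi = NA_real_),
                `next` = c(phi = NA_real_, psi = NA_real_)))
  by_id <- function(id) {
    if (is.na(id)) return(NULL)
    for (u in units) if (u$unit_id == id) return(u)
    NULL
  }
  xyz <- frame$xyz
  pair_for <- function(uA, uB) {
    ## shared residue s: uA$res_n == uB$res_c
    if (is.null(uA) || is.null(uB)) return(c(phi = NA_real_, psi = NA_real_))
    c(phi = dihedral_angle(xyz[uA$atoms["C"], ], xyz[uA$atoms["N"], ],
                           xyz[uA$atoms["CA_next"], ], xyz[uB$atoms["C"], ]),
      psi = dihedral_angle(xyz[uA$atoms["N"], ], xyz[uA$atoms["CA_next"], ],
                           xyz[uB$atoms["C"], ], xyz[uB$atoms["N"], ]))
  }
  list(prev = pair_for(by_id(unit$prev_unit), unit),
       `next` = pair_for(unit, by_id(unit$next_unit)))
}
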