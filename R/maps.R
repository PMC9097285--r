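## Frequency maps and nearest-neighbour grids.
##
## A map is a pure linear form: site frequency = gas-phase frequency + sum of
## coefficients times electrostatic components at the map atoms. Components
## are contracted in the local amide frame (x along C=O, z normal to the
## O=C-N plane), which makes the predicted frequency invariant under rigid
## rotations of the system. The engine is value-agnostic: coefficient values
## are data, loaded from YAML map files; the maps shipped under
## inst/extdata/maps are synthetic demonstration maps.

.map_roles <- c("C", "O", "N", "H")
.comp_names <- c("potential",
                 "field_x", "field_y", "field_z",
                 "gradient_xx", "gradient_xy", "gradient_xz",
                 "gradient_yy", "gradient_yz", "gradient_zz")

#' Construct an electrostatic frequency map
#'
#' @param name Map name.
#' @param gas_phase_frequency Gas-phase site frequency omega_0, cm^-1.
#' @param coefficients Named list per map atom role (`C`, `O`, `N`, `H`); each
#'   entry a named numeric vector over (a subset of) `potential`,
#'   `field_x/y/z`, `gradient_xx/xy/xz/yy/yz/zz`, in cm^-1 per atomic unit.
#' @param dipole List `magnitude` (Debye), `angle` (degrees from the C=O axis
#'   in the O=C-N plane, positive toward N), `offset` (nm along C=O from C).
#' @param classes Amide classes the map applies to.
#' @param transition_charges Optional named numeric (e) per role, used by the
#'   transition-charge coupling scheme.
#' @param exclusion Exclusion rule name (`"nearest_residues"`, `"own_residue"`
#'   or `"none"`).
#' @return An `electrostatic_map`.
#' @export
electrostatic_map <- function(name, gas_phase_frequency, coefficients,
                              dipole = list(magnitude = 0.37, angle = 20,
                                            offset = 0),
                              classes = "secondary",
                              transition_charges = NULL,
                              exclusion = "nearest_residues") {
  stopifnot(is.numeric(gas_phase_frequency), is.finite(gas_phase_frequency))
  bad_roles <- setdiff(names(coefficients), .map_roles)
  if (length(bad_roles))
    stop("unknown map atom role(s): ", paste(bad_roles, collapse = ", "))
  for (role in names(coefficients)) {
    cf <- coefficients[[role]]
    bad <- setdiff(names(cf), .comp_names)
    if (length(bad))
      stop("unknown coefficient component(s) for atom ", role, ": ",
           paste(bad, collapse = ", "))
    if (!all(is.finite(cf))) stop("non-finite coefficient for atom ", role)
  }
  if (!is.null(dipole)) {
    if (!is.numeric(dipole$magnitude) || dipole$magnitude <= 0)
      stop("dipole magnitude must be > 0")
  }
  if (!is.null(transition_charges)) {
    bad <- setdiff(names(transition_charges), .map_roles)
    if (length(bad))
      stop("transition charges for unknown role(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(name = name, gas_phase_frequency = gas_phase_frequency,
                 coefficients = coefficients, dipole = dipole,
                 classes = classes, transition_charges = transition_charges,
                 exclusion = exclusion),
            class = "electrostatic_map")
}

#' @export
print.electrostatic_map <- function(x, ...) {
  cat("electrostatic_map '", x$name, "': omega0 = ", x$gas_phase_frequency,
      " cm^-1, atoms {", paste(names(x$coefficients), collapse = ", "),
      "}, classes {", paste(x$classes, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Site frequency from a map and a field sample
#'
#' Pure linear form: omega_0 plus the dot product of the declared
#' coefficients with the matching electrostatic components. Components
#' present in the sample but not declared by the map are ignored. The field
#' sample must already be expressed in the frame the map coefficients assume
#' (see [build_frame()], which rotates into the local amide frame).
#'
#' @param map `electrostatic_map`.
#' @param fs `field_sample`.
#' @return Frequency, cm^-1.
#' @export
site_frequency <- function(map, fs) {
  omega <- map$gas_phase_frequency
  for (role in names(map$coefficients)) {
    if (is.null(fs[[role]])) {
      if (role == "H")
        stop("map '", map$name, "' requires H/D electrostatics but the unit ",
             "has no amide hydrogen (tertiary amide); use a tertiary-capable ",
             "map or the class shift")
      stop("field sample lacks map atom ", role)
    }
    cf <- map$coefficients[[role]]
    s <- fs[[role]]
    comp <- c(potential = s$potential,
              field_x = s$field[1], field_y = s$field[2], field_z = s$field[3],
              gradient_xx = s$gradient[1, 1], gradient_xy = s$gradient[1, 2],
              gradient_xz = s$gradient[1, 3], gradient_yy = s$gradient[2, 2],
              gradient_yz = s$gradient[2, 3], gradient_zz = s$gradient[3, 3])
    omega <- omega + sum(cf * comp[names(cf)])
  }
  omega
}

#' Construct a Ramachandran lookup grid
#'
#' @param values Numeric matrix, rows indexed by phi and columns by psi at
#'   nodes `seq(-180, 180 - spacing, by = spacing)`; periodic in both axes.
#' @param spacing Node spacing in degrees (must divide 360).
#' @param payload `"shift_prev"` (shift of the unit preceding the shared
#'   residue), `"shift_next"`, or `"coupling"`, all cm^-1.
#' @return A `rama_grid`.
#' @export
rama_grid <- function(values, spacing,
                      payload = c("shift_prev", "shift_next", "coupling")) {
  payload <- match.arg(payload)
  n <- 360 / spacing
  if (n != round(n)) stop("grid spacing must divide 360 degrees")
  if (!is.matrix(values) || nrow(values) != n || ncol(values) != n)
    stop("grid table must be a ", n, " x ", n, " matrix for spacing ",
         spacing, " degrees")
  if (!all(is.finite(values))) stop("grid values must be finite")
  structure(list(values = values, spacing = spacing, payload = payload),
            class = "rama_grid")
}

#' Periodic bilinear interpolation on a Ramachandran grid
#'
#' @param grid `rama_grid`.
#' @param phi,psi Angles in degrees (any real value; wrapped periodically).
#' @return Interpolated value(s), cm^-1 (vectorized over `phi`/`psi`).
#' @export
nn_lookup <- function(grid, phi, psi) {
  s <- grid$spacing
  n <- nrow(grid$values)
  u <- (phi + 180) / s
  v <- (psi + 180) / s
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  i0 <- ((i0 %% n) + n) %% n
  j0 <- ((j0 %% n) + n) %% n
  i1 <- (i0 + 1) %% n
  j1 <- (j0 + 1) %% n
  V <- grid$values
  (1 - fu) * (1 - fv) * V[cbind(i0 + 1, j0 + 1)] +
    fu * (1 - fv) * V[cbind(i1 + 1, j0 + 1)] +
    (1 - fu) * fv * V[cbind(i0 + 1, j1 + 1)] +
    fu * fv * V[cbind(i1 + 1, j1 + 1)]
}

#' Nearest-neighbour frequency shift of one unit
#'
#' Sum of the two grid lookups a backbone unit receives: the `shift_prev`
#' grid evaluated at the dihedrals it shares with its following neighbour
#' (where this unit is the preceding one of the pair) and the `shift_next`
#' grid at the dihedrals shared with its preceding neighbour. Missing
#' neighbours contribute zero.
#'
#' @param unit One amide unit.
#' @param topology,units,frame Context for the dihedral computation.
#' @param grids List with `shift_prev` and `shift_next` [rama_grid()]s
#'   (either may be `NULL`).
#' @return Shift, cm^-1.
#' @export
nn_frequency_shift <- function(unit, topology, units, frame, grids) {
  ra <- ramachandran_angles(unit, topology, units, frame)
  shift <- 0
  if (!is.null(grids$shift_prev) && !any(is.na(ra$`next`)))
    shift <- shift + nn_lookup(grids$shift_prev, ra$`next`["phi"],
                               ra$`next`["psi"])
  if (!is.null(grids$shift_next) && !any(is.na(ra$prev)))
    shift <- shift + nn_lookup(grids$shift_next, ra$prev["phi"],
                               ra$prev["psi"])
  unname(shift)
}

#' Amide-class frequency correction
#'
#' When a unit is handled by a secondary-amide map, tertiary (preproline)
#' amides are red-shifted and primary side-chain amides blue-shifted by
#' empirical constants (defaults 27 and 30 cm^-1, user-configurable).
#'
#' @param freq Frequency from the secondary-amide map, cm^-1.
#' @param amide_class Unit class.
#' @param preproline_shift Redshift magnitude for preproline units, cm^-1.
#' @param sidechain_shift Blueshift magnitude for primary amides, cm^-1.
#' @return Corrected frequency, cm^-1.
#' @export
class_shift <- function(freq, amide_class, preproline_shift = 27,
                        sidechain_shift = 30) {
  switch(amide_class,
         secondary = freq,
         tertiary_preproline = freq - preproline_shift,
         primary_sidechain = freq + sidechain_shift,
         stop("unknown amide class: ", amide_class))
}

#' Transition dipole and site position of a unit
#'
#' Deterministic construction from the map's dipole model: the dipole lies in
#' the O=C-N plane at the stated angle from the C=O axis (positive rotation
#' toward N), with the stated magnitude; its origin is the carbonyl carbon
#' displaced by the offset along C=O. The recorded site position is the
#' carbonyl carbon.
#'
#' @param map `electrostatic_map` (supplies the dipole model).
#' @param unit One amide unit.
#' @param frame Coordinates.
#' @return List with `mu` (Debye, length 3), `origin` (nm) and `position`
#'   (nm, the C atom).
#' @export
site_dipole <- function(map, unit, frame) {
  xyz <- frame$xyz
  rC <- xyz[unit$atoms["C"], ]
  rO <- xyz[unit$atoms["O"], ]
  rN <- xyz[unit$atoms["N"], ]
  R <- tryCatch(amide_frame(rC, rO, rN), error = function(e)
    stop("unit ", unit$unit_id, " (", unit$residue_label, "): ",
         conditionMessage(e)))
  th <- map$dipole$angle * pi / 180
  dir <- cos(th) * R[, 1] + sin(th) * R[, 2]
  list(mu = map$dipole$magnitude * dir,
       origin = rC + map$dipole$offset * R[, 1],
       position = rC)
}

#' Load the shipped demonstration map set
#'
#' Synthetic demonstration maps and nearest-neighbour grids (see the
#' commented YAML files under `inst/extdata/maps`). Useful for examples and
#' end-to-end runs without transcribing a literature map.
#'
#' @return List with `maps` (per-class map list) and `grids` (`shift_prev`,
#'   `shift_next`, `coupling`).
#' @export
demo_map_set <- function() {
  d <- system.file("extdata", "maps", package = "amidemap")
  list(
    maps = list(
      secondary = load_map(file.path(d, "demo_backbone.yaml")),
      primary_sidechain = load_map(file.path(d, "demo_sidechain.yaml"))
    ),
    grids = list(
      shift_prev = load_map(file.path(d, "demo_nn_shift_prev.yaml")),
      shift_next = load_map(file.path(d, "demo_nn_shift_next.yaml")),
      coupling = load_map(file.path(d, "demo_nn_coupling.yaml"))
    )
  )
}

## YAML 1.1 parses a bare N/Y/n/y key as a boolean; restore the atom roles.
.fix_role_names <- function(x) {
  if (is.null(x)) return(x)
  nm <- names(x)
  nm[nm %in% c("FALSE", "F", "no", "No", "NO")] <- "N"
  nm[nm %in% c("TRUE", "T", "yes", "Yes", "YES")] <- "Y"
  names(x) <- nm
  x
}

#' Load a map or grid file
#'
#' YAML schema; `kind: electrostatic_map` files carry the header (name,
#' gas-phase frequency, classes, exclusion rule, dipole model), coefficient
#' stanzas keyed by atom role and component, and optional transition charges;
#' `kind: ramachandran_grid` files carry the spacing, payload semantic and
#' the row-major value table. See the commented examples in
#' `system.file("extdata", "maps", package = "amidemap")`.
#'
#' @param path YAML file.
#' @return An `electrostatic_map` or `rama_grid`.
#' @export
load_map <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$kind))
    stop(path, ": missing 'kind' (electrostatic_map or ramachandran_grid)")
  if (doc$kind == "electrostatic_map") {
    if (is.null(doc$gas_phase_frequency))
      stop(path, ": missing gas_phase_frequency")
    coef <- lapply(.fix_role_names(doc$coefficients), function(cf) unlist(cf))
    tq <- if (!is.null(doc$transition_charges))
      .fix_role_names(unlist(doc$transition_charges))
    electrostatic_map(
      name = if (is.null(doc$name)) basename(path) else doc$name,
      gas_phase_frequency = doc$gas_phase_frequency,
      coefficients = coef,
      dipole = doc$dipole,
      classes = if (is.null(doc$classes)) "secondary" else doc$classes,
      transition_charges = tq,
      exclusion = if (is.null(doc$exclusion)) "nearest_residues" else doc$exclusion
    )
  } else if (doc$kind == "ramachandran_grid") {
    if (is.null(doc$spacing)) stop(path, ": missing grid spacing")
    rows <- doc$values
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop(path, ": grid table is not rectangular (row ",
           which(lens != lens[1])[1], " has ", lens[lens != lens[1]][1],
           " values, expected ", lens[1], ")")
    rama_grid(do.call(rbind, lapply(rows, as.numeric)),
              spacing = doc$spacing, payload = doc$payload)
  } else {
    stop(path, ": unknown kind '", doc$kind, "'")
  }
}

#' Write a map or grid to a YAML file
#'
#' Inverse of [load_map()]; a written file loads back to an identical object.
#'
#' @param x `electrostatic_map` or `rama_grid`.
#' @param path Output path.
#' @export
write_map <- function(x, path) {
  if (inherits(x, "electrostatic_map")) {
    doc <- list(kind = "electrostatic_map", name = x$name,
                gas_phase_frequency = x$gas_phase_frequency,
                classes = x$classes, exclusion = x$exclusion,
                dipole = x$dipole,
                coefficients = lapply(x$coefficients, as.list))
    if (!is.null(x$transition_charges))
      doc$transition_charges <- as.list(x$transition_charges)
  } else if (inherits(x, "rama_grid")) {
    doc <- list(kind = "ramachandran_grid", spacing = x$spacing,
                payload = x$payload,
                values = lapply(seq_len(nrow(x$values)),
                                function(i) as.numeric(x$values[i, ])))
  } else stop("write_map: unsupported object")
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}
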