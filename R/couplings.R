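## Inter-site couplings J_ij.
##
## Three routes: the point-dipole (transition-dipole coupling, TDC) formula,
## the transition-charge coupling (TCC) double sum, which carries the higher
## multipole corrections and converges to TDC at long range, and
## DFT-parametrized nearest-neighbour grid values for backbone-adjacent
## pairs. Through-space couplings scale as 1/epsilon_r; nearest-neighbour
## grid values come from vacuum dimer calculations and are used unscaled.

#' Coupling-scheme configuration
#'
#' @param scheme `"TDC"` or `"TCC"` for non-neighbour pairs.
#' @param epsilon_r Relative dielectric constant (> 0, default 1).
#' @param prune_threshold Couplings with magnitude below this are zeroed
#'   (cm^-1, default 0.01; set 0 to disable).
#' @param nn_override Use the Ramachandran coupling grid for backbone
#'   nearest-neighbour pairs instead of the electrostatic scheme (default
#'   `TRUE`).
#' @return A `coupling_config`.
#' @export
coupling_config <- function(scheme = c("TDC", "TCC"), epsilon_r = 1,
                            prune_threshold = 0.01, nn_override = TRUE) {
  scheme <- match.arg(scheme)
  if (!is.numeric(epsilon_r) || epsilon_r <= 0)
    stop("epsilon_r must be > 0")
  if (!is.numeric(prune_threshold) || prune_threshold < 0)
    stop("prune_threshold must be >= 0")
  structure(list(scheme = scheme, epsilon_r = epsilon_r,
                 prune_threshold = prune_threshold,
                 nn_override = isTRUE(nn_override)),
            class = "coupling_config")
}

#' Transition-dipole (point-dipole) coupling
#'
#' \deqn{J = \frac{A}{\epsilon_r}\,
#'   \frac{\mu_i\cdot\mu_j - 3(\mu_i\cdot\hat r)(\mu_j\cdot\hat r)}{r^3}}
#' with \eqn{r} the minimum-image distance between the dipole origins and
#' \eqn{A} = [tdc_prefactor()].
#'
#' @param mu_i,mu_j Transition dipoles, Debye (length 3).
#' @param r_i,r_j Dipole origins, nm.
#' @param epsilon_r Relative dielectric constant.
#' @param box Periodic box (nm) or `NULL`.
#' @return Coupling, cm^-1.
#' @export
tdc <- function(mu_i, mu_j, r_i, r_j, epsilon_r = 1, box = NULL) {
  d <- minimum_image(r_j - r_i, box)
  r <- sqrt(sum(d * d))
  if (r == 0) stop("tdc: coincident dipole positions")
  if (r < 0.05)
    warning("tdc: separation ", signif(r, 3),
            " nm; point-dipole approximation unreliable below 0.05 nm")
  rhat <- d / r
  .const$tdc_prefactor / epsilon_r *
    (sum(mu_i * mu_j) - 3 * sum(mu_i * rhat) * sum(mu_j * rhat)) / r^3
}

#' Transition-charge coupling
#'
#' Coulomb double sum over the map atoms of the two units carrying the map's
#' transition charges: \eqn{J = (C/\epsilon_r)\sum_{ab} t_a t_b / r_{ab}}
#' with charges in e, distances (minimum image) in nm and \eqn{C} the
#' Coulomb energy of two unit charges 1 nm apart in cm^-1. At long range this
#' reduces to the point-dipole formula for the dipole implied by the charges.
#'
#' @param tq_i,tq_j Transition charges (e), named by role.
#' @param pos_i,pos_j Matrices of the corresponding atom positions (nm), rows
#'   matching the charge vectors.
#' @param epsilon_r Relative dielectric constant.
#' @param box Periodic box or `NULL`.
#' @return Coupling, cm^-1.
#' @export
tcc <- function(tq_i, pos_i, tq_j, pos_j, epsilon_r = 1, box = NULL) {
  J <- 0
  for (a in seq_along(tq_i)) {
    d <- minimum_image(pos_j - matrix(pos_i[a, ], nrow(pos_j), 3, byrow = TRUE),
                       box)
    r <- sqrt(rowSums(d * d))
    if (any(r < 0.02))
      stop("tcc: overlapping atoms (pair distance ", signif(min(r), 3),
           " nm < 0.02 nm)")
    J <- J + sum(tq_i[a] * tq_j / r)
  }
  .const$coulomb_cm / epsilon_r * J
}

## Transition charges and positions of one unit under a map.
unit_transition_charges <- function(map, unit, frame) {
  tq <- map$transition_charges
  if (is.null(tq))
    stop("map '", map$name, "' declares no transition charges; ",
         "TCC unavailable")
  roles <- names(tq)
  if ("H" %in% roles && is.na(unit$atoms["H"])) {
    roles <- setdiff(roles, "H")  # tertiary amide: no H site
    tq <- tq[roles]
  }
  pos <- frame$xyz[unit$atoms[roles], , drop = FALSE]
  list(tq = tq, pos = pos)
}

#' Nearest-neighbour coupling from the Ramachandran grid
#'
#' For a backbone-linked pair (`unit_i$next_unit == unit_j$unit_id`), looks
#' up the coupling grid at the (phi, psi) of the residue the two bonds share.
#'
#' @param unit_i,unit_j Backbone-adjacent units.
#' @param topology,units,frame Context for the dihedral computation.
#' @param grid Coupling [rama_grid()].
#' @return Coupling, cm^-1.
#' @export
nn_coupling <- function(unit_i, unit_j, topology, units, frame, grid) {
  if (is.na(unit_i$next_unit) || unit_i$next_unit != unit_j$unit_id)
    stop("nn_coupling: units ", unit_i$unit_id, " and ", unit_j$unit_id,
         " are not backbone neighbours")
  ra <- ramachandran_angles(unit_i, topology, units, frame)$`next`
  if (any(is.na(ra)))
    stop("nn_coupling: shared Ramachandran angles not computable")
  unname(nn_lookup(grid, ra["phi"], ra["psi"]))
}

#' Assemble the full coupling matrix of one frame
#'
#' Backbone nearest-neighbour pairs take the grid value (when `nn_override`
#' and a coupling grid is available); every other pair uses the configured
#' through-space scheme. The result is symmetric with zero diagonal; entries
#' below the pruning threshold are zeroed.
#'
#' @param frame Frame.
#' @param topology `amide_topology`.
#' @param units `amide_units`.
#' @param dipoles List of [site_dipole()] results, one per unit.
#' @param config [coupling_config()].
#' @param grids List of grids (`coupling` used here), or `NULL`.
#' @param maps_by_class Named list of maps per amide class (for TCC charges).
#' @return N x N symmetric matrix, cm^-1.
#' @export
assemble_couplings <- function(frame, topology, units, dipoles, config,
                               grids = NULL, maps_by_class = NULL) {
  n <- length(units)
  J <- matrix(0, n, n)
  if (n < 2) return(J)
  box <- frame$box
  tqs <- NULL
  if (config$scheme == "TCC") {
    tqs <- lapply(seq_len(n), function(i) {
      map <- map_for_class(maps_by_class, units[[i]]$amide_class)
      unit_transition_charges(map, units[[i]], frame)
    })
  }
  nn_grid <- grids$coupling
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ui <- units[[i]]; uj <- units[[j]]
    is_nn <- (!is.na(ui$next_unit) && ui$next_unit == uj$unit_id) ||
      (!is.na(uj$next_unit) && uj$next_unit == ui$unit_id)
    if (is_nn && config$nn_override && !is.null(nn_grid)) {
      val <- if (!is.na(ui$next_unit) && ui$next_unit == uj$unit_id)
        nn_coupling(ui, uj, topology, units, frame, nn_grid)
      else
        nn_coupling(uj, ui, topology, units, frame, nn_grid)
    } else if (config$scheme == "TCC") {
      val <- tcc(tqs[[i]]$tq, tqs[[i]]$pos, tqs[[j]]$tq, tqs[[j]]$pos,
                 config$epsilon_r, box)
    } else {
      val <- tdc(dipoles[[i]]$mu, dipoles[[j]]$mu,
                 dipoles[[i]]$origin, dipoles[[j]]$origin,
                 config$epsilon_r, box)
    }
    J[i, j] <- J[j, i] <- val
  }
  if (config$prune_threshold > 0)
    J[abs(J) < config$prune_threshold] <- 0
  J
}

## Pick the map handling a given amide class: a class-specific map when
## present, else the secondary map (the class shift then corrects frequency).
map_for_class <- function(maps_by_class, amide_class) {
  if (inherits(maps_by_class, "electrostatic_map")) return(maps_by_class)
  m <- maps_by_class[[amide_class]]
  if (!is.null(m)) return(m)
  m <- maps_by_class[["secondary"]]
  if (is.null(m)) stop("no map available for class ", amide_class)
  m
}
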