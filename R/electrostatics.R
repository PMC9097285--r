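## Point-charge electrostatics at the amide map atoms.
##
## The frequency maps consume the electrostatic potential, field and field
## gradient evaluated at the C, O, N and (for secondary amides) H/D atoms.
## Sources are all non-excluded partial charges within the map cutoff of the
## unit's carbonyl carbon (one inclusion decision per source per unit, so a
## source either contributes to all map atoms of a unit or to none), with
## minimum-image periodicity and plain truncation. Results are converted to
## atomic units (Hartree/e, lengths in Bohr) as expected by published map
## coefficient conventions.

#' Minimum-image convention for an orthorhombic box
#'
#' @param dr Displacement vector (length 3) or n x 3 matrix, nm.
#' @param box Box lengths, length-3, nm; `NULL` for a non-periodic system
#'   (returns `dr` unchanged).
#' @return Wrapped displacement(s), each component in `[-L/2, L/2)`.
#' @export
minimum_image <- function(dr, box) {
  if (is.null(box)) return(dr)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("minimum_image: need three positive box lengths (orthorhombic only)")
  if (is.matrix(dr)) {
    for (k in 1:3) dr[, k] <- dr[, k] - box[k] * floor(dr[, k] / box[k] + 0.5)
    dr
  } else {
    dr - box * floor(dr / box + 0.5)
  }
}

#' Build a reusable neighbor list for the map electrostatics
#'
#' Cell-grid search collecting, for every unit, the source atoms within
#' `search_cutoff` of the unit's carbonyl carbon. Because the search cutoff
#' exceeds the map cutoff by more than the intra-unit extent, the list is a
#' superset of all contributing sources and can be reused for
#' `rebuild_interval` frames.
#'
#' @param frame Frame (`xyz`, `box`).
#' @param units `amide_units`.
#' @param search_cutoff nm (default 2.5).
#' @param rebuild_interval Frames between rebuilds (default 50).
#' @param map_cutoff The map cutoff the list must cover, nm; an error is
#'   raised if `search_cutoff < map_cutoff` (silent undercounting forbidden).
#' @return `neighbor_list`: per-unit integer vectors of candidate sources,
#'   plus `build_frame_index`, `search_cutoff`, `rebuild_interval`.
#' @export
build_neighbor_list <- function(frame, units, search_cutoff = 2.5,
                                rebuild_interval = 50, map_cutoff = 2.0,
                                frame_index = 1L) {
  if (search_cutoff < map_cutoff)
    stop("search_cutoff (", search_cutoff, " nm) must be >= map_cutoff (",
         map_cutoff, " nm)")
  xyz <- frame$xyz
  box <- frame$box
  n <- nrow(xyz)
  centers <- t(vapply(units, function(u) xyz[u$atoms["C"], ], numeric(3)))

  lists <- vector("list", length(units))
  periodic <- !is.null(box) && all(is.finite(box)) && all(box > 0)
  ncell <- if (periodic) pmax(1L, floor(box / search_cutoff)) else c(1L, 1L, 1L)
  if (periodic && all(ncell >= 3L)) {
    ## cell grid, linear in atom count
    cell_len <- box / ncell
    ix <- cbind(floor(xyz[, 1] %% box[1] / cell_len[1]),
                floor(xyz[, 2] %% box[2] / cell_len[2]),
                floor(xyz[, 3] %% box[3] / cell_len[3]))
    ix[, 1] <- pmin(ix[, 1], ncell[1] - 1)
    ix[, 2] <- pmin(ix[, 2], ncell[2] - 1)
    ix[, 3] <- pmin(ix[, 3], ncell[3] - 1)
    code <- ix[, 1] + ncell[1] * (ix[, 2] + ncell[2] * ix[, 3])
    by_cell <- split(seq_len(n), code)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (ui in seq_along(units)) {
      cc <- centers[ui, ] %% box
      c0 <- pmin(floor(cc / cell_len), ncell - 1)
      cand <- integer(0)
      for (k in seq_len(nrow(off))) {
        cx <- (c0 + off[k, ]) %% ncell
        hit <- by_cell[[as.character(cx[1] + ncell[1] * (cx[2] + ncell[2] * cx[3]))]]
        if (!is.null(hit)) cand <- c(cand, hit)
      }
      d <- minimum_image(xyz[cand, , drop = FALSE] -
                           matrix(centers[ui, ], length(cand), 3, byrow = TRUE),
                         box)
      lists[[ui]] <- sort(cand[rowSums(d * d) <= search_cutoff^2])
    }
  } else {
    ## small or aperiodic system: direct vectorized distances
    for (ui in seq_along(units)) {
      d <- xyz - matrix(centers[ui, ], n, 3, byrow = TRUE)
      if (periodic) d <- minimum_image(d, box)
      lists[[ui]] <- which(rowSums(d * d) <= search_cutoff^2)
    }
  }
  structure(list(candidates = lists, build_frame_index = frame_index,
                 search_cutoff = search_cutoff,
                 rebuild_interval = rebuild_interval),
            class = "neighbor_list")
}

## Default exclusion set: every atom of the residues forming the unit's own
## amide group plus the immediately preceding/following backbone residues
## (their influence enters through the nearest-neighbour maps instead).
default_exclusions <- function(unit, topology, units) {
  res_rows <- c(unit$res_c, unit$res_n)
  by_id <- function(id) {
    if (is.na(id)) return(NULL)
    for (u in units) if (u$unit_id == id) return(u)
    NULL
  }
  for (v in list(by_id(unit$prev_unit), by_id(unit$next_unit)))
    if (!is.null(v)) res_rows <- c(res_rows, v$res_c, v$res_n)
  sort(unique(unlist(topology$residues$atoms[unique(res_rows)])))
}

#' Electrostatic potential, field and gradient at a unit's map atoms
#'
#' Direct Coulomb sums over all non-excluded sources within `map_cutoff` of
#' the unit's C atom: potential \eqn{\phi = \sum q/r}, field
#' \eqn{E = \sum q \hat r / r^2} (equal to \eqn{-\nabla\phi}), and the
#' analytic field-gradient tensor \eqn{G = \nabla E},
#' \eqn{G_{jk} = \sum q (\delta_{jk}/r^3 - 3 d_j d_k / r^5)}, all in atomic
#' units. The gradient is symmetric and traceless for external sources.
#'
#' @param frame Frame (`xyz` nm, `box`).
#' @param unit One amide unit.
#' @param charges Numeric vector of partial charges (e) for all atoms.
#' @param map_cutoff nm (default 2).
#' @param exclusions Integer atom indices excluded as sources.
#' @param candidates Optional candidate source indices (from a
#'   [build_neighbor_list()] entry); defaults to all atoms.
#' @return `field_sample`: per map atom (`C`, `O`, `N`, and `H` when the
#'   unit has one) a list with `potential`, `field` (3), `gradient` (3 x 3)
#'   in atomic units, and `position` (nm).
#' @export
field_at_unit <- function(frame, unit, charges, map_cutoff = 2.0,
                          exclusions = integer(0), candidates = NULL) {
  xyz <- frame$xyz
  dimnames(xyz) <- NULL
  box <- frame$box
  if (is.null(candidates)) candidates <- seq_len(nrow(xyz))
  src <- setdiff(candidates, exclusions)
  src <- src[charges[src] != 0]
  rC <- xyz[unit$atoms["C"], ]
  if (length(src)) {
    d <- minimum_image(xyz[src, , drop = FALSE] -
                         matrix(rC, length(src), 3, byrow = TRUE), box)
    keep <- rowSums(d * d) <= map_cutoff^2
    src <- src[keep]
  }
  roles <- c("C", "O", "N", if (!is.na(unit$atoms["H"])) "H")
  bohr <- .const$bohr_nm
  out <- list()
  for (role in roles) {
    re <- xyz[unit$atoms[role], ]
    if (length(src) == 0L) {
      out[[role]] <- list(potential = 0, field = numeric(3),
                          gradient = matrix(0, 3, 3), position = re)
      next
    }
    dd <- minimum_image(matrix(re, length(src), 3, byrow = TRUE) -
                          xyz[src, , drop = FALSE], box) / bohr
    r2 <- rowSums(dd * dd)
    r1 <- sqrt(r2)
    if (any(r1 * bohr < 0.05))
      warning("clash: source atom within 0.05 nm of map atom ", role,
              " of unit ", unit$unit_id, " (", unit$residue_label, ")")
    q <- charges[src]
    inv1 <- 1 / r1
    inv3 <- inv1 / r2
    inv5 <- inv3 / r2
    pot <- sum(q * inv1)
    fld <- colSums(q * inv3 * dd)
    G <- matrix(0, 3, 3)
    for (j in 1:3) for (k in j:3) {
      G[j, k] <- sum(q * ((j == k) * inv3 -
                            3 * dd[, j] * dd[, k] * inv5))
      G[k, j] <- G[j, k]
    }
    out[[role]] <- list(potential = pot, field = fld, gradient = G,
                        position = re)
  }
  structure(out, class = "field_sample")
}

## Rotate a field sample into a local (molecular) frame given by the columns
## of R: scalars unchanged, vectors v -> R^T v, tensors G -> R^T G R.
rotate_field_sample <- function(fs, R) {
  for (role in names(fs)) {
    fs[[role]]$field <- as.numeric(crossprod(R, fs[[role]]$field))
    fs[[role]]$gradient <- crossprod(R, fs[[role]]$gradient %*% R)
  }
  fs
}
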