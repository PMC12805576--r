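## CG system assembly: solute volume, water/ion bookkeeping (4 waters per
## W bead, density 1 g/cm^3, ions on the represented water volume),
## random-insertion packing, and repeat-unit concatenation.

#' Cubic box specification
#'
#' @param edge cubic edge length (nm), > 0.
#' @param periodic periodic boundaries flag.
#' @return Object of class `box_spec`.
#' @export
box_spec <- function(edge, periodic = TRUE) {
  stopifnot(edge > 0)
  structure(list(edge = edge, periodic = isTRUE(periodic)),
            class = "box_spec")
}

#' Estimate the volume of a CG solute
#'
#' Volume of the union of the bead vdW spheres, computed on a regular
#' grid (voxel centres inside any sphere are counted once, so overlaps do
#' not double-count). Virtual beads are excluded.
#'
#' @param top a [cg_topology()].
#' @param voxel grid spacing (nm), default 0.02.
#' @return Volume in nm^3 (0 for an empty topology).
#' @export
estimate_molecular_volume <- function(top, voxel = 0.02) {
  keep <- !is_virtual_bead(top)
  if (!any(keep)) return(0)
  xyz <- bead_positions(top)[keep, , drop = FALSE]
  rad <- bead_radii(top)[keep]
  rmax <- max(rad)
  lo <- apply(xyz, 2, min) - rmax - voxel
  hi <- apply(xyz, 2, max) + rmax + voxel
  gx <- seq(lo[1], hi[1], by = voxel)
  gy <- seq(lo[2], hi[2], by = voxel)
  gz <- seq(lo[3], hi[3], by = voxel)
  inside <- array(FALSE, c(length(gx), length(gy), length(gz)))
  for (b in seq_len(nrow(xyz))) {
    ## only the sub-block around this bead
    ix <- which(abs(gx - xyz[b, 1]) <= rad[b])
    iy <- which(abs(gy - xyz[b, 2]) <= rad[b])
    iz <- which(abs(gz - xyz[b, 3]) <= rad[b])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[b, 1])^2
    dy2 <- (gy[iy] - xyz[b, 2])^2
    dz2 <- (gz[iz] - xyz[b, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    inside[ix, iy, iz] <- inside[ix, iy, iz] | (d2 <= rad[b]^2)
  }
  sum(inside) * voxel^3
}

#' Plan solvation and neutralization of a CG system
#'
#' Fills the free box volume with W beads (four water molecules each) to
#' 1 g/cm^3: `n_water_beads = floor((V_box - V_solute) * rho / (4 m_w))`.
#' Salt pairs are computed on the REPRESENTED WATER volume (the volume of
#' `4 n_W` water molecules at 1 g/cm^3), rounded half-to-even; extra
#' cations (or anions) are then added to cancel the solute charge, so the
#' final system is electroneutral.
#'
#' @param box a [box_spec()] (or a numeric edge length, nm).
#' @param solute_volume solute volume (nm^3), e.g. from
#'   [estimate_molecular_volume()].
#' @param charge solute net charge (e), e.g. from [net_charge()].
#' @param concentration background salt concentration (mol/L).
#' @param n_water_beads optionally force the W-bead count (e.g. to
#'   reproduce a printed system composition); overrides the volume
#'   arithmetic.
#' @return Object of class `solvation_plan`: `n_water_beads`, `n_na`,
#'   `n_cl`, `n_pairs`, `target_concentration`, `solute_volume`.
#' @examples
#' plan_solvation(box_spec(12.5), solute_volume = 55, charge = -13,
#'                concentration = 0.150)
#' @export
plan_solvation <- function(box, solute_volume = 0, charge = 0,
                           concentration = 0.150, n_water_beads = NULL) {
  if (is.numeric(box)) box <- box_spec(box)
  stopifnot(concentration >= 0)
  v_box <- box$edge^3
  if (is.null(n_water_beads)) {
    if (solute_volume >= v_box)
      stop("geometry error: solute volume (", solute_volume,
           " nm^3) does not fit the box (", v_box, " nm^3)", call. = FALSE)
    n_water_beads <- floor((v_box - solute_volume) *
                             water_molecules_per_nm3() /
                             cg_constants$waters_per_bead)
  }
  n_water_beads <- as.integer(n_water_beads)
  ## represented water volume in litres: mass of 4 n_W molecules at 1 g/cm3
  n_mol <- cg_constants$waters_per_bead * as.numeric(n_water_beads)
  grams <- n_mol * cg_constants$water_molar_mass / cg_constants$avogadro
  litres <- grams / cg_constants$water_density / 1000
  n_pairs <- round(concentration * litres * cg_constants$avogadro)
  n_na <- n_pairs + max(0, -charge)
  n_cl <- n_pairs + max(0, charge)
  structure(list(n_water_beads = n_water_beads, n_na = as.integer(n_na),
                 n_cl = as.integer(n_cl), n_pairs = as.integer(n_pairs),
                 target_concentration = concentration,
                 solute_volume = solute_volume, solute_charge = charge,
                 box = box),
            class = "solvation_plan")
}

#' @export
print.solvation_plan <- function(x, ...) {
  cat(sprintf(
    "<solvation_plan> %d W beads (%d waters), %d Na+, %d Cl- (%d pairs + neutralization of %+d e)\n",
    x$n_water_beads, x$n_water_beads * cg_constants$waters_per_bead,
    x$n_na, x$n_cl, x$n_pairs, x$solute_charge))
  invisible(x)
}

#' Pack solvent and ions around a solute by random insertion
#'
#' Places the planned W beads and TQ5 ions uniformly in the box, rejecting
#' candidates closer than `min_dist` to any already-placed particle or
#' solute bead (a simple stochastic packing in the spirit of PACKMOL).
#' Deterministic for a fixed seed.
#'
#' @param top solute [cg_topology()] (may be empty via `NULL`).
#' @param plan a [solvation_plan()].
#' @param box a [box_spec()] (defaults to the plan's box).
#' @param min_dist minimum pair distance (nm), default 0.40.
#' @param seed integer seed.
#' @param max_attempts insertion attempts per particle before giving up.
#' @return A data frame with columns `kind` (`solute`/`W`/`NA+`/`CL-`),
#'   `x`, `y`, `z` (nm).
#' @export
pack_system <- function(top, plan, box = plan$box, min_dist = 0.40,
                        seed = 1, max_attempts = 10000) {
  stopifnot(min_dist > 0)
  set.seed(stream_seed(seed, 37))
  edge <- box$edge
  solute <- if (is.null(top)) matrix(numeric(), ncol = 3)
            else bead_positions(top)[!is_virtual_bead(top), , drop = FALSE]
  n_new <- plan$n_water_beads + plan$n_na + plan$n_cl
  kinds <- c(rep("W", plan$n_water_beads), rep("NA+", plan$n_na),
             rep("CL-", plan$n_cl))
  ## cell list over the box for O(1) neighbour queries
  cell <- max(min_dist, 1e-6)
  ncell <- max(1L, floor(edge / cell))
  cell <- edge / ncell
  key <- function(p) {
    ijk <- pmin(pmax(floor(p / cell), 0), ncell - 1)
    1 + ijk[1] + ncell * (ijk[2] + ncell * ijk[3])
  }
  cells <- vector("list", ncell^3)
  put <- function(p) {
    k <- key(p)
    cells[[k]] <<- rbind(cells[[k]], p)
  }
  near_ok <- function(p) {
    ijk <- pmin(pmax(floor(p / cell), 0), ncell - 1)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      c2 <- (ijk + c(dx, dy, dz)) %% ncell    # periodic neighbour cells
      k <- 1 + c2[1] + ncell * (c2[2] + ncell * c2[3])
      pts <- cells[[k]]
      if (is.null(pts)) next
      d <- sweep(pts, 2, p)
      d <- d - edge * round(d / edge)          # minimum image
      if (any(rowSums(d * d) < min_dist^2)) return(FALSE)
    }
    TRUE
  }
  for (r in seq_len(nrow(solute))) put(solute[r, ] %% edge)
  out <- matrix(NA_real_, n_new, 3)
  for (i in seq_len(n_new)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- stats::runif(3, 0, edge)
      if (near_ok(p)) { out[i, ] <- p; put(p); placed <- TRUE; break }
    }
    if (!placed)
      stop("density too high: failed to place particle ", i, " of ", n_new,
           " after ", max_attempts, " attempts (box ", edge, " nm, min_dist ",
           min_dist, " nm)", call. = FALSE)
  }
  rbind(
    if (nrow(solute)) data.frame(kind = "solute", x = solute[, 1],
                                 y = solute[, 2], z = solute[, 3]),
    if (n_new) data.frame(kind = kinds, x = out[, 1], y = out[, 2],
                          z = out[, 3]))
}

#' Concatenate repeat units of a CG construct
#'
#' Builds an `n_repeats`-fold tandem repeat of a glycopeptide unit: copies
#' are translated along x (or grown as a random-walk backbone for
#' unglycosylated chains) and joined by a backbone bond between the C- and
#' N-terminal backbone beads of consecutive copies. Mass and charge scale
#' exactly n-fold; angle/dihedral terms are re-enumerated across the new
#' junctions.
#'
#' @param unit a [cg_topology()] with recorded backbone beads (as produced
#'   by [map_structure()]).
#' @param n_repeats number of copies (>= 1).
#' @param placement `"translate"` (default) or `"walk"`.
#' @param seed seed for `"walk"` placement.
#' @return The concatenated [cg_topology()].
#' @export
build_repeats <- function(unit, n_repeats, placement = c("translate", "walk"),
                          seed = 1) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  placement <- match.arg(placement)
  if (n_repeats == 1) return(unit)
  if (is.null(unit$backbone) || !length(unit$backbone))
    stop("unit topology has no designated backbone termini", call. = FALSE)
  set.seed(stream_seed(seed, 51))
  nb <- n_beads(unit)
  xyz <- bead_positions(unit)
  span <- max(xyz[, 1]) - min(xyz[, 1]) + 0.5
  max_resid <- max(vapply(unit$beads, `[[`, integer(1), "resid"),
                   na.rm = TRUE)

  beads <- list(); bonds <- list(); rigid <- list(); backbone <- integer()
  names_all <- character()
  edges <- bond_edges(unit)
  for (k in seq_len(n_repeats)) {
    off <- (k - 1L) * nb
    shift <- if (placement == "translate") c((k - 1) * span, 0, 0)
             else c((k - 1) * span * 0.7, 0, 0) +
                  stats::rnorm(3, 0, 0.3 * (k > 1))
    for (i in seq_len(nb)) {
      b <- unit$beads[[i]]
      b$id <- i + off
      b$position <- b$position + shift
      b$resid <- b$resid + (k - 1L) * max_resid
      if (length(b$atoms))          # keep atom keys unique across copies
        b$atoms <- sprintf("r%d:%s", b$resid, sub("^r[0-9]+:", "", b$atoms))
      beads[[i + off]] <- b
    }
    names_all <- c(names_all, paste0("rep", k, ":", unit$bead_names))
    for (r in seq_len(nrow(edges)))
      bonds[[length(bonds) + 1L]] <- edges[r, ] + off
    for (g in unit$rigid_groups) rigid[[length(rigid) + 1L]] <- g + off
    backbone <- c(backbone, unit$backbone + off)
    if (k > 1) {
      cterm <- unit$backbone[length(unit$backbone)] + off - nb
      nterm <- unit$backbone[1] + off
      bonds[[length(bonds) + 1L]] <- c(cterm, nterm)
    }
  }
  top <- cg_topology(beads, rigid_groups = rigid,
                     name = sprintf("%s_x%d", unit$name, n_repeats),
                     validate = FALSE)
  top$bead_names <- names_all
  top$backbone <- backbone
  top <- set_bonds_from_edges(top, do.call(rbind, bonds))
  top <- instantiate_bonded_terms(top)
  validate_topology(top)
  top
}
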