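## The CG topology container: beads, bonded terms, rigid groups, virtual
## sites and the bead connectivity graph.

#' Construct a single CG bead
#'
#' @param id 1-based bead index.
#' @param type a [bead_type()] object or a type label.
#' @param position numeric 3-vector, nm.
#' @param atoms character vector of constituent heavy-atom identifiers;
#'   must be empty exactly when the bead is virtual. Non-virtual beads
#'   carry 2 (T), 3 (S) or 4 (R) heavy atoms.
#' @param virtual logical; virtual sites have no constituent atoms and
#'   negligible mass.
#' @param rigid_group optional integer id of the rigid monosaccharide unit
#'   the bead belongs to.
#' @param resid,resname residue bookkeeping (integer id, name).
#' @param group interaction group: `"protein"`, `"glycan"`, `"water"` or
#'   `"ion"`.
#' @return An object of class `cg_bead`.
#' @export
cg_bead <- function(id, type, position = c(0, 0, 0), atoms = character(),
                    virtual = FALSE, rigid_group = NA_integer_,
                    resid = NA_integer_, resname = NA_character_,
                    group = "protein") {
  if (is.character(type)) type <- lookup_bead_type(type)
  stopifnot(inherits(type, "bead_type"), length(position) == 3)
  if (virtual) {
    if (length(atoms) > 0)
      stop("a virtual bead has no constituent atoms", call. = FALSE)
    type$mass <- .virtual_mass
  } else if (length(atoms) > 0) {
    expect <- .size_class_atoms[[type$size_class]]
    if (length(atoms) != expect)
      stop(sprintf(
        "bead %s (%s, class %s) must have %d constituent heavy atoms, got %d",
        id, type$name, type$size_class, expect, length(atoms)), call. = FALSE)
  }
  structure(
    list(id = as.integer(id), type = type, position = as.numeric(position),
         atoms = as.character(atoms), virtual = isTRUE(virtual),
         rigid_group = as.integer(rigid_group), resid = as.integer(resid),
         resname = resname, group = group),
    class = "cg_bead")
}

#' Assemble a CG topology
#'
#' A `cg_topology` bundles an ordered bead list, the bonded terms, the
#' rigid monosaccharide groups (each with one TC4 virtual site at its
#' centre of geometry once [add_ring_virtual_sites()] has run) and the bead
#' connectivity graph.
#'
#' @param beads list of [cg_bead()] objects (ids must be 1..n in order).
#' @param bonds,angles,dihedrals lists of bonded terms.
#' @param rigid_groups list of integer index vectors, one per rigid
#'   monosaccharide unit.
#' @param name molecule label.
#' @param validate check invariants (bead id ordering, term indices in
#'   range, atom-partition disjointness).
#' @return An object of class `cg_topology`.
#' @export
cg_topology <- function(beads, bonds = list(), angles = list(),
                        dihedrals = list(), rigid_groups = list(),
                        name = "molecule", validate = TRUE) {
  top <- structure(
    list(name = name, beads = beads, bonds = bonds, angles = angles,
         dihedrals = dihedrals, rigid_groups = rigid_groups),
    class = "cg_topology")
  if (validate) validate_topology(top)
  top
}

validate_topology <- function(top) {
  n <- length(top$beads)
  ids <- unname(vapply(top$beads, function(b) b$id, integer(1)))
  if (!identical(ids, seq_len(n)))
    stop("bead ids must be 1..n in list order", call. = FALSE)
  idx <- unlist(lapply(c(top$bonds, top$angles, top$dihedrals),
                       function(t) unlist(t[intersect(names(t),
                                                      c("i","j","k","l"))])))
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    stop("bonded term references bead index out of range", call. = FALSE)
  atoms <- unlist(lapply(top$beads, `[[`, "atoms"))
  if (anyDuplicated(atoms))
    stop("atom partition violated: an atom appears in more than one bead",
         call. = FALSE)
  for (g in top$rigid_groups) {
    if (min(g) < 1 || max(g) > n)
      stop("rigid group references bead index out of range", call. = FALSE)
  }
  invisible(top)
}

#' Topology accessors
#'
#' `bead_positions()` returns the n x 3 coordinate matrix (nm),
#' `bead_masses()` the mass vector (Da), `bead_charges()` the integer
#' charges, `bead_radii()` the vdW radii (nm), `bead_groups()` the
#' protein/glycan/water/ion group labels, `is_virtual_bead()` the virtual
#' flags, `total_mass()` the summed bead mass, and `net_charge()` the
#' summed elementary charge of the molecule.
#'
#' @param top a [cg_topology()].
#' @return See individual descriptions.
#' @examples
#' top <- toy_glycopeptide(3, glycans = list(), seed = 1)$topology
#' net_charge(top)
#' @name topology-accessors
NULL

#' @rdname topology-accessors
#' @export
n_beads <- function(top) length(top$beads)

#' @rdname topology-accessors
#' @export
bead_positions <- function(top) {
  unname(do.call(rbind, lapply(top$beads, `[[`, "position")))
}

#' @rdname topology-accessors
#' @export
bead_masses <- function(top)
  unname(vapply(top$beads, function(b) b$type$mass, numeric(1)))

#' @rdname topology-accessors
#' @export
bead_charges <- function(top)
  unname(vapply(top$beads, function(b) b$type$charge, integer(1)))

#' @rdname topology-accessors
#' @export
bead_radii <- function(top)
  unname(vapply(top$beads, function(b) b$type$vdw_radius, numeric(1)))

#' @rdname topology-accessors
#' @export
bead_groups <- function(top)
  unname(vapply(top$beads, function(b) b$group, character(1)))

#' @rdname topology-accessors
#' @export
is_virtual_bead <- function(top)
  unname(vapply(top$beads, function(b) b$virtual, logical(1)))

#' @rdname topology-accessors
#' @export
total_mass <- function(top) sum(bead_masses(top))

#' @rdname topology-accessors
#' @export
net_charge <- function(top) sum(bead_charges(top))

set_bead_positions <- function(top, xyz) {
  stopifnot(nrow(xyz) == n_beads(top), ncol(xyz) == 3)
  for (i in seq_len(nrow(xyz))) top$beads[[i]]$position <- xyz[i, ]
  top
}

## Edge matrix (2 columns, i < j) of the bead graph implied by the bond
## terms.
bond_edges <- function(top) {
  if (!length(top$bonds)) return(matrix(integer(), ncol = 2))
  e <- t(vapply(top$bonds, function(b) sort(c(b$i, b$j)), integer(2)))
  unique(e)
}

adjacency_list <- function(top) {
  n <- n_beads(top)
  adj <- vector("list", n)
  e <- bond_edges(top)
  for (r in seq_len(nrow(e))) {
    adj[[e[r, 1]]] <- c(adj[[e[r, 1]]], e[r, 2])
    adj[[e[r, 2]]] <- c(adj[[e[r, 2]]], e[r, 1])
  }
  adj
}

## All connected triples (i-j-k paths, j the apex) and quadruples of the
## bead graph. Used when instantiating angle/dihedral terms from
## connectivity.
connected_triples <- function(adj) {
  out <- list()
  for (j in seq_along(adj)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    for (c1 in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- c(cmb[1, c1], j, cmb[2, c1])
  }
  out
}

connected_quadruples <- function(adj) {
  out <- list()
  for (j in seq_along(adj)) for (k in adj[[j]]) {
    if (k <= j) next                       # each central edge j-k once
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next                     # 4-ring degenerate path
      out[[length(out) + 1L]] <- c(i, j, k, l)
    }
  }
  out
}

#' @export
print.cg_topology <- function(x, ...) {
  nv <- sum(is_virtual_bead(x))
  cat(sprintf("<cg_topology '%s'>\n", x$name))
  cat(sprintf("  %d beads (%d virtual), %d bonds, %d angles, %d dihedrals\n",
              n_beads(x), nv, length(x$bonds), length(x$angles),
              length(x$dihedrals)))
  cat(sprintf("  %d rigid groups; mass %.1f Da; net charge %+d e\n",
              length(x$rigid_groups), total_mass(x), net_charge(x)))
  invisible(x)
}
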