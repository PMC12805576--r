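## Atomistic -> CG mapping with the O-glycan rules:
##   * beads at the centre of geometry of 2-4 constituent heavy atoms;
##   * the glycosidic oxygen belongs to the glycosyl ACCEPTOR sugar;
##   * a glycosylated N-acetylhexosamine keeps only its -CH-CH- anomeric
##     moiety, retyped SN6 -> TC5;
##   * Thr-glycan and Ser-glycan linkage beads are SN4ar and TN4ar;
##   * sulfated sugars carry a Q4n bead (charge -1);
##   * each monosaccharide is a rigid 3-bead ring with a TC4 virtual site
##     at its centre of geometry.

#' Residue/sugar mapping template
#'
#' One template per residue or monosaccharide: the bead list (name, type,
#' constituent atom names), the intra-residue bead bonds, and the roles the
#' mapper needs (backbone bead, rigid ring beads, anomeric bead and its
#' post-linkage type, the glycosidic oxygen atom, the bead that receives a
#' bridging oxygen when this residue is the acceptor, and the side-chain
#' bead retyped when a glycan is attached to Thr/Ser).
#'
#' @param resname residue name the template applies to.
#' @param beads list of `list(name=, type=, atoms=)` entries; every atom of
#'   the residue must appear in exactly one bead, and every bead carries
#'   2-4 heavy atoms according to its size class.
#' @param bonds 2-column character matrix of intra-residue bead bonds
#'   (by bead name).
#' @param backbone name of the backbone bead (`NA` for sugars).
#' @param ring names of the rigid-ring beads (monosaccharides; usually 3).
#' @param anomeric name of the anomeric bead (sugars).
#' @param anomeric_core_atoms atoms retained by the anomeric bead once the
#'   residue becomes a glycosyl donor (the -CH-CH- pair for HexNAc).
#' @param anomeric_linked_type bead type of the anomeric bead after
#'   donation (`"TC5"` for N-acetylhexosamines).
#' @param linkage_oxygen atom name of the donor's anomeric hydroxyl
#'   oxygen, condensed out when this sugar donates a glycosidic bond.
#' @param acceptor_oxygen atom name of the hydroxyl oxygen through which
#'   this residue accepts a glycosidic bond; the bead holding it becomes
#'   the bridging-oxygen (acceptor) bead. `NA` if the residue cannot
#'   accept.
#' @param linkage_bead side-chain bead retyped on protein-glycan
#'   attachment (amino acids).
#' @param linkage_bead_type type the linkage bead takes on attachment
#'   (SN4ar for Thr, TN4ar for Ser).
#' @param hexnac is this sugar an N-acetylhexosamine?
#' @return An object of class `residue_template`.
#' @export
residue_template <- function(resname, beads, bonds = NULL, backbone = NA,
                             ring = character(), anomeric = NA,
                             anomeric_core_atoms = character(),
                             anomeric_linked_type = NA,
                             linkage_oxygen = NA, acceptor_oxygen = NA,
                             linkage_bead = NA, linkage_bead_type = NA,
                             hexnac = FALSE) {
  atom_names <- unlist(lapply(beads, `[[`, "atoms"))
  if (anyDuplicated(atom_names))
    stop("template ", resname,
         ": each atom may appear in exactly one bead", call. = FALSE)
  for (b in beads) {
    tp <- lookup_bead_type(b$type)
    expect <- .size_class_atoms[[tp$size_class]]
    if (length(b$atoms) != expect)
      stop(sprintf("template %s bead %s (%s): %d atoms required, got %d",
                   resname, b$name, b$type, expect, length(b$atoms)),
           call. = FALSE)
  }
  structure(list(
    resname = resname, beads = beads, bonds = bonds, backbone = backbone,
    ring = ring, anomeric = anomeric,
    anomeric_core_atoms = anomeric_core_atoms,
    anomeric_linked_type = anomeric_linked_type,
    linkage_oxygen = linkage_oxygen, acceptor_oxygen = acceptor_oxygen,
    linkage_bead = linkage_bead, linkage_bead_type = linkage_bead_type,
    hexnac = isTRUE(hexnac)), class = "residue_template")
}

#' Mapping specification
#'
#' A set of residue templates plus the protein-glycan attachment rules
#' (Thr side chain -> SN4ar linkage bead, Ser -> TN4ar).
#'
#' @param templates list of [residue_template()]s (named by resname, or a
#'   plain list).
#' @param bead_table bead-type table used to resolve type labels; defaults
#'   to [bead_type_table()].
#' @return An object of class `mapping_spec`.
#' @seealso [default_mapping_spec()] for the packaged glycopeptide
#'   templates, [read_mapping_spec()]/[write_mapping_spec()] for the text
#'   format.
#' @export
mapping_spec <- function(templates, bead_table = NULL) {
  if (is.null(names(templates)) || any(names(templates) == ""))
    names(templates) <- vapply(templates, `[[`, "", "resname")
  structure(list(templates = templates, bead_table = bead_table),
            class = "mapping_spec")
}

#' @export
print.mapping_spec <- function(x, ...) {
  cat(sprintf("<mapping_spec> %d residue templates: %s\n",
              length(x$templates),
              paste(names(x$templates), collapse = ", ")))
  invisible(x)
}

get_template <- function(spec, resname) {
  tpl <- spec$templates[[resname]]
  if (is.null(tpl))
    stop("unmapped residue: no template for '", resname, "'", call. = FALSE)
  tpl
}

atom_key <- function(resid, name) sprintf("r%d:%s", resid, name)

## ---- map_structure --------------------------------------------------------

#' Map an atomistic structure onto CG beads
#'
#' Places one bead at the unweighted centre of geometry of each template
#' bead's constituent heavy atoms, instantiates bond terms from
#' connectivity (explicit atom-atom bonds when the structure provides
#' them, otherwise template-internal bonds plus consecutive-backbone
#' bonds), enumerates angle terms over connected bead triples and dihedral
#' terms over connected quadruples (skipping terms internal to rigid
#' rings), and records one rigid group per monosaccharide ring.
#'
#' Every heavy atom of the structure must end up in exactly one bead (the
#' partition property, asserted); an atom named by a template but missing
#' from the structure raises a mapping error naming the residue and atom.
#'
#' @param structure an [atomistic_structure()].
#' @param spec a [mapping_spec()].
#' @param name molecule label for the topology.
#' @param default_k_bond,default_k_angle,default_k_dihedral placeholder
#'   force constants for terms instantiated from geometry (replaced by
#'   Boltzmann inversion downstream).
#' @return A [cg_topology()]; equilibrium values of the instantiated terms
#'   are taken from the input geometry.
#' @export
map_structure <- function(structure, spec, name = "mapped",
                          default_k_bond = 5000, default_k_angle = 25,
                          default_k_dihedral = 1) {
  at <- structure$atoms
  resids <- unique(at$resid)
  beads <- list()
  atom_used <- rep(FALSE, nrow(at))
  bead_of_atom <- integer(nrow(at))
  backbone_bead <- integer(0)      # bead index per protein residue, ordered
  rigid_groups <- list()
  atom_xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(atom_xyz) <- atom_key(at$resid, at$name)

  for (rid in resids) {
    rows <- which(at$resid == rid)
    resname <- at$resname[rows[1]]
    tpl <- get_template(spec, resname)
    for (b in tpl$beads) {
      sel <- rows[match(b$atoms, at$name[rows])]
      if (anyNA(sel))
        stop(sprintf(
          "mapping error: residue %d (%s): atom(s) %s named by template bead %s missing from structure",
          rid, resname,
          paste(b$atoms[is.na(match(b$atoms, at$name[rows]))],
                collapse = ", "), b$name), call. = FALSE)
      pos <- colMeans(atom_xyz[sel, , drop = FALSE])
      idx <- length(beads) + 1L
      beads[[idx]] <- cg_bead(idx, b$type, pos,
                              atoms = atom_key(rid, b$atoms),
                              resid = rid, resname = resname,
                              group = if (is.na(tpl$backbone)) "glycan"
                                      else "protein")
      atom_used[sel] <- TRUE
      bead_of_atom[sel] <- idx
      names(beads)[idx] <- paste0(rid, ":", b$name)
    }
    if (!is.na(tpl$backbone))
      backbone_bead <- c(backbone_bead,
                         match(paste0(rid, ":", tpl$backbone), names(beads)))
    if (length(tpl$ring) >= 2)
      rigid_groups[[length(rigid_groups) + 1L]] <-
        match(paste0(rid, ":", tpl$ring), names(beads))
  }
  if (!all(atom_used))
    stop("mapping error: unassigned heavy atoms: ",
         paste(utils::head(at$name[!atom_used], 5), collapse = ", "),
         call. = FALSE)

  ## bond edges
  edges <- matrix(integer(), ncol = 2)
  if (!is.null(structure$bonds)) {
    bi <- bead_of_atom[structure$bonds[, 1]]
    bj <- bead_of_atom[structure$bonds[, 2]]
    keep <- bi != bj
    edges <- unique(t(apply(cbind(bi[keep], bj[keep]), 1, sort)))
    if (length(edges) && !is.matrix(edges)) edges <- matrix(edges, ncol = 2)
  } else {
    for (rid in resids) {
      tpl <- get_template(spec, at$resname[which(at$resid == rid)[1]])
      if (!is.null(tpl$bonds))
        for (r in seq_len(nrow(tpl$bonds)))
          edges <- rbind(edges, sort(match(
            paste0(rid, ":", tpl$bonds[r, ]), names(beads))))
    }
    if (length(backbone_bead) > 1)
      for (q in seq_len(length(backbone_bead) - 1))
        edges <- rbind(edges, sort(backbone_bead[q + 0:1]))
  }

  top <- cg_topology(beads, bonds = list(), rigid_groups = rigid_groups,
                     name = name, validate = FALSE)
  top$atom_xyz <- atom_xyz
  top$bead_names <- names(beads)
  top$backbone <- backbone_bead      # ordered backbone bead indices
  top <- set_bonds_from_edges(top, edges, default_k_bond)
  top <- instantiate_bonded_terms(top, default_k_angle, default_k_dihedral)
  validate_topology(top)
  top
}

set_bonds_from_edges <- function(top, edges, k_bond = 5000) {
  xyz <- bead_positions(top)
  top$bonds <- lapply(seq_len(nrow(edges)), function(r) {
    i <- edges[r, 1]; j <- edges[r, 2]
    harmonic_bond(i, j, r0 = sqrt(sum((xyz[i, ] - xyz[j, ])^2)), k_b = k_bond)
  })
  top
}

in_rigid_group <- function(idx, rigid_groups) {
  for (g in rigid_groups) if (all(idx %in% g)) return(TRUE)
  FALSE
}

#' Re-enumerate angle and dihedral terms from bead connectivity
#'
#' Angles are created for every connected bead triple and dihedrals for
#' every connected quadruple, except terms lying entirely inside one rigid
#' monosaccharide group (rigid rings carry no internal bonded terms).
#' Equilibrium values are measured from the current bead geometry;
#' force constants are placeholders until fitted by inversion.
#'
#' @param top a [cg_topology()].
#' @param k_angle,k_dihedral placeholder force constants.
#' @return The topology with rebuilt `angles` and `dihedrals` lists.
#' @export
instantiate_bonded_terms <- function(top, k_angle = 25, k_dihedral = 1) {
  adj <- adjacency_list(top)
  xyz <- bead_positions(top)
  rg <- top$rigid_groups
  virt <- is_virtual_bead(top)
  one <- function(i) matrix(xyz[i, ], 1)
  top$angles <- list()
  for (tr in connected_triples(adj)) {
    if (any(virt[tr]) || in_rigid_group(tr, rg)) next
    th <- frame_angles(one(tr[1]), one(tr[2]), one(tr[3]))
    if (th <= 0 || th >= 180) next   # collinear: ReB undefined
    top$angles[[length(top$angles) + 1L]] <-
      reb_angle(tr[1], tr[2], tr[3], theta0 = th, k_theta = k_angle)
  }
  top$dihedrals <- list()
  for (qd in connected_quadruples(adj)) {
    if (any(virt[qd]) || in_rigid_group(qd, rg)) next
    ph <- frame_dihedrals(one(qd[1]), one(qd[2]), one(qd[3]), one(qd[4]))
    top$dihedrals[[length(top$dihedrals) + 1L]] <-
      periodic_dihedral(qd[1], qd[2], qd[3], qd[4], k_phi = k_dihedral,
                        n = 1L, phi_s = wrap_angle(ph - 180))
  }
  top
}

## recompute a bead's position as COG of its constituent atoms
recompute_bead_position <- function(top, idx) {
  b <- top$beads[[idx]]
  if (b$virtual || is.null(top$atom_xyz)) return(top)
  top$beads[[idx]]$position <-
    colMeans(top$atom_xyz[b$atoms, , drop = FALSE])
  top
}

beads_of_residue <- function(top, resid) {
  which(vapply(top$beads, function(b) identical(b$resid, as.integer(resid)),
               logical(1)))
}

find_bead_with_atom <- function(top, key) {
  for (i in seq_along(top$beads))
    if (key %in% top$beads[[i]]$atoms) return(i)
  NA_integer_
}

## ---- glycosidic linkage ---------------------------------------------------

#' Apply a glycosidic linkage between two mapped sugars
#'
#' Implements the O-glycan linkage convention. Glycosidic-bond formation
#' condenses out the donor's anomeric hydroxyl oxygen and the acceptor's
#' hydroxyl hydrogen, so the surviving bridging oxygen is the acceptor
#' sugar's own hydroxyl oxygen: it remains in (is assigned to) a bead of
#' the glycosyl acceptor. The donor's anomeric bead is reduced to the
#' remaining -CH-CH- moiety and retyped (SN6 -> TC5 for an
#' N-acetylhexosamine donor). Bead positions are recomputed from the
#' constituent atoms and a bond between the anomeric and acceptor beads is
#' added.
#'
#' @param top a mapped [cg_topology()].
#' @param donor_resid,acceptor_resid residue ids of donor and acceptor
#'   sugars.
#' @param spec the [mapping_spec()] used for the mapping.
#' @return The updated topology (angles/dihedrals re-enumerated).
#' @export
apply_glycosidic_linkage <- function(top, donor_resid, acceptor_resid, spec) {
  don <- beads_of_residue(top, donor_resid)
  acc <- beads_of_residue(top, acceptor_resid)
  if (!length(don) || !length(acc))
    stop("both sugars must be mapped before linking", call. = FALSE)
  dtpl <- get_template(spec, top$beads[[don[1]]]$resname)
  atpl <- get_template(spec, top$beads[[acc[1]]]$resname)
  if (is.na(atpl$acceptor_oxygen) || is.na(dtpl$anomeric))
    stop("consistency error: acceptor template defines no acceptor oxygen; ",
         "the bridging oxygen cannot be assigned to the acceptor sugar",
         call. = FALSE)

  ## the bridging oxygen must live in a bead of the acceptor sugar
  bkey <- atom_key(acceptor_resid, atpl$acceptor_oxygen)
  bbead <- find_bead_with_atom(top, bkey)
  if (is.na(bbead))
    stop("bridging oxygen ", bkey, " not found in any bead", call. = FALSE)
  if (!(bbead %in% acc))
    stop("consistency error: bridging oxygen ", bkey,
         " sits in a bead of the donor/other residue; it must belong to ",
         "the glycosyl acceptor", call. = FALSE)

  ## donor side: condense out the anomeric hydroxyl oxygen, shrink the
  ## anomeric bead to its core moiety and retype it
  anob <- match(paste0(donor_resid, ":", dtpl$anomeric), top$bead_names)
  if (!is.na(dtpl$linkage_oxygen)) {
    okey <- atom_key(donor_resid, dtpl$linkage_oxygen)
    ob <- find_bead_with_atom(top, okey)
    if (!is.na(ob)) {
      top$beads[[ob]]$atoms <- setdiff(top$beads[[ob]]$atoms, okey)
      top$atom_xyz <- top$atom_xyz[setdiff(rownames(top$atom_xyz), okey), ,
                                   drop = FALSE]
      top <- recompute_bead_position(top, ob)
    }
  }
  if (length(dtpl$anomeric_core_atoms))
    top$beads[[anob]]$atoms <- atom_key(donor_resid,
                                        dtpl$anomeric_core_atoms)
  if (!is.na(dtpl$anomeric_linked_type))
    top$beads[[anob]]$type <- lookup_bead_type(dtpl$anomeric_linked_type)
  top <- recompute_bead_position(top, anob)

  edges <- unique(rbind(bond_edges(top), sort(c(anob, bbead))))
  top <- set_bonds_from_edges(top, edges)
  instantiate_bonded_terms(top)
}

#' Attach a mapped glycan to a Thr or Ser residue
#'
#' Retypes the side-chain bead of the attachment residue to the
#' protein-glycan linkage bead (SN4ar for threonine, TN4ar for serine) and
#' performs the donor-side anomeric adjustment of the glycan's root sugar
#' (the Thr/Ser side-chain oxygen is the glycosidic oxygen and stays on
#' the protein side, i.e. with the acceptor).
#'
#' @param top a mapped [cg_topology()].
#' @param residue_id resid of the Thr/Ser attachment residue.
#' @param glycan_resid resid of the glycan's root sugar.
#' @param spec the [mapping_spec()].
#' @return The updated topology.
#' @export
apply_protein_glycan_attachment <- function(top, residue_id, glycan_resid,
                                            spec) {
  res <- beads_of_residue(top, residue_id)
  if (!length(res)) stop("attachment residue not mapped", call. = FALSE)
  resname <- top$beads[[res[1]]]$resname
  rtpl <- get_template(spec, resname)
  if (is.na(rtpl$linkage_bead) || is.na(rtpl$linkage_bead_type))
    stop("unsupported attachment: O-glycans attach to Thr or Ser only (got ",
         resname, ")", call. = FALSE)
  scb <- match(paste0(residue_id, ":", rtpl$linkage_bead), top$bead_names)
  top$beads[[scb]]$type <- lookup_bead_type(rtpl$linkage_bead_type)

  gly <- beads_of_residue(top, glycan_resid)
  if (!length(gly)) stop("glycan root sugar not mapped", call. = FALSE)
  gtpl <- get_template(spec, top$beads[[gly[1]]]$resname)
  anob <- match(paste0(glycan_resid, ":", gtpl$anomeric), top$bead_names)
  if (!is.na(gtpl$linkage_oxygen)) {
    ## drop the sugar's own anomeric oxygen (condensed out on attachment)
    okey <- atom_key(glycan_resid, gtpl$linkage_oxygen)
    ob <- find_bead_with_atom(top, okey)
    if (!is.na(ob)) {
      top$beads[[ob]]$atoms <- setdiff(top$beads[[ob]]$atoms, okey)
      top$atom_xyz <- top$atom_xyz[setdiff(rownames(top$atom_xyz), okey), ,
                                   drop = FALSE]
    }
  }
  core <- atom_key(glycan_resid, gtpl$anomeric_core_atoms)
  if (!is.na(gtpl$anomeric_linked_type)) {
    top$beads[[anob]]$type <- lookup_bead_type(gtpl$anomeric_linked_type)
    top$beads[[anob]]$atoms <- core
    top <- recompute_bead_position(top, anob)
  }
  edges <- unique(rbind(bond_edges(top), sort(c(scb, anob))))
  top <- set_bonds_from_edges(top, edges)
  instantiate_bonded_terms(top)
}

#' Add TC4 virtual sites at monosaccharide ring centres
#'
#' Appends one massless TC4 virtual bead per rigid ring group, positioned
#' at the centre of geometry of the group's three ring beads, and adds it
#' to the group. Re-applying is a no-op (groups already holding a virtual
#' bead are skipped). A rigid group whose real-bead count differs from
#' three is rejected.
#'
#' @param top a [cg_topology()] with rigid groups identified.
#' @return The topology with virtual sites appended.
#' @export
add_ring_virtual_sites <- function(top) {
  virt <- is_virtual_bead(top)
  for (gi in seq_along(top$rigid_groups)) {
    g <- top$rigid_groups[[gi]]
    if (any(virt[g])) next                 # already done: idempotent
    if (length(g) != 3)
      stop("unsupported ring: rigid group must have exactly 3 member beads, ",
           "got ", length(g), call. = FALSE)
    cog <- colMeans(bead_positions(top)[g, , drop = FALSE])
    idx <- n_beads(top) + 1L
    b0 <- top$beads[[g[1]]]
    top$beads[[idx]] <- cg_bead(idx, "TC4", cog, virtual = TRUE,
                                rigid_group = gi, resid = b0$resid,
                                resname = b0$resname, group = b0$group)
    top$bead_names <- c(top$bead_names,
                        paste0(b0$resid, ":VS", gi))
    names(top$beads)[idx] <- top$bead_names[idx]
    top$rigid_groups[[gi]] <- c(g, idx)
    virt <- c(virt, TRUE)
  }
  top
}

## ---- trajectory mapping ---------------------------------------------------

#' Map an atomistic trajectory to pseudo-CG frames
#'
#' Applies the centre-of-geometry mapping frame-by-frame, producing the
#' pseudo-CG trajectory used for Boltzmann inversion and for
#' atomistic-vs-CG validation. Frame count is preserved.
#'
#' @param frames a [trajectory()] whose particle count equals the heavy
#'   atom count of `structure`.
#' @param structure the [atomistic_structure()] the frames belong to.
#' @param spec a [mapping_spec()].
#' @param topology optionally, the mapped [cg_topology()] (e.g. after
#'   linkage operations); when given, its constituent-atom sets define the
#'   mapping. Virtual beads are recomputed as ring centroids.
#' @return A [trajectory()] of bead coordinates.
#' @export
map_trajectory <- function(frames, structure, spec, topology = NULL) {
  if (n_particles(frames) != nrow(structure$atoms))
    stop("shape error: trajectory particle count (", n_particles(frames),
         ") does not match structure atom count (", nrow(structure$atoms),
         ")", call. = FALSE)
  if (is.null(topology)) topology <- map_structure(structure, spec)
  keys <- atom_key(structure$atoms$resid, structure$atoms$name)
  nb <- n_beads(topology)
  nf <- n_frames(frames)
  virt <- is_virtual_bead(topology)
  ## averaging matrix: beads x atoms
  A <- matrix(0, nb, length(keys))
  for (i in seq_len(nb)) {
    b <- topology$beads[[i]]
    if (b$virtual) next
    cols <- match(b$atoms, keys)
    if (anyNA(cols))
      stop("topology names atoms absent from the structure", call. = FALSE)
    A[i, cols] <- 1 / length(cols)
  }
  out <- array(NA_real_, c(nf, nb, 3))
  for (d in 1:3) out[, , d] <- frames$coords[, , d] %*% t(A)
  ## virtual sites at ring centroids, per frame
  for (gi in seq_along(topology$rigid_groups)) {
    g <- topology$rigid_groups[[gi]]
    v <- g[virt[g]]; r <- g[!virt[g]]
    for (vv in v) for (d in 1:3)
      out[, vv, d] <- rowMeans(out[, r, d, drop = FALSE])
  }
  trajectory(out, box = frames$box, dt = frames$dt)
}
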