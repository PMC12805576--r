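## GROMACS topology export/import: .itp (moleculetype), .top (system) and
## .gro (coordinates). 1-based indices, nm, kJ/mol. GROMACS' harmonic bond
## V = 1/2 k (r-r0)^2 matches the internal convention, so k is written
## as-is; angles use the restricted-bending function (funct 10); dihedrals
## the proper periodic form (funct 1). Intra-ring edges are emitted as
## [ constraints ] and the rigid groups / ring virtual sites as
## [ virtual_sitesn ] plus structured comments, so a write -> read -> write
## cycle is byte-stable.

fmt_atom_line <- function(i, type, resnr, resname, atom, charge, mass)
  sprintf("%6d %10s %6d %6s %6s %6d %10.4f %10.4f",
          i, type, resnr, resname, atom, i, charge, mass)

#' Write a CG system in GROMACS format
#'
#' Writes `name.itp` (moleculetype with atoms, bonds, constraints for
#' rigid-ring edges, restricted-bending angles, periodic dihedrals,
#' virtual sites and rigid-group comments), `name.gro` (coordinates) and
#' `name.top` (system wrapper).
#'
#' @param top a [cg_topology()].
#' @param dir output directory (created if needed).
#' @param name file stem; defaults to the topology name.
#' @param box box edge(s) (nm) for the .gro file.
#' @return Invisibly, the named list of written paths (`itp`, `gro`,
#'   `top`).
#' @seealso [read_gromacs()] for the inverse.
#' @export
write_gromacs <- function(top, dir, name = top$name, box = c(10, 10, 10)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(itp = file.path(dir, paste0(name, ".itp")),
                gro = file.path(dir, paste0(name, ".gro")),
                top = file.path(dir, paste0(name, ".top")))
  virt <- is_virtual_bead(top)
  rg <- top$rigid_groups

  lines <- c("; CG glycopeptide topology (mucincg)",
             "[ moleculetype ]",
             sprintf("%s    1", name),
             "", "[ atoms ]",
             ";  nr       type  resnr    res   atom   cgnr     charge       mass")
  for (b in top$beads)
    lines <- c(lines, fmt_atom_line(
      b$id, b$type$name, ifelse(is.na(b$resid), 1L, b$resid),
      substr(ifelse(is.na(b$resname), "MOL", b$resname), 1, 6),
      sprintf("B%d", b$id), b$type$charge,
      if (b$virtual) 0 else b$type$mass))

  bonds <- Filter(function(t) !in_rigid_group(c(t$i, t$j), rg), top$bonds)
  cons <- Filter(function(t) in_rigid_group(c(t$i, t$j), rg), top$bonds)
  if (length(bonds)) {
    lines <- c(lines, "", "[ bonds ]",
               ";   i     j funct         r0            k")
    for (t in bonds)
      lines <- c(lines, sprintf("%5d %5d %5d %10.6f %12.4f",
                                t$i, t$j, 1L, t$r0, t$k_b))
  }
  if (length(cons)) {
    lines <- c(lines, "", "[ constraints ]",
               ";   i     j funct         r0")
    for (t in cons)
      lines <- c(lines, sprintf("%5d %5d %5d %10.6f", t$i, t$j, 1L, t$r0))
  }
  if (length(top$angles)) {
    lines <- c(lines, "", "[ angles ]",
               ";   i     j     k funct     theta0            k")
    for (t in top$angles)
      lines <- c(lines, sprintf("%5d %5d %5d %5d %10.4f %12.4f",
                                t$i, t$j, t$k, 10L, t$theta0, t$k_theta))
  }
  if (length(top$dihedrals)) {
    lines <- c(lines, "", "[ dihedrals ]",
               ";   i     j     k     l funct      phi_s            k     n")
    for (t in top$dihedrals)
      lines <- c(lines, sprintf("%5d %5d %5d %5d %5d %10.4f %12.4f %5d",
                                t$i, t$j, t$k, t$l, 1L, t$phi_s, t$k_phi,
                                t$n))
  }
  if (any(virt)) {
    lines <- c(lines, "", "[ virtual_sitesn ]",
               "; site funct constructing-atoms (centre of geometry)")
    for (gi in seq_along(rg)) {
      g <- rg[[gi]]
      v <- g[virt[g]]; r <- g[!virt[g]]
      for (s in v)
        lines <- c(lines, sprintf("%5d %5d %s", s, 1L,
                                  paste(sprintf("%5d", r), collapse = " ")))
    }
  }
  if (length(rg)) {
    lines <- c(lines, "", "; rigid monosaccharide groups")
    for (gi in seq_along(rg))
      lines <- c(lines, sprintf("; rigidgroup %d: %s", gi,
                                paste(rg[[gi]], collapse = " ")))
  }
  writeLines(lines, paths$itp)

  resid <- vapply(top$beads, function(b) ifelse(is.na(b$resid), 1L, b$resid),
                  integer(1))
  resname <- vapply(top$beads, function(b)
    ifelse(is.na(b$resname), "MOL", b$resname), "")
  write_gro_file(paths$gro, paste0(name, " CG coordinates"), resid,
                 substr(resname, 1, 5),
                 vapply(top$beads, function(b) b$type$name, ""),
                 bead_positions(top), rep(box, length.out = 3))

  writeLines(c(sprintf("#include \"%s.itp\"", name), "",
               "[ system ]", name, "", "[ molecules ]",
               sprintf("%s    1", name)), paths$top)
  invisible(paths)
}

#' Read a GROMACS .itp/.gro pair back into a CG topology
#'
#' Inverse of [write_gromacs()] for files this package writes (funct 1
#' bonds, funct 10 restricted-bending angles, funct 1 periodic dihedrals,
#' virtual_sitesn, rigid-group comments). Constraint entries are restored
#' as bonds with the package's placeholder force constant (their k is
#' irrelevant: rigid groups supersede them).
#'
#' @param itp path to the .itp file.
#' @param gro optional path to the matching .gro (positions; zeros if
#'   absent).
#' @return A [cg_topology()].
#' @export
read_gromacs <- function(itp, gro = NULL) {
  raw <- readLines(itp)
  rigid_lines <- grep("^; rigidgroup", raw, value = TRUE)
  section <- ""
  atoms <- list(); bonds <- list(); cons <- list(); angles <- list()
  dihedrals <- list(); vsites <- list()
  name <- "molecule"
  expect_name <- FALSE
  for (ln in raw) {
    s <- trimws(sub(";.*$", "", ln))
    if (!nzchar(s)) next
    if (grepl("^\\[", s)) {
      section <- gsub("\\[|\\]| ", "", s)
      expect_name <- section == "moleculetype"
      next
    }
    f <- strsplit(s, "\\s+")[[1]]
    if (expect_name) { name <- f[1]; expect_name <- FALSE; next }
    switch(section,
      atoms = { atoms[[length(atoms) + 1L]] <- f },
      bonds = { bonds[[length(bonds) + 1L]] <- as.numeric(f) },
      constraints = { cons[[length(cons) + 1L]] <- as.numeric(f) },
      angles = { angles[[length(angles) + 1L]] <- as.numeric(f) },
      dihedrals = { dihedrals[[length(dihedrals) + 1L]] <- as.numeric(f) },
      virtual_sitesn = { vsites[[length(vsites) + 1L]] <- as.numeric(f) },
      NULL)
  }
  pos <- NULL
  if (!is.null(gro)) pos <- as.matrix(read_gro(gro)$atoms[, c("x", "y", "z")])
  virt_ids <- vapply(vsites, function(v) as.integer(v[1]), integer(1))
  beads <- vector("list", length(atoms))
  for (i in seq_along(atoms)) {
    f <- atoms[[i]]
    tp <- bead_type(f[2], charge = as.integer(as.numeric(f[7])),
                    mass = as.numeric(f[8]))
    beads[[i]] <- cg_bead(as.integer(f[1]), tp,
                          position = if (is.null(pos)) c(0, 0, 0)
                                     else pos[i, ],
                          virtual = as.integer(f[1]) %in% virt_ids,
                          resid = as.integer(f[3]), resname = f[4])
  }
  rigid <- lapply(rigid_lines, function(ln)
    as.integer(strsplit(sub("^; rigidgroup \\d+: ", "", ln), " ")[[1]]))
  top <- cg_topology(
    beads,
    bonds = c(lapply(bonds, function(v)
                harmonic_bond(v[1], v[2], r0 = v[4], k_b = v[5])),
              lapply(cons, function(v)
                harmonic_bond(v[1], v[2], r0 = v[4], k_b = 5000))),
    angles = lapply(angles, function(v)
      reb_angle(v[1], v[2], v[3], theta0 = v[5], k_theta = v[6])),
    dihedrals = lapply(dihedrals, function(v)
      periodic_dihedral(v[1], v[2], v[3], v[4], k_phi = v[7], n = v[8],
                        phi_s = v[6])),
    rigid_groups = rigid, name = name, validate = FALSE)
  top$bead_names <- sprintf("B%d", seq_along(beads))
  validate_topology(top)
  top
}
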