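## LAMMPS export: data file (full atom style, Angstrom / kcal/mol "real"
## units) plus a tabulated angle file for the restricted-bending
## potential, which has no native LAMMPS style. Dialect conversions:
##   bonds:     V = K (r-r0)^2  ->  K = k_b / 2, kJ/mol/nm^2 -> kcal/mol/A^2
##   dihedrals: fourier style, one term: K [1 + cos(n phi - d)]
##   angles:    angle_style table (721 points, 0.25 deg spacing)
## Rigid groups and virtual sites are emitted as structured comments
## (LAMMPS realises them via fix rigid at run time).

KJ_PER_KCAL <- 4.184

#' Write a CG topology as a LAMMPS data file
#'
#' Writes `<stem>.data` (full atom style, Angstrom, charges in e) and
#' `<stem>.angles.table` (tabulated restricted-bending angle potentials in
#' kcal/mol, 721 points at 0.25 degree spacing, with the fitted theta0/k
#' recorded in each section header). Bond coefficients are converted to
#' the LAMMPS harmonic dialect `V = K (r - r0)^2` in kcal/mol/A^2;
#' dihedrals to the fourier style in kcal/mol.
#'
#' @param top a [cg_topology()].
#' @param dir output directory.
#' @param name file stem (defaults to the topology name).
#' @param box box edge(s), nm.
#' @return Invisibly, list of paths (`data`, `angles`).
#' @export
write_lammps_data <- function(top, dir, name = top$name,
                              box = c(10, 10, 10)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(data = file.path(dir, paste0(name, ".data")),
                angles = file.path(dir, paste0(name, ".angles.table")))
  box <- rep(box, length.out = 3) * 10          # nm -> A
  rg <- top$rigid_groups
  virt <- is_virtual_bead(top)

  types <- unique(vapply(top$beads, function(b) b$type$name, ""))
  tid <- stats::setNames(seq_along(types), types)
  bonds <- Filter(function(t) !in_rigid_group(c(t$i, t$j), rg), top$bonds)
  key_of <- function(x) paste(signif(unlist(x), 10), collapse = "_")
  btypes <- unique(vapply(bonds, function(t) key_of(t[c("r0", "k_b")]), ""))
  atypes <- unique(vapply(top$angles, function(t)
    key_of(t[c("theta0", "k_theta")]), ""))
  dtypes <- unique(vapply(top$dihedrals, function(t)
    key_of(t[c("k_phi", "n", "phi_s")]), ""))

  lines <- c(sprintf("LAMMPS data file: CG glycopeptide '%s' (mucincg)",
                     name), "")
  for (gi in seq_along(rg))
    lines <- c(lines, sprintf("# rigidgroup %d: %s", gi,
                              paste(rg[[gi]], collapse = " ")))
  if (any(virt))
    lines <- c(lines, sprintf("# virtual %s",
                              paste(which(virt), collapse = " ")))
  lines <- c(lines, "",
             sprintf("%d atoms", n_beads(top)),
             sprintf("%d bonds", length(bonds)),
             sprintf("%d angles", length(top$angles)),
             sprintf("%d dihedrals", length(top$dihedrals)), "",
             sprintf("%d atom types", length(types)),
             sprintf("%d bond types", length(btypes)),
             sprintf("%d angle types", length(atypes)),
             sprintf("%d dihedral types", length(dtypes)), "",
             sprintf("0.0 %.6f xlo xhi", box[1]),
             sprintf("0.0 %.6f ylo yhi", box[2]),
             sprintf("0.0 %.6f zlo zhi", box[3]), "",
             "Masses", "")
  for (t in types) {
    m <- top$beads[[which(vapply(top$beads, function(b)
      b$type$name == t, logical(1)))[1]]]$type$mass
    lines <- c(lines, sprintf("%d %.10g # %s", tid[[t]], m, t))
  }
  if (length(btypes)) {
    lines <- c(lines, "", "Bond Coeffs # harmonic: K (kcal/mol/A^2) r0 (A)",
               "")
    for (bi in seq_along(btypes)) {
      t <- bonds[[match(btypes[bi], vapply(bonds, function(t)
        key_of(t[c("r0", "k_b")]), ""))]]
      lines <- c(lines, sprintf("%d %.6f %.6f", bi,
                                t$k_b / 2 / KJ_PER_KCAL / 100, t$r0 * 10))
    }
  }
  if (length(dtypes)) {
    lines <- c(lines, "",
               "Dihedral Coeffs # fourier: m K (kcal/mol) n d (deg)", "")
    for (di in seq_along(dtypes)) {
      t <- top$dihedrals[[match(dtypes[di], vapply(top$dihedrals,
        function(t) key_of(t[c("k_phi", "n", "phi_s")]), ""))]]
      lines <- c(lines, sprintf("%d 1 %.6f %d %.6f", di,
                                t$k_phi / KJ_PER_KCAL, t$n, t$phi_s))
    }
  }
  lines <- c(lines, "", "Atoms # full", "")
  for (b in top$beads)
    lines <- c(lines, sprintf("%d %d %d %.4f %.6f %.6f %.6f",
                              b$id, ifelse(is.na(b$resid), 1L, b$resid),
                              tid[[b$type$name]], b$type$charge,
                              b$position[1] * 10, b$position[2] * 10,
                              b$position[3] * 10))
  if (length(bonds)) {
    lines <- c(lines, "", "Bonds", "")
    for (i in seq_along(bonds)) {
      t <- bonds[[i]]
      lines <- c(lines, sprintf("%d %d %d %d", i,
                                match(key_of(t[c("r0", "k_b")]), btypes),
                                t$i, t$j))
    }
  }
  if (length(top$angles)) {
    lines <- c(lines, "", "Angles", "")
    for (i in seq_along(top$angles)) {
      t <- top$angles[[i]]
      lines <- c(lines, sprintf("%d %d %d %d %d", i,
                                match(key_of(t[c("theta0", "k_theta")]),
                                      atypes), t$i, t$j, t$k))
    }
  }
  if (length(top$dihedrals)) {
    lines <- c(lines, "", "Dihedrals", "")
    for (i in seq_along(top$dihedrals)) {
      t <- top$dihedrals[[i]]
      lines <- c(lines, sprintf("%d %d %d %d %d %d", i,
                                match(key_of(t[c("k_phi", "n", "phi_s")]),
                                      dtypes), t$i, t$j, t$k, t$l))
    }
  }
  writeLines(lines, paths$data)
  write_reb_angle_table(top$angles, atypes, paths$angles)
  invisible(paths)
}

## 721-point tabulated ReB angle potentials (0.25 deg spacing), kcal/mol
write_reb_angle_table <- function(angles, atypes, path) {
  lines <- c("# tabulated restricted-bending angle potentials (mucincg)",
             "# energies kcal/mol, angles deg")
  grid <- seq(0, 180, by = 0.25)
  inner <- pmin(pmax(grid, 0.25), 179.75)   # clamp the singular endpoints
  key_of <- function(x) paste(signif(unlist(x), 10), collapse = "_")
  for (ai in seq_along(atypes)) {
    t <- angles[[match(atypes[ai], vapply(angles, function(t)
      key_of(t[c("theta0", "k_theta")]), ""))]]
    ## tabulate from the header-precision parameters so that a
    ## write -> read -> write cycle reproduces the table bytes
    t <- reb_angle(t$i, t$j, t$k, theta0 = round(t$theta0, 6),
                   k_theta = round(t$k_theta, 6))
    e <- reb_angle_energy(t, inner) / KJ_PER_KCAL
    f <- -reb_angle_energy(t, inner, deriv = TRUE) / KJ_PER_KCAL
    lines <- c(lines, "",
               sprintf("REB_%d # theta0 %.6f k %.6f (kJ/mol)", ai,
                       t$theta0, t$k_theta),
               sprintf("N %d", length(grid)), "",
               sprintf("%d %.2f %.10g %.10g", seq_along(grid), grid, e, f))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a LAMMPS data file written by [write_lammps_data()]
#'
#' Restores beads (type labels from the Masses comments, charges and
#' positions from the Atoms section), harmonic bonds (dialect converted
#' back to the internal half-k kJ/mol/nm^2 convention), restricted-bending
#' angles (parameters from the angle-table section headers) and fourier
#' dihedrals, plus rigid groups and virtual-site flags from the structured
#' comments.
#'
#' @param data_path path to the .data file.
#' @param angles_path path to the matching angle table (defaults to
#'   `<stem>.angles.table`).
#' @return A [cg_topology()].
#' @export
read_lammps_data <- function(data_path,
                             angles_path = sub("\\.data$", ".angles.table",
                                               data_path)) {
  raw <- readLines(data_path)
  rigid <- lapply(grep("^# rigidgroup", raw, value = TRUE), function(ln)
    as.integer(strsplit(sub("^# rigidgroup \\d+: ", "", ln), " ")[[1]]))
  vln <- grep("^# virtual ", raw, value = TRUE)
  virt_ids <- if (length(vln))
    as.integer(strsplit(sub("^# virtual ", "", vln[1]), " ")[[1]])
  else integer()
  name <- sub("^LAMMPS data file: CG glycopeptide '(.*)' .*$", "\\1", raw[1])

  section <- ""; store <- list()
  for (ln in raw[-1]) {
    s <- trimws(ln)
    if (!nzchar(s) || grepl("^#", s)) next
    if (grepl("^(Masses|Atoms|Bonds|Angles|Dihedrals|Bond Coeffs|Dihedral Coeffs)",
              s)) {
      section <- sub(" #.*$", "", s)
      next
    }
    if (grepl("(atoms|bonds|angles|dihedrals|types|xlo|ylo|zlo)", s)) next
    if (nzchar(section))
      store[[section]] <- c(store[[section]], list(s))
  }
  split_num <- function(s) as.numeric(strsplit(sub("#.*$", "", s),
                                               "\\s+")[[1]])
  mass_lines <- store[["Masses"]]
  type_label <- vapply(mass_lines, function(s)
    sub("^.*# ", "", s), "")
  type_mass <- vapply(mass_lines, function(s) split_num(s)[2], numeric(1))

  atom_rows <- lapply(store[["Atoms"]], split_num)
  beads <- vector("list", length(atom_rows))
  for (r in atom_rows) {
    i <- as.integer(r[1])
    lab <- type_label[as.integer(r[3])]
    tp <- bead_type(lab, charge = as.integer(r[4]),
                    mass = type_mass[as.integer(r[3])])
    beads[[i]] <- cg_bead(i, tp, position = r[5:7] / 10,
                          virtual = i %in% virt_ids,
                          resid = as.integer(r[2]), resname = "MOL")
  }
  bc <- lapply(store[["Bond Coeffs"]], split_num)
  bonds <- lapply(store[["Bonds"]], function(s) {
    v <- split_num(s)
    cf <- bc[[as.integer(v[2])]]
    harmonic_bond(v[3], v[4], r0 = cf[3] / 10,
                  k_b = cf[2] * 2 * KJ_PER_KCAL * 100)
  })
  ## angle parameters from the table headers
  ah <- grep("^REB_", readLines(angles_path), value = TRUE)
  apar <- lapply(ah, function(s) {
    m <- regmatches(s, regexec("theta0 ([0-9.eE+-]+) k ([0-9.eE+-]+)", s))[[1]]
    as.numeric(m[2:3])
  })
  angles <- lapply(store[["Angles"]], function(s) {
    v <- split_num(s)
    p <- apar[[as.integer(v[2])]]
    reb_angle(v[3], v[4], v[5], theta0 = p[1], k_theta = p[2])
  })
  dc <- lapply(store[["Dihedral Coeffs"]], split_num)
  dihedrals <- lapply(store[["Dihedrals"]], function(s) {
    v <- split_num(s)
    cf <- dc[[as.integer(v[2])]]
    periodic_dihedral(v[3], v[4], v[5], v[6], k_phi = cf[3] * KJ_PER_KCAL,
                      n = cf[4], phi_s = cf[5])
  })
  ## intra-ring edges are not written to LAMMPS bonds; restore them from
  ## the rigid groups so the bead graph is complete
  ring_bonds <- list()
  xyz <- do.call(rbind, lapply(beads, `[[`, "position"))
  for (g in rigid) {
    rr <- setdiff(g, virt_ids)
    cmb <- utils::combn(sort(rr), 2)
    for (cc in seq_len(ncol(cmb))) {
      i <- cmb[1, cc]; j <- cmb[2, cc]
      ring_bonds[[length(ring_bonds) + 1L]] <-
        harmonic_bond(i, j, r0 = max(sqrt(sum((xyz[i, ] - xyz[j, ])^2)),
                                     1e-6), k_b = 5000)
    }
  }
  top <- cg_topology(beads, bonds = c(bonds, ring_bonds), angles = angles,
                     dihedrals = dihedrals, rigid_groups = rigid,
                     name = name, validate = FALSE)
  top$bead_names <- sprintf("B%d", seq_along(beads))
  validate_topology(top)
  top
}
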