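test_that("beads sit at the centre of geometry of their atoms", {
  spec <- mapping_spec(list(residue_template("XX", list(
    list(name = "B1", type = "TC3", atoms = c("A1", "A2"))),
    backbone = "B1")))
  st <- atomistic_structure(data.frame(
    name = c("A1", "A2"), element = "C", resid = 1, resname = "XX",
    x = c(0, 1), y = 0, z = 0))
  top <- map_structure(st, spec)
  expect_equal(top$beads[[1]]$position, c(0.5, 0, 0))
})

test_that("a 3-residue one-bead-per-residue peptide maps to 3 beads, 2 bonds, 1 angle", {
  tpl <- residue_template("YY", list(
    list(name = "B1", type = "SC3", atoms = c("A1", "A2", "A3"))),
    backbone = "B1")
  spec <- mapping_spec(list(tpl))
  atoms <- do.call(rbind, lapply(1:3, function(r) data.frame(
    name = c("A1", "A2", "A3"), element = "C", resid = r, resname = "YY",
    x = 0.4 * r + c(-0.05, 0, 0.05), y = 0.1 * (r %% 2), z = 0)))
  top <- map_structure(atomistic_structure(atoms), spec)
  expect_equal(n_beads(top), 3)
  expect_equal(length(top$bonds), 2)
  expect_equal(length(top$angles), 1)
  expect_equal(length(top$dihedrals), 0)
})

test_that("mapping errors identify the failing residue or atom", {
  spec <- default_mapping_spec()
  st <- atomistic_structure(data.frame(
    name = "XX1", element = "C", resid = 1, resname = "UNKNOWN",
    x = 0, y = 0, z = 0))
  expect_error(map_structure(st, spec), "unmapped residue.*UNKNOWN")
  ## atom named by the template but absent from the structure
  st2 <- atomistic_structure(data.frame(
    name = c("N", "CA", "C"), element = c("N", "C", "C"), resid = 1,
    resname = "GLY", x = c(0, 0.1, 0.2), y = 0, z = 0))
  expect_error(map_structure(st2, spec), "mapping error.*GLY.*O")
})

test_that("atom partition property holds on glycosylated fixtures", {
  fx <- toy_glycopeptide(6, glycans = list(
    list(site = 2, sugars = c("GALNAC", "GAL", "NEUAC")),
    list(site = 5, sugars = c("GALNAC", "GALS"))), seed = 3)
  atoms_in_beads <- unlist(lapply(fx$topology$beads, `[[`, "atoms"))
  expect_false(anyDuplicated(atoms_in_beads) > 0)
  ## every surviving heavy atom is in exactly one bead (condensed
  ## glycosidic oxygens are removed from the bookkeeping matrix too)
  expect_setequal(atoms_in_beads, rownames(fx$topology$atom_xyz))
})

test_that("mapping commutes with rigid rotations and translations", {
  fx <- toy_glycopeptide(4, glycans = list(list(site = 2,
    sugars = c("GALNAC", "GAL"))), seed = 7)
  st <- fx$structure
  spec <- fx$spec
  top0 <- map_structure(st, spec)
  set.seed(11)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- c(1.3, -0.7, 2.1)
  st2 <- st
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  st2$atoms$x <- xyz[, 1] + shift[1]
  st2$atoms$y <- xyz[, 2] + shift[2]
  st2$atoms$z <- xyz[, 3] + shift[3]
  top2 <- map_structure(st2, spec)
  expect_equal(bead_positions(top2),
               sweep(bead_positions(top0) %*% t(R), 2, shift, "+"),
               tolerance = 1e-10)
})

test_that("glycosidic linkage: TC5 donor anomeric bead, bridging O on acceptor", {
  fx <- linked_disaccharide_fixture()
  top <- fx$topology
  resids <- vapply(top$beads, `[[`, integer(1), "resid")
  resnames <- vapply(top$beads, `[[`, "", "resname")
  types <- vapply(top$beads, function(b) b$type$name, "")
  ## GAL donated to GALNAC: the GAL anomeric bead was retyped and trimmed
  gal_anob <- which(resnames == "GAL" & types == "TN6d")
  expect_length(gal_anob, 1)
  expect_length(top$beads[[gal_anob]]$atoms, 2)
  ## GALNAC donated to Thr: its anomeric bead is TC5 with the 2-atom core
  gn_anob <- which(resnames == "GALNAC" & types == "TC5")
  expect_length(gn_anob, 1)
  expect_length(top$beads[[gn_anob]]$atoms, 2)
  ## graph assertion: the bridging oxygen (GalNAc O3) lives in a GalNAc
  ## (acceptor) bead and that bead is bonded to the donor anomeric bead
  gn_resid <- unique(resids[resnames == "GALNAC"])
  okey <- sprintf("r%d:O3", gn_resid)
  ob <- which(vapply(top$beads, function(b) okey %in% b$atoms, logical(1)))
  expect_equal(unname(resnames[ob]), "GALNAC")
  e <- bond_edges(top)
  expect_true(any((e[, 1] == ob & e[, 2] == gal_anob) |
                  (e[, 1] == gal_anob & e[, 2] == ob)))
})

test_that("an unlinked monosaccharide keeps its SN6 anomeric bead", {
  spec <- default_mapping_spec()
  tpl <- get_template(spec, "GALNAC")
  atoms <- residue_atoms(tpl, 1L, layout_residue(tpl, c(0, 0, 0)))
  top <- map_structure(atomistic_structure(atoms), spec)
  types <- vapply(top$beads, function(b) b$type$name, "")
  expect_true("SN6" %in% types)
  expect_false("TC5" %in% types)
})

test_that("a linkage whose bridging oxygen is not on the acceptor errors", {
  spec <- default_mapping_spec()
  tpl <- get_template(spec, "GALNAC")
  atoms <- rbind(residue_atoms(tpl, 1L, layout_residue(tpl, c(0, 0, 0))),
                 residue_atoms(tpl, 2L, layout_residue(tpl, c(1, 0, 0))))
  top <- map_structure(atomistic_structure(atoms), spec)
  ## doctored topology: move the acceptor's bridging oxygen into a donor
  ## bead, violating the acceptor-sugar convention
  okey <- "r1:O3"
  src <- which(vapply(top$beads, function(b) okey %in% b$atoms, logical(1)))
  dst <- which(vapply(top$beads, `[[`, integer(1), "resid") == 2L)[1]
  top$beads[[src]]$atoms <- setdiff(top$beads[[src]]$atoms, okey)
  top$beads[[dst]]$atoms <- c(top$beads[[dst]]$atoms, okey)
  expect_error(apply_glycosidic_linkage(top, 2, 1, spec),
               "consistency error")
  ## and a spec without an acceptor oxygen cannot take the linkage at all
  tpl2 <- tpl; tpl2$acceptor_oxygen <- NA
  spec2 <- mapping_spec(list(GALNAC = tpl2))
  top2 <- map_structure(atomistic_structure(atoms), spec2)
  expect_error(apply_glycosidic_linkage(top2, 2, 1, spec2),
               "consistency error")
})

test_that("protein-glycan attachment types the linkage bead SN4ar (Thr) or TN4ar (Ser)", {
  thr <- toy_glycopeptide(3, glycans = list(list(site = 2,
    sugars = "GALNAC")), seed = 1,
    sequence = c("GLY", "THR", "GLY"))
  types <- vapply(thr$topology$beads, function(b) b$type$name, "")
  expect_true("SN4ar" %in% types)

  ser <- toy_glycopeptide(3, glycans = list(list(site = 2,
    sugars = "GALNAC")), seed = 1,
    sequence = c("GLY", "SER", "GLY"))
  types <- vapply(ser$topology$beads, function(b) b$type$name, "")
  expect_true("TN4ar" %in% types)

  ## attachment to anything but Thr/Ser is rejected
  spec <- default_mapping_spec()
  tpl <- get_template(spec, "PRO")
  g <- get_template(spec, "GALNAC")
  atoms <- rbind(residue_atoms(tpl, 1L, layout_residue(tpl, c(0, 0, 0))),
                 residue_atoms(g, 2L, layout_residue(g, c(0, 0, 1))))
  top <- map_structure(atomistic_structure(atoms), spec)
  expect_error(apply_protein_glycan_attachment(top, 1, 2, spec),
               "unsupported attachment")
})

test_that("sulfated sugars carry one Q4n bead with charge -1", {
  fx <- toy_glycopeptide(3, glycans = list(list(site = 2,
    sugars = c("GALNAC", "GALS"))), seed = 1)
  q <- Filter(function(b) b$type$name == "Q4n", fx$topology$beads)
  expect_length(q, 1)
  expect_identical(q[[1]]$type$charge, -1L)
})

test_that("ring virtual sites: centroid placement, one per ring, idempotent", {
  beads <- list(cg_bead(1, "SN6", c(0, 0, 0)),
                cg_bead(2, "SP4r", c(1, 0, 0)),
                cg_bead(3, "SP1r", c(0, 1, 0)))
  top <- cg_topology(beads,
                     bonds = list(harmonic_bond(1, 2, 1, 100),
                                  harmonic_bond(2, 3, sqrt(2), 100),
                                  harmonic_bond(1, 3, 1, 100)),
                     rigid_groups = list(1:3))
  top <- add_ring_virtual_sites(top)
  expect_equal(n_beads(top), 4)
  expect_true(top$beads[[4]]$virtual)
  expect_equal(top$beads[[4]]$position, c(1 / 3, 1 / 3, 0))
  ## idempotence
  again <- add_ring_virtual_sites(top)
  expect_equal(n_beads(again), 4)
  expect_equal(bead_positions(again), bead_positions(top))

  ## one virtual site per monosaccharide on a 4-sugar glycan
  fx <- toy_glycopeptide(4, glycans = list(list(site = 2,
    sugars = c("GALNAC", "GAL", "NEUAC", "NEUAC"))), seed = 1)
  expect_equal(sum(is_virtual_bead(fx$topology)), 4)

  ## degenerate 2-bead "ring"
  bad <- cg_topology(list(cg_bead(1, "SN6", c(0, 0, 0)),
                          cg_bead(2, "SP4r", c(1, 0, 0))),
                     bonds = list(harmonic_bond(1, 2, 1, 100)),
                     rigid_groups = list(1:2))
  expect_error(add_ring_virtual_sites(bad), "unsupported ring")
})

test_that("trajectory mapping preserves frames and commutes with translation", {
  fx <- toy_glycopeptide(3, glycans = list(list(site = 2,
    sugars = "GALNAC")), seed = 5)
  st <- fx$structure
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  ## single frame: identical to map_structure positions
  tr1 <- trajectory(list(xyz))
  cg1 <- map_trajectory(tr1, st, fx$spec, topology = fx$topology)
  expect_equal(frame_coords(cg1, 1), unname(bead_positions(fx$topology)),
               tolerance = 1e-10, ignore_attr = TRUE)
  ## rigid translation moves every bead identically
  tr2 <- trajectory(list(xyz, sweep(xyz, 2, c(1, 1, 1), "+")))
  cg2 <- map_trajectory(tr2, st, fx$spec, topology = fx$topology)
  expect_equal(frame_coords(cg2, 2) - frame_coords(cg2, 1),
               matrix(1, n_beads(fx$topology), 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## 100-frame shape contract
  tr100 <- trajectory(replicate(100, xyz, simplify = FALSE))
  cg100 <- map_trajectory(tr100, st, fx$spec, topology = fx$topology)
  expect_equal(n_frames(cg100), 100)
  expect_equal(n_particles(cg100), n_beads(fx$topology))
  ## atom-count mismatch
  expect_error(map_trajectory(trajectory(list(xyz[-1, ])), st, fx$spec),
               "shape error")
})

test_that("mapping-spec text format round-trips", {
  spec <- default_mapping_spec()
  dir <- tempfile()
  write_mapping_spec(spec, dir)
  spec2 <- read_mapping_spec(dir)
  expect_setequal(names(spec2$templates), names(spec$templates))
  for (nm in names(spec$templates)) {
    a <- spec$templates[[nm]]; b <- spec2$templates[[nm]]
    expect_equal(a$beads, b$beads, info = nm)
    expect_equal(a$ring, b$ring, info = nm)
    expect_equal(a$hexnac, b$hexnac, info = nm)
  }
})
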