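test_that("union volume: single sphere, additivity, coincident beads", {
  one <- cg_topology(list(cg_bead(1, "W", c(0, 0, 0))))
  v1 <- estimate_molecular_volume(one)
  expect_equal(v1, 4 / 3 * pi * 0.264^3, tolerance = 0.02)

  two_far <- cg_topology(list(cg_bead(1, "W", c(0, 0, 0)),
                              cg_bead(2, "W", c(3, 0, 0))))
  expect_equal(estimate_molecular_volume(two_far), 2 * v1, tolerance = 0.02)

  coincident <- cg_topology(list(cg_bead(1, "W", c(0, 0, 0)),
                                 cg_bead(2, "W", c(0, 0, 0))))
  expect_equal(estimate_molecular_volume(coincident), v1, tolerance = 0.02)

  expect_equal(estimate_molecular_volume(
    cg_topology(list(cg_bead(1, "TC4", c(0, 0, 0), virtual = TRUE)))), 0)
})

test_that("grid union volume agrees with hit-or-miss Monte Carlo", {
  set.seed(77)
  for (rep in 1:5) {
    xyz <- matrix(runif(15, 0, 0.6), 5, 3)
    types <- sample(c("W", "SP1", "TC5"), 5, replace = TRUE)
    top <- cg_topology(lapply(1:5, function(i)
      cg_bead(i, types[i], xyz[i, ])))
    v <- estimate_molecular_volume(top)
    ## independent oracle: uniform points in the bounding box
    rad <- bead_radii(top)
    lo <- apply(xyz, 2, min) - max(rad)
    hi <- apply(xyz, 2, max) + max(rad)
    npts <- 2e5
    pts <- cbind(runif(npts, lo[1], hi[1]), runif(npts, lo[2], hi[2]),
                 runif(npts, lo[3], hi[3]))
    inside <- rep(FALSE, npts)
    for (b in 1:5)
      inside <- inside |
        (rowSums(sweep(pts, 2, xyz[b, ])^2) <= rad[b]^2)
    vmc <- mean(inside) * prod(hi - lo)
    expect_equal(v, vmc, tolerance = 0.02)
  }
})

test_that("solvation arithmetic reproduces the printed ion counts", {
  ## 15,860 W beads at 150 mM on the represented water volume
  plan <- plan_solvation(box_spec(12.5), charge = -13,
                         concentration = 0.150, n_water_beads = 15860)
  expect_identical(plan$n_pairs, 171L)
  expect_identical(plan$n_na, 184L)     # 171 + 13 neutralizing cations
  expect_identical(plan$n_cl, 171L)

  ## neutral, salt-free
  p0 <- plan_solvation(box_spec(10), charge = 0, concentration = 0)
  expect_identical(p0$n_na, 0L)
  expect_identical(p0$n_cl, 0L)

  ## positive solute neutralized with anions
  pp <- plan_solvation(box_spec(10), charge = +5, concentration = 0)
  expect_identical(pp$n_na, 0L)
  expect_identical(pp$n_cl, 5L)

  ## solute bigger than the box
  expect_error(plan_solvation(box_spec(2), solute_volume = 10),
               "geometry error")
})

test_that("every solvation plan is electroneutral and monotone", {
  set.seed(88)
  for (rep in 1:25) {
    q <- sample(-20:20, 1)
    conc <- runif(1, 0, 0.5)
    vol <- runif(1, 0, 300)
    plan <- plan_solvation(box_spec(10), solute_volume = vol, charge = q,
                           concentration = conc)
    expect_identical(q + plan$n_na - plan$n_cl, 0L)
  }
  ## water count non-increasing in solute volume; pairs non-decreasing in
  ## concentration
  w <- vapply(c(0, 50, 100, 200), function(v)
    plan_solvation(box_spec(10), solute_volume = v)$n_water_beads,
    integer(1))
  expect_true(all(diff(w) <= 0))
  pr <- vapply(c(0, 0.05, 0.15, 0.3), function(cc)
    plan_solvation(box_spec(10), concentration = cc)$n_pairs, integer(1))
  expect_true(all(diff(pr) >= 0))
})

test_that("solvent granularity: exactly 4 water molecules per W bead", {
  expect_identical(cg_constants$waters_per_bead, 4L)
  ## the bead count follows molecules/4 of the free volume
  edge <- 8; vol <- 40
  plan <- plan_solvation(box_spec(edge), solute_volume = vol)
  molecules <- (edge^3 - vol) * water_molecules_per_nm3()
  expect_identical(plan$n_water_beads, as.integer(floor(molecules / 4)))
  ## and the ion arithmetic runs on 4 n_W molecules of represented water
  plan2 <- plan_solvation(box_spec(edge), solute_volume = vol,
                          concentration = 0.2)
  litres <- 4 * plan2$n_water_beads * 18.015 / 6.02214076e23 / 1 / 1000
  expect_identical(plan2$n_pairs,
                   as.integer(round(0.2 * litres * 6.02214076e23)))
})

test_that("random-insertion packing respects counts and distances", {
  plan <- plan_solvation(box_spec(10), charge = -2, concentration = 0,
                         n_water_beads = 100)
  top <- bond_topology()
  coords <- pack_system(top, plan, box_spec(10), min_dist = 0.4, seed = 7)
  expect_equal(sum(coords$kind == "W"), 100)
  expect_equal(sum(coords$kind == "NA+"), 2)
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz)); diag(d) <- Inf
  expect_gte(min(d[-(1:2), ]), 0.4)   # solvent-solvent and solvent-solute
  ## deterministic for a fixed seed
  coords2 <- pack_system(top, plan, box_spec(10), min_dist = 0.4, seed = 7)
  expect_identical(coords, coords2)
  ## zero solvent: solute unchanged
  p0 <- plan_solvation(box_spec(10), charge = 0, concentration = 0,
                       n_water_beads = 0)
  c0 <- pack_system(top, p0, box_spec(10), seed = 1)
  expect_equal(nrow(c0), 2)
  ## infeasible density fails with a diagnostic
  pbad <- plan_solvation(box_spec(2), charge = 0, concentration = 0,
                         n_water_beads = 2000)
  expect_error(pack_system(NULL, pbad, box_spec(2), min_dist = 0.45,
                           seed = 1, max_attempts = 50),
               "density too high")
})

test_that("repeat building scales mass/charge exactly and joins backbones", {
  fx <- toy_glycopeptide(4, glycans = list(list(site = 2,
    sugars = c("GALNAC", "NEUAC"))), seed = 1)
  unit <- fx$topology
  expect_identical(build_repeats(unit, 1), unit)
  r3 <- build_repeats(unit, 3)
  expect_identical(net_charge(r3), 3L * net_charge(unit))
  expect_equal(total_mass(r3), 3 * total_mass(unit), tolerance = 1e-12)
  expect_equal(length(r3$backbone), 3 * length(unit$backbone))
  ## junction bonds: one fewer gap than copies
  e <- bond_edges(r3)
  expect_equal(nrow(e), 3 * nrow(bond_edges(unit)) + 2)
  expect_error(build_repeats(unit, 0), "n_repeats")
})

test_that("five repeats of the 30-residue construct give 150 backbone residues", {
  m2 <- build_mini2_construct()
  r5 <- build_repeats(m2, 5)
  expect_equal(length(r5$backbone), 150)
  expect_identical(net_charge(r5), -65L)   # 5 x (-13)
})

test_that("GROMACS round trip is byte-stable and parameter-faithful", {
  fx <- toy_glycopeptide(4, glycans = list(list(site = 2,
    sugars = c("GALNAC", "GAL"))), seed = 1)
  top <- fx$topology
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_gromacs(top, d1)
  t2 <- read_gromacs(p1$itp, p1$gro)
  p2 <- write_gromacs(t2, d2)
  expect_identical(readLines(p1$itp), readLines(p2$itp))
  expect_identical(readLines(p1$gro), readLines(p2$gro))
  ## bead/bond/angle/dihedral bookkeeping survives
  expect_equal(n_beads(t2), n_beads(top))
  expect_identical(bead_charges(t2), bead_charges(top))
  expect_equal(length(t2$angles), length(top$angles))
  expect_equal(length(t2$dihedrals), length(top$dihedrals))
  expect_equal(vapply(t2$angles, `[[`, numeric(1), "theta0"),
               vapply(top$angles, `[[`, numeric(1), "theta0"),
               tolerance = 1e-4)
  ## .gro is in nm: positions match the topology to writing precision
  expect_equal(bead_positions(t2), bead_positions(top), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("LAMMPS round trip is byte-stable and converts dialects correctly", {
  ## hand-computed conversion: k_b = 5000 kJ/mol/nm^2, half-k dialect,
  ## kcal and Angstrom: 2500 / 4.184 / 100 = 5.9751
  top <- bond_topology(r0 = 0.35, k_b = 5000)
  p <- write_lammps_data(top, tempfile())
  raw <- readLines(p$data)
  coeff <- strsplit(raw[grep("Bond Coeffs", raw) + 2], " ")[[1]]
  expect_equal(as.numeric(coeff[2]), 5.9751, tolerance = 1e-4)
  expect_equal(as.numeric(coeff[3]), 3.5)     # r0 in Angstrom

  fx <- toy_glycopeptide(4, glycans = list(list(site = 2,
    sugars = c("GALNAC", "GAL"))), seed = 1)
  p1 <- write_lammps_data(fx$topology, tempfile())
  t2 <- read_lammps_data(p1$data)
  p2 <- write_lammps_data(t2, tempfile())
  expect_identical(readLines(p1$data), readLines(p2$data))
  expect_identical(readLines(p1$angles), readLines(p2$angles))
  ## coordinates written in Angstrom (x10 of the nm .gro convention)
  g <- write_gromacs(fx$topology, tempfile())
  gro_x <- as.numeric(substr(readLines(g$gro)[3], 21, 28))
  atom1 <- strsplit(raw <- grep("^1 ", readLines(p1$data), value = TRUE)[2],
                    " ")[[1]]
  lx <- as.numeric(strsplit(readLines(p1$data)[
    grep("Atoms", readLines(p1$data)) + 2], " ")[[1]][5])
  expect_equal(lx / 10, bead_positions(fx$topology)[1, 1], tolerance = 1e-5)
  ## the ReB table has 721 points at 0.25 degree spacing
  tab <- readLines(p1$angles)
  expect_true(any(grepl("^N 721$", tab)))
  expect_identical(bead_charges(t2), bead_charges(fx$topology))
})
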