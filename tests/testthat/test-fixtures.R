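test_that("toy glycopeptide: linkage bead, rigid rings, determinism", {
  fx <- toy_glycopeptide(5, glycans = list(list(site = 3,
    sugars = c("GALNAC", "GAL", "NEUAC"))), seed = 1)
  types <- vapply(fx$topology$beads, function(b) b$type$name, "")
  expect_true("SN4ar" %in% types)
  expect_equal(length(fx$topology$rigid_groups), 3)

  bare <- toy_glycopeptide(1, seed = 1)
  expect_equal(length(bare$topology$rigid_groups), 0)
  expect_true(all(bead_groups(bare$topology) == "protein"))

  ## same seed -> identical structure and topology
  fx2 <- toy_glycopeptide(5, glycans = list(list(site = 3,
    sugars = c("GALNAC", "GAL", "NEUAC"))), seed = 1)
  expect_identical(fx$structure$atoms, fx2$structure$atoms)
  expect_equal(bead_positions(fx$topology), bead_positions(fx2$topology))
  ## different seed -> different coordinates
  fx3 <- toy_glycopeptide(5, glycans = list(list(site = 3,
    sugars = c("GALNAC", "GAL", "NEUAC"))), seed = 2)
  expect_false(isTRUE(all.equal(bead_positions(fx$topology),
                                bead_positions(fx3$topology))))

  expect_error(toy_glycopeptide(3, glycans = list(list(site = 9,
    sugars = "GALNAC"))), "invalid glycan pattern")
  expect_error(toy_glycopeptide(0), "n_residues")
})

test_that("packaged construct: 30 residues, 18 glycans, net charge -13", {
  m2 <- build_mini2_construct()
  cs <- construct_summary(m2)
  expect_identical(cs$n_residues, 30L)
  expect_identical(cs$n_glycans, 18L)
  expect_identical(net_charge(m2), -13L)
  ## Thr-linked glycans use SN4ar, Ser-linked TN4ar
  types <- vapply(m2$beads, function(b) b$type$name, "")
  expect_identical(sum(types == "SN4ar"), 12L)
  expect_identical(sum(types == "TN4ar"), 6L)
  ## one TC4 virtual site per monosaccharide ring
  expect_identical(sum(is_virtual_bead(m2)),
                   length(m2$rigid_groups))
  expect_error(build_mini2_construct(composition_path = "/nonexistent.tsv"),
               "packaging error")
})

test_that("fragment splitting: one 5-residue fragment per glycan", {
  m2 <- build_mini2_construct()
  fr <- split_into_fragments(m2, 5)
  expect_length(fr, 18)
  for (f in fr) {
    cs <- construct_summary(f)
    expect_identical(cs$n_residues, 5L)
    expect_identical(cs$n_glycans, 1L)
  }
  ## a construct with a single glycan yields a single fragment
  fx <- toy_glycopeptide(5, glycans = list(list(site = 3,
    sugars = "GALNAC")), seed = 1)
  expect_length(split_into_fragments(fx$topology, 3), 1)
  expect_error(split_into_fragments(m2, 0), "fragment_length")
  expect_error(split_into_fragments(m2, 31), "fragment_length")
})

test_that("synthetic trajectories reproduce prescribed Boltzmann widths", {
  ## single bond: sd within 2% of sqrt(kB T / k_b) = 0.0223 nm
  top <- bond_topology(r0 = 0.35, k_b = 5000)
  tr <- generate_synthetic_trajectory(top, temperature = 300,
                                      n_frames = 1e5, seed = 3)
  r <- frame_distances(traj_slab(tr, 1), traj_slab(tr, 2))
  expect_equal(sd(r), sqrt(0.0083145 * 300 / 5000), tolerance = 0.02)
  expect_equal(mean(r), 0.35, tolerance = 0.01)

  ## rigid 3-bead ring: zero variance of intra-ring distances
  ring <- cg_topology(list(cg_bead(1, "SN6", c(0, 0, 0)),
                           cg_bead(2, "SP4r", c(0.3, 0, 0)),
                           cg_bead(3, "SP1r", c(0.15, 0.25, 0))),
                      bonds = list(harmonic_bond(1, 2, 0.3, 100),
                                   harmonic_bond(2, 3, 0.29, 100),
                                   harmonic_bond(1, 3, 0.29, 100)),
                      rigid_groups = list(1:3))
  trr <- generate_synthetic_trajectory(ring, n_frames = 200, seed = 5)
  for (pair in list(c(1, 2), c(2, 3), c(1, 3))) {
    d <- frame_distances(traj_slab(trr, pair[1]), traj_slab(trr, pair[2]))
    expect_lt(stats::var(d), 1e-20)
  }

  ## single frame is valid
  tr1 <- generate_synthetic_trajectory(top, n_frames = 1, seed = 1)
  expect_equal(n_frames(tr1), 1)

  ## a cycle outside rigid groups is rejected
  cyc <- cg_topology(lapply(1:3, function(i)
    cg_bead(i, "P2", c(i, 0, 0))),
    bonds = list(harmonic_bond(1, 2, 1, 100), harmonic_bond(2, 3, 1, 100),
                 harmonic_bond(1, 3, 2, 100)))
  expect_error(generate_synthetic_trajectory(cyc, n_frames = 10, seed = 1),
               "unsupported topology")
})

test_that("virtual sites track ring centroids along synthetic trajectories", {
  fx <- toy_glycopeptide(3, glycans = list(list(site = 2,
    sugars = "GALNAC")), seed = 2)
  tr <- generate_synthetic_trajectory(fx$topology, n_frames = 50, seed = 7)
  g <- fx$topology$rigid_groups[[1]]
  virt <- is_virtual_bead(fx$topology)
  vidx <- g[virt[g]]; ridx <- g[!virt[g]]
  for (f in c(1, 25, 50)) {
    xyz <- frame_coords(tr, f)
    expect_equal(xyz[vidx, ], colMeans(xyz[ridx, , drop = FALSE]),
                 tolerance = 1e-10)
  }
})

test_that("Metropolis sampling matches exact marginals and is deterministic", {
  ## single harmonic bond: compare against the Cartesian-measure target
  ## density r^2 exp(-V/kBT)
  top <- bond_topology(r0 = 0.35, k_b = 5000)
  cfg <- sampler_config(n_steps = 60000, thin = 5, seed = 4, step = 0.04)
  tr <- mc_sample_molecule(top, cfg)
  expect_gt(attr(tr, "acceptance"), 0.1)
  r <- frame_distances(traj_slab(tr, 1), traj_slab(tr, 2))
  grid <- seq(0.25, 0.45, by = 0.002)
  dens <- grid^2 * exp(-bond_energy(harmonic_bond(1, 2, 0.35, 5000), grid) /
                         (0.0083145 * 300))
  ov <- overlap_with_density(r[-(1:1000)], grid, dens, bin = 0.005)
  expect_gte(ov, 0.98)

  ## determinism
  tr2 <- mc_sample_molecule(top, cfg)
  expect_identical(tr$coords, tr2$coords)

  ## single ReB angle: the divergence at 180 degrees is never crossed
  top3 <- cg_topology(lapply(1:3, function(i)
    cg_bead(i, "P2", c(0.35 * i, 0.1 * (i %% 2), 0))),
    bonds = list(harmonic_bond(1, 2, 0.35, 5000),
                 harmonic_bond(2, 3, 0.35, 5000)),
    angles = list(reb_angle(1, 2, 3, theta0 = 120, k_theta = 50)))
  tr3 <- mc_sample_molecule(top3, sampler_config(n_steps = 20000, thin = 10,
                                                 seed = 8))
  th <- frame_angles(traj_slab(tr3, 1), traj_slab(tr3, 2),
                     traj_slab(tr3, 3))
  expect_true(all(th < 180))
})

test_that("MC marginals of a 5-bead molecule overlap their Boltzmann densities", {
  top <- cg_topology(lapply(1:5, function(i)
    cg_bead(i, "P2", c(0.35 * i, 0.08 * (i %% 2), 0))),
    bonds = lapply(1:4, function(i) harmonic_bond(i, i + 1, 0.35, 4000)),
    angles = lapply(1:3, function(i)
      reb_angle(i, i + 1, i + 2, theta0 = 115, k_theta = 40)))
  tr <- mc_sample_molecule(top, sampler_config(n_steps = 60000, thin = 10,
                                               seed = 12, step = 0.05))
  burn <- 1000
  ## bond marginal (with Cartesian r^2 Jacobian)
  r <- frame_distances(traj_slab(tr, 2), traj_slab(tr, 3))[-(1:burn)]
  grid <- seq(0.25, 0.46, by = 0.002)
  dens <- grid^2 * exp(-bond_energy(harmonic_bond(2, 3, 0.35, 4000), grid) /
                         (0.0083145 * 300))
  expect_gte(overlap_with_density(r, grid, dens, bin = 0.005), 0.95)
  ## angle marginal (sin-theta Jacobian target)
  th <- frame_angles(traj_slab(tr, 1), traj_slab(tr, 2),
                     traj_slab(tr, 3))[-(1:burn)]
  agrid <- seq(60, 179, by = 0.5)
  adens <- reb_boltzmann_density(reb_angle(1, 2, 3, 115, 40), agrid, 300)
  expect_gte(overlap_with_density(th, agrid, adens, bin = 2), 0.95)
})

test_that("sampler detects hopeless configurations", {
  ## a bond so stiff that the default step is always rejected
  top <- bond_topology(r0 = 0.35, k_b = 5e12)
  expect_error(
    mc_sample_molecule(top, sampler_config(n_steps = 30000, step = 0.5,
                                           seed = 2)),
    "stuck sampler")
})

test_that("glycosylated chains scale with a larger Flory exponent than bare backbones", {
  ## bottlebrush contrast: a sticky (attractive) flexible backbone
  ## collapses when bare, while dense repulsive glycans keep the backbone
  ## extended; the exponent is fitted on the backbone Rg vs total Mw
  soften <- function(top, k = 6) {
    top$dihedrals <- list()
    top$angles <- lapply(top$angles, function(a) { a$k_theta <- k; a })
    top
  }
  mean_rg_bb <- function(top, seed) {
    cfg <- sampler_config(n_steps = 25000, thin = 20, seed = seed,
                          excluded_volume = TRUE, step = 0.035,
                          pivot_prob = 0.4, wca_sigma = 0.5,
                          backbone_attraction = 3.0)
    tr <- mc_sample_molecule(top, cfg)
    m <- bead_masses(top)
    m[bead_groups(top) != "protein"] <- 0
    mean(rg_trajectory(tr, m)[-(1:400)])
  }
  unit_g <- toy_glycopeptide(1, glycans = list(list(site = 1,
    sugars = c("GALNAC", "GAL"))), seed = 1)$topology
  unit_b <- toy_glycopeptide(1, sequence = "THR", seed = 1)$topology
  v <- sapply(list(glyc = unit_g, bare = unit_b), function(unit) {
    rg <- c(); mw <- c()
    for (r in c(4, 6, 9, 12)) {
      top <- soften(build_repeats(unit, r))
      rg <- c(rg, mean_rg_bb(top, seed = 100 + r))
      mw <- c(mw, total_mass(top))
    }
    fit_flory(rg, mw)$v
  })
  expect_gt(v["glyc"], v["bare"] + 0.05)
})

test_that("end-to-end pipeline: prescribed parameters are recovered by inversion", {
  top <- chain4_topology()
  tr <- generate_synthetic_trajectory(top, n_frames = 5e4, seed = 17)
  fit <- boltzmann_invert(tr, top)
  cf <- coef(fit)
  bonds <- cf[cf$kind == "bond", ]
  expect_equal(bonds$p1, c(0.35, 0.47, 0.40), tolerance = 0.01)
  expect_equal(bonds$p2, c(5000, 3000, 4000), tolerance = 0.15)
  angs <- cf[cf$kind == "angle", ]
  expect_lt(max(abs(angs$p1 - c(120, 100))), 2)
  expect_equal(angs$p2, c(50, 30), tolerance = 0.15)
  dih <- cf[cf$kind == "dihedral", ]
  expect_identical(as.integer(dih$p2), 1L)
  expect_equal(dih$p1, 3, tolerance = 0.15)
})
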