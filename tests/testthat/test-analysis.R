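test_that("radius of gyration: point, pair, square, mass weighting", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5)
  sq <- rbind(c(0.5, 0.5, 0), c(0.5, -0.5, 0), c(-0.5, 0.5, 0),
              c(-0.5, -0.5, 0))
  expect_equal(radius_of_gyration(sq), sqrt(0.5), tolerance = 1e-12)
  ## virtual (negligible-mass) particles are excluded
  withv <- rbind(sq, c(100, 100, 100))
  expect_equal(radius_of_gyration(withv, c(1, 1, 1, 1, 1e-100)),
               sqrt(0.5), tolerance = 1e-12)
  expect_error(radius_of_gyration(sq, rep(1e-100, 4)), "selection error")
})

test_that("end-to-end distance: identity, collinear chain, 3-4-5 triangle", {
  expect_equal(end_to_end_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(end_to_end_distance(c(0, 0, 0), 10 * c(0.35, 0, 0)), 3.5)
  expect_equal(end_to_end_distance(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_error(end_to_end_distance(NULL, c(0, 0, 0)), "selection error")
})

test_that("SASA: analytic sphere, additivity, burial, rigid-motion invariance", {
  one <- cg_topology(list(cg_bead(1, "W", c(0, 0, 0))))
  s1 <- sasa(one)
  expect_equal(s1$total, 4 * pi * (0.264 + 0.191)^2, tolerance = 0.01)

  two_far <- cg_topology(list(cg_bead(1, "W", c(0, 0, 0)),
                              cg_bead(2, "W", c(5, 0, 0))))
  expect_equal(sasa(two_far)$total, 2 * s1$total, tolerance = 0.01)

  ## bead fully buried inside a tight shell of large neighbours
  shell_dirs <- rbind(diag(3), -diag(3), fibonacci_sphere(20))
  shell <- sweep(shell_dirs / sqrt(rowSums(shell_dirs^2)), 1, 0.30, "*")
  buried <- cg_topology(c(list(cg_bead(1, "TC5", c(0, 0, 0))),
                          lapply(seq_len(nrow(shell)), function(i)
                            cg_bead(i + 1, "W", shell[i, ]))))
  expect_equal(sasa(buried)$per_bead[1], 0)

  ## rigid motion leaves SASA unchanged to sampling tolerance
  fx <- toy_glycopeptide(3, glycans = list(list(site = 2,
    sugars = "GALNAC")), seed = 2)
  top <- fx$topology
  s0 <- sasa(top)$total
  set.seed(5)
  R <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- sweep(bead_positions(top) %*% t(R), 2, c(2, -1, 3), "+")
  s2 <- sasa(top, coords = moved)$total
  expect_equal(s2, s0, tolerance = 0.005)

  ## virtual beads are excluded from the surface
  expect_true(all(sasa(top)$per_bead[is_virtual_bead(top)] == 0))
  expect_error(sasa(one, config = sasa_config(probe_radius = -0.1)),
               "probe")
})

test_that("SASA agrees with an independent Monte Carlo surface oracle", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 6
    xyz <- matrix(runif(3 * n, 0, 0.7), n, 3)
    types <- sample(c("W", "SP1", "TC5"), n, replace = TRUE)
    top <- cg_topology(lapply(seq_len(n), function(i)
      cg_bead(i, types[i], xyz[i, ])))
    s <- sasa(top)
    ## oracle: random (not lattice) points on each extended sphere,
    ## exposed fraction times sphere area
    R <- bead_radii(top) + 0.191
    tot <- 0
    for (i in seq_len(n)) {
      m <- 20000
      u <- matrix(rnorm(3 * m), m, 3)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * R[i], 2, xyz[i, ], "+")
      expos <- rep(TRUE, m)
      for (j in setdiff(seq_len(n), i))
        expos <- expos & (rowSums(sweep(pts, 2, xyz[j, ])^2) > R[j]^2)
      tot <- tot + mean(expos) * 4 * pi * R[i]^2
    }
    expect_equal(s$total, tot, tolerance = 0.02)
  }
})

test_that("RDF: single-distance pair, ideal gas flatness, normalization", {
  ## two particles at a fixed distance: one nonzero bin at d
  pr <- rdf(rbind(c(0, 0, 0)), rbind(c(1.02, 0, 0)), box = 20, dr = 0.1,
            r_max = 5)
  nz <- which(pr$counts > 0)
  expect_length(nz, 1)
  expect_lt(abs(pr$r[nz] - 1.02), 0.1)

  set.seed(33)
  a <- matrix(runif(2000 * 3, 0, 5), ncol = 3)
  pr2 <- rdf(a, box = 5, dr = 0.1)
  expect_true(all(abs(pr2$g[pr2$r > 0.3] - 1) < 0.1))
  ## integral of rho g 4 pi r^2 dr recovers the in-range pair count
  rho <- (nrow(a) - 1) / 125
  integral <- sum(rho * pr2$g * 4 * pi * pr2$r^2 * pr2$dr)
  expect_equal(integral, 4 / 3 * pi * 2.5^3 / 125 * (nrow(a) - 1),
               tolerance = 0.02)

  expect_error(rdf(matrix(numeric(), ncol = 3), a, box = 5), "empty group")
  expect_error(rdf(a, box = 5, r_max = 4), "half the smallest")
})

test_that("glycan-level RDF uses per-glycan centres of geometry", {
  fx <- toy_glycopeptide(8, glycans = list(
    list(site = 2, sugars = c("GALNAC", "GAL")),
    list(site = 5, sugars = "GALNAC"),
    list(site = 7, sugars = c("GALNAC", "NEUAC"))), seed = 6)
  ctr <- glycan_centers(fx$topology)
  expect_equal(dim(ctr), c(3, 3))
  ## centre of a glycan equals the mean of its non-virtual sugar beads
  resids <- vapply(fx$topology$beads, `[[`, integer(1), "resid")
  chain <- fx$topology$glycan_sites[[1]]
  idx <- which(resids %in% chain & !is_virtual_bead(fx$topology))
  expect_equal(unname(ctr[1, ]),
               colMeans(bead_positions(fx$topology)[idx, ]))
})

test_that("RMSD: zero cases, rotation removal, known displacement", {
  set.seed(44)
  ref <- matrix(rnorm(30), 10, 3)
  tr <- trajectory(list(ref))
  expect_equal(rmsd_pseudo_cg(tr, ref), 0, tolerance = 1e-12)

  R <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  rot <- sweep(ref %*% t(R), 2, c(1, 2, 3), "+")
  expect_lt(rmsd_pseudo_cg(trajectory(list(rot)), ref, superpose = TRUE),
            1e-8)
  expect_gt(rmsd_pseudo_cg(trajectory(list(rot)), ref, superpose = FALSE),
            0.5)

  ## 0.1 nm displacement of one bead in 10, no superposition
  disp <- ref; disp[4, 1] <- disp[4, 1] + 0.1
  expect_equal(rmsd_pseudo_cg(trajectory(list(disp)), ref,
                              superpose = FALSE),
               sqrt(0.01 / 10), tolerance = 1e-10)
  expect_error(rmsd_pseudo_cg(tr, ref[-1, ]), "shape error")
})

test_that("Flory fit: exact recovery, hand slope, unbiased under noise", {
  mw <- c(5e3, 1e4, 3e4, 1e5, 3e5, 1e6)
  f <- fit_flory(1.0 * mw^0.6, mw)
  expect_equal(f$v, 0.6, tolerance = 1e-12)
  expect_equal(f$R0, 1.0, tolerance = 1e-10)

  f2 <- fit_flory(c(1, 10^0.5), c(1, 10))
  expect_equal(unname(coef(f2)["v"]), 0.5, tolerance = 1e-12)

  ## 500 noisy replicates: mean slope within 0.01 of the truth
  set.seed(55)
  vs <- replicate(500, {
    rg <- 0.05 * mw^0.52 * exp(rnorm(6, 0, 0.05))
    fit_flory(rg, mw)$v
  })
  expect_lt(abs(mean(vs) - 0.52), 0.01)

  expect_error(fit_flory(c(1, -1), c(1, 10)), "domain error")
  expect_error(fit_flory(1, 1), "two")
  ## predict follows the power law
  expect_equal(predict(f, 2e4), 1.0 * (2e4)^0.6, tolerance = 1e-10)
})

test_that("LJ downscaling hits protein-protein pairs only and composes", {
  fx <- toy_glycopeptide(3, glycans = list(list(site = 2,
    sugars = c("GALNAC", "GALS"))), seed = 2)
  par0 <- default_nonbonded_params(fx$topology, epsilon = 1.0)
  par <- downscale_protein_lj(par0, 0.88)
  expect_equal(lj_epsilon(par, "P2", "P2"), 0.88)
  expect_equal(lj_epsilon(par, "P2", "SN4ar"), 0.88)   # protein-glycan
  expect_equal(lj_epsilon(par, "P2", "W"), 1.0)        # protein-water
  expect_equal(lj_epsilon(par, "W", "W"), 1.0)
  expect_equal(lj_epsilon(par, "W", "TQ5"), 1.0)
  ## sigma untouched
  expect_identical(par$pairs$sigma, par0$pairs$sigma)
  ## identity at factor 1
  expect_identical(downscale_protein_lj(par0, 1)$pairs, par0$pairs)
  ## composition: f1 then f2 equals f1*f2
  a <- downscale_protein_lj(downscale_protein_lj(par0, 0.9), 0.8)
  b <- downscale_protein_lj(par0, 0.72)
  expect_equal(a$pairs$epsilon, b$pairs$epsilon, tolerance = 1e-12)
  expect_error(downscale_protein_lj(par0, 0), "factor")
  expect_error(downscale_protein_lj(par0, 1.2), "factor")
})

test_that("structural metrics summarise a trajectory", {
  fx <- toy_glycopeptide(4, seed = 3)
  tr <- generate_synthetic_trajectory(fx$topology, n_frames = 50, seed = 4)
  sm <- structural_metrics(tr, fx$topology, include_sasa = TRUE,
                           sasa_cfg = sasa_config(n_points = 120))
  expect_equal(nrow(sm$per_frame), 50)
  expect_true(all(sm$per_frame$rg >= 0))
  expect_true(all(sm$per_frame$ree >= 0))
  expect_true(all(sm$per_frame$sasa > 0))
  ## translation invariance of the per-frame metrics
  shifted <- tr
  shifted$coords <- tr$coords + 2.5
  sm2 <- structural_metrics(shifted, fx$topology)
  expect_equal(sm2$per_frame$rg, sm$per_frame$rg, tolerance = 1e-10)
  expect_equal(sm2$per_frame$ree, sm$per_frame$ree, tolerance = 1e-10)
})
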