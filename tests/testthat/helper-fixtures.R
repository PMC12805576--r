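## Shared in-code fixtures for the test suite.

## plain 4-bead chain with known bonded parameters (no rigid groups)
chain4_topology <- function(k_bonds = c(5000, 3000, 4000),
                            r0 = c(0.35, 0.47, 0.40),
                            theta0 = c(120, 100), k_theta = c(50, 30),
                            k_phi = 3, n_dih = 1, phi_s = 0) {
  beads <- lapply(1:4, function(i)
    cg_bead(i, "P2", c(0.35 * i, 0.05 * (i %% 2), 0),
            atoms = sprintf("r%d:A%d", i, 1:4), resid = i, resname = "MOL"))
  cg_topology(
    beads,
    bonds = lapply(1:3, function(i)
      harmonic_bond(i, i + 1, r0 = r0[i], k_b = k_bonds[i])),
    angles = lapply(1:2, function(i)
      reb_angle(i, i + 1, i + 2, theta0 = theta0[i], k_theta = k_theta[i])),
    dihedrals = list(periodic_dihedral(1, 2, 3, 4, k_phi = k_phi, n = n_dih,
                                       phi_s = phi_s)))
}

## two-bead topology with a single harmonic bond
bond_topology <- function(r0 = 0.35, k_b = 5000) {
  cg_topology(list(cg_bead(1, "P2", c(0, 0, 0)),
                   cg_bead(2, "P2", c(r0, 0, 0))),
              bonds = list(harmonic_bond(1, 2, r0 = r0, k_b = k_b)))
}

## a GalNAc -> Gal disaccharide attached to a Thr tripeptide, mapped and
## linked with the packaged rules
linked_disaccharide_fixture <- function(seed = 1) {
  toy_glycopeptide(3, glycans = list(list(site = 2,
    sugars = c("GALNAC", "GAL"))), seed = seed)
}

## histogram overlap of samples against a tabulated density on a grid
overlap_with_density <- function(samples, grid, dens, bin) {
  breaks <- seq(min(grid) - bin / 2, max(grid) + bin, by = bin)
  h <- hist(pmin(pmax(samples, breaks[1]), breaks[length(breaks)]),
            breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  q <- approx(grid, dens, xout = h$mids, rule = 2)$y
  q <- q / sum(q)
  sum(pmin(p, q))
}
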