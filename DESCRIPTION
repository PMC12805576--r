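Package: mucincg
Title: MARTINI 3 Coarse-Grained Models of O-Glycosylated Mucin Glycopeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates MARTINI 3 coarse-grained (CG) models of
    densely O-glycosylated mucin glycopeptides. Maps atomistic structures
    and trajectories to CG beads with O-glycan-specific rules (glycosidic
    oxygen assigned to the acceptor sugar, TC5 anomeric bead for
    glycosylated N-acetylhexosamines, SN4ar/TN4ar protein-glycan linkage
    beads, Q4n sulfate beads, TC4 ring virtual sites), fits harmonic bond,
    restricted-bending angle and periodic dihedral parameters by modified
    Boltzmann inversion of bonded distributions, assembles solvated and
    neutralized CG systems with four-to-one water beads and exports
    GROMACS and LAMMPS topologies, and computes the structural validation
    metrics used for bottlebrush glycoproteins: radius of gyration,
    end-to-end distance, solvent-accessible surface area, radial
    distribution functions, RMSD, and Flory power-law scaling of the
    radius of gyration with molecular weight.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
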