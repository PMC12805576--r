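## Synthetic inputs: toy glycopeptides with pseudo-atoms, the packaged
## 30-residue / 18-glycan mucin construct, and trajectories whose bonded
## degrees of freedom follow prescribed Boltzmann distributions.
##
## Pseudo-atoms are placed at fixed offsets around each intended bead
## centre, so structures are mapping-consistent by construction; they are
## not chemically realistic.

## counter-based stream seeding: one user seed fans out to independent
## sub-streams without coupling draw order between operations
stream_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 65011) * 33029 + 7919 * stream) %% 2147483629
}

## fixed centred offsets (nm) giving exact centre-of-geometry placement
.atom_offsets <- list(
  `2` = rbind(c( 0.08, 0, 0), c(-0.08, 0, 0)),
  `3` = rbind(c( 0.08, 0, 0), c(-0.04,  0.0693, 0), c(-0.04, -0.0693, 0)),
  `4` = rbind(c( 0.065,  0.065,  0.065), c( 0.065, -0.065, -0.065),
              c(-0.065,  0.065, -0.065), c(-0.065, -0.065,  0.065)))

## atoms of one template bead around a centre
place_bead_atoms <- function(centre, n) {
  off <- .atom_offsets[[as.character(n)]]
  sweep(off, 2, centre, "+")
}

## lay out bead centres of one residue template relative to an anchor
layout_residue <- function(tpl, anchor, updir = c(0, 0, 1)) {
  out <- list()
  bn <- vapply(tpl$beads, `[[`, "", "name")
  for (i in seq_along(tpl$beads)) {
    nm <- bn[i]
    out[[nm]] <- anchor + switch(nm,
      BB  = c(0, 0, 0),
      SC1 = 0.30 * updir,
      SC2 = 0.30 * updir + c( 0.22, 0, 0.14),
      SC3 = 0.30 * updir + c(-0.22, 0, 0.14),
      R1  = c(0, 0, 0),
      R2  = c(0.26,  0.15, 0),
      R3  = c(0.26, -0.15, 0),
      SD1 = c(0.50,  0.30, 0.05),
      SD2 = c(0.50, -0.30, 0.05),
      c(0.3 * i, 0, 0))
  }
  out
}

## assemble the atoms data frame for a residue at given bead centres
residue_atoms <- function(tpl, resid, centres) {
  rows <- list()
  for (b in tpl$beads) {
    xyz <- place_bead_atoms(centres[[b$name]], length(b$atoms))
    rows[[length(rows) + 1L]] <- data.frame(
      name = b$atoms, element = substr(b$atoms, 1, 1), resid = resid,
      resname = tpl$resname, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## Build a glycopeptide structure + mapped topology from a composition
## table: data.frame(position, resname, glycan) where glycan is a
## comma-separated root-to-tip sugar chain or "".
build_glycopeptide <- function(composition, spec, seed = 1,
                               name = "glycopeptide") {
  set.seed(stream_seed(seed, 1))
  atoms <- list()
  next_resid <- max(composition$position) + 1L
  glycan_of_site <- list()

  for (r in seq_len(nrow(composition))) {
    pos <- composition$position[r]
    tpl <- get_template(spec, composition$resname[r])
    ## zig-zag backbone, small seeded jitter to break symmetry
    anchor <- c(0.32 * pos, 0.12 * (pos %% 2), 0) + stats::rnorm(3, 0, 0.01)
    centres <- layout_residue(tpl, anchor)
    atoms[[length(atoms) + 1L]] <- residue_atoms(tpl, pos, centres)

    gl <- composition$glycan[r]
    if (nzchar(gl) && gl != "-") {
      sugars <- strsplit(gl, ",")[[1]]
      chain <- integer()
      base <- anchor + c(0, 0, 0.65)
      for (si in seq_along(sugars)) {
        stpl <- get_template(spec, sugars[si])
        sanchor <- base + c(0, 0, 0.55 * (si - 1)) +
          stats::rnorm(3, 0, 0.01)
        scent <- layout_residue(stpl, sanchor)
        atoms[[length(atoms) + 1L]] <- residue_atoms(stpl, next_resid, scent)
        chain <- c(chain, next_resid)
        next_resid <- next_resid + 1L
      }
      glycan_of_site[[as.character(pos)]] <- chain
    }
  }
  struct <- atomistic_structure(do.call(rbind, atoms))
  top <- map_structure(struct, spec, name = name)
  for (site in names(glycan_of_site)) {
    chain <- glycan_of_site[[site]]
    top <- apply_protein_glycan_attachment(top, as.integer(site), chain[1],
                                           spec)
    if (length(chain) > 1)
      for (k in seq_len(length(chain) - 1))
        top <- apply_glycosidic_linkage(top, donor_resid = chain[k + 1],
                                        acceptor_resid = chain[k], spec)
  }
  top <- add_ring_virtual_sites(top)
  top$composition <- composition
  top$glycan_sites <- glycan_of_site
  list(structure = struct, topology = top)
}

#' Generate a toy glycopeptide fixture
#'
#' Builds a pseudo-atomistic peptide of `n_residues` with optional
#' O-glycans, the mapping spec it obeys, and the mapped ground-truth CG
#' topology (attachment, glycosidic linkages and ring virtual sites
#' applied). Deterministic for a fixed seed.
#'
#' @param n_residues number of backbone residues (>= 1).
#' @param glycans list of glycan descriptors: `list(site =, sugars =)`
#'   with `sugars` a root-to-tip character vector (e.g.
#'   `c("GALNAC", "GAL", "NEUAC")`). The attachment residue is forced to
#'   Thr unless the composition says Ser.
#' @param seed integer seed.
#' @param sequence optional explicit residue-name vector (length
#'   `n_residues`).
#' @return List with elements `structure` ([atomistic_structure()]),
#'   `spec` ([mapping_spec()]) and `topology` ([cg_topology()]).
#' @examples
#' fx <- toy_glycopeptide(5, glycans = list(list(site = 3,
#'   sugars = c("GALNAC", "GAL", "NEUAC"))), seed = 1)
#' fx$topology
#' @export
toy_glycopeptide <- function(n_residues, glycans = list(), seed = 1,
                             sequence = NULL) {
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  base <- c("THR", "PRO", "SER", "GLY", "ALA")
  user_sequence <- !is.null(sequence)
  if (!user_sequence)
    sequence <- base[((seq_len(n_residues) - 1) %% 5) + 1]
  glycan_str <- rep("", n_residues)
  for (g in glycans) {
    if (is.null(g$site) || g$site < 1 || g$site > n_residues ||
        is.null(g$sugars) || !length(g$sugars))
      stop("invalid glycan pattern: each entry needs a valid site and a ",
           "non-empty sugar chain", call. = FALSE)
    ## attachment residues default to threonine (mucin PTS domains are
    ## Thr-rich); serine via g$residue or an explicit sequence
    if (!is.null(g$residue)) sequence[g$site] <- g$residue
    else if (!user_sequence || !sequence[g$site] %in% c("THR", "SER"))
      sequence[g$site] <- "THR"
    glycan_str[g$site] <- paste(g$sugars, collapse = ",")
  }
  spec <- default_mapping_spec()
  comp <- data.frame(position = seq_len(n_residues), resname = sequence,
                     glycan = glycan_str, stringsAsFactors = FALSE)
  out <- build_glycopeptide(comp, spec, seed = seed, name = "toy")
  list(structure = out$structure, spec = spec, topology = out$topology)
}

#' The packaged 30-residue mucin PTS construct
#'
#' Builds the packaged CG model of a 30-amino-acid mucin PTS-domain
#' consensus segment carrying 18 O-glycans (12 threonine-linked via SN4ar
#' beads, 6 serine-linked via TN4ar), with sialylated and sulfated glycans
#' contributing a net charge of -13 e. The residue-by-residue composition
#' is read from a packaged table; because the full per-site glycan
#' assignment of the original construct is not published in machine-readable
#' form, the packaged table is a documented synthetic assignment with the
#' correct residue, glycan and charge bookkeeping, and is user-replaceable.
#'
#' @param composition_path optional path to a replacement composition
#'   table (TSV: `position`, `resname`, `glycan`).
#' @param seed seed for the synthetic coordinates.
#' @return A [cg_topology()] with the composition table attached.
#' @examples
#' m2 <- build_mini2_construct()
#' net_charge(m2)   # -13
#' @export
build_mini2_construct <- function(composition_path = NULL, seed = 1) {
  if (is.null(composition_path))
    composition_path <- system.file("extdata",
                                    "mini2_composition_synthetic.tsv",
                                    package = "mucincg")
  if (!nzchar(composition_path) || !file.exists(composition_path))
    stop("packaging error: construct composition table not found",
         call. = FALSE)
  comp <- utils::read.table(composition_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
  comp$glycan[is.na(comp$glycan)] <- ""
  out <- build_glycopeptide(comp, default_mapping_spec(), seed = seed,
                            name = "mini2")
  out$topology
}

#' Count residues and glycans of a built construct
#'
#' @param top a topology built by [build_mini2_construct()] or
#'   [toy_glycopeptide()].
#' @return Named list: `n_residues` (backbone), `n_glycans`.
#' @export
construct_summary <- function(top) {
  comp <- top$composition
  if (is.null(comp)) stop("topology carries no composition table",
                          call. = FALSE)
  list(n_residues = nrow(comp),
       n_glycans = sum(nzchar(comp$glycan) & comp$glycan != "-"))
}

#' Split a glycosylated construct into single-glycan fragments
#'
#' Reproduces the parameterization strategy of cutting a long glycopeptide
#' into short fragments, one per glycan: each fragment carries
#' `fragment_length` backbone residues centred on the glycan's attachment
#' site (clamped at the construct boundaries) and exactly one glycan.
#'
#' @param top a construct topology with a composition table (e.g. from
#'   [build_mini2_construct()]).
#' @param fragment_length backbone residues per fragment (default 5).
#' @param seed seed for fragment coordinates.
#' @return List of [cg_topology()] fragments, one per glycan.
#' @export
split_into_fragments <- function(top, fragment_length = 5, seed = 1) {
  comp <- top$composition
  if (is.null(comp)) stop("topology carries no composition table",
                          call. = FALSE)
  n <- nrow(comp)
  if (fragment_length < 1 || fragment_length > n)
    stop("fragment_length must be between 1 and the construct length",
         call. = FALSE)
  sites <- comp$position[nzchar(comp$glycan) & comp$glycan != "-"]
  spec <- default_mapping_spec()
  half <- (fragment_length - 1) %/% 2
  lapply(seq_along(sites), function(k) {
    s <- sites[k]
    start <- min(max(s - half, 1), n - fragment_length + 1)
    rows <- comp[comp$position %in% seq(start, start + fragment_length - 1), ]
    rows$glycan[rows$position != s] <- ""       # exactly one glycan
    rows$position <- seq_len(nrow(rows))        # renumber
    frag <- build_glycopeptide(rows, spec, seed = stream_seed(seed, k),
                               name = sprintf("fragment_%d", k))
    frag$topology
  })
}
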