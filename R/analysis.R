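## Structural validation metrics: Rg, Ree, SASA (sphere-point sampling),
## RDF under minimum image, RMSD with optional superposition, Flory
## scaling of Rg with molecular weight, and protein-protein LJ
## downscaling.

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the particles from their
#' centre of mass. Particles with negligible mass (virtual sites, mass
#' below `1e-6` Da) are excluded.
#'
#' @param positions n x 3 coordinate matrix (nm).
#' @param masses particle masses (Da); default unit masses.
#' @return Rg in nm.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)))  # 0.5
#' @export
radius_of_gyration <- function(positions, masses = NULL) {
  positions <- rbind(positions)
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  keep <- masses > 1e-6
  if (!any(keep)) stop("selection error: no particles with mass",
                       call. = FALSE)
  p <- positions[keep, , drop = FALSE]
  m <- masses[keep]
  com <- colSums(p * m) / sum(m)
  d2 <- rowSums(sweep(p, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' Per-frame radius of gyration of a trajectory
#'
#' @param traj a [trajectory()].
#' @param masses particle masses (Da).
#' @return Numeric vector, one Rg (nm) per frame.
#' @export
rg_trajectory <- function(traj, masses = NULL) {
  vapply(seq_len(n_frames(traj)), function(f)
    radius_of_gyration(frame_coords(traj, f), masses), numeric(1))
}

#' End-to-end distance
#'
#' @param first,last positions (length-3) of the two terminal backbone
#'   beads, or a [trajectory()] plus indices via `ree_trajectory()`.
#' @return Euclidean distance (nm).
#' @export
end_to_end_distance <- function(first, last) {
  if (is.null(first) || is.null(last))
    stop("selection error: both termini must be defined", call. = FALSE)
  sqrt(sum((as.numeric(last) - as.numeric(first))^2))
}

#' @rdname end_to_end_distance
#' @param traj a [trajectory()].
#' @param i,j particle indices of the termini.
#' @export
ree_trajectory <- function(traj, i, j) {
  frame_distances(traj_slab(traj, i), traj_slab(traj, j))
}

## ---- SASA -----------------------------------------------------------------

#' SASA configuration
#'
#' @param probe_radius probe radius in nm (default 0.191, a tiny-bead
#'   radius).
#' @param radii per-size-class vdW radii (nm).
#' @param n_points sphere sample points per bead (deterministic Fibonacci
#'   lattice).
#' @return Object of class `sasa_config`.
#' @export
sasa_config <- function(probe_radius = 0.191,
                        radii = c(T = 0.191, S = 0.230, R = 0.264),
                        n_points = 960) {
  if (probe_radius < 0) stop("probe radius must be >= 0", call. = FALSE)
  stopifnot(all(radii > 0), n_points > 0)
  structure(list(probe_radius = probe_radius, radii = radii,
                 n_points = as.integer(n_points)), class = "sasa_config")
}

## deterministic quasi-uniform points on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by sphere-point sampling
#'
#' Shrake-Rupley-style SASA: each bead is inflated by the probe radius,
#' sampled with a deterministic Fibonacci point lattice, and points buried
#' inside any neighbour's inflated sphere are discarded; the exposed
#' fraction times the inflated sphere area gives the per-bead SASA.
#' Virtual beads are excluded.
#'
#' @param top a [cg_topology()] (radii taken per bead size class), or
#'   `NULL` if `radii` is given.
#' @param coords n x 3 coordinates (nm); defaults to the topology's bead
#'   positions.
#' @param config a [sasa_config()].
#' @param radii optional explicit per-particle vdW radii (overrides the
#'   topology).
#' @return List: `total` (nm^2), `per_bead` (nm^2 per particle; 0 for
#'   virtual beads).
#' @examples
#' b <- cg_topology(list(cg_bead(1, "W", c(0, 0, 0))))
#' sasa(b)$total                    # ~ 4*pi*(0.264+0.191)^2
#' @export
sasa <- function(top, coords = NULL, config = sasa_config(), radii = NULL) {
  if (is.null(radii)) {
    cls <- vapply(top$beads, function(b) b$type$size_class, "")
    radii <- unname(config$radii[cls])
    virt <- is_virtual_bead(top)
  } else virt <- rep(FALSE, length(radii))
  if (is.null(coords)) coords <- bead_positions(top)
  keep <- which(!virt)
  R <- radii + config$probe_radius
  pts <- fibonacci_sphere(config$n_points)
  per <- numeric(length(radii))
  for (i in keep) {
    nb <- keep[keep != i]
    d <- sqrt(rowSums(sweep(coords[nb, , drop = FALSE], 2, coords[i, ])^2))
    nb <- nb[d < R[i] + R[nb]]
    surf <- sweep(pts * R[i], 2, coords[i, ], "+")
    exposed <- rep(TRUE, nrow(surf))
    for (j in nb) {
      d2 <- rowSums(sweep(surf, 2, coords[j, ])^2)
      exposed <- exposed & (d2 > R[j]^2)
    }
    per[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  list(total = sum(per), per_bead = per)
}

## ---- RDF ------------------------------------------------------------------

#' Radial distribution function under minimum image
#'
#' Pair-distance histogram between two particle groups in a periodic cubic
#' box, normalized by the ideal-gas shell expectation, so g(r) tends to 1
#' at large r for homogeneous systems.
#'
#' @param a,b n x 3 coordinate matrices (nm); pass the same matrix (or
#'   `b = NULL`) for an intra-group RDF (self pairs excluded).
#' @param box cubic box edge (nm) or length-3 vector.
#' @param dr bin width (nm).
#' @param r_max maximum distance; must not exceed half the smallest box
#'   edge.
#' @return Object of class `rdf_profile`: `r` (bin centres), `g`,
#'   `counts`, and normalization metadata.
#' @export
rdf <- function(a, b = NULL, box, dr = 0.05, r_max = NULL) {
  a <- rbind(a)
  same <- is.null(b) || identical(a, rbind(b))
  b <- if (is.null(b)) a else rbind(b)
  if (!nrow(a) || !nrow(b))
    stop("empty group: RDF needs at least one particle per group",
         call. = FALSE)
  box <- rep(as.numeric(box), length.out = 3)
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max must not exceed half the smallest box edge", call. = FALSE)
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  ## minimum-image pair distances
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d <- sqrt(d2)
  if (same) d[upper.tri(d, diag = TRUE)] <- NA   # self/duplicate pairs
  d <- d[!is.na(d) & d <= r_max & d > 0]
  counts <- graphics::hist(d, breaks = breaks, plot = FALSE)$counts
  if (same) counts <- 2 * counts                 # restore ordered pairs
  v <- prod(box)
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  rho <- if (same) (nrow(b) - 1) / v else nrow(b) / v
  g <- counts / (nrow(a) * rho * shell)
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2, g = g,
                 counts = counts, box = box, dr = dr,
                 n_a = nrow(a), n_b = nrow(b), same_group = same),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("<rdf_profile> %d bins to %.2f nm, %d x %d particles\n",
              length(x$r), max(x$r) + x$dr / 2, x$n_a, x$n_b))
  invisible(x)
}

#' Per-glycan centres of geometry
#'
#' Used for glycan-glycan RDFs at the glycan level (one point per glycan
#' tree); bead-level RDFs can be computed by passing the glycan bead
#' coordinates to [rdf()] directly.
#'
#' @param top a glycosylated topology with recorded glycan chains.
#' @param coords optional coordinates (defaults to bead positions).
#' @return Matrix (n_glycans x 3) of glycan centres.
#' @export
glycan_centers <- function(top, coords = NULL) {
  if (is.null(top$glycan_sites) || !length(top$glycan_sites))
    stop("topology has no recorded glycan chains", call. = FALSE)
  if (is.null(coords)) coords <- bead_positions(top)
  virt <- is_virtual_bead(top)
  resids <- vapply(top$beads, `[[`, integer(1), "resid")
  t(vapply(top$glycan_sites, function(chain) {
    idx <- which(resids %in% chain & !virt)
    colMeans(coords[idx, , drop = FALSE])
  }, numeric(3)))
}

## ---- RMSD -----------------------------------------------------------------

#' Per-frame RMSD of a pseudo-CG trajectory against a reference
#'
#' @param traj a [trajectory()].
#' @param ref n x 3 reference coordinates.
#' @param superpose least-squares rigid superposition (Kabsch) before the
#'   deviation is computed?
#' @return Numeric vector of per-frame RMSD values (nm).
#' @export
rmsd_pseudo_cg <- function(traj, ref, superpose = TRUE) {
  ref <- rbind(ref)
  if (n_particles(traj) != nrow(ref))
    stop("shape error: trajectory and reference particle counts differ",
         call. = FALSE)
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    if (superpose) x <- kabsch_superpose(x, ref)
    sqrt(mean(rowSums((x - ref)^2)))
  }, numeric(1))
}

## ---- Flory scaling --------------------------------------------------------

#' Fit the Flory power law Rg = R0 * Mw^v
#'
#' Ordinary least squares on log-log axes: `v` is the slope and
#' `R0 = exp(intercept)`. A weighted fit is available through `weights`.
#' The scaling exponent discriminates collapsed globules (~0.33), random
#' coils (0.5-0.6) and rigid rods (1.0).
#'
#' @param rg radii of gyration (nm), all > 0.
#' @param mw molecular weights (Da), all > 0.
#' @param weights optional least-squares weights.
#' @return Object of class `flory_fit` with `R0`, `v`, `se_v`,
#'   `residuals` and the underlying `lm` fit. Methods: `print`, `coef`,
#'   `predict`, `plot`.
#' @examples
#' f <- fit_flory(c(1, 10^0.5), c(1, 10))
#' coef(f)   # v = 0.5
#' @export
fit_flory <- function(rg, mw, weights = NULL) {
  if (length(rg) < 2 || length(rg) != length(mw))
    stop("at least two (Rg, Mw) pairs required", call. = FALSE)
  if (any(rg <= 0) || any(mw <= 0))
    stop("domain error: Rg and Mw must be positive", call. = FALSE)
  df <- data.frame(lrg = log(rg), lmw = log(mw))
  fit <- if (is.null(weights)) stats::lm(lrg ~ lmw, data = df)
         else stats::lm(lrg ~ lmw, data = df, weights = weights)
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))[2]),
                 error = function(e) NA)
  structure(list(R0 = exp(unname(cf[1])), v = unname(cf[2]),
                 se_v = unname(se), residuals = stats::residuals(fit),
                 lm = fit, rg = rg, mw = mw),
            class = "flory_fit")
}

#' @export
print.flory_fit <- function(x, ...) {
  cat(sprintf("<flory_fit> Rg = %.4g * Mw^%.4f  (se_v %.3g, n %d)\n",
              x$R0, x$v, x$se_v, length(x$rg)))
  invisible(x)
}

#' @export
coef.flory_fit <- function(object, ...) c(R0 = object$R0, v = object$v)

#' @export
predict.flory_fit <- function(object, mw, ...) object$R0 * mw^object$v

#' @export
plot.flory_fit <- function(x, ...) {
  graphics::plot(x$mw, x$rg, log = "xy", xlab = "Mw (Da)",
                 ylab = "Rg (nm)", pch = 19, ...)
  mwg <- exp(seq(log(min(x$mw)), log(max(x$mw)), length.out = 100))
  graphics::lines(mwg, predict(x, mwg), col = "firebrick")
}

## ---- nonbonded parameters and LJ downscaling ------------------------------

#' Pairwise Lennard-Jones parameter table
#'
#' Symmetric LJ table keyed by bead-type pairs, with an interaction group
#' (protein / glycan / water / ion) per type.
#'
#' @param pairs data frame with columns `type_i`, `type_j`, `sigma` (nm),
#'   `epsilon` (kJ/mol).
#' @param groups named character vector: group label per bead type.
#' @return Object of class `nonbonded_params`.
#' @export
nonbonded_params <- function(pairs, groups) {
  stopifnot(all(c("type_i", "type_j", "sigma", "epsilon") %in% names(pairs)))
  if (any(pairs$epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  ## canonicalize key order so the table is symmetric by construction
  swap <- pairs$type_i > pairs$type_j
  tmp <- pairs$type_i[swap]
  pairs$type_i[swap] <- pairs$type_j[swap]
  pairs$type_j[swap] <- tmp
  pairs <- pairs[!duplicated(pairs[, c("type_i", "type_j")]), ]
  structure(list(pairs = pairs, groups = groups),
            class = "nonbonded_params")
}

#' @rdname nonbonded_params
#' @param top a [cg_topology()]; one pair entry is generated per type
#'   combination present (generic MARTINI-like sigma by size class,
#'   uniform epsilon), with W and ion types appended.
#' @param epsilon uniform epsilon (kJ/mol) for the generated table.
#' @export
default_nonbonded_params <- function(top, epsilon = 2.0) {
  tn <- vapply(top$beads, function(b) b$type$name, "")
  gr <- bead_groups(top)
  groups <- c(tapply(gr, tn, function(g) g[1]), W = "water", TQ5 = "ion",
              TQ5m = "ion")
  types <- names(groups)
  sig <- c(T = 0.34, S = 0.41, R = 0.47)[size_class_of(types)]
  idx <- which(upper.tri(matrix(0, length(types), length(types)),
                         diag = TRUE), arr.ind = TRUE)
  pairs <- data.frame(type_i = types[idx[, 1]], type_j = types[idx[, 2]],
                      sigma = (sig[idx[, 1]] + sig[idx[, 2]]) / 2,
                      epsilon = epsilon, stringsAsFactors = FALSE)
  nonbonded_params(pairs, groups)
}

#' @export
print.nonbonded_params <- function(x, ...) {
  cat(sprintf("<nonbonded_params> %d pairs over %d types\n",
              nrow(x$pairs), length(x$groups)))
  invisible(x)
}

#' @rdname nonbonded_params
#' @param type_a,type_b bead type labels; `lj_epsilon()` looks up the
#'   epsilon of one pair.
#' @export
lj_epsilon <- function(params, type_a, type_b) {
  i <- min(type_a, type_b); j <- max(type_a, type_b)
  row <- params$pairs$type_i == i & params$pairs$type_j == j
  params$pairs$epsilon[row]
}

#' Downscale protein-protein LJ interactions
#'
#' Multiplies the LJ epsilon by `factor` for pairs where BOTH bead types
#' belong to the protein moiety (backbone, side chains and, by default,
#' glycans), leaving protein-water, water-water and ion interactions
#' untouched — the standard remedy for over-sticky protein-protein
#' interactions of CG IDP models. Sigma is never changed.
#'
#' @param params a [nonbonded_params()].
#' @param factor scaling factor in (0, 1].
#' @param protein_groups group labels counted as "protein".
#' @return The modified [nonbonded_params()].
#' @examples
#' \dontrun{downscale_protein_lj(params, 0.88)}
#' @export
downscale_protein_lj <- function(params, factor,
                                 protein_groups = c("protein", "glycan")) {
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  if (factor > 1) stop("factor must be <= 1", call. = FALSE)
  isprot <- function(t) params$groups[t] %in% protein_groups
  both <- isprot(params$pairs$type_i) & isprot(params$pairs$type_j)
  params$pairs$epsilon[both] <- params$pairs$epsilon[both] * factor
  params
}

## ---- per-frame structural metrics -----------------------------------------

#' Per-frame structural metrics of a CG trajectory
#'
#' Computes Rg, Ree and (optionally) SASA for every frame plus their
#' means and standard deviations.
#'
#' @param traj a [trajectory()].
#' @param top the matching [cg_topology()].
#' @param termini indices of the terminal backbone beads (default: first
#'   and last recorded backbone bead).
#' @param include_sasa compute per-frame SASA (slower)?
#' @param sasa_cfg a [sasa_config()].
#' @return Object of class `structural_metrics`: data frame `per_frame`
#'   and list `summary`.
#' @export
structural_metrics <- function(traj, top, termini = NULL,
                               include_sasa = FALSE,
                               sasa_cfg = sasa_config()) {
  m <- bead_masses(top)
  if (is.null(termini)) {
    if (is.null(top$backbone) || length(top$backbone) < 2)
      stop("selection error: no backbone termini available", call. = FALSE)
    termini <- c(top$backbone[1], top$backbone[length(top$backbone)])
  }
  rg <- rg_trajectory(traj, m)
  ree <- ree_trajectory(traj, termini[1], termini[2])
  sa <- if (include_sasa)
    vapply(seq_len(n_frames(traj)), function(f)
      sasa(top, frame_coords(traj, f), sasa_cfg)$total, numeric(1))
  else rep(NA_real_, n_frames(traj))
  per <- data.frame(frame = seq_len(n_frames(traj)), rg = rg, ree = ree,
                    sasa = sa)
  structure(list(per_frame = per,
                 summary = list(rg_mean = mean(rg), rg_sd = stats::sd(rg),
                                ree_mean = mean(ree),
                                ree_sd = stats::sd(ree),
                                sasa_mean = mean(sa),
                                sasa_sd = stats::sd(sa))),
            class = "structural_metrics")
}

#' @export
print.structural_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<structural_metrics> %d frames: Rg %.3f +/- %.3f nm, Ree %.3f +/- %.3f nm%s\n",
    nrow(x$per_frame), s$rg_mean, s$rg_sd, s$ree_mean, s$ree_sd,
    if (is.na(s$sasa_mean)) ""
    else sprintf(", SASA %.1f +/- %.1f nm^2", s$sasa_mean, s$sasa_sd)))
  invisible(x)
}
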