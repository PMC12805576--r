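## Boltzmann-distributed synthetic trajectories (exact per-DOF sampling +
## chain-wise Cartesian reconstruction) and a desk-scale Metropolis Monte
## Carlo sampler over bead positions.

## inverse-CDF sampling from a tabulated density on a grid
sample_from_density <- function(grid, dens, n) {
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  ## strictly increasing for approx()
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], grid[keep], xout = stats::runif(n),
                rule = 2)$y
}

sample_bond_lengths <- function(term, n, temperature) {
  sd <- sqrt(kBT(temperature) / term$k_b)
  r <- stats::rnorm(n, term$r0, sd)
  bad <- r <= 0
  while (any(bad)) { r[bad] <- stats::rnorm(sum(bad), term$r0, sd)
                     bad <- r <= 0 }
  r
}

sample_reb_angles <- function(term, n, temperature) {
  grid <- seq(0.05, 179.95, by = 0.05)
  sample_from_density(grid, reb_boltzmann_density(term, grid, temperature), n)
}

sample_dihedral_angles <- function(term, n, temperature) {
  grid <- seq(-179.9, 180, by = 0.1)
  sample_from_density(grid,
                      dihedral_boltzmann_density(term, grid, temperature), n)
}

## lookup tables for terms by canonical index keys
term_lookup <- function(terms, kind) {
  env <- new.env(parent = emptyenv())
  for (t in terms) {
    key <- switch(kind,
      bond = paste(sort(c(t$i, t$j)), collapse = "-"),
      angle = paste(min(t$i, t$k), t$j, max(t$i, t$k), sep = "-"),
      dihedral = {
        f <- c(t$i, t$j, t$k, t$l)
        r <- rev(f)
        paste(if (paste(f, collapse = "-") < paste(r, collapse = "-")) f
              else r, collapse = "-")
      })
    assign(key, t, envir = env)
  }
  env
}

get_term <- function(env, idx, kind) {
  key <- switch(kind,
    bond = paste(sort(idx), collapse = "-"),
    angle = paste(min(idx[1], idx[3]), idx[2], max(idx[1], idx[3]),
                  sep = "-"),
    dihedral = {
      r <- rev(idx)
      paste(if (paste(idx, collapse = "-") < paste(r, collapse = "-")) idx
            else r, collapse = "-")
    })
  if (exists(key, envir = env, inherits = FALSE))
    get(key, envir = env, inherits = FALSE) else NULL
}

#' Generate a synthetic trajectory with exactly Boltzmann-distributed
#' bonded degrees of freedom
#'
#' Builds frames by sampling every bonded internal coordinate along a
#' spanning tree of the bead graph from its exact Boltzmann density
#' (Gaussian for harmonic bonds; sin-Jacobian-weighted ReB density for
#' angles; periodic-potential density for dihedrals; inverse-CDF on a fine
#' grid) and reconstructing Cartesian coordinates chain-wise. Internal
#' coordinates of rigid monosaccharide groups are held at their reference
#' geometry, so intra-ring distances have zero variance; virtual sites are
#' recomputed per frame as ring centroids.
#'
#' Degrees of freedom without a matching bonded term are held fixed at the
#' reference geometry. The bead graph minus rigid-group-internal edges
#' must be acyclic.
#'
#' @param top a [cg_topology()] whose bond/angle/dihedral terms carry the
#'   target parameters.
#' @param temperature temperature (K).
#' @param n_frames number of frames to generate.
#' @param seed integer seed (deterministic output).
#' @return A [trajectory()] with `n_frames` frames over the topology's
#'   beads.
#' @examples
#' fx <- toy_glycopeptide(3, seed = 1)
#' tr <- generate_synthetic_trajectory(fx$topology, n_frames = 100, seed = 2)
#' @export
generate_synthetic_trajectory <- function(top, temperature = 300,
                                          n_frames = 1000, seed = 1) {
  stopifnot(n_frames >= 1)
  set.seed(stream_seed(seed, 11))
  nb <- n_beads(top)
  xyz0 <- bead_positions(top)
  virt <- is_virtual_bead(top)
  adj <- adjacency_list(top)
  in_same_rigid <- function(i, j) {
    for (g in top$rigid_groups) if (i %in% g && j %in% g) return(TRUE)
    FALSE
  }
  ## BFS spanning tree over real beads
  real <- which(!virt)
  root <- real[1]
  parent <- rep(NA_integer_, nb)
  order <- integer(0)
  visited <- rep(FALSE, nb)
  queue <- root; visited[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in adj[[v]]) {
      if (virt[w]) next
      if (!visited[w]) {
        visited[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
      } else if (!identical(parent[v], w) && !in_same_rigid(v, w)) {
        stop("unsupported topology: bead graph contains a cycle outside ",
             "rigid groups", call. = FALSE)
      }
    }
  }
  if (!all(visited[real]))
    stop("unsupported topology: bead graph is disconnected", call. = FALSE)

  bond_env <- term_lookup(top$bonds, "bond")
  ang_env <- term_lookup(top$angles, "angle")
  dih_env <- term_lookup(top$dihedrals, "dihedral")
  one <- function(i) matrix(xyz0[i, ], 1)
  rep_slab <- function(v) matrix(rep(v, each = n_frames), n_frames)

  coords <- array(NA_real_, c(n_frames, nb, 3))
  for (v in order) {
    p <- parent[v]
    if (is.na(p)) { coords[, v, ] <- rep_slab(xyz0[v, ]); next }
    g <- parent[p]
    rigid <- in_same_rigid(v, p)
    r_ref <- sqrt(sum((xyz0[v, ] - xyz0[p, ])^2))
    bt <- get_term(bond_env, c(p, v), "bond")
    r <- if (!rigid && !is.null(bt)) sample_bond_lengths(bt, n_frames,
                                                         temperature)
         else rep(r_ref, n_frames)
    if (is.na(g)) {
      ## second bead of the chain: place along +x from the parent
      coords[, v, ] <- coords[, p, , drop = FALSE][, 1, ] +
        cbind(r, 0, 0)
      next
    }
    gg <- parent[g]
    th_ref <- frame_angles(one(g), one(p), one(v))
    at <- get_term(ang_env, c(g, p, v), "angle")
    rigid_a <- rigid || in_same_rigid(v, g)
    theta <- if (!rigid_a && !is.null(at))
      sample_reb_angles(at, n_frames, temperature)
    else rep(th_ref, n_frames)
    if (is.na(gg)) {
      ## third bead: fixed reference plane (fake previous point)
      aslab <- coords[, g, , drop = FALSE][, 1, ] +
        rep_slab(c(0, 0, 1))
      phi <- rep(0, n_frames)
      ph_ref <- 0
    } else {
      aslab <- coords[, gg, , drop = FALSE][, 1, ]
      ph_ref <- frame_dihedrals(one(gg), one(g), one(p), one(v))
      dt <- get_term(dih_env, c(gg, g, p, v), "dihedral")
      rigid_d <- rigid_a || in_same_rigid(v, gg)
      phi <- if (!rigid_d && !is.null(dt))
        sample_dihedral_angles(dt, n_frames, temperature)
      else rep(ph_ref, n_frames)
    }
    coords[, v, ] <- place_nerf(aslab,
                                coords[, g, , drop = FALSE][, 1, ],
                                coords[, p, , drop = FALSE][, 1, ],
                                r, theta, phi)
  }
  ## virtual sites: ring centroids per frame
  for (gi in seq_along(top$rigid_groups)) {
    g <- top$rigid_groups[[gi]]
    vv <- g[virt[g]]; rr <- g[!virt[g]]
    for (s in vv) for (d in 1:3)
      coords[, s, d] <- rowMeans(coords[, rr, d, drop = FALSE])
  }
  trajectory(coords)
}

## ---- Metropolis sampler ---------------------------------------------------

#' Sampler configuration
#'
#' @param temperature temperature (K).
#' @param n_steps number of Metropolis attempts.
#' @param step translation step size (nm).
#' @param rot_step rigid-group rotation step (radians).
#' @param thin record a frame every `thin` accepted-or-rejected steps.
#' @param seed integer seed.
#' @param excluded_volume add a WCA-style soft repulsion between
#'   non-bonded bead pairs?
#' @param wca_sigma,wca_eps repulsion range (nm) and strength (kJ/mol).
#' @param pivot_prob probability of attempting a chain pivot move (rotate
#'   a whole subtree about a backbone bead) instead of a local move;
#'   pivots leave bonded geometry through the pivot bead's subtree intact
#'   and dramatically speed up conformational sampling of polymers.
#' @param backbone_attraction well depth (kJ/mol) of an attractive LJ
#'   between protein-group bead pairs; 0 (default) keeps all non-bonded
#'   interactions purely repulsive. A non-zero value emulates the sticky
#'   protein-protein interactions that collapse bare IDP backbones, while
#'   glycan-bead pairs stay repulsive (charged-brush surrogate).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 300, n_steps = 10000, step = 0.06,
                           rot_step = 0.3, thin = 10, seed = 1,
                           excluded_volume = FALSE, wca_sigma = 0.47,
                           wca_eps = 2.0, pivot_prob = 0,
                           backbone_attraction = 0) {
  stopifnot(n_steps > 0, temperature > 0, pivot_prob >= 0, pivot_prob <= 1,
            backbone_attraction >= 0)
  structure(list(temperature = temperature, n_steps = as.integer(n_steps),
                 step = step, rot_step = rot_step, thin = as.integer(thin),
                 seed = seed, excluded_volume = isTRUE(excluded_volume),
                 wca_sigma = wca_sigma, wca_eps = wca_eps,
                 pivot_prob = pivot_prob,
                 backbone_attraction = backbone_attraction),
            class = "sampler_config")
}

## WCA (purely repulsive, shifted LJ) pair energy, vectorised over rows
wca_energy <- function(d2, sigma, eps) {
  rc2 <- (2^(1 / 3)) * sigma^2
  out <- numeric(length(d2))
  act <- d2 < rc2 & d2 > 0
  if (any(act)) {
    s6 <- (sigma^2 / d2[act])^3
    out[act] <- 4 * eps * (s6^2 - s6) + eps
  }
  out
}

#' Metropolis Monte Carlo sampling of a CG molecule
#'
#' Desk-scale sampler targeting \eqn{\exp(-V/k_BT)} with V the sum of the
#' topology's bonded terms plus an optional WCA-style soft repulsion
#' between non-bonded beads (a deliberate surrogate for excluded volume
#' and glycan-glycan repulsion; there is no solvent and no Coulomb term).
#' Rigid monosaccharide groups move as rigid bodies (random translation +
#' rotation about their centroid) and virtual sites follow their group;
#' free beads take Gaussian translation moves. Deterministic for a fixed
#' seed.
#'
#' @param top a [cg_topology()] with parameterized bonded terms.
#' @param config a [sampler_config()].
#' @return A [trajectory()] of recorded frames with attributes
#'   `acceptance` (acceptance rate) and `energy` (recorded total
#'   energies).
#' @export
mc_sample_molecule <- function(top, config = sampler_config()) {
  set.seed(stream_seed(config$seed, 23))
  nb <- n_beads(top)
  xyz <- bead_positions(top)
  virt <- is_virtual_bead(top)
  beta <- 1 / kBT(config$temperature)
  rg <- top$rigid_groups

  ## movers: each rigid group is one mover; each free real bead is one
  group_of <- rep(0L, nb)
  for (gi in seq_along(rg)) group_of[rg[[gi]]] <- gi
  movers <- c(lapply(which(group_of == 0L & !virt), function(i) i), rg)

  ## flat term tables (rigid-internal terms excluded)
  keep_term <- function(t) {
    idx <- unlist(t[intersect(names(t), c("i", "j", "k", "l"))])
    !in_rigid_group(idx, rg)
  }
  bt <- Filter(keep_term, top$bonds)
  at <- Filter(keep_term, top$angles)
  dt <- Filter(keep_term, top$dihedrals)
  B <- if (length(bt)) t(vapply(bt, function(t)
    c(t$i, t$j, t$r0, t$k_b), numeric(4))) else matrix(0, 0, 4)
  A <- if (length(at)) t(vapply(at, function(t)
    c(t$i, t$j, t$k, cos(deg2rad(t$theta0)), t$k_theta), numeric(5)))
  else matrix(0, 0, 5)
  D <- if (length(dt)) t(vapply(dt, function(t)
    c(t$i, t$j, t$k, t$l, t$k_phi, t$n, deg2rad(t$phi_s)), numeric(7)))
  else matrix(0, 0, 7)

  ## per-mover affected-term index lists
  touches <- function(idx_mat, cols, mv)
    which(rowSums(matrix(idx_mat[, cols] %in% mv,
                         nrow = nrow(idx_mat))) > 0)
  ## terms crossing the boundary of a moved set (internal geometry of the
  ## set is preserved by rigid motion, so fully-internal terms drop out)
  crossing <- function(idx_mat, cols, set) {
    inm <- matrix(idx_mat[, cols] %in% set, nrow = nrow(idx_mat))
    cnt <- rowSums(inm)
    which(cnt > 0 & cnt < length(cols))
  }
  mov_b <- lapply(movers, function(mv) touches(B, 1:2, mv))
  mov_a <- lapply(movers, function(mv) touches(A, 1:3, mv))
  mov_d <- lapply(movers, function(mv) touches(D, 1:4, mv))

  ## non-bonded exclusions: virtual, same rigid group, directly bonded
  bonded_pair <- matrix(FALSE, nb, nb)
  e <- bond_edges(top)
  for (r in seq_len(nrow(e))) bonded_pair[e[r, 1], e[r, 2]] <-
      bonded_pair[e[r, 2], e[r, 1]] <- TRUE
  for (g in rg) bonded_pair[g, g] <- TRUE
  diag(bonded_pair) <- TRUE
  partners <- lapply(seq_len(nb), function(i)
    if (virt[i]) integer() else which(!virt & !bonded_pair[i, ]))
  ## attractive (protein-protein) vs purely repulsive pair classification
  is_prot <- bead_groups(top) == "protein" & config$backbone_attraction > 0
  patt <- lapply(seq_len(nb), function(i) is_prot[i] & is_prot[partners[[i]]])

  ## non-bonded pair energy: WCA repulsion, or truncated LJ with an
  ## attractive well for protein-protein pairs
  pair_energy <- function(d2, att) {
    e <- wca_energy(d2[!att], config$wca_sigma, config$wca_eps)
    tot <- sum(e)
    if (any(att)) {
      d2a <- d2[att]
      d2a <- d2a[d2a < 1.44]             # 1.2 nm cutoff
      if (length(d2a)) {
        s6 <- (config$wca_sigma^2 / d2a)^3
        tot <- tot + sum(4 * config$backbone_attraction * (s6 * s6 - s6))
      }
    }
    tot
  }

  ## pivot movers: rotate the BFS subtree hanging below a bead about that
  ## bead; only beads outside rigid groups whose subtree is non-trivial
  pivots <- list()
  if (config$pivot_prob > 0 && nb > 3) {
    parent <- rep(NA_integer_, nb)
    ordv <- integer(0)
    visited <- rep(FALSE, nb)
    adj <- adjacency_list(top)
    root <- which(!virt)[1]
    queue <- root; visited[root] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; ordv <- c(ordv, v)
      for (w in adj[[v]]) if (!visited[w]) {
        visited[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
      }
    }
    desc <- lapply(seq_len(nb), function(i) integer())
    for (v in rev(ordv)) if (!is.na(parent[v]))
      desc[[parent[v]]] <- c(desc[[parent[v]]], v, desc[[v]])
    for (p in ordv) {
      sub <- desc[[p]]
      if (length(sub) < 2 || length(sub) >= nb - 1) next
      if (group_of[p] != 0L) next            # never split a rigid ring
      ## virtual sites of rings wholly inside the subtree come along
      pivots[[length(pivots) + 1L]] <- list(
        p = p, sub = sub,
        tb = crossing(B, 1:2, sub), ta = crossing(A, 1:3, sub),
        td = crossing(D, 1:4, sub),
        sub_real = sub[!virt[sub]],
        pset = lapply(sub[!virt[sub]], function(m)
          setdiff(partners[[m]], sub)),
        pat = lapply(sub[!virt[sub]], function(m)
          is_prot[m] & is_prot[setdiff(partners[[m]], sub)]))
    }
  }

  ebond <- function(x, idx) {
    if (!length(idx)) return(0)
    d <- sqrt(rowSums((x[B[idx, 1], , drop = FALSE] -
                       x[B[idx, 2], , drop = FALSE])^2))
    sum(0.5 * B[idx, 4] * (d - B[idx, 3])^2)
  }
  eang <- function(x, idx) {
    if (!length(idx)) return(0)
    u <- x[A[idx, 1], , drop = FALSE] - x[A[idx, 2], , drop = FALSE]
    v <- x[A[idx, 3], , drop = FALSE] - x[A[idx, 2], , drop = FALSE]
    cth <- rowSums(u * v) / sqrt(rowSums(u * u) * rowSums(v * v))
    cth <- pmin(1, pmax(-1, cth))
    s2 <- 1 - cth * cth
    if (any(s2 < 1e-12)) return(Inf)
    sum(0.5 * A[idx, 5] * (cth - A[idx, 4])^2 / s2)
  }
  edih <- function(x, idx) {
    if (!length(idx)) return(0)
    phi <- frame_dihedrals(x[D[idx, 1], , drop = FALSE],
                           x[D[idx, 2], , drop = FALSE],
                           x[D[idx, 3], , drop = FALSE],
                           x[D[idx, 4], , drop = FALSE])
    sum(D[idx, 5] * (1 + cos(D[idx, 6] * deg2rad(phi) - D[idx, 7])))
  }
  ewca <- function(x, mv) {
    if (!config$excluded_volume) return(0)
    tot <- 0
    for (m in mv) {
      pl <- partners[[m]]
      if (!length(pl)) next
      d2 <- (x[pl, 1] - x[m, 1])^2 + (x[pl, 2] - x[m, 2])^2 +
        (x[pl, 3] - x[m, 3])^2
      tot <- tot + pair_energy(d2, patt[[m]])
    }
    tot
  }
  local_energy <- function(x, mi, mv)
    ebond(x, mov_b[[mi]]) + eang(x, mov_a[[mi]]) + edih(x, mov_d[[mi]]) +
      ewca(x, mv)

  pivot_energy <- function(x, pv) {
    tot <- ebond(x, pv$tb) + eang(x, pv$ta) + edih(x, pv$td)
    if (config$excluded_volume)
      for (q in seq_along(pv$sub_real)) {
        m <- pv$sub_real[q]; pl <- pv$pset[[q]]
        if (!length(pl)) next
        d2 <- (x[pl, 1] - x[m, 1])^2 + (x[pl, 2] - x[m, 2])^2 +
          (x[pl, 3] - x[m, 3])^2
        tot <- tot + pair_energy(d2, pv$pat[[q]])
      }
    tot
  }

  rot_mat <- function(ang) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }

  frames <- list()
  acc <- 0L
  last_acc <- 0L
  nmov <- length(movers)
  npiv <- length(pivots)
  for (s in seq_len(config$n_steps)) {
    do_pivot <- npiv > 0 && stats::runif(1) < config$pivot_prob
    if (do_pivot) {
      pv <- pivots[[1L + as.integer(stats::runif(1) * npiv) %% npiv]]
      mv <- pv$sub
      e_old <- pivot_energy(xyz, pv)
      old_rows <- xyz[mv, , drop = FALSE]
      R <- rot_mat(stats::runif(1, -pi, pi))
      ctr <- xyz[pv$p, ]
      xyz[mv, ] <- sweep(sweep(old_rows, 2, ctr) %*% t(R), 2, ctr, "+")
      dE <- pivot_energy(xyz, pv) - e_old
    } else {
      mi <- 1L + as.integer(stats::runif(1) * nmov) %% nmov
      mv <- movers[[mi]]
      e_old <- local_energy(xyz, mi, mv)
      old_rows <- xyz[mv, , drop = FALSE]
      if (length(mv) == 1L) {
        xyz[mv, ] <- old_rows + stats::rnorm(3, 0, config$step)
      } else {
        shift <- stats::rnorm(3, 0, config$step)
        R <- rot_mat(stats::runif(1, -config$rot_step, config$rot_step))
        ctr <- colMeans(old_rows)
        xyz[mv, ] <- sweep(sweep(old_rows, 2, ctr) %*% t(R), 2,
                           ctr + shift, "+")
      }
      dE <- local_energy(xyz, mi, mv) - e_old
    }
    if (is.finite(dE) && (dE <= 0 || stats::runif(1) < exp(-beta * dE))) {
      acc <- acc + 1L; last_acc <- s
    } else {
      xyz[mv, ] <- old_rows
    }
    if (s - last_acc >= 10000L)
      stop("stuck sampler: no accepted move in 10000 steps (last acceptance ",
           "at step ", last_acc, ")", call. = FALSE)
    if (s %% config$thin == 0L) {
      ## virtual sites follow their ring centroids (pivot moves displace
      ## rings without touching the derived sites)
      for (g in rg) {
        vv <- g[virt[g]]
        if (length(vv))
          xyz[vv, ] <- rep(colMeans(xyz[g[!virt[g]], , drop = FALSE]),
                           each = length(vv))
      }
      frames[[length(frames) + 1L]] <- xyz
    }
  }
  out <- trajectory(frames)
  attr(out, "acceptance") <- acc / config$n_steps
  out
}
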