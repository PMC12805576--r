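## Modified Boltzmann inversion of bonded distributions:
##   bonds    — Gaussian moment matching: r0 = mean, k_b = kB*T / Var;
##   angles   — theta0 from the (sin-Jacobian-corrected) PMF mode, k_theta
##              by matching the variance of the exact ReB Boltzmann
##              density (1-D root find);
##   dihedrals — least-squares fit of k_phi (1 + cos(n phi - phi_s)) to the
##              PMF over candidate multiplicities.

.default_bins <- list(bond = 0.001, angle = 1, dihedral = 5)

#' Measure bonded distributions from a (pseudo-)CG trajectory
#'
#' One distribution per bonded term of the topology: bond lengths (nm),
#' angles and dihedrals (degrees, dihedrals wrapped to (-180, 180]).
#' Terms internal to rigid monosaccharide groups are excluded (rigid rings
#' carry no fitted bonded terms). Angle samples at 180 degrees are flagged
#' in the distribution's `warnings`, since the ReB form is singular there.
#'
#' @param traj a [trajectory()] whose particle count matches the topology.
#' @param top a [cg_topology()].
#' @param bins histogram bin widths, nm or deg (defaults: 0.001 nm bonds,
#'   1 deg angles, 5 deg dihedrals).
#' @return A list of `bonded_distribution` objects.
#' @export
measure_distributions <- function(traj, top, bins = .default_bins) {
  if (n_particles(traj) != n_beads(top))
    stop("topology bead count does not match trajectory", call. = FALSE)
  if (n_frames(traj) < 2)
    stop("insufficient data: at least 2 frames required", call. = FALSE)
  rg <- top$rigid_groups
  out <- list()
  grab <- function(i) traj_slab(traj, i)
  for (t in top$bonds) {
    if (in_rigid_group(c(t$i, t$j), rg)) next
    out[[length(out) + 1L]] <-
      bonded_distribution("bond", c(t$i, t$j),
                          frame_distances(grab(t$i), grab(t$j)),
                          bins$bond)
  }
  for (t in top$angles) {
    if (in_rigid_group(c(t$i, t$j, t$k), rg)) next
    out[[length(out) + 1L]] <-
      bonded_distribution("angle", c(t$i, t$j, t$k),
                          frame_angles(grab(t$i), grab(t$j), grab(t$k)),
                          bins$angle)
  }
  for (t in top$dihedrals) {
    if (in_rigid_group(c(t$i, t$j, t$k, t$l), rg)) next
    out[[length(out) + 1L]] <-
      bonded_distribution("dihedral", c(t$i, t$j, t$k, t$l),
                          frame_dihedrals(grab(t$i), grab(t$j), grab(t$k),
                                          grab(t$l)),
                          bins$dihedral)
  }
  out
}

#' Bonded distribution container
#'
#' @param kind `"bond"`, `"angle"` or `"dihedral"`.
#' @param indices bead indices of the term.
#' @param samples measured values (nm or deg).
#' @param bin histogram bin width.
#' @return Object of class `bonded_distribution` with histogram, mean and
#'   variance.
#' @export
bonded_distribution <- function(kind, indices, samples, bin = NULL) {
  if (is.null(bin)) bin <- .default_bins[[kind]]
  rng <- switch(kind,
    bond = c(floor(min(samples) / bin) * bin - bin,
             ceiling(max(samples) / bin) * bin + bin),
    angle = c(0, 180),
    dihedral = c(-180, 180))
  breaks <- seq(rng[1], rng[2], by = bin)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  warn <- character()
  if (kind == "angle" && any(samples >= 180 - 1e-9))
    warn <- "degenerate geometry: angle samples at 180 deg (ReB singular)"
  structure(list(kind = kind, indices = as.integer(indices),
                 samples = samples, breaks = breaks, counts = h$counts,
                 mids = h$mids, mean = mean(samples),
                 variance = stats::var(samples), n = length(samples),
                 warnings = warn),
            class = "bonded_distribution")
}

#' @export
print.bonded_distribution <- function(x, ...) {
  cat(sprintf("<bonded_distribution %s (%s)> n %d, mean %.4g, sd %.3g\n",
              x$kind, paste(x$indices, collapse = "-"), x$n, x$mean,
              sqrt(x$variance)))
  invisible(x)
}

fit_result <- function(term, gof, n, warnings = character()) {
  structure(list(term = term, gof = gof, n = n, warnings = warnings),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  print(x$term)
  cat(sprintf("  fit residual %.4g, n %d%s\n", x$gof, x$n,
              if (length(x$warnings))
                paste0(" [", paste(x$warnings, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Fit a harmonic bond by Gaussian Boltzmann inversion
#'
#' Moment matching against the Gaussian Boltzmann density of the harmonic
#' form: `r0` is the sample mean and `k_b = kB*T / Var(r)`, so the
#' identity `k_b * Var = kB*T` holds exactly by construction.
#'
#' @param dist a `bonded_distribution` of kind `"bond"`.
#' @param temperature temperature (K).
#' @return A `fit_result` whose `term` is a [harmonic_bond()].
#' @export
fit_harmonic_bond <- function(dist, temperature = 300) {
  stopifnot(dist$kind == "bond")
  if (dist$variance <= 0)
    stop("rigid degree of freedom: zero variance; constrain this bond ",
         "instead of fitting it", call. = FALSE)
  warns <- character()
  if (dist$n < 100) {
    warns <- sprintf("only %d samples (< 100)", dist$n)
    warning(warns, call. = FALSE)
  }
  term <- harmonic_bond(dist$indices[1], dist$indices[2],
                        r0 = dist$mean,
                        k_b = kBT(temperature) / dist$variance)
  ## residual of the implied PMF fit on the histogram support
  gof <- pmf_residual_bond(dist, term, temperature)
  fit_result(term, gof, dist$n, warns)
}

pmf_residual_bond <- function(dist, term, temperature) {
  p <- dist$counts / sum(dist$counts)
  nz <- p > 0
  pmf <- -kBT(temperature) * log(p[nz])
  pmf <- pmf - min(pmf)
  model <- bond_energy(term, dist$mids[nz])
  model <- model - min(model)
  sqrt(mean((pmf - model)^2))
}

## variance of the ReB Boltzmann density (sin-Jacobian included)
reb_density_variance <- function(theta0, k_theta, temperature,
                                 grid = seq(0.02, 179.98, by = 0.04)) {
  t <- reb_angle(1, 2, 3, theta0 = theta0, k_theta = k_theta)
  w <- reb_boltzmann_density(t, grid, temperature)
  w <- w / sum(w)
  m <- sum(w * grid)
  sum(w * (grid - m)^2)
}

#' Fit a restricted-bending angle by modified Boltzmann inversion
#'
#' `theta0` is located as the mode of the smoothed, sin-Jacobian-corrected
#' angle PMF (quadratic interpolation around the minimum bin); `k_theta`
#' is found by a 1-D root search so that the variance of the exact ReB
#' Boltzmann density matches the sample variance.
#'
#' @param dist a `bonded_distribution` of kind `"angle"`; samples must lie
#'   strictly inside (0, 180).
#' @param temperature temperature (K).
#' @param smooth apply a 3-bin moving average to the PMF before mode
#'   finding.
#' @return A `fit_result` whose `term` is a [reb_angle()].
#' @export
fit_reb_angle <- function(dist, temperature = 300, smooth = TRUE) {
  stopifnot(dist$kind == "angle")
  if (any(dist$samples >= 180 | dist$samples <= 0))
    stop("singularity: angle samples at or beyond 180 deg cannot be ",
         "described by the ReB form", call. = FALSE)
  if (dist$variance <= 0)
    stop("rigid degree of freedom: zero variance; constrain this angle ",
         "instead of fitting it", call. = FALSE)
  p <- dist$counts / sum(dist$counts)
  jac <- sin(deg2rad(pmin(pmax(dist$mids, 1e-3), 180 - 1e-3)))
  dens <- p / jac
  nz <- which(dens > 0)
  pmf <- rep(NA_real_, length(dens))
  pmf[nz] <- -kBT(temperature) * log(dens[nz])
  if (smooth) pmf <- moving_average(pmf, 3)
  i0 <- nz[which.min(pmf[nz])]
  theta0 <- quad_interp_min(dist$mids, pmf, i0)
  theta0 <- min(max(theta0, 1), 179)

  s2 <- dist$variance
  f <- function(logk) reb_density_variance(theta0, exp(logk),
                                           temperature) - s2
  lo <- log(1e-2); hi <- log(1e6)
  if (f(lo) < 0) k_theta <- 1e-2
  else if (f(hi) > 0) k_theta <- 1e6
  else k_theta <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-8)$root)
  term <- reb_angle(dist$indices[1], dist$indices[2], dist$indices[3],
                    theta0 = theta0, k_theta = k_theta)
  ## residual: histogram overlap deficit against the fitted density
  w <- reb_boltzmann_density(term, dist$mids, temperature)
  gof <- 1 - sum(pmin(p, w / sum(w)))
  fit_result(term, gof, dist$n)
}

moving_average <- function(x, k = 3, circular = FALSE) {
  n <- length(x)
  half <- k %/% 2
  out <- x
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half)
    if (circular) idx <- ((idx - 1) %% n) + 1
    else idx <- idx[idx >= 1 & idx <= n]
    v <- x[idx]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

## sub-bin minimum by quadratic interpolation through three points
quad_interp_min <- function(x, y, i0) {
  if (i0 <= 1 || i0 >= length(x) || anyNA(y[(i0 - 1):(i0 + 1)]))
    return(x[i0])
  y1 <- y[i0 - 1]; y2 <- y[i0]; y3 <- y[i0 + 1]
  den <- y1 - 2 * y2 + y3
  if (den <= 0) return(x[i0])
  x[i0] + 0.5 * (y1 - y3) / den * (x[i0] - x[i0 - 1])
}

#' Fit a periodic dihedral to the PMF of its distribution
#'
#' The PMF is computed as `-kB*T*log` of the normalized histogram, offset
#' so its minimum is zero, and `k_phi (1 + cos(n phi - phi_s))` is fitted
#' by linear least squares (free offset, so the fit is invariant to PMF
#' offset) for each candidate multiplicity; the best `n` is chosen by
#' residual. The number of PMF minima is reported as a multimodality
#' diagnostic.
#'
#' @param dist a `bonded_distribution` of kind `"dihedral"`.
#' @param temperature temperature (K).
#' @param multiplicities candidate multiplicities (default 1:3).
#' @param smooth 3-bin circular moving average before the multimodality
#'   count.
#' @return A `fit_result` with a [periodic_dihedral()] term; the result
#'   carries `n_minima` (multimodality diagnostic) and `residuals_by_n`.
#' @export
fit_periodic_dihedral <- function(dist, temperature = 300,
                                  multiplicities = 1:3, smooth = TRUE) {
  stopifnot(dist$kind == "dihedral")
  warns <- character()
  if (dist$n < 1000) {
    warns <- sprintf("only %d samples (< 1000)", dist$n)
    warning(warns, call. = FALSE)
  }
  p <- dist$counts / sum(dist$counts)
  if (mean(p == 0) > 0.5)
    stop("unsupported dihedral: empty histogram bins span more than half ",
         "the range (too rigid for a single periodic term)", call. = FALSE)
  nz <- which(p > 0)
  pmf <- -kBT(temperature) * log(p[nz])
  pmf <- pmf - min(pmf)
  phi <- deg2rad(dist$mids[nz])

  best <- NULL
  resids <- numeric(0)
  for (n in multiplicities) {
    X <- cbind(1, cos(n * phi), sin(n * phi))
    cf <- stats::lm.fit(X, pmf)$coefficients
    k <- sqrt(cf[2]^2 + cf[3]^2)
    phs <- rad2deg(atan2(cf[3], cf[2]))
    rss <- sqrt(mean((pmf - X %*% cf)^2))
    resids[as.character(n)] <- rss
    if (is.null(best) || rss < best$rss)
      best <- list(n = n, k = k, phs = phs, rss = rss)
  }
  term <- periodic_dihedral(dist$indices[1], dist$indices[2],
                            dist$indices[3], dist$indices[4],
                            k_phi = unname(best$k), n = best$n,
                            phi_s = unname(wrap_angle(best$phs)))
  ## multimodality: minima of the smoothed circular PMF
  pfull <- p
  pfull[pfull == 0] <- min(p[nz]) / 10
  pmf_full <- -kBT(temperature) * log(pfull)
  if (smooth) pmf_full <- moving_average(pmf_full, 3, circular = TRUE)
  nmin <- count_circular_minima(pmf_full)
  out <- fit_result(term, best$rss, dist$n, warns)
  out$n_minima <- nmin
  out$residuals_by_n <- resids
  out
}

count_circular_minima <- function(y, tol = 1e-9) {
  n <- length(y)
  prev <- y[((seq_len(n) - 2) %% n) + 1]
  nxt <- y[(seq_len(n) %% n) + 1]
  sum(y < prev - tol & y < nxt - tol)
}

#' Compare two bonded distributions
#'
#' Absolute percentage deviation of the means and the overlap coefficient
#' of the normalized histograms on a common grid; the statistics used to
#' judge agreement between atomistic (pseudo-CG) and CG bonded
#' distributions.
#'
#' @param ref,test `bonded_distribution`s of the same kind.
#' @return List: `apd_mean` (percent), `overlap` (0..1).
#' @export
compare_distributions <- function(ref, test) {
  if (!identical(ref$kind, test$kind))
    stop("unit error: cannot compare a ", ref$kind, " with a ", test$kind,
         call. = FALSE)
  apd <- abs(ref$mean - test$mean) / abs(ref$mean) * 100
  bin <- min(diff(ref$breaks)[1], diff(test$breaks)[1])
  lo <- min(ref$breaks[1], test$breaks[1])
  hi <- max(ref$breaks[length(ref$breaks)],
            test$breaks[length(test$breaks)])
  grid <- seq(lo, hi, by = bin)
  hr <- graphics::hist(ref$samples, breaks = grid, plot = FALSE)$counts
  ht <- graphics::hist(test$samples, breaks = grid, plot = FALSE)$counts
  ov <- sum(pmin(hr / sum(hr), ht / sum(ht)))
  list(apd_mean = apd, overlap = ov)
}

## ---- the model object -----------------------------------------------------

#' Boltzmann-invert all bonded terms of a topology
#'
#' The package's central fitting routine: measures every bonded
#' distribution of `top` on `traj` (excluding rigid-ring internals) and
#' fits the matching potential form to each — harmonic bonds by Gaussian
#' moment matching, ReB angles by PMF-mode location plus exact-density
#' variance matching, periodic dihedrals by least squares on the PMF over
#' candidate multiplicities.
#'
#' @param traj a (pseudo-)CG [trajectory()].
#' @param top the [cg_topology()] the trajectory belongs to.
#' @param temperature temperature (K) of the underlying ensemble.
#' @param multiplicities candidate dihedral multiplicities.
#' @return An object of class `cg_fit`: the fitted terms, per-term
#'   diagnostics, the measured distributions, and the input topology with
#'   its bonded parameters replaced by the fitted ones (`$topology`).
#'   Methods: `print`, `summary`, `coef`, `plot`, `simulate`, `residuals`.
#' @examples
#' fx <- toy_glycopeptide(3, seed = 1)
#' tr <- generate_synthetic_trajectory(fx$topology, n_frames = 2000,
#'                                     seed = 2)
#' fit <- boltzmann_invert(tr, fx$topology)
#' coef(fit)
#' @export
boltzmann_invert <- function(traj, top, temperature = 300,
                             multiplicities = 1:3) {
  dists <- measure_distributions(traj, top)
  fits <- vector("list", length(dists))
  skipped <- character()
  for (i in seq_along(dists)) {
    d <- dists[[i]]
    fits[[i]] <- tryCatch(
      switch(d$kind,
        bond = fit_harmonic_bond(d, temperature),
        angle = fit_reb_angle(d, temperature),
        dihedral = fit_periodic_dihedral(d, temperature, multiplicities)),
      error = function(e) {
        skipped <<- c(skipped, sprintf("%s (%s): %s", d$kind,
                                       paste(d$indices, collapse = "-"),
                                       conditionMessage(e)))
        NULL
      })
  }
  keep <- !vapply(fits, is.null, logical(1))
  fitted_top <- replace_terms(top, lapply(fits[keep], `[[`, "term"))
  structure(list(fits = fits[keep], distributions = dists,
                 skipped = skipped, temperature = temperature,
                 topology = fitted_top),
            class = "cg_fit")
}

## swap fitted terms into the topology (matched by kind + indices)
replace_terms <- function(top, terms) {
  keyof <- function(t) paste(class(t)[1],
                             paste(unlist(t[intersect(names(t),
                                                      c("i","j","k","l"))]),
                                   collapse = "-"))
  tab <- stats::setNames(terms, vapply(terms, keyof, ""))
  swap <- function(lst) lapply(lst, function(t) {
    r <- tab[[keyof(t)]]
    if (is.null(r)) t else r
  })
  top$bonds <- swap(top$bonds)
  top$angles <- swap(top$angles)
  top$dihedrals <- swap(top$dihedrals)
  top
}

#' @export
print.cg_fit <- function(x, ...) {
  kinds <- vapply(x$fits, function(f) class(f$term)[1], "")
  cat(sprintf(
    "<cg_fit> %d fitted terms (%d bonds, %d angles, %d dihedrals) at %g K\n",
    length(x$fits), sum(kinds == "harmonic_bond"),
    sum(kinds == "reb_angle"), sum(kinds == "periodic_dihedral"),
    x$temperature))
  if (length(x$skipped))
    cat("  skipped:", length(x$skipped), "term(s)\n")
  invisible(x)
}

#' @export
coef.cg_fit <- function(object, ...) {
  rows <- lapply(object$fits, function(f) {
    t <- f$term
    switch(class(t)[1],
      harmonic_bond = data.frame(kind = "bond",
        indices = paste(t$i, t$j, sep = "-"), p1 = t$r0, p2 = t$k_b,
        p3 = NA_real_, gof = f$gof, n = f$n),
      reb_angle = data.frame(kind = "angle",
        indices = paste(t$i, t$j, t$k, sep = "-"), p1 = t$theta0,
        p2 = t$k_theta, p3 = NA_real_, gof = f$gof, n = f$n),
      periodic_dihedral = data.frame(kind = "dihedral",
        indices = paste(t$i, t$j, t$k, t$l, sep = "-"), p1 = t$k_phi,
        p2 = t$n, p3 = t$phi_s, gof = f$gof, n = f$n))
  })
  out <- do.call(rbind, rows)
  ## p1/p2/p3: bond (r0, k_b, -), angle (theta0, k_theta, -),
  ## dihedral (k_phi, n, phi_s)
  rownames(out) <- NULL
  out
}

#' @export
summary.cg_fit <- function(object, ...) {
  cf <- coef(object)
  structure(list(coef = cf, skipped = object$skipped,
                 temperature = object$temperature), class = "summary.cg_fit")
}

#' @export
print.summary.cg_fit <- function(x, ...) {
  cat(sprintf("Boltzmann-inversion fit at %g K\n", x$temperature))
  print(x$coef, digits = 4)
  if (length(x$skipped)) {
    cat("Skipped terms:\n")
    for (s in x$skipped) cat("  -", s, "\n")
  }
  invisible(x)
}

#' @export
residuals.cg_fit <- function(object, ...) {
  vapply(object$fits, `[[`, numeric(1), "gof")
}

#' @export
simulate.cg_fit <- function(object, nsim = 1000, seed = 1, ...) {
  generate_synthetic_trajectory(object$topology,
                                temperature = object$temperature,
                                n_frames = nsim, seed = seed)
}

#' @export
plot.cg_fit <- function(x, which = seq_along(x$fits), ask = FALSE, ...) {
  oldpar <- graphics::par(ask = ask)
  on.exit(graphics::par(oldpar))
  dist_key <- vapply(x$distributions, function(d)
    paste(d$kind, paste(d$indices, collapse = "-")), "")
  for (i in which) {
    f <- x$fits[[i]]
    t <- f$term
    idx <- unlist(t[intersect(names(t), c("i", "j", "k", "l"))])
    d <- x$distributions[[match(
      paste(switch(class(t)[1], harmonic_bond = "bond",
                   reb_angle = "angle", periodic_dihedral = "dihedral"),
            paste(idx, collapse = "-")), dist_key)]]
    p <- d$counts / sum(d$counts) / diff(d$breaks)[1]
    grid <- seq(min(d$breaks), max(d$breaks), length.out = 400)
    dens <- switch(d$kind,
      bond = bond_boltzmann_density(t, pmax(grid, 1e-6), x$temperature),
      angle = reb_boltzmann_density(t, pmin(pmax(grid, 1e-3), 180 - 1e-3),
                                    x$temperature),
      dihedral = dihedral_boltzmann_density(t, grid, x$temperature))
    dens <- dens / (sum(dens) * diff(grid)[1])
    graphics::plot(d$mids, p, type = "h", col = "grey60",
                   xlab = switch(d$kind, bond = "r (nm)",
                                 angle = "theta (deg)", "phi (deg)"),
                   ylab = "density",
                   main = sprintf("%s %s", d$kind,
                                  paste(d$indices, collapse = "-")))
    graphics::lines(grid, dens, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
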