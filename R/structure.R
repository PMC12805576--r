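## Atomistic structure and trajectory containers, plus readers.
## All coordinates in nm (PDB Angstrom converted on read).

#' Construct an atomistic structure
#'
#' Heavy-atom structure container used as mapping input. Hydrogens should
#' not be included: CG mapping combines 2-4 heavy atoms per bead.
#'
#' @param atoms data frame with columns `name`, `element`, `resid`,
#'   `resname`, `x`, `y`, `z` (coordinates in nm).
#' @param bonds optional 2-column integer matrix of covalent atom-atom
#'   bonds (row indices into `atoms`).
#' @param box optional length-3 box vector (nm).
#' @return An object of class `atomistic_structure`.
#' @export
atomistic_structure <- function(atoms, bonds = NULL, box = NULL) {
  need <- c("name", "element", "resid", "resname", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (any(atoms$element %in% c("H", "h")))
    stop("hydrogens must be excluded: mapping uses heavy atoms only",
         call. = FALSE)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    stopifnot(all(bonds >= 1), all(bonds <= nrow(atoms)))
  }
  structure(list(atoms = atoms, bonds = bonds, box = box),
            class = "atomistic_structure")
}

#' @export
print.atomistic_structure <- function(x, ...) {
  cat(sprintf("<atomistic_structure> %d heavy atoms, %d residues, %s bonds\n",
              nrow(x$atoms), length(unique(x$atoms$resid)),
              if (is.null(x$bonds)) "no" else nrow(x$bonds)))
  invisible(x)
}

#' Read a structure file (PDB or GRO)
#'
#' PDB files are parsed with bio3d and converted from Angstrom to nm; GRO
#' files are parsed directly (already nm). Hydrogens are dropped.
#'
#' @param path file path; format chosen by extension (`.pdb` or `.gro`).
#' @return An [atomistic_structure()].
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("reading PDB requires the bio3d package", call. = FALSE)
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    keep <- !(a$elesy %in% c("H", "h"))
    a <- a[keep, , drop = FALSE]
    atomistic_structure(data.frame(
      name = a$elety, element = a$elesy, resid = a$resno,
      resname = a$resid, x = a$x / 10, y = a$y / 10, z = a$z / 10,
      stringsAsFactors = FALSE))
  } else if (ext == "gro") {
    g <- read_gro(path)
    atomistic_structure(g$atoms, box = g$box)
  } else stop("unsupported structure format: .", ext, call. = FALSE)
}

## ---- GRO format -----------------------------------------------------------

## Minimal fixed-column GRO parser (single frame).
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  atoms <- data.frame(
    resid   = as.integer(substr(body, 1, 5)),
    resname = trimws(substr(body, 6, 10)),
    name    = trimws(substr(body, 11, 15)),
    x = as.numeric(substr(body, 21, 28)),
    y = as.numeric(substr(body, 29, 36)),
    z = as.numeric(substr(body, 37, 44)),
    stringsAsFactors = FALSE)
  atoms$element <- substr(atoms$name, 1, 1)
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  list(atoms = atoms, box = box, title = lines[1])
}

write_gro_file <- function(path, title, resid, resname, name, xyz, box) {
  n <- nrow(xyz)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid %% 100000L, resname, substr(name, 1, 5),
                     seq_len(n) %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]),
             sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

## ---- trajectories ---------------------------------------------------------

#' Construct a trajectory frame set
#'
#' Ordered coordinate frames with per-frame (or constant) box vectors. The
#' same container holds atomistic frames (mapping input) and CG/pseudo-CG
#' frames (inversion and analysis input).
#'
#' @param coords array `[frame, particle, xyz]` in nm, or a list of n x 3
#'   matrices.
#' @param box length-3 vector or `n_frames` x 3 matrix of box edges (nm);
#'   optional.
#' @param dt time step between frames (ps), metadata only.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(coords, box = NULL, dt = NA_real_) {
  if (is.list(coords)) {
    nf <- length(coords)
    np <- nrow(coords[[1]])
    arr <- array(NA_real_, c(nf, np, 3))
    for (f in seq_len(nf)) {
      if (nrow(coords[[f]]) != np)
        stop("constant particle count required across frames", call. = FALSE)
      arr[f, , ] <- coords[[f]]
    }
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  structure(list(coords = coords, box = box, dt = dt), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d particles%s\n", d[1], d[2],
              if (is.null(x$box)) "" else ", periodic box"))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_particles <- function(traj) dim(traj$coords)[2]

## slab of one particle across frames: n_frames x 3
traj_slab <- function(traj, i) traj$coords[, i, , drop = FALSE][, 1, ]

frame_coords <- function(traj, f) traj$coords[f, , , drop = FALSE][1, , ]

#' Read/write multi-frame GRO trajectories
#'
#' A multi-frame GRO file is a concatenation of single-frame GRO blocks.
#'
#' @param path file path.
#' @param traj a [trajectory()] (for writing).
#' @param names,resid,resname per-particle metadata for writing.
#' @return `read_trajectory_gro()` returns a [trajectory()].
#' @export
read_trajectory_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); pos <- 1L
  while (pos <= length(lines)) {
    n <- as.integer(trimws(lines[pos + 1L]))
    body <- lines[(pos + 2L):(pos + 1L + n)]
    frames[[length(frames) + 1L]] <- cbind(
      as.numeric(substr(body, 21, 28)),
      as.numeric(substr(body, 29, 36)),
      as.numeric(substr(body, 37, 44)))
    boxes[[length(boxes) + 1L]] <-
      as.numeric(strsplit(trimws(lines[pos + 2L + n]), "\\s+")[[1]])[1:3]
    pos <- pos + 3L + n
  }
  trajectory(frames, box = do.call(rbind, boxes))
}

#' @rdname read_trajectory_gro
#' @export
write_trajectory_gro <- function(path, traj, names = NULL, resid = NULL,
                                 resname = NULL) {
  np <- n_particles(traj)
  if (is.null(names)) names <- sprintf("B%d", seq_len(np))
  if (is.null(resid)) resid <- rep(1L, np)
  if (is.null(resname)) resname <- rep("MOL", np)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    box <- if (is.null(traj$box)) c(0, 0, 0)
           else if (is.matrix(traj$box)) traj$box[f, ] else traj$box
    writeLines(c(sprintf("frame %d", f), sprintf("%5d", np),
                 sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         resid %% 100000L, resname, substr(names, 1, 5),
                         seq_len(np) %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]),
                 sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), con)
  }
  invisible(path)
}
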