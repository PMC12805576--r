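## Bead-type tables: MARTINI 3 size classes, vdW radii, masses, charges.

.size_class_radius <- c(T = 0.191, S = 0.230, R = 0.264)
.size_class_mass   <- c(T = 36, S = 54, R = 72)
.size_class_atoms  <- c(T = 2L, S = 3L, R = 4L)
.virtual_mass      <- 1e-100  # "negligible mass" virtual sites

## Size class from a MARTINI 3 type label: leading T/S means tiny/small,
## anything else (incl. Q4n, P2, W) is a regular bead.
size_class_of <- function(name) {
  first <- substr(name, 1, 1)
  ifelse(first %in% c("T", "S") & nchar(name) > 1, first, "R")
}

#' Construct a CG bead type
#'
#' A bead type carries the MARTINI 3 interaction label, its size class
#' (T/S/R), formal charge, van der Waals radius and mass. Radius and mass
#' default to the size-class conventions (radii 0.191/0.230/0.264 nm;
#' masses 36/54/72 Da) but can be overridden explicitly.
#'
#' @param name MARTINI 3 type label, e.g. `"TC5"`, `"SN4ar"`, `"Q4n"`, `"W"`.
#' @param size_class `"T"`, `"S"` or `"R"`; inferred from `name` if omitted.
#' @param charge integer elementary charge (-1, 0 or +1 in packaged tables).
#' @param vdw_radius radius in nm; defaults by size class.
#' @param mass mass in Da; defaults by size class.
#' @return An object of class `bead_type`.
#' @examples
#' bead_type("TC5")              # tiny, r = 0.191 nm, 36 Da
#' bead_type("Q4n", charge = -1) # regular sulfate bead
#' @export
bead_type <- function(name, size_class = NULL, charge = 0L,
                      vdw_radius = NULL, mass = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(size_class)) size_class <- size_class_of(name)
  if (!size_class %in% c("T", "S", "R"))
    stop("size_class must be one of 'T', 'S', 'R'", call. = FALSE)
  if (is.null(vdw_radius)) vdw_radius <- .size_class_radius[[size_class]]
  if (is.null(mass)) mass <- .size_class_mass[[size_class]]
  stopifnot(vdw_radius > 0, mass >= 0)
  structure(
    list(name = name, size_class = size_class, charge = as.integer(charge),
         vdw_radius = vdw_radius, mass = mass),
    class = "bead_type")
}

#' @export
print.bead_type <- function(x, ...) {
  cat(sprintf("<bead_type %s> class %s, q %+d e, r %.3f nm, %g Da\n",
              x$name, x$size_class, x$charge, x$vdw_radius, x$mass))
  invisible(x)
}

#' Packaged bead-type table
#'
#' The bead types used by the packaged glycopeptide mapping: protein
#' backbone and side-chain beads, the O-glycan sugar beads (including the
#' TC5 anomeric bead of glycosylated N-acetylhexosamines, the SN4ar/TN4ar
#' protein-glycan linkage beads, the Q4n sulfate bead and the charged
#' sialic-acid carboxylate bead), the TC4 ring virtual site, the 4-to-1 W
#' water bead and TQ5 monovalent ions.
#'
#' @param path optional path to a whitespace-separated table
#'   (columns `name size_class charge vdw_radius mass`) overriding the
#'   packaged defaults; see
#'   `system.file("extdata", "bead_types.tsv", package = "mucincg")`.
#' @return A data frame with columns `name`, `size_class`, `charge`,
#'   `vdw_radius`, `mass`.
#' @export
bead_type_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bead_types.tsv", package = "mucincg")
  }
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("name", "size_class", "charge", "vdw_radius", "mass")
  if (!all(need %in% names(tab)))
    stop("bead-type table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$size_class %in% c("T", "S", "R")))
    stop("size_class must be T, S or R", call. = FALSE)
  if (!all(tab$charge %in% -1:1))
    stop("packaged bead charges are restricted to -1, 0, +1", call. = FALSE)
  tab
}

## Resolve one bead type from the table (falls back to conventions for
## labels not in the table).
lookup_bead_type <- function(name, table = NULL) {
  if (is.null(table)) table <- bead_type_table()
  i <- match(name, table$name)
  if (is.na(i)) return(bead_type(name))
  bead_type(table$name[i], table$size_class[i], table$charge[i],
            table$vdw_radius[i], table$mass[i])
}
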