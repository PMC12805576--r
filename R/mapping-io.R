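## Declarative text format for residue templates: one file per
## residue/sugar, line-oriented keyword format, auditable by eye.
##
##   residue GALNAC
##   hexnac true
##   ring R1 R2 R3
##   anomeric R1
##   anomeric_core C1 C2
##   anomeric_linked_type TC5
##   linkage_oxygen O1
##   acceptor_oxygen O3
##   bead R1 SN6 C1 C2 O1
##   bond R1 R2

#' Read or write mapping-spec template files
#'
#' `read_mapping_spec()` loads every `*.map` file in a directory into a
#' [mapping_spec()]; `write_mapping_spec()` writes one file per template.
#' `default_mapping_spec()` returns the packaged glycopeptide templates
#' (amino acids Gly/Ala/Pro/Thr/Ser/neutral-His, and the O-glycan sugars
#' GalNAc, GlcNAc, Gal, sulfated Gal and sialic acid). The sugar templates
#' use synthetic pseudo-atom names consistent with the packaged fixture
#' generator; they are user-replaceable.
#'
#' @param dir directory containing (or receiving) `*.map` files.
#' @param spec a [mapping_spec()] (for writing).
#' @return `read_mapping_spec()` and `default_mapping_spec()` return a
#'   [mapping_spec()]; `write_mapping_spec()` returns `dir` invisibly.
#' @export
read_mapping_spec <- function(dir) {
  files <- list.files(dir, pattern = "\\.map$", full.names = TRUE)
  if (!length(files)) stop("no .map template files in ", dir, call. = FALSE)
  mapping_spec(lapply(files, read_template_file))
}

read_template_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  kw <- vapply(toks, `[[`, "", 1)
  val1 <- function(key, default = NA) {
    i <- which(kw == key)
    if (!length(i)) default else toks[[i[1]]][2]
  }
  valv <- function(key) {
    i <- which(kw == key)
    if (!length(i)) character() else toks[[i[1]]][-1]
  }
  beads <- lapply(toks[kw == "bead"], function(t)
    list(name = t[2], type = t[3], atoms = t[-(1:3)]))
  bonds <- NULL
  bl <- toks[kw == "bond"]
  if (length(bl))
    bonds <- do.call(rbind, lapply(bl, function(t) t[2:3]))
  residue_template(
    resname = val1("residue"),
    beads = beads, bonds = bonds,
    backbone = val1("backbone"),
    ring = valv("ring"),
    anomeric = val1("anomeric"),
    anomeric_core_atoms = valv("anomeric_core"),
    anomeric_linked_type = val1("anomeric_linked_type"),
    linkage_oxygen = val1("linkage_oxygen"),
    acceptor_oxygen = val1("acceptor_oxygen"),
    linkage_bead = val1("linkage_bead"),
    linkage_bead_type = val1("linkage_bead_type"),
    hexnac = identical(val1("hexnac"), "true"))
}

#' @rdname read_mapping_spec
#' @export
write_mapping_spec <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tpl in spec$templates) {
    lines <- c(paste("residue", tpl$resname))
    if (tpl$hexnac) lines <- c(lines, "hexnac true")
    add1 <- function(lines, key, v)
      if (length(v) == 1 && !is.na(v)) c(lines, paste(key, v)) else lines
    addv <- function(lines, key, v)
      if (length(v)) c(lines, paste(key, paste(v, collapse = " "))) else lines
    lines <- add1(lines, "backbone", tpl$backbone)
    lines <- addv(lines, "ring", tpl$ring)
    lines <- add1(lines, "anomeric", tpl$anomeric)
    lines <- addv(lines, "anomeric_core", tpl$anomeric_core_atoms)
    lines <- add1(lines, "anomeric_linked_type", tpl$anomeric_linked_type)
    lines <- add1(lines, "linkage_oxygen", tpl$linkage_oxygen)
    lines <- add1(lines, "acceptor_oxygen", tpl$acceptor_oxygen)
    lines <- add1(lines, "linkage_bead", tpl$linkage_bead)
    lines <- add1(lines, "linkage_bead_type", tpl$linkage_bead_type)
    for (b in tpl$beads)
      lines <- c(lines, paste("bead", b$name, b$type,
                              paste(b$atoms, collapse = " ")))
    if (!is.null(tpl$bonds))
      for (r in seq_len(nrow(tpl$bonds)))
        lines <- c(lines, paste("bond", tpl$bonds[r, 1], tpl$bonds[r, 2]))
    writeLines(lines, file.path(dir, paste0(tolower(tpl$resname), ".map")))
  }
  invisible(dir)
}

#' @rdname read_mapping_spec
#' @export
default_mapping_spec <- function() {
  dir <- system.file("extdata", "mapping", package = "mucincg")
  read_mapping_spec(dir)
}
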