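#' @importFrom stats sd kmeans rnorm runif setNames dist dnorm
#' @importFrom utils read.delim write.table head data
NULL

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses coordinate files into a `structure3d` object: an atom table plus one
#' coordinate matrix per model. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by file order), so every atom is
#' unique on (chain, residue, insertion code, atom name). All ATOM and HETATM
#' records are retained; downstream geometry operations exclude hydrogens,
#' waters and non-protein heteroatoms unless asked otherwise.
#'
#' Author (PDB) residue numbering is kept verbatim and is the only numbering
#' used anywhere in the package. Chains with unmodelled residue stretches
#' (disordered loops) are represented simply by the absence of those residues.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `structure3d` object: list with `atoms` (data.frame with columns
#'   `chain`, `res_seq`, `icode`, `res_name`, `atom_name`, `element`,
#'   `occupancy`, `bfactor`, `het`), `models` (list of n x 3 coordinate
#'   matrices, angstrom) and `source_id`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
      stop("cannot infer format from extension '.", ext, "'; pass format=")
    )
  }
  p <- tryCatch(
    if (format == "pdb")
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("parse error reading ", format, " file '", path,
                             "': ", conditionMessage(e))
  )
  at <- p$atom
  atoms <- data.frame(
    chain = as.character(at$chain),
    res_seq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    res_name = as.character(at$resid),
    atom_name = as.character(at$elety),
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             guess_element(at$elety), at$elesy)),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    bfactor = ifelse(is.na(at$b), 0, as.numeric(at$b)),
    het = as.character(at$type) == "HETATM",
    stringsAsFactors = FALSE
  )
  alt <- ifelse(is.na(at$alt), "", as.character(at$alt))

  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  models <- lapply(seq_len(n_models), function(m) {
    matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  })

  # altloc resolution: within each (chain, res_seq, icode, atom_name) group
  # keep the highest-occupancy record; ties go to the first in file order
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$atom_name,
                 sep = "\r")
    ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
    keep_sorted <- !duplicated(key[ord])
    keep <- logical(nrow(atoms))
    keep[ord] <- keep_sorted
    atoms <- atoms[keep, , drop = FALSE]
    models <- lapply(models, function(m) m[keep, , drop = FALSE])
    rownames(atoms) <- NULL
  }

  new_structure3d(atoms, models, source_id = basename(path))
}

new_structure3d <- function(atoms, models, source_id = "") {
  stopifnot(is.data.frame(atoms), is.list(models), length(models) >= 1)
  if (!all(vapply(models, nrow, 1L) == nrow(atoms)))
    stop("every model must have one coordinate row per atom")
  structure(list(atoms = atoms, models = models, source_id = source_id),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", x$source_id, "\n")
  cat("  atoms:", nrow(x$atoms), " models:", length(x$models),
      " chains:", paste(unique(x$atoms$chain), collapse = ","), "\n")
  invisible(x)
}

# element from atom name when the element column is absent (PDB v2 files)
guess_element <- function(atom_name) {
  nm <- gsub("[0-9'\"]", "", trimws(atom_name))
  el <- substr(nm, 1, 1)
  el[nm %in% c("SE", "FE", "ZN", "MG", "MN", "NA", "CL", "BR")] <-
    nm[nm %in% c("SE", "FE", "ZN", "MG", "MN", "NA", "CL", "BR")]
  el
}

#' Coordinates of one model
#'
#' @param s A `structure3d`.
#' @param model Model index (1-based).
#' @return n x 3 numeric matrix (angstrom).
#' @export
coords <- function(s, model = 1) {
  stopifnot(inherits(s, "structure3d"))
  s$models[[model]]
}

#' Atom table with coordinates of one model attached
#'
#' @inheritParams coords
#' @return `s$atoms` with `x`, `y`, `z` columns appended.
#' @export
atom_table <- function(s, model = 1) {
  xyz <- coords(s, model)
  cbind(s$atoms, data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

#' Select a subset of atoms
#'
#' Subsetting preserves atom order and applies to every model. An empty
#' selection is legal and returns a zero-atom structure. Selection is
#' idempotent and individual filters commute.
#'
#' @param s A `structure3d`.
#' @param chain Chain identifier(s), or `NULL` for all.
#' @param residues Integer vector of author residue numbers, or `NULL` for all.
#' @param atom_names Atom name(s) (e.g. `"CA"`), or `NULL` for all.
#' @param elements Element symbol(s), or `NULL` for all.
#' @param het `NULL` to keep both ATOM and HETATM records, `FALSE` for ATOM
#'   only, `TRUE` for HETATM only.
#' @return A `structure3d` containing the matching atoms.
#' @export
select_atoms <- function(s, chain = NULL, residues = NULL, atom_names = NULL,
                         elements = NULL, het = NULL) {
  stopifnot(inherits(s, "structure3d"))
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
  if (!is.null(residues)) keep <- keep & s$atoms$res_seq %in% residues
  if (!is.null(atom_names)) keep <- keep & s$atoms$atom_name %in% atom_names
  if (!is.null(elements)) keep <- keep & s$atoms$element %in% elements
  if (!is.null(het)) keep <- keep & s$atoms$het == het
  atoms <- s$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  models <- lapply(s$models, function(m) m[keep, , drop = FALSE])
  new_structure3d(atoms, models, s$source_id)
}

# protein heavy atoms: no hydrogens, no waters, no het records
protein_heavy <- function(s) {
  keep <- !s$atoms$het & s$atoms$element != "H" & s$atoms$element != "D" &
    !(s$atoms$res_name %in% c("HOH", "DOD", "WAT"))
  atoms <- s$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  new_structure3d(atoms, lapply(s$models, function(m) m[keep, , drop = FALSE]),
                  s$source_id)
}

#' Write a structure to a PDB file
#'
#' Multi-model structures are written as MODEL/ENDMDL blocks. Coordinates are
#' written at PDB precision (3 decimals), B-factors at 2.
#'
#' @param s A `structure3d`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  fmt_one <- function(xyz) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$het, "HETATM", "ATOM"),
            seq_len(nrow(a)) %% 100000,
            ifelse(nchar(a$atom_name) >= 4, a$atom_name,
                   paste0(" ", a$atom_name)),
            "", a$res_name, a$chain, a$res_seq, a$icode,
            xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy, a$bfactor, a$element)
  }
  lines <- character(0)
  multi <- length(s$models) > 1
  for (m in seq_along(s$models)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    lines <- c(lines, fmt_one(s$models[[m]]))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Residues modelled per chain
#'
#' @param s A `structure3d`.
#' @return Named list: for each chain, the sorted set of modelled residue
#'   numbers. Gaps in the numbering correspond to disordered, unmodelled
#'   stretches.
#' @export
resolved_residues <- function(s) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  lapply(split(a$res_seq, a$chain), function(r) sort(unique(r)))
}

#' Default transmembrane segment map
#'
#' Named residue ranges (author numbering, inclusive) dividing the receptor
#' into the inter-domain linker, the five TM helices and the two extracellular
#' loops: linker 114-120, helix I 121-140, helix II 160-178, ECL1 179-185,
#' helix III 186-207, helix IV 224-242, ECL2 243-250, helix V 251-278.
#'
#' @return A `segment_map`: data.frame with columns `name`, `start`, `end`.
#' @export
default_segment_map <- function() {
  sm <- data.frame(
    name = c("linker", "helix I", "helix II", "ECL1", "helix III",
             "helix IV", "ECL2", "helix V"),
    start = c(114L, 121L, 160L, 179L, 186L, 224L, 243L, 251L),
    end = c(120L, 140L, 178L, 185L, 207L, 242L, 250L, 278L),
    stringsAsFactors = FALSE
  )
  class(sm) <- c("segment_map", "data.frame")
  sm
}

#' Look up a segment's residue range
#'
#' @param seg A `segment_map`.
#' @param name Segment name.
#' @return Integer vector `c(start, end)`.
#' @export
segment_lookup <- function(seg, name) {
  i <- match(name, seg$name)
  if (is.na(i)) stop("unknown segment '", name, "'; known: ",
                     paste(seg$name, collapse = ", "))
  c(start = seg$start[i], end = seg$end[i])
}

#' Residue numbers covered by one or more segments
#'
#' @param seg A `segment_map`.
#' @param names Segment names; default all.
#' @return Integer vector of residue numbers.
#' @export
segment_residues <- function(seg, names = seg$name) {
  idx <- match(names, seg$name)
  if (anyNA(idx)) stop("unknown segment(s): ",
                       paste(names[is.na(idx)], collapse = ", "))
  unlist(lapply(idx, function(i) seq(seg$start[i], seg$end[i])),
         use.names = FALSE)
}

# segment name for each residue number (NA if unassigned)
segment_of <- function(res_seq, seg) {
  out <- rep(NA_character_, length(res_seq))
  for (i in seq_len(nrow(seg))) {
    hit <- res_seq >= seg$start[i] & res_seq <= seg$end[i]
    out[hit] <- seg$name[i]
  }
  out
}
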