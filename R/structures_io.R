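#' Default van der Waals radii table
#'
#' Per-element radii (in Angstroms) used to inflate atoms for grid labelling
#' and ray-sphere intersection. The defaults are conventional van der Waals
#' radii (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, halogens per element);
#' unknown elements fall back to `default` with a warning. Users can supply
#' their own table from a YAML file via [read_radii_table()].
#'
#' @param radii named numeric vector, element symbol -> radius in Angstroms.
#' @param default radius assigned to elements missing from `radii`.
#' @return An object of class `radii_table`.
#' @export
#' @examples
#' tab <- default_radii_table()
#' assign_radii(data.frame(element = "C", x = 0, y = 0, z = 0), tab)$radius
default_radii_table <- function(radii = c(
                                  C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85,
                                  I = 1.98, H = 1.20
                                ),
                                default = 1.70) {
  radii <- setNames(as.numeric(radii), toupper(names(radii)))
  if (length(radii) == 0) darc_input_error("radii table must be non-empty")
  if (any(radii <= 0.5 | radii >= 3.0) || default <= 0.5 || default >= 3.0) {
    darc_input_error("all radii must lie in (0.5, 3.0) Angstroms")
  }
  structure(list(radii = radii, default = default), class = "radii_table")
}

#' Read a radii table from a YAML file
#'
#' The file holds a `radii` mapping (element symbol -> Angstroms) and a
#' scalar `default`. See `inst/extdata/radii.yaml` for the shipped default.
#'
#' @param path path to a YAML file.
#' @return A `radii_table`.
#' @export
read_radii_table <- function(path) {
  if (!file.exists(path)) darc_input_error(paste0("no such file: ", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$radii)) darc_format_error("radii file lacks a 'radii' mapping")
  default_radii_table(unlist(y$radii), y$default %||% 1.70)
}

#' Assign per-atom radii from a radii table
#'
#' @param atoms data frame with at least an `element` column.
#' @param table a [default_radii_table()]-style `radii_table`.
#' @return `atoms` with a `radius` column filled in; unknown elements receive
#'   the table default and raise one warning naming them.
#' @export
assign_radii <- function(atoms, table = default_radii_table()) {
  stopifnot(inherits(table, "radii_table"))
  if (nrow(atoms) == 0) {
    atoms$radius <- numeric(0)
    return(atoms)
  }
  key <- toupper(atoms$element)
  r <- unname(table$radii[key])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf(
      "unknown element(s) %s assigned default radius %.2f",
      paste(unique(atoms$element[unknown]), collapse = ", "), table$default
    ), call. = FALSE)
    r[unknown] <- table$default
  }
  atoms$radius <- r
  atoms
}

# Element symbol from a PDB record: prefer columns 77-78, fall back to the
# leading letters of the atom name (digits and primes stripped).
element_from_record <- function(elesy, name) {
  e <- toupper(trimws(elesy))
  bad <- is.na(e) | e == ""
  if (any(bad)) {
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", trimws(name[bad])))
    two <- toupper(substr(nm, 1, 2))
    one <- toupper(substr(nm, 1, 1))
    e[bad] <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
      two, one
    )
  }
  e
}

new_protein <- function(atoms, path = NA_character_) {
  if (nrow(atoms) == 0) darc_format_error("protein has no atoms")
  structure(
    list(
      atoms = atoms,
      center_of_mass = colMeans(atoms[, c("x", "y", "z")]),
      path = path
    ),
    class = "darc_protein"
  )
}

new_conformer <- function(conformer_id, atoms) {
  if (nrow(atoms) == 0) darc_format_error("conformer has no heavy atoms")
  conformer(atoms, conformer_id)
}

#' Construct a ligand conformer from an atom table
#'
#' @param atoms data frame with element, x, y, z, radius columns. A zero-row
#'   table is allowed (a degenerate ligand that every ray misses), mainly
#'   for scoring edge cases.
#' @param conformer_id conformer label (ordinal by convention).
#' @return A `darc_conformer`.
#' @export
conformer <- function(atoms, conformer_id = 1L) {
  if (nrow(atoms) > 0 &&
    (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))) ||
      any(atoms$radius <= 0))) {
    darc_input_error("atom positions must be finite and radii positive")
  }
  centroid <- if (nrow(atoms) == 0) {
    c(x = 0, y = 0, z = 0)
  } else {
    colMeans(atoms[, c("x", "y", "z")])
  }
  structure(
    list(conformer_id = conformer_id, atoms = atoms, centroid = centroid),
    class = "darc_conformer"
  )
}

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally non-water HETATM) records, keeps altloc 'A' or
#' blank, and assigns per-atom radii. The center of mass is the unweighted
#' mean of the retained atom positions.
#'
#' @param path PDB file.
#' @param include_het also keep HETATM records (waters always excluded).
#' @param radii a `radii_table` for radius assignment.
#' @return A `darc_protein`: list with `atoms` (data frame: element, x, y, z,
#'   radius, chain, resno, resid), `center_of_mass`, `path`.
#' @export
read_protein_pdb <- function(path, include_het = FALSE,
                             radii = default_radii_table()) {
  if (!file.exists(path)) darc_input_error(paste0("no such file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)),
    error = function(e) {
      darc_format_error(paste0("cannot parse PDB file ", path, ": ",
                               conditionMessage(e)))
    }
  )
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (include_het) {
    keep <- keep | (at$type == "HETATM" & !(at$resid %in% WATER_RESIDUES))
  }
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) darc_format_error(paste0("no atoms parsed from ", path))
  atoms <- data.frame(
    element = element_from_record(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    chain = at$chain, resno = at$resno, resid = at$resid,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    darc_format_error("non-finite coordinates in PDB file")
  }
  atoms <- assign_radii(atoms, radii)
  new_protein(atoms, path)
}

#' Atoms belonging to one residue
#'
#' @param protein a `darc_protein`.
#' @param chain chain identifier.
#' @param resno residue number.
#' @return Data frame of the residue's atoms (error if absent).
#' @export
residue_atoms <- function(protein, chain, resno) {
  a <- protein$atoms
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel)) {
    darc_input_error(sprintf("residue %s/%s not found in protein", chain, resno))
  }
  a[sel, , drop = FALSE]
}

# Split a PDB file into MODEL blocks (whole file when no MODEL records).
split_pdb_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    return(list(lines))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends[seq_along(starts)],
    SIMPLIFY = FALSE
  )
}

read_conformers_pdb <- function(path, radii) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split_pdb_models(lines)
  confs <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(blocks[[i]], tmp)
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(tmp, rm.alt = TRUE, verbose = FALSE)),
      error = function(e) {
        darc_format_error(sprintf(
          "cannot parse conformer block %d of %s: %s", i, path,
          conditionMessage(e)
        ))
      }
    )
    at <- pdb$atom
    atoms <- data.frame(
      element = element_from_record(at$elesy, at$elety),
      x = at$x, y = at$y, z = at$z,
      stringsAsFactors = FALSE
    )
    atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
    if (nrow(atoms) == 0) {
      darc_format_error(sprintf(
        "conformer block %d of %s has no heavy atoms", i, path
      ))
    }
    confs[[i]] <- new_conformer(i, assign_radii(atoms, radii))
  }
  confs
}

read_conformers_sdf <- function(path, radii) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    darc_input_error("SDF support requires the ChemmineR package")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) {
      darc_format_error(paste0("cannot parse SDF file ", path, ": ",
                               conditionMessage(e)))
    }
  )
  n <- length(sdf)
  if (n == 0) darc_format_error(paste0("no molecule blocks in ", path))
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    ab <- tryCatch(ChemmineR::atomblock(sdf[[i]]), error = function(e) {
      darc_format_error(sprintf("cannot parse molecule block %d of %s", i, path))
    })
    el <- toupper(sub("_.*$", "", rownames(ab)))
    atoms <- data.frame(
      element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
      stringsAsFactors = FALSE
    )
    atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
    rownames(atoms) <- NULL
    if (nrow(atoms) == 0) {
      darc_format_error(sprintf("molecule block %d of %s has no heavy atoms",
                                i, path))
    }
    confs[[i]] <- new_conformer(i, assign_radii(atoms, radii))
  }
  confs
}

#' Read multi-conformer ligand files
#'
#' One conformer per MODEL block (PDB) or molecule block (SDF V2000).
#' Hydrogens are filtered out; conformer ids are ordinals starting at 1.
#' Conformers of one compound must share the same heavy-atom count.
#'
#' @param path ligand file.
#' @param format "pdb", "sdf", or "auto" (by extension).
#' @param radii a `radii_table`.
#' @return List of `darc_conformer` objects.
#' @export
read_ligand_conformers <- function(path, format = c("auto", "pdb", "sdf"),
                                   radii = default_radii_table()) {
  format <- match.arg(format)
  if (!file.exists(path)) darc_input_error(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "pdb"
  }
  confs <- switch(format,
    pdb = read_conformers_pdb(path, radii),
    sdf = read_conformers_sdf(path, radii)
  )
  counts <- vapply(confs, function(cf) nrow(cf$atoms), integer(1))
  if (length(unique(counts)) > 1) {
    darc_format_error(sprintf(
      "conformers of %s have mixed heavy-atom counts (%s)",
      path, paste(unique(counts), collapse = ", ")
    ))
  }
  confs
}

format_pdb_atom <- function(serial, name, resid, chain, resno, x, y, z,
                            element, record = "HETATM") {
  serial <- as.integer(serial)
  resno <- as.integer(resno)
  # strict PDB columns: name 13-16, altloc 17 (blank), resName 18-20,
  # chain 22, resSeq 23-26, x/y/z from column 31, element 77-78
  sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, substr(name, 1, 4), resid, chain, resno, x, y, z,
    1.0, 0.0, element
  )
}

#' Write ligand conformers as a (multi-model) PDB file
#'
#' @param conformers a `darc_conformer` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ligand_pdb <- function(conformers, path) {
  if (inherits(conformers, "darc_conformer")) conformers <- list(conformers)
  out <- character(0)
  multi <- length(conformers) > 1
  for (m in seq_along(conformers)) {
    atoms <- conformers[[m]]$atoms
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(atoms))) {
      out <- c(out, format_pdb_atom(
        i, paste0(atoms$element[i], i), "LIG", "X", 1,
        atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i]
      ))
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Write a protein structure as a PDB file
#'
#' @param protein a `darc_protein`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protein_pdb <- function(protein, path) {
  atoms <- protein$atoms
  out <- vapply(seq_len(nrow(atoms)), function(i) {
    format_pdb_atom(
      i, paste0(atoms$element[i], i),
      substr(atoms$resid[i] %||% "GLY", 1, 3),
      atoms$chain[i] %||% "A", atoms$resno[i] %||% 1L,
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i],
      record = "ATOM"
    )
  }, character(1))
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' @export
print.darc_protein <- function(x, ...) {
  cat(sprintf(
    "<darc_protein> %d atoms, center of mass (%.2f, %.2f, %.2f)\n",
    nrow(x$atoms), x$center_of_mass[1], x$center_of_mass[2],
    x$center_of_mass[3]
  ))
  invisible(x)
}

#' @export
print.darc_conformer <- function(x, ...) {
  cat(sprintf(
    "<darc_conformer %s> %d heavy atoms, centroid (%.2f, %.2f, %.2f)\n",
    x$conformer_id, nrow(x$atoms), x$centroid[1], x$centroid[2], x$centroid[3]
  ))
  invisible(x)
}
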