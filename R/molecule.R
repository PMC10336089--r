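## Molecule containers, structure readers and atom subsetting.

#' Molecule container
#'
#' @param coords numeric `N x 3` matrix of coordinates in Angstrom.
#' @param elements character vector of element symbols, length N.
#' @param charges optional numeric per-atom partial charges (elementary
#'   charge units), length N.
#' @param name identifier.
#' @return object of class `molecule`.
#' @export
molecule <- function(coords, elements, charges = NULL, name = "molecule") {
  coords <- check_points(coords)
  elements <- as.character(elements)
  if (length(elements) != nrow(coords))
    stop("need one element symbol per atom")
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != nrow(coords))
      stop("charges must have one value per atom")
  }
  structure(list(coords = coords, elements = elements, charges = charges,
                 name = name),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("Molecule '%s': %d atoms (%s)%s\n", x$name, nrow(x$coords),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = ", "),
              if (is.null(x$charges)) "" else ", with charges"))
  invisible(x)
}

## normalize an element symbol: "CA " -> "Ca", "O1" -> "O"
normalize_element <- function(x) {
  x <- gsub("[^A-Za-z]", "", trimws(x))
  ifelse(nchar(x) == 0L, x,
         paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, 2L))))
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed XYZ file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("malformed XYZ file: line 1 is not an atom count")
  if (length(lines) < n + 2L)
    stop("malformed XYZ file: expected ", n, " atom records")
  recs <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  bad <- which(vapply(recs, length, integer(1)) < 4L)
  if (length(bad))
    stop("malformed XYZ record at line ", bad[1L] + 2L)
  elements <- vapply(recs, `[[`, character(1), 1L)
  coords <- t(vapply(recs, function(r) as.numeric(r[2:4]), numeric(3)))
  if (!all(is.finite(coords))) stop("non-numeric coordinates in XYZ file")
  molecule(coords, normalize_element(elements),
           name = sub("\\.[^.]*$", "", basename(path)))
}

read_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom
  elements <- atoms$elesy
  if (is.null(elements) || all(is.na(elements) | trimws(elements) == "")) {
    ## fall back on the first letter of the atom name column
    elements <- substr(trimws(atoms$elety), 1L, 1L)
  }
  molecule(as.matrix(atoms[, c("x", "y", "z")]), normalize_element(elements),
           name = sub("\\.[^.]*$", "", basename(path)))
}

## formal charges from the "M  CHG" property lines of an SDF/MOL block
sdf_charges <- function(lines, n_atoms) {
  charges <- rep(0, n_atoms)
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (line in chg) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG", "", line)), "\\s+")[[1L]])
    n <- f[1L]
    for (i in seq_len(n)) {
      charges[f[2L * i]] <- f[2L * i + 1L]
    }
  }
  charges
}

read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF files requires the 'ChemmineR' package")
  sdf <- ChemmineR::read.SDFset(path)[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  coords <- ab[, 1:3, drop = FALSE]
  elements <- normalize_element(sub("_.*$", "", rownames(ab)))
  lines <- readLines(path, warn = FALSE)
  molecule(coords, elements, charges = sdf_charges(lines, nrow(coords)),
           name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read a molecular structure file
#'
#' Supports XYZ (count / comment / `element x y z` records), PDB
#' (ATOM/HETATM via bio3d, element column preferred over atom names) and
#' SDF/MOL V2000 (via ChemmineR; formal charges from `M CHG` lines). A
#' sidecar CSV with a `charge` column can supply partial charges for any
#' format.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"xyz"`, `"pdb"` or `"sdf"`.
#' @param charges optional path to a CSV whose `charge` column (or single
#'   column) holds one partial charge per atom.
#' @return a [molecule()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb", "sdf"),
                           charges = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub("^.*\\.", "", path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", ent = "pdb",
                     sdf = "sdf", mol = "sdf",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  mol <- switch(format, xyz = read_xyz(path), pdb = read_pdb(path),
                sdf = read_sdf(path))
  if (!is.null(charges)) {
    tab <- read.csv(charges)
    col <- if ("charge" %in% names(tab)) tab$charge else tab[[1L]]
    if (length(col) != nrow(mol$coords))
      stop("charge table has ", length(col), " rows but the molecule has ",
           nrow(mol$coords), " atoms")
    mol$charges <- as.numeric(col)
  }
  mol
}

#' Atom subset schemes
#'
#' Scheme A keeps all atoms, B removes hydrogens, C removes hydrogens and
#' carbons.
#'
#' @param mol a [molecule()].
#' @param scheme `"A"`, `"B"` or `"C"`.
#' @return the subset molecule; an empty result is an error.
#' @export
subset_atoms <- function(mol, scheme = c("A", "B", "C")) {
  scheme <- match.arg(scheme)
  drop <- switch(scheme, A = character(), B = "H", C = c("H", "C"))
  keep <- !(mol$elements %in% drop)
  if (!any(keep))
    stop("atom subset '", scheme, "' leaves no atoms in '", mol$name, "'")
  molecule(mol$coords[keep, , drop = FALSE], mol$elements[keep],
           charges = if (!is.null(mol$charges)) mol$charges[keep],
           name = mol$name)
}
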