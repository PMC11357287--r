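# Element tables used across the package.
#
# - vdW radii: Bondi's empirical set, with the common extensions for the
#   handful of main-group elements Bondi left out. Overridable per call via
#   a two-column CSV (element, radius in angstrom).
# - valence electrons: main-group counts, used by the molecular-complexity
#   descriptor.
# - Pauling electronegativity: default vertex property of the
#   autocorrelation descriptor.
bondi_radii <- c(
  H = 1.20, He = 1.40, Li = 1.82, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
  F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80,
  S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75, Ca = 2.31, Ga = 1.87, Ge = 2.11,
  As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, I = 1.98, Xe = 2.16,
  Zn = 1.39, Cu = 1.40, Ni = 1.63, Te = 2.06, Sn = 2.17
)

valence_electron_table <- c(
  H = 1, He = 2, Li = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Ne = 8,
  Na = 1, Mg = 2, Al = 3, Si = 4, P = 5, S = 6, Cl = 7, Ar = 8,
  K = 1, Ca = 2, Ga = 3, Ge = 4, As = 5, Se = 6, Br = 7, Kr = 8,
  I = 7, Xe = 8, Zn = 2, Cu = 1, Ni = 2, Te = 6, Sn = 4
)

pauling_electronegativity <- c(
  H = 2.20, Li = 0.98, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
  Na = 0.93, Mg = 1.31, Al = 1.61, Si = 1.90, P = 2.19, S = 2.58,
  Cl = 3.16, K = 0.82, Ca = 1.00, Ga = 1.81, Ge = 2.01, As = 2.18,
  Se = 2.55, Br = 2.96, I = 2.66, Zn = 1.65, Cu = 1.90, Ni = 1.91,
  Te = 2.10, Sn = 1.96
)

#' Molecule record
#'
#' The geometric unit of the package: named atoms with 3D centres and van
#' der Waals radii, plus an optional bond list. Radii default to Bondi's
#' empirical values looked up by element; an unknown element is an error.
#'
#' @param id molecule identifier.
#' @param atoms tibble with columns `element`, `x`, `y`, `z` (angstrom) and
#'   optionally `vdw_radius`, `valence_electrons`, `is_stereocenter`.
#' @param bonds tibble with columns `from`, `to` (1-based atom indices) and
#'   `order` (1, 2, 3; aromatic bonds are conventionally 1.5). May be empty.
#' @param name human-readable name.
#' @param radius_table optional named numeric vector overriding the Bondi
#'   radii (element -> angstrom).
#' @return An object of class `mol_record`.
#' @export
mol_record <- function(id, atoms, bonds = NULL, name = id,
                       radius_table = NULL) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)),
            nrow(atoms) >= 1)
  radii <- radius_table %||% bondi_radii
  if (!"vdw_radius" %in% names(atoms)) {
    unknown <- setdiff(unique(atoms$element), names(radii))
    if (length(unknown) > 0) {
      stop("record '", id, "': no van der Waals radius for element(s) ",
           paste(unknown, collapse = ", "))
    }
    atoms$vdw_radius <- unname(radii[atoms$element])
  }
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0)) {
    stop("record '", id, "': nonpositive van der Waals radius")
  }
  if (!"valence_electrons" %in% names(atoms)) {
    atoms$valence_electrons <-
      unname(valence_electron_table[atoms$element])
  }
  if (!"is_stereocenter" %in% names(atoms)) {
    atoms$is_stereocenter <- FALSE
  }
  if (is.null(bonds)) {
    bonds <- tibble::tibble(from = integer(0), to = integer(0),
                            order = numeric(0))
  }
  bonds <- tibble::as_tibble(bonds)
  if (nrow(bonds) > 0) {
    if (any(bonds$from == bonds$to)) stop("record '", id, "': self-bond")
    if (min(bonds$from, bonds$to) < 1 ||
        max(bonds$from, bonds$to) > nrow(atoms)) {
      stop("record '", id, "': bond index out of range")
    }
  }
  structure(list(id = id, name = name, atoms = atoms, bonds = bonds),
            class = "mol_record")
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record> %s: %d atoms, %d bonds\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Read molecular structures from SDF, SMILES or PDB
#'
#' SDF (V2000) entries are read with ChemmineR; SMILES input (one molecule
#' per line, optionally `SMILES<TAB>id`) is converted to a single 3D
#' conformer through the Open Babel backend; PDB coordinates come from
#' bio3d. Van der Waals radii are assigned from the Bondi table (or an
#' override CSV with columns element, radius). SMILES records whose 3D
#' generation fails are reported with a warning and skipped.
#'
#' @param path input file.
#' @param format one of `"sdf"`, `"smiles"`, `"pdb"`.
#' @param radius_file optional two-column CSV (element, radius in angstrom)
#'   overriding the built-in radii.
#' @return A list of [mol_record()]s (possibly empty, with a warning).
#' @export
read_structures <- function(path, format = c("sdf", "smiles", "pdb"),
                            radius_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  radius_table <- NULL
  if (!is.null(radius_file)) {
    rt <- utils::read.csv(radius_file, stringsAsFactors = FALSE)
    radius_table <- stats::setNames(as.numeric(rt[[2]]), rt[[1]])
  }
  switch(format,
    sdf = read_sdf_records(path, radius_table),
    smiles = read_smiles_records(path, radius_table),
    pdb = read_pdb_records(path, radius_table)
  )
}

read_sdf_records <- function(path, radius_table = NULL) {
  if (length(readLines(path, warn = FALSE)) == 0 ||
      all(!nzchar(readLines(path, warn = FALSE)))) {
    warning("empty structure file: ", path)
    return(list())
  }
  sdfset <- ChemmineR::read.SDFset(path)
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    out[[i]] <- sdf_to_record(sdf, fallback_id = paste0("mol_", i),
                              radius_table = radius_table)
  }
  out
}

sdf_to_record <- function(sdf, fallback_id, radius_table = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  hdr <- ChemmineR::header(sdf)
  id <- hdr[["Molecule_Name"]]
  if (is.null(id) || !nzchar(trimws(id))) id <- fallback_id
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    NULL
  } else {
    tibble::tibble(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                   order = as.numeric(bb[, 3]))
  }
  mol_record(
    id = trimws(id),
    atoms = tibble::tibble(
      element = elements,
      x = as.numeric(ab[, 1]), y = as.numeric(ab[, 2]),
      z = as.numeric(ab[, 3])
    ),
    bonds = bonds,
    radius_table = radius_table
  )
}

read_smiles_records <- function(path, radius_table = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty structure file: ", path)
    return(list())
  }
  parts <- strsplit(lines, "\t")
  smiles <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][[2]] else paste0("mol_", i)
  }, character(1))
  out <- list()
  for (i in seq_along(smiles)) {
    rec <- tryCatch({
      # single lowest-energy conformer through the Open Babel gen3d pass
      txt <- ChemmineOB::convertFormat(
        "SMI", "SDF", source = paste0(smiles[i], " ", ids[i], "\n"),
        options = data.frame(names = "gen3d", args = "")
      )
      sdfset <- suppressWarnings(
        ChemmineR::read.SDFset(unlist(strsplit(txt, "\n", fixed = TRUE)))
      )
      sdf_to_record(sdfset[[1]], fallback_id = ids[i],
                    radius_table = radius_table)
    }, error = function(e) {
      warning("3D generation failed for record '", ids[i], "' (",
              conditionMessage(e), "); skipped")
      NULL
    })
    if (!is.null(rec)) {
      rec$id <- ids[i]
      out[[length(out) + 1]] <- rec
    }
  }
  out
}

read_pdb_records <- function(path, radius_table = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (nrow(at) == 0) {
    warning("empty structure file: ", path)
    return(list())
  }
  elements <- trimws(at$elesy)
  # normalize case: "CL" -> "Cl"
  elements <- paste0(substr(elements, 1, 1),
                     tolower(substr(elements, 2, nchar(elements))))
  list(mol_record(
    id = basename(path),
    atoms = tibble::tibble(
      element = elements, x = at$x, y = at$y, z = at$z
    ),
    radius_table = radius_table
  ))
}

#' Write molecule records to an SDF (V2000) file
#'
#' @param mols a [mol_record()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("writing SDF requires the ChemmineR package")
  }
  sdf_class <- methods::getClass("SDF", where = asNamespace("ChemmineR"))
  if (inherits(mols, "mol_record")) mols <- list(mols)
  sdfs <- lapply(mols, function(mol) {
    n_at <- nrow(mol$atoms)
    n_bd <- nrow(mol$bonds)
    ab <- cbind(as.matrix(mol$atoms[, c("x", "y", "z")]),
                matrix(0, n_at, 13))
    rownames(ab) <- paste0(mol$atoms$element, "_", seq_len(n_at))
    colnames(ab) <- paste0("C", 1:16)
    bb <- if (n_bd > 0) {
      b <- cbind(mol$bonds$from, mol$bonds$to, round(mol$bonds$order),
                 matrix(0, n_bd, 4))
      colnames(b) <- paste0("C", 1:7)
      b
    } else {
      matrix(numeric(0), 0, 7, dimnames = list(NULL, paste0("C", 1:7)))
    }
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      n_at, n_bd)
    methods::new(sdf_class,
                 header = c(Molecule_Name = mol$id, Source = "molspec",
                            Comment = "", Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = character(0))
  })
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sdfs) ChemmineR::write.SDF(s, con)
  invisible(path)
}
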