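# MoleculeRecord: one molecule/conformer with identifiers, 3D coordinates,
# space-group label and polymorph-family id. Implemented as a classed list;
# `record_table()` gives a flat metadata view for curation operations.

#' Construct a molecule record
#'
#' @param record_id,family_id character identifiers; records of the same
#'   molecule (polymorph family) share `family_id`.
#' @param smiles SMILES string of the molecule.
#' @param elements character vector of element symbols (explicit hydrogens).
#' @param coordinates numeric matrix (n x 3), Cartesian angstroms.
#' @param space_group integer space-group number in 1--230.
#' @param deposition_rank integer >= 1; order of the record within its family
#'   (rank 1 = first deposited structure).
#' @param chiral logical; enantiopure chiral molecules may only carry Sohncke
#'   space-group labels.
#' @param geometry_source `"optimized"` (relaxed conformer) or `"crystal"`
#'   (geometry as found in the crystal structure).
#' @param bonds optional data.frame (i, j, order, aromatic) describing the
#'   bond table; carried by generated/read records and used by the graph and
#'   descriptor modules.
#' @param latent optional named numeric vector of generator diagnostics.
#' @return Object of class `xtal_record`.
#' @export
molecule_record <- function(record_id, family_id, smiles, elements,
                            coordinates, space_group, deposition_rank = 1L,
                            chiral = FALSE,
                            geometry_source = c("optimized", "crystal"),
                            bonds = NULL, latent = NULL) {
  geometry_source <- match.arg(geometry_source)
  coordinates <- as.matrix(coordinates)
  space_group <- as.integer(space_group)
  if (length(space_group) != 1L || is.na(space_group) ||
      space_group < 1L || space_group > 230L) {
    stop("space_group must be an integer in 1..230")
  }
  if (length(elements) < 2L) stop("a record needs at least 2 atoms")
  if (nrow(coordinates) != length(elements) || ncol(coordinates) != 3L) {
    stop("coordinates must be an n x 3 matrix matching `elements`")
  }
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (deposition_rank < 1L) stop("deposition_rank must be >= 1")
  if (isTRUE(chiral) && !is_sohncke(space_group)) {
    stop("chiral record ", record_id, " carries non-Sohncke space group ",
         space_group)
  }
  structure(list(record_id = as.character(record_id),
                 family_id = as.character(family_id),
                 smiles = as.character(smiles),
                 elements = as.character(elements),
                 coordinates = unname(coordinates),
                 space_group = space_group,
                 deposition_rank = as.integer(deposition_rank),
                 chiral = isTRUE(chiral),
                 geometry_source = geometry_source,
                 bonds = bonds, latent = latent),
            class = "xtal_record")
}

#' @export
print.xtal_record <- function(x, ...) {
  cat(sprintf("<xtal_record %s (family %s): %s, %d atoms, SG %d, rank %d%s>\n",
              x$record_id, x$family_id, x$smiles, length(x$elements),
              x$space_group, x$deposition_rank,
              if (x$chiral) ", chiral" else ""))
  invisible(x)
}

#' Metadata table of a record list
#'
#' @param records list of `xtal_record` objects.
#' @return data.frame with one row per record (ids, label, rank, chirality,
#'   geometry source, atom count, SMILES).
#' @export
record_table <- function(records) {
  stopifnot(length(records) > 0)
  data.frame(
    record_id = vapply(records, `[[`, "", "record_id"),
    family_id = vapply(records, `[[`, "", "family_id"),
    space_group = vapply(records, `[[`, 0L, "space_group"),
    deposition_rank = vapply(records, `[[`, 0L, "deposition_rank"),
    chiral = vapply(records, `[[`, FALSE, "chiral"),
    geometry_source = vapply(records, `[[`, "", "geometry_source"),
    n_atoms = vapply(records, function(r) length(r$elements), 0L),
    smiles = vapply(records, `[[`, "", "smiles"),
    stringsAsFactors = FALSE)
}
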