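# SDF (V2000) I/O for molecule records, via ChemmineR. Space-group number,
# family id, deposition rank, chirality flag, geometry source and SMILES
# travel as SDF data fields, so datasets round-trip losslessly (coordinates
# at the format's 4-decimal precision).

.record_to_sdf <- function(r) {
  n <- length(r$elements)
  ab <- cbind(r$coordinates, 0)
  dimnames(ab) <- list(paste(r$elements, seq_len(n), sep = "_"),
                       c("C1", "C2", "C3", "C5"))
  b <- r$bonds
  if (is.null(b) || nrow(b) == 0L) {
    bb <- matrix(numeric(0), 0, 7)
  } else {
    type <- ifelse(b$aromatic, 4, b$order)
    bb <- cbind(b$i, b$j, type, 0, 0, 0, 0)
  }
  dimnames(bb) <- list(as.character(seq_len(nrow(bb))),
                       paste0("C", 1:7))
  h <- c(Molecule_Name = r$record_id, Source = "  -xtalgroup-", Comment = "",
         Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                               n, nrow(bb)))
  db <- c(space_group = as.character(r$space_group),
          family_id = r$family_id,
          deposition_rank = as.character(r$deposition_rank),
          chiral = as.character(as.integer(r$chiral)),
          geometry_source = r$geometry_source,
          smiles = r$smiles)
  methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
               header = h, atomblock = ab, bondblock = bb, datablock = db)
}

#' Write molecule records to an SDF file
#'
#' @param records non-empty list of `xtal_record` objects.
#' @param path output file path.
#' @return Invisibly, the path.
#' @seealso [read_sdf()] for the inverse.
#' @export
write_sdf <- function(records, path) {
  if (length(records) == 0L) stop("cannot write an empty record list")
  for (r in records) {
    if (!inherits(r, "xtal_record")) stop("records must be xtal_record objects")
    if (r$space_group < 1L || r$space_group > 230L) {
      stop("record ", r$record_id, ": space group ", r$space_group,
           " outside 1..230")
    }
  }
  sdfs <- lapply(records, .record_to_sdf)
  ids <- vapply(records, `[[`, "", "record_id")
  sset <- methods::new(methods::getClass("SDFset",
                                         where = asNamespace("ChemmineR")),
                       SDF = sdfs, ID = ids)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  close(con)
  ChemmineR::write.SDF(sset, file = path)
  invisible(path)
}

#' Read molecule records from an SDF file
#'
#' Entries missing the `space_group` data field (or carrying an out-of-range
#' value) are skipped with a warning that reports the count; reading fails if
#' no valid entry remains.
#'
#' @param path SDF file with the data fields written by [write_sdf()]
#'   (minimally `space_group`; missing auxiliary fields get defaults).
#' @return List of `xtal_record` objects.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sset)
  if (any(!valid)) warning(sum(!valid), " malformed SDF entr(ies) skipped")
  sset <- sset[valid]
  out <- list()
  n_skipped <- 0L
  for (k in seq_len(length(sset))) {
    sdf <- sset[[k]]
    db <- ChemmineR::datablock(sdf)
    sg <- if ("space_group" %in% names(db)) {
      suppressWarnings(as.integer(db[["space_group"]]))
    } else NA_integer_
    if (length(sg) == 0L || is.na(sg) || sg < 1L || sg > 230L) {
      n_skipped <- n_skipped + 1L
      next
    }
    ab <- ChemmineR::atomblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (nrow(bb) > 0) {
      .new_bonds(bb[, 1], bb[, 2], ifelse(bb[, 3] == 4, 1, bb[, 3]),
                 bb[, 3] == 4)
    } else .new_bonds()
    rid <- ChemmineR::header(sdf)[["Molecule_Name"]]
    get <- function(field, default) {
      if (field %in% names(db)) db[[field]] else default
    }
    out[[length(out) + 1L]] <- molecule_record(
      record_id = rid,
      family_id = get("family_id", rid),
      smiles = get("smiles", ""),
      elements = elements,
      coordinates = coords,
      space_group = sg,
      deposition_rank = as.integer(get("deposition_rank", "1")),
      chiral = get("chiral", "0") == "1",
      geometry_source = get("geometry_source", "optimized"),
      bonds = bonds)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " entr(ies) without a valid space_group field skipped")
  }
  if (length(out) == 0L) stop("no valid records in ", path)
  out
}
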