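# Molecular descriptor blocks: general (size/ring counts), geometric (shape
# anisotropy, planarity, symmetry census) and chemical (functional-group
# counts + topological polar surface area), plus correlation/variance feature
# removal. Feature tables are the input of the random-forest model track.

#' General molecular features
#'
#' Molecular weight, atom count (explicit hydrogens included), ring count
#' (cycle rank, equal to the number of smallest rings) and aromatic ring
#' count (cycle rank of the aromatic-bond subgraph).
#'
#' @param record an `xtal_record` with a bond table (records produced by
#'   [generate_dataset()] or [read_sdf()] carry one).
#' @return Named numeric vector `mol_weight`, `n_atoms`, `n_rings`,
#'   `n_aromatic_rings`.
#' @export
general_features <- function(record) {
  if (is.null(record$bonds)) stop("record ", record$record_id,
                                  " carries no bond table")
  b <- record$bonds
  c(mol_weight = sum(atomic_weights(record$elements)),
    n_atoms = length(record$elements),
    n_rings = .cycle_rank(length(record$elements), b),
    n_aromatic_rings = .cycle_rank(length(record$elements),
                                   b[b$aromatic, , drop = FALSE]))
}

#' Shape descriptors from the inertia tensor
#'
#' Principal moments of inertia I1 <= I2 <= I3 of the mass-weighted conformer
#' give the normalized principal moment ratios `npr1 = I1/I3`,
#' `npr2 = I2/I3` (the rod--disc--sphere shape triangle), the asphericity
#' `0.5 * ((I1-I2)^2 + (I1-I3)^2 + (I2-I3)^2) / (I1^2 + I2^2 + I3^2)` and the
#' eccentricity `sqrt(I3^2 - I1^2) / I3`. Planarity is the mean absolute
#' distance to the least-squares plane (normal = smallest principal direction
#' of the centred coordinate second-moment matrix; for an isotropic cloud the
#' third principal direction is used and the result flagged degenerate).
#'
#' @param elements element symbols (>= 3 atoms).
#' @param coordinates n x 3 matrix, angstroms.
#' @param mass_weighted use standard atomic weights for the inertia tensor
#'   (default); `FALSE` gives the unit-mass variant.
#' @return List with `npr1`, `npr2`, `asphericity`, `eccentricity`,
#'   `planarity` (angstroms) and logical `degenerate_plane`.
#' @export
shape_descriptors <- function(elements, coordinates, mass_weighted = TRUE) {
  X <- as.matrix(coordinates)
  if (nrow(X) < 3L) stop("shape descriptors need >= 3 atoms")
  if (!all(is.finite(X))) stop("coordinates must be finite")
  m <- if (mass_weighted) atomic_weights(elements) else rep(1, nrow(X))
  com <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, com)
  r2 <- rowSums(Xc^2)
  I <- diag(c(sum(m * r2), sum(m * r2), sum(m * r2))) -
    crossprod(sqrt(m) * Xc)
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)
  I1 <- ev[1]; I2 <- ev[2]; I3 <- ev[3]
  if (I3 < 1e-12) stop("degenerate geometry: zero inertia")
  aspher <- 0.5 * ((I1 - I2)^2 + (I1 - I3)^2 + (I2 - I3)^2) /
    (I1^2 + I2^2 + I3^2)
  ecc <- sqrt(max(I3^2 - I1^2, 0)) / I3

  # plane of best fit on unweighted centred coordinates
  ctr <- colMeans(X)
  Y <- sweep(X, 2, ctr)
  S <- crossprod(Y) / nrow(Y)
  es <- eigen(S, symmetric = TRUE)
  degen <- (es$values[1] - es$values[3]) <= 1e-8 * max(es$values[1], 1e-12)
  normal <- es$vectors[, 3]
  planarity <- mean(abs(Y %*% normal))
  if (planarity < 1e-10) planarity <- 0

  list(npr1 = I1 / I3, npr2 = I2 / I3, asphericity = aspher,
       eccentricity = ecc, planarity = planarity, degenerate_plane = degen)
}

.read_group_patterns <- function() {
  path <- system.file("extdata", "functional_groups.smarts",
                      package = "xtalgroup")
  if (path == "") {                      # sourced during development
    path <- file.path("inst", "extdata", "functional_groups.smarts")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t")
  stats::setNames(vapply(parts, `[[`, "", 2), vapply(parts, `[[`, "", 1))
}

# Batched chemical features over a SMILES vector; one OpenBabel pass per
# pattern. Unparsable SMILES yield NA rows.
.chemical_feature_matrix <- function(smiles) {
  pats <- .read_group_patterns()
  nm <- smiles
  names(nm) <- sprintf("q%06d", seq_along(smiles))
  sset <- tryCatch(ChemmineR::smiles2sdf(nm), error = function(e)
    stop("SMILES parsing failed: ", conditionMessage(e)))
  out <- matrix(NA_real_, length(smiles), length(pats) + 1L,
                dimnames = list(NULL, c(names(pats), "tpsa")))
  refs <- ChemmineR::obmol(sset)      # one OBMol conversion per molecule
  for (p in names(pats)) {
    out[, p] <- ChemmineOB::smartsSearch_OB(refs, pats[[p]],
                                            uniqueMatches = TRUE)
  }
  out[, "tpsa"] <- ChemmineR::propOB(sset)$TPSA
  out
}

#' Chemical features from a SMILES string
#'
#' Counts of 18 common functional groups (alcohol, amide, imine, nitro,
#' nitrile, amine, ether, aldehyde, halide, ketone, carboxylic acid,
#' anhydride, ester, thiol, thiocarbonyl, thioether, sulfone, phosphoric
#' acid) using the versioned SMARTS pattern file shipped in
#' `extdata/functional_groups.smarts`, plus the Ertl topological polar
#' surface area. Patterns are mutually disambiguated (an ester oxygen is not
#' an ether; a carboxylic acid is not an ester or alcohol).
#'
#' @param smiles a single SMILES string.
#' @return Named numeric vector of the 18 counts and `tpsa`.
#' @export
chemical_features <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  m <- .chemical_feature_matrix(smiles)
  v <- m[1, ]
  if (anyNA(v)) stop("unparsable SMILES: ", smiles)
  v
}

# ---- feature table ---------------------------------------------------------

.new_feature_table <- function(values, column_class, geometry_source = NULL,
                               selection = NULL) {
  structure(list(values = values,
                 row_ids = rownames(values),
                 column_names = colnames(values),
                 column_class = column_class,
                 geometry_source = geometry_source,
                 selection = selection),
            class = "xtal_features")
}

#' @export
print.xtal_features <- function(x, ...) {
  cat(sprintf("<xtal_features: %d molecules x %d features (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(names(table(x$column_class)),
                    table(x$column_class), sep = "=", collapse = " ")))
  invisible(x)
}

#' Assemble the full feature table for a record set
#'
#' Concatenates the general, geometric (shape + symmetry census) and
#' chemical blocks in a fixed, documented column order. Records for which
#' any block fails are excluded with a warning naming them.
#'
#' @param records list of `xtal_record` objects.
#' @param tolerance symmetry-detection displacement tolerance (angstroms);
#'   see [detect_symmetry()].
#' @return An `xtal_features` table: numeric matrix (rows = record ids) plus
#'   per-column class tags (`general`, `geometric`, `chemical`) and the
#'   records' geometry source.
#' @export
assemble_features <- function(records, tolerance = 0.05) {
  stopifnot(length(records) > 0)
  smiles <- vapply(records, `[[`, "", "smiles")
  usmi <- unique(smiles)
  chem_u <- .chemical_feature_matrix(usmi)
  rownames(chem_u) <- usmi

  rows <- list(); ids <- character(); failed <- character()
  # records sharing an identical SMILES + conformer (polymorph siblings,
  # repeated grammar draws) reuse one computed row
  memo <- new.env(parent = emptyenv())
  for (r in records) {
    key <- paste0(r$smiles, "#", length(r$elements), "#",
                  signif(sum(r$coordinates^2), 10))
    row <- get0(key, envir = memo)
    if (is.null(row)) {
      row <- tryCatch({
        gen <- general_features(r)
        shp <- shape_descriptors(r$elements, r$coordinates)
        sym <- symmetry_features(detect_symmetry(r$elements, r$coordinates,
                                                 tolerance = tolerance))
        chm <- chem_u[r$smiles, ]
        v <- c(gen,
               npr1 = shp$npr1, npr2 = shp$npr2, asphericity = shp$asphericity,
               eccentricity = shp$eccentricity, planarity = shp$planarity,
               sym, chm)
        if (!all(is.finite(v))) stop("non-finite feature value")
        v
      }, error = function(e) NULL)
      assign(key, if (is.null(row)) "failed" else row, envir = memo)
    }
    if (is.character(row) || is.null(row)) failed <- c(failed, r$record_id)
    else { rows[[length(rows) + 1L]] <- row; ids <- c(ids, r$record_id) }
  }
  if (length(failed)) {
    warning(length(failed), " record(s) excluded from the feature table: ",
            paste(utils::head(failed, 10), collapse = ", "))
  }
  if (length(rows) == 0L) stop("no record produced a complete feature row")
  vals <- do.call(rbind, rows)
  rownames(vals) <- ids
  cls <- c(rep("general", 4),
           rep("geometric", 5 + length(.symmetry_classes()) + 1L),
           rep("chemical", ncol(chem_u)))
  names(cls) <- colnames(vals)
  .new_feature_table(vals, cls,
                     geometry_source = unique(vapply(records, `[[`, "",
                                                     "geometry_source")))
}

#' Remove low-variance and highly correlated features
#'
#' Columns with variance below `var_threshold` are dropped; then columns are
#' scanned in fixed (stored) order and a column is dropped when its absolute
#' Pearson correlation with an already-retained column exceeds
#' `corr_threshold`. The fitted selection (retained column set) is stored on
#' the result and can be re-applied to another table with
#' [apply_feature_selection()], so a selection fitted on a balanced dataset
#' can be reused on an unbalanced one.
#'
#' @param table an `xtal_features` table with >= 2 rows.
#' @param corr_threshold absolute-correlation cutoff (default 0.9).
#' @param var_threshold variance cutoff (default 1e-8).
#' @return Filtered `xtal_features` table (selection stored in `$selection`).
#' @export
select_features <- function(table, corr_threshold = 0.9, var_threshold = 1e-8) {
  stopifnot(inherits(table, "xtal_features"), nrow(table$values) >= 2)
  V <- table$values
  vars <- apply(V, 2, stats::var)
  cand <- colnames(V)[vars >= var_threshold]
  if (length(cand) == 0L) stop("all features removed by the variance filter")
  kept <- character()
  for (cn in cand) {
    ok <- TRUE
    for (kn in kept) {
      r <- stats::cor(V[, cn], V[, kn])
      if (is.finite(r) && abs(r) > corr_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, cn)
  }
  if (length(kept) == 0L) stop("all features removed")
  apply_feature_selection(table, kept)
}

#' Subset a feature table by rows
#'
#' @param table an `xtal_features` table.
#' @param rows logical/integer index or character record ids.
#' @return The row-subsetted `xtal_features` table (columns, class tags and
#'   any fitted selection unchanged).
#' @export
subset_features <- function(table, rows) {
  stopifnot(inherits(table, "xtal_features"))
  if (is.character(rows)) rows <- match(rows, rownames(table$values))
  .new_feature_table(table$values[rows, , drop = FALSE], table$column_class,
                     geometry_source = table$geometry_source,
                     selection = table$selection)
}

#' @rdname select_features
#' @param selection character vector of retained column names (from a fitted
#'   `select_features()` result's `$selection`).
#' @export
apply_feature_selection <- function(table, selection) {
  stopifnot(inherits(table, "xtal_features"))
  missing_cols <- setdiff(selection, colnames(table$values))
  if (length(missing_cols)) {
    stop("selection names absent from table: ",
         paste(missing_cols, collapse = ", "))
  }
  .new_feature_table(table$values[, selection, drop = FALSE],
                     table$column_class[selection],
                     geometry_source = table$geometry_source,
                     selection = selection)
}
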