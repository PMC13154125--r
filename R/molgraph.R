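# Attributed molecular graphs for the GNN model track, plus the
# rotation-based coordinate augmentation.
#
# Nodes carry atomic number, hybridization one-hot (sp/sp2/sp3/other),
# formal charge, an aromaticity flag and the Gasteiger partial charge
# (iterative partial equalization of orbital electronegativity, 32 damped
# iterations). Edges are stored in both directions with bond-order one-hot
# (single/double/triple/aromatic), a conjugation flag and an in-ring flag.

# Gasteiger-Marsili electronegativity parameters (a, b, c) per atom type.
.gasteiger_params <- function(elements, hyb) {
  key <- ifelse(elements %in% c("C", "N", "O", "S"),
                paste0(elements, ".", hyb), elements)
  tab <- list(
    H      = c(7.17, 6.24, -0.56),
    C.sp3  = c(7.98, 9.18, 1.88),
    C.sp2  = c(8.79, 9.32, 1.51),
    C.sp   = c(10.39, 9.45, 0.73),
    N.sp3  = c(11.54, 10.82, 1.36),
    N.sp2  = c(12.87, 11.15, 0.85),
    N.sp   = c(15.68, 11.70, -0.27),
    O.sp3  = c(14.18, 12.92, 1.39),
    O.sp2  = c(17.07, 13.79, 0.47),
    F      = c(14.66, 13.85, 2.31),
    Cl     = c(11.00, 9.69, 1.35),
    Br     = c(10.08, 8.47, 1.16),
    I      = c(9.90, 7.96, 0.96),
    S.sp3  = c(10.14, 9.13, 1.38),
    S.sp2  = c(10.14, 9.13, 1.38),
    P.sp3  = c(8.90, 8.24, 0.96)
  )
  key[key %in% c("C.other", "N.other", "O.other", "S.other")] <-
    sub("other", "sp3", key[key %in% c("C.other", "N.other", "O.other", "S.other")])
  key[key %in% c("S.sp", "P.sp2", "P.sp", "P.other")] <- "S.sp3"
  key[!key %in% names(tab) & elements == "P"] <- "P.sp3"
  out <- t(vapply(key, function(k) {
    p <- tab[[k]]
    if (is.null(p)) tab[["C.sp3"]] else p
  }, numeric(3)))
  dimnames(out) <- list(NULL, c("a", "b", "c"))
  out
}

.atom_hybridizations <- function(elements, bonds) {
  n <- length(elements)
  hyb <- rep("sp3", n)
  n_double <- integer(n); has_triple <- logical(n); has_arom <- logical(n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    if (bonds$aromatic[r]) { has_arom[i] <- TRUE; has_arom[j] <- TRUE }
    else if (bonds$order[r] == 2) { n_double[i] <- n_double[i] + 1L; n_double[j] <- n_double[j] + 1L }
    else if (bonds$order[r] >= 3) { has_triple[i] <- TRUE; has_triple[j] <- TRUE }
  }
  hyb[has_arom | n_double == 1L] <- "sp2"
  hyb[has_triple | n_double >= 2L] <- "sp"
  hyb[elements %in% c("H", "F", "Cl", "Br", "I")] <- "other"
  hyb
}

#' Gasteiger partial charges
#'
#' Iterative partial equalization of orbital electronegativity with the
#' classic parameter set and damping 0.5^k over 32 iterations. The charge sum
#' equals the total formal charge by construction (pairwise transfers).
#'
#' @param elements element symbols.
#' @param bonds bond data.frame (i, j, order, aromatic).
#' @param formal_charges integer vector (default all 0).
#' @param n_iter iterations (default 32).
#' @return Numeric vector of partial charges.
#' @export
gasteiger_charges <- function(elements, bonds, formal_charges = NULL,
                              n_iter = 32L) {
  n <- length(elements)
  if (is.null(formal_charges)) formal_charges <- numeric(n)
  hyb <- .atom_hybridizations(elements, bonds)
  par <- .gasteiger_params(elements, hyb)
  q <- as.numeric(formal_charges)
  chi_plus <- par[, "a"] + par[, "b"] + par[, "c"]
  chi_plus[elements == "H"] <- 20.02
  damp <- 1
  for (k in seq_len(n_iter)) {
    damp <- damp * 0.5
    chi <- par[, "a"] + par[, "b"] * q + par[, "c"] * q^2
    dq <- numeric(n)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      hi <- if (lo == i) j else i
      tr <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
      dq[lo] <- dq[lo] + tr
      dq[hi] <- dq[hi] - tr
    }
    q <- q + dq
  }
  q
}

#' Build an attributed molecular graph
#'
#' @param record an `xtal_record` with a bond table.
#' @param include_coordinates attach the conformer's Cartesian coordinates
#'   to the graph (required by the coordinate-aware GNN variants).
#' @param include_hydrogens keep explicit hydrogen nodes (default TRUE;
#'   hydrogen bonding is central to space-group preference).
#' @return Object of class `xtal_graph`: `node_attrs` (n x 8 matrix:
#'   atomic_number, hyb_sp, hyb_sp2, hyb_sp3, hyb_other, formal_charge,
#'   aromatic, gasteiger), `edge_index` (m x 2, both directions),
#'   `edge_attrs` (m x 6: order_single, order_double, order_triple,
#'   order_aromatic, conjugated, in_ring), optional `coordinates`, `label`
#'   (space-group number) and `record_id`.
#' @export
build_graph <- function(record, include_coordinates = TRUE,
                        include_hydrogens = TRUE) {
  if (is.null(record$bonds) || nrow(record$bonds) == 0L) {
    stop("record ", record$record_id, " carries no bond table")
  }
  elements <- record$elements
  bonds <- record$bonds
  coords <- record$coordinates
  if (!include_hydrogens) {
    keep <- which(elements != "H")
    remap <- match(seq_along(elements), keep)
    bonds <- bonds[bonds$i %in% keep & bonds$j %in% keep, , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    elements <- elements[keep]; coords <- coords[keep, , drop = FALSE]
  }
  n <- length(elements)
  hyb <- .atom_hybridizations(elements, bonds)
  q <- tryCatch(gasteiger_charges(elements, bonds),
                error = function(e) stop("partial-charge computation failed ",
                                         "for record ", record$record_id,
                                         ": ", conditionMessage(e)))
  if (!all(is.finite(q))) {
    stop("partial-charge computation failed for record ", record$record_id)
  }
  arom_atom <- logical(n)
  arom_atom[c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic])] <- TRUE
  node_attrs <- cbind(atomic_number = atomic_numbers(elements),
                      hyb_sp = as.numeric(hyb == "sp"),
                      hyb_sp2 = as.numeric(hyb == "sp2"),
                      hyb_sp3 = as.numeric(hyb == "sp3"),
                      hyb_other = as.numeric(hyb == "other"),
                      formal_charge = 0,
                      aromatic = as.numeric(arom_atom),
                      gasteiger = q)

  # in-ring bonds = non-bridge edges (removal keeps endpoints connected)
  in_ring <- logical(nrow(bonds))
  adj <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], r)
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], r)
  }
  connected_without <- function(rexcl, from, to) {
    seen <- logical(n); stack <- from; seen[from] <- TRUE
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v == to) return(TRUE)
      for (r2 in adj[[v]]) {
        if (r2 == rexcl) next
        w <- if (bonds$i[r2] == v) bonds$j[r2] else bonds$i[r2]
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    FALSE
  }
  for (r in seq_len(nrow(bonds))) {
    in_ring[r] <- connected_without(r, bonds$i[r], bonds$j[r])
  }

  # conjugation: aromatic bonds, or bonds whose two endpoints each carry a
  # multiple/aromatic bond other than this one (package definition)
  has_mult <- function(at, rexcl) {
    any(vapply(adj[[at]], function(r2) {
      r2 != rexcl && (bonds$aromatic[r2] || bonds$order[r2] >= 2)
    }, TRUE))
  }
  conj <- logical(nrow(bonds))
  for (r in seq_len(nrow(bonds))) {
    conj[r] <- bonds$aromatic[r] ||
      (has_mult(bonds$i[r], r) && has_mult(bonds$j[r], r))
  }

  ea1 <- cbind(order_single = as.numeric(!bonds$aromatic & bonds$order == 1),
               order_double = as.numeric(!bonds$aromatic & bonds$order == 2),
               order_triple = as.numeric(!bonds$aromatic & bonds$order >= 3),
               order_aromatic = as.numeric(bonds$aromatic),
               conjugated = as.numeric(conj),
               in_ring = as.numeric(in_ring))
  edge_index <- rbind(cbind(bonds$i, bonds$j), cbind(bonds$j, bonds$i))
  edge_attrs <- rbind(ea1, ea1)

  structure(list(node_attrs = node_attrs,
                 edge_index = edge_index,
                 edge_attrs = edge_attrs,
                 coordinates = if (include_coordinates) coords else NULL,
                 label = record$space_group,
                 record_id = record$record_id),
            class = "xtal_graph")
}

#' @export
print.xtal_graph <- function(x, ...) {
  cat(sprintf("<xtal_graph %s: %d nodes, %d directed edges%s, label SG %s>\n",
              x$record_id, nrow(x$node_attrs), nrow(x$edge_index),
              if (is.null(x$coordinates)) "" else ", 3D",
              x$label))
  invisible(x)
}

#' Rotation augmentation of a graph batch
#'
#' Each input graph yields four graphs: the original (coordinates retained)
#' plus three copies rotated about the x-, y- and z-axis respectively, each
#' by an independent uniform angle in `[0, 2pi)`. Labels, topology and all
#' node/edge attributes are unchanged; an input batch of 16 graphs becomes
#' 64.
#'
#' @param graphs list of `xtal_graph` objects, all carrying coordinates.
#' @param seed integer seed making the drawn angles reproducible.
#' @return List of `4 * length(graphs)` graphs (original first, then the
#'   x/y/z rotated copies, per input graph).
#' @export
augment_batch <- function(graphs, seed) {
  if (any(vapply(graphs, function(g) is.null(g$coordinates), TRUE))) {
    stop("all graphs must carry coordinates for rotation augmentation")
  }
  set.seed(seed)
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  out <- vector("list", 4L * length(graphs))
  k <- 0L
  for (g in graphs) {
    k <- k + 1L; out[[k]] <- g
    for (ax in axes) {
      R <- .rotmat(ax, stats::runif(1, 0, 2 * pi))
      g2 <- g
      g2$coordinates <- g$coordinates %*% t(R)
      k <- k + 1L; out[[k]] <- g2
    }
  }
  out
}
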