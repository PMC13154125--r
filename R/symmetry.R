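# Molecular point-group symmetry detection.
#
# The detector centres the conformer at its centre of mass, enumerates
# candidate proper/improper rotation axes and mirror normals from the
# principal inertia axes, atom position vectors, same-element pair midpoints,
# differences and cross products, and accepts an operation when it maps the
# element-labelled point set onto itself with max displacement <= tolerance.
# Accepted operations are deduplicated as 3x3 matrices and classified from
# their determinant and rotation angle, so the census does not depend on
# which candidate produced an operation. Each distinct operation is counted
# (C3 and C3^2 are two operations), so the total equals the group order.

.symmetry_classes <- function(n_max = 8L) {
  c("E", paste0("C", 2:n_max), "sigma", "i", paste0("S", 3:n_max))
}

# Rationalize x in (0, 1) as p/q with q <= qmax; returns q or NA.
.rational_order <- function(x, qmax, tol = 1e-4) {
  for (q in 2:qmax) {
    p <- round(x * q)
    if (p >= 1 && p < q && abs(x - p / q) < tol && gcd2(p, q) == 1L) return(q)
  }
  NA_integer_
}

gcd2 <- function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }

# Classify an accepted orthogonal matrix into an operator class.
.classify_operation <- function(M, n_max) {
  d <- det(M)
  tr <- sum(diag(M))
  if (d > 0) {
    ct <- max(-1, min(1, (tr - 1) / 2))
    th <- acos(ct)
    if (th < 1e-4) return("E")
    q <- .rational_order(th / (2 * pi), n_max)
    if (is.na(q)) return(NA_character_)
    paste0("C", q)
  } else {
    ct <- max(-1, min(1, (tr + 1) / 2))
    th <- acos(ct)
    if (th < 1e-4) return("sigma")
    if (abs(th - pi) < 1e-4) return("i")
    q <- .rational_order(th / (2 * pi), 2L * n_max)
    if (is.na(q) || q > n_max) return(NA_character_)
    paste0("S", q)
  }
}

# Axis of a proper rotation / normal of a reflection (unit, sign-canonical).
.operation_axis <- function(M) {
  ev <- eigen(M, symmetric = FALSE)
  k <- which.min(abs(ev$values - det(M)))
  a <- Re(ev$vectors[, k])
  n <- sqrt(sum(a^2))
  if (n < 1e-8) return(c(0, 0, 1))
  a <- a / n
  nz <- which(abs(a) > 1e-6)[1]
  if (length(nz) && a[nz] < 0) a <- -a
  a
}

# If the orthogonal map M sends the centred, element-labelled point set onto
# itself within `tol`, return the induced atom permutation; otherwise NULL.
# Fast path: one reference atom must land on a same-element atom before the
# full bijection is checked. The bijection test is a vectorised
# nearest-neighbour assignment (valid because `tol` is small against
# interatomic distances).
.induced_permutation <- function(X, elements, M, tol, ref = 1L,
                                 elem_mask = NULL) {
  t_ref <- as.numeric(M %*% X[ref, ])
  d_ref <- sqrt(colSums((t(X) - t_ref)^2))
  if (!any(d_ref <= tol & elements == elements[ref])) return(NULL)
  TX <- X %*% t(M)
  D2 <- outer(rowSums(TX^2), rowSums(X^2), `+`) - 2 * tcrossprod(TX, X)
  if (!is.null(elem_mask)) D2[elem_mask] <- Inf
  j <- max.col(-D2, ties.method = "first")
  dmin <- D2[cbind(seq_len(nrow(X)), j)]
  if (all(dmin <= tol^2 + 1e-12) && !anyDuplicated(j)) j else NULL
}

.dedupe_matrices <- function(mats, eps = 1e-4) {
  out <- list()
  for (M in mats) {
    dup <- FALSE
    for (K in out) if (max(abs(M - K)) < eps) { dup <- TRUE; break }
    if (!dup) out[[length(out) + 1L]] <- M
  }
  out
}

#' Detect the point-group symmetry of a conformer
#'
#' @param elements character vector of element symbols (>= 2 atoms).
#' @param coordinates numeric n x 3 matrix, Cartesian angstroms.
#' @param tolerance maximum displacement (angstroms) allowed when an
#'   operation maps the atom set onto itself. The default (0.05) suits
#'   relaxed geometries; 0.1 is a documented alternative for geometries taken
#'   directly from crystal structures.
#' @param n_max maximum rotation order enumerated for Cn/Sn (default 8).
#' @return Object of class `xtal_symmetry`: `total_operations`,
#'   `count_by_class` (fixed schema: E, C2..Cn_max, sigma, i, S3..Sn_max),
#'   `point_group_name`, `tolerance`, `linear` flag, and the accepted
#'   operation matrices/axes (`operations`).
#' @export
detect_symmetry <- function(elements, coordinates, tolerance = 0.05,
                            n_max = 8L) {
  X <- as.matrix(coordinates)
  if (length(elements) < 2L || nrow(X) != length(elements) || ncol(X) != 3L) {
    stop("need >= 2 atoms with n x 3 coordinates")
  }
  if (!all(is.finite(X))) stop("coordinates must be finite")
  if (tolerance <= 0) stop("tolerance must be positive")
  m <- atomic_weights(elements)
  com <- colSums(X * m) / sum(m)
  X <- sweep(X, 2, com)
  r <- sqrt(rowSums(X^2))
  if (max(r) < 1e-6) stop("degenerate geometry: all atoms coincident")

  # second-moment principal directions (also used for linearity)
  S <- crossprod(X) / nrow(X)
  es <- eigen(S, symmetric = TRUE)
  axes_principal <- lapply(1:3, function(k) es$vectors[, k])
  linear <- {
    a <- es$vectors[, 1]
    perp <- sqrt(rowSums((X - outer(as.numeric(X %*% a), a))^2))
    max(perp) <= tolerance
  }
  if (linear) {
    # a linear molecule has infinitely many operations; report a canonical
    # capped census (rotations about the axis up to n_max, n_max vertical
    # mirrors, and the centrosymmetric extras when inversion holds) and flag
    # it. The census depends only on whether the molecule is
    # centrosymmetric, so it is rigid-motion invariant.
    phi <- function(q) sum(vapply(seq_len(q - 1),
                                  function(p) gcd2(p, q) == 1L, TRUE))
    counts <- stats::setNames(integer(length(.symmetry_classes(n_max))),
                              .symmetry_classes(n_max))
    counts["E"] <- 1L
    for (q in 2:n_max) counts[paste0("C", q)] <- phi(q)
    counts["sigma"] <- n_max
    centro <- {
      TX <- -X
      D2 <- outer(rowSums(TX^2), rowSums(X^2), `+`) - 2 * tcrossprod(TX, X)
      D2[outer(elements, elements, `!=`)] <- Inf
      j <- max.col(-D2, ties.method = "first")
      all(D2[cbind(seq_len(nrow(X)), j)] <= tolerance^2 + 1e-12) &&
        !anyDuplicated(j)
    }
    if (centro) {
      counts["i"] <- 1L
      counts["sigma"] <- counts["sigma"] + 1L
      counts["C2"] <- counts["C2"] + n_max
      for (q in 3:n_max) counts[paste0("S", q)] <- phi(q)
    }
    return(structure(list(total_operations = sum(counts),
                          count_by_class = counts,
                          tolerance = tolerance, linear = TRUE,
                          n_max = as.integer(n_max), operations = list(),
                          point_group_name = if (centro) "Dinfh" else "Cinfv"),
                     class = "xtal_symmetry"))
  }

  # reference atom for the fast rejection test: off-centre atom of the
  # rarest element class (most constraining)
  off <- which(r > tolerance)
  ref <- if (length(off)) {
    cls <- table(elements[off])
    cand <- off[elements[off] %in% names(cls)[cls == min(cls)]]
    cand[which.max(r[cand])]
  } else 1L

  # candidate directions
  same_class_pairs <- function() {
    idx <- which(r > tolerance)
    out <- list()
    if (length(idx) >= 2) {
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in (a + 1):length(idx)) {
          i <- idx[a]; j <- idx[b]
          if (elements[i] == elements[j] && abs(r[i] - r[j]) <= 2 * tolerance) {
            out[[length(out) + 1L]] <- c(i, j)
          }
        }
      }
    }
    out
  }
  pairs <- same_class_pairs()
  dirs <- axes_principal
  for (i in which(r > tolerance)) dirs[[length(dirs) + 1L]] <- X[i, ] / r[i]
  for (pr in pairs) {
    mid <- (X[pr[1], ] + X[pr[2], ]) / 2
    dif <- X[pr[1], ] - X[pr[2], ]
    crs <- c(X[pr[1], 2] * X[pr[2], 3] - X[pr[1], 3] * X[pr[2], 2],
             X[pr[1], 3] * X[pr[2], 1] - X[pr[1], 1] * X[pr[2], 3],
             X[pr[1], 1] * X[pr[2], 2] - X[pr[1], 2] * X[pr[2], 1])
    if (.vnorm(mid) > tolerance) dirs[[length(dirs) + 1L]] <- .unit(mid)
    if (.vnorm(dif) > 1e-8) dirs[[length(dirs) + 1L]] <- .unit(dif)
    if (.vnorm(crs) > 1e-8) dirs[[length(dirs) + 1L]] <- .unit(crs)
  }
  # canonical sign + dedupe
  canon <- function(v) { nz <- which(abs(v) > 1e-6)[1]; if (length(nz) && v[nz] < 0) -v else v }
  dirs <- lapply(dirs, canon)
  keep <- list()
  for (v in dirs) {
    dup <- FALSE
    for (w in keep) if (sum(v * w) > 1 - 1e-8) { dup <- TRUE; break }
    if (!dup) keep[[length(keep) + 1L]] <- v
  }
  dirs <- keep

  # enumerate and test candidate operations. Accepted candidates are keyed
  # by (induced permutation, parity): for a non-linear point set this pair
  # identifies the operation uniquely, so near-duplicate candidate matrices
  # collapse; the reported matrix is the Kabsch-refined optimum for the
  # permutation.
  elem_mask <- outer(elements, elements, `!=`)
  accepted <- new.env(parent = emptyenv())
  assign(paste(c(seq_len(nrow(X)), "+"), collapse = ","),
         diag(3), envir = accepted)                       # identity
  try_op <- function(M) {
    perm <- .induced_permutation(X, elements, M, tolerance, ref, elem_mask)
    if (is.null(perm)) return(invisible())
    parity <- if (det(M) > 0) "+" else "-"
    key <- paste(c(perm, parity), collapse = ",")
    if (is.null(get0(key, envir = accepted))) {
      pr <- .procrustes_residuals(X, X[perm, , drop = FALSE])
      side <- if (parity == "+") pr$rot else pr$imp
      # keep the refined matrix when it still realises the operation,
      # otherwise the raw candidate
      Mref <- if (side$max_disp <= tolerance) side$O else M
      assign(key, Mref, envir = accepted)
    }
    invisible()
  }
  try_op(-diag(3))
  angle_tab <- list()
  for (q in 2:n_max) for (p in seq_len(q - 1)) {
    if (gcd2(p, q) == 1L) {
      angle_tab[[length(angle_tab) + 1L]] <- c(q = q, th = 2 * pi * p / q)
    }
  }
  # an off-axis reference orbit bounds the feasible rotation order about an
  # axis: a Cq needs >= q atoms in the reference atom's (element, axial
  # projection, axial distance) class
  max_order_about <- function(a) {
    proj <- as.numeric(X %*% a)
    rho2 <- r^2 - proj^2
    offs <- which(rho2 > tolerance^2)
    if (length(offs) == 0L) return(n_max)   # all atoms on axis (linear)
    i0 <- offs[which.min(rho2[offs])]       # most constraining off-axis atom
    # |projection| classes, so improper rotations (which flip the axial
    # side) are never pruned away
    cls <- offs[elements[offs] == elements[i0] &
                  abs(abs(proj[offs]) - abs(proj[i0])) <= 2 * tolerance &
                  abs(sqrt(pmax(rho2[offs], 0)) - sqrt(rho2[i0])) <= 2 * tolerance]
    length(cls)
  }
  for (a in dirs) {
    refl <- .reflmat(a)
    try_op(refl)
    qcap <- max_order_about(a)
    if (qcap < 2L) next
    for (at in angle_tab) {
      if (at["q"] > qcap) next
      R <- .rotmat(a, at["th"])
      try_op(R)
      try_op(refl %*% R)   # improper rotation about a
    }
  }
  accepted_mats <- as.list(accepted)

  counts <- stats::setNames(integer(length(.symmetry_classes(n_max))),
                            .symmetry_classes(n_max))
  ops <- list()
  for (M in accepted_mats) {
    cl <- .classify_operation(M, n_max)
    if (is.na(cl) || !cl %in% names(counts)) next
    counts[cl] <- counts[cl] + 1L
    ops[[length(ops) + 1L]] <- list(matrix = M, class = cl,
                                    axis = .operation_axis(M))
  }
  counts["E"] <- 1L

  res <- structure(list(total_operations = sum(counts),
                        count_by_class = counts,
                        tolerance = tolerance,
                        linear = linear,
                        n_max = as.integer(n_max),
                        operations = ops), class = "xtal_symmetry")
  res$point_group_name <- .point_group_name(res, es$vectors[, 1])
  res
}

# Schoenflies name from the operation census (standard flowchart).
.point_group_name <- function(rep, linear_axis) {
  cnt <- rep$count_by_class
  ops <- rep$operations
  if (rep$linear) return(if (cnt["i"] > 0) "Dinfh" else "Cinfv")
  if (rep$total_operations == 1L) return("C1")
  if (rep$total_operations == 2L) {
    if (cnt["sigma"] == 1L) return("Cs")
    if (cnt["i"] == 1L) return("Ci")
  }
  nmax <- rep$n_max
  if (cnt["C3"] >= 8L) {            # cubic/icosahedral families
    if (!is.na(cnt["C5"]) && cnt["C5"] >= 24L) {
      return(if (cnt["i"] > 0) "Ih" else "I")
    }
    if (cnt["C4"] >= 6L) return(if (cnt["i"] > 0) "Oh" else "O")
    if (rep$total_operations == 12L) return("T")
    if (any(grepl("^S4$", names(cnt)) & cnt["S4"] > 0)) return("Td")
    return("Th")
  }
  orders <- c(2:nmax)
  present <- orders[vapply(orders, function(q) cnt[paste0("C", q)] > 0, TRUE)]
  if (length(present) == 0L) {
    # no proper rotation beyond E, but sigma/i/S present in combination
    if (cnt["sigma"] > 0) return("Cs")
    return("Ci")
  }
  n <- max(present)
  # principal axis: axis of a Cn operation of maximal order
  ax_n <- NULL
  for (o in ops) if (o$class == paste0("C", n)) { ax_n <- o$axis; break }
  c2_perp <- 0L
  for (o in ops) {
    if (o$class == "C2" && !is.null(ax_n) &&
        abs(sum(o$axis * ax_n)) < 1e-3) c2_perp <- c2_perp + 1L
  }
  sigma_h <- FALSE; sigma_v <- 0L
  for (o in ops) {
    if (o$class == "sigma" && !is.null(ax_n)) {
      al <- abs(sum(o$axis * ax_n))
      if (al > 1 - 1e-3) sigma_h <- TRUE
      if (al < 1e-3) sigma_v <- sigma_v + 1L
    }
  }
  if (c2_perp >= n && n > 2 || (n == 2 && c2_perp >= 2)) {
    if (sigma_h) return(paste0("D", n, "h"))
    if (sigma_v >= n) return(paste0("D", n, "d"))
    return(paste0("D", n))
  }
  if (sigma_h) return(paste0("C", n, "h"))
  if (sigma_v >= n) return(paste0("C", n, "v"))
  s2n <- paste0("S", 2L * n)
  if (s2n %in% names(cnt) && cnt[s2n] > 0) return(paste0("S", 2L * n))
  paste0("C", n)
}

#' @export
print.xtal_symmetry <- function(x, ...) {
  nz <- x$count_by_class[x$count_by_class > 0]
  cat(sprintf("<xtal_symmetry %s: order %d (%s)%s>\n", x$point_group_name,
              x$total_operations,
              paste(names(nz), nz, sep = "=", collapse = " "),
              if (x$linear) ", linear (capped)" else ""))
  invisible(x)
}

#' Fixed-schema symmetry feature vector
#'
#' @param report an `xtal_symmetry` object from [detect_symmetry()].
#' @return Named numeric vector: `sym_total`, then one count per operator
#'   class (`sym_E`, `sym_C2`..`sym_C8`, `sym_sigma`, `sym_i`,
#'   `sym_S3`..`sym_S8`); identical length for all molecules.
#' @export
symmetry_features <- function(report) {
  if (!inherits(report, "xtal_symmetry")) {
    stop("report must come from detect_symmetry()")
  }
  cnt <- report$count_by_class
  stats::setNames(c(report$total_operations, as.numeric(cnt)),
                  c("sym_total", paste0("sym_", names(cnt))))
}
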