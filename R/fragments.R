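# Fragment grammar for the synthetic molecule generator.
#
# Molecules are assembled from a curated scaffold library (rings, chains,
# small pi systems) plus substituents covering the 18 functional-group
# classes counted by the chemical descriptor block. Scaffolds carry exact
# template 3D geometries for their heavy atoms; substituents carry local
# geometries expressed in a frame where the link atom sits at the origin and
# the scaffold lies along -z. Hydrogens are placed automatically from
# standard valences and idealised angles, so every emitted molecule is
# valence-correct and its conformer is a deterministic function of the
# (scaffold, substituent) choice.

# ---- internal molecule representation -------------------------------------
# list(elements = character, coords = n x 3 matrix,
#      bonds = data.frame(i, j, order, aromatic), h_override = named int)

.new_bonds <- function(i = integer(), j = integer(), order = numeric(),
                       aromatic = logical()) {
  data.frame(i = as.integer(i), j = as.integer(j),
             order = as.numeric(order), aromatic = as.logical(aromatic))
}

.ring_bonds <- function(n, order = 1, aromatic = FALSE, offset = 0L) {
  .new_bonds(offset + seq_len(n), offset + c(seq_len(n - 1) + 1L, 1L),
             rep(order, length.out = n), rep(aromatic, n))
}

.bond_order_sums <- function(n_atoms, bonds) {
  eff <- ifelse(bonds$aromatic, 1.5, bonds$order)
  s <- numeric(n_atoms)
  for (r in seq_len(nrow(bonds))) {
    s[bonds$i[r]] <- s[bonds$i[r]] + eff[r]
    s[bonds$j[r]] <- s[bonds$j[r]] + eff[r]
  }
  s
}

.neighbors <- function(bonds, i) {
  c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])
}

# Cycle rank (number of independent rings) of a bond subgraph.
.cycle_rank <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(0L)
  verts <- sort(unique(c(bonds$i, bonds$j)))
  parent <- seq_len(n_atoms)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(bonds))) {
    a <- find(bonds$i[r]); b <- find(bonds$j[r])
    if (a != b) parent[a] <- b
  }
  n_comp <- length(unique(vapply(verts, find, integer(1))))
  nrow(bonds) - length(verts) + n_comp
}

# ---- automatic placement of missing single-bond directions ----------------

.free_directions <- function(elements, coords, bonds, i, m) {
  if (m < 1L) return(matrix(numeric(0), 0, 3))
  nb <- .neighbors(bonds, i)
  k <- length(nb)
  inc <- bonds[bonds$i == i | bonds$j == i, , drop = FALSE]
  sp <- if (any(inc$order >= 3)) "sp"
        else if (any(inc$order == 2) || any(inc$aromatic)) "sp2"
        else "sp3"
  theta <- switch(sp, sp = pi, sp2 = 120 * pi / 180, sp3 = 109.47 * pi / 180)
  U <- t(vapply(nb, function(j) .unit(coords[j, ] - coords[i, ]), numeric(3)))
  if (k == 0L) stop("cannot place bonds on an isolated atom")
  if (k == 1L) {
    u <- U[1, ]
    if (sp == "sp") return(matrix(-u, m, 3, byrow = TRUE)[seq_len(m), , drop = FALSE])
    a <- -u
    phi <- pi - theta            # angle of new bonds from the anti direction
    p1 <- .perp(u)
    p2 <- c(a[2] * p1[3] - a[3] * p1[2], a[3] * p1[1] - a[1] * p1[3],
            a[1] * p1[2] - a[2] * p1[1])
    out <- matrix(0, m, 3)
    for (t in seq_len(m)) {
      psi <- 2 * pi * (t - 1) / m
      out[t, ] <- cos(phi) * a + sin(phi) * (cos(psi) * p1 + sin(psi) * p2)
    }
    return(out)
  }
  if (k == 2L) {
    s <- U[1, ] + U[2, ]
    if (.vnorm(s) < 1e-8) {            # near-linear pair; arbitrary normal
      w <- .perp(U[1, ])
    } else w <- -.unit(s)
    if (m == 1L) return(matrix(w, 1, 3))
    cr <- c(U[1, 2] * U[2, 3] - U[1, 3] * U[2, 2],
            U[1, 3] * U[2, 1] - U[1, 1] * U[2, 3],
            U[1, 1] * U[2, 2] - U[1, 2] * U[2, 1])
    p <- if (.vnorm(cr) < 1e-8) .perp(w) else .unit(cr)
    alpha <- theta / 2
    return(rbind(cos(alpha) * w + sin(alpha) * p,
                 cos(alpha) * w - sin(alpha) * p)[seq_len(m), , drop = FALSE])
  }
  if (k == 3L && m == 1L) {
    s <- colSums(U)
    if (.vnorm(s) < 1e-8) s <- .perp(U[1, ])  # planar centre: pick a side
    return(matrix(-.unit(s), 1, 3))
  }
  stop("no free valence direction available (", k, " neighbours, ", m, " requested)")
}

.h_bond_length <- function(element) {
  switch(element, C = 1.09, N = 1.01, O = 0.96, S = 1.34, 1.00)
}

.link_bond_length <- function(e1, e2) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  len <- c(`C-C` = 1.50, `C-O` = 1.40, `C-N` = 1.42, `C-S` = 1.77,
           `C-F` = 1.35, `C-Cl` = 1.74, `Br-C` = 1.90, `C-I` = 2.10,
           `N-N` = 1.40, `N-O` = 1.40, `O-P` = 1.60)
  if (key %in% names(len)) unname(len[key]) else 1.50
}

# Append explicit hydrogens to every heavy atom with unused valence.
.place_hydrogens <- function(mol) {
  els <- mol$elements; coords <- mol$coords; bonds <- mol$bonds
  n_heavy <- length(els)
  bos <- .bond_order_sums(n_heavy, bonds)
  vals <- .default_valences(els)
  h_xyz <- list(); h_at <- integer()
  for (i in seq_len(n_heavy)) {
    target <- max(vals[i], ceiling(bos[i] - 1e-9))
    nh <- max(0L, as.integer(round(target - bos[i])))
    ov <- mol$h_override[[as.character(i)]]
    if (!is.null(ov)) nh <- as.integer(ov)
    if (nh == 0L) next
    dirs <- .free_directions(els, coords, bonds, i, nh)
    len <- .h_bond_length(els[i])
    for (t in seq_len(nh)) {
      h_xyz[[length(h_xyz) + 1L]] <- coords[i, ] + len * dirs[t, ]
      h_at <- c(h_at, i)
    }
  }
  if (length(h_at)) {
    els <- c(els, rep("H", length(h_at)))
    coords <- rbind(coords, do.call(rbind, h_xyz))
    bonds <- rbind(bonds, .new_bonds(h_at, n_heavy + seq_along(h_at),
                                     rep(1, length(h_at)),
                                     rep(FALSE, length(h_at))))
  }
  list(elements = els, coords = coords, bonds = bonds)
}

# ---- geometry builders -----------------------------------------------------

# Regular n-ring in the xy-plane; optional per-atom z pucker, with the
# projected radius shrunk so neighbouring atoms still sit ~`bond` apart.
.ring_coords <- function(n, bond, z = rep(0, n)) {
  R <- bond / (2 * sin(pi / n))
  if (length(unique(z)) > 1) {
    dz <- abs(z[1] - z[2])
    R <- sqrt(max(bond^2 - dz^2, 0.25)) / (2 * sin(pi / n))
  }
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(R * cos(th), R * sin(th), z)
}

.chain_coords <- function(n, bond = 1.53, angle = 111 * pi / 180) {
  x <- (seq_len(n) - 1) * bond * sin(angle / 2)
  y <- (seq_len(n) %% 2) * bond * cos(angle / 2)
  cbind(x, y, 0)
}

# ---- scaffold library ------------------------------------------------------
# Each scaffold: elements/coords/bonds for the heavy-atom skeleton, a SMILES
# template with {k} placeholders (k-th substitution site), site atom indices,
# optional h_override, and the point-group order of the unsubstituted
# hydrogen-complete scaffold (a latent generator feature).

.scaffold_library <- function() {
  b_ar <- 1.39
  scaf <- list()

  hex <- .ring_coords(6, b_ar)
  scaf$benzene <- list(
    elements = rep("C", 6), coords = hex, bonds = .ring_bonds(6, 1, TRUE),
    smiles = "c1{1}c{2}c{3}c{4}c{5}c1{6}", sites = 1:6, sym_order = 24)

  scaf$pyridine <- list(
    elements = c("N", rep("C", 5)), coords = hex, bonds = .ring_bonds(6, 1, TRUE),
    smiles = "n1c{1}c{2}c{3}c{4}c1{5}", sites = 2:6, sym_order = 4)

  scaf$pyrimidine <- list(
    elements = c("N", "C", "N", "C", "C", "C"), coords = hex,
    bonds = .ring_bonds(6, 1, TRUE),
    smiles = "n1c{1}nc{2}c{3}c1{4}", sites = c(2L, 4L, 5L, 6L), sym_order = 4)

  pent <- .ring_coords(5, 1.37)
  scaf$furan <- list(
    elements = c("O", rep("C", 4)), coords = pent, bonds = .ring_bonds(5, 1, TRUE),
    smiles = "o1c{1}c{2}c{3}c1{4}", sites = 2:5, sym_order = 4)

  scaf$thiophene <- list(
    elements = c("S", rep("C", 4)), coords = .ring_coords(5, 1.40),
    bonds = .ring_bonds(5, 1, TRUE),
    smiles = "s1c{1}c{2}c{3}c1{4}", sites = 2:5, sym_order = 4)

  scaf$pyrrole <- list(
    elements = c("N", rep("C", 4)), coords = pent, bonds = .ring_bonds(5, 1, TRUE),
    smiles = "[nH]1c{1}c{2}c{3}c1{4}", sites = 2:5,
    h_override = c(`1` = 1L), sym_order = 4)

  chair_z <- rep(c(0.25, -0.25), 3)
  scaf$cyclohexane <- list(
    elements = rep("C", 6), coords = .ring_coords(6, 1.53, chair_z),
    bonds = .ring_bonds(6, 1, FALSE),
    smiles = "C1{1}C{2}C{3}C{4}C{5}C1{6}", sites = 1:6, sym_order = 12)

  env_z <- c(0.45, 0, 0, 0, 0)   # envelope pucker: one flap atom lifted
  scaf$cyclopentane <- list(
    elements = rep("C", 5), coords = .ring_coords(5, 1.53, env_z),
    bonds = .ring_bonds(5, 1, FALSE),
    smiles = "C1{1}C{2}C{3}C{4}C1{5}", sites = 1:5, sym_order = 2)

  scaf$cyclopropane <- list(
    elements = rep("C", 3), coords = .ring_coords(3, 1.51),
    bonds = .ring_bonds(3, 1, FALSE),
    smiles = "C1{1}C{2}C1{3}", sites = 1:3, sym_order = 12)

  scaf$cyclobutane <- list(
    elements = rep("C", 4), coords = .ring_coords(4, 1.55),
    bonds = .ring_bonds(4, 1, FALSE),
    smiles = "C1{1}C{2}C{3}C1{4}", sites = 1:4, sym_order = 16)

  scaf$piperidine <- list(
    elements = c("N", rep("C", 5)), coords = .ring_coords(6, 1.52, chair_z),
    bonds = .ring_bonds(6, 1, FALSE),
    smiles = "N1C{1}C{2}C{3}C{4}C1{5}", sites = 2:6, sym_order = 2)

  scaf$tetrahydrofuran <- list(
    elements = c("O", rep("C", 4)), coords = .ring_coords(5, 1.52, env_z),
    bonds = .ring_bonds(5, 1, FALSE),
    smiles = "O1C{1}C{2}C{3}C1{4}", sites = 2:5, sym_order = 2)

  # naphthalene: two fused aromatic hexagons sharing the edge 1-6.
  # ring1 atoms 1..6 at angles 30,90,...,330 about the origin (1 and 6 are
  # the fusion carbons); ring2 adds atoms 7..10 at angles 90,270,330,30
  # about the second ring centre.
  ang1 <- (30 + 60 * 0:5) * pi / 180
  ring1 <- cbind(b_ar * cos(ang1), b_ar * sin(ang1), 0)
  c2x <- sqrt(3) * b_ar
  ang2 <- c(90, 270, 330, 30) * pi / 180
  ring2 <- cbind(c2x + b_ar * cos(ang2), b_ar * sin(ang2), 0)
  naph_bonds <- .new_bonds(
    i = c(1L, 2L, 3L, 4L, 5L, 6L, 1L, 7L, 10L, 9L, 8L),
    j = c(2L, 3L, 4L, 5L, 6L, 1L, 7L, 10L, 9L, 8L, 6L),
    order = rep(1, 11), aromatic = rep(TRUE, 11))
  # smiles walk c1{b}c{b}c{a}c2c{a}cccc2c1: slots 1,2 = beta CH (geometry
  # atoms 3,4), slots 3,4 = alpha CH (geometry atoms 2,5)
  scaf$naphthalene <- list(
    elements = rep("C", 10), coords = rbind(ring1, ring2), bonds = naph_bonds,
    smiles = "c1{1}c{2}c{3}c2c{4}cccc2c1", sites = c(3L, 4L, 2L, 5L),
    sym_order = 8)

  scaf$ethene <- list(
    elements = c("C", "C"), coords = rbind(c(0, 0, 0), c(1.33, 0, 0)),
    bonds = .new_bonds(1, 2, 2, FALSE),
    smiles = "C{1}{2}=C{3}{4}", sites = c(1L, 1L, 2L, 2L), sym_order = 8)

  bd <- .chain_coords(4, 1.45)
  scaf$butadiene <- list(
    elements = rep("C", 4), coords = bd,
    bonds = .new_bonds(1:3, 2:4, c(2, 1, 2), FALSE),
    smiles = "C{1}=C{2}C{3}=C{4}", sites = 1:4, sym_order = 4)

  scaf$butane <- list(
    elements = rep("C", 4), coords = .chain_coords(4),
    bonds = .new_bonds(1:3, 2:4, 1, FALSE),
    smiles = "C{1}C{2}C{3}C{4}", sites = 1:4, sym_order = 4)

  scaf$hexane <- list(
    elements = rep("C", 6), coords = .chain_coords(6),
    bonds = .new_bonds(1:5, 2:6, 1, FALSE),
    smiles = "C{1}C{2}C{3}C{4}C{5}C{6}", sites = 1:6, sym_order = 4)

  # neopentane core: central sp3 carbon + 4 methyl carbons (tetrahedral)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  scaf$neopentane <- list(
    elements = rep("C", 5), coords = rbind(c(0, 0, 0), 1.53 * tet),
    bonds = .new_bonds(rep(1L, 4), 2:5, 1, FALSE),
    smiles = "C(C{1})(C{2})(C{3})C{4}", sites = 2:5, sym_order = 24)

  # biphenyl: second ring twisted 45 degrees about the inter-ring axis
  r1 <- .ring_coords(6, b_ar)
  twist <- .rotmat(c(1, 0, 0), pi / 4)
  r2 <- sweep(.ring_coords(6, b_ar) %*% t(twist), 2,
              c(2 * b_ar + 1.49, 0, 0), `+`)
  # connect r1 atom 1 (at angle 0, x = +R) to r2 atom 10 (at angle 180);
  # substitution offered at the two para positions (geometry atoms 4 and 7)
  scaf$biphenyl <- list(
    elements = rep("C", 12), coords = rbind(r1, r2),
    bonds = rbind(.ring_bonds(6, 1, TRUE), .ring_bonds(6, 1, TRUE, offset = 6L),
                  .new_bonds(1L, 10L, 1, FALSE)),
    smiles = "c1cc{1}ccc1-c2cc{2}ccc2", sites = c(4L, 7L),
    sym_order = 4)

  scaf$ethyne <- list(
    elements = c("C", "C"), coords = rbind(c(0, 0, 0), c(1.20, 0, 0)),
    bonds = .new_bonds(1, 2, 3, FALSE),
    smiles = "C{1}#C{2}", sites = c(1L, 2L), sym_order = 20)

  for (nm in names(scaf)) scaf[[nm]]$name <- nm
  scaf
}

# ---- substituent library ---------------------------------------------------
# Local frames: link atom (index 1) at the origin, scaffold along -z.

.sub_dir <- function(alpha_deg, psi_deg = 0) {
  a <- alpha_deg * pi / 180; p <- psi_deg * pi / 180
  c(sin(a) * cos(p), sin(a) * sin(p), cos(a))
}

.substituent_library <- function() {
  t3 <- 70.53   # 180 - 109.47: sp3 continuation angle from +z
  t2 <- 60      # 180 - 120:    sp2 continuation angle from +z
  sub <- function(smiles, elements, coords, bonds, tags = c(), hb = 0) {
    list(smiles = smiles, elements = elements,
         coords = matrix(coords, ncol = 3, byrow = TRUE), bonds = bonds,
         tags = tags, hb = hb)
  }
  O <- c(0, 0, 0)
  s <- list()

  s$methyl   <- sub("C", "C", O, .new_bonds())
  s$ethyl    <- sub("CC", c("C", "C"), c(O, 1.53 * .sub_dir(t3)),
                    .new_bonds(1, 2, 1, FALSE))
  s$hydroxyl <- sub("O", "O", O, .new_bonds(), tags = c(alcohol = 1), hb = 2)
  s$hydroxymethyl <- sub("CO", c("C", "O"), c(O, 1.42 * .sub_dir(t3)),
                         .new_bonds(1, 2, 1, FALSE), tags = c(alcohol = 1), hb = 2)
  s$amino    <- sub("N", "N", O, .new_bonds(), tags = c(amine = 1), hb = 2)
  s$methylamino <- sub("NC", c("N", "C"), c(O, 1.45 * .sub_dir(t3)),
                       .new_bonds(1, 2, 1, FALSE), tags = c(amine = 1), hb = 1)
  s$fluoro   <- sub("F", "F", O, .new_bonds(), tags = c(halide = 1))
  s$chloro   <- sub("Cl", "Cl", O, .new_bonds(), tags = c(halide = 1))
  s$bromo    <- sub("Br", "Br", O, .new_bonds(), tags = c(halide = 1))
  s$iodo     <- sub("I", "I", O, .new_bonds(), tags = c(halide = 1))
  s$trifluoromethyl <- sub("C(F)(F)F", c("C", "F", "F", "F"),
                           c(O, 1.35 * .sub_dir(t3, 0), 1.35 * .sub_dir(t3, 120),
                             1.35 * .sub_dir(t3, 240)),
                           .new_bonds(c(1, 1, 1), 2:4, 1, FALSE),
                           tags = c(halide = 3))
  s$formyl   <- sub("C=O", c("C", "O"), c(O, 1.22 * .sub_dir(t2)),
                    .new_bonds(1, 2, 2, FALSE), tags = c(aldehyde = 1), hb = 1)
  s$acetyl   <- sub("C(=O)C", c("C", "O", "C"),
                    c(O, 1.22 * .sub_dir(t2, 0), 1.50 * .sub_dir(t2, 180)),
                    .new_bonds(c(1, 1), c(2, 3), c(2, 1), FALSE),
                    tags = c(ketone = 1), hb = 1)
  s$carboxyl <- sub("C(=O)O", c("C", "O", "O"),
                    c(O, 1.22 * .sub_dir(t2, 0), 1.33 * .sub_dir(t2, 180)),
                    .new_bonds(c(1, 1), c(2, 3), c(2, 1), FALSE),
                    tags = c(carboxylic_acid = 1), hb = 2)
  s$methoxycarbonyl <- sub("C(=O)OC", c("C", "O", "O", "C"),
                           c(O, 1.22 * .sub_dir(t2, 0), 1.33 * .sub_dir(t2, 180),
                             1.33 * .sub_dir(t2, 180) + 1.43 * .sub_dir(10, 180)),
                           .new_bonds(c(1, 1, 3), c(2, 3, 4), c(2, 1, 1), FALSE),
                           tags = c(ester = 1), hb = 1)
  s$acetoxy  <- sub("OC(=O)C", c("O", "C", "O", "C"),
                    c(O, 1.36 * .sub_dir(t3),
                      1.36 * .sub_dir(t3) + 1.22 * .sub_dir(t3 + 60, 180),
                      1.36 * .sub_dir(t3) + 1.50 * .sub_dir(t3 - 55, 0)),
                    .new_bonds(c(1, 2, 2), c(2, 3, 4), c(1, 2, 1), FALSE),
                    tags = c(ester = 1), hb = 1)
  s$carbamoyl <- sub("C(=O)N", c("C", "O", "N"),
                     c(O, 1.22 * .sub_dir(t2, 0), 1.35 * .sub_dir(t2, 180)),
                     .new_bonds(c(1, 1), c(2, 3), c(2, 1), FALSE),
                     tags = c(amide = 1), hb = 3)
  s$acetamido <- sub("NC(=O)C", c("N", "C", "O", "C"),
                     c(O, 1.35 * .sub_dir(t3),
                       1.35 * .sub_dir(t3) + 1.22 * .sub_dir(t3 + 60, 180),
                       1.35 * .sub_dir(t3) + 1.50 * .sub_dir(t3 - 55, 0)),
                     .new_bonds(c(1, 2, 2), c(2, 3, 4), c(1, 2, 1), FALSE),
                     tags = c(amide = 1), hb = 2)
  s$methoxy  <- sub("OC", c("O", "C"), c(O, 1.43 * .sub_dir(t3)),
                    .new_bonds(1, 2, 1, FALSE), tags = c(ether = 1), hb = 1)
  s$nitro    <- sub("N(=O)=O", c("N", "O", "O"),
                    c(O, 1.21 * .sub_dir(t2, 0), 1.21 * .sub_dir(t2, 180)),
                    .new_bonds(c(1, 1), c(2, 3), c(2, 2), FALSE),
                    tags = c(nitro = 1), hb = 1)
  s$cyano    <- sub("C#N", c("C", "N"), c(O, 1.16 * .sub_dir(0)),
                    .new_bonds(1, 2, 3, FALSE), tags = c(nitrile = 1), hb = 1)
  s$iminomethyl <- sub("C=N", c("C", "N"), c(O, 1.28 * .sub_dir(t2)),
                       .new_bonds(1, 2, 2, FALSE), tags = c(imine = 1), hb = 1)
  s$thiol    <- sub("S", "S", O, .new_bonds(), tags = c(thiol = 1), hb = 1)
  s$methylthio <- sub("SC", c("S", "C"), c(O, 1.81 * .sub_dir(t3)),
                      .new_bonds(1, 2, 1, FALSE), tags = c(thioether = 1))
  s$thiocarbamoyl <- sub("C(=S)N", c("C", "S", "N"),
                         c(O, 1.67 * .sub_dir(t2, 0), 1.35 * .sub_dir(t2, 180)),
                         .new_bonds(c(1, 1), c(2, 3), c(2, 1), FALSE),
                         tags = c(thiocarbonyl = 1), hb = 2)
  s$methylsulfonyl <- sub("S(=O)(=O)C", c("S", "O", "O", "C"),
                          c(O, 1.44 * .sub_dir(t3, 60), 1.44 * .sub_dir(t3, 300),
                            1.78 * .sub_dir(t3, 180)),
                          .new_bonds(c(1, 1, 1), c(2, 3, 4), c(2, 2, 1), FALSE),
                          tags = c(sulfone = 1), hb = 1)
  s$phosphonooxy <- sub("OP(=O)(O)O", c("O", "P", "O", "O", "O"),
                        c(O, 1.60 * .sub_dir(t3),
                          1.60 * .sub_dir(t3) + 1.48 * .sub_dir(t3 + 40, 180),
                          1.60 * .sub_dir(t3) + 1.60 * .sub_dir(t3 - 50, 60),
                          1.60 * .sub_dir(t3) + 1.60 * .sub_dir(t3 - 50, 300)),
                        .new_bonds(c(1, 2, 2, 2), c(2, 3, 4, 5),
                                   c(1, 2, 1, 1), FALSE),
                        tags = c(phosphoric_acid = 1), hb = 3)
  s$anhydridyl <- sub("C(=O)OC(=O)C", c("C", "O", "O", "C", "O", "C"),
                      c(O, 1.22 * .sub_dir(t2, 0), 1.36 * .sub_dir(t2, 180),
                        1.36 * .sub_dir(t2, 180) + 1.36 * .sub_dir(10, 180),
                        1.36 * .sub_dir(t2, 180) + 1.36 * .sub_dir(10, 180) +
                          1.22 * .sub_dir(70, 90),
                        1.36 * .sub_dir(t2, 180) + 1.36 * .sub_dir(10, 180) +
                          1.50 * .sub_dir(70, 270)),
                      .new_bonds(c(1, 1, 3, 4, 4), c(2, 3, 4, 5, 6),
                                 c(2, 1, 1, 2, 1), FALSE),
                      tags = c(anhydride = 1), hb = 2)
  s$vinyl    <- sub("C=C", c("C", "C"), c(O, 1.33 * .sub_dir(t2)),
                    .new_bonds(1, 2, 2, FALSE))
  # phenyl ring in the xz-plane, link vertex at the origin, extending along +z
  Rb <- 1.39
  th6 <- (0:5) * pi / 3
  s$phenyl <- sub("c9ccccc9", rep("C", 6),
                  as.numeric(t(cbind(Rb * sin(th6), 0, Rb * (1 - cos(th6))))),
                  .ring_bonds(6, 1, TRUE))

  for (nm in names(s)) s[[nm]]$name <- nm
  s
}

# Library construction is pure but not cheap; memoize per session.
.fragment_cache <- new.env(parent = emptyenv())

.scaffolds <- function() {
  if (is.null(.fragment_cache$scaffolds)) {
    .fragment_cache$scaffolds <- .scaffold_library()
  }
  .fragment_cache$scaffolds
}

.substituents <- function() {
  if (is.null(.fragment_cache$substituents)) {
    .fragment_cache$substituents <- .substituent_library()
  }
  .fragment_cache$substituents
}

# 18 functional-group classes tracked by the chemical feature block.
.functional_group_names <- function() {
  c("alcohol", "amide", "imine", "nitro", "nitrile", "amine", "ether",
    "aldehyde", "halide", "ketone", "carboxylic_acid", "anhydride", "ester",
    "thiol", "thiocarbonyl", "thioether", "sulfone", "phosphoric_acid")
}

#' Fragment grammar inventory
#'
#' Names of the scaffolds and substituents in the built-in fragment grammar
#' from which the synthetic generator assembles molecules, and the 18
#' functional-group classes the substituents cover.
#'
#' @return List with character vectors `scaffolds`, `substituents`, `groups`.
#' @export
fragment_library <- function() {
  list(scaffolds = names(.scaffolds()),
       substituents = names(.substituents()),
       groups = .functional_group_names())
}

# ---- molecule assembly -----------------------------------------------------

.fill_smiles <- function(template, n_sites, branches) {
  out <- template
  for (k in seq_len(n_sites)) {
    rep_ <- if (!is.null(branches[[as.character(k)]]))
      paste0("(", branches[[as.character(k)]], ")") else ""
    out <- gsub(paste0("{", k, "}"), rep_, out, fixed = TRUE)
  }
  out
}

# Compose a molecule: scaffold name + named substituent assignment
# (names = site slot as character, values = substituent names).
.compose_molecule <- function(scaffold_name, site_subs = character()) {
  scaf <- .scaffolds()[[scaffold_name]]
  if (is.null(scaf)) stop("unknown scaffold: ", scaffold_name)
  subs_lib <- .substituents()
  els <- scaf$elements
  coords <- scaf$coords
  bonds <- scaf$bonds
  h_override <- as.list(scaf$h_override)
  names(h_override) <- names(scaf$h_override)
  branches <- list()
  for (slot in names(site_subs)) {
    sub <- subs_lib[[site_subs[[slot]]]]
    if (is.null(sub)) stop("unknown substituent: ", site_subs[[slot]])
    site <- scaf$sites[as.integer(slot)]
    d <- .free_directions(els, coords, bonds, site, 1L)[1, ]
    len <- .link_bond_length(els[site], sub$elements[1])
    base <- nrow(coords)
    A <- .align_z_to(d)
    sub_coords <- sub$coords %*% t(A)
    sub_coords <- sweep(sub_coords, 2, coords[site, ] + len * d, `+`)
    els <- c(els, sub$elements)
    coords <- rbind(coords, sub_coords)
    if (nrow(sub$bonds) > 0) {
      sb <- sub$bonds
      sb$i <- sb$i + base; sb$j <- sb$j + base
      bonds <- rbind(bonds, sb)
    }
    bonds <- rbind(bonds, .new_bonds(site, base + 1L, 1, FALSE))
    branches[[slot]] <- sub$smiles
  }
  mol <- list(elements = els, coords = coords, bonds = bonds,
              h_override = h_override)
  mol <- .place_hydrogens(mol)
  mol$smiles <- .fill_smiles(scaf$smiles, length(scaf$sites), branches)
  mol$scaffold <- scaffold_name
  mol$substituents <- unname(unlist(site_subs))
  mol
}

# Latent generator features (used for the planted label rule).
.latent_features <- function(mol, scaf_order) {
  hv <- mol$elements != "H"
  P <- mol$coords
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  sv <- svd(crossprod(X) / nrow(X))
  nrm <- sv$u[, 3]
  planarity <- mean(abs(X %*% nrm))
  subs <- mol$substituents
  lib <- .substituents()
  hb <- if (length(subs)) sum(vapply(subs, function(s) lib[[s]]$hb, numeric(1))) else 0
  sym <- log2(scaf_order) / (1 + length(subs))
  c(planarity = planarity, hb_groups = hb, symmetry = sym)
}
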