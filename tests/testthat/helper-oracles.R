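# Shared test helpers: independent oracles and record/graph builders.

# All element-preserving permutations of 1..n (elements grouped).
element_permutations <- function(elements) {
  perms_of <- function(k) {
    if (k == 1) return(list(1L))
    out <- list()
    for (i in seq_len(k)) {
      for (p in perms_of(k - 1L)) {
        out[[length(out) + 1L]] <- c(i, ifelse(p >= i, p + 1L, p))
      }
    }
    out
  }
  groups <- split(seq_along(elements), elements)
  out <- list(integer(length(elements)))
  for (g in groups) {
    new <- list()
    for (base in out) {
      for (p in perms_of(length(g))) {
        v <- base
        v[g] <- g[p]
        new[[length(new) + 1L]] <- v
      }
    }
    out <- new
  }
  out
}

# Brute-force symmetry oracle: tests every element-preserving atom
# permutation for realizability by a proper or improper orthogonal transform
# (Kabsch-style superposition, residual <= tol). Counts distinct operations.
oracle_symmetry_order <- function(elements, coordinates, tol = 0.05) {
  m <- atomic_weights(elements)
  X <- as.matrix(coordinates)
  X <- sweep(X, 2, colSums(X * m) / sum(m))
  mats <- list()
  for (perm in element_permutations(elements)) {
    pr <- xtalgroup:::.procrustes_residuals(X, X[perm, , drop = FALSE])
    for (side in pr) {
      if (side$max_disp <= tol) mats[[length(mats) + 1L]] <- side$O
    }
  }
  mats <- xtalgroup:::.dedupe_matrices(mats)
  length(mats)
}

# Naive per-example tally for the 1/N-scaled precision/recall rules.
oracle_scaled_pr <- function(truths, P) {
  n <- ncol(P)
  classes <- sort(unique(c(truths, as.integer(P))))
  tp <- setNames(numeric(length(classes)), classes)
  fp <- tp; fn <- tp
  for (i in seq_along(truths)) {
    hit <- truths[i] %in% P[i, ]
    for (cl in P[i, ]) {
      if (hit && cl == truths[i]) next
      fp[as.character(cl)] <- fp[as.character(cl)] + 1 / n
    }
    if (hit) tp[as.character(truths[i])] <- tp[as.character(truths[i])] + 1
    else fn[as.character(truths[i])] <- fn[as.character(truths[i])] + 1
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Minimal record with metadata only (2 dummy atoms), for curation tests.
meta_record <- function(id, family, sg, rank = 1L, chiral = FALSE) {
  molecule_record(record_id = id, family_id = family, smiles = "CC",
                  elements = c("C", "C"),
                  coordinates = rbind(c(0, 0, 0), c(1.5, 0, 0)),
                  space_group = sg, deposition_rank = rank, chiral = chiral,
                  bonds = xtalgroup:::.new_bonds(1L, 2L, 1, FALSE))
}

# A record built from the fragment grammar (full geometry + bonds).
grammar_record <- function(scaffold, site_subs = character(), sg = 14L,
                           id = "t1") {
  mol <- xtalgroup:::.compose_molecule(scaffold, site_subs)
  molecule_record(record_id = id, family_id = id, smiles = mol$smiles,
                  elements = mol$elements, coordinates = mol$coords,
                  space_group = sg, bonds = mol$bonds)
}

# Feature table from a plain matrix (for selection/metric tests).
feature_table <- function(V, class = "general") {
  if (is.null(rownames(V))) rownames(V) <- sprintf("r%04d", seq_len(nrow(V)))
  cls <- setNames(rep(class, ncol(V)), colnames(V))
  xtalgroup:::.new_feature_table(V, cls)
}

# Random point cluster with mixed elements (asymmetric with prob ~ 1).
random_cluster <- function(n_atoms, seed) {
  set.seed(seed)
  els <- sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE)
  list(elements = els,
       coordinates = matrix(stats::runif(3 * n_atoms, -2, 2), ncol = 3))
}
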