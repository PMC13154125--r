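# Descriptor blocks: general counts, inertia-based shape, SMARTS chemical
# counts + TPSA, table assembly and feature selection.

test_that("general features count atoms and rings correctly", {
  bz <- grammar_record("benzene")
  g <- general_features(bz)
  expect_equal(unname(g["n_atoms"]), 12)
  expect_equal(unname(g["n_rings"]), 1)
  expect_equal(unname(g["n_aromatic_rings"]), 1)
  expect_equal(unname(g["mol_weight"]), 78.11, tolerance = 0.01)

  naph <- grammar_record("naphthalene")
  gn <- general_features(naph)
  expect_equal(unname(gn["n_rings"]), 2)
  expect_equal(unname(gn["n_aromatic_rings"]), 2)

  chx <- grammar_record("cyclohexane")
  expect_equal(unname(general_features(chx)["n_aromatic_rings"]), 0)

  # methane built by hand: 5 atoms, no rings; H2O molecular weight
  fx <- fixture_geometries()$methane
  met <- molecule_record("m", "m", "C", fx$elements, fx$coordinates, 14L,
                         bonds = xtalgroup:::.new_bonds(rep(1L, 4), 2:5, 1,
                                                        FALSE))
  gm <- general_features(met)
  expect_equal(unname(gm["n_atoms"]), 5)
  expect_equal(unname(gm["n_rings"]), 0)
  expect_equal(sum(atomic_weights(c("O", "H", "H"))), 18.015,
               tolerance = 0.01)
})

test_that("shape descriptors hit the analytic special cases", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  s <- shape_descriptors(rep("C", 4), tet)
  expect_equal(s$npr1, 1, tolerance = 1e-10)
  expect_equal(s$npr2, 1, tolerance = 1e-10)
  expect_equal(s$asphericity, 0, tolerance = 1e-10)
  expect_equal(s$eccentricity, 0, tolerance = 1e-10)
  expect_true(s$degenerate_plane)

  lin <- shape_descriptors(rep("C", 5), cbind(0:4, 0, 0))
  expect_equal(lin$npr1, 0, tolerance = 1e-10)
  expect_equal(lin$npr2, 1, tolerance = 1e-10)
  expect_equal(lin$asphericity, 0.5, tolerance = 1e-10)
  expect_equal(lin$eccentricity, 1, tolerance = 1e-10)

  th <- (0:5) * pi / 3
  hx <- shape_descriptors(rep("C", 6), cbind(cos(th), sin(th), 0))
  expect_equal(hx$npr1, 0.5, tolerance = 1e-10)   # perpendicular-axis theorem
  expect_equal(hx$npr2, 0.5, tolerance = 1e-10)
  expect_equal(hx$planarity, 0)

  expect_error(shape_descriptors(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0))),
               ">= 3 atoms")
})

test_that("shape bounds hold on random point clouds", {
  set.seed(41)
  for (rep in 1:1000) {
    n <- sample(4:12, 1)
    els <- sample(c("C", "N", "O"), n, replace = TRUE)
    s <- shape_descriptors(els, matrix(rnorm(3 * n, sd = 2), ncol = 3))
    expect_true(s$npr1 <= s$npr2 + 1e-12 && s$npr2 <= 1 + 1e-12)
    expect_true(s$npr1 + s$npr2 >= 1 - 1e-12)   # moment triangle rule
    expect_true(s$asphericity >= -1e-12 && s$asphericity <= 1 + 1e-12)
    expect_true(s$eccentricity >= -1e-12 && s$eccentricity <= 1 + 1e-12)
    expect_true(s$planarity >= 0)
  }
})

test_that("chemical features match hand-derived counts", {
  b <- chemical_features("c1ccccc1")
  expect_true(all(b == 0))
  e <- chemical_features("CCO")
  expect_equal(unname(e["alcohol"]), 1)
  expect_equal(sum(e[setdiff(names(e), c("alcohol", "tpsa"))]), 0)
  expect_equal(unname(e["tpsa"]), 20.23, tolerance = 1e-6)
  a <- chemical_features("CC(=O)Oc1ccccc1C(=O)O")   # aspirin
  expect_equal(unname(a["carboxylic_acid"]), 1)
  expect_equal(unname(a["ester"]), 1)
  expect_equal(unname(a["ether"]), 0)
  expect_equal(unname(a["alcohol"]), 0)
  expect_error(chemical_features("not-a-smiles("), "SMILES")
})

test_that("chemical counts agree with the grammar's group tags", {
  subs <- xtalgroup:::.substituents()
  groups <- fragment_library()$groups
  for (nm in names(subs)) {
    rec <- grammar_record("cyclohexane", c(`1` = nm))
    counts <- chemical_features(rec$smiles)
    tags <- subs[[nm]]$tags
    for (gr in groups) {
      expected <- if (gr %in% names(tags)) unname(tags[gr]) else 0
      expect_equal(unname(counts[gr]), expected,
                   info = paste(nm, gr))
    }
  }
})

test_that("chemical counts are invariant to SMILES atom ordering", {
  cases <- c("c1cc(O)ccc1C(=O)OC", "OC(=O)c1ccccc1N", "CC(=O)NC1CCCCC1")
  canon <- as.character(ChemmineR::sdf2smiles(ChemmineR::smiles2sdf(
    setNames(cases, paste0("c", seq_along(cases))))))
  for (k in seq_along(cases)) {
    expect_equal(chemical_features(cases[k]), chemical_features(canon[k]),
                 info = cases[k])
  }
})

test_that("assembled tables are rigid-motion invariant in the geometric block", {
  ds <- generate_dataset(generator_config(25, seed = 33))
  ft <- assemble_features(ds)
  expect_equal(nrow(ft$values), length(ds))
  expect_false(any(!is.finite(ft$values)))
  expect_setequal(unique(ft$column_class),
                  c("general", "geometric", "chemical"))
  set.seed(8)
  mo <- xtalgroup:::.random_rigid_motion()
  ds2 <- lapply(ds, function(r) {
    r$coordinates <- xtalgroup:::.apply_rigid(r$coordinates, mo)
    r
  })
  ft2 <- assemble_features(ds2)
  expect_lt(max(abs(ft2$values - ft$values)), 1e-8)
})

test_that("records failing a block are excluded with a warning", {
  ds <- generate_dataset(generator_config(6, seed = 34))
  ds[[3]]$coordinates <- ds[[3]]$coordinates * 0   # degenerate geometry
  expect_warning(ft <- assemble_features(ds), "excluded")
  expect_equal(nrow(ft$values), length(ds) - 1L)
  expect_false(ds[[3]]$record_id %in% ft$row_ids)
})

test_that("select_features drops duplicates and constants, keeps the rest", {
  set.seed(9)
  V <- matrix(rnorm(1000 * 6), ncol = 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  V <- cbind(V, dup = V[, 1], const = 1)
  ft <- feature_table(V)
  out <- select_features(ft, corr_threshold = 0.9, var_threshold = 1e-8)
  expect_false("const" %in% colnames(out$values))   # zero variance
  expect_true(xor("dup" %in% colnames(out$values),
                  "f1" %in% colnames(out$values)))  # exactly one of the pair
  expect_true(all(paste0("f", 2:6) %in% colnames(out$values)))
  # re-application reproduces the same drop on another table
  V2 <- matrix(rnorm(50 * 8), ncol = 8, dimnames = list(NULL, colnames(V)))
  out2 <- apply_feature_selection(feature_table(V2), out$selection)
  expect_identical(colnames(out2$values), colnames(out$values))
  # idempotence
  again <- select_features(out, corr_threshold = 0.9, var_threshold = 1e-8)
  expect_identical(colnames(again$values), colnames(out$values))
  expect_error(select_features(feature_table(matrix(1, 10, 2,
    dimnames = list(NULL, c("a", "b"))))), "variance filter")
})
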