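# Synthetic generator: configuration validation, determinism, marginal
# recovery, Sohncke constraint, polymorph families, fixtures and SDF I/O.

test_that("generator configuration validates its invariants", {
  expect_error(generator_config(0), "positive count")
  bad <- c(`14` = 0.6, `2` = 0.5)
  expect_error(generator_config(10, label_marginal = bad), "sum to 1")
  expect_error(generator_config(10, polymorph_rate = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(10, noise_temperature = 0), "positive")
  p <- default_label_marginal(25)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_length(default_label_marginal(10), 10)
})

test_that("identical config and seed give byte-identical datasets", {
  cfg <- generator_config(60, seed = 9)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  cfg2 <- generator_config(60, seed = 10)
  expect_false(identical(generate_dataset(cfg), generate_dataset(cfg2)))
})

test_that("with zero planted weights the marginal is recovered", {
  # binomial 3-SE check on a 10-class uniform marginal, plus chi-square
  # goodness of fit over 5 seeds (at most 1 rejection at alpha = 0.01)
  groups <- names(default_label_marginal(10))
  unif <- setNames(rep(0.1, 10), groups)
  rejections <- 0L
  for (s in 1:5) {
    cfg <- generator_config(20000, label_marginal = unif,
                            planted_weights = list(),
                            polymorph_rate = 0, chiral_fraction = 0,
                            seed = 30 + s)
    obs <- table(factor(record_table(generate_dataset(cfg))$space_group,
                        levels = groups))
    if (s == 1L) {
      se <- sqrt(0.1 * 0.9 / sum(obs))
      expect_true(all(abs(as.numeric(obs) / sum(obs) - 0.1) <= 3 * se))
    }
    pv <- suppressWarnings(stats::chisq.test(as.numeric(obs),
                                             p = rep(0.1, 10))$p.value)
    if (pv < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("chiral records only ever carry Sohncke labels", {
  cfg <- generator_config(400, chiral_fraction = 1, seed = 12)
  tab <- record_table(generate_dataset(cfg))
  expect_true(all(is_sohncke(tab$space_group)))
  # and with the default mixed fraction, only the chiral ones are restricted
  cfg2 <- generator_config(400, chiral_fraction = 0.5, seed = 13)
  tab2 <- record_table(generate_dataset(cfg2))
  expect_true(all(is_sohncke(tab2$space_group[tab2$chiral])))
})

test_that("polymorph families share molecule and id but differ in label", {
  cfg <- generator_config(300, polymorph_rate = 0.5, seed = 14)
  ds <- generate_dataset(cfg)
  tab <- record_table(ds)
  fams <- split(seq_along(ds), tab$family_id)
  n_poly <- 0L
  for (idx in fams) {
    if (length(idx) < 2) next
    n_poly <- n_poly + 1L
    expect_length(idx, 2L)
    expect_identical(ds[[idx[1]]]$smiles, ds[[idx[2]]]$smiles)
    expect_identical(ds[[idx[1]]]$coordinates, ds[[idx[2]]]$coordinates)
    expect_false(ds[[idx[1]]]$space_group == ds[[idx[2]]]$space_group)
    expect_setequal(tab$deposition_rank[idx], c(1L, 2L))
  }
  expect_gt(n_poly, 50)
})

test_that("generated molecules are valence-consistent with their SMILES", {
  # element counts (incl. implicit H) of the record SMILES, parsed with
  # OpenBabel, must match the record's explicit atom table
  cfg <- generator_config(40, seed = 15)
  ds <- generate_dataset(cfg)
  smi <- vapply(ds, `[[`, "", "smiles")
  names(smi) <- sprintf("m%03d", seq_along(smi))
  props <- ChemmineR::propOB(ChemmineR::smiles2sdf(smi))
  for (k in seq_along(ds)) {
    toks <- regmatches(props$formula[k],
                       gregexpr("[A-Z][a-z]?[0-9]*", props$formula[k]))[[1]]
    cnt <- setNames(as.integer(ifelse(gsub("[^0-9]", "", toks) == "", 1,
                                      gsub("[^0-9]", "", toks))),
                    gsub("[0-9]", "", toks))
    mine <- table(ds[[k]]$elements)
    for (el in union(names(cnt), names(mine))) {
      expect_equal(unname(ifelse(el %in% names(cnt), cnt[el], 0L)),
                   unname(ifelse(el %in% names(mine), mine[el], 0L)),
                   info = paste(ds[[k]]$smiles, el))
    }
  }
})

test_that("fixture geometries cover the documented point groups", {
  fx <- fixture_geometries()
  expect_true(all(c("water", "benzene", "methane", "co2", "asymmetric") %in%
                    names(fx)))
  bz <- fx$benzene
  expect_length(bz$elements, 12L)
  expect_true(all(abs(bz$coordinates[bz$elements == "C", 3]) < 1e-12))
  expect_identical(fx$water$expected_point_group, "C2v")
  # the asymmetric cluster admits no nontrivial operation at any tol <= 0.1
  expect_equal(oracle_symmetry_order(fx$asymmetric$elements,
                                     fx$asymmetric$coordinates, tol = 0.1), 1L)
})

test_that("SDF round-trip is lossless for ids, labels and coordinates", {
  ds <- generate_dataset(generator_config(50, seed = 16,
                                          polymorph_rate = 0.3))
  path <- tempfile(fileext = ".sdf")
  write_sdf(ds, path)
  back <- read_sdf(path)
  expect_length(back, length(ds))
  t1 <- record_table(ds); t2 <- record_table(back)
  expect_identical(t2$record_id, t1$record_id)
  expect_identical(t2$space_group, t1$space_group)
  expect_identical(t2$family_id, t1$family_id)
  expect_identical(t2$chiral, t1$chiral)
  expect_identical(t2$n_atoms, t1$n_atoms)
  for (k in c(1L, 25L, 50L)) {
    expect_lt(max(abs(back[[k]]$coordinates - ds[[k]]$coordinates)), 1e-4)
    expect_identical(back[[k]]$bonds$order, ds[[k]]$bonds$order)
  }
})

test_that("write_sdf refuses bad input", {
  expect_error(write_sdf(list(), tempfile()), "empty")
  r <- meta_record("a", "a", 14L)
  r$space_group <- 300L   # corrupt past the constructor
  expect_error(write_sdf(list(r), tempfile(fileext = ".sdf")), "1..230")
  expect_error(molecule_record("x", "x", "CC", c("C", "C"),
                               rbind(c(0, 0, 0), c(1, 0, 0)), 300L),
               "1..230")
})

test_that("yaml configuration round-trips into generator_config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_molecules: 25",
               "label_marginal: {'14': 0.5, '2': 0.3, '19': 0.2}",
               "polymorph_rate: 0.1", "seed: 4"), path)
  cfg <- generator_config_from_yaml(path)
  expect_s3_class(cfg, "xtal_generator_config")
  expect_equal(cfg$n_molecules, 25L)
  expect_equal(unname(cfg$label_marginal[["19"]]), 0.2)
  ds <- generate_dataset(cfg)
  expect_true(all(record_table(ds)$space_group %in% c(14L, 2L, 19L)))
})
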