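# Synthetic molecule/space-group data generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# highly uneven space-group marginal, polymorph families (same molecule, a
# second record with a different label), chiral molecules restricted to
# Sohncke groups, and planted probabilistic dependencies of the label on
# molecular planarity, hydrogen-bonding group counts and molecular symmetry.
# Molecules are assembled from the built-in fragment grammar, so every record
# carries a valid, valence-correct conformer. All distributions here are
# synthetic defaults of this package, not measured database statistics.

#' Generator configuration
#'
#' @param n_molecules positive number of molecule families to generate.
#' @param label_marginal named numeric vector mapping space-group numbers to
#'   probabilities (nonnegative, summing to 1 within 1e-9). Default: the
#'   package's CSD-like synthetic marginal over 25 groups.
#' @param planted_weights named list mapping latent feature names
#'   (`planarity`, `hb_groups`, `symmetry`) to either a single shared
#'   coefficient or a per-group named vector aligned with `label_marginal`.
#'   Labels are drawn from `softmax(log marginal + W' z / temperature)` where
#'   `z` holds the standardized latent features. A shared scalar cancels in
#'   the softmax; per-group coefficients plant a learnable dependency.
#' @param polymorph_rate probability in \[0,1\] that a family emits a second
#'   record with a different space group.
#' @param chiral_fraction probability in \[0,1\] that a molecule is flagged
#'   enantiopure chiral (restricting its labels to Sohncke groups).
#' @param noise_temperature positive softmax temperature; larger values push
#'   labels toward the marginal (higher Bayes error), smaller values make the
#'   planted rule more deterministic.
#' @param seed integer RNG seed; the generated dataset is a deterministic
#'   function of the full configuration.
#' @return Object of class `xtal_generator_config`.
#' @export
generator_config <- function(n_molecules,
                             label_marginal = default_label_marginal(25),
                             planted_weights = default_planted_weights(names(label_marginal)),
                             polymorph_rate = 0.05,
                             chiral_fraction = 0.15,
                             noise_temperature = 1,
                             seed = 1L) {
  if (length(n_molecules) != 1L || is.na(n_molecules) || n_molecules < 1) {
    stop("n_molecules must be a positive count")
  }
  p <- as.numeric(label_marginal)
  if (is.null(names(label_marginal)) || any(is.na(p)) || any(p < 0)) {
    stop("label_marginal must be a named, nonnegative probability vector")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("label_marginal must sum to 1 (got ", format(sum(p)), ")")
  }
  sg <- as.integer(names(label_marginal))
  if (anyNA(sg) || any(sg < 1L) || any(sg > 230L)) {
    stop("label_marginal names must be space-group numbers in 1..230")
  }
  for (rate in c(polymorph_rate, chiral_fraction)) {
    if (is.na(rate) || rate < 0 || rate > 1) stop("rates must lie in [0, 1]")
  }
  if (is.na(noise_temperature) || noise_temperature <= 0) {
    stop("noise_temperature must be positive")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 label_marginal = stats::setNames(p, names(label_marginal)),
                 planted_weights = planted_weights,
                 polymorph_rate = polymorph_rate,
                 chiral_fraction = chiral_fraction,
                 noise_temperature = noise_temperature,
                 seed = as.integer(seed)),
            class = "xtal_generator_config")
}

#' Default planted label-dependence weights
#'
#' A deterministic per-group coefficient table linking the three latent
#' generator features to space-group preference, echoing qualitative
#' crystallographic observations: planar molecules favour the common
#' centrosymmetric groups (mirror/inversion packing), hydrogen-bond-rich
#' molecules favour the dominant H-bonded motif groups, and high molecular
#' symmetry favours centrosymmetric/high-symmetry groups. The `planarity`
#' latent is a deviation (larger = less planar), hence its negative sign on
#' the favoured groups.
#'
#' @param groups character vector of space-group numbers (marginal names).
#' @param strength positive multiplier on all coefficients (0 switches the
#'   planted rule off).
#' @return Named list of per-group coefficient vectors.
#' @export
default_planted_weights <- function(groups, strength = 1) {
  g <- as.integer(groups)
  pick <- function(fav, up, down) {
    w <- ifelse(g %in% fav, up, down)
    stats::setNames(w * strength, groups)
  }
  list(
    planarity = pick(c(14L, 2L, 15L, 61L), -1.3, 0.7),
    hb_groups = pick(c(14L, 19L, 4L, 33L, 9L, 29L), 1.1, -0.6),
    symmetry  = pick(c(2L, 15L, 61L, 60L, 13L, 88L, 148L, 147L, 86L), 1.0, -0.5)
  )
}

.expand_weights <- function(planted_weights, groups) {
  W <- matrix(0, nrow = 3, ncol = length(groups),
              dimnames = list(c("planarity", "hb_groups", "symmetry"), groups))
  for (f in names(planted_weights)) {
    if (!f %in% rownames(W)) {
      stop("unknown planted feature '", f, "' (latent features: ",
           paste(rownames(W), collapse = ", "), ")")
    }
    w <- planted_weights[[f]]
    if (length(w) == 1L && is.null(names(w))) {
      W[f, ] <- as.numeric(w)
    } else {
      if (!all(groups %in% names(w))) {
        stop("per-group weights for '", f, "' must cover all marginal groups")
      }
      W[f, ] <- as.numeric(w[groups])
    }
  }
  W
}

# Sample a random molecule specification (scaffold + substituent placement)
# from the grammar, using the current RNG stream.
.sample_molecule_spec <- function(scaf_lib, sub_names) {
  scaffold <- sample(names(scaf_lib), 1L)
  n_slots <- length(scaf_lib[[scaffold]]$sites)
  n_subs <- sample(0:2, 1L, prob = c(0.15, 0.50, 0.35))
  n_subs <- min(n_subs, n_slots)
  slots <- if (n_subs > 0) sort(sample.int(n_slots, n_subs)) else integer()
  subs <- if (n_subs > 0) sample(sub_names, n_subs, replace = TRUE) else character()
  list(scaffold = scaffold,
       site_subs = stats::setNames(as.list(subs), as.character(slots)))
}

#' Generate a synthetic molecule/space-group dataset
#'
#' Draws molecules from the fragment grammar, computes their latent features
#' (planarity, hydrogen-bonding group count, scaffold symmetry), standardizes
#' them across the dataset, and samples each record's space-group label from
#' `softmax(log marginal + W' z / temperature)`. Enantiopure chiral records
#' only receive Sohncke labels; polymorph families emit a second record whose
#' label is redrawn from the same softmax with the first label excluded.
#'
#' @param config an [generator_config()] object.
#' @return List of `xtal_record` objects (more than `n_molecules` entries
#'   when polymorph families are emitted).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "xtal_generator_config")) {
    stop("config must be created with generator_config()")
  }
  n <- config$n_molecules
  groups <- names(config$label_marginal)
  gnum <- as.integer(groups)
  logp <- log(pmax(config$label_marginal, 1e-300))
  W <- .expand_weights(config$planted_weights, groups)
  sohncke_ok <- is_sohncke(gnum)
  if (config$chiral_fraction > 0 &&
      !any(sohncke_ok & config$label_marginal > 0)) {
    stop("label_marginal assigns no mass to any Sohncke group, ",
         "but chiral_fraction > 0")
  }

  set.seed(config$seed)
  scaf_lib <- .scaffolds()
  sub_names <- names(.substituents())

  specs <- vector("list", n)
  chiral <- stats::runif(n) < config$chiral_fraction
  poly <- stats::runif(n) < config$polymorph_rate
  for (i in seq_len(n)) specs[[i]] <- .sample_molecule_spec(scaf_lib, sub_names)

  cache <- new.env(parent = emptyenv())
  mols <- vector("list", n)
  Z <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    key <- paste(sp$scaffold,
                 paste(names(sp$site_subs), unlist(sp$site_subs),
                       sep = ":", collapse = ","), sep = "|")
    hit <- get0(key, envir = cache)
    if (is.null(hit)) {
      mol <- .compose_molecule(sp$scaffold, sp$site_subs)
      lat <- .latent_features(mol, scaf_lib[[sp$scaffold]]$sym_order)
      hit <- list(mol = mol, lat = lat)
      assign(key, hit, envir = cache)
    }
    mols[[i]] <- hit$mol
    Z[i, ] <- hit$lat
  }
  mu <- colMeans(Z)
  sdv <- apply(Z, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, mu), 2, sdv, `/`)

  draw_label <- function(z, is_chiral, exclude = NULL) {
    logits <- logp + as.numeric(crossprod(W, z)) / config$noise_temperature
    keep <- config$label_marginal > 0
    if (is_chiral) keep <- keep & sohncke_ok
    if (!is.null(exclude)) keep <- keep & (gnum != exclude)
    if (!any(keep)) return(NA_integer_)
    logits[!keep] <- -Inf
    pr <- exp(logits - max(logits[keep]))
    pr[!keep] <- 0
    gnum[sample.int(length(gnum), 1L, prob = pr / sum(pr))]
  }

  records <- vector("list", n + sum(poly))
  k <- 0L
  for (i in seq_len(n)) {
    fam <- sprintf("F%06d", i)
    lab <- draw_label(Zs[i, ], chiral[i])
    k <- k + 1L
    records[[k]] <- molecule_record(
      record_id = sprintf("M%06d", i), family_id = fam,
      smiles = mols[[i]]$smiles, elements = mols[[i]]$elements,
      coordinates = mols[[i]]$coords, space_group = lab,
      deposition_rank = 1L, chiral = chiral[i],
      geometry_source = "optimized", bonds = mols[[i]]$bonds,
      latent = stats::setNames(Zs[i, ], c("planarity", "hb_groups", "symmetry")))
    if (poly[i]) {
      lab2 <- draw_label(Zs[i, ], chiral[i], exclude = lab)
      if (!is.na(lab2)) {
        k <- k + 1L
        records[[k]] <- molecule_record(
          record_id = sprintf("M%06d-2", i), family_id = fam,
          smiles = mols[[i]]$smiles, elements = mols[[i]]$elements,
          coordinates = mols[[i]]$coords, space_group = lab2,
          deposition_rank = 2L, chiral = chiral[i],
          geometry_source = "optimized", bonds = mols[[i]]$bonds,
          latent = stats::setNames(Zs[i, ], c("planarity", "hb_groups", "symmetry")))
      }
    }
  }
  records[seq_len(k)]
}

#' Read a generator configuration from YAML
#'
#' Reads the fields of [generator_config()] from a YAML file;
#' `label_marginal` and per-group `planted_weights` entries are given as
#' maps from space-group number to value. Missing fields fall back to the
#' package defaults.
#'
#' @param path YAML file path.
#' @return An `xtal_generator_config`.
#' @export
generator_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(n_molecules = y$n_molecules)
  if (!is.null(y$label_marginal)) {
    args$label_marginal <- unlist(y$label_marginal)
  }
  if (!is.null(y$planted_weights)) {
    args$planted_weights <- lapply(y$planted_weights, function(w) {
      if (length(w) == 1L && is.null(names(w))) as.numeric(w) else unlist(w)
    })
  }
  for (f in c("polymorph_rate", "chiral_fraction", "noise_temperature",
              "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(generator_config, args)
}

#' Reference point-group fixture geometries
#'
#' Small exact geometries with known point groups, used to validate the
#' symmetry detector: water (C2v), ammonia (C3v), benzene (D6h), methane
#' (Td), carbon dioxide (linear, D-inf-h) and a fully asymmetric 4-atom
#' cluster (C1).
#'
#' @return Named list; each element has `name`, `elements`, `coordinates`
#'   (n x 3, angstroms) and `expected_point_group`.
#' @export
fixture_geometries <- function() {
  fix <- function(name, elements, coordinates, pg) {
    list(name = name, elements = elements,
         coordinates = matrix(coordinates, ncol = 3, byrow = TRUE),
         expected_point_group = pg)
  }
  th <- (0:5) * pi / 3
  benz <- rbind(cbind(1.39 * cos(th), 1.39 * sin(th), 0),
                cbind(2.48 * cos(th), 2.48 * sin(th), 0))
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  list(
    water = fix("water", c("O", "H", "H"),
                c(0, 0, 0.1173,
                  0, 0.7572, -0.4692,
                  0, -0.7572, -0.4692), "C2v"),
    ammonia = fix("ammonia", c("N", "H", "H", "H"),
                  c(0, 0, 0.1111,
                    0.9316, 0, -0.2592,
                    -0.4658, 0.8068, -0.2592,
                    -0.4658, -0.8068, -0.2592), "C3v"),
    benzene = fix("benzene", rep(c("C", "H"), each = 6),
                  as.numeric(t(benz)), "D6h"),
    methane = fix("methane", c("C", "H", "H", "H", "H"),
                  as.numeric(t(rbind(c(0, 0, 0), 1.09 * tet))), "Td"),
    co2 = fix("co2", c("O", "C", "O"),
              c(-1.16, 0, 0,
                0, 0, 0,
                1.16, 0, 0), "Dinfh"),
    asymmetric = fix("asymmetric", c("C", "N", "O", "S"),
                     c(0, 0, 0,
                       1.31, 0.22, 0.13,
                       -0.47, 1.12, -0.71,
                       0.63, -0.94, 1.27), "C1")
  )
}
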