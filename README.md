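# xtalgroup

Predicting the crystallographic space-group preference of organic molecules
from molecular structure.

## Why

Crystal structure prediction (CSP) generates trial crystal structures of a
molecule inside a fixed set of space groups, because searching all 230 is
too expensive. That set is usually chosen from the global frequency
statistics of organic crystals (P2₁/c, P-1, P2₁2₁2₁, C2/c, P2₁, ... cover
most structures) — with the risk that the molecule at hand crystallizes
elsewhere. `xtalgroup` treats the choice as a supervised multiclass
problem: given a molecule (3D conformer + connectivity), predict the *N*
space groups most likely to host its crystal, and measure whether the
prediction beats the frequency prior it would replace.

## What is inside

* **Synthetic data** — `generator_config()` / `generate_dataset()` build
  molecule/space-group datasets from a valence-correct fragment grammar,
  with a CSD-like uneven label marginal, polymorph families, chiral
  molecules restricted to the 65 Sohncke groups, and a planted softmax
  dependency of the label on planarity, hydrogen-bonding group counts and
  molecular symmetry. `write_sdf()` / `read_sdf()` round-trip records
  through SDF V2000.
* **Curation** — `first_polymorph_only()`, `unique_space_group_polymorphs()`,
  `balanced_subset()`, `split_records()`.
* **Descriptors** — `assemble_features()`: general block (weight, atoms,
  rings, aromatic rings), geometric block (normalized principal-moment
  ratios, asphericity, eccentricity, plane-of-best-fit planarity, and a
  point-group symmetry census from `detect_symmetry()`), chemical block
  (18 SMARTS-counted functional groups + Ertl TPSA);
  `select_features()` for correlation/variance feature removal.
* **Graphs** — `build_graph()` (nodes: atomic number, hybridization,
  formal charge, aromaticity, Gasteiger charge; edges: bond-order one-hot,
  conjugation, ring flags), `augment_batch()` rotation augmentation.
* **Models** — `train_forest()` (randomForest; probabilities = tree-vote
  shares; tuning hook) and a native GNN track (`gnn_spec()`,
  `build_gnn()`, `train_gnn()`): edge-conditioned message passing with
  optional coordinates / rotation augmentation, and an E(3)-invariant
  variant whose outputs are unchanged under rigid motions.
* **Evaluation** — `evaluate_predictions()`: top-N accuracy against a
  frequency or balanced (100·N/m) reference, 1/N-scaled per-class
  precision/recall, plus `cross_validate()` and
  `permutation_importance()`.

## Worked example

```r
library(xtalgroup)

cfg <- generator_config(n_molecules = 2000,
                        label_marginal = default_label_marginal(10),
                        polymorph_rate = 0, seed = 101)
records  <- generate_dataset(cfg)
features <- assemble_features(records)
tab      <- record_table(records)
labels   <- tab$space_group[match(features$row_ids, tab$record_id)]

sp <- split_records(records, c(0.8, 0.1, 0.1), seed = 5)
tr <- features$row_ids %in% sp$train_ids
te <- features$row_ids %in% sp$test_ids

sel   <- select_features(subset_features(features, tr))   # fit on train only
model <- train_forest(sel, labels[tr], seed = 7)

test_tbl   <- apply_feature_selection(subset_features(features, te), sel$selection)
freq_order <- as.integer(names(sort(table(labels[tr]), decreasing = TRUE)))
report <- evaluate_model(model, test_tbl, labels[te],
                         reference = "frequency", frequency_order = freq_order)
print(report)
#> <xtal_eval: 200 test molecules, frequency reference>
#>   top-1  acc  36.50%  ref  30.50%  delta  +6.00%
#>   top-3  acc  70.50%  ref  67.00%  delta  +3.50%
#>   top-5  acc  85.00%  ref  84.50%  delta  +0.50%
#>   top-10 acc 100.00%  ref 100.00%  delta  +0.00%
```

The `acc` column is the forest's held-out top-N accuracy; `ref` is what one
gets by always predicting the N most frequent groups of the training split;
`delta` is the gain from using molecular structure. Top-10 covers all ten
groups of this marginal, so both accuracies saturate at 100%.

At the package's documented learnability scale (5,000 molecules, 10
groups) the forest's top-1 delta exceeds 5 percentage points, confirming
that the planted structure–label dependency is recovered from the
descriptors.

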