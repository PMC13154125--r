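# Evaluation framework: top-N accuracy, reference baselines, scaled
# precision/recall (with oracle equivalence), cross-validation, permutation
# importance, report assembly and serialization.

test_that("top_n_accuracy follows the membership rule", {
  expect_equal(top_n_accuracy(c(14L, 2L, 19L),
                              rbind(c(14L, 2L), c(14L, 2L), c(14L, 2L))),
               66.67, tolerance = 0.01)
  expect_equal(top_n_accuracy(c(14L, 2L), rbind(c(2L, 14L), c(14L, 2L))), 100)
  expect_equal(top_n_accuracy(c(14L, 2L), rbind(c(19L, 61L), c(19L, 61L))), 0)
  expect_error(top_n_accuracy(c(14L, 2L), rbind(c(14L, 2L))), "align")
})

test_that("frequency reference equals the covered test proportion", {
  expect_equal(reference_accuracy_frequency(c(14L, 14L, 2L, 19L),
                                            c(14L, 2L, 19L), 1), 50)
  expect_equal(reference_accuracy_frequency(c(14L, 14L, 2L, 19L),
                                            c(14L, 2L, 19L), 3), 100)
  expect_equal(reference_accuracy_frequency(rep(14L, 5), c(14L, 2L), 1), 100)
  expect_error(reference_accuracy_frequency(c(14L, 61L), c(14L, 2L), 1),
               "cover")
})

test_that("balanced reference reproduces the analytic 100*n/m values", {
  expect_identical(reference_accuracy_balanced(25, 1), 4)
  expect_identical(reference_accuracy_balanced(25, 3), 12)
  expect_identical(reference_accuracy_balanced(25, 5), 20)
  expect_identical(reference_accuracy_balanced(25, 10), 40)
  expect_identical(reference_accuracy_balanced(10, 1), 10)
  expect_identical(reference_accuracy_balanced(10, 3), 30)
  expect_identical(reference_accuracy_balanced(10, 5), 50)
  expect_identical(reference_accuracy_balanced(12, 12), 100)
  expect_error(reference_accuracy_balanced(10, 11), "1..10")
})

test_that("scaled precision/recall matches the hand-derived examples", {
  # truth 14, top-3 [2, 19, 61]: fn[14] = 1, fp each 1/3, recall(14) = 0
  r1 <- scaled_precision_recall(14L, rbind(c(2L, 19L, 61L)))
  expect_equal(r1$fn[r1$class == 14], 1)
  expect_equal(r1$recall[r1$class == 14], 0)
  expect_equal(r1$fp[r1$class %in% c(2, 19, 61)], rep(1 / 3, 3))
  expect_true(is.na(r1$precision[r1$class == 14]))   # never predicted
  # truth 14, top-3 [14, 2, 19]: tp[14] = 1, fp[2] = fp[19] = 1/3
  r2 <- scaled_precision_recall(14L, rbind(c(14L, 2L, 19L)))
  expect_equal(r2$tp[r2$class == 14], 1)
  expect_equal(r2$recall[r2$class == 14], 1)
  expect_equal(r2$precision[r2$class == 14], 1)
  expect_equal(r2$fp[r2$class == 2], 1 / 3)
  expect_equal(r2$precision[r2$class == 2], 0)
  # perfect top-1 predictions: every defined precision and recall is 1
  y <- c(14L, 2L, 19L, 2L)
  r3 <- scaled_precision_recall(y, matrix(y, ncol = 1))
  expect_true(all(r3$recall == 1))
  expect_true(all(r3$precision == 1))
})

test_that("scaled precision/recall equals a naive tally on random sets", {
  set.seed(70)
  classes <- as.integer(names(default_label_marginal(12)))
  for (rep in 1:50) {
    n_ex <- sample(5:40, 1)
    nn <- sample(1:5, 1)
    truths <- sample(classes, n_ex, replace = TRUE)
    P <- t(replicate(n_ex, sample(classes, nn)))
    if (nn == 1) P <- matrix(P, ncol = 1)
    got <- scaled_precision_recall(truths, P)
    want <- oracle_scaled_pr(truths, P)
    expect_equal(setNames(got$tp, got$class), want$tp)
    expect_equal(setNames(got$fp, got$class), want$fp)
    expect_equal(setNames(got$fn, got$class), want$fn)
    # conservation: sum(tp + fn) = examples; sum(fp) = misassigned slots / n
    expect_equal(sum(got$tp) + sum(got$fn), n_ex)
    mis <- sum(vapply(seq_len(n_ex), function(i)
      sum(P[i, ] != truths[i]), numeric(1)))
    expect_equal(sum(got$fp), mis / nn, tolerance = 1e-9)
  }
})

test_that("accuracies and references are nondecreasing in n", {
  set.seed(71)
  classes <- as.integer(names(default_label_marginal(10)))
  truths <- sample(classes, 100, replace = TRUE, prob = 10:1)
  probs <- matrix(runif(100 * 10), 100, 10,
                  dimnames = list(NULL, classes))
  probs <- probs / rowSums(probs)
  rep_ <- evaluate_predictions(probs, truths, n_set = c(1, 3, 5, 10),
                               reference = "balanced")
  expect_true(all(diff(rep_$summary$accuracy) >= 0))
  expect_true(all(diff(rep_$summary$reference) >= 0))
  expect_equal(rep_$summary$accuracy[rep_$summary$n == 10], 100)
  freq_order <- as.integer(names(sort(table(truths), decreasing = TRUE)))
  rep2 <- evaluate_predictions(probs, truths, n_set = c(1, 3, 5, 10),
                               reference = "frequency",
                               frequency_order = freq_order)
  expect_true(all(diff(rep2$summary$reference) >= 0))
})

test_that("balanced and frequency references agree for random guessing", {
  # on a perfectly balanced test set, random top-n guessing attains the
  # balanced reference in expectation
  set.seed(72)
  m <- 8L
  classes <- as.integer(names(default_label_marginal(m)))
  truths <- rep(classes, each = 250)
  n <- 3L
  hits <- vapply(seq_along(truths), function(i)
    truths[i] %in% sample(classes, n), TRUE)
  mc <- 100 * mean(hits)
  anal <- reference_accuracy_balanced(m, n)
  se <- 100 * sqrt((n / m) * (1 - n / m) / length(truths))
  expect_lt(abs(mc - anal), 3 * se)
})

test_that("evaluation report: perfect and frequency-oracle classifiers", {
  classes <- as.integer(names(default_label_marginal(25)))
  set.seed(73)
  truths <- sample(classes, 200, replace = TRUE)
  perfect <- matrix(1e-9, 200, 25, dimnames = list(NULL, classes))
  perfect[cbind(seq_len(200), match(truths, classes))] <- 1
  perfect <- perfect / rowSums(perfect)
  repp <- evaluate_predictions(perfect, truths, n_set = 1,
                               reference = "balanced")
  expect_equal(repp$summary$accuracy, 100)
  expect_equal(repp$summary$delta, 96)            # 100 - 100/25
  # a classifier that always ranks classes by frequency has delta 0 at all n
  freq_order <- as.integer(names(sort(table(truths), decreasing = TRUE)))
  freq_order <- c(freq_order, setdiff(classes, freq_order))
  const <- matrix(rep(seq(25, 1) / sum(1:25), each = 200), 200,
                  dimnames = list(NULL, freq_order))
  const <- const[, as.character(classes)]
  repf <- evaluate_predictions(const, truths, n_set = c(1, 3, 5, 10),
                               reference = "frequency",
                               frequency_order = freq_order)
  expect_true(all(abs(repf$summary$delta) < 1e-9))
  expect_error(evaluate_predictions(perfect, integer(0)), "empty")
})

test_that("evaluation reports round-trip through JSON", {
  classes <- c(2L, 14L, 19L)
  set.seed(74)
  truths <- sample(classes, 30, replace = TRUE)
  probs <- matrix(runif(90), 30, 3, dimnames = list(NULL, classes))
  probs <- probs / rowSums(probs)
  rep_ <- evaluate_predictions(probs, truths, n_set = c(1, 2),
                               reference = "balanced")
  path <- tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  back <- read_eval_report(path)
  expect_equal(back$summary, rep_$summary)
  expect_equal(back$per_class[["1"]], rep_$per_class[["1"]])
  expect_equal(back$n_test, rep_$n_test)
})

test_that("cross-validation partitions the data and matches the constant case", {
  set.seed(75)
  V <- matrix(rnorm(200 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- sample(c(14L, 2L), 200, replace = TRUE, prob = c(0.7, 0.3))
  ft <- feature_table(V)
  # constant majority-class trainer: fold accuracy = fold frequency of 14
  const_trainer <- function(tbl, labs, s) {
    structure(list(classes = sort(unique(labs))), class = "const_model")
  }
  assign("predict.const_model", function(object, tbl, ...) {
    P <- matrix(0, nrow(tbl$values), length(object$classes),
                dimnames = list(NULL, object$classes))
    P[, "14"] <- 1
    P
  }, envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()), add = TRUE)
  cv <- cross_validate(ft, y, k = 10, seed = 6, n_set = 1,
                       trainer = const_trainer)
  expect_equal(nrow(cv$folds), 10L)
  expect_true(all(cv$folds$n_test == 20L))
  for (f in 1:10) {
    row <- cv$folds[cv$folds$fold == f, ]
    expect_equal(row$accuracy, row$reference)    # both = fold share of SG 14
  }
  expect_equal(cv$mean$delta, 0)
})

test_that("permutation importance separates planted from null features", {
  set.seed(76)
  n <- 500
  planted <- rnorm(n)
  null_f <- rnorm(n)
  y <- ifelse(planted + rnorm(n, sd = 0.4) > 0, 14L, 2L)
  V <- cbind(planted = planted, null_f = null_f)
  tr <- seq_len(350); te <- 351:500
  m <- train_forest(feature_table(V[tr, ]), y[tr], seed = 2)
  pi <- permutation_importance(m, feature_table(V[te, , drop = FALSE]),
                               y[te], n_repeats = 10, seed = 3)
  imp_planted <- pi[pi$feature == "planted", ]
  imp_null <- pi[pi$feature == "null_f", ]
  # standard error of an importance estimate: paired binomial error of two
  # accuracies measured on the same 150 held-out examples
  acc <- imp_planted$baseline / 100
  se <- 100 * sqrt(2 * acc * (1 - acc) / 150)
  expect_gt(imp_planted$importance, 3 * imp_planted$sd / sqrt(10))
  expect_lt(abs(imp_null$importance), 3 * se)
  expect_error(permutation_importance(m, feature_table(V[te, , drop = FALSE]),
                                      y[te], n_repeats = 0), "n_repeats")
})
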