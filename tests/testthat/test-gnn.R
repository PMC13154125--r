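# GNN track: spec invariants, analytic vs numeric gradients, probability
# outputs, invariances, overfitting capacity and the training contract.

make_graphs <- function(n, k_groups = 4, seed = 60) {
  ds <- generate_dataset(generator_config(
    n, seed = seed, label_marginal = default_label_marginal(k_groups)))
  lapply(ds[seq_len(n)], build_graph)
}

test_that("layer counts are tied to the variant", {
  s1 <- gnn_spec("no_coords")
  expect_equal(unname(c(s1$n_message_layers, s1$n_edge_layers,
                        s1$n_dense_layers)), c(3L, 1L, 2L))
  s2 <- gnn_spec("coords")
  expect_equal(unname(c(s2$n_message_layers, s2$n_edge_layers,
                        s2$n_dense_layers)), c(3L, 1L, 2L))
  s3 <- gnn_spec("augmented")
  expect_equal(unname(c(s3$n_message_layers, s3$n_edge_layers,
                        s3$n_dense_layers)), c(4L, 2L, 3L))
  s4 <- gnn_spec("equivariant")
  expect_equal(unname(c(s4$n_message_layers, s4$n_dense_layers)), c(3L, 2L))
  expect_error(gnn_spec("coords", grad_clip = 0), "positive")
})

test_that("analytic gradients match finite differences", {
  g <- make_graphs(1, seed = 61)[[1]]
  get_path <- function(tree, pp) { for (k in pp) tree <- tree[[k]]; tree }
  set_path <- function(tree, pp, ii, val) {
    if (length(pp) == 1) { tree[[pp]][ii] <- val; return(tree) }
    tree[[pp[1]]] <- set_path(tree[[pp[1]]], pp[-1], ii, val)
    tree
  }
  flat_paths <- function(tree, pre = integer()) {
    if (is.list(tree)) {
      out <- list()
      for (k in seq_along(tree)) out <- c(out, flat_paths(tree[[k]], c(pre, k)))
      out
    } else list(pre)
  }
  for (variant in c("coords", "equivariant")) {
    spec <- gnn_spec(variant, hidden_width = 5, seed = 3)
    model <- build_gnn(spec, ncol(g$node_attrs), ncol(g$edge_attrs), 4L)
    # jitter all parameters away from the exact ReLU kinks that zero-bias
    # initialization creates (finite differences are ill-defined on a kink)
    set.seed(17)
    model$params <- xtalgroup:::.map_params(
      function(x) x + stats::runif(length(x), 0.01, 0.05) *
        sample(c(-1, 1), length(x), replace = TRUE), model$params)
    fw <- xtalgroup:::.gnn_forward(model, g, need_cache = TRUE)
    gr <- xtalgroup:::.gnn_backward(model, g, fw, 2L)
    loss <- function(m) -log(xtalgroup:::.gnn_forward(m, g)$probs[2L])
    maxerr <- 0
    for (pp in flat_paths(model$params)) {
      arr <- get_path(model$params, pp)
      for (ii in unique(pmin(length(arr), c(1L, length(arr))))) {
        eps <- 1e-5
        up <- model; up$params <- set_path(up$params, pp, ii, arr[ii] + eps)
        dn <- model; dn$params <- set_path(dn$params, pp, ii, arr[ii] - eps)
        num <- (loss(up) - loss(dn)) / (2 * eps)
        ana <- get_path(gr, pp)[ii]
        maxerr <- max(maxerr, abs(num - ana) /
                        max(1e-4, abs(num), abs(ana)))
      }
    }
    expect_lt(maxerr, 1e-4)
  }
})

test_that("forward passes emit valid probability vectors", {
  gs <- make_graphs(5, seed = 62)
  for (variant in c("no_coords", "coords", "augmented", "equivariant")) {
    spec <- gnn_spec(variant, hidden_width = 8, seed = 1)
    m <- build_gnn(spec, ncol(gs[[1]]$node_attrs), ncol(gs[[1]]$edge_attrs),
                   6L)
    for (g in gs) {
      p <- xtalgroup:::.gnn_forward(m, g)$probs
      expect_length(p, 6L)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-6)
    }
  }
})

test_that("the invariant variant ignores rigid motions; no_coords ignores coordinates", {
  gs <- make_graphs(24, seed = 63)
  nd <- ncol(gs[[1]]$node_attrs); ed <- ncol(gs[[1]]$edge_attrs)
  k <- length(unique(vapply(gs, `[[`, 0L, "label")))
  spec_e <- gnn_spec("equivariant", hidden_width = 8, max_epochs = 3, seed = 2)
  me <- train_gnn(build_gnn(spec_e, nd, ed, k), gs[1:18], gs[19:24])
  g <- gs[[20]]
  p0 <- predict_gnn(me, g)
  set.seed(11)
  for (rep in 1:20) {
    mo <- xtalgroup:::.random_rigid_motion()
    g2 <- g
    g2$coordinates <- xtalgroup:::.apply_rigid(g$coordinates, mo)
    expect_lt(max(abs(predict_gnn(me, g2) - p0)), 1e-5)
  }
  spec_n <- gnn_spec("no_coords", hidden_width = 8, max_epochs = 2, seed = 2)
  mn <- train_gnn(build_gnn(spec_n, nd, ed, k), gs[1:18], gs[19:24])
  g3 <- g
  g3$coordinates <- NULL
  expect_identical(predict_gnn(mn, g), predict_gnn(mn, g3))
})

test_that("a small model can overfit 32 graphs", {
  gs <- make_graphs(32, k_groups = 5, seed = 64)
  k <- length(unique(vapply(gs, `[[`, 0L, "label")))
  spec <- gnn_spec("coords", hidden_width = 32, learning_rate = 5e-3,
                   max_epochs = 200, batch_size = 16, seed = 4)
  m <- build_gnn(spec, ncol(gs[[1]]$node_attrs), ncol(gs[[1]]$edge_attrs), k)
  m <- train_gnn(m, gs, gs)     # capacity check: validate on the train set
  labs <- vapply(gs, `[[`, 0L, "label")
  P <- predict_gnn(m, gs)
  ce <- -mean(log(P[cbind(seq_along(labs), match(labs, m$class_levels))]))
  expect_lt(ce, 0.05)
})

test_that("training honours the best-checkpoint contract and logs", {
  gs <- make_graphs(30, seed = 65)
  k <- length(unique(vapply(gs, `[[`, 0L, "label")))
  spec <- gnn_spec("coords", hidden_width = 8, max_epochs = 12, seed = 5)
  m <- train_gnn(build_gnn(spec, ncol(gs[[1]]$node_attrs),
                           ncol(gs[[1]]$edge_attrs), k), gs[1:24], gs[25:30])
  expect_equal(nrow(m$log), 12L)
  expect_lte(m$best_val_loss, utils::tail(m$log$val_loss, 1))
  expect_equal(m$best_val_loss, min(m$log$val_loss))
  # returned parameters really are the checkpointed ones
  yv <- match(vapply(gs[25:30], `[[`, 0L, "label"), m$class_levels)
  P <- predict_gnn(m, gs[25:30])
  ce <- -mean(log(P[cbind(seq_along(yv), yv)]))
  expect_equal(ce, m$best_val_loss, tolerance = 1e-10)
})

test_that("the augmented variant trains on quadrupled batches", {
  gs <- make_graphs(16, seed = 66)
  k <- length(unique(vapply(gs, `[[`, 0L, "label")))
  expect_length(augment_batch(gs, seed = 1), 64L)
  spec <- gnn_spec("augmented", hidden_width = 6, max_epochs = 2,
                   batch_size = 16, seed = 6)
  m <- train_gnn(build_gnn(spec, ncol(gs[[1]]$node_attrs),
                           ncol(gs[[1]]$edge_attrs), k), gs[1:12], gs[13:16])
  expect_s3_class(m, "xtal_gnn")
  expect_true(all(is.finite(m$log$train_loss)))
})
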