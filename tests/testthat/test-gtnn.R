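# GTNN core: message-passing layer against a hand-computed oracle,
# permutation/rigid-motion invariances, conformer averaging, training
# mechanics, and equality of the compiled fast path with the R reference.

test_that("message passing matches a hand-evaluated 3-node path graph", {
  # path 1-2-3, 2-dim features, small hand-picked MLP weights
  H <- matrix(c(0.1, -0.2,
                0.3, 0.05,
                -0.4, 0.25), nrow = 3, byrow = TRUE)
  edges <- rbind(c(1L, 2L), c(2L, 3L))
  w <- list(
    psi_W1 = matrix(c(0.2, -0.1, 0.3, 0.05, -0.25, 0.15, 0.1, 0.2), 4, 2),
    psi_b1 = c(0.01, -0.02),
    psi_W2 = matrix(c(0.5, -0.3, 0.2, 0.4), 2, 2),
    psi_b2 = c(0.03, 0),
    phi_W1 = matrix(c(-0.2, 0.1, 0.25, -0.15, 0.3, 0.2, -0.1, 0.05), 4, 2),
    phi_b1 = c(0, 0.02),
    phi_W2 = matrix(c(0.6, -0.2, 0.1, 0.35), 2, 2),
    phi_b2 = c(-0.01, 0.04)
  )
  # independent scalar oracle: explicit loops over Eq-style sums
  relu_s <- function(x) pmax(x, 0)
  psi_o <- function(hi, hj) {
    z <- relu_s(as.numeric(c(hi, hj) %*% w$psi_W1) + w$psi_b1)
    as.numeric(z %*% w$psi_W2) + w$psi_b2
  }
  phi_o <- function(hi, mi) {
    z <- relu_s(as.numeric(c(hi, mi) %*% w$phi_W1) + w$phi_b1)
    as.numeric(z %*% w$phi_W2) + w$phi_b2
  }
  nbrs <- list(2L, c(1L, 3L), 2L)
  expected <- t(vapply(1:3, function(i) {
    m <- c(0, 0)
    for (j in nbrs[[i]]) m <- m + psi_o(H[i, ], H[j, ])
    phi_o(H[i, ], m)
  }, numeric(2)))
  got <- message_passing_layer(H, edges, w)
  expect_equal(got, expected, tolerance = 1e-10)

  # neighbor relabeling: reversing the edge list changes nothing
  got2 <- message_passing_layer(H, edges[2:1, , drop = FALSE], w)
  expect_equal(got2, got, tolerance = 1e-12)

  # isolated node: empty neighbor sum is the zero vector
  iso <- message_passing_layer(H[1, , drop = FALSE],
                               matrix(integer(0), 0, 2), w)
  expect_equal(drop(iso), phi_o(H[1, ], c(0, 0)), tolerance = 1e-12)

  bad <- w; bad$psi_W1 <- bad$psi_W1[1:3, , drop = FALSE]
  expect_error(message_passing_layer(H, edges, bad), class = "shape_error")
})

test_that("pooling is invariant to atom order and isomorphic relabeling", {
  cfg <- tiny_gtnn_config()
  model <- init_gtnn(cfg, small_vocab())
  set.seed(20)
  n <- 7L
  feats <- matrix(rnorm(n * cfg$n_layers * cfg$hidden_dim), nrow = n)
  v <- pool_graph(feats, model, tower = "arene")
  expect_length(v, cfg$embed_dim)
  for (k in 1:5) {
    perm <- sample(n)
    expect_equal(pool_graph(feats[perm, , drop = FALSE], model, "arene"), v,
                 tolerance = 1e-6)
  }
  # single-atom graph: attention over one element, finite output
  one <- pool_graph(feats[1, , drop = FALSE], model, "arene")
  expect_true(all(is.finite(one)))
  # identically-featurized isomorphic graphs pool identically
  expect_equal(pool_graph(rbind(feats, feats[n:1, ]), model, "arene"),
               pool_graph(rbind(feats[n:1, ], feats), model, "arene"),
               tolerance = 1e-9)
  expect_error(pool_graph(feats[0, , drop = FALSE], model, "arene"),
               class = "empty_input_error")
})

test_that("forward returns deterministic values in [0,1], towers unshared", {
  cfg <- tiny_gtnn_config()
  vocab <- small_vocab()
  model <- init_gtnn(cfg, vocab)
  ga <- mol_to_graph("c1ccncc1")
  gb <- mol_to_graph("OC(=O)CC")
  cond <- encode_conditions(list(reagent = "r1", solvent = "s1",
                                 catalyst = "c2", additive = "a1",
                                 atmosphere = "air"), vocab)
  y1 <- forward_gtnn(model, ga, gb, cond)
  expect_true(y1 >= 0 && y1 <= 1)
  expect_identical(y1, forward_gtnn(model, ga, gb, cond))
  # swapping the reactant roles changes the prediction (towers unshared;
  # coincidental equality has probability zero for continuous weights)
  expect_false(isTRUE(all.equal(forward_gtnn(model, gb, ga, cond), y1)))
  expect_error(forward_gtnn(model, ga, gb, cond[-1]), class = "shape_error")

  # predictions stay finite over random structure pairs
  set.seed(5)
  for (s in c("Cc1cncnc1", "CC(C)c1ccncc1", "Clc1ccnnc1")) {
    yy <- forward_gtnn(model, mol_to_graph(s), gb, cond)
    expect_true(is.finite(yy) && yy >= 0 && yy <= 1)
  }
})

test_that("atom relabeling of the input graph leaves the forward pass fixed", {
  cfg <- tiny_gtnn_config()
  vocab <- small_vocab()
  model <- init_gtnn(cfg, vocab)
  g <- mol_to_graph("Cc1ccncc1")
  cond <- encode_conditions(list(reagent = "r2", solvent = "s1",
                                 catalyst = "c1", additive = "none",
                                 atmosphere = "air"), vocab)
  y0 <- forward_gtnn(model, g, mol_to_graph("OC(=O)C"), cond)
  set.seed(14)
  for (k in 1:3) {
    perm <- sample(length(g$elements))
    gp <- g
    gp$features <- g$features[perm, , drop = FALSE]
    inv <- order(perm)
    gp$edges <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
    yp <- forward_gtnn(model, gp, mol_to_graph("OC(=O)C"), cond)
    expect_equal(yp, y0, tolerance = 1e-9)
  }
})

test_that("3D predictions are invariant to rigid motions of conformers", {
  cfg <- tiny_gtnn_config(mode = "3d")
  vocab <- small_vocab()
  model <- init_gtnn(cfg, vocab)
  ga <- mol_to_graph("c1ccncc1", with_conformers = TRUE, n_conformers = 2L,
                     seed = 3L)
  gb <- mol_to_graph("OC(=O)CC", with_conformers = TRUE, n_conformers = 2L,
                     seed = 4L)
  cond <- encode_conditions(list(reagent = "r1", solvent = "s1",
                                 catalyst = "c3", additive = "a1",
                                 atmosphere = "air"), vocab)
  y0 <- forward_gtnn(model, ga, gb, cond, conformer = 1L)
  set.seed(77)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  ga2 <- ga
  ga2$conformers[[1]] <- ga$conformers[[1]] %*% rot +
    matrix(c(3, -1, 2), nrow(ga$conformers[[1]]), 3, byrow = TRUE)
  expect_equal(forward_gtnn(model, ga2, gb, cond, conformer = 1L), y0,
               tolerance = 1e-9)
})

test_that("conformer-averaged prediction equals the mean of single passes", {
  cfg <- tiny_gtnn_config(mode = "3d", seed = 6L)
  rec <- toy_records(c("c1ccncc1", "Cc1cncnc1"), c("OC(=O)C", "OC(=O)CC"),
                     catalysts = "c1")
  ds <- reaction_dataset(rec)
  model <- init_gtnn(cfg, ds$vocabulary)
  pred <- predict(model, ds)
  # per-conformer passes with the same derived conformer seeds
  for (i in c(1L, 4L)) {
    r <- ds$records[i, ]
    ga <- mol_to_graph(r$arene, TRUE, cfg$n_conformers,
                       seed = miniscifunnel:::derive_seed(
                         miniscifunnel:::derive_seed(cfg$seed,
                                                     "conformers-arene"),
                         r$arene))
    gb <- mol_to_graph(r$acid, TRUE, cfg$n_conformers,
                       seed = miniscifunnel:::derive_seed(
                         miniscifunnel:::derive_seed(cfg$seed,
                                                     "conformers-acid"),
                         r$acid))
    cond <- encode_conditions(r, ds$vocabulary)
    per_conf <- vapply(seq_len(cfg$n_conformers), function(k) {
      forward_gtnn(model, ga, gb, cond, conformer = k)
    }, 0)
    expect_equal(pred$predicted_yield[i], mean(per_conf), tolerance = 1e-12)
    # n_conformers = 1 reduces to a single forward pass
    expect_equal(per_conf[1],
                 forward_gtnn(model, ga, gb, cond, conformer = 1L))
  }
})

test_that("compiled pass equals the R reference to machine precision", {
  for (mode in c("2d", "3d")) {
    cfg <- tiny_gtnn_config(mode = mode, seed = 31L)
    vocab <- small_vocab()
    model <- init_gtnn(cfg, vocab)
    freqs <- model$frequencies
    mk <- function(s, seed) mol_to_graph(s, mode == "3d", cfg$n_conformers,
                                         seed = seed)
    b1 <- single_batch(mk("c1ccncc1", 1L), mk("OC(=O)CC", 2L),
                       encode_conditions(list(reagent = "r1", solvent = "s1",
                                              catalyst = "c1",
                                              additive = "a1",
                                              atmosphere = "air"), vocab),
                       cfg, freqs)
    y <- 0.35
    fwd <- miniscifunnel:::gtnn_forward(model$params, cfg, b1)
    gr <- miniscifunnel:::gtnn_backward(model$params, cfg, b1, fwd,
                                        2 * (fwd$y - y))
    theta <- miniscifunnel:::flatten_params(model$params)
    res <- miniscifunnel:::gtnn_pass(theta, cfg, b1, y = y, want_grad = TRUE)
    expect_equal(res$y, unname(fwd$y), tolerance = 1e-12)
    gvec <- miniscifunnel:::flatten_params(gr[names(model$params)])
    expect_equal(res$grad, gvec, tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_gtnn_config(seed = 12L)
  vocab <- small_vocab()
  model <- init_gtnn(cfg, vocab)
  b <- single_batch(mol_to_graph("c1ccncc1"), mol_to_graph("OC(=O)C(C)C"),
                    encode_conditions(list(reagent = "r2", solvent = "s1",
                                           catalyst = "c2",
                                           additive = "none",
                                           atmosphere = "air"), vocab),
                    cfg)
  y <- 0.6
  theta <- miniscifunnel:::flatten_params(model$params)
  res <- miniscifunnel:::gtnn_pass(theta, cfg, b, y = y, want_grad = TRUE)
  lossfn <- function(th) miniscifunnel:::gtnn_pass(th, cfg, b, y = y)$loss
  set.seed(42)
  idx <- sample(length(theta), 40L)
  eps <- 1e-5
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    num <- (lossfn(tp) - lossfn(tm)) / (2 * eps)
    expect_equal(res$grad[i], num, tolerance = 1e-4)
  }
})

test_that("the learning-rate schedule halves every 100 epochs", {
  cfg <- gtnn_config()
  expect_equal(learning_rate_schedule(cfg, 1), 1e-4)
  expect_equal(learning_rate_schedule(cfg, 100), 1e-4)
  expect_equal(learning_rate_schedule(cfg, 150), 5e-5)
  expect_equal(learning_rate_schedule(cfg, 250), 2.5e-5)
  once <- gtnn_config(decay_mode = "once")
  expect_equal(learning_rate_schedule(once, 150), 5e-5)
  expect_equal(learning_rate_schedule(once, 450), 5e-5)
})

test_that("training early-stops at the validation-MAE argmin", {
  rec <- toy_records(toy_arenes(6), toy_acids(4))
  set.seed(50)
  rec$yield_mono <- runif(nrow(rec), 0, 0.4)
  ds <- reaction_dataset(rec)
  sp <- make_split(ds, "0D", k = 3L, seed = 2L)
  cfg <- tiny_gtnn_config(seed = 3L, max_epochs = 4L)
  fit <- train_gtnn(ds, sp, cfg, target = "yield", fold = 1L)
  expect_equal(fit$best_epoch, which.min(fit$history$val_mae))
  expect_equal(nrow(fit$history), 4L)
  expect_equal(fit$best_val_mae, min(fit$history$val_mae))

  # binary target trains on 0/1 labels
  fitb <- train_gtnn(ds, sp, cfg, target = "binary", fold = 1L)
  expect_true(all(is.finite(fitb$history$val_mae)))

  # empty partitions are rejected
  broken <- sp
  broken$folds[[1]]$val <- character(0)
  expect_error(train_gtnn(ds, broken, cfg), class = "split_error")
})

test_that("checkpoints round-trip with config and vocabulary embedded", {
  cfg <- tiny_gtnn_config(seed = 8L)
  model <- init_gtnn(cfg, small_vocab())
  path <- tempfile(fileext = ".rds")
  save_gtnn(model, path)
  back <- load_gtnn(path)
  expect_identical(back$params, model$params)
  expect_identical(back$vocab, model$vocab)
  expect_equal(parameter_count(back), parameter_count(model))
})

test_that("ensemble predictions are the mean of member predictions", {
  rec <- toy_records(toy_arenes(5), toy_acids(3))
  set.seed(60)
  rec$yield_mono <- runif(nrow(rec), 0, 0.4)
  ds <- reaction_dataset(rec)
  sp <- make_split(ds, "0D", k = 3L, seed = 4L)
  ens <- train_gtnn_ensemble(ds, sp, tiny_gtnn_config(seed = 9L),
                             target = "yield", n_models = 2L)
  expect_length(ens$models, 2L)
  # distinct member initializations
  expect_false(identical(ens$models[[1]]$params, ens$models[[2]]$params))
  te <- ds$records[ds$records$reaction_id %in% ens$test_ids, ]
  pe <- predict(ens, te)
  members <- vapply(ens$models, function(m) predict(m, te)$predicted_yield,
                    numeric(nrow(te)))
  expect_equal(pe$predicted_yield, rowMeans(members), tolerance = 1e-12)
  expect_equal(pe$predicted_binary,
               as.integer(rowMeans(members) >= 0.05))
})
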