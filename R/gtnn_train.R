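# GTNN training loop, prediction, pooling entry point and checkpointing.

# ---- featurized-graph cache -------------------------------------------------

# one cache entry per unique structure: node features, directed edge lists,
# and (3D mode) per-conformer Fourier distance features on directed edges
graph_cache <- function(smiles_vec, cfg, freqs, seed) {
  uniq <- unique(smiles_vec)
  entries <- vector("list", length(uniq))
  names(entries) <- uniq
  for (s in uniq) {
    g <- mol_to_graph(s, with_conformers = cfg$mode == "3d",
                      n_conformers = cfg$n_conformers,
                      seed = derive_seed(seed, s))
    src <- c(g$edges[, 1], g$edges[, 2])
    dst <- c(g$edges[, 2], g$edges[, 1])
    Rconf <- NULL
    if (cfg$mode == "3d") {
      Rconf <- lapply(g$conformers, function(xyz) {
        d <- sqrt(rowSums((xyz[g$edges[, 1], , drop = FALSE] -
                             xyz[g$edges[, 2], , drop = FALSE])^2))
        enc <- fourier_distance(d, freqs)
        if (is.null(dim(enc))) enc <- matrix(enc, nrow = 1)
        rbind(enc, enc)
      })
    }
    entries[[s]] <- list(X = g$features, src = src, dst = dst,
                         n = nrow(g$features), Rconf = Rconf)
  }
  entries
}

stack_side <- function(entries, keys, conf_idx, cfg) {
  es <- entries[keys]
  ns <- vapply(es, `[[`, 0L, "n")
  offsets <- c(0L, cumsum(ns))
  X <- do.call(rbind, lapply(es, `[[`, "X"))
  src <- unlist(lapply(seq_along(es), function(i) es[[i]]$src + offsets[i]),
                use.names = FALSE)
  dst <- unlist(lapply(seq_along(es), function(i) es[[i]]$dst + offsets[i]),
                use.names = FALSE)
  gid <- rep(seq_along(es), ns)
  R <- NULL
  if (cfg$mode == "3d") {
    R <- do.call(rbind, lapply(seq_along(es), function(i) {
      es[[i]]$Rconf[[conf_idx[i]]]
    }))
  }
  list(X = X, src = src, dst = dst, gid = gid, R = R)
}

# each unique molecule appears once in the stacked tower input; `map`
# scatters the pooled molecular vectors back to the per-reaction rows.
# conf_* are per-unique-molecule conformer indices (named by structure).
dedup_side <- function(cache, keys, conf, cfg) {
  uk <- unique(keys)
  ci <- if (is.null(conf)) rep(1L, length(uk)) else unname(conf[uk])
  side <- stack_side(cache, uk, ci, cfg)
  side$map <- match(keys, uk)
  side
}

build_batch <- function(cache_ar, cache_ac, arene_keys, acid_keys, Cmat,
                        cfg, conf_ar = NULL, conf_ac = NULL) {
  list(ar = dedup_side(cache_ar, arene_keys, conf_ar, cfg),
       ac = dedup_side(cache_ac, acid_keys, conf_ac, cfg),
       C = Cmat)
}

model_dims <- function(cfg, n_cond) {
  c(ATOM_FEATURE_DIM, cfg$hidden_dim, cfg$embed_dim, cfg$post_pool_dim,
    cfg$n_layers, cfg$pool_heads,
    if (cfg$mode == "3d") 2L * cfg$n_fourier else 0L, n_cond)
}

# single compiled pass over a stacked batch: predictions, and optionally the
# MSE loss and its gradient with respect to the flattened parameters
gtnn_pass <- function(theta, cfg, batch, y = numeric(0), want_grad = FALSE) {
  .gtnn_pass_cpp(theta, model_dims(cfg, ncol(batch$C)),
                 batch$ar$X, batch$ar$src, batch$ar$dst, batch$ar$gid,
                 batch$ar$R, batch$ac$X, batch$ac$src, batch$ac$dst,
                 batch$ac$gid, batch$ac$R, batch$ar$map, batch$ac$map,
                 batch$C, y, want_grad)
}

# chunked evaluation pass (single conformer index per molecule)
eval_pass <- function(theta, cfg, cache_ar, cache_ac, arene_keys, acid_keys,
                      Cmat, conf_ar = NULL, conf_ac = NULL,
                      chunk = 4096L) {
  n <- length(arene_keys)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    b <- build_batch(cache_ar, cache_ac, arene_keys[idx], acid_keys[idx],
                     Cmat[idx, , drop = FALSE], cfg, conf_ar, conf_ac)
    out[idx] <- gtnn_pass(theta, cfg, b)$y
  }
  out
}

#' Learning-rate schedule
#'
#' Step decay: the base learning rate is multiplied by `lr_decay` every
#' `lr_decay_every` epochs (`decay_mode = "step"`), or exactly once after
#' `lr_decay_every` epochs (`"once"`).
#'
#' @param config a `gtnn_config`.
#' @param epoch 1-based epoch number.
#' @return the learning rate in effect at `epoch`.
#' @export
learning_rate_schedule <- function(config, epoch) {
  k <- if (config$decay_mode == "step") {
    floor((epoch - 1) / config$lr_decay_every)
  } else {
    as.integer(epoch > config$lr_decay_every)
  }
  config$learning_rate * config$lr_decay^k
}

#' Train a GTNN on a reaction dataset
#'
#' Minibatch Adam training with mean-squared-error loss on \[0, 1\] targets
#' (reaction yield, or the 0/1 binary outcome treated as regression), a step
#' learning-rate decay, exponential moving-average weight smoothing, and
#' early stopping at the epoch with the lowest validation MAE.  In 3D mode
#' one of the precomputed conformers is selected per molecule at random each
#' epoch.
#'
#' @param dataset a `reaction_dataset`.
#' @param split an `mf_split` (see [make_split()]).
#' @param config a [gtnn_config()].
#' @param target `"yield"` (total yield) or `"binary"` (outcome at the 5%
#'   threshold).
#' @param fold which fold of the split to train on.
#' @param verbose print progress every 25 epochs.
#' @return object of class `mf_train_result`: `model` (the early-stopped
#'   `mf_gtnn`), `history` (per-epoch train loss and validation MAE),
#'   `best_epoch`, and `test_ids` for downstream evaluation.
#' @export
train_gtnn <- function(dataset, split, config = gtnn_config(),
                       target = c("yield", "binary"), fold = 1L,
                       verbose = FALSE) {
  target <- match.arg(target)
  rec <- dataset$records
  assert_that(fold >= 1L && fold <= length(split$folds), "argument_error",
              "fold out of range")
  f <- split$folds[[fold]]
  assert_that(length(f$train) > 0L && length(f$val) > 0L, "split_error",
              "empty train or validation partition")

  idx_of <- stats::setNames(seq_len(nrow(rec)), rec$reaction_id)
  tr <- idx_of[f$train]; va <- idx_of[f$val]; te <- idx_of[f$test]
  assert_that(!anyNA(tr) && !anyNA(va), "split_error",
              "split ids absent from dataset")

  vocab <- dataset$vocabulary
  model <- init_gtnn(config, vocab, target)
  freqs <- model$frequencies

  cache_ar <- graph_cache(rec$arene, config, freqs,
                          derive_seed(config$seed, "conformers-arene"))
  cache_ac <- graph_cache(rec$acid, config, freqs,
                          derive_seed(config$seed, "conformers-acid"))

  Cmat <- t(vapply(seq_len(nrow(rec)),
                   function(i) encode_conditions(rec[i, ], vocab),
                   numeric(condition_vector_length(vocab))))
  y_all <- if (target == "yield") total_yield(rec)
  else as.numeric(binary_outcome(rec))

  P <- model$params
  theta <- flatten_params(P)
  ema_vec <- if (config$use_ema) theta else NULL
  state <- adam_init(theta)
  n_tr <- length(tr)
  bs <- config$batch_size
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_mae = numeric(0))
  best_val <- Inf; best_theta <- theta; best_epoch <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    lr <- learning_rate_schedule(config, epoch)
    ord <- with_seed(derive_seed(config$seed, paste0("shuffle-", epoch)),
                     sample(tr))
    conf_sel <- NULL
    if (config$mode == "3d") {
      # one conformer draw per unique molecule per epoch
      conf_sel <- with_seed(
        derive_seed(config$seed, paste0("conf-", epoch)),
        list(ar = stats::setNames(
               sample.int(config$n_conformers, length(cache_ar), TRUE),
               names(cache_ar)),
             ac = stats::setNames(
               sample.int(config$n_conformers, length(cache_ac), TRUE),
               names(cache_ac))))
    }
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n_tr, by = bs)) {
      bidx <- ord[start:min(start + bs - 1L, n_tr)]
      batch <- build_batch(
        cache_ar, cache_ac, rec$arene[bidx], rec$acid[bidx],
        Cmat[bidx, , drop = FALSE], config,
        if (is.null(conf_sel)) NULL else conf_sel$ar,
        if (is.null(conf_sel)) NULL else conf_sel$ac)
      res <- gtnn_pass(theta, config, batch, y = y_all[bidx],
                       want_grad = TRUE)
      upd <- adam_step_flat(theta, res$grad, state, lr,
                            config$weight_decay)
      theta <- upd$theta; state <- upd$state
      if (config$use_ema) {
        ema_vec <- config$ema_factor * ema_vec +
          (1 - config$ema_factor) * theta
      }
      ep_loss <- ep_loss + res$loss; n_batches <- n_batches + 1L
    }
    theta_eval <- if (config$use_ema) ema_vec else theta
    val_pred <- eval_pass(theta_eval, config, cache_ar, cache_ac,
                          rec$arene[va], rec$acid[va],
                          Cmat[va, , drop = FALSE],
                          if (is.null(conf_sel)) NULL else conf_sel$ar,
                          if (is.null(conf_sel)) NULL else conf_sel$ac)
    val_mae <- mean(abs(val_pred - y_all[va]))
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = ep_loss / n_batches,
                                val_mae = val_mae))
    if (val_mae < best_val) {
      best_val <- val_mae
      best_theta <- if (config$use_ema) ema_vec else theta
      best_epoch <- epoch
    }
    if (verbose && epoch %% 25L == 0L) {
      message(sprintf("epoch %4d  train MSE %.5f  val MAE %.5f  (best %.5f @ %d)",
                      epoch, ep_loss / n_batches, val_mae, best_val,
                      best_epoch))
    }
  }

  model$params <- unflatten_params(best_theta, P)
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 best_val_mae = best_val, test_ids = f$test),
            class = "mf_train_result")
}

#' @export
print.mf_train_result <- function(x, ...) {
  cat(sprintf(
    "<mf_train_result> %d epochs, best validation MAE %.4f at epoch %d\n",
    nrow(x$history), x$best_val_mae, x$best_epoch))
  invisible(x)
}

#' Forward pass for one reaction
#'
#' Deterministic single-reaction evaluation.  In 3D mode a conformer index
#' selects which precomputed coordinate set of each graph is used.
#'
#' @param model an `mf_gtnn`.
#' @param arene,acid `mf_graph` objects (with conformers in 3D mode).
#' @param conditions numeric condition one-hot of the model's vocabulary
#'   length.
#' @param conformer conformer index (3D mode).
#' @return predicted value in \[0, 1\].
#' @export
forward_gtnn <- function(model, arene, acid, conditions, conformer = 1L) {
  cfg <- model$config
  n_cond <- condition_vector_length(model$vocab)
  if (length(conditions) != n_cond) {
    stop_mf("shape_error",
            "condition vector has length %d; model expects %d",
            length(conditions), n_cond)
  }
  entry <- function(g) {
    Rconf <- NULL
    if (cfg$mode == "3d") {
      assert_that(!is.null(g$conformers), "argument_error",
                  "3D model requires graphs with conformers")
      xyz <- g$conformers[[conformer]]
      d <- sqrt(rowSums((xyz[g$edges[, 1], , drop = FALSE] -
                           xyz[g$edges[, 2], , drop = FALSE])^2))
      enc <- fourier_distance(d, model$frequencies)
      if (is.null(dim(enc))) enc <- matrix(enc, nrow = 1)
      Rconf <- list(rbind(enc, enc))
    }
    list(X = g$features, src = c(g$edges[, 1], g$edges[, 2]),
         dst = c(g$edges[, 2], g$edges[, 1]), n = nrow(g$features),
         Rconf = Rconf)
  }
  # entry() already extracted the requested conformer
  sa <- stack_side(list(a = entry(arene)), "a", 1L, cfg)
  sa$map <- 1L
  sb <- stack_side(list(b = entry(acid)), "b", 1L, cfg)
  sb$map <- 1L
  batch <- list(ar = sa, ac = sb, C = matrix(conditions, nrow = 1))
  unname(gtnn_forward(model$params, cfg, batch)$y)
}

#' Predict reaction outcomes for a dataset
#'
#' In 3D mode the prediction for each reaction is the arithmetic mean of the
#' forward passes over each of the `n_conformers` conformers; 2D mode is a
#' single pass.
#'
#' @param object a trained `mf_gtnn`.
#' @param newdata a `reaction_dataset` or records data.frame.
#' @param threshold binary-outcome threshold on the predicted yield.
#' @param ... unused.
#' @return data.frame with `reaction_id`, `predicted_yield`,
#'   `predicted_binary`.
#' @export
predict.mf_gtnn <- function(object, newdata, threshold = 0.05, ...) {
  rec <- if (inherits(newdata, "reaction_dataset")) newdata$records
  else newdata
  cfg <- object$config
  vocab <- object$vocab
  freqs <- object$frequencies
  cache_ar <- graph_cache(rec$arene, cfg, freqs,
                          derive_seed(cfg$seed, "conformers-arene"))
  cache_ac <- graph_cache(rec$acid, cfg, freqs,
                          derive_seed(cfg$seed, "conformers-acid"))
  Cmat <- t(vapply(seq_len(nrow(rec)),
                   function(i) encode_conditions(rec[i, ], vocab),
                   numeric(condition_vector_length(vocab))))
  n_pass <- if (cfg$mode == "3d") cfg$n_conformers else 1L
  theta <- flatten_params(object$params)
  acc <- numeric(nrow(rec))
  for (cidx in seq_len(n_pass)) {
    conf_ar <- stats::setNames(rep(cidx, length(cache_ar)), names(cache_ar))
    conf_ac <- stats::setNames(rep(cidx, length(cache_ac)), names(cache_ac))
    acc <- acc + eval_pass(theta, cfg, cache_ar, cache_ac,
                           rec$arene, rec$acid, Cmat,
                           conf_ar = conf_ar, conf_ac = conf_ac)
  }
  pred <- acc / n_pass
  data.frame(reaction_id = rec$reaction_id, predicted_yield = pred,
             predicted_binary = as.integer(pred >= threshold),
             stringsAsFactors = FALSE)
}

#' Pool per-atom representations into a molecular vector
#'
#' Applies a tower's post-message-passing MLP and seed-query attention
#' pooling to the concatenated per-layer atom representations.  The result
#' is invariant to atom ordering.
#'
#' @param features n x (n_layers * hidden_dim) matrix of concatenated
#'   per-layer atom representations.
#' @param model an `mf_gtnn`.
#' @param tower `"arene"` or `"acid"`.
#' @return molecular vector of length `embed_dim`.
#' @export
pool_graph <- function(features, model, tower = c("arene", "acid")) {
  tower <- match.arg(tower)
  t <- if (tower == "arene") "ar" else "ac"
  cfg <- model$config
  P <- model$params
  assert_that(is.matrix(features) && nrow(features) > 0L,
              "empty_input_error", "features must be a non-empty matrix")
  assert_that(ncol(features) == cfg$n_layers * cfg$hidden_dim,
              "shape_error", "features must have %d columns",
              cfg$n_layers * cfg$hidden_dim)
  h <- cfg$hidden_dim
  Z1f <- sweep(features %*% P[[paste0(t, ".fin.W1")]], 2,
               P[[paste0(t, ".fin.b1")]], "+")
  A1f <- relu(Z1f)
  Ffin <- sweep(A1f %*% P[[paste0(t, ".fin.W2")]], 2,
                P[[paste0(t, ".fin.b2")]], "+")
  K <- sweep(Ffin %*% P[[paste0(t, ".pool.Wk")]], 2,
             P[[paste0(t, ".pool.bk")]], "+")
  V <- sweep(Ffin %*% P[[paste0(t, ".pool.Wv")]], 2,
             P[[paste0(t, ".pool.bv")]], "+")
  Q <- sweep(P[[paste0(t, ".pool.S")]] %*% P[[paste0(t, ".pool.Wq")]], 2,
             P[[paste0(t, ".pool.bq")]], "+")
  Sc <- pmin(pmax(K %*% t(Q) / sqrt(h), -CLAMP), CLAMP)
  Eexp <- exp(Sc)
  Attn <- sweep(Eexp, 2, colSums(Eexp), "/")
  Pcat <- do.call(cbind, lapply(seq_len(cfg$pool_heads), function(k) {
    colSums(V * Attn[, k])
  }))
  Pm <- drop(matrix(Pcat, nrow = 1) %*% P[[paste0(t, ".pool.Wo")]] +
               P[[paste0(t, ".pool.bo")]])
  Pm
}

#' Save / load a GTNN checkpoint
#'
#' The checkpoint embeds the configuration and condition vocabulary.
#'
#' @param model an `mf_gtnn`.
#' @param path file path (RDS).
#' @return `save_gtnn` the path invisibly; `load_gtnn` the model.
#' @export
save_gtnn <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gtnn
#' @export
load_gtnn <- function(path) {
  m <- readRDS(path)
  assert_that(inherits(m, "mf_gtnn"), "io_error",
              "'%s' is not a GTNN checkpoint", path)
  m
}

#' Yield scorer backed by a trained GTNN
#'
#' Wraps a trained model into the scorer contract: candidates are scored as
#' reactions of their scaffold and acid under fixed plate conditions.
#'
#' @param model a trained `mf_gtnn`.
#' @param conditions named list/one-row data.frame with `catalyst`,
#'   `additive`, `reagent`, `solvent`, `atmosphere`; defaults to the first
#'   level of each category in the model vocabulary.
#' @return a scorer function mapping a candidate data.frame (columns
#'   `scaffold_smiles`, `acid_smiles`) to predicted yields.
#' @export
scorer_yield_gtnn <- function(model, conditions = NULL) {
  vocab <- model$vocab
  if (is.null(conditions)) {
    conditions <- lapply(vocab, `[[`, 1L)
  }
  function(candidates) {
    rec <- data.frame(
      reaction_id = sprintf("cand%d", seq_len(nrow(candidates))),
      arene = candidates$scaffold_smiles,
      acid = candidates$acid_smiles,
      catalyst = conditions$catalyst, additive = conditions$additive,
      reagent = conditions$reagent, solvent = conditions$solvent,
      atmosphere = conditions$atmosphere,
      stringsAsFactors = FALSE
    )
    predict(model, rec)$predicted_yield
  }
}

#' Train an ensemble of GTNNs and predict by model averaging
#'
#' Synthesizability predictions are made by averaging several independently
#' initialized and shuffled models trained on the same split (three by
#' default).  Averaging a few models removes most of the run-to-run variance
#' of a single short CPU training and is the package's standard inference
#' procedure for funnel decisions.
#'
#' @inheritParams train_gtnn
#' @param n_models ensemble size (default 3).
#' @return object of class `mf_gtnn_ensemble`: list with `models`, the
#'   per-model `fits` (histories), and `test_ids`.
#' @export
train_gtnn_ensemble <- function(dataset, split, config = gtnn_config_reduced(),
                                target = c("yield", "binary"), fold = 1L,
                                n_models = 3L, verbose = FALSE) {
  target <- match.arg(target)
  assert_that(n_models >= 1L, "argument_error", "n_models must be >= 1")
  fits <- lapply(seq_len(n_models), function(m) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("ensemble-", m))
    train_gtnn(dataset, split, cfg, target = target, fold = fold,
               verbose = verbose)
  })
  structure(list(models = lapply(fits, `[[`, "model"),
                 fits = fits, test_ids = fits[[1]]$test_ids,
                 target = target),
            class = "mf_gtnn_ensemble")
}

#' @export
print.mf_gtnn_ensemble <- function(x, ...) {
  cat(sprintf("<mf_gtnn_ensemble> %d models, %s target; best val MAEs: %s\n",
              length(x$models), x$target,
              paste(sprintf("%.4f", vapply(x$fits, `[[`, 0, "best_val_mae")),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname train_gtnn_ensemble
#' @param object an `mf_gtnn_ensemble`.
#' @param newdata a `reaction_dataset` or records data.frame.
#' @param threshold binary threshold on the averaged predicted yield.
#' @param ... unused.
#' @export
predict.mf_gtnn_ensemble <- function(object, newdata, threshold = 0.05, ...) {
  preds <- lapply(object$models, predict, newdata = newdata,
                  threshold = threshold)
  avg <- Reduce(`+`, lapply(preds, `[[`, "predicted_yield")) /
    length(preds)
  data.frame(reaction_id = preds[[1]]$reaction_id, predicted_yield = avg,
             predicted_binary = as.integer(avg >= threshold),
             stringsAsFactors = FALSE)
}
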