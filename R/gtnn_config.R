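# Graph transformer neural network for reaction forward prediction:
# configuration, parameter initialization and parameter accounting.
#
# Architecture: a shared two-layer atom-embedding MLP feeds two unshared
# message-passing towers (one per reactant graph).  Each tower applies
# n_layers rounds of
#     h_i^{l+1} = h_i^l + phi(h_i^l, sum_{j in N(i)} psi(h_i^l, h_j^l[, r_ij]))
# with psi and phi two-layer MLPs and, in 3D mode, r_ij the Fourier encoding
# of the conformer inter-atomic distance on covalent edges.  The per-layer
# atom representations [h^1, h^2, h^3] are concatenated, transformed by an
# MLP, and pooled by attention with learnable seed queries (the pooling core
# of a graph multiset transformer).  The two molecular vectors are
# concatenated with a learned reaction-condition embedding and mapped through
# a final MLP to a logistic-squashed scalar in [0, 1].

#' GTNN configuration
#'
#' Defaults: hidden size 128, embedding
#' size 64, 256-dimensional first post-pooling layer, three message-passing
#' layers, two pooling attention heads, batch size 16, Adam with learning
#' rate 1e-4 and a step decay of 0.5 every 100 epochs, weight smoothing
#' (EMA) factor 0.9, early stopping on validation MAE within at most 1000
#' epochs.
#'
#' @param hidden_dim atom representation width.
#' @param embed_dim molecular/condition embedding width.
#' @param post_pool_dim width of the output MLP.
#' @param n_layers message-passing rounds.
#' @param pool_heads attention heads of the multiset pooling (2 or 4).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param lr_decay_every epoch interval of the decay.
#' @param decay_mode `"step"` (decay every interval) or `"once"` (a single
#'   decay after the interval).
#' @param weight_decay decoupled (AdamW-style) L2 weight decay per step
#'   applied to all weights; 0 disables.
#' @param ema_factor exponential smoothing factor for the weight average used
#'   at validation/test time; `use_ema = FALSE` disables smoothing.
#' @param use_ema logical.
#' @param max_epochs training epoch budget (early stopping picks the best).
#' @param mode `"2d"` (bond graph only) or `"3d"` (Fourier distance features
#'   on covalent edges, conformer ensembles).
#' @param n_fourier number of Fourier frequencies (3D mode).
#' @param n_conformers conformers per molecule (3D mode).
#' @param seed integer seed driving initialization, batching and conformer
#'   selection.
#' @return object of class `gtnn_config`.
#' @export
gtnn_config <- function(hidden_dim = 128L, embed_dim = 64L,
                        post_pool_dim = 256L, n_layers = 3L, pool_heads = 2L,
                        batch_size = 16L, learning_rate = 1e-4,
                        lr_decay = 0.5, lr_decay_every = 100L,
                        decay_mode = c("step", "once"), weight_decay = 0,
                        ema_factor = 0.9,
                        use_ema = TRUE, max_epochs = 1000L,
                        mode = c("2d", "3d"), n_fourier = 16L,
                        n_conformers = 10L, seed = 1L) {
  mode <- match.arg(mode)
  decay_mode <- match.arg(decay_mode)
  dims <- c(hidden_dim, embed_dim, post_pool_dim, n_layers, pool_heads,
            batch_size, n_fourier, n_conformers)
  assert_that(all(dims >= 1), "argument_error", "all dimensions must be >= 1")
  assert_that(lr_decay > 0 && lr_decay <= 1, "argument_error",
              "lr_decay must be in (0, 1]")
  assert_that(ema_factor >= 0 && ema_factor < 1, "argument_error",
              "ema_factor must be in [0, 1)")
  assert_that(learning_rate > 0, "argument_error",
              "learning_rate must be positive")
  structure(list(
    hidden_dim = as.integer(hidden_dim), embed_dim = as.integer(embed_dim),
    post_pool_dim = as.integer(post_pool_dim), n_layers = as.integer(n_layers),
    pool_heads = as.integer(pool_heads), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, lr_decay = lr_decay,
    lr_decay_every = as.integer(lr_decay_every), decay_mode = decay_mode,
    weight_decay = weight_decay,
    ema_factor = ema_factor, use_ema = isTRUE(use_ema),
    max_epochs = as.integer(max_epochs), mode = mode,
    n_fourier = as.integer(n_fourier), n_conformers = as.integer(n_conformers),
    seed = as.integer(seed)
  ), class = "gtnn_config")
}

ATOM_FEATURE_DIM <- 20L

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize a GTNN model
#'
#' @param config a [gtnn_config()].
#' @param vocab an `mf_condition_vocab` defining the condition one-hot
#'   layout.
#' @param target `"yield"` or `"binary"` (both trained as \[0, 1\]
#'   regression).
#' @return object of class `mf_gtnn`: list with `params` (named list of
#'   weight matrices), `config`, `vocab`, `frequencies`, `target`.
#' @export
init_gtnn <- function(config, vocab, target = c("yield", "binary")) {
  target <- match.arg(target)
  h <- config$hidden_dim; e <- config$embed_dim; p <- config$post_pool_dim
  L <- config$n_layers; heads <- config$pool_heads
  n_cond <- condition_vector_length(vocab)
  rdim <- if (config$mode == "3d") 2L * config$n_fourier else 0L

  P <- with_seed(derive_seed(config$seed, "init"), {
    P <- list(
      emb.W1 = glorot(ATOM_FEATURE_DIM, e), emb.b1 = numeric(e),
      emb.W2 = glorot(e, h), emb.b2 = numeric(h),
      cond.W = glorot(n_cond, e), cond.b = numeric(e),
      head.W1 = glorot(3L * e, p), head.b1 = numeric(p),
      head.W2 = glorot(p, p), head.b2 = numeric(p),
      # start the squashed output at a low-yield prior typical of HTE
      # reaction data rather than at 0.5; avoids the early saturation plunge
      head.W3 = glorot(p, 1L), head.b3 = stats::qlogis(0.2)
    )
    for (t in c("ar", "ac")) {
      for (l in seq_len(L)) {
        P[[sprintf("%s.psi%d.W1", t, l)]] <- glorot(2L * h + rdim, 2L * h)
        P[[sprintf("%s.psi%d.b1", t, l)]] <- numeric(2L * h)
        P[[sprintf("%s.psi%d.W2", t, l)]] <- glorot(2L * h, h)
        P[[sprintf("%s.psi%d.b2", t, l)]] <- numeric(h)
        P[[sprintf("%s.phi%d.W1", t, l)]] <- glorot(2L * h, 2L * h)
        P[[sprintf("%s.phi%d.b1", t, l)]] <- numeric(2L * h)
        P[[sprintf("%s.phi%d.W2", t, l)]] <- glorot(2L * h, h)
        P[[sprintf("%s.phi%d.b2", t, l)]] <- numeric(h)
      }
      P[[paste0(t, ".fin.W1")]] <- glorot(L * h, 2L * h)
      P[[paste0(t, ".fin.b1")]] <- numeric(2L * h)
      P[[paste0(t, ".fin.W2")]] <- glorot(2L * h, h)
      P[[paste0(t, ".fin.b2")]] <- numeric(h)
      P[[paste0(t, ".pool.S")]] <- glorot(heads, h)
      P[[paste0(t, ".pool.Wq")]] <- glorot(h, h)
      P[[paste0(t, ".pool.bq")]] <- numeric(h)
      P[[paste0(t, ".pool.Wk")]] <- glorot(h, h)
      P[[paste0(t, ".pool.bk")]] <- numeric(h)
      P[[paste0(t, ".pool.Wv")]] <- glorot(h, h)
      P[[paste0(t, ".pool.bv")]] <- numeric(h)
      P[[paste0(t, ".pool.Wo")]] <- glorot(heads * h, e)
      P[[paste0(t, ".pool.bo")]] <- numeric(e)
    }
    P
  })

  structure(list(params = P, config = config, vocab = vocab,
                 frequencies = fourier_frequencies(config$n_fourier),
                 target = target),
            class = "mf_gtnn")
}

#' Number of trainable parameters
#'
#' @param x an `mf_gtnn` model, or a `gtnn_config` (then `n_cond` gives the
#'   condition vector length).
#' @param n_cond condition one-hot length (default 25: four reagents, four
#'   solvents, 11 catalysts, four additives, two atmospheres).
#' @return integer parameter count.
#' @export
parameter_count <- function(x, n_cond = 25L) {
  if (inherits(x, "gtnn_config")) {
    vocab <- structure(list(reagent = character(n_cond)),
                       class = "mf_condition_vocab")
    # build a throwaway model with a flat single-category vocabulary of the
    # requested total length
    x <- init_gtnn(x, vocab)
  }
  sum(vapply(x$params, length, 0L))
}

#' @export
print.mf_gtnn <- function(x, ...) {
  cat(sprintf(
    "<mf_gtnn> %s mode, hidden %d, %d layers, %d pooling heads, %s target\n",
    x$config$mode, x$config$hidden_dim, x$config$n_layers,
    x$config$pool_heads, x$target))
  cat(sprintf("  %d trainable parameters, condition vector length %d\n",
              parameter_count(x), condition_vector_length(x$vocab)))
  invisible(x)
}

#' Reduced desk-scale GTNN configuration
#'
#' A down-scaled configuration for CPU-only demonstration and testing:
#' hidden size 32, embedding size 16, 64-dimensional output MLP, 200 epochs.
#' The minibatch is enlarged to 256 and the learning rate raised to 2e-3 to
#' fit the shorter schedule, and a decoupled weight decay of 1e-4 counters
#' overfitting of the noise at this small hidden size.  All other settings
#' follow [gtnn_config()].
#'
#' @param seed integer seed.
#' @param mode `"2d"` or `"3d"`.
#' @param ... overrides passed to [gtnn_config()].
#' @return a `gtnn_config`.
#' @export
gtnn_config_reduced <- function(seed = 1L, mode = "2d", ...) {
  args <- list(hidden_dim = 32L, embed_dim = 16L, post_pool_dim = 64L,
               n_layers = 3L, pool_heads = 2L, batch_size = 256L,
               learning_rate = 2e-3, weight_decay = 1e-4, max_epochs = 200L,
               mode = mode, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(gtnn_config, args)
}
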