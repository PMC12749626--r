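# Shared fixtures: all built in code at test time.

# condition vocabulary with the training-plate category sizes (4/4/11/4/2)
plate_sized_vocab <- function() {
  structure(list(
    reagent = paste0("reagent", 1:4),
    solvent = paste0("solvent", 1:4),
    catalyst = paste0("catalyst", 1:11),
    additive = c("TFA", "H2SO4", "HNO3", "none"),
    atmosphere = c("air", "N2")
  ), class = "mf_condition_vocab")
}

small_vocab <- function() {
  structure(list(
    reagent = c("r1", "r2"), solvent = "s1", catalyst = c("c1", "c2", "c3"),
    additive = c("a1", "none"), atmosphere = "air"
  ), class = "mf_condition_vocab")
}

# fully crossed toy reaction table over given arene/acid/condition sets
toy_records <- function(arenes, acids, catalysts = c("c1", "c2"),
                        additives = "a1", yields = NULL) {
  g <- expand.grid(arene = arenes, acid = acids, catalyst = catalysts,
                   additive = additives, stringsAsFactors = FALSE)
  n <- nrow(g)
  data.frame(
    reaction_id = sprintf("T%04d", seq_len(n)),
    arene = g$arene, acid = g$acid, product = NA_character_,
    catalyst = g$catalyst, additive = g$additive,
    reagent = "(NH4)2S2O8", solvent = "MeCN/H2O 3:2", atmosphere = "air",
    temperature = 80, time = 18, concentration = 0.016, scale = 8e-7,
    yield_mono = if (is.null(yields)) rep(0.1, n) else yields,
    yield_di = 0,
    stringsAsFactors = FALSE
  )
}

# a small pool of distinct, valid azine and acid SMILES for split tests
toy_arenes <- function(n) {
  pool <- c("c1ccncc1", "c1cncnc1", "c1cnccn1", "c1ccnnc1", "Cc1ccncc1",
            "CCc1ccncc1", "Fc1ccncc1", "Clc1ccncc1", "Cc1cncnc1",
            "Fc1cncnc1", "CCc1cnccn1", "Cc1ccnnc1")
  stopifnot(n <= length(pool))
  pool[seq_len(n)]
}

toy_acids <- function(n) {
  pool <- c("OC(=O)C", "OC(=O)CC", "OC(=O)CCC", "OC(=O)C(C)C",
            "OC(=O)CCCC", "OC(=O)C1CC1", "OC(=O)C1CCC1", "OC(=O)C1CCCC1",
            "OC(=O)CC(C)C", "OC(=O)C(C)(C)C", "OC(=O)CCCCC", "OC(=O)CC1CC1")
  stopifnot(n <= length(pool))
  pool[seq_len(n)]
}

tiny_gtnn_config <- function(mode = "2d", seed = 7L, ...) {
  args <- list(hidden_dim = 8L, embed_dim = 5L, post_pool_dim = 6L,
               n_layers = 2L, pool_heads = 2L, batch_size = 8L,
               n_fourier = 4L, n_conformers = 2L, max_epochs = 2L,
               mode = mode, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(gtnn_config, args)
}

# stack a single pair of graphs into the internal batch layout
single_batch <- function(arene_g, acid_g, cond, cfg, freqs = NULL,
                         conf = 1L) {
  ent <- function(g) {
    Rconf <- NULL
    if (cfg$mode == "3d") {
      xyz <- g$conformers[[conf]]
      d <- sqrt(rowSums((xyz[g$edges[, 1], , drop = FALSE] -
                           xyz[g$edges[, 2], , drop = FALSE])^2))
      enc <- fourier_distance(d, freqs)
      if (is.null(dim(enc))) enc <- matrix(enc, nrow = 1)
      Rconf <- list(rbind(enc, enc))
    }
    list(X = g$features, src = c(g$edges[, 1], g$edges[, 2]),
         dst = c(g$edges[, 2], g$edges[, 1]), n = nrow(g$features),
         Rconf = Rconf)
  }
  a <- miniscifunnel:::stack_side(list(x = ent(arene_g)), "x", 1L, cfg)
  a$map <- 1L
  b <- miniscifunnel:::stack_side(list(x = ent(acid_g)), "x", 1L, cfg)
  b$map <- 1L
  list(ar = a, ac = b, C = matrix(cond, nrow = 1))
}
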