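# Atom featurization, condition encoding, Fourier distance features and the
# seeded conformer embedder.

test_that("atom features are 20-long one-hot blocks with four set bits", {
  v <- featurize_atom("C", in_ring = TRUE, aromatic = TRUE,
                      hybridization = "SP2")
  expect_length(v, 20L)
  expect_equal(sum(v), 4)
  expect_equal(v[2], 1)           # carbon slot
  expect_equal(v[13], 1)          # ring = TRUE
  expect_equal(v[15], 1)          # aromatic = TRUE
  expect_equal(v[18], 1)          # SP2

  # every supported element featurizes, including selenium and silicon
  for (el in c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I",
               "Si", "Se")) {
    vv <- featurize_atom(el, FALSE, FALSE, "SP3")
    expect_equal(sum(vv), 4)
  }
  expect_error(featurize_atom("B", FALSE, FALSE, "SP3"),
               class = "unsupported_atom_error")
  expect_error(featurize_atom("Sn", FALSE, FALSE, "SP3"),
               class = "unsupported_atom_error")
})

test_that("mol_to_graph builds explicit-hydrogen graphs", {
  g <- mol_to_graph("C")
  expect_equal(nrow(g$features), 5L)   # CH4
  expect_equal(nrow(g$edges), 4L)
  expect_true(all(rowSums(g$features) == 4))

  g2 <- mol_to_graph("c1ccncc1")
  expect_equal(length(g2$elements), 11L)  # C5H5N
  expect_equal(sum(g2$elements == "H"), 5L)
  expect_error(mol_to_graph("B1CCCCC1"), class = "unsupported_atom_error")
})

test_that("conformer ensembles have the requested size and are seeded", {
  g <- mol_to_graph("Cc1ccncc1", with_conformers = TRUE, n_conformers = 10L,
                    seed = 42L)
  expect_length(g$conformers, 10L)
  expect_true(all(vapply(g$conformers, nrow, 0L) == length(g$elements)))
  g2 <- mol_to_graph("Cc1ccncc1", with_conformers = TRUE, n_conformers = 10L,
                     seed = 42L)
  expect_identical(g$conformers, g2$conformers)   # bitwise reproducible
  g3 <- mol_to_graph("Cc1ccncc1", with_conformers = TRUE, n_conformers = 2L,
                     seed = 43L)
  expect_false(identical(g$conformers[[1]], g3$conformers[[1]]))

  # bonded distances near covalent expectations
  xyz <- g$conformers[[1]]
  d <- sqrt(rowSums((xyz[g$edges[, 1], ] - xyz[g$edges[, 2], ])^2))
  expect_true(all(d > 0.8 & d < 1.8))
})

test_that("Fourier encoding matches the analytic transcendental values", {
  f <- fourier_frequencies(16L)
  expect_length(f, 16L)
  enc0 <- fourier_distance(0, f)
  expect_equal(enc0[1:16], rep(0, 16))
  expect_equal(enc0[17:32], rep(1, 16))

  single <- 2.1
  enc <- fourier_distance(pi / single, single)
  expect_equal(enc, c(sin(pi), cos(pi)), tolerance = 1e-12)

  # random distances against a direct elementwise oracle
  set.seed(11)
  r <- runif(20, 0, 12)
  enc_m <- fourier_distance(r, f)
  oracle <- cbind(sin(outer(r, f)), cos(outer(r, f)))
  expect_equal(enc_m, oracle, tolerance = 1e-14)
  expect_error(fourier_distance(-0.1, f), class = "argument_error")
})

test_that("rigid motions leave edge Fourier encodings unchanged", {
  g <- mol_to_graph("CCc1ccncc1", with_conformers = TRUE, n_conformers = 3L,
                    seed = 5L)
  f <- fourier_frequencies(16L)
  edge_enc <- function(xyz) {
    d <- sqrt(rowSums((xyz[g$edges[, 1], ] - xyz[g$edges[, 2], ])^2))
    fourier_distance(d, f)
  }
  set.seed(99)
  for (k in seq_along(g$conformers)) {
    xyz <- g$conformers[[k]]
    # random rotation (QR of a random matrix) + translation
    qr_ <- qr(matrix(rnorm(9), 3))
    rot <- qr.Q(qr_)
    moved <- xyz %*% rot + matrix(rnorm(3), nrow(xyz), 3, byrow = TRUE)
    expect_equal(edge_enc(moved), edge_enc(xyz), tolerance = 1e-9)
  }
})

test_that("condition encoding concatenates per-category one-hots", {
  vocab <- plate_sized_vocab()
  expect_equal(miniscifunnel:::condition_vector_length(vocab), 25L)
  rec <- list(reagent = "reagent2", solvent = "solvent1",
              catalyst = "catalyst11", additive = "none", atmosphere = "N2")
  v <- encode_conditions(rec, vocab)
  expect_length(v, 25L)
  expect_equal(sum(v), 5)
  expect_equal(which(v == 1), c(2L, 5L, 19L, 23L, 25L))

  # identical labels encode identically
  expect_identical(v, encode_conditions(rec, vocab))

  rec$solvent <- "water"
  expect_error(encode_conditions(rec, vocab), class = "vocabulary_error")

  # UNK level absorbs unseen labels when enabled
  recs <- toy_records("c1ccncc1", "OC(=O)C")
  vocab2 <- condition_vocabulary(recs, unk = "solvent")
  one <- as.list(recs[1, ])
  one$solvent <- "THF"
  v2 <- encode_conditions(one, vocab2)
  expect_equal(sum(v2), 5)
})

test_that("conformers export to a readable multi-record SDF", {
  g <- mol_to_graph("CC", with_conformers = TRUE, n_conformers = 3L,
                    seed = 1L)
  path <- tempfile(fileext = ".sdf")
  write_conformers_sdf(g, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "$$$$"), 3L)
})
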