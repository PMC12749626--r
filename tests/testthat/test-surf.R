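# SURF-dialect IO and per-reaction outcome quantities.

write_fixture_surf <- function(path, n = 6L) {
  rec <- toy_records(toy_arenes(3), toy_acids(2),
                     yields = seq(0.02, 0.52, length.out = 12))[seq_len(n), ]
  ds <- reaction_dataset(rec)
  write_surf(ds, path)
  ds
}

test_that("a well-formed file round-trips through write_surf/read_surf", {
  path <- tempfile(fileext = ".surf")
  ds <- write_fixture_surf(path, 6L)
  back <- read_surf(path)
  expect_equal(nrow(back$records), 6L)
  expect_equal(back$records$arene, ds$records$arene)
  expect_equal(back$records$yield_mono, ds$records$yield_mono,
               tolerance = 1e-9)
  expect_equal(back$vocabulary, ds$vocabulary)

  # byte-identity modulo float formatting: a second write is byte-identical
  path2 <- tempfile(fileext = ".surf")
  write_surf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("yields serialize in percent and normalize back to fractions", {
  rec <- toy_records("c1ccncc1", "OC(=O)C", catalysts = "c1",
                     yields = 0.305)
  path <- tempfile(fileext = ".surf")
  write_surf(reaction_dataset(rec), path)
  raw <- read.delim(path, colClasses = "character")
  expect_equal(as.numeric(raw$product_1_yield), 30.5)
  expect_equal(read_surf(path)$records$yield_mono, 0.305)

  # fraction-dialect input is auto-detected
  raw$product_1_yield <- "0.305"
  raw$product_2_yield <- "0"
  path3 <- tempfile(fileext = ".surf")
  write.table(raw, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_surf(path3)$records$yield_mono, 0.305)
})

test_that("schema and validation errors are specific", {
  path <- tempfile(fileext = ".surf")
  write_fixture_surf(path, 4L)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")

  broken <- raw[, setdiff(names(raw), "catalyst_1_smiles")]
  p2 <- tempfile(); write.table(broken, p2, sep = "\t", quote = FALSE,
                                row.names = FALSE)
  expect_error(read_surf(p2), class = "schema_error",
               regexp = "catalyst_1_smiles")

  neg <- raw; neg$product_1_yield[2] <- "-5"
  p3 <- tempfile(); write.table(neg, p3, sep = "\t", quote = FALSE,
                                row.names = FALSE)
  expect_error(read_surf(p3), class = "validation_error")

  bad <- raw; bad$startingmat_1_smiles[1] <- "xx(("
  p4 <- tempfile(); write.table(bad, p4, sep = "\t", quote = FALSE,
                                row.names = FALSE)
  expect_error(read_surf(p4), class = "structure_error", regexp = "T0001")

  expect_error(read_surf(tempfile()), class = "io_error")

  # empty dataset: header-only file
  ds <- read_surf(p2 <- {
    empty <- raw[0, ]
    p <- tempfile(); write.table(empty, p, sep = "\t", quote = FALSE,
                                 row.names = FALSE); p
  })
  expect_equal(nrow(ds$records), 0L)
})

test_that("a column-mapping shim adapts foreign headers", {
  path <- tempfile(fileext = ".surf")
  write_fixture_surf(path, 3L)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  names(raw)[names(raw) == "rxn_id"] <- "reaction_identifier"
  p2 <- tempfile(); write.table(raw, p2, sep = "\t", quote = FALSE,
                                row.names = FALSE)
  expect_error(read_surf(p2), class = "schema_error")
  ds <- read_surf(p2, column_map = c(rxn_id = "reaction_identifier"))
  expect_equal(nrow(ds$records), 3L)
})

test_that("total yield is the clipped mono+di sum", {
  rec <- data.frame(yield_mono = c(0.25, 0, 0.9), yield_di = c(0.05, 0, 0.2))
  expect_equal(total_yield(rec), c(0.30, 0, 1.0))
  # monotone and bounded over random components
  set.seed(4)
  m <- runif(50, 0, 1); d <- runif(50, 0, 1)
  ty <- total_yield(data.frame(yield_mono = m, yield_di = d))
  expect_true(all(ty >= 0 & ty <= 1))
  ty2 <- total_yield(data.frame(yield_mono = m + 0.01, yield_di = d))
  expect_true(all(ty2 >= ty))
})

test_that("binary outcome thresholds inclusively at 5%", {
  rec <- data.frame(yield_mono = c(0.05, 0.049, 0.051, 0),
                    yield_di = c(0, 0, 0, 0))
  expect_equal(binary_outcome(rec), c(1L, 0L, 1L, 0L))
  # the label flips only across the threshold
  eps <- 1e-9
  expect_equal(binary_outcome(data.frame(yield_mono = 0.05 - eps,
                                         yield_di = 0)), 0L)
  expect_equal(binary_outcome(data.frame(yield_mono = 0.05 + eps,
                                         yield_di = 0)), 1L)
  expect_error(binary_outcome(rec, threshold = 1.2),
               class = "argument_error")
})

test_that("dataset_summary counts positives and coverage", {
  yields <- c(rep(0.2, 3), rep(0.01, 7))
  rec <- toy_records(toy_arenes(5), toy_acids(2), catalysts = "c1",
                     yields = yields)
  ds <- reaction_dataset(rec)
  s <- dataset_summary(ds)
  expect_equal(s$n, 10L)
  expect_equal(s$positive_rate, 0.3)
  expect_equal(sum(s$yield_histogram), 3)
  expect_equal(dim(s$coverage), c(5L, 2L))

  all_low <- reaction_dataset(toy_records("c1ccncc1", toy_acids(3),
                                          yields = 0.01))
  expect_equal(dataset_summary(all_low)$positive_rate, 0)

  empty <- reaction_dataset(toy_records("c1ccncc1", "OC(=O)C")[0, ])
  expect_error(dataset_summary(empty), class = "empty_input_error")
})
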