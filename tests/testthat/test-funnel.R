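# Prioritization funnel: staged thresholds, ranking, unit conversions and
# the scorer registry.

test_that("funnel stages equal brute-force set filtering", {
  cards <- generate_scorecards(100L, seed = 5L)
  cfg <- funnel_config()
  fr <- apply_funnel(cards, cfg)
  s1 <- cards$pic50_pred >= 6
  s2 <- s1 & cards$yield_pred >= 0.05
  s3 <- s2 & cards$pic50_pred >= 8
  expect_equal(unname(fr$counts["stage1_potency"]), sum(s1))
  expect_equal(unname(fr$counts["stage2_yield"]), sum(s2))
  expect_equal(unname(fr$counts["stage3_potency"]), sum(s3))
  expect_setequal(fr$stage3, paste(cards$scaffold_id, cards$acid_id,
                                   sep = "|")[s3])
})

test_that("boundary candidates survive all inclusive thresholds", {
  card <- data.frame(scaffold_id = "S", acid_id = "A", pic50_pred = 8.0,
                     yield_pred = 0.05, logd = 2, lysa = 100,
                     pgp_ratio = 1, pampa = 10)
  fr <- apply_funnel(card, funnel_config())
  expect_equal(unname(fr$counts["stage3_potency"]), 1L)

  empty <- apply_funnel(card[0, ], funnel_config())
  expect_equal(unname(empty$counts["stage1_potency"]), 0L)
  expect_equal(nrow(empty$ranked), 0L)
})

test_that("stages nest and respond monotonically to thresholds", {
  cards <- generate_scorecards(2000L, seed = 9L)
  prev <- c(Inf, Inf, Inf)
  for (s1 in c(5, 6, 7)) {
    for (yld in c(0.02, 0.05, 0.2)) {
      fr <- apply_funnel(cards, funnel_config(potency_stage1_min = s1,
                                              yield_min = yld,
                                              potency_stage3_min = max(8, s1)))
      expect_true(all(fr$stage3 %in% fr$stage2))
      expect_true(all(fr$stage2 %in% fr$stage1))
    }
  }
  # raising one threshold never increases downstream counts
  base <- apply_funnel(cards, funnel_config())
  tighter <- apply_funnel(cards, funnel_config(yield_min = 0.2))
  expect_true(all(tighter$counts[1:3] <= base$counts[1:3] |
                    is.na(tighter$counts[1:3])))
})

test_that("ranking is deterministic: potency, then yield, then key", {
  cards <- data.frame(
    scaffold_id = c("S1", "S2", "S3", "S4"), acid_id = rep("A", 4),
    pic50_pred = c(9, 9, 10, 9), yield_pred = c(0.3, 0.5, 0.1, 0.3),
    logd = 1, lysa = 1, pgp_ratio = 1, pampa = 1)
  fr <- apply_funnel(cards, funnel_config())
  expect_equal(fr$ranked$scaffold_id, c("S3", "S2", "S1", "S4"))
})

test_that("ADME windows annotate by default and eliminate in strict mode", {
  cards <- generate_scorecards(500L, seed = 2L)
  win <- list(logd = c(1, 3), pampa = c(5, 30))
  soft <- apply_funnel(cards, funnel_config(adme_windows = win))
  expect_true(is.na(soft$counts["stage4_adme"]))
  expect_true("adme_in_window" %in% names(soft$ranked))
  strict <- apply_funnel(cards, funnel_config(adme_windows = win,
                                              strict_adme = TRUE))
  expect_lte(unname(strict$counts["stage4_adme"]),
             unname(strict$counts["stage3_potency"]))
  in_all <- cards$logd >= 1 & cards$logd <= 3 & cards$pampa >= 5 &
    cards$pampa <= 30 & cards$pic50_pred >= 8 & cards$yield_pred >= 0.05
  expect_equal(unname(strict$counts["stage4_adme"]), sum(in_all))
})

test_that("LipE and pIC50 conversions follow their definitions", {
  expect_equal(lipe(7, 3), 4)
  expect_equal(lipe(5.5, 5.5), 0)
  set.seed(1)
  a <- runif(20, 4, 11); b <- runif(20, -1, 6)
  expect_equal(lipe(a, b), a - b)

  expect_equal(pic50_from_ic50(1), 9)
  expect_equal(pic50_from_ic50(0.025), 10.6, tolerance = 5e-3)
  expect_equal(pic50_from_ic50(5.01), 8.3, tolerance = 5e-3)
  expect_equal(ic50_from_pic50(pic50_from_ic50(0.398)), 0.398,
               tolerance = 1e-12)
  expect_error(pic50_from_ic50(0), class = "argument_error")
  expect_error(pic50_from_ic50(-1), class = "argument_error")
})

test_that("the scorer registry enforces unique names and runs built-ins", {
  expect_true(all(c("potency:synthetic", "adme:toy-logp") %in%
                    list_scorers()))
  expect_error(register_scorer("potency:synthetic", function(x) 0),
               class = "registration_error")
  register_scorer("test:dummy", function(cand) rep(1, nrow(cand)),
                  overwrite = TRUE)
  expect_true("test:dummy" %in% list_scorers())
  expect_error(get_scorer("nope"), class = "registration_error")

  st <- generate_structures(synthetic_spec(n_arenes = 5L, n_acids = 2L,
                                           seed = 8L))
  lib <- enumerate_products(st$scaffolds, st$acids)
  cand <- data.frame(
    scaffold_smiles = st$scaffolds$smiles[match(lib$scaffold_id,
                                                st$scaffolds$scaffold_id)],
    acid_smiles = st$acids$smiles[match(lib$acid_id, st$acids$acid_id)],
    product_smiles = lib$product)
  pot <- get_scorer("potency:synthetic")$fun(cand)
  expect_length(pot, 10L)
  expect_true(all(is.finite(pot) & pot >= 4 & pot <= 10))
  # deterministic across calls
  expect_identical(pot, get_scorer("potency:synthetic")$fun(cand))
  logd <- get_scorer("adme:toy-logp")$fun(cand)
  expect_true(all(is.finite(logd)))
})
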