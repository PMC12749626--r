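# Fully synthetic Minisci-style reaction data with a planted, recoverable
# yield surface, so the entire pipeline is testable without experimental data.
#
# The generator emulates the screening campaign's shape: a grid of N-arenes x
# carboxylic acids x a 24-well condition plate (six silver-salt catalysts x
# four additive levels, single oxidant/solvent/atmosphere), screened at ~12%
# coverage, with ~30% of reactions positive at the 5% total-yield threshold.
# The latent yield surface is additive per-arene + per-acid effects plus one
# catalyst x additive interaction plus Gaussian noise; entity-held-out splits
# are therefore provably harder than random splits (a novel arene carries an
# unseen arene effect).

PLATE_CATALYSTS <- c("AgNO3", "AgBF4", "Ag-pTsOH", "AgCF3SO3", "AgCO2CH3",
                     "AgSCF3")
PLATE_ADDITIVES <- c("TFA", "H2SO4", "HNO3", "none")
PLATE_REAGENT <- "(NH4)2S2O8"
PLATE_SOLVENT <- "MeCN/H2O 3:2"
PLATE_ATMOSPHERE <- "air"

ARENE_CORES <- c(
  pyridine = "c1ccncc1",
  pyrimidine = "c1cncnc1",
  pyrazine = "c1cnccn1",
  pyridazine = "c1ccnnc1",
  quinoline = "c1ccc2ncccc2c1",
  isoquinoline = "c1ccc2cnccc2c1",
  quinoxaline = "c1ccc2nccnc2c1"
)
ARENE_SUBSTITUENTS <- c("C", "CC", "C(C)C", "F", "Cl", "OC", "C(F)(F)F",
                        "CC(C)C")

#' Specification for the synthetic reaction-data generator
#'
#' Defaults mirror the screening campaign's dimensions: 80 N-arene fragments,
#' 59 carboxylic acids, a 6 catalyst x 4 additive condition plate, 12% grid
#' coverage and a 30% positive rate at the 5% total-yield threshold.
#'
#' @param n_arenes number of distinct N-heteroarene scaffolds.
#' @param n_acids number of distinct carboxylic acids.
#' @param n_catalysts,n_additives condition plate dimensions (at most the 6
#'   silver salts / 4 additive levels of the screening plate).
#' @param coverage_fraction fraction of the arene x acid x condition grid that
#'   is "screened".
#' @param target_positive_rate intended fraction of reactions with total
#'   yield >= 5%.
#' @param noise_sd standard deviation of the Gaussian yield noise (fraction
#'   units).
#' @param arene_effect_sd,acid_effect_sd,interaction_sd scales of the planted
#'   entity and condition effects (yield-fraction units).
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_arenes = 80L, n_acids = 59L, n_catalysts = 6L,
                           n_additives = 4L, coverage_fraction = 0.12,
                           target_positive_rate = 0.30, noise_sd = 0.05,
                           arene_effect_sd = 0.14, acid_effect_sd = 0.10,
                           interaction_sd = 0.07, seed = 1L) {
  assert_that(n_arenes >= 1 && n_acids >= 1, "argument_error",
              "counts must be positive")
  assert_that(n_catalysts >= 1 && n_catalysts <= length(PLATE_CATALYSTS),
              "argument_error", "n_catalysts must be in 1..%d",
              length(PLATE_CATALYSTS))
  assert_that(n_additives >= 1 && n_additives <= length(PLATE_ADDITIVES),
              "argument_error", "n_additives must be in 1..%d",
              length(PLATE_ADDITIVES))
  assert_that(coverage_fraction > 0 && coverage_fraction <= 1,
              "argument_error", "coverage_fraction must be in (0, 1]")
  assert_that(target_positive_rate > 0 && target_positive_rate < 1,
              "argument_error", "target_positive_rate must be in (0, 1)")
  assert_that(noise_sd >= 0, "argument_error", "noise_sd must be >= 0")
  structure(list(
    n_arenes = as.integer(n_arenes), n_acids = as.integer(n_acids),
    n_catalysts = as.integer(n_catalysts),
    n_additives = as.integer(n_additives),
    coverage_fraction = coverage_fraction,
    target_positive_rate = target_positive_rate, noise_sd = noise_sd,
    arene_effect_sd = arene_effect_sd, acid_effect_sd = acid_effect_sd,
    interaction_sd = interaction_sd, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

sample_arene_smiles <- function() {
  core <- sample(ARENE_CORES, 1L)
  n_sub <- sample(0:2, 1L, prob = c(0.2, 0.45, 0.35))
  s <- core
  if (n_sub > 0L) {
    for (dummy in seq_len(n_sub)) {
      mol <- parse_smiles(s)
      cand <- which(mol$atoms$aromatic & mol$atoms$element == "C" &
                      mol$atoms$nH >= 1L) - 1L
      if (length(cand) <= 1L) break  # keep at least one free site
      pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
      s <- splice_smiles(s, pos, sample(ARENE_SUBSTITUENTS, 1L))
    }
  }
  # must retain a resolvable Minisci site
  ok <- tryCatch({suggest_site(s); TRUE}, error = function(e) FALSE)
  if (!ok) return(NULL)
  s
}

sample_acid_smiles <- function() {
  # branched/cyclic alkyl fragment, then the carboxyl head
  ring_opts <- c("C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1",
                 "C1CC(C)C1", "C1CCC(C)C1", "C1CC1C", "C1CCC1C")
  n_chain <- sample(0:5, 1L)
  frag <- character(0)
  if (n_chain > 0L) {
    units <- sample(c("C", "C(C)", "C(C)(C)"), n_chain, replace = TRUE,
                    prob = c(0.7, 0.2, 0.1))
    frag <- units
  }
  u <- stats::runif(1)
  tail_part <- if (u < 0.4) sample(ring_opts, 1L)
  else if (u < 0.5) "C(F)(F)F" else "C"
  paste0("OC(=O)", paste(frag, collapse = ""), tail_part)
}

#' Generate synthetic scaffold and acid structure lists
#'
#' Draws `n_arenes` distinct substituted azine/diazine/quinoline SMILES from a
#' parametric scaffold grammar (each with a resolvable alkylation site) and
#' `n_acids` distinct sp3-rich alkyl/cycloalkyl carboxylic acids with
#' molecular weight below 230 g/mol.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `scaffolds` (data.frame: `scaffold_id`, `smiles`, `site`)
#'   and `acids` (data.frame: `acid_id`, `smiles`, `mw`, `fsp3`).
#' @export
generate_structures <- function(spec) {
  with_seed(derive_seed(spec$seed, "structures"), {
    draw_unique <- function(n, sampler, what) {
      seen_canon <- character(0)
      smiles <- character(0)
      tries <- 0L
      while (length(smiles) < n) {
        tries <- tries + 1L
        if (tries > 300L * n) {
          stop_mf("generation_error",
                  "could not draw %d distinct %s structures", n, what)
        }
        s <- sampler()
        if (is.null(s) || s %in% smiles) next
        cn <- canonical_smiles(s)
        if (is.na(cn) || cn %in% seen_canon) next
        seen_canon <- c(seen_canon, cn)
        smiles <- c(smiles, s)
      }
      smiles
    }
    arene_smiles <- draw_unique(spec$n_arenes, sample_arene_smiles, "arene")
    acid_smiles <- draw_unique(spec$n_acids, function() {
      s <- sample_acid_smiles()
      if (mol_weight(s) < 230) s else NULL
    }, "acid")

    scaffolds <- data.frame(
      scaffold_id = sprintf("F%d", seq_len(spec$n_arenes)),
      smiles = arene_smiles,
      site = vapply(arene_smiles, suggest_site, 0L, USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
    acids <- data.frame(
      acid_id = sprintf("A%d", seq_len(spec$n_acids)),
      smiles = acid_smiles,
      mw = vapply(acid_smiles, mol_weight, 0, USE.NAMES = FALSE),
      fsp3 = vapply(acid_smiles, fsp3, 0, USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
    list(scaffolds = scaffolds, acids = acids)
  })
}

#' Generate a synthetic reaction dataset with a planted yield surface
#'
#' Subsamples the arene x acid x condition grid and assigns each sampled
#' reaction a latent yield `clip01(base + arene_effect + acid_effect +
#' catalyst:additive interaction + noise)`.  The global intercept `base` is
#' calibrated on the sampled latents so that the fraction of reactions with
#' total yield >= 5% matches `target_positive_rate`.  The total yield is then
#' split into mono/di components with the di share at most the mono share.
#'
#' @param spec a `synthetic_spec`.
#' @param n_records optional record-count override (subsample size of the
#'   grid); defaults to `coverage_fraction` of the full grid.
#' @param structures optional precomputed output of [generate_structures()].
#' @return a `reaction_dataset`; the planted effects are attached as
#'   `attr(x, "planted")` (list: `arene_effect`, `acid_effect`, `interaction`,
#'   `base`, `latent`).
#' @export
generate_dataset <- function(spec, n_records = NULL, structures = NULL) {
  if (is.null(structures)) structures <- generate_structures(spec)
  scaff <- structures$scaffolds
  acids <- structures$acids
  n_cond <- spec$n_catalysts * spec$n_additives
  grid_size <- nrow(scaff) * nrow(acids) * n_cond
  n <- if (is.null(n_records)) round(spec$coverage_fraction * grid_size)
  else as.integer(n_records)
  assert_that(n >= 1L, "generation_error",
              "coverage too low: empty dataset (grid %d cells)", grid_size)
  assert_that(n <= grid_size, "argument_error",
              "n_records exceeds grid size %d", grid_size)

  with_seed(derive_seed(spec$seed, "dataset"), {
    cells <- sample.int(grid_size, n)
    # cell -> (arene, acid, condition) in condition-fastest order
    cond_i <- (cells - 1L) %% n_cond + 1L
    rest <- (cells - 1L) %/% n_cond
    acid_i <- rest %% nrow(acids) + 1L
    arene_i <- rest %/% nrow(acids) + 1L
    cat_i <- (cond_i - 1L) %% spec$n_catalysts + 1L
    add_i <- (cond_i - 1L) %/% spec$n_catalysts + 1L

    arene_eff <- stats::rnorm(nrow(scaff), sd = spec$arene_effect_sd)
    acid_eff <- stats::rnorm(nrow(acids), sd = spec$acid_effect_sd)
    inter <- matrix(stats::rnorm(n_cond, sd = spec$interaction_sd),
                    nrow = spec$n_catalysts)
    noise <- stats::rnorm(n, sd = spec$noise_sd)

    raw <- arene_eff[arene_i] + acid_eff[acid_i] +
      inter[cbind(cat_i, add_i)] + noise
    base <- 0.05 - stats::quantile(raw, 1 - spec$target_positive_rate,
                                   names = FALSE)
    latent <- clip01(raw + base)

    mono_share <- stats::runif(n, 0.6, 1)
    records <- data.frame(
      reaction_id = sprintf("R%05d", seq_len(n)),
      arene = scaff$smiles[arene_i],
      acid = acids$smiles[acid_i],
      product = NA_character_,
      catalyst = PLATE_CATALYSTS[cat_i],
      additive = PLATE_ADDITIVES[add_i],
      reagent = PLATE_REAGENT,
      solvent = PLATE_SOLVENT,
      atmosphere = PLATE_ATMOSPHERE,
      temperature = 80,
      time = 18,
      concentration = 0.016,
      scale = 8e-07,
      yield_mono = latent * mono_share,
      yield_di = latent * (1 - mono_share),
      stringsAsFactors = FALSE
    )
    ds <- reaction_dataset(records, validate_structures = FALSE)
    attr(ds, "planted") <- list(
      arene_effect = stats::setNames(arene_eff, scaff$smiles),
      acid_effect = stats::setNames(acid_eff, acids$smiles),
      interaction = inter, base = base, latent = latent,
      structures = structures
    )
    ds
  })
}

#' Generate synthetic candidate scorecards
#'
#' Cards with independent uniform endpoint draws, so funnel stage counts have
#' closed-form expectations: pIC50 ~ U(4, 10), predicted yield ~ U(0, 0.5),
#' LogD ~ U(0, 4), LYSA ~ U(1, 500) ug/mL, P-gp efflux ratio ~ U(0.2, 5),
#' PAMPA ~ U(0, 30) 1e-6 cm/s.
#'
#' @param n number of cards.
#' @param seed integer seed.
#' @return data.frame of class `mf_scorecards` with columns `scaffold_id`,
#'   `acid_id`, `pic50_pred`, `yield_pred`, `logd`, `lysa`, `pgp_ratio`,
#'   `pampa`.
#' @export
generate_scorecards <- function(n, seed = 1L) {
  assert_that(n >= 0L, "argument_error", "n must be >= 0")
  with_seed(derive_seed(seed, "scorecards"), {
    df <- data.frame(
      scaffold_id = sprintf("S%d", seq_len(n)),
      acid_id = sprintf("A%d", seq_len(n)),
      pic50_pred = stats::runif(n, 4, 10),
      yield_pred = stats::runif(n, 0, 0.5),
      logd = stats::runif(n, 0, 4),
      lysa = stats::runif(n, 1, 500),
      pgp_ratio = stats::runif(n, 0.2, 5),
      pampa = stats::runif(n, 0, 30),
      stringsAsFactors = FALSE
    )
    class(df) <- c("mf_scorecards", "data.frame")
    df
  })
}
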