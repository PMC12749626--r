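# Multi-dimensional optimization funnel: staged potency / synthesizability
# filters over candidate scorecards, ADME annotation, ranking, and the
# pluggable scorer registry.

#' Funnel configuration
#'
#' Staged thresholds of the prioritization cascade: stage 1 keeps candidates
#' with predicted pIC50 at or above `potency_stage1_min`, stage 2 additionally
#' requires a predicted reaction yield at or above `yield_min` (synthetic
#' accessibility), stage 3 tightens potency to `potency_stage3_min`.  All
#' boundaries are inclusive.  ADME windows, when given, annotate and rank by
#' default; `strict_adme = TRUE` adds a fourth elimination stage (sequential
#' hard ADME cuts propagate model error, so annotation is the default).
#'
#' @param potency_stage1_min stage-1 pIC50 threshold (default 6).
#' @param yield_min stage-2 predicted-yield threshold, fraction (default
#'   0.05).
#' @param potency_stage3_min stage-3 pIC50 threshold (default 8).
#' @param adme_windows optional named list of `c(lo, hi)` ranges for any of
#'   `logd`, `lysa`, `pgp_ratio`, `pampa`.
#' @param strict_adme eliminate (rather than annotate) outside the windows.
#' @return object of class `funnel_config`.
#' @export
funnel_config <- function(potency_stage1_min = 6, yield_min = 0.05,
                          potency_stage3_min = 8, adme_windows = NULL,
                          strict_adme = FALSE) {
  assert_that(yield_min >= 0 && yield_min <= 1, "argument_error",
              "yield_min must be in [0, 1]")
  assert_that(potency_stage3_min >= potency_stage1_min, "argument_error",
              "stage-3 potency threshold must be >= stage-1 threshold")
  if (!is.null(adme_windows)) {
    bad <- setdiff(names(adme_windows), c("logd", "lysa", "pgp_ratio", "pampa"))
    assert_that(length(bad) == 0L, "argument_error",
                "unknown ADME endpoint(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(potency_stage1_min = potency_stage1_min,
                 yield_min = yield_min,
                 potency_stage3_min = potency_stage3_min,
                 adme_windows = adme_windows, strict_adme = strict_adme),
            class = "funnel_config")
}

card_key <- function(cards) paste(cards$scaffold_id, cards$acid_id, sep = "|")

#' Apply the multi-stage prioritization funnel
#'
#' @param cards a data.frame of candidate scorecards (see
#'   [generate_scorecards()] for the columns).
#' @param config a [funnel_config()].
#' @return object of class `funnel_result`: per-stage survivor keys and
#'   counts, ADME window annotations, and the final ranked table (descending
#'   predicted pIC50, ties by descending predicted yield, then key).
#' @export
apply_funnel <- function(cards, config = funnel_config()) {
  assert_that(inherits(config, "funnel_config"), "argument_error",
              "config must be a funnel_config")
  cards <- as.data.frame(cards)
  key <- card_key(cards)

  s1 <- cards$pic50_pred >= config$potency_stage1_min
  s2 <- s1 & cards$yield_pred >= config$yield_min
  s3 <- s2 & cards$pic50_pred >= config$potency_stage3_min

  annotations <- NULL
  s4 <- s3
  if (!is.null(config$adme_windows) && nrow(cards) > 0L) {
    in_win <- vapply(names(config$adme_windows), function(ep) {
      w <- config$adme_windows[[ep]]
      cards[[ep]] >= w[1] & cards[[ep]] <= w[2]
    }, logical(nrow(cards)))
    in_win <- matrix(in_win, nrow = nrow(cards),
                     dimnames = list(NULL, names(config$adme_windows)))
    annotations <- data.frame(key = key, in_win,
                              n_in_window = rowSums(in_win),
                              check.names = FALSE)
    if (config$strict_adme) s4 <- s3 & rowSums(in_win) == ncol(in_win)
  }

  final <- if (config$strict_adme) s4 else s3
  ranked <- cards[final, , drop = FALSE]
  ranked_key <- key[final]
  if (nrow(ranked) > 0L) {
    ord <- order(-ranked$pic50_pred, -ranked$yield_pred, ranked_key)
    ranked <- ranked[ord, , drop = FALSE]
    rownames(ranked) <- NULL
  }
  if (!is.null(annotations) && nrow(ranked) > 0L) {
    m <- match(card_key(ranked), annotations$key)
    ranked$adme_in_window <- annotations$n_in_window[m]
  }

  structure(list(
    n_input = nrow(cards),
    counts = c(stage1_potency = sum(s1), stage2_yield = sum(s2),
               stage3_potency = sum(s3),
               stage4_adme = if (config$strict_adme) sum(s4) else NA_integer_),
    stage1 = key[s1], stage2 = key[s2], stage3 = key[s3],
    stage4 = if (config$strict_adme) key[s4] else NULL,
    annotations = annotations,
    ranked = ranked,
    config = config
  ), class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat(sprintf("<funnel_result> %d candidates in\n", x$n_input))
  cat(sprintf("  stage 1 (pIC50 >= %g):        %d\n",
              x$config$potency_stage1_min, x$counts[["stage1_potency"]]))
  cat(sprintf("  stage 2 (+ yield >= %g%%):     %d\n",
              100 * x$config$yield_min, x$counts[["stage2_yield"]]))
  cat(sprintf("  stage 3 (pIC50 >= %g):        %d\n",
              x$config$potency_stage3_min, x$counts[["stage3_potency"]]))
  if (!is.na(x$counts[["stage4_adme"]])) {
    cat(sprintf("  stage 4 (ADME windows):       %d\n",
                x$counts[["stage4_adme"]]))
  }
  invisible(x)
}

#' Lipophilic efficiency
#'
#' `LipE = pIC50 - cLogP`, the standard potency/lipophilicity balance metric.
#'
#' @param pic50 potency in -log10 mol/L units.
#' @param clogp calculated LogP.
#' @return LipE value(s).
#' @export
lipe <- function(pic50, clogp) {
  assert_that(all(is.finite(pic50)) && all(is.finite(clogp)),
              "argument_error", "inputs must be finite")
  pic50 - clogp
}

#' Convert between IC50 (nM) and pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar IC50; for an IC50
#' given in nanomolar, `pIC50 = 9 - log10(IC50_nM)`.
#'
#' @param ic50 half-maximal inhibitory concentration in nM (positive).
#' @return `pic50_from_ic50`: pIC50 in log units; `ic50_from_pic50`: nM.
#' @export
#' @examples
#' pic50_from_ic50(1)      # 9
#' pic50_from_ic50(0.025)  # 10.6
pic50_from_ic50 <- function(ic50) {
  assert_that(all(ic50 > 0), "argument_error", "ic50 must be positive")
  9 - log10(ic50)
}

#' @rdname pic50_from_ic50
#' @param pic50 potency in pIC50 units.
#' @export
ic50_from_pic50 <- function(pic50) {
  assert_that(all(is.finite(pic50)), "argument_error",
              "pic50 must be finite")
  10^(9 - pic50)
}

# ---- scorer registry --------------------------------------------------------

scorer_registry <- new.env(parent = emptyenv())

#' Register a candidate scorer
#'
#' Scorers are pluggable endpoint predictors used to build scorecards for the
#' funnel.  A scorer is a function taking a data.frame of candidates (columns
#' `scaffold_smiles`, `acid_smiles`, `product_smiles`; plus condition columns
#' when the scorer needs them) and returning one numeric value per row.
#'
#' Built-ins registered at load: `potency:synthetic` (a deterministic toy
#' pIC50 in \[4, 10\] hashed from the product structure; for pipeline testing
#' only, no relation to any real potency model) and `adme:toy-logp` (a crude
#' atom-count lipophilicity score; equally a stand-in).  A yield scorer
#' wrapping a trained model is created with [scorer_yield_gtnn()] and can be
#' registered as `yield:gtnn`.
#'
#' @param name scorer name, conventionally `endpoint:flavor`.
#' @param scorer the scoring function.
#' @param endpoint endpoint label (e.g. `"pic50"`, `"yield"`, `"logd"`).
#' @param units unit string for documentation.
#' @param overwrite replace an existing registration.
#' @return invisibly, the name.
#' @export
register_scorer <- function(name, scorer, endpoint = NA_character_,
                            units = NA_character_, overwrite = FALSE) {
  assert_that(is.function(scorer), "argument_error", "scorer must be a function")
  if (!overwrite && !is.null(scorer_registry[[name]])) {
    stop_mf("registration_error", "scorer '%s' already registered", name)
  }
  scorer_registry[[name]] <- list(fun = scorer, endpoint = endpoint,
                                  units = units)
  invisible(name)
}

#' @rdname register_scorer
#' @export
get_scorer <- function(name) {
  s <- scorer_registry[[name]]
  if (is.null(s)) stop_mf("registration_error", "no scorer named '%s'", name)
  s
}

#' @rdname register_scorer
#' @export
list_scorers <- function() sort(ls(scorer_registry))

# deterministic string hash -> [0, 1)
unit_hash <- function(x) {
  vapply(x, function(s) {
    v <- utf8ToInt(s)
    h <- 0
    for (ch in v) h <- (h * 131 + ch) %% 1e9
    h / 1e9
  }, 0, USE.NAMES = FALSE)
}

toy_potency_scorer <- function(candidates) {
  4 + 6 * unit_hash(paste0("potency|", candidates$product_smiles))
}

toy_logp_scorer <- function(candidates) {
  vapply(candidates$product_smiles, function(s) {
    mol <- parse_smiles(s)
    nc <- sum(mol$atoms$element == "C")
    n_het <- sum(mol$atoms$element %in% c("N", "O"))
    n_hal <- sum(mol$atoms$element %in% c("F", "Cl", "Br", "I"))
    0.35 * nc - 0.6 * n_het + 0.3 * n_hal
  }, 0, USE.NAMES = FALSE)
}

register_builtin_scorers <- function() {
  register_scorer("potency:synthetic", toy_potency_scorer,
                  endpoint = "pic50", units = "-log10(mol/L)",
                  overwrite = TRUE)
  register_scorer("adme:toy-logp", toy_logp_scorer,
                  endpoint = "logd", units = "log units", overwrite = TRUE)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_scorers()
}
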