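# Reading, validating and writing reaction datasets in a SURF-compatible
# tab-separated dialect, and per-reaction outcome quantities.
#
# Dialect (UTF-8, tab-separated, header required): columns `rxn_id`,
# `startingmat_1_smiles` (N-arene), `startingmat_2_smiles` (carboxylic acid),
# `product_1_smiles` (optional), `catalyst_1_smiles`, `additive_1_smiles`,
# `reagent_1_smiles`, `solvent_1_smiles`, `atmosphere`, `temperature_deg_c`,
# `time_h`, `concentration_moll`, `scale_mol`, `product_1_yield` (mono),
# `product_2_yield` (di, optional, default 0).  Yields are serialized as
# percent and held internally as fractions in [0, 1].  Extra columns are
# accepted silently.

SURF_REQUIRED <- c(
  "rxn_id", "startingmat_1_smiles", "startingmat_2_smiles",
  "catalyst_1_smiles", "additive_1_smiles", "reagent_1_smiles",
  "solvent_1_smiles", "atmosphere", "temperature_deg_c", "time_h",
  "concentration_moll", "scale_mol", "product_1_yield"
)
SURF_OPTIONAL <- c("product_1_smiles", "product_2_yield")

SURF_TO_INTERNAL <- c(
  rxn_id = "reaction_id", startingmat_1_smiles = "arene",
  startingmat_2_smiles = "acid", product_1_smiles = "product",
  catalyst_1_smiles = "catalyst", additive_1_smiles = "additive",
  reagent_1_smiles = "reagent", solvent_1_smiles = "solvent",
  atmosphere = "atmosphere", temperature_deg_c = "temperature",
  time_h = "time", concentration_moll = "concentration", scale_mol = "scale",
  product_1_yield = "yield_mono", product_2_yield = "yield_di"
)

#' Construct a reaction dataset
#'
#' Validates records and builds the per-category condition vocabulary
#' (first-appearance order).
#'
#' @param records data.frame with columns `reaction_id`, `arene`, `acid`,
#'   `product` (optional, may be `NA`), `catalyst`, `additive`, `reagent`,
#'   `solvent`, `atmosphere`, `temperature`, `time`, `concentration`,
#'   `scale`, `yield_mono`, `yield_di`.  Yields are fractions in \[0, 1\].
#' @param validate_structures parse every arene/acid SMILES (slower; disable
#'   for very large, already-validated tables).
#' @return object of class `reaction_dataset`: list with `records` and
#'   `vocabulary`.
#' @export
reaction_dataset <- function(records, validate_structures = TRUE) {
  needed <- c("reaction_id", "arene", "acid", "catalyst", "additive",
              "reagent", "solvent", "atmosphere", "temperature", "time",
              "concentration", "scale", "yield_mono", "yield_di")
  missing_cols <- setdiff(needed, names(records))
  assert_that(length(missing_cols) == 0L, "schema_error",
              "missing required column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (!"product" %in% names(records)) records$product <- NA_character_

  assert_that(!anyDuplicated(records$reaction_id), "validation_error",
              "duplicate reaction_id values")
  if (any(records$yield_mono < 0 | records$yield_di < 0, na.rm = TRUE)) {
    stop_mf("validation_error", "negative yield values present")
  }
  for (cat in CONDITION_CATEGORIES) {
    v <- as.character(records[[cat]])
    assert_that(all(!is.na(v) & nzchar(v)), "validation_error",
                "empty %s label(s)", cat)
  }
  # LC-MS area percentages can slightly oversum; clip rather than error
  records$yield_mono <- pmin(records$yield_mono, 1)
  records$yield_di <- pmin(records$yield_di, 1 - records$yield_mono)

  if (isTRUE(validate_structures)) {
    for (k in seq_len(nrow(records))) {
      for (col in c("arene", "acid")) {
        ok <- tryCatch({parse_smiles(records[[col]][k]); TRUE},
                       error = function(e) conditionMessage(e))
        if (!isTRUE(ok)) {
          stop_mf("structure_error",
                  "record '%s': unparsable %s structure (%s)",
                  records$reaction_id[k], col, ok)
        }
      }
    }
  }

  structure(
    list(records = records, vocabulary = condition_vocabulary(records)),
    class = "reaction_dataset"
  )
}

#' @export
print.reaction_dataset <- function(x, ...) {
  cat(sprintf(
    "<reaction_dataset> %d reactions, %d arenes x %d acids, %d catalysts\n",
    nrow(x$records), length(unique(x$records$arene)),
    length(unique(x$records$acid)), length(x$vocabulary$catalyst)))
  invisible(x)
}

#' Read a SURF-dialect reaction table
#'
#' @param path file path.
#' @param yields `"auto"` (percent when any yield exceeds 1.5, else fraction),
#'   `"percent"`, or `"fraction"`.
#' @param column_map optional named character vector mapping dialect column
#'   names to the file's actual header names (loader shim for externally
#'   deposited files), e.g. `c(rxn_id = "reaction_identifier")`.
#' @param validate_structures parse and validate every structure (default
#'   TRUE).
#' @return a `reaction_dataset`.
#' @export
read_surf <- function(path, yields = c("auto", "percent", "fraction"),
                      column_map = NULL, validate_structures = TRUE) {
  yields <- match.arg(yields)
  assert_that(file.exists(path), "io_error", "file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      actual <- column_map[[std]]
      if (actual %in% names(raw)) {
        names(raw)[names(raw) == actual] <- std
      }
    }
  }
  missing_cols <- setdiff(SURF_REQUIRED, names(raw))
  assert_that(length(missing_cols) == 0L, "schema_error",
              "SURF file lacks required column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (!"product_2_yield" %in% names(raw)) raw$product_2_yield <- "0"
  if (!"product_1_smiles" %in% names(raw)) raw$product_1_smiles <- NA_character_

  keep <- intersect(names(SURF_TO_INTERNAL), names(raw))
  rec <- raw[, keep, drop = FALSE]
  names(rec) <- SURF_TO_INTERNAL[keep]

  for (col in c("temperature", "time", "concentration", "scale",
                "yield_mono", "yield_di")) {
    rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))
  }
  rec$yield_mono[is.na(rec$yield_mono)] <- 0
  rec$yield_di[is.na(rec$yield_di)] <- 0
  if (any(rec$yield_mono < 0 | rec$yield_di < 0)) {
    stop_mf("validation_error", "negative yield values in %s", path)
  }

  yvals <- c(rec$yield_mono, rec$yield_di)
  dialect <- if (yields == "auto") {
    if (length(yvals) > 0 && max(yvals) > 1.5) "percent" else "fraction"
  } else yields
  if (dialect == "percent") {
    rec$yield_mono <- rec$yield_mono / 100
    rec$yield_di <- rec$yield_di / 100
  }
  reaction_dataset(rec, validate_structures = validate_structures)
}

#' Write a reaction dataset as a SURF-dialect table
#'
#' Yields are serialized in the percent dialect; the output round-trips
#' through [read_surf()] up to floating-point formatting.
#'
#' @param dataset a `reaction_dataset`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_surf <- function(dataset, path) {
  rec <- dataset$records
  out <- data.frame(
    rxn_id = rec$reaction_id,
    startingmat_1_smiles = rec$arene,
    startingmat_2_smiles = rec$acid,
    product_1_smiles = ifelse(is.na(rec$product), "", rec$product),
    catalyst_1_smiles = rec$catalyst,
    additive_1_smiles = rec$additive,
    reagent_1_smiles = rec$reagent,
    solvent_1_smiles = rec$solvent,
    atmosphere = rec$atmosphere,
    temperature_deg_c = rec$temperature,
    time_h = rec$time,
    concentration_moll = rec$concentration,
    scale_mol = rec$scale,
    product_1_yield = format(rec$yield_mono * 100, trim = TRUE, digits = 10,
                             scientific = FALSE),
    product_2_yield = format(rec$yield_di * 100, trim = TRUE, digits = 10,
                             scientific = FALSE),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) conditionMessage(e), warning = function(w) conditionMessage(w))
  if (!isTRUE(ok)) stop_mf("io_error", "cannot write '%s': %s", path, ok)
  invisible(path)
}

#' Total reaction yield
#'
#' Sum of the mono- and di-alkylation yields, clipped at 1.
#'
#' @param record a reaction record (one- or multi-row data.frame with
#'   `yield_mono`, `yield_di`) or a `reaction_dataset`.
#' @return numeric vector of total yields in \[0, 1\].
#' @export
total_yield <- function(record) {
  rec <- if (inherits(record, "reaction_dataset")) record$records else record
  pmin(1, rec$yield_mono + rec$yield_di)
}

#' Binary reaction outcome at a detection threshold
#'
#' A reaction is positive (1) when its total yield reaches the threshold;
#' the default 5% matches the LC-MS detection cut-off used for the binary
#' outcome analysis.  The boundary is inclusive.
#'
#' @inheritParams total_yield
#' @param threshold yield fraction in \[0, 1\].
#' @return integer vector of 0/1 labels.
#' @export
binary_outcome <- function(record, threshold = 0.05) {
  assert_that(is.numeric(threshold) && length(threshold) == 1L &&
                threshold >= 0 && threshold <= 1,
              "argument_error", "threshold must be a fraction in [0, 1]")
  as.integer(total_yield(record) >= threshold)
}

#' Summary statistics of a reaction dataset
#'
#' @param dataset a `reaction_dataset`.
#' @param threshold positive-outcome threshold (total yield fraction).
#' @return list with `n`, `positive_rate`, `yield_histogram` (counts of total
#'   yield among positive reactions, 10 bins on \[0, 1\]), and `coverage`
#'   (arene x acid table of screened combination counts).
#' @export
dataset_summary <- function(dataset, threshold = 0.05) {
  rec <- dataset$records
  assert_that(nrow(rec) > 0L, "empty_input_error", "dataset has no records")
  ty <- total_yield(rec)
  pos <- binary_outcome(rec, threshold)
  hist_breaks <- seq(0, 1, by = 0.1)
  hcounts <- table(cut(ty[pos == 1L], hist_breaks, include.lowest = TRUE))
  structure(list(
    n = nrow(rec),
    positive_rate = mean(pos),
    yield_histogram = hcounts,
    coverage = table(rec$arene, rec$acid),
    threshold = threshold
  ), class = "mf_dataset_summary")
}

#' @export
print.mf_dataset_summary <- function(x, ...) {
  cat(sprintf("%d reactions; positive rate %.1f%% at total yield >= %g%%\n",
              x$n, 100 * x$positive_rate, 100 * x$threshold))
  cat(sprintf("coverage: %d arenes x %d acids, %d screened combinations\n",
              nrow(x$coverage), ncol(x$coverage), sum(x$coverage > 0)))
  invisible(x)
}
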