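# Cross-validation split construction for four extrapolation regimes:
#   0D  - random split over reactions (interpolation),
#   1DN - entire N-arenes held out,
#   1DA - entire acids held out,
#   2D  - both simultaneously (test folds are intersections of held-out
#         arene and acid partitions; records with exactly one held-out
#         component are dropped from that fold entirely).
# Entity identity is the canonical structure string, so duplicate entries of
# the same molecule cannot leak across folds.

partition_round_robin <- function(items, k) {
  # items already shuffled; round-robin keeps fold sizes within 1 of each other
  split(items, rep_len(seq_len(k), length(items)))
}

#' Construct a cross-validation split
#'
#' @param dataset a `reaction_dataset`.
#' @param mode one of `"0D"`, `"1DN"` (novel N-arenes), `"1DA"` (novel
#'   acids), `"2D"` (both novel).
#' @param k number of folds (default 4).
#' @param seed integer seed; identical seeds give bitwise identical splits.
#' @param val_fraction fraction of each fold's training records held out (at
#'   random, seeded) as the validation set used for early stopping.
#' @return object of class `mf_split`: list with `mode`, `k`, `seed` and
#'   `folds`, each fold a list of disjoint `train` / `val` / `test`
#'   reaction-id vectors.
#' @export
make_split <- function(dataset, mode = c("0D", "1DN", "1DA", "2D"), k = 4L,
                       seed = 1L, val_fraction = 0.1) {
  mode <- match.arg(mode)
  rec <- dataset$records
  assert_that(nrow(rec) >= k, "split_error",
              "fewer records (%d) than folds (%d)", nrow(rec), k)
  ids <- rec$reaction_id

  arene_key <- canonical_smiles(rec$arene)
  acid_key <- canonical_smiles(rec$acid)
  arene_key[is.na(arene_key)] <- rec$arene[is.na(arene_key)]
  acid_key[is.na(acid_key)] <- rec$acid[is.na(acid_key)]

  folds <- with_seed(derive_seed(seed, paste0("split-", mode)), {
    if (mode == "0D") {
      shuffled <- sample(ids)
      test_sets <- partition_round_robin(shuffled, k)
      lapply(test_sets, function(test) {
        train <- setdiff(ids, test)
        list(train = train, test = test)
      })
    } else if (mode %in% c("1DN", "1DA")) {
      key <- if (mode == "1DN") arene_key else acid_key
      entities <- unique(key)
      assert_that(length(entities) >= k, "split_error",
                  "fewer %s entities (%d) than folds (%d)",
                  if (mode == "1DN") "arene" else "acid",
                  length(entities), k)
      groups <- partition_round_robin(sample(entities), k)
      lapply(groups, function(held) {
        test <- ids[key %in% held]
        train <- ids[!key %in% held]
        list(train = train, test = test)
      })
    } else {
      arenes <- unique(arene_key)
      acids <- unique(acid_key)
      assert_that(length(arenes) >= k && length(acids) >= k, "split_error",
                  "need at least k distinct arenes and acids for a 2D split")
      # k aligned pairings of independently partitioned entity sets
      agroups <- partition_round_robin(sample(arenes), k)
      bgroups <- partition_round_robin(sample(acids), k)
      lapply(seq_len(k), function(f) {
        a_held <- arene_key %in% agroups[[f]]
        b_held <- acid_key %in% bgroups[[f]]
        test <- ids[a_held & b_held]
        train <- ids[!a_held & !b_held]  # single-novel records dropped
        if (length(test) == 0L) {
          stop_mf("split_error",
                  "2D fold %d has an empty test set; reduce k", f)
        }
        list(train = train, test = test)
      })
    }
  })

  folds <- with_seed(derive_seed(seed, "split-val"), {
    lapply(folds, function(fold) {
      n_val <- max(1L, round(val_fraction * length(fold$train)))
      assert_that(length(fold$train) > n_val, "split_error",
                  "training partition too small to carve a validation set")
      val <- sample(fold$train, n_val)
      list(train = setdiff(fold$train, val), val = val, test = fold$test)
    })
  })
  names(folds) <- NULL
  structure(list(mode = mode, k = as.integer(k), seed = as.integer(seed),
                 folds = folds),
            class = "mf_split")
}

#' @export
print.mf_split <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) {
    sprintf("%d/%d/%d", length(f$train), length(f$val), length(f$test))
  }, "")
  cat(sprintf("<mf_split> mode %s, k=%d, seed=%d (train/val/test): %s\n",
              x$mode, x$k, x$seed, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Write / read a split as JSON
#'
#' @param split an `mf_split`.
#' @param path JSON file path.
#' @return `write_split` returns the path invisibly; `read_split` the
#'   `mf_split`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(mode = split$mode, k = split$k, seed = split$seed,
         folds = lapply(split$folds, function(f) {
           list(train = f$train, val = f$val, test = f$test)
         })),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(x$k), function(f) {
    list(train = as.character(x$folds$train[[f]]),
         val = as.character(x$folds$val[[f]]),
         test = as.character(x$folds$test[[f]]))
  })
  structure(list(mode = x$mode, k = as.integer(x$k),
                 seed = as.integer(x$seed), folds = folds),
            class = "mf_split")
}
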