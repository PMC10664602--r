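# activity_scorer: ECFP6 random-forest activity classifier.
#
# Early-stage compounds are labelled active/inactive around the mean early
# pXC50 and a 100-tree random forest (max depth 20) is fit on ECFP6
# descriptors (radius 3, 1024 bits) after a stratified 70/30 split, with
# balanced accuracy recorded on the held-out 30%.  The fitted forest lives
# in a scikit-learn pickle referenced by the returned model object; scoring
# returns the predicted probability of the active class.

#' ECFP6 descriptor bit sets
#'
#' Hashed circular fingerprint of radius 3 folded to 1024 bits.
#'
#' @param smiles character vector of parseable SMILES.
#' @return list of 0-based on-bit integer vectors (`NULL` for unparseable
#'   input).
#' @export
ecfp6_features <- function(smiles) {
  fingerprint_bits(smiles, radius = 3, nbits = 1024, kind = "morgan")
}

#' Binary activity labels around the mean
#'
#' Active (1) iff pXC50 is strictly greater than the mean pXC50 of the
#' input records; values exactly at the mean are inactive.
#'
#' @param pxc50 numeric vector (typically early-stage compounds).
#' @return integer 0/1 labels.
#' @export
label_by_mean_activity <- function(pxc50) {
  if (length(pxc50) < 2) stop("need at least 2 records", call. = FALSE)
  labels <- as.integer(pxc50 > mean(pxc50))
  if (length(unique(labels)) < 2) {
    stop("all compounds fall in one class; model untrainable", call. = FALSE)
  }
  labels
}

#' Train the in-silico activity classification model
#'
#' @param early_records early-stage record `data.frame` (needs
#'   `smiles_canonical` and `pxc50`), or `NULL` when `features`/`labels`
#'   are given directly.
#' @param seed split + forest seed; training is deterministic given it.
#' @param features optional precomputed bit-set list (bypasses ECFP6).
#' @param labels optional 0/1 labels (bypasses mean-activity labelling).
#' @param nbits descriptor length used with `features`.
#' @param model_path where to persist the fitted forest (default: a
#'   session temporary file).
#' @return object of class `scorer_model` with `balanced_accuracy_test`,
#'   split sizes, descriptor config and training-mean pXC50.
#' @export
train_scorer <- function(early_records = NULL, seed = 42, features = NULL,
                         labels = NULL, nbits = 1024, model_path = NULL) {
  if (is.null(features)) {
    stopifnot(is.data.frame(early_records), nrow(early_records) >= 20)
    features <- ecfp6_features(early_records$smiles_canonical)
    if (any(vapply(features, is.null, logical(1)))) {
      stop("unparseable SMILES in training records", call. = FALSE)
    }
    nbits <- 1024
  }
  if (is.null(labels)) labels <- label_by_mean_activity(early_records$pxc50)
  stopifnot(length(features) == length(labels))
  if (is.null(model_path)) model_path <- tempfile(fileext = ".pkl")
  res <- bridge_call(list(
    op = "rf_train", features = features, labels = as.integer(labels),
    nbits = nbits, seed = as.integer(seed), model_path = model_path,
    n_estimators = 100, max_depth = 20, test_fraction = 0.3,
    stratify = TRUE
  ), cache = FALSE)
  structure(list(
    model_path = model_path,
    nbits = nbits, radius = 3, seed = as.integer(seed),
    split = c(train = res$n_train, test = res$n_test),
    stratified = TRUE,
    training_mean_pxc50 = if (!is.null(early_records))
      mean(early_records$pxc50) else NA_real_,
    balanced_accuracy_test = res$balanced_accuracy
  ), class = "scorer_model")
}

#' Score compounds with a fitted activity model
#'
#' @param model a [train_scorer()] model.
#' @param smiles character vector; unparseable entries get `NA`, never 0.
#' @param features optional precomputed bit sets (overrides `smiles`).
#' @return numeric probabilities of the active class in \[0, 1\] (`NA` for
#'   unparseable molecules).
#' @export
score_compounds <- function(model, smiles = NULL, features = NULL) {
  stopifnot(inherits(model, "scorer_model"))
  if (!file.exists(model$model_path)) {
    stop("persisted model not found at ", model$model_path,
         "; scorer models are session-scoped", call. = FALSE)
  }
  if (is.null(features)) {
    stopifnot(is.character(smiles))
    features <- fingerprint_bits(smiles, radius = model$radius,
                                 nbits = model$nbits, kind = "morgan")
  }
  res <- bridge_call(list(op = "rf_score", model_path = model$model_path,
                          features = features, nbits = model$nbits),
                     cache = FALSE)
  vapply(res$proba, function(p) if (is.null(p)) NA_real_ else as.numeric(p),
         numeric(1))
}

#' Score distributions over the alpha/beta/gamma regions
#'
#' @param model a fitted [train_scorer()] model.
#' @param labelled labelled records with a `region` column.
#' @return `data.frame` with one row per populated region: n, mean, median,
#'   q25, q75 of the model score.  Empty regions are absent.
#' @export
region_scores <- function(model, labelled) {
  stopifnot("region" %in% names(labelled))
  rows <- list()
  for (reg in c("alpha", "beta", "gamma")) {
    sub <- labelled[labelled$region == reg, , drop = FALSE]
    if (nrow(sub) == 0) next
    s <- score_compounds(model, sub$smiles_canonical)
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      region = reg, n = nrow(sub), mean = mean(s, na.rm = TRUE),
      q25 = q[1], median = q[2], q75 = q[3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.scorer_model <- function(x, ...) {
  cat(sprintf(paste0("activity scorer: ECFP6 (radius %d, %d bits), ",
                     "random forest (100 trees, depth 20)\n",
                     "  split %d/%d (stratified, seed %d); ",
                     "balanced accuracy (test) = %.3f\n"),
              x$radius, x$nbits, x$split["train"], x$split["test"], x$seed,
              x$balanced_accuracy_test))
  invisible(x)
}
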