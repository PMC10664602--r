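# metrics: validity, uniqueness, novelty, rediscovery, aSNN, top-k.
#
# The four funnel metrics follow the usual distribution-learning
# definitions:
#   validity    = 100 * Nval  / Ngen   (parseable, sanitizable SMILES)
#   uniqueness  = 100 * Nuni  / Nval   (distinct canonical structures)
#   novelty     = 100 * Nunk  / Nuni   (not present in the reference corpus)
#   rediscovery = 100 * Nredis/ Ngen   (exact canonical matches to known
#                                       late/middle-stage actives)

#' Validity of a generated SMILES set
#'
#' A string is valid iff it parses and sanitizes in the chemistry toolkit.
#'
#' @param generated_raw character vector of raw generated SMILES.
#' @return list with `n_gen`, `n_val`, `pct`, `valid_raw`,
#'   `valid_canonical` (canonical non-isomeric forms of the valid subset).
#' @export
validity <- function(generated_raw) {
  if (length(generated_raw) == 0) stop("empty generated set", call. = FALSE)
  canonical <- standardize_smiles(generated_raw)
  ok <- !is.na(canonical)
  list(n_gen = length(generated_raw), n_val = sum(ok),
       pct = 100 * sum(ok) / length(generated_raw),
       valid_raw = generated_raw[ok], valid_canonical = canonical[ok])
}

#' Uniqueness of the valid subset
#'
#' De-duplicates by canonical SMILES over the whole list; the first
#' occurrence of each structure is kept.
#'
#' @param valid_canonical canonical SMILES of the valid generated compounds.
#' @return list with `n_val`, `n_uni`, `pct`, `unique_canonical`.
#' @export
uniqueness <- function(valid_canonical) {
  if (length(valid_canonical) == 0) stop("empty valid set", call. = FALSE)
  uni <- valid_canonical[!duplicated(valid_canonical)]
  list(n_val = length(valid_canonical), n_uni = length(uni),
       pct = 100 * length(uni) / length(valid_canonical),
       unique_canonical = uni)
}

#' Novelty against a reference corpus
#'
#' @param unique_canonical unique canonical generated SMILES.
#' @param reference_canonical canonical SMILES of the training reference
#'   (pre-training corpus, focus set, or their union).
#' @return list with `n_uni`, `n_unk`, `pct`, `novel_canonical`.
#' @export
novelty <- function(unique_canonical, reference_canonical) {
  if (length(unique_canonical) == 0) stop("empty unique set", call. = FALSE)
  unk <- setdiff(unique_canonical, reference_canonical)
  list(n_uni = length(unique_canonical), n_unk = length(unk),
       pct = 100 * length(unk) / length(unique_canonical),
       novel_canonical = unk)
}

#' Rediscovery of known actives
#'
#' Counts generated structures (valid, de-duplicated) whose canonical
#' non-isomeric SMILES exactly matches a reference active; each reference
#' compound is counted at most once.  The denominator is the size of the
#' evaluated generated list (the full sample or a top-k cut).
#'
#' @param generated_raw raw generated SMILES of the evaluated list.
#' @param reference_actives_canonical canonical SMILES of the gamma-region
#'   (middle/late-stage high or ultra-high activity) compounds.
#' @return list with `n_gen`, `n_redis`, `pct`, `rediscovered` (canonical).
#' @export
rediscovery <- function(generated_raw, reference_actives_canonical) {
  if (length(generated_raw) == 0) stop("empty generated set", call. = FALSE)
  if (length(reference_actives_canonical) == 0) {
    warning("empty rediscovery reference; rediscovery defined as 0",
            call. = FALSE)
    return(list(n_gen = length(generated_raw), n_redis = 0L, pct = 0,
                rediscovered = character(0)))
  }
  val <- validity(generated_raw)
  uni <- unique(val$valid_canonical)
  hits <- intersect(uni, unique(reference_actives_canonical))
  list(n_gen = length(generated_raw), n_redis = length(hits),
       pct = 100 * length(hits) / length(generated_raw),
       rediscovered = hits)
}

#' aSNN from precomputed fingerprint bit sets
#'
#' Mean over query fingerprints of the maximum Tanimoto similarity to any
#' reference fingerprint.  Directional: `asnn_from_bits(a, b)` need not
#' equal `asnn_from_bits(b, a)`.
#'
#' @param query_bits,ref_bits lists of 0-based on-bit integer vectors.
#' @param nbits fingerprint length.
#' @export
asnn_from_bits <- function(query_bits, ref_bits, nbits = 2048) {
  if (length(query_bits) == 0 || length(ref_bits) == 0) {
    stop("empty fingerprint set", call. = FALSE)
  }
  sim <- tanimoto_matrix(query_bits, ref_bits, nbits)
  mean(apply(sim, 1, max))
}

#' Average single-nearest-neighbour Tanimoto similarity
#'
#' @param query_smiles,reference_smiles canonical SMILES sets (query and
#'   reference); both must be non-empty and parseable.
#' @param radius,nbits Morgan fingerprint configuration (defaults: radius 2,
#'   2048 bits).
#' @return numeric scalar in \[0, 1\].
#' @export
asnn <- function(query_smiles, reference_smiles, radius = 2, nbits = 2048) {
  if (length(query_smiles) == 0 || length(reference_smiles) == 0) {
    stop("empty SMILES set", call. = FALSE)
  }
  qb <- fingerprint_bits(query_smiles, radius = radius, nbits = nbits)
  rb <- fingerprint_bits(reference_smiles, radius = radius, nbits = nbits)
  if (any(vapply(qb, is.null, logical(1))) ||
      any(vapply(rb, is.null, logical(1)))) {
    stop("unparseable SMILES in aSNN input", call. = FALSE)
  }
  asnn_from_bits(qb, rb, nbits)
}

#' Stratified aSNN table over stage and activity class
#'
#' For each (stage in middle/late, activity class) cell with at least one
#' member, the aSNN of the generated set against that subset.  Empty cells
#' are absent from the table, never reported as 0.  The conventional 0.3
#' similarity cutoff is attached as an annotation only; it never filters the
#' computation.
#'
#' @param generated_canonical canonical SMILES of the evaluated generated
#'   compounds.
#' @param labelled labelled records ([label_dataset()]).
#' @param radius,nbits Morgan fingerprint configuration.
#' @param cutoff annotation: aSNN above this is conventionally "similar".
#' @return `data.frame` with columns stage, activity_class, asnn,
#'   n_reference.
#' @export
stratified_asnn <- function(generated_canonical, labelled, radius = 2,
                            nbits = 2048, cutoff = 0.3) {
  stopifnot(all(c("stage", "activity_class") %in% names(labelled)))
  if (!any(labelled$stage %in% c("middle", "late"))) {
    stop("no middle/late stage records", call. = FALSE)
  }
  rows <- list()
  for (st in c("middle", "late")) {
    for (cl in .activity_levels) {
      ref <- labelled$smiles_canonical[labelled$stage == st &
                                         labelled$activity_class == cl]
      if (length(ref) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        stage = st, activity_class = cl,
        asnn = asnn(generated_canonical, ref, radius = radius, nbits = nbits),
        n_reference = length(ref), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cutoff") <- cutoff
  out
}

#' Top-k selection by score
#'
#' @param x vector/list to subset (typically raw SMILES).
#' @param scores aligned numeric scores (`NA` ranks last).
#' @param k number of entries to keep; ties broken by original order.
#' @return the selected entries, with the chosen indices as attribute
#'   `"indices"`.
#' @export
top_k_by_score <- function(x, scores, k) {
  stopifnot(length(x) == length(scores))
  if (k > length(x)) stop("k exceeds the number of entries", call. = FALSE)
  idx <- order(-replace(scores, is.na(scores), -Inf), seq_along(scores))[seq_len(k)]
  idx <- sort(idx)  # keep original relative order within the cut
  out <- x[idx]
  attr(out, "indices") <- idx
  out
}

#' Full generation report (the metric funnel plus rediscovery)
#'
#' @param generated_raw raw generated SMILES (the evaluated list).
#' @param novelty_reference canonical SMILES the model has seen in training
#'   (pre-training corpus, focus set, or their union).
#' @param rediscovery_reference canonical SMILES of gamma-region actives.
#' @return object of class `generation_report` with counts
#'   `n_gen, n_val, n_uni, n_unk, n_redis` and the four percentages.
#' @export
generation_report <- function(generated_raw, novelty_reference,
                              rediscovery_reference) {
  val <- validity(generated_raw)
  if (val$n_val == 0) {
    rep <- list(n_gen = val$n_gen, n_val = 0L, n_uni = 0L, n_unk = 0L,
                n_redis = 0L, validity_pct = 0, uniqueness_pct = NA_real_,
                novelty_pct = NA_real_, rediscovery_pct = 0)
    return(structure(rep, class = "generation_report"))
  }
  uni <- uniqueness(val$valid_canonical)
  nov <- novelty(uni$unique_canonical, novelty_reference)
  red <- rediscovery(generated_raw, rediscovery_reference)
  structure(list(
    n_gen = val$n_gen, n_val = val$n_val, n_uni = uni$n_uni,
    n_unk = nov$n_unk, n_redis = red$n_redis,
    validity_pct = val$pct, uniqueness_pct = uni$pct,
    novelty_pct = nov$pct, rediscovery_pct = red$pct
  ), class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf(
    paste0("generation report: Ngen=%d Nval=%d Nuni=%d Nunk=%d Nredis=%d\n",
           "  validity %.2f%%  uniqueness %.2f%%  novelty %.2f%%  ",
           "rediscovery %.2f%%\n"),
    x$n_gen, x$n_val, x$n_uni, x$n_unk, x$n_redis,
    x$validity_pct, x$uniqueness_pct, x$novelty_pct, x$rediscovery_pct))
  invisible(x)
}

#' @export
as.data.frame.generation_report <- function(x, ...) {
  data.frame(n_gen = x$n_gen, n_val = x$n_val, n_uni = x$n_uni,
             n_unk = x$n_unk, n_redis = x$n_redis,
             validity_pct = x$validity_pct, uniqueness_pct = x$uniqueness_pct,
             novelty_pct = x$novelty_pct, rediscovery_pct = x$rediscovery_pct)
}
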