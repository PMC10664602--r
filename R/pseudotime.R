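# pseudotime: project a dateless bioactivity table onto a pseudo-time axis.
#
# The axis is built in three steps: (1) a structural fingerprint per
# compound, reduced by PCA to 3 components; (2) a second PCA of those 3
# (standardized) scores together with pXC50; (3) the Euclidean distance, in
# the second score space, of every compound to the least-potent compound.
# Sorting by ascending distance orders the project from its low-potency
# starting point outwards in joint chemistry/potency space.

#' Principal component scores
#'
#' Thin wrapper over SVD-based PCA returning the top `n_components` score
#' columns.  Errors when the centered matrix has fewer than `n_components`
#' non-degenerate directions, rather than silently padding.
#'
#' @param x numeric matrix (rows = compounds).
#' @param n_components number of components to keep (default 3).
#' @param standardize_scores scale each kept score column to unit variance.
#' @return numeric matrix `nrow(x) x n_components`.
#' @export
pca_scores <- function(x, n_components = 3, standardize_scores = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ok <- p$sdev > max(p$sdev[1] * 1e-9, 1e-12)
  if (sum(ok) < n_components) {
    stop("rank deficiency: only ", sum(ok), " non-degenerate component(s), ",
         n_components, " requested", call. = FALSE)
  }
  s <- p$x[, seq_len(n_components), drop = FALSE]
  if (standardize_scores) s <- scale(s, center = FALSE, scale = apply(s, 2, stats::sd))
  unname(s)
}

#' Pseudo-time ordering of a project
#'
#' @param records record `data.frame` with `smiles_canonical`, `pxc50`,
#'   `source_row` columns (see [molecule_records()]).
#' @param fingerprints optional pre-computed numeric feature matrix, one row
#'   per record (tests and non-default descriptors); computed with
#'   [structural_fingerprint()] when `NULL`.
#' @param fp_nbits,fp_max_path structural fingerprint parameters.
#' @param standardize_scores scale stage-1 PCA scores to unit variance before
#'   appending pXC50 (default `TRUE`, so potency enters on a comparable
#'   scale).
#' @param standardize_pxc50 also scale the pXC50 column to unit variance
#'   before the second PCA (default `FALSE`: potency keeps its native
#'   log-molar units).
#' @return object of class `pseudo_time_map`: list with `distances`
#'   (per-record, input order), `order` (record indices by ascending
#'   distance), `anchor_index` (least-potent record, ties broken by smallest
#'   `source_row`), `pc_scores_stage1`, `pc_scores_stage2`.
#' @export
pseudo_time_order <- function(records, fingerprints = NULL,
                              fp_nbits = 1024, fp_max_path = 7,
                              standardize_scores = TRUE,
                              standardize_pxc50 = FALSE) {
  stopifnot(is.data.frame(records), all(c("pxc50", "source_row") %in% names(records)))
  n <- nrow(records)
  if (n < 4) stop("pseudo-time needs at least 4 records", call. = FALSE)
  if (!all(is.finite(records$pxc50))) stop("non-finite pXC50", call. = FALSE)
  if (is.null(fingerprints)) {
    fingerprints <- structural_fingerprint(records$smiles_canonical,
                                           nbits = fp_nbits,
                                           max_path = fp_max_path)
  }
  stopifnot(nrow(fingerprints) == n)
  s1 <- pca_scores(fingerprints, 3, standardize_scores = standardize_scores)
  px <- records$pxc50
  if (standardize_pxc50) px <- as.numeric(scale(px))
  s2 <- pca_scores(cbind(s1, px), 3, standardize_scores = FALSE)
  anchor <- order(records$pxc50, records$source_row)[1]
  d <- sqrt(rowSums((s2 - matrix(s2[anchor, ], n, 3, byrow = TRUE))^2))
  structure(list(
    distances = d,
    order = order(d, records$source_row),
    anchor_index = anchor,
    pc_scores_stage1 = s1,
    pc_scores_stage2 = s2
  ), class = "pseudo_time_map")
}

#' @export
print.pseudo_time_map <- function(x, ...) {
  cat("pseudo-time map:", length(x$distances), "compounds; anchor index",
      x$anchor_index, "\n")
  cat("distance range: [", format(min(x$distances), digits = 4), ", ",
      format(max(x$distances), digits = 4), "]\n", sep = "")
  invisible(x)
}
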