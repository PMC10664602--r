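# Hashed fingerprints and Tanimoto similarity.
#
# Fingerprints are computed by the chemistry worker and handled here as
# 0-based on-bit index lists (sparse) or 0/1 matrices (dense), whichever a
# consumer needs.  Tanimoto arithmetic is done in R.

#' Structural path fingerprint (pseudo-time descriptor)
#'
#' Hashed linear-path fingerprint used to build the pseudo-time axis:
#' subgraph paths up to `max_path` bonds, folded to `nbits` bits.  This is a
#' stand-in for proprietary fragment-dictionary fingerprints; bit-level
#' agreement with any external tool is not claimed.
#'
#' @param smiles character vector of parseable SMILES.
#' @param nbits fingerprint length (default 1024).
#' @param max_path maximum path length in bonds (default 7).
#' @return numeric 0/1 matrix, one row per molecule.
#' @export
structural_fingerprint <- function(smiles, nbits = 1024, max_path = 7) {
  bits <- fingerprint_bits(smiles, kind = "path", nbits = nbits,
                           max_path = max_path)
  bad <- vapply(bits, is.null, logical(1))
  if (any(bad)) {
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  fingerprint_matrix(bits, nbits)
}

#' Morgan (circular) fingerprint on-bit sets
#'
#' @param smiles character vector.
#' @param radius circular radius (2 for similarity work, 3 for ECFP6).
#' @param nbits folded length.
#' @param kind `"morgan"` or `"path"`.
#' @param max_path maximum path length (path kind only).
#' @return list of integer vectors of 0-based on-bit indices; `NULL` entries
#'   for unparseable SMILES.
#' @export
fingerprint_bits <- function(smiles, radius = 2, nbits = 2048,
                             kind = c("morgan", "path"), max_path = 7) {
  kind <- match.arg(kind)
  stopifnot(is.character(smiles), length(smiles) > 0)
  # per-string memoisation keyed by fingerprint configuration
  keys <- sprintf("fp|%s|%d|%d|%d|%s", kind, radius, nbits, max_path, smiles)
  out <- vector("list", length(smiles))
  cached <- vapply(keys, function(k)
    !is.null(get0(k, envir = .bridge_cache, inherits = FALSE)), logical(1))
  for (i in which(cached)) {
    v <- get(keys[i], envir = .bridge_cache)
    # out[i] <- list(...): assigning NULL with [[<- would delete the slot
    out[i] <- list(if (identical(v, FALSE)) NULL else v)
  }
  todo <- which(!cached)
  if (length(todo) > 0) {
    res <- bridge_call(list(op = "fingerprints",
                            smiles = as.list(smiles[todo]), kind = kind,
                            nbits = nbits, radius = radius,
                            max_path = max_path), cache = FALSE)
    for (j in seq_along(todo)) {
      b <- res$bits[[j]]
      b <- if (is.null(b)) NULL else as.integer(unlist(b))
      out[todo[j]] <- list(b)
      assign(keys[todo[j]], if (is.null(b)) FALSE else b,
             envir = .bridge_cache)
    }
  }
  out
}

#' Densify on-bit index lists to a 0/1 matrix
#'
#' @param bits list of 0-based on-bit integer vectors (`NULL` rows become
#'   all-zero).
#' @param nbits number of columns.
#' @return numeric matrix `length(bits) x nbits`.
#' @export
fingerprint_matrix <- function(bits, nbits) {
  m <- matrix(0, nrow = length(bits), ncol = nbits)
  for (i in seq_along(bits)) {
    b <- bits[[i]]
    if (!is.null(b) && length(b) > 0) m[i, b + 1L] <- 1
  }
  m
}

#' Pairwise Tanimoto similarity between two fingerprint sets
#'
#' @param query_bits,ref_bits lists of 0-based on-bit integer vectors.
#' @param nbits fingerprint length (any value exceeding the largest index).
#' @return numeric matrix `|query| x |ref|` of Tanimoto similarities; a pair
#'   with an empty union is assigned 0.
#' @export
tanimoto_matrix <- function(query_bits, ref_bits, nbits = 2048) {
  q <- fingerprint_matrix(query_bits, nbits)
  r <- fingerprint_matrix(ref_bits, nbits)
  inter <- q %*% t(r)
  uni <- outer(rowSums(q), rowSums(r), `+`) - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  dimnames(sim) <- NULL
  sim
}
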