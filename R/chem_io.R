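# chem_io: compound table and generated-set I/O plus SMILES standardization.

#' Standardize SMILES to canonical, de-salted, non-isomeric form
#'
#' Each input string is parsed and sanitized with the chemistry toolkit, the
#' fragment with the most heavy atoms is kept (de-salting; ties broken by the
#' lexicographically smallest canonical SMILES), stereochemistry is stripped,
#' and the canonical non-isomeric SMILES is returned.  All downstream
#' identity matching in the package (uniqueness, novelty, rediscovery) is on
#' this form.
#'
#' @param smiles character vector of raw SMILES.
#' @return character vector of the same length; `NA` where the input does not
#'   parse or sanitize.
#' @examples
#' \dontrun{
#' standardize_smiles(c("OCC", "CC(=O)O.[Na+]", "C[C@@H](N)C(=O)O", "not("))
#' }
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  # per-string memoisation: only strings not seen this session go to Python
  keys <- paste0("std|", smiles)
  out <- rep(NA_character_, length(smiles))
  cached <- vapply(keys, function(k)
    !is.null(get0(k, envir = .bridge_cache, inherits = FALSE)), logical(1))
  for (i in which(cached)) {
    v <- get(keys[i], envir = .bridge_cache)
    out[i] <- if (identical(v, FALSE)) NA_character_ else v
  }
  todo <- which(!cached)
  if (length(todo) > 0) {
    res <- bridge_call(list(op = "standardize",
                            smiles = as.list(smiles[todo])), cache = FALSE)
    vals <- .unlist_or_na(res$canonical)
    out[todo] <- vals
    for (j in seq_along(todo)) {
      assign(keys[todo[j]],
             if (is.na(vals[j])) FALSE else vals[j], envir = .bridge_cache)
    }
  }
  out
}

#' Build molecule records from SMILES and potencies
#'
#' Standardizes the SMILES and assembles the package's canonical record
#' table: one row per compound with columns `id`, `smiles_raw`,
#' `smiles_canonical`, `pxc50`, `date` and `source_row` (0-based input
#' order).  Rows whose SMILES fail to parse, or whose pXC50 is missing, are
#' dropped; the drop counts are attached as the `"load_report"` attribute.
#'
#' @param smiles_raw character vector of raw SMILES.
#' @param pxc50 numeric vector, -log10 of the XC50 in molar.
#' @param date optional vector of dates (anything orderable).
#' @param id optional character ids; defaults to `cpd<source_row>`.
#' @return a `data.frame` of records, ordered as input.
#' @export
molecule_records <- function(smiles_raw, pxc50, date = NULL, id = NULL) {
  stopifnot(length(smiles_raw) == length(pxc50))
  n <- length(smiles_raw)
  source_row <- seq_len(n) - 1L
  if (is.null(id)) id <- sprintf("cpd%d", source_row)
  canonical <- standardize_smiles(as.character(smiles_raw))
  pxc50 <- suppressWarnings(as.numeric(pxc50))
  bad_smiles <- is.na(canonical)
  bad_pxc50 <- !is.finite(pxc50)
  keep <- !bad_smiles & !bad_pxc50
  rec <- data.frame(
    id = as.character(id)[keep],
    smiles_raw = as.character(smiles_raw)[keep],
    smiles_canonical = canonical[keep],
    pxc50 = pxc50[keep],
    date = if (is.null(date)) NA else date[keep],
    source_row = source_row[keep],
    stringsAsFactors = FALSE
  )
  attr(rec, "load_report") <- list(
    n_input = n,
    n_dropped_smiles = sum(bad_smiles),
    n_dropped_pxc50 = sum(bad_pxc50 & !bad_smiles),
    n_kept = nrow(rec)
  )
  rec
}

#' Load a project bioactivity table
#'
#' Reads a CSV or XLSX compound table, standardizes the SMILES column and
#' returns molecule records (see [molecule_records()]).  Unparseable rows are
#' dropped with a warning; an empty result is an error.
#'
#' @param path CSV or XLSX file.
#' @param column_map named list mapping the roles `smiles`, `pxc50` and
#'   (optionally) `date` to column names in the file.
#' @param aggregate_duplicates if `TRUE`, rows sharing a canonical structure
#'   are collapsed to one record carrying the maximum pXC50 (earliest
#'   occurrence kept for id/date/order).  Off by default: a project table may
#'   legitimately re-measure a compound.
#' @return record `data.frame` with a `"load_report"` attribute.
#' @export
load_project_table <- function(path,
                               column_map = list(smiles = "SMILES",
                                                 pxc50 = "pXC50",
                                                 date = "date"),
                               aggregate_duplicates = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package", call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (nrow(tab) == 0) stop("project table has zero rows: ", path, call. = FALSE)
  for (role in c("smiles", "pxc50")) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(tab)) {
      stop("mapped column for '", role, "' (", col %||% "<missing>",
           ") not present in ", path, call. = FALSE)
    }
  }
  date_col <- column_map$date
  dates <- if (!is.null(date_col) && date_col %in% names(tab)) {
    tab[[date_col]]
  } else NULL
  id <- if ("id" %in% names(tab)) as.character(tab$id) else NULL
  rec <- molecule_records(as.character(tab[[column_map$smiles]]),
                          tab[[column_map$pxc50]], date = dates, id = id)
  rep <- attr(rec, "load_report")
  if (rep$n_dropped_smiles + rep$n_dropped_pxc50 > 0) {
    warning(sprintf("dropped %d unparseable-SMILES and %d missing-pXC50 rows",
                    rep$n_dropped_smiles, rep$n_dropped_pxc50), call. = FALSE)
  }
  if (nrow(rec) == 0) stop("no parseable rows in ", path, call. = FALSE)
  if (aggregate_duplicates) {
    ord <- order(rec$smiles_canonical, -rec$pxc50, rec$source_row)
    rec2 <- rec[ord, ]
    rec2 <- rec2[!duplicated(rec2$smiles_canonical), ]
    rec2 <- rec2[order(rec2$source_row), ]
    rownames(rec2) <- NULL
    attr(rec2, "load_report") <- c(rep, list(n_aggregated = nrow(rec) - nrow(rec2)))
    rec <- rec2
  }
  rec
}

#' Load a generated compound set
#'
#' Reads a plain-text SMILES list, one compound per line, optionally followed
#' by a whitespace-separated numeric score.  Raw strings are preserved
#' verbatim: chemical validity is judged later by [validity()], not at load.
#' Blank lines are skipped.
#'
#' @param path text file path.
#' @return list with `smiles` (character) and `scores` (numeric or `NULL`).
#' @export
load_generated_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  scores <- NULL
  if (length(parts) > 0 && all(lengths(parts) >= 2)) {
    scores <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  }
  list(smiles = smiles, scores = scores)
}

#' Write a normalized project table
#'
#' Fixed column order `(id, smiles_canonical, pxc50, date, source_row)`, so
#' writing and re-reading records round-trips their identifying fields.
#'
#' @param records record `data.frame` (see [molecule_records()]).
#' @param path output CSV path.
#' @export
write_project_table <- function(records, path) {
  cols <- c("id", "smiles_canonical", "pxc50", "date", "source_row")
  stopifnot(all(cols %in% names(records)))
  extra <- intersect(c("distance", "pseudo_rank", "stage", "activity_class",
                       "region"), names(records))
  utils::write.csv(records[, c(cols, extra)], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
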