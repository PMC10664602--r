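# Bridge to the Python chemistry worker (RDKit + scikit-learn).
#
# Every call is batched: one subprocess handles a whole vector of molecules.
# Results of pure (side-effect free) operations are memoised for the R
# session, keyed by a digest of the request, so repeated standardization or
# fingerprinting of the same compound set is free.

.bridge_cache <- new.env(parent = emptyenv())

python_binary <- function() {
  bin <- getOption("retromol.python", Sys.getenv("RETROMOL_PYTHON", "python"))
  path <- Sys.which(bin)
  if (!nzchar(path)) {
    stop("python interpreter '", bin, "' not found on PATH; ",
         "set options(retromol.python=) or RETROMOL_PYTHON", call. = FALSE)
  }
  path
}

chem_worker_script <- function() {
  script <- system.file("python", "chem_tools.py", package = "retromol")
  if (!nzchar(script)) stop("bundled chem_tools.py not found", call. = FALSE)
  script
}

#' @keywords internal
bridge_call <- function(req, cache = TRUE) {
  stopifnot(is.list(req), !is.null(req$op))
  key <- NULL
  if (cache) {
    key <- digest::digest(req, algo = "xxhash64")
    hit <- get0(key, envir = .bridge_cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
  }
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, null = "null",
                       digits = NA)
  status <- system2(python_binary(),
                    c(shQuote(chem_worker_script()), shQuote(infile),
                      shQuote(outfile)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("chemistry worker failed (op=", req$op, "):\n",
         paste(status, collapse = "\n"), call. = FALSE)
  }
  res <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  if (cache) assign(key, res, envir = .bridge_cache)
  res
}

# NULL-preserving flatten of a worker list column to a character/numeric vec
.unlist_or_na <- function(x, coerce = as.character) {
  vapply(x, function(v) if (is.null(v)) coerce(NA) else coerce(v),
         coerce(NA))
}
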