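# baseline_generator: a token-level Markov-chain SMILES model.
#
# A desk-scale stand-in for an external neural generative engine, exposing
# the contract the framework needs: fit (pre-train), focus (fine-tune
# analog), sample, and per-molecule negative log likelihood (in nats).
# The model is an order-k Markov chain over SMILES tokens with begin/end
# sentinels, additive smoothing applied at query time, and focusing by
# per-context interpolation between the prior and a focus-corpus
# distribution.

.BEGIN <- "^"
.END <- "$"
.CTX_SEP <- "\x1f"

#' Tokenize a SMILES string
#'
#' Multi-character units are kept atomic: bracket atoms (`[nH]`, `[C@@H]`),
#' two-letter halogens (`Cl`, `Br`), and `%nn` ring-bond labels.  The
#' concatenation of the tokens reproduces the input exactly.
#'
#' @param smiles a non-empty string.
#' @return character vector of tokens.
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, nzchar(smiles))
  chars <- strsplit(smiles, "")[[1]]
  tokens <- character(0)
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("dangling '[' in SMILES: ", smiles, call. = FALSE)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else if (ch == "%" && i + 2 <= n) {
      tokens <- c(tokens, paste(chars[i:(i + 2)], collapse = ""))
      i <- i + 3
    } else if (i < n && paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1]))
      i <- i + 2
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1
    }
  }
  tokens
}

.count_transitions <- function(corpus, order) {
  counts <- new.env(parent = emptyenv())
  vocab <- character(0)
  for (s in corpus) {
    toks <- smiles_tokenize(s)
    vocab <- union(vocab, toks)
    seq <- c(rep(.BEGIN, order), toks, .END)
    for (i in seq_along(seq)[-seq_len(order)]) {
      ctx <- paste(seq[(i - order):(i - 1)], collapse = .CTX_SEP)
      tok <- seq[i]
      cur <- get0(ctx, envir = counts, inherits = FALSE)
      if (is.null(cur)) cur <- numeric(0)
      cur[tok] <- (if (tok %in% names(cur)) cur[[tok]] else 0) + 1
      assign(ctx, cur, envir = counts)
    }
  }
  list(counts = as.list(counts), vocab = sort(vocab))
}

#' Fit a Markov SMILES model
#'
#' @param corpus character vector of (canonical) SMILES; at least one.
#' @param order context length in tokens (default 3).
#' @param smoothing additive pseudo-count applied at query time
#'   (default 0.01); with `smoothing > 0` every string over the training
#'   alphabet has finite NLL.
#' @return object of class `markov_smiles_model`.
#' @export
markov_fit <- function(corpus, order = 3, smoothing = 0.01) {
  stopifnot(length(corpus) >= 1, order >= 1, smoothing >= 0)
  ct <- .count_transitions(corpus, order)
  structure(list(
    order = as.integer(order), smoothing = smoothing,
    vocab = ct$vocab, counts = ct$counts,
    focus_counts = NULL, lambda = 0
  ), class = "markov_smiles_model")
}

#' Focus (fine-tune analog) a Markov model on a corpus
#'
#' Per context, the transition distribution becomes
#' `(1 - lambda) * prior + lambda * focus`; contexts never seen in the focus
#' corpus fall back to the prior unchanged.
#'
#' @param model a fitted [markov_fit()] model.
#' @param focus_corpus non-empty character vector of SMILES.
#' @param lambda interpolation weight in \[0, 1\].
#' @return a new `markov_smiles_model`.
#' @export
markov_focus <- function(model, focus_corpus, lambda = 0.5) {
  stopifnot(inherits(model, "markov_smiles_model"),
            length(focus_corpus) >= 1, lambda >= 0, lambda <= 1)
  ct <- .count_transitions(focus_corpus, model$order)
  model$focus_counts <- ct$counts
  model$vocab <- sort(union(model$vocab, ct$vocab))
  model$lambda <- lambda
  model
}

# Probability vector over (vocab, END) for one context key.
.context_prob <- function(model, ctx) {
  toks <- c(model$vocab, .END)
  v <- length(toks)
  smoothed <- function(counts_list) {
    c0 <- counts_list[[ctx]]
    x <- stats::setNames(rep(0, v), toks)
    if (!is.null(c0)) x[names(c0)] <- c0
    tot <- sum(x)
    if (model$smoothing == 0) {
      if (tot == 0) return(NULL)
      return(x / tot)
    }
    (x + model$smoothing) / (tot + model$smoothing * v)
  }
  p_prior <- smoothed(model$counts)
  if (is.null(p_prior)) p_prior <- stats::setNames(rep(1 / v, v), toks)
  if (!is.null(model$focus_counts) && model$lambda > 0 &&
      !is.null(model$focus_counts[[ctx]])) {
    p_focus <- smoothed(model$focus_counts)
    return((1 - model$lambda) * p_prior + model$lambda * p_focus)
  }
  p_prior
}

#' Negative log likelihood of a SMILES string (nats)
#'
#' `-sum(log p(token | context))` over the tokenized string including the
#' end-sentinel term.
#'
#' @param model a fitted `markov_smiles_model`.
#' @param smiles character vector.
#' @return numeric vector of NLLs (may be `Inf` when `smoothing = 0` and an
#'   unseen transition occurs).
#' @export
markov_nll <- function(model, smiles) {
  stopifnot(inherits(model, "markov_smiles_model"))
  vapply(smiles, function(s) {
    seqs <- c(rep(.BEGIN, model$order), smiles_tokenize(s), .END)
    nll <- 0
    for (i in seq_along(seqs)[-seq_len(model$order)]) {
      ctx <- paste(seqs[(i - model$order):(i - 1)], collapse = .CTX_SEP)
      p <- .context_prob(model, ctx)
      tok <- seqs[i]
      pi <- if (tok %in% names(p)) p[[tok]] else 0
      nll <- nll - log(pi)
    }
    nll
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sample raw SMILES strings from a Markov model
#'
#' Strings are sampled token by token until the end sentinel or `max_len`
#' tokens; results are returned raw and may be chemically invalid --
#' validity is judged by [validity()].
#'
#' @param model a fitted `markov_smiles_model`.
#' @param n number of samples.
#' @param max_len token cap per sample (default 100).
#' @param seed RNG seed; identical seeds give identical samples.
#' @return character vector of length `n`.
#' @export
markov_sample <- function(model, n, max_len = 100, seed = 42) {
  stopifnot(inherits(model, "markov_smiles_model"), n >= 1)
  memo <- new.env(parent = emptyenv())
  prob_of <- function(ctx) {
    p <- get0(ctx, envir = memo, inherits = FALSE)
    if (is.null(p)) {
      p <- .context_prob(model, ctx)
      assign(ctx, p, envir = memo)
    }
    p
  }
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      ctx_toks <- rep(.BEGIN, model$order)
      out <- character(0)
      repeat {
        p <- prob_of(paste(ctx_toks, collapse = .CTX_SEP))
        tok <- sample(names(p), 1, prob = p)
        if (tok == .END || length(out) >= max_len) break
        out <- c(out, tok)
        ctx_toks <- c(ctx_toks[-1], tok)
      }
      paste(out, collapse = "")
    }, character(1))
  })
}

#' Per-region NLL summary across models
#'
#' Tabulates mean and median NLL of the real compounds in each populated
#' region, for each supplied model, enabling prior-vs-focused comparisons.
#'
#' @param models named list of `markov_smiles_model` objects.
#' @param labelled labelled records with `region` and `smiles_canonical`.
#' @return `data.frame` with model, region, n, mean_nll, median_nll.
#' @export
region_nll_summary <- function(models, labelled) {
  stopifnot(length(models) >= 1, !is.null(names(models)),
            "region" %in% names(labelled))
  rows <- list()
  for (mn in names(models)) {
    for (reg in c("alpha", "beta", "gamma")) {
      smi <- labelled$smiles_canonical[labelled$region == reg]
      if (length(smi) == 0) next
      nll <- markov_nll(models[[mn]], smi)
      rows[[length(rows) + 1]] <- data.frame(
        model = mn, region = reg, n = length(smi),
        mean_nll = mean(nll), median_nll = stats::median(nll),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Persist / restore a Markov model as JSON
#'
#' @param model a `markov_smiles_model`.
#' @param path JSON file path.
#' @export
markov_save <- function(model, path) {
  stopifnot(inherits(model, "markov_smiles_model"))
  payload <- list(order = model$order, smoothing = model$smoothing,
                  vocab = model$vocab, lambda = model$lambda,
                  counts = lapply(model$counts, as.list),
                  focus_counts = if (is.null(model$focus_counts)) NULL else
                    lapply(model$focus_counts, as.list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname markov_save
#' @export
markov_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  relist <- function(x) {
    if (is.null(x)) return(NULL)
    lapply(x, function(ct) {
      stats::setNames(vapply(ct, as.numeric, numeric(1)), names(ct))
    })
  }
  structure(list(
    order = as.integer(p$order), smoothing = as.numeric(p$smoothing),
    vocab = vapply(p$vocab, as.character, character(1)),
    counts = relist(p$counts),
    focus_counts = relist(p$focus_counts),
    lambda = as.numeric(p$lambda)
  ), class = "markov_smiles_model")
}

#' @export
print.markov_smiles_model <- function(x, ...) {
  cat(sprintf("Markov SMILES model: order %d, smoothing %g, %d vocab tokens, %d contexts%s\n",
              x$order, x$smoothing, length(x$vocab), length(x$counts),
              if (!is.null(x$focus_counts))
                sprintf(", focused (lambda=%g)", x$lambda) else ""))
  invisible(x)
}
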