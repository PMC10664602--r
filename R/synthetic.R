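# synthetic_data: simulated drug-discovery projects.
#
# Chemistry is template substitution: two scaffold chemotypes, each with two
# substitution sites and a small substituent alphabet, so every product is
# valid by construction (validated once at spec construction).  Potency
# follows the documented formula
#
#     pXC50 = base + substituent_effect + drift * u + N(0, noise_sd),
#
# with u in [0, 1] the position along the project time axis.  A latent
# potency target (base + target_slope * u + noise) drives substituent
# selection, so potency rises with time as in a real optimization campaign.
#
# The two regimes plant the similarity structure that distinguishes public
# from in-house project data:
#   * public_like  -- mid/late ACTIVE compounds stay on the early scaffold
#     (chemotype A) while low-potency excursions move to chemotype B, so
#     aSNN(alpha, gamma) > aSNN(alpha, beta);
#   * inhouse_like -- the project jumps scaffold to reach potency: mid/late
#     actives are chemotype B while the early series stalls at low potency,
#     so aSNN(alpha, gamma) < aSNN(alpha, beta).

.default_templates <- function() {
  aromatic_subs <- c("[H]", "F", "Cl", "Br", "C", "CC", "OC", "O", "N",
                     "N(C)C", "C(F)(F)F", "S(C)(=O)=O")
  aromatic_eff <- c("[H]" = 0, "F" = 0.2, "Cl" = 0.45, "Br" = 0.5,
                    "C" = 0.3, "CC" = 0.55, "OC" = 0.6, "O" = 0.15,
                    "N" = 0.35, "N(C)C" = 1.0, "C(F)(F)F" = 1.05,
                    "S(C)(=O)=O" = 1.3)
  amine_subs <- c("C", "CC", "CCC", "CC(C)C", "CCO", "CC(=O)C", "Cc9ccccc9")
  amine_eff <- c("C" = 0.2, "CC" = 0.4, "CCC" = 0.55, "CC(C)C" = 0.75,
                 "CCO" = 0.6, "CC(=O)C" = 0.9, "Cc9ccccc9" = 1.2)
  list(
    A = list(template = "O=C(Nc1ccc(<R1>)cc1)c1ccc(<R2>)cc1",
             sites = list(R1 = aromatic_subs, R2 = aromatic_subs),
             effects = list(R1 = aromatic_eff, R2 = aromatic_eff)),
    B = list(template = "O=C(c1ccncc1<R2>)N1CCN(<R1>)CC1",
             sites = list(R1 = amine_subs, R2 = aromatic_subs),
             effects = list(R1 = amine_eff, R2 = aromatic_eff))
  )
}

#' Enumerate a template-substitution library
#'
#' Substitutes every combination of site substituents into each template,
#' standardizes the products and de-duplicates by canonical SMILES.
#'
#' @param templates named list of templates; each has `template` (a SMILES
#'   string with `<R1>`, `<R2>`, ... placeholders), `sites` (named list of
#'   substituent alphabets) and optionally `effects` (aligned named numeric
#'   potency contributions).
#' @return `data.frame` with columns template_id, the substituent per site,
#'   `smiles_raw` (substituted string), `smiles_canonical` and `effect`.
#' @export
enumerate_library <- function(templates = .default_templates()) {
  out <- list()
  for (tid in names(templates)) {
    tp <- templates[[tid]]
    grid <- expand.grid(tp$sites, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    raw <- vapply(seq_len(nrow(grid)), function(i) {
      s <- tp$template
      for (site in names(tp$sites)) {
        s <- sub(paste0("<", site, ">"), grid[[site]][i], s, fixed = TRUE)
      }
      s
    }, character(1))
    eff <- rep(0, nrow(grid))
    if (!is.null(tp$effects)) {
      for (site in names(tp$effects)) {
        eff <- eff + unname(tp$effects[[site]][grid[[site]]])
      }
    }
    canonical <- standardize_smiles(raw)
    if (any(is.na(canonical))) {
      bad <- which(is.na(canonical))[1]
      stop("template '", tid, "' produced unparseable SMILES for combination ",
           paste(unlist(grid[bad, ]), collapse = " + "), ": ", raw[bad],
           call. = FALSE)
    }
    df <- data.frame(template_id = tid, grid, smiles_raw = raw,
                     smiles_canonical = canonical, effect = eff,
                     stringsAsFactors = FALSE)
    out[[tid]] <- df
  }
  lib <- do.call(rbind, out)
  lib <- lib[!duplicated(lib$smiles_canonical), , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Specification of a synthetic project
#'
#' Validates the template chemistry (every substituent combination must
#' standardize) and freezes the generative parameters.
#'
#' @param n_compounds project size (>= 40 so stages and regions stay
#'   viable; default 200).
#' @param regime `"public_like"` or `"inhouse_like"` (see the module notes).
#' @param templates template list as in [enumerate_library()].
#' @param base baseline pXC50 of the unsubstituted chemistry (default 5).
#' @param drift potency drift attributable to time alone over the whole
#'   project, in pXC50 units (default 1).
#' @param target_slope rise of the latent potency target over the project
#'   (default 3.2), the main engine of the potency/time trend.
#' @param noise_sd Gaussian assay noise, pXC50 units (default 0.4).
#' @param chemotype_flip probability a mid/late compound ignores the regime
#'   chemotype rule (default 0.03).  Kept small: nearest-neighbour
#'   similarity saturates once even a handful of cross-series actives leak
#'   into a region.
#' @param thresholds an [activity_thresholds()] object.
#' @param seed simulation seed.
#' @return object of class `synthetic_project_spec` (includes the validated
#'   library).
#' @export
synthetic_project_spec <- function(n_compounds = 200,
                                   regime = c("public_like", "inhouse_like"),
                                   templates = .default_templates(),
                                   base = 5, drift = 1, target_slope = 3.2,
                                   noise_sd = 0.4, chemotype_flip = 0.03,
                                   thresholds = activity_thresholds(),
                                   seed = 42) {
  regime <- match.arg(regime)
  if (n_compounds < 40) stop("n_compounds must be >= 40", call. = FALSE)
  lib <- enumerate_library(templates)
  structure(list(
    n_compounds = as.integer(n_compounds), regime = regime,
    templates = templates, library = lib,
    base = base, drift = drift, target_slope = target_slope,
    noise_sd = noise_sd, chemotype_flip = chemotype_flip,
    thresholds = thresholds, seed = as.integer(seed)
  ), class = "synthetic_project_spec")
}

.simulate_once <- function(spec, seed) {
  lib <- spec$library
  n <- spec$n_compounds
  mid <- spec$thresholds$mid_high
  # first template = early series ("A"), second = divergent series ("B");
  # a single-template spec collapses both roles onto it
  tnames <- unique(lib$template_id)
  series <- c(A = tnames[1], B = tnames[min(2, length(tnames))])
  with_seed(seed, {
    u <- (seq_len(n) - 1) / (n - 1)
    target <- spec$base + spec$target_slope * u + stats::rnorm(n, 0, 0.8)
    eps <- stats::rnorm(n, 0, spec$noise_sd)   # assay noise, drawn up front
    flip <- stats::runif(n) < spec$chemotype_flip
    # chemotype from the (provisional) realized class, so the planted
    # series/potency coupling survives assay noise
    active <- target + eps >= mid
    early <- u < 0.5
    chemo <- character(n)
    chemo[early] <- "A"
    active_series <- if (spec$regime == "public_like") "A" else "B"
    inactive_series <- if (spec$regime == "public_like") "B" else "A"
    chemo[!early] <- ifelse(active[!early], active_series, inactive_series)
    chemo[!early & flip[!early]] <-
      ifelse(chemo[!early & flip[!early]] == "A", "B", "A")
    rows <- integer(n)
    for (i in seq_len(n)) {
      pool <- which(lib$template_id == series[[chemo[i]]])
      cand <- pool[sample.int(length(pool), min(12, length(pool)))]
      need <- target[i] - spec$base - spec$drift * u[i]
      rows[i] <- cand[which.min(abs(lib$effect[cand] - need))]
    }
    pxc50 <- spec$base + lib$effect[rows] + spec$drift * u + eps
    pxc50 <- pmin(pmax(pxc50, 3), 11)
    data.frame(
      id = sprintf("S%04d", seq_len(n) - 1L),
      smiles_raw = lib$smiles_raw[rows],
      smiles_canonical = lib$smiles_canonical[rows],
      pxc50 = round(pxc50, 3),
      date = seq_len(n) - 1L,          # one compound per day
      source_row = seq_len(n) - 1L,
      chemotype = chemo,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a synthetic drug-discovery project
#'
#' Draws a project from a [synthetic_project_spec()]: compounds are dated in
#' series order, potency follows the documented drift-plus-effects model and
#' the regime plants the public-like or in-house-like similarity structure.
#' Resamples (bounded retries with derived seeds) until every activity class
#' has at least `min_per_class` members.
#'
#' @param spec a `synthetic_project_spec`.
#' @param min_per_class minimum compounds per activity class (default 5).
#' @param max_attempts resampling bound (default 5).
#' @return record `data.frame` ready for [label_dataset()] (a `chemotype`
#'   column records the planted series).
#' @export
simulate_project <- function(spec, min_per_class = 5, max_attempts = 5) {
  stopifnot(inherits(spec, "synthetic_project_spec"))
  for (attempt in seq_len(max_attempts)) {
    rec <- .simulate_once(spec, derive_seed(spec$seed, attempt - 1))
    classes <- assign_activity_class(rec$pxc50, spec$thresholds)
    if (all(table(classes) >= min_per_class)) {
      attr(rec, "spec_seed") <- spec$seed
      attr(rec, "attempt") <- attempt
      return(rec)
    }
  }
  stop("could not populate all four activity classes in ", max_attempts,
       " attempts; spec infeasible", call. = FALSE)
}

#' Write the offline fixture suite
#'
#' One public-like project, one in-house-like project, a pre-training corpus
#' (the enumerated library superset) and a reference generated set (Markov
#' samples from the corpus) -- everything the full pipeline needs, as plain
#' text.  Regeneration with the same seed is byte-identical.
#'
#' @param out_dir writable directory (created if missing).
#' @param seed master seed; per-artifact seeds are derived from it.
#' @param n_compounds per-project size (default 200).
#' @param n_generated reference generated-set size (default 300).
#' @return named character vector of the files written.
#' @export
make_fixture_suite <- function(out_dir, seed = 42, n_compounds = 200,
                               n_generated = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_project <- function(rec, path) {
    utils::write.csv(
      data.frame(id = rec$id, SMILES = rec$smiles_raw, pXC50 = rec$pxc50,
                 date = rec$date, stringsAsFactors = FALSE),
      path, row.names = FALSE, quote = FALSE)
    path
  }
  pub <- simulate_project(synthetic_project_spec(
    n_compounds, "public_like", seed = derive_seed(seed, 1)))
  inh <- simulate_project(synthetic_project_spec(
    n_compounds, "inhouse_like", seed = derive_seed(seed, 2)))
  lib <- enumerate_library()
  files <- c(
    public = write_project(pub, file.path(out_dir, "project_public.csv")),
    inhouse = write_project(inh, file.path(out_dir, "project_inhouse.csv")))
  corpus_path <- file.path(out_dir, "pretraining_corpus.smi")
  writeLines(lib$smiles_canonical, corpus_path)
  model <- markov_fit(lib$smiles_canonical, order = 3)
  gen_path <- file.path(out_dir, "generated_reference.smi")
  writeLines(markov_sample(model, n_generated, seed = derive_seed(seed, 3)),
             gen_path)
  c(files, corpus = corpus_path, generated = gen_path)
}
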