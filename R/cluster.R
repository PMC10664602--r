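# cluster_predictivity: k-means chemical clusters and the predictive /
# unpredictive verdict.
#
# Real project compounds are clustered in ECFP6 space (k-means with
# k-means++ initialization, squared-Euclidean objective on the binary
# vectors).  Per cluster the alpha/beta/gamma members are counted; a cluster
# is predictive when it contains at least one alpha compound and more gamma
# than beta members -- the chemistry of the late actives was already seeded
# in the early stage.

#' k-means clusters in fingerprint space
#'
#' @param labelled labelled record `data.frame` (or any records with
#'   `smiles_canonical`).
#' @param k number of clusters (default 10).
#' @param seed RNG seed for the k-means++ initialization (mandatory,
#'   recorded downstream).
#' @param features optional precomputed numeric feature matrix.
#' @return integer cluster labels in `1..k`, aligned with the records.
#' @export
kmeans_clusters <- function(labelled, k = 10, seed = 42, features = NULL) {
  if (is.null(features)) {
    bits <- ecfp6_features(labelled$smiles_canonical)
    features <- fingerprint_matrix(bits, 1024)
  }
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k) stop("fewer records (", n, ") than clusters (", k, ")",
                  call. = FALSE)
  if (nrow(unique(features)) < k) {
    stop("degenerate features: fewer than k distinct points", call. = FALSE)
  }
  centers <- with_seed(seed, .kmeanspp_centers(features, k))
  fit <- stats::kmeans(features, centers = centers, iter.max = 100,
                       algorithm = "Lloyd")
  as.integer(fit$cluster)
}

# k-means++ seeding: first center uniform, then D^2-weighted draws.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      cand <- setdiff(seq_len(n), idx[seq_len(j)])
      idx[j + 1] <- cand[sample.int(length(cand), 1)]
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    nd <- rowSums((x - matrix(x[idx[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[idx, , drop = FALSE]
}

#' Per-cluster region counts
#'
#' @param cluster_labels integer labels from [kmeans_clusters()].
#' @param region_labels aligned region factor; `none` is excluded from all
#'   tallies.
#' @return `data.frame` with cluster_id, n_alpha, n_beta, n_gamma.
#' @export
region_counts <- function(cluster_labels, region_labels) {
  stopifnot(length(cluster_labels) == length(region_labels))
  ids <- sort(unique(cluster_labels))
  out <- data.frame(cluster_id = ids)
  for (reg in c("alpha", "beta", "gamma")) {
    out[[paste0("n_", reg)]] <- vapply(ids, function(cid) {
      sum(cluster_labels == cid & region_labels == reg)
    }, integer(1))
  }
  out
}

#' Predictive / unpredictive cluster verdict
#'
#' Predictive iff `n_alpha > 0` and `n_gamma > n_beta`; unpredictive iff
#' `n_alpha > 0` and `n_gamma < n_beta`; anything else (no alpha members, or
#' a gamma/beta tie) is indeterminate.
#'
#' @param n_alpha,n_beta,n_gamma non-negative counts (vectorized).
#' @return character vector of verdicts.
#' @export
classify_cluster <- function(n_alpha, n_beta, n_gamma) {
  stopifnot(all(n_alpha >= 0), all(n_beta >= 0), all(n_gamma >= 0))
  ifelse(n_alpha > 0 & n_gamma > n_beta, "predictive",
         ifelse(n_alpha > 0 & n_gamma < n_beta, "unpredictive",
                "indeterminate"))
}

#' Cluster representatives
#'
#' The centroid member (minimum Euclidean distance to the cluster mean
#' vector) and the top active (maximum pXC50); ties go to the smallest
#' `source_row`.
#'
#' @param members record `data.frame` of one cluster.
#' @param features aligned numeric feature matrix.
#' @return list with `centroid_member` and `top_active` ids.
#' @export
cluster_representatives <- function(members, features) {
  stopifnot(nrow(members) > 0, nrow(members) == nrow(features))
  features <- as.matrix(features)
  mu <- colMeans(features)
  d <- sqrt(rowSums((features - matrix(mu, nrow(features), ncol(features),
                                       byrow = TRUE))^2))
  cent <- order(d, members$source_row)[1]
  top <- order(-members$pxc50, members$source_row)[1]
  list(centroid_member = members$id[cent], top_active = members$id[top])
}

#' Cluster predictivity analysis of a labelled project
#'
#' Runs [kmeans_clusters()], [region_counts()], [classify_cluster()] and
#' [cluster_representatives()] and returns the per-cluster table plus a
#' project-level verdict summary.
#'
#' @param labelled labelled records ([label_dataset()]).
#' @param k number of clusters (default 10).
#' @param seed k-means seed.
#' @return object of class `cluster_predictivity`: list with `table`
#'   (per-cluster data.frame), `summary` (verdict counts) and `seed`.
#' @export
cluster_predictivity <- function(labelled, k = 10, seed = 42) {
  bits <- ecfp6_features(labelled$smiles_canonical)
  features <- fingerprint_matrix(bits, 1024)
  cl <- kmeans_clusters(labelled, k = k, seed = seed, features = features)
  tab <- region_counts(cl, labelled$region)
  tab$verdict <- classify_cluster(tab$n_alpha, tab$n_beta, tab$n_gamma)
  reps <- lapply(tab$cluster_id, function(cid) {
    sel <- cl == cid
    cluster_representatives(labelled[sel, , drop = FALSE],
                            features[sel, , drop = FALSE])
  })
  tab$centroid_member_id <- vapply(reps, `[[`, character(1), "centroid_member")
  tab$top_active_id <- vapply(reps, `[[`, character(1), "top_active")
  structure(list(
    table = tab,
    summary = c(n_predictive = sum(tab$verdict == "predictive"),
                n_unpredictive = sum(tab$verdict == "unpredictive"),
                n_indeterminate = sum(tab$verdict == "indeterminate")),
    seed = seed, k = k, cluster_labels = cl
  ), class = "cluster_predictivity")
}

#' @export
print.cluster_predictivity <- function(x, ...) {
  cat(sprintf("cluster predictivity (k=%d, seed=%d): %d predictive, %d unpredictive, %d indeterminate\n",
              x$k, x$seed, x$summary["n_predictive"],
              x$summary["n_unpredictive"], x$summary["n_indeterminate"]))
  print(x$table)
  invisible(x)
}
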