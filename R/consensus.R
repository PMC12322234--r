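#' Consensus clustering by repeated correlation K-means
#'
#' Runs [kmeans_correlation()] `n_reps` times with the derived seed stream
#' `seed, seed + 1, ...`, accumulates the co-association matrix `C` whose
#' entry (i, j) is the fraction of runs in which samples i and j share a
#' cluster, and extracts the consensus partition by average-linkage
#' hierarchical clustering of the distance `1 - C`, cut into `k` groups.
#' Repetition makes the result robust to K-means' sensitivity to
#' initialization.
#'
#' @param x Samples-by-features data (matrix or ratio/abundance tibble).
#' @param k Number of clusters.
#' @param n_reps Number of K-means repetitions (default 1000).
#' @param seed Base seed of the repetition stream.
#' @param diagnostics Optional `metabo_kdiag` to attach to the result.
#' @return A `metabo_clusters` list: `labels` (tibble `sample_id`,
#'   `cluster`), `k`, `coassociation` (matrix with unit diagonal),
#'   `n_reps`, `seed`, `diagnostics`.
#' @export
consensus_cluster <- function(x, k, n_reps = 1000L, seed = 1L,
                              diagnostics = NULL) {
  check_number(n_reps, "n_reps", min = 1)
  n_reps <- as.integer(n_reps)
  X <- as_feature_matrix(x)
  n <- nrow(X)
  C <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (r in seq_len(n_reps)) {
    lab <- kmeans_correlation(X, k, seed = derive_seed(seed, r - 1L))$labels
    same <- outer(lab, lab, "==")
    C <- C + same
  }
  C <- C / n_reps
  diag(C) <- 1
  hc <- hclust(as.dist(1 - C), method = "average")
  labels <- cutree(hc, k = k)
  structure(list(labels = tibble(sample_id = rownames(X),
                                 cluster = as.integer(labels)),
                 k = k,
                 coassociation = C,
                 n_reps = n_reps,
                 seed = seed,
                 diagnostics = diagnostics),
            class = "metabo_clusters")
}

#' @export
print.metabo_clusters <- function(x, ...) {
  cat(sprintf("Consensus clustering: %d samples, k = %d, %d repetitions\n",
              nrow(x$labels), x$k, x$n_reps))
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

#' @export
#' @method tidy metabo_clusters
tidy.metabo_clusters <- function(x, ...) x$labels

#' @export
#' @method glance metabo_clusters
glance.metabo_clusters <- function(x, ...) {
  sil <- tryCatch({
    s <- silhouette_widths(1 - x$coassociation, cluster_labels(x))
    mean(s$width)
  }, error = function(e) NA_real_)
  tibble(k = x$k,
         n_samples = nrow(x$labels),
         n_reps = x$n_reps,
         mean_consensus_silhouette = sil)
}

#' Extract cluster labels as a named vector
#'
#' @param x A `metabo_clusters` object, a labels tibble (`sample_id`,
#'   `cluster`), or an already-named vector.
#' @return Named integer vector of cluster ids.
#' @export
cluster_labels <- function(x) {
  if (inherits(x, "metabo_clusters")) x <- x$labels
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "cluster") %in% names(x))) {
      abort("labels tibble needs `sample_id` and `cluster` columns.")
    }
    return(setNames(as.integer(x$cluster), x$sample_id))
  }
  if (is.null(names(x))) abort("label vector must be named by sample id.")
  setNames(as.integer(x), names(x))
}
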