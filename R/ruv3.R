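#' Replicate design matrix for RUV-III
#'
#' Builds the samples-by-replicate-groups membership matrix `M` from sample
#' metadata: row order follows `samples`, group order follows first
#' appearance, and each row has exactly one 1 (every sample belongs to one
#' replicate group, typically its cell line). Cell lines measured in
#' several batches therefore tie those batches together — they are the
#' anchors the correction leans on.
#'
#' @param meta Metadata tibble with `sample_id` and `replicate_group`.
#' @param samples Ordered character vector of sample ids.
#' @return A `replicate_design` list with elements `M` (binary matrix),
#'   `groups` and `samples`.
#' @export
build_replicate_design <- function(meta, samples) {
  if (length(samples) < 1L) abort("`samples` must list at least one sample.")
  meta <- validate_metadata(meta)
  idx <- match(samples, meta$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples without metadata: ",
                 paste(head(samples[is.na(idx)], 10L), collapse = ", ")))
  }
  grp <- as.character(meta$replicate_group[idx])
  groups <- unique(grp)
  M <- matrix(0L, length(samples), length(groups),
              dimnames = list(samples, groups))
  M[cbind(seq_along(samples), match(grp, groups))] <- 1L
  structure(list(M = M, groups = groups, samples = samples),
            class = "replicate_design")
}

#' RUV-III batch correction of a log10 abundance matrix
#'
#' Removes `k` latent unwanted factors (batch/run effects) from a log10
#' abundance matrix using technical replicates, following the RUV-III
#' scheme: (i) residualize the matrix on replicate-group means,
#' `Y0 = (I - M (M'M)^-1 M') Y`, so that biology shared by replicates is
#' protected; (ii) estimate unwanted directions as the top-`k` left
#' singular vectors `U_k` of `Y0` and their loadings `alpha = U_k' Y`;
#' (iii) score every sample on those directions through the control
#' features, `W = Y_c alpha_c' (alpha_c alpha_c')^-1`; (iv) subtract the
#' fitted unwanted variation, `corrected = Y - W alpha`. With `k = 0` the
#' input is returned unchanged.
#'
#' All metabolites act as negative controls by default (`controls =
#' "all"`), the usual choice for targeted panels without spike-ins; a
#' metabolite subset can be supplied instead.
#'
#' @param y Abundance tibble with `scale = "log10"` and no missing values.
#' @param design A [build_replicate_design()] whose samples match `y`.
#' @param controls `"all"` or a character vector of control metabolites.
#' @param k Number of unwanted factors (default 9). Must satisfy
#'   `k <= n_samples - n_groups` and `k <= number of controls`.
#' @return A `metabo_ruv3` list: `corrected` (log10 abundance tibble),
#'   `W` (samples x k scores), `alpha` (k x metabolites loadings), `k`,
#'   `controls`.
#' @export
ruv3_correct <- function(y, design, controls = "all", k = 9) {
  if (abundance_scale(y) != "log10") abort("`y` must be on the log10 scale.")
  if (!inherits(design, "replicate_design")) {
    abort("`design` must come from build_replicate_design().")
  }
  Y <- abn_matrix(y)
  if (anyNA(Y)) abort("`y` has missing values; impute before correction.")
  if (!identical(rownames(Y), design$samples)) {
    abort("sample order of `y` and `design` must agree.")
  }
  if (identical(controls, "all")) {
    controls <- colnames(Y)
  } else {
    missing_c <- setdiff(controls, colnames(Y))
    if (length(missing_c)) {
      abort(paste0("control metabolites absent from `y`: ",
                   paste(missing_c, collapse = ", ")))
    }
  }
  n <- nrow(Y); G <- ncol(design$M)
  check_number(k, "k", min = 0)
  k <- as.integer(k)
  if (k > n - G) {
    abort(sprintf("k = %d exceeds samples - replicate groups = %d.", k, n - G))
  }
  if (k > length(controls)) {
    abort(sprintf("k = %d exceeds the number of control features (%d).",
                  k, length(controls)))
  }
  if (k == 0L) {
    return(structure(list(corrected = y, W = NULL, alpha = NULL, k = 0L,
                          controls = controls),
                     class = "metabo_ruv3"))
  }
  M <- design$M
  grp_idx <- max.col(M)
  grp_means <- rowsum(Y, grp_idx) / as.vector(table(grp_idx))
  Y0 <- Y - grp_means[grp_idx, , drop = FALSE]
  sv <- svd(Y0, nu = k, nv = 0)
  U <- sv$u
  alpha <- crossprod(U, Y)                       # k x m
  ac <- alpha[, controls, drop = FALSE]
  gram <- tcrossprod(ac)
  if (!all(is.finite(gram)) || kappa(gram, exact = TRUE) > 1e12) {
    abort("control loadings are numerically singular; try a smaller k.")
  }
  W <- Y[, controls, drop = FALSE] %*% t(ac) %*% solve(gram)
  corrected <- Y - W %*% alpha
  Wtbl <- dplyr::bind_cols(tibble(sample_id = rownames(Y)),
                           as_tibble(W, .name_repair = ~ paste0("W", seq_len(k))))
  structure(list(corrected = abn_from_matrix(corrected, scale = "log10"),
                 W = Wtbl,
                 alpha = alpha,
                 k = k,
                 controls = controls),
            class = "metabo_ruv3")
}

#' Average corrected replicates per cell line
#'
#' Downstream clustering operates on cell lines, not individual injections:
#' after batch correction, replicate samples of each cell line (within and
#' across batches) are averaged on the log10 scale.
#'
#' @param y A log10 abundance tibble of corrected samples.
#' @param meta Metadata with `sample_id` and `cell_line`.
#' @return A log10 abundance tibble with one row per cell line.
#' @export
aggregate_replicates <- function(y, meta) {
  if (abundance_scale(y) != "log10") abort("`y` must be on the log10 scale.")
  meta <- validate_metadata(meta, y)
  Y <- abn_matrix(y)
  cell <- meta$cell_line[match(rownames(Y), meta$sample_id)]
  agg <- rowsum(Y, cell, reorder = FALSE) / as.vector(table(factor(cell, unique(cell))))
  abn_from_matrix(agg, scale = "log10")
}

#' Post-correction replicate cohesion report
#'
#' Quality gate on the corrected matrix: samples are re-clustered with
#' correlation K-means and each replicate group is checked to land in a
#' single cluster, the criterion used to judge whether batch correction
#' succeeded. Replicate groups spanning several clusters trigger a warning.
#'
#' @param y Corrected log10 abundance tibble (sample level).
#' @param meta Metadata with `replicate_group`.
#' @param k Number of clusters for the check.
#' @param seed Seed for the K-means run.
#' @return A tibble (`replicate_group`, `n_samples`, `n_clusters_spanned`,
#'   `coherent`), invisibly warned about if any group is incoherent.
#' @export
replicate_cohesion <- function(y, meta, k, seed = 1) {
  meta <- validate_metadata(meta, y)
  labels <- kmeans_correlation(y, k = k, seed = seed)$labels
  grp <- meta$replicate_group[match(names(labels), meta$sample_id)]
  rep_tbl <- tibble(replicate_group = grp, cluster = labels)
  out <- dplyr::summarise(dplyr::group_by(rep_tbl, .data$replicate_group),
                          n_samples = dplyr::n(),
                          n_clusters_spanned = dplyr::n_distinct(.data$cluster))
  out$coherent <- out$n_clusters_spanned == 1L
  if (any(!out$coherent)) {
    warn(paste0("replicate groups split across clusters after correction: ",
                paste(out$replicate_group[!out$coherent], collapse = ", ")))
  }
  out
}

#' @export
#' @method tidy metabo_ruv3
tidy.metabo_ruv3 <- function(x, ...) {
  if (is.null(x$W)) return(tibble(sample_id = x$corrected$sample_id))
  x$W
}

#' @export
#' @method glance metabo_ruv3
glance.metabo_ruv3 <- function(x, ...) {
  tibble(k = x$k,
         n_samples = nrow(x$corrected),
         n_metabolites = length(metabolite_ids(x$corrected)),
         n_controls = length(x$controls))
}

#' @export
print.metabo_ruv3 <- function(x, ...) {
  cat(sprintf("RUV-III correction: k = %d, %d samples x %d metabolites (%d controls)\n",
              x$k, nrow(x$corrected), length(metabolite_ids(x$corrected)),
              length(x$controls)))
  invisible(x)
}
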