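#' Build the pathway ratio feature list
#'
#' One ratio feature per (pathway, member) pair whose member is present on
#' the measured panel: the feature's numerator is the member metabolite and
#' its denominator the pathway's precursor. A metabolite belonging to two
#' pathways yields two features with distinct pathway tags. Members missing
#' from the panel are skipped with a warning; a missing precursor is an
#' error, since every feature of that pathway would be undefined.
#'
#' @param pathways Pathway set tibble (see [as_pathway_set()]).
#' @param available Character vector of measured metabolite ids.
#' @return A tibble of features: `pathway`, `numerator`, `denominator`,
#'   `feature_id` (`"numerator/denominator@pathway"`), in pathway order
#'   then member order.
#' @export
build_ratio_features <- function(pathways, available) {
  pathways <- as_pathway_set(pathways)
  prec <- dplyr::distinct(pathways, .data$pathway, .data$precursor)
  missing_prec <- prec$pathway[!prec$precursor %in% available]
  if (length(missing_prec)) {
    abort(paste0("precursor metabolite missing from the panel for: ",
                 paste(missing_prec, collapse = ", ")))
  }
  skipped <- pathways[!pathways$member %in% available, ]
  if (nrow(skipped)) {
    warn(paste0("skipping pathway members absent from the panel: ",
                paste(paste0(skipped$member, "@", skipped$pathway), collapse = ", ")))
  }
  feats <- pathways[pathways$member %in% available, ]
  tibble(pathway = feats$pathway,
         numerator = feats$member,
         denominator = feats$precursor,
         feature_id = paste0(feats$member, "/", feats$precursor, "@", feats$pathway))
}

#' Compute the pathway ratio matrix
#'
#' Turns a (typically replicate-aggregated, batch-corrected) log10
#' abundance table into ratio features: each feature value is
#' `log10(numerator) - log10(denominator)`, i.e. the log10 of the
#' product-to-precursor concentration ratio. Any per-sample global shift
#' on the log scale — cell amount, extraction efficiency — cancels exactly
#' in every feature, which is what makes this the clustering substrate.
#'
#' @param y Log10 abundance tibble (one row per cell line).
#' @param features Feature tibble from [build_ratio_features()].
#' @return A `metabo_ratio` tibble: `sample_id` plus one numeric column per
#'   `feature_id`, with the feature table in the `"features"` attribute and
#'   `scaled = FALSE`.
#' @export
compute_ratio_matrix <- function(y, features) {
  if (abundance_scale(y) != "log10") abort("`y` must be on the log10 scale.")
  Y <- abn_matrix(y)
  need <- unique(c(features$numerator, features$denominator))
  missing_m <- setdiff(need, colnames(Y))
  if (length(missing_m)) {
    abort(paste0("metabolites referenced by features but absent: ",
                 paste(missing_m, collapse = ", ")))
  }
  if (anyNA(Y[, need])) abort("missing values among referenced metabolites.")
  vals <- Y[, features$numerator, drop = FALSE] -
    Y[, features$denominator, drop = FALSE]
  colnames(vals) <- features$feature_id
  new_ratio_matrix(vals, features, scaled = FALSE)
}

new_ratio_matrix <- function(vals, features, scaled) {
  out <- dplyr::bind_cols(tibble(sample_id = rownames(vals)),
                          as_tibble(vals, .name_repair = "minimal"))
  attr(out, "features") <- features
  attr(out, "scaled") <- scaled
  class(out) <- unique(c("metabo_ratio", class(out)))
  out
}

#' @rdname compute_ratio_matrix
#' @param x A `metabo_ratio` tibble.
#' @export
ratio_features <- function(x) {
  f <- attr(x, "features")
  if (is.null(f)) abort("not a ratio matrix: missing `features` attribute.")
  f
}

ratio_values <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  m
}

#' Z-score ratio features
#'
#' Centers every feature to mean 0 and scales to sd 1 (n-1 denominator),
#' the "scaled" representation used for clustering and heatmaps. Features
#' with zero variance carry no contrast and are dropped with a warning.
#'
#' @param x A `metabo_ratio` tibble with at least two samples.
#' @return The scaled `metabo_ratio` tibble (`scaled = TRUE`).
#' @export
zscore_features <- function(x) {
  vals <- ratio_values(x)
  if (nrow(vals) < 2L) abort("need at least two samples to scale features.")
  sds <- apply(vals, 2, sd)
  drop <- sds == 0
  if (any(drop)) {
    warn(paste0("dropping zero-variance features: ",
                paste(colnames(vals)[drop], collapse = ", ")))
    vals <- vals[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  if (!ncol(vals)) abort("no features left after dropping constant ones.")
  scaled <- sweep(sweep(vals, 2, colMeans(vals)), 2, sds, "/")
  feats <- ratio_features(x)
  new_ratio_matrix(scaled, feats[feats$feature_id %in% colnames(scaled), ],
                   scaled = TRUE)
}

#' Write a ratio matrix as TSV
#'
#' @param x A `metabo_ratio` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
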