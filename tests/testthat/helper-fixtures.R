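# Shared fixtures built in code. `small_cfg()` is a reduced panel (3 planted
# clusters, 12 cell lines, 3 batches) for fast unit/property tests; the
# acceptance tests use the full defaults.

small_cfg <- function(seed = 1, ...) {
  synthetic_config(n_clusters = 3, cell_lines_per_cluster = 4,
                   n_batches = 3, replicates_per_cell_line = 3,
                   n_anchor_cell_lines = 2, seed = seed, ...)
}

toy_abundance <- function() {
  as_abundance(tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    glucose = c(10, 1000, 2),
    pyruvate = c(1, 2, 3)
  ), scale = "raw")
}

toy_log_abundance <- function(values, mets = NULL) {
  m <- as.matrix(values)
  if (!is.null(mets)) colnames(m) <- mets
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), tbl)
  as_abundance(tbl, scale = "log10")
}

# truth-aligned ARI for a metabo_clusters fit on cell lines
truth_ari <- function(clusters, truth) {
  lab <- cluster_labels(clusters)
  adjusted_rand_index(lab[truth$cell_lines$cell_line],
                      truth$cell_lines$cluster)
}

run_ratio_pipeline <- function(panel, ruv_k = 9) {
  logged <- log10_transform(panel$abundance)
  design <- build_replicate_design(panel$metadata, logged$sample_id)
  ruv <- ruv3_correct(logged, design, k = ruv_k)
  agg <- aggregate_replicates(ruv$corrected, panel$metadata)
  feats <- build_ratio_features(panel$truth$config$pathways,
                                setdiff(names(agg), "sample_id"))
  ratios <- compute_ratio_matrix(agg, feats)
  list(logged = logged, ruv = ruv, aggregated = agg,
       ratios = ratios, scaled = zscore_features(ratios))
}
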