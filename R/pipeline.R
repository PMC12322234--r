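#' Pipeline configuration
#'
#' Collects the file paths and stage parameters of an end-to-end run.
#' Either build it in code or load a YAML file with the same field names.
#'
#' @param abundance,metadata,pathways Paths to the input tables.
#' @param out_dir Output directory (created if absent).
#' @param screens Optional named character vector of screen table paths.
#' @param kegg_map Optional path to a target-to-pathway map.
#' @param ruv_k Number of RUV-III unwanted factors (default 9).
#' @param controls `"all"` or a vector of control metabolites.
#' @param impute_lod Apply the half-minimum rule to non-positive cells.
#' @param k `"auto"` or a fixed integer number of clusters.
#' @param k_range Candidate k for the diagnostics (default 2:8; the gap
#'   curve additionally probes k = 1).
#' @param n_reps Consensus repetitions (default 1000).
#' @param gap_B Gap-statistic reference datasets (default 50).
#' @param q_star FDR level for contrasts (default 0.05).
#' @param contrast Optional integer pair `c(a, b)` of clusters to
#'   contrast (and to mine screens for).
#' @param top_n Top-list size for screen mining (default 20).
#' @param seed Seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(abundance, metadata, pathways, out_dir,
                            screens = NULL, kegg_map = NULL,
                            ruv_k = 9, controls = "all", impute_lod = FALSE,
                            k = "auto", k_range = 2:8, n_reps = 1000,
                            gap_B = 50, q_star = 0.05, contrast = NULL,
                            top_n = 20, seed = 1) {
  cfg <- list(abundance = abundance, metadata = metadata, pathways = pathways,
              out_dir = out_dir, screens = screens, kegg_map = kegg_map,
              ruv_k = ruv_k, controls = controls, impute_lod = impute_lod,
              k = k, k_range = k_range, n_reps = n_reps, gap_B = gap_B,
              q_star = q_star, contrast = contrast, top_n = top_n,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file with `pipeline_config()` fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  raw$screens <- if (!is.null(raw$screens)) unlist(raw$screens)
  do.call(pipeline_config, raw)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
  })
}

stage_tsv <- function(tbl, path, stage, seed) {
  cat(sprintf("# metaboratio %s seed=%d\n", stage, seed),
      readr::format_tsv(as_tibble(tbl)), sep = "", file = path)
  invisible(path)
}

#' Run the full pathway-ratio clustering pipeline
#'
#' Executes read, log10 transform, RUV-III correction, replicate
#' aggregation, ratio transform, feature scaling, consensus clustering
#' with cluster-number selection, and — when configured — the cluster
#' contrast and screen mining. All intermediates are written as TSV with a
#' `# metaboratio <stage> seed=<s>` header line, plus `diagnostics.json`
#' and a `manifest.json` recording the package version, seed, config hash
#' and per-stage dimensions. Identical configs and seeds give
#' byte-identical outputs.
#'
#' @param cfg A [pipeline_config()] or the path to a YAML config.
#' @return Invisibly, a list with the in-memory stage results
#'   (`corrected`, `aggregated`, `ratios`, `ratios_scaled`, `clusters`,
#'   `contrast`, `screens`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (!inherits(cfg, "pipeline_config")) {
    abort("`cfg` must be a pipeline_config or a YAML path.")
  }
  for (f in c("abundance", "metadata", "pathways")) {
    if (!file.exists(cfg[[f]])) {
      abort(sprintf("pipeline stage `read`: missing %s file: %s", f, cfg[[f]]))
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  manifest <- list(package = "metaboratio",
                   version = as.character(packageVersion("metaboratio")),
                   seed = seed,
                   # hash of the analysis-defining fields; the output
                   # location does not change what is computed
                   config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg),
                                                                  "out_dir")]),
                   stages = list())
  note <- function(stage, nrow, ncol) {
    manifest$stages[[stage]] <<- list(rows = nrow, cols = ncol)
  }

  abn <- run_stage("read", read_abundance_table(cfg$abundance))
  meta <- run_stage("read", read_metadata(cfg$metadata))
  meta <- run_stage("read", validate_metadata(meta, abn))
  pathways <- run_stage("read", read_pathways(cfg$pathways))
  note("read", nrow(abn), length(metabolite_ids(abn)))

  logged <- run_stage("log10", log10_transform(abn, impute_lod = cfg$impute_lod))
  design <- run_stage("ruv3", build_replicate_design(meta, logged$sample_id))
  ruv <- run_stage("ruv3", ruv3_correct(logged, design,
                                        controls = cfg$controls, k = cfg$ruv_k))
  stage_tsv(ruv$corrected, file.path(cfg$out_dir, "corrected.tsv"), "correct", seed)
  if (!is.null(ruv$W)) {
    stage_tsv(ruv$W, file.path(cfg$out_dir, "W.tsv"), "correct", seed)
    alpha_tbl <- dplyr::bind_cols(
      tibble(factor = paste0("W", seq_len(ruv$k))),
      as_tibble(ruv$alpha, .name_repair = "minimal"))
    stage_tsv(alpha_tbl, file.path(cfg$out_dir, "alpha.tsv"), "correct", seed)
  }
  note("correct", nrow(ruv$corrected), length(metabolite_ids(ruv$corrected)))

  agg <- run_stage("aggregate", aggregate_replicates(ruv$corrected, meta))
  stage_tsv(agg, file.path(cfg$out_dir, "aggregated.tsv"), "aggregate", seed)
  note("aggregate", nrow(agg), length(metabolite_ids(agg)))

  feats <- run_stage("ratios", build_ratio_features(pathways, metabolite_ids(agg)))
  ratios <- run_stage("ratios", compute_ratio_matrix(agg, feats))
  scaled <- run_stage("ratios", zscore_features(ratios))
  stage_tsv(ratios, file.path(cfg$out_dir, "ratios.tsv"), "ratios", seed)
  stage_tsv(scaled, file.path(cfg$out_dir, "ratios.scaled.tsv"), "ratios", seed)
  note("ratios", nrow(ratios), nrow(feats))

  clusters <- run_stage("cluster",
                        cluster_cells(scaled, k = cfg$k, k_range = cfg$k_range,
                                      n_reps = cfg$n_reps, B = cfg$gap_B,
                                      seed = seed))
  stage_tsv(clusters$labels, file.path(cfg$out_dir, "labels.tsv"), "cluster", seed)
  coassoc <- dplyr::bind_cols(
    tibble(sample_id = rownames(clusters$coassociation)),
    as_tibble(clusters$coassociation, .name_repair = "minimal"))
  stage_tsv(coassoc, file.path(cfg$out_dir, "coassociation.tsv"), "cluster", seed)
  diag_json <- list(table = clusters$diagnostics$table,
                    chosen = clusters$diagnostics$chosen,
                    k_used = clusters$k)
  jsonlite::write_json(diag_json, file.path(cfg$out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("cluster", nrow(clusters$labels), clusters$k)

  contrast_tbl <- NULL
  if (!is.null(cfg$contrast)) {
    contrast_tbl <- run_stage("contrast",
                              contrast_clusters(ratios, clusters,
                                                a = cfg$contrast[1L],
                                                b = cfg$contrast[2L],
                                                q_star = cfg$q_star))
    stage_tsv(contrast_tbl, file.path(cfg$out_dir, "contrast.tsv"),
              "contrast", seed)
    note("contrast", nrow(contrast_tbl), ncol(contrast_tbl))
  }

  screen_results <- NULL
  if (!is.null(cfg$screens) && !is.null(cfg$kegg_map) && !is.null(cfg$contrast)) {
    kegg <- run_stage("screens", read_pathway_map(cfg$kegg_map))
    tops <- list()
    for (nm in names(cfg$screens)) {
      scr <- run_stage("screens", read_screen_table(cfg$screens[[nm]]))
      filt <- run_stage("screens", join_screens(scr, clusters, kegg))
      dt <- run_stage("screens",
                      differential_response(filt, clusters,
                                            a = cfg$contrast[1L],
                                            b = cfg$contrast[2L],
                                            pathway_map = kegg))
      stage_tsv(dt, file.path(cfg$out_dir, sprintf("differential_%s.tsv", nm)),
                "screens", seed)
      top <- top_n_targets(dt, n = cfg$top_n)
      stage_tsv(top, file.path(cfg$out_dir, sprintf("top%d_%s.tsv", cfg$top_n, nm)),
                "screens", seed)
      tops[[nm]] <- top
    }
    all_top <- dplyr::bind_rows(tops)
    scores <- run_stage("screens",
                        consolidate_pathways(all_top, kegg, n = cfg$top_n))
    stage_tsv(scores, file.path(cfg$out_dir, "pathway_scores.tsv"), "screens", seed)
    screen_results <- list(top = all_top, pathway_scores = scores)
    note("screens", nrow(all_top), nrow(scores))
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(corrected = ruv, aggregated = agg, ratios = ratios,
                 ratios_scaled = scaled, clusters = clusters,
                 contrast = contrast_tbl, screens = screen_results,
                 manifest = manifest))
}

#' Write a synthetic study to disk
#'
#' Materializes a [generate_panel()] draw (and optionally screens) in the
#' file layout [run_pipeline()] consumes: `abundance.tsv`, `metadata.tsv`,
#' `pathways.tsv`, `truth.json`, and `screens/<db>.tsv` plus
#' `kegg_map.tsv`.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory.
#' @param screens Also write synthetic screen tables (default `TRUE`).
#' @param ... Passed to [generate_screens()].
#' @return Invisibly, the list of written paths.
#' @export
write_synthetic_study <- function(cfg, dir, screens = TRUE, ...) {
  panel <- generate_panel(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(abundance = file.path(dir, "abundance.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                pathways = file.path(dir, "pathways.tsv"))
  readr::write_tsv(as_tibble(panel$abundance), paths$abundance, progress = FALSE)
  readr::write_tsv(panel$metadata, paths$metadata, progress = FALSE)
  readr::write_tsv(cfg$pathways, paths$pathways, progress = FALSE)
  truth <- panel$truth
  jsonlite::write_json(
    list(cell_lines = truth$cell_lines,
         delta = as.data.frame(truth$delta),
         vulnerable_pathways = truth$vulnerable_pathways),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$truth <- file.path(dir, "truth.json")
  if (screens) {
    scr <- generate_screens(panel$truth, seed = cfg$seed, ...)
    dir.create(file.path(dir, "screens"), showWarnings = FALSE)
    paths$screens <- vapply(names(scr$screens), function(nm) {
      p <- file.path(dir, "screens", paste0(nm, ".tsv"))
      readr::write_tsv(as_tibble(scr$screens[[nm]]), p, progress = FALSE)
      p
    }, character(1))
    paths$kegg_map <- file.path(dir, "kegg_map.tsv")
    readr::write_tsv(scr$pathway_map, paths$kegg_map, progress = FALSE)
  }
  invisible(paths)
}
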