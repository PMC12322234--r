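#' Configuration for the synthetic panel generator
#'
#' Describes a synthetic targeted-metabolomics study: cell lines grouped
#' into planted metabolic clusters, measured in replicate across several
#' batches with shared anchor (control) cell lines, on a metabolite panel
#' defined by a pathway set. Cluster identity is expressed *only* as
#' pathway activity shifts `delta` added to the log10 abundance of pathway
#' member metabolites (never to the pathway precursor), so the planted
#' structure is by construction a product-to-precursor ratio signal.
#'
#' On top of the cluster signal, every metabolite gets a per-batch additive
#' offset (log10 scale, sd `batch_effect_sd`), every sample a global
#' scaling factor applied to all metabolites (sd `sample_scaling_sd`, the
#' cell-amount/extraction artifact that masks clustering on abundances),
#' and every cell i.i.d. technical noise (sd `technical_noise_sd`).
#'
#' @param n_clusters Number of planted clusters (default 5).
#' @param cell_lines_per_cluster Cell lines per cluster (default 12).
#' @param n_batches Number of measurement batches (default 6).
#' @param replicates_per_cell_line Technical replicates per cell line and
#'   batch (default 3).
#' @param n_anchor_cell_lines Cell lines re-measured in every batch as
#'   batch-correction controls (default 3).
#' @param pathways Pathway set tibble (see [as_pathway_set()]); defaults to
#'   the seven-pathway example shipped with the package.
#' @param delta Optional cluster-by-pathway matrix of log10 activity shifts
#'   (rownames `cluster_1..`, colnames = pathway names). By default each
#'   cluster raises one pathway by `delta_magnitude` and lowers another.
#' @param delta_magnitude Magnitude of the default shifts, log10 units
#'   (default 0.5).
#' @param baseline_log_mean,baseline_log_sd Mean and sd of the
#'   per-metabolite baseline log10 abundance (defaults 1.0 and 0.4).
#' @param batch_effect_sd Sd of per-(batch, metabolite) offsets (default 0.3).
#' @param sample_scaling_sd Sd of the per-sample global shift (default 0.3).
#' @param technical_noise_sd Sd of cell-wise noise (default 0.08).
#' @param n_extra_metabolites Panel metabolites outside any pathway
#'   (default 9, bringing the example panel to 50).
#' @param vulnerable_pathways Optional tibble (`cluster`, `pathway`) of
#'   screen vulnerabilities; by default each cluster is vulnerable to the
#'   pathway its `delta` raises most.
#' @param seed Integer seed for all draws.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_clusters = 5,
                             cell_lines_per_cluster = 12,
                             n_batches = 6,
                             replicates_per_cell_line = 3,
                             n_anchor_cell_lines = 3,
                             pathways = NULL,
                             delta = NULL,
                             delta_magnitude = 0.5,
                             baseline_log_mean = 1.0,
                             baseline_log_sd = 0.4,
                             batch_effect_sd = 0.3,
                             sample_scaling_sd = 0.3,
                             technical_noise_sd = 0.08,
                             n_extra_metabolites = 9,
                             vulnerable_pathways = NULL,
                             seed = 1) {
  check_number(n_clusters, "n_clusters", min = 1)
  check_number(cell_lines_per_cluster, "cell_lines_per_cluster", min = 1)
  check_number(n_batches, "n_batches", min = 1)
  check_number(replicates_per_cell_line, "replicates_per_cell_line", min = 1)
  check_number(n_anchor_cell_lines, "n_anchor_cell_lines", min = 0)
  for (nm in c("baseline_log_sd", "batch_effect_sd", "sample_scaling_sd",
               "technical_noise_sd")) {
    check_number(get(nm), nm, min = 0)
  }
  n_cells <- n_clusters * cell_lines_per_cluster
  if (n_anchor_cell_lines > n_cells) {
    abort("`n_anchor_cell_lines` cannot exceed the total number of cell lines.")
  }
  if (is.null(pathways)) {
    pathways <- read_pathways(system.file("extdata", "pathways_example.tsv",
                                          package = "metaboratio"))
  } else {
    pathways <- as_pathway_set(pathways)
  }
  path_names <- unique(pathways$pathway)
  if (is.null(delta)) {
    delta <- default_delta(n_clusters, path_names, delta_magnitude)
  } else {
    delta <- as.matrix(delta)
    if (nrow(delta) != n_clusters || !all(colnames(delta) %in% path_names)) {
      abort("`delta` must have one row per cluster and pathway-named columns.")
    }
  }
  if (is.null(vulnerable_pathways)) {
    vulnerable_pathways <- tibble(
      cluster = seq_len(n_clusters),
      pathway = colnames(delta)[apply(delta, 1, which.max)]
    )
  }
  structure(
    list(n_clusters = n_clusters,
         cell_lines_per_cluster = cell_lines_per_cluster,
         n_batches = n_batches,
         replicates_per_cell_line = replicates_per_cell_line,
         n_anchor_cell_lines = n_anchor_cell_lines,
         pathways = pathways,
         delta = delta,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         batch_effect_sd = batch_effect_sd,
         sample_scaling_sd = sample_scaling_sd,
         technical_noise_sd = technical_noise_sd,
         n_extra_metabolites = n_extra_metabolites,
         vulnerable_pathways = as_tibble(vulnerable_pathways),
         seed = as.integer(seed)),
    class = "synthetic_config")
}

# Each cluster c raises one pathway and lowers another, chosen so that every
# pair of clusters differs on at least two pathways; with the default
# seven-pathway set and five clusters, clusters 3 and 4 differ maximally on
# the TCA cycle (the contrast the study conditions highlight).
default_delta <- function(n_clusters, path_names, mag) {
  P <- length(path_names)
  delta <- matrix(0, n_clusters, P,
                  dimnames = list(paste0("cluster_", seq_len(n_clusters)),
                                  path_names))
  if (P >= 7 && n_clusters == 5) {
    up <- c(1, 2, 4, 3, 5)    # gly, ppp, proline, tca, serine
    dn <- c(5, 6, 3, 6, 7)    # serine, glutamine, tca, glutamine, methionine
    for (c in seq_len(n_clusters)) {
      delta[c, up[c]] <- mag
      delta[c, dn[c]] <- -mag
    }
  } else {
    for (c in seq_len(n_clusters)) {
      delta[c, 1 + (c - 1) %% P] <- mag
      delta[c, 1 + c %% P] <- -mag
    }
  }
  delta
}

# spare metabolites present on the panel but outside every pathway
extra_metabolite_names <- function(n) {
  pool <- c("alanine", "leucine", "isoleucine", "valine", "threonine",
            "lysine", "tryptophan", "tyrosine", "phenylalanine")
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, sprintf("extra_%02d", seq_len(n - length(pool))))
}

#' Generate a synthetic abundance panel
#'
#' Draws a raw-scale abundance table, matching sample metadata, and the
#' ground truth (planted labels, batch effects, sample scalings) from a
#' [synthetic_config()]. Log10 abundance of metabolite j in a sample of
#' cell line c in batch b is
#' `mu0_j + sum of delta(cluster(c), p) over pathways p having j as member
#'  + batch(b, j) + s_sample + noise`,
#' and the emitted matrix is `10^x` (raw concentrations). Anchor cell lines
#' appear in every batch; every other cell line is measured in one batch,
#' assigned round-robin. The truth object is for evaluation only — nothing
#' downstream may consume it.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `abundance` (raw-scale abundance tibble),
#'   `metadata` (tibble), and `truth` (a `synthetic_truth` list with
#'   `cell_lines`, `delta`, `batch_effects`, `sample_scaling`,
#'   `vulnerable_pathways`, `baseline`, `config`).
#' @examples
#' panel <- generate_panel(synthetic_config(seed = 7))
#' dim(panel$abundance)
#' @export
generate_panel <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) abort("`cfg` must be a synthetic_config.")
  with_rng(cfg$seed, {
    pw <- cfg$pathways
    mets <- unique(c(rbind_order_metabolites(pw),
                     extra_metabolite_names(cfg$n_extra_metabolites)))
    n_met <- length(mets)
    n_cells <- cfg$n_clusters * cfg$cell_lines_per_cluster
    cells <- sprintf("CL%02d", seq_len(n_cells))
    cluster_of <- rep(seq_len(cfg$n_clusters), each = cfg$cell_lines_per_cluster)
    # anchors drawn evenly across clusters so controls span the panel
    anchor_idx <- unique(round(seq(1, n_cells,
                                   length.out = max(cfg$n_anchor_cell_lines, 1))))
    anchor_idx <- anchor_idx[seq_len(min(cfg$n_anchor_cell_lines, length(anchor_idx)))]
    anchors <- cells[anchor_idx]

    # membership-weighted delta per (cluster, metabolite): effects of all
    # pathways a metabolite belongs to (as member) add on the log scale
    shift <- matrix(0, cfg$n_clusters, n_met, dimnames = list(NULL, mets))
    for (p in unique(pw$pathway)) {
      members <- pw$member[pw$pathway == p]
      members <- intersect(members, mets)
      shift[, members] <- shift[, members] + cfg$delta[, p]
    }

    # draw unit normals and scale, so the RNG stream is identical across
    # sd settings (needed for the sigma_s ratio-cancellation invariant)
    mu0 <- cfg$baseline_log_mean + rnorm(n_met) * cfg$baseline_log_sd
    names(mu0) <- mets
    batch_eff <- matrix(rnorm(cfg$n_batches * n_met) * cfg$batch_effect_sd,
                        cfg$n_batches, n_met, dimnames = list(NULL, mets))

    meta <- list()
    non_anchor <- setdiff(cells, anchors)
    home_batch <- setNames(rep_len(seq_len(cfg$n_batches), length(non_anchor)),
                           non_anchor)
    for (cl in cells) {
      batches <- if (cl %in% anchors) seq_len(cfg$n_batches) else home_batch[[cl]]
      for (b in batches) {
        meta[[length(meta) + 1L]] <- tibble(
          sample_id = sprintf("%s_b%d_r%d", cl, b, seq_len(cfg$replicates_per_cell_line)),
          cell_line = cl,
          batch = b,
          replicate_group = cl
        )
      }
    }
    meta <- dplyr::bind_rows(meta)
    meta$is_anchor <- meta$cell_line %in% anchors
    # decorative annotations of the kind real panels carry
    tissue <- setNames(sample(c("tumor", "normal"), n_cells, TRUE, c(0.85, 0.15)), cells)
    cancer <- setNames(sample(c("breast", "prostate", "lung", "liver",
                                "pancreas", "endometrial"), n_cells, TRUE), cells)
    media <- setNames(sample(c("DMEM", "RPMI", "DMEM/F12"), n_cells, TRUE), cells)
    meta$tissue_type <- tissue[meta$cell_line]
    meta$cancer_type <- cancer[meta$cell_line]
    meta$media <- media[meta$cell_line]

    n_samp <- nrow(meta)
    s_i <- rnorm(n_samp) * cfg$sample_scaling_sd
    cl_idx <- match(meta$cell_line, cells)
    x <- matrix(mu0, n_samp, n_met, byrow = TRUE, dimnames = list(meta$sample_id, mets))
    x <- x + shift[cluster_of[cl_idx], , drop = FALSE]
    x <- x + batch_eff[meta$batch, , drop = FALSE]
    x <- x + s_i
    x <- x + matrix(rnorm(n_samp * n_met) * cfg$technical_noise_sd, n_samp, n_met)

    truth <- structure(
      list(cell_lines = tibble(cell_line = cells,
                               cluster = cluster_of,
                               is_anchor = cells %in% anchors),
           delta = cfg$delta,
           batch_effects = batch_eff,
           sample_scaling = tibble(sample_id = meta$sample_id, scaling = s_i),
           vulnerable_pathways = cfg$vulnerable_pathways,
           baseline = mu0,
           config = cfg),
      class = "synthetic_truth")

    list(abundance = abn_from_matrix(10^x, scale = "raw"),
         metadata = meta,
         truth = truth)
  })
}

# panel order: precursors and members in first-appearance order
rbind_order_metabolites <- function(pw) {
  unique(c(t(cbind(pw$precursor, pw$member))))
}

#' Generate synthetic loss-of-function / drug-sensitivity screens
#'
#' Builds one screen table per database in the shape of DEMETER / Project
#' Score fitness scores or PRISM / GDSC2 drug AUCs, with a matching
#' target-to-pathway map. Every pathway of the truth's delta matrix gets
#' `n_targets_per_pathway` targets; a cell line's score for a target is
#' `baseline + effect * [cluster vulnerable to the target's pathway] + noise`.
#' All default databases use the lower-is-more-sensitive convention, so a
#' negative `effect` makes vulnerable lines score lower.
#'
#' @param truth A `synthetic_truth` from [generate_panel()].
#' @param n_targets_per_pathway Targets simulated per pathway (default 20).
#' @param effect Score shift for vulnerable lines (default -1).
#' @param noise_sd Sd of score noise (default 0.1).
#' @param databases Character vector of database names (default the four
#'   study-shaped screens).
#' @param baselines Named numeric vector of per-database baseline scores;
#'   defaults to 0 for fitness screens and 1 for AUC screens.
#' @param seed Integer seed.
#' @return A list with `screens` (named list of screen tibbles, see
#'   [as_screen_table()]) and `pathway_map` (tibble `target`,
#'   `kegg_pathway`).
#' @export
generate_screens <- function(truth,
                             n_targets_per_pathway = 20,
                             effect = -1,
                             noise_sd = 0.1,
                             databases = c("DEMETER", "ProjectScore",
                                           "PRISM", "GDSC2"),
                             baselines = NULL,
                             seed = 1) {
  if (!inherits(truth, "synthetic_truth")) abort("`truth` must come from generate_panel().")
  if (length(databases) < 1L) abort("`databases` must name at least one screen.")
  check_number(n_targets_per_pathway, "n_targets_per_pathway", min = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  if (nrow(truth$vulnerable_pathways) < 1L) {
    abort("truth has no vulnerable pathway for any cluster.")
  }
  if (is.null(baselines)) {
    baselines <- ifelse(databases %in% c("PRISM", "GDSC2"), 1, 0)
    names(baselines) <- databases
  }
  with_rng(seed, {
    path_names <- colnames(truth$delta)
    map <- tidyr::expand_grid(kegg_pathway = path_names,
                              idx = seq_len(n_targets_per_pathway))
    map$target <- sprintf("%s_t%02d", map$kegg_pathway, map$idx)
    map <- dplyr::select(map, "target", "kegg_pathway")

    cells <- truth$cell_lines
    vuln <- truth$vulnerable_pathways
    vuln_key <- paste(vuln$cluster, vuln$pathway)

    screens <- lapply(databases, function(db) {
      grid <- tidyr::expand_grid(cell_line = cells$cell_line, target = map$target)
      grid$kegg_pathway <- map$kegg_pathway[match(grid$target, map$target)]
      cl <- cells$cluster[match(grid$cell_line, cells$cell_line)]
      hit <- paste(cl, grid$kegg_pathway) %in% vuln_key
      grid$score <- baselines[[db]] + effect * as.numeric(hit) +
        rnorm(nrow(grid)) * noise_sd
      grid$database <- db
      as_screen_table(dplyr::select(grid, "cell_line", "target", "score", "database"),
                      score_direction = "lower_is_more_sensitive")
    })
    names(screens) <- databases
    list(screens = screens, pathway_map = map)
  })
}
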