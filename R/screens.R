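#' Filter a screen table to clustered cell lines and mapped targets
#'
#' Mirrors the mining setup for public loss-of-function and drug screens:
#' keep records whose cell line carries a cluster label and whose target
#' appears in the target-to-pathway map (e.g. KEGG metabolic pathway
#' genes). Retained/dropped counts are stored in the `"filter_counts"`
#' attribute.
#'
#' @param screen A screen tibble (see [as_screen_table()]).
#' @param labels Cluster labels (named vector, tibble, or
#'   `metabo_clusters`).
#' @param pathway_map Tibble `target`, `kegg_pathway`.
#' @return The filtered screen tibble (same `score_direction`).
#' @export
join_screens <- function(screen, labels, pathway_map) {
  dir <- screen_direction(screen)
  lab <- cluster_labels(labels)
  if (!length(lab)) abort("`labels` is empty.")
  pathway_map <- as_pathway_map(pathway_map)
  if (!any(screen$cell_line %in% names(lab))) {
    abort("no screen cell line overlaps the clustered panel.")
  }
  keep_cell <- screen$cell_line %in% names(lab)
  keep_target <- screen$target %in% pathway_map$target
  out <- screen[keep_cell & keep_target, ]
  out <- as_screen_table(out, score_direction = dir)
  attr(out, "filter_counts") <- c(
    retained = nrow(out),
    dropped_unlabeled_cell = sum(!keep_cell),
    dropped_unmapped_target = sum(keep_cell & !keep_target)
  )
  out
}

#' Differential screen response between two clusters
#'
#' Within each database, every target's scores are z-scored across the
#' screen's full filtered cell-line set (mean 0, sd 1, n-1 denominator)
#' and the differential score is the mean z over cluster `a` minus the
#' mean z over cluster `b`. Under the lower-is-more-sensitive convention
#' targets are ranked ascending, so the targets cluster `a` is most
#' vulnerable to come first. Targets measured in fewer than two cell lines
#' of either cluster, or with zero score variance, are excluded with a
#' warning.
#'
#' @param screen A filtered screen tibble (from [join_screens()]).
#' @param labels Cluster labels.
#' @param a,b Cluster ids (differential is mean z of `a` minus `b`).
#' @param pathway_map Optional `target`/`kegg_pathway` tibble used to
#'   annotate targets (several pathways are collapsed with `";"`).
#' @return A `metabo_screen_diff` tibble: `database`, `target`,
#'   `pathways`, `n_a`, `n_b`, `mean_z_a`, `mean_z_b`, `differential`,
#'   `rank` (within database; ties broken by target id).
#' @export
differential_response <- function(screen, labels, a, b, pathway_map = NULL) {
  dir <- screen_direction(screen)
  lab <- cluster_labels(labels)
  screen <- screen[screen$cell_line %in% names(lab), ]
  cl <- lab[screen$cell_line]
  per_db <- lapply(split(seq_len(nrow(screen)), screen$database), function(idx) {
    db <- screen[idx, ]
    dbcl <- cl[idx]
    rows <- lapply(split(seq_len(nrow(db)), db$target), function(ti) {
      sc <- db$score[ti]
      gi <- dbcl[ti]
      n_a <- sum(gi == a); n_b <- sum(gi == b)
      if (n_a < 2L || n_b < 2L || sd(sc) == 0) return(NULL)
      z <- (sc - mean(sc)) / sd(sc)
      tibble(database = db$database[ti[1L]], target = db$target[ti[1L]],
             n_a = n_a, n_b = n_b,
             mean_z_a = mean(z[gi == a]), mean_z_b = mean(z[gi == b]),
             differential = mean(z[gi == a]) - mean(z[gi == b]))
    })
    dropped <- sum(vapply(rows, is.null, logical(1)))
    if (dropped) {
      warn(sprintf("%d target(s) excluded in %s (undersampled cluster or zero variance).",
                   dropped, db$database[1L]))
    }
    out <- dplyr::bind_rows(rows)
    if (!nrow(out)) return(out)
    asc <- dir == "lower_is_more_sensitive"
    out <- out[order(if (asc) out$differential else -out$differential,
                     out$target), ]
    out$rank <- seq_len(nrow(out))
    out
  })
  out <- dplyr::bind_rows(per_db)
  if (!nrow(out)) abort("no target had enough labeled cell lines in both clusters.")
  if (!is.null(pathway_map)) {
    pathway_map <- as_pathway_map(pathway_map)
    ann <- dplyr::summarise(dplyr::group_by(pathway_map, .data$target),
                            pathways = paste(sort(.data$kegg_pathway),
                                             collapse = ";"))
    out$pathways <- ann$pathways[match(out$target, ann$target)]
  } else {
    out$pathways <- NA_character_
  }
  out <- dplyr::relocate(out, "database", "target", "pathways")
  attr(out, "clusters") <- c(a = a, b = b)
  attr(out, "score_direction") <- dir
  class(out) <- unique(c("metabo_screen_diff", class(out)))
  out
}

#' Top differential targets per database
#'
#' @param dt A `metabo_screen_diff` tibble.
#' @param n Targets to keep per database (default 20).
#' @return The rows with `rank <= n` in each database.
#' @export
top_n_targets <- function(dt, n = 20) {
  check_number(n, "n", min = 1)
  if (!nrow(dt)) abort("`dt` is empty.")
  dt[dt$rank <= n, ]
}

#' Consolidate top-target lists into pathway scores
#'
#' Scores each pathway by how strongly it is represented among the most
#' differential targets across databases: per database, the number of its
#' targets inside that database's top list, divided by `n`; summed over
#' databases. A target annotated to several pathways counts once for each.
#' Pathways are ranked by descending score, ties broken alphabetically.
#'
#' @param top A `metabo_screen_diff` tibble already cut to top lists (see
#'   [top_n_targets()]), or a full table plus `n`.
#' @param pathway_map Tibble `target`, `kegg_pathway`.
#' @param n Top-list size used for normalization (default 20).
#' @return A tibble: `kegg_pathway`, per-database counts (long column
#'   `database`, `n_in_top` aggregated), `score`, `rank`.
#' @export
consolidate_pathways <- function(top, pathway_map, n = 20) {
  check_number(n, "n", min = 1)
  pathway_map <- as_pathway_map(pathway_map)
  top <- top[top$rank <= n, ]
  hits <- dplyr::inner_join(
    dplyr::select(as_tibble(top), "database", "target"),
    pathway_map, by = "target", relationship = "many-to-many")
  per_db <- dplyr::summarise(
    dplyr::group_by(hits, .data$kegg_pathway, .data$database),
    n_in_top = dplyr::n_distinct(.data$target), .groups = "drop")
  scores <- dplyr::summarise(dplyr::group_by(per_db, .data$kegg_pathway),
                             n_databases = dplyr::n(),
                             score = sum(.data$n_in_top) / n, .groups = "drop")
  scores <- scores[order(-scores$score, scores$kegg_pathway), ]
  scores$rank <- seq_len(nrow(scores))
  attr(scores, "per_database") <- per_db
  scores
}
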