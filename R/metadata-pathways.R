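#' Validate sample metadata against an abundance table
#'
#' Sample metadata is a plain tibble with at least `sample_id`,
#' `cell_line`, `batch` and `replicate_group` columns; optional annotation
#' columns (`tissue_type`, `cancer_type`, `media`, oncogene mutation flags)
#' ride along untouched. The replicate group is the identifier shared by all
#' samples of one cell line, within and across batches — it anchors the
#' RUV-III correction.
#'
#' @param meta A data frame of sample metadata.
#' @param abundance Optionally, an abundance tibble whose samples must each
#'   appear exactly once in `meta`.
#' @return The metadata as a tibble, invisibly validated.
#' @export
validate_metadata <- function(meta, abundance = NULL) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "cell_line", "batch", "replicate_group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("metadata is missing columns: ", paste(miss, collapse = ", ")))
  }
  meta$sample_id <- as.character(meta$sample_id)
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) {
    abort(paste0("duplicate sample ids in metadata: ", paste(dup, collapse = ", ")))
  }
  if (anyNA(meta$replicate_group)) abort("every sample needs a replicate_group.")
  if (!is.null(abundance)) {
    missing_s <- setdiff(abundance$sample_id, meta$sample_id)
    if (length(missing_s)) {
      abort(paste0("samples absent from metadata: ",
                   paste(head(missing_s, 10L), collapse = ", ")))
    }
  }
  meta
}

#' Read sample metadata from a delimited file
#'
#' @param path TSV/CSV file with a header; delimiter auto-detected.
#' @return A validated metadata tibble (see [validate_metadata()]).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- guess_delim(path)
  validate_metadata(readr::read_delim(path, delim = delim,
                                      show_col_types = FALSE, progress = FALSE, comment = "#"))
}

#' Pathway definitions
#'
#' A pathway set is a tibble in long form with columns `pathway`,
#' `precursor` and `member`: one row per (pathway, member) pair, with the
#' pathway's single precursor (denominator) metabolite repeated on each row.
#' The precursor is the pathway entry or hub metabolite — e.g. glucose for
#' glycolysis and the pentose phosphate pathway, pyruvate for the TCA
#' cycle, glutamine for glutamine metabolism — and member metabolites are
#' the numerators of the ratio features. A metabolite may be a member of
#' several pathways (each occurrence yields its own ratio feature) but not
#' twice within one pathway, and never the precursor of its own pathway.
#'
#' An editable example with seven central-carbon and amino-acid pathways
#' ships with the package:
#' `system.file("extdata", "pathways_example.tsv", package = "metaboratio")`.
#' Pathway membership is a modelling choice the user owns; the example file
#' is illustrative, not canonical.
#'
#' @param x A data frame with columns `pathway`, `precursor`, `member`.
#' @return The validated pathway tibble.
#' @export
as_pathway_set <- function(x) {
  x <- as_tibble(x)
  need <- c("pathway", "precursor", "member")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("pathway table is missing columns: ", paste(miss, collapse = ", ")))
  }
  x <- dplyr::mutate(x, dplyr::across(dplyr::all_of(need), as.character))
  if (any(!nzchar(x$pathway)) || anyNA(x$pathway)) abort("empty pathway names.")
  per_path <- dplyr::summarise(dplyr::group_by(x, .data$pathway),
                               n_prec = dplyr::n_distinct(.data$precursor),
                               self = any(.data$member == .data$precursor),
                               dup = anyDuplicated(.data$member) > 0L)
  bad <- per_path$pathway[per_path$n_prec != 1L]
  if (length(bad)) {
    abort(paste0("pathways with more than one precursor: ", paste(bad, collapse = ", ")))
  }
  bad <- per_path$pathway[per_path$self]
  if (length(bad)) {
    abort(paste0("precursor listed among its own members in: ",
                 paste(bad, collapse = ", ")))
  }
  bad <- per_path$pathway[per_path$dup]
  if (length(bad)) {
    abort(paste0("duplicated members within: ", paste(bad, collapse = ", ")))
  }
  x
}

#' @rdname as_pathway_set
#' @param path TSV/CSV file with columns `pathway`, `precursor`, `member`.
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- guess_delim(path)
  as_pathway_set(readr::read_delim(path, delim = delim,
                                   show_col_types = FALSE, progress = FALSE, comment = "#"))
}

#' Screen tables and target-to-pathway maps
#'
#' A screen table is a long tibble with columns `cell_line`, `target`
#' (gene or drug id), `score` and `database`, carrying a `score_direction`
#' attribute: `"lower_is_more_sensitive"` for loss-of-function fitness
#' scores and drug AUCs (the usual convention), or
#' `"higher_is_more_sensitive"`. `(cell_line, target, database)` must be
#' unique and scores finite.
#'
#' @param x A data frame with the four screen columns.
#' @param score_direction Direction convention of the scores.
#' @return The validated screen tibble.
#' @export
as_screen_table <- function(x,
                            score_direction = c("lower_is_more_sensitive",
                                                "higher_is_more_sensitive")) {
  score_direction <- match.arg(score_direction)
  x <- as_tibble(x)
  need <- c("cell_line", "target", "score", "database")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("screen table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(x$score) || !all(is.finite(x$score))) {
    abort("screen scores must be finite numbers.")
  }
  key <- paste(x$cell_line, x$target, x$database, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (cell_line, target, database) records in screen table.")
  }
  attr(x, "score_direction") <- score_direction
  x
}

#' @rdname as_screen_table
#' @param path TSV/CSV file with columns `cell_line`, `target`, `score`,
#'   `database`.
#' @export
read_screen_table <- function(path,
                              score_direction = c("lower_is_more_sensitive",
                                                  "higher_is_more_sensitive")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- guess_delim(path)
  as_screen_table(readr::read_delim(path, delim = delim,
                                    show_col_types = FALSE, progress = FALSE, comment = "#"),
                  score_direction = score_direction)
}

#' @rdname as_screen_table
#' @export
screen_direction <- function(x) {
  dir <- attr(x, "score_direction")
  if (is.null(dir)) abort("not a screen table: missing `score_direction`.")
  dir
}

#' Read a target-to-pathway map
#'
#' Maps screen targets (genes or drugs) to metabolic pathway names, e.g.
#' KEGG metabolic pathways; a target may map to several pathways. Supplied
#' as a static user file so results do not depend on a live database
#' version.
#'
#' @param path TSV/CSV file with columns `target`, `kegg_pathway`.
#' @return A tibble with columns `target`, `kegg_pathway`.
#' @export
read_pathway_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- guess_delim(path)
  as_pathway_map(readr::read_delim(path, delim = delim,
                                   show_col_types = FALSE, progress = FALSE, comment = "#"))
}

#' @rdname read_pathway_map
#' @param x A data frame with columns `target`, `kegg_pathway`.
#' @export
as_pathway_map <- function(x) {
  x <- as_tibble(x)
  miss <- setdiff(c("target", "kegg_pathway"), names(x))
  if (length(miss)) {
    abort(paste0("pathway map is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(!nzchar(x$kegg_pathway)) || anyNA(x$kegg_pathway)) {
    abort("empty pathway names in pathway map.")
  }
  dplyr::distinct(x, .data$target, .data$kegg_pathway)
}
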