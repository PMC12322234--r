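#' Abundance tables
#'
#' A metabolite abundance table is a tibble with one row per sample: a
#' `sample_id` character column followed by one numeric column per
#' metabolite. The measurement scale travels with the table as the
#' `"scale"` attribute, either `"raw"` (concentrations, pmol-scale) or
#' `"log10"`. All pipeline stages check the scale they require, so raw
#' concentrations cannot be ratioed or batch-corrected by accident.
#'
#' @param x A data frame with a `sample_id` column and numeric metabolite
#'   columns.
#' @param scale `"raw"` or `"log10"`.
#' @return `as_abundance()` returns the validated tibble with class
#'   `metabo_abundance`; `abundance_scale()` returns the scale string.
#' @examples
#' abn <- as_abundance(
#'   tibble::tibble(sample_id = c("s1", "s2"), glucose = c(10, 20)),
#'   scale = "raw"
#' )
#' abundance_scale(abn)
#' @export
as_abundance <- function(x, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("abundance table must have a `sample_id` column.")
  }
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  mets <- setdiff(names(x), "sample_id")
  if (length(mets) == 0L) abort("abundance table has no metabolite columns.")
  dup_s <- unique(x$sample_id[duplicated(x$sample_id)])
  if (length(dup_s)) {
    abort(paste0("duplicate sample ids: ", paste(dup_s, collapse = ", ")))
  }
  dup_m <- unique(mets[duplicated(mets)])
  if (length(dup_m)) {
    abort(paste0("duplicate metabolite ids: ", paste(dup_m, collapse = ", ")))
  }
  for (m in mets) {
    if (!is.numeric(x[[m]])) {
      abort(sprintf("metabolite column `%s` is not numeric.", m))
    }
  }
  if (scale == "raw") {
    vals <- as.matrix(x[mets])
    bad <- is.finite(vals) & vals <= 0
    # non-positive raw values are tolerated here as "missing"; consumers
    # decide between erroring and LOD imputation (see log10_transform)
    vals[bad] <- NA_real_
    x[mets] <- as.data.frame(vals)
  }
  attr(x, "scale") <- scale
  class(x) <- unique(c("metabo_abundance", class(x)))
  x
}

#' @rdname as_abundance
#' @export
abundance_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) abort("not an abundance table: missing `scale` attribute.")
  sc
}

metabolite_ids <- function(x) setdiff(names(x), "sample_id")

# samples x metabolites numeric matrix with sample ids as rownames
abn_matrix <- function(x) {
  m <- as.matrix(x[metabolite_ids(x)])
  rownames(m) <- x$sample_id
  m
}

abn_from_matrix <- function(m, scale) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
  as_abundance(out, scale = scale)
}

guess_delim <- function(path) {
  lines <- readLines(path, n = 10L)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) abort(sprintf("`%s` is empty.", path))
  if (lengths(regmatches(lines[1L], gregexpr("\t", lines[1L]))) > 0) "\t" else ","
}

#' Read a delimited abundance table
#'
#' Reads a samples-by-metabolites concentration table from a TSV or CSV file
#' (the delimiter is auto-detected from the header line). The file must have
#' a header row and a first id column; by default rows are samples and
#' columns are metabolites, and `orientation = "metabolites_in_rows"` reads
#' the transposed layout.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"metabolites_in_rows"`.
#' @return An abundance tibble with `scale = "raw"` (see [as_abundance()]).
#'   Empty cells become `NA` (missing).
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_in_rows",
                                                 "metabolites_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE, comment = "#",
                           name_repair = "minimal")
  if (ncol(raw) < 2L) abort(sprintf("`%s` has no value columns.", path))
  ids <- as.character(raw[[1L]])
  cols <- names(raw)[-1L]
  dup_cols <- unique(cols[duplicated(cols)])
  if (length(dup_cols)) {
    abort(paste0("duplicate column ids in ", path, ": ",
                 paste(dup_cols, collapse = ", ")))
  }
  dup_rows <- unique(ids[duplicated(ids)])
  if (length(dup_rows)) {
    abort(paste0("duplicate row ids in ", path, ": ",
                 paste(dup_rows, collapse = ", ")))
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(cols),
                 dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      abort(sprintf("non-numeric value %s at row `%s`, column `%s` of %s",
                    dQuote(cell[bad[1L]]), ids[bad[1L]], cols[j], path))
    }
    vals[, j] <- num
  }
  if (orientation == "metabolites_in_rows") vals <- t(vals)
  abn_from_matrix(vals, scale = "raw")
}

#' Write an abundance table as TSV
#'
#' @param x An abundance tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Log10-transform raw concentrations
#'
#' Replaces raw concentrations by their base-10 logarithm, the scale on
#' which batch correction and ratio features operate. Non-positive or
#' missing cells are below the limit of detection: with `impute_lod = TRUE`
#' each such cell is replaced by half the smallest positive value of that
#' metabolite before taking logs (the usual half-minimum LOD rule);
#' otherwise they are an error.
#'
#' @param x An abundance tibble with `scale = "raw"`.
#' @param impute_lod Impute non-positive/missing cells by the half-minimum
#'   rule instead of erroring. Default `FALSE`.
#' @return An abundance tibble with `scale = "log10"`.
#' @examples
#' abn <- as_abundance(
#'   tibble::tibble(sample_id = c("a", "b"), pyruvate = c(10, 1000)),
#'   scale = "raw"
#' )
#' log10_transform(abn)
#' @export
log10_transform <- function(x, impute_lod = FALSE) {
  if (abundance_scale(x) != "raw") abort("`x` must be on the raw scale.")
  m <- abn_matrix(x)
  bad <- is.na(m) | m <= 0
  if (any(bad) && !impute_lod) {
    idx <- which(bad, arr.ind = TRUE)
    cells <- paste0(rownames(m)[idx[, 1]], "/", colnames(m)[idx[, 2]])
    abort(paste0("non-positive or missing values (set `impute_lod = TRUE` ",
                 "to apply the half-minimum rule): ",
                 paste(head(cells, 10L), collapse = ", "),
                 if (length(cells) > 10L) " ..."))
  }
  if (any(bad)) {
    for (j in which(colSums(bad) > 0)) {
      pos <- m[!bad[, j], j]
      if (!length(pos)) {
        abort(sprintf("metabolite `%s` has no positive value to impute from.",
                      colnames(m)[j]))
      }
      m[bad[, j], j] <- min(pos) / 2
    }
  }
  abn_from_matrix(log10(m), scale = "log10")
}

#' Percent relative standard deviation of a metabolite over a sample group
#'
#' The quality metric `100 * sd / mean` (sample sd, n-1 denominator) of raw
#' concentrations over a group of samples, e.g. repeated injections of a
#' pooled QC sample or technical replicates of one cell line.
#'
#' @param x An abundance tibble with `scale = "raw"`.
#' @param samples Character vector of at least two sample ids.
#' @param metabolite A single metabolite id.
#' @return Percent RSD as a single number.
#' @examples
#' abn <- as_abundance(
#'   tibble::tibble(sample_id = c("a", "b", "c"), pyruvate = c(1, 2, 3)),
#'   scale = "raw"
#' )
#' compute_rsd(abn, c("a", "b", "c"), "pyruvate")  # 50
#' @export
compute_rsd <- function(x, samples, metabolite) {
  if (abundance_scale(x) != "raw") abort("`x` must be on the raw scale.")
  if (length(samples) < 2L) abort("need at least two samples for an RSD.")
  if (length(metabolite) != 1L || !metabolite %in% metabolite_ids(x)) {
    abort("`metabolite` must name one metabolite present in `x`.")
  }
  missing_s <- setdiff(samples, x$sample_id)
  if (length(missing_s)) {
    abort(paste0("samples not in table: ", paste(missing_s, collapse = ", ")))
  }
  v <- x[[metabolite]][match(samples, x$sample_id)]
  if (anyNA(v)) abort("missing values in the requested group.")
  mu <- mean(v)
  if (mu <= 0) abort("group mean must be positive for a %RSD.")
  100 * sd(v) / mu
}

#' Per-metabolite correlation between two log10 abundance datasets
#'
#' Cross-dataset comparison: both tables are restricted to their shared
#' sample ids (cell lines) and shared metabolite ids, and a Pearson
#' correlation is computed per shared metabolite across the shared samples.
#' A metabolite with zero variance in either table gets an undefined
#' correlation (`NA`, `defined = FALSE`) rather than 0, so counts of
#' negative/positive correlations are not diluted.
#'
#' @param a,b Abundance tibbles with `scale = "log10"`.
#' @return A tibble with columns `metabolite`, `r`, `defined`, plus
#'   attributes `n_shared_samples` and `n_shared_metabolites`.
#' @export
correlate_shared_metabolites <- function(a, b) {
  if (abundance_scale(a) != "log10" || abundance_scale(b) != "log10") {
    abort("both tables must be on the log10 scale.")
  }
  shared_s <- intersect(a$sample_id, b$sample_id)
  shared_m <- intersect(metabolite_ids(a), metabolite_ids(b))
  if (length(shared_s) < 3L) {
    abort(sprintf("only %d shared samples; need at least 3.", length(shared_s)))
  }
  if (length(shared_m) < 1L) abort("no shared metabolites.")
  ma <- abn_matrix(a)[shared_s, shared_m, drop = FALSE]
  mb <- abn_matrix(b)[shared_s, shared_m, drop = FALSE]
  r <- vapply(seq_along(shared_m), function(j) {
    va <- ma[, j]; vb <- mb[, j]
    if (sd(va) == 0 || sd(vb) == 0) NA_real_ else cor(va, vb)
  }, numeric(1))
  out <- tibble(metabolite = shared_m, r = r, defined = !is.na(r))
  attr(out, "n_shared_samples") <- length(shared_s)
  attr(out, "n_shared_metabolites") <- length(shared_m)
  out
}
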