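#' Construct a per-donor probe expression bundle
#'
#' A bundle holds one donor's probe-by-sample matrix of normalized
#' log-intensity values together with its two annotation maps: sample id to
#' named brain region, and probe id to gene symbol. Probes without a gene
#' mapping are kept in the matrix but absent from `probe_gene`; they are
#' dropped later at the probe-collapsing stage.
#'
#' @param donor_id Donor identifier string.
#' @param expression Numeric matrix, probes in rows (unique rownames),
#'   samples in columns.
#' @param sample_region Named character vector mapping sample id to region
#'   name; every expression column must have an entry.
#' @param probe_gene Named character vector mapping probe id to gene symbol.
#' @return An object of class `probe_bundle`.
#' @export
probe_bundle <- function(donor_id, expression, sample_region, probe_gene = character()) {
  stopifnot(is.character(donor_id), length(donor_id) == 1L, nzchar(donor_id))
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("`expression` must be a numeric matrix", call. = FALSE)
  probes <- rownames(expression)
  if (is.null(probes) || anyNA(probes))
    stop("`expression` must have probe-id rownames", call. = FALSE)
  if (anyDuplicated(probes)) {
    dup <- probes[duplicated(probes)][1L]
    stop(sprintf("duplicate probe id in expression matrix: '%s'", dup), call. = FALSE)
  }
  samples <- colnames(expression)
  if (is.null(samples))
    stop("`expression` must have sample-id colnames", call. = FALSE)
  sample_region <- vapply(sample_region, trimws, character(1))
  missing_ann <- setdiff(samples, names(sample_region))
  if (length(missing_ann))
    stop(sprintf("%d sample(s) lack region annotation (e.g. '%s')",
                 length(missing_ann), missing_ann[1L]), call. = FALSE)
  if (any(!nzchar(sample_region[samples])))
    stop("region names must be non-empty strings", call. = FALSE)
  if (nrow(expression) && any(rowSums(!is.na(expression)) == 0L))
    stop("expression matrix contains entirely-missing probe rows", call. = FALSE)
  if (length(probe_gene)) {
    probe_gene <- probe_gene[names(probe_gene) %in% probes]
  }
  structure(
    list(donor_id = donor_id,
         expression = expression,
         sample_region = sample_region[samples],
         probe_gene = probe_gene),
    class = "probe_bundle"
  )
}

#' @export
print.probe_bundle <- function(x, ...) {
  cat(sprintf("<probe_bundle> donor %s: %d probes x %d samples, %d regions, %d mapped probes\n",
              x$donor_id, nrow(x$expression), ncol(x$expression),
              length(unique(x$sample_region)), length(x$probe_gene)))
  invisible(x)
}

#' Read one donor's atlas bundle from its three-file layout
#'
#' Mirrors the standard atlas download layout: a probe-by-sample expression
#' matrix with probe ids in the first column (header row optional), a sample
#' annotation table mapping sample ids to named brain regions, and a probe
#' annotation table mapping probe ids to gene symbols. Samples lacking a
#' region annotation are dropped with a logged count; probes absent from the
#' probe annotation are retained in the matrix but excluded from the
#' probe-to-gene map.
#'
#' @param expression_path,sample_annot_path,probe_annot_path File paths
#'   (CSV/TSV, optionally gzipped).
#' @param donor_id Donor identifier attached to the bundle.
#' @param columns Named list giving the annotation column names; defaults
#'   are `sample_id`, `region`, `probe_id`, `gene_symbol`.
#' @param delimiter Optional delimiter override for all three files.
#' @return A [probe_bundle()].
#' @export
read_bundle <- function(expression_path, sample_annot_path, probe_annot_path,
                        donor_id,
                        columns = list(sample_id = "sample_id", region = "region",
                                       probe_id = "probe_id", gene_symbol = "gene_symbol"),
                        delimiter = NULL) {
  expr_df <- read_delim_auto(expression_path, delimiter, header = NA_header(expression_path, delimiter))
  if (!nrow(expr_df) || ncol(expr_df) < 2L)
    stop(sprintf("expression file '%s' has no usable data", expression_path), call. = FALSE)
  probes <- as.character(expr_df[[1L]])
  if (anyDuplicated(probes)) {
    dup <- probes[duplicated(probes)][1L]
    stop(sprintf("duplicate probe id '%s' in '%s'", dup, expression_path), call. = FALSE)
  }
  mat <- as.matrix(expr_df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- probes
  if (is.null(colnames(mat)) || all(grepl("^V[0-9]+$", colnames(mat))))
    colnames(mat) <- paste0("S", seq_len(ncol(mat)))

  sa <- read_delim_auto(sample_annot_path, delimiter, header = TRUE)
  for (cn in c(columns$sample_id, columns$region))
    if (!cn %in% names(sa))
      stop(sprintf("sample annotation '%s' lacks column '%s'", sample_annot_path, cn),
           call. = FALSE)
  region <- trimws(as.character(sa[[columns$region]]))
  keep_ann <- nzchar(region) & !is.na(region)
  sample_region <- stats::setNames(region[keep_ann],
                                   as.character(sa[[columns$sample_id]])[keep_ann])

  annotated <- colnames(mat) %in% names(sample_region)
  n_dropped <- sum(!annotated)
  if (n_dropped)
    message(sprintf("read_bundle: dropped %d sample(s) without region annotation", n_dropped))
  mat <- mat[, annotated, drop = FALSE]
  if (ncol(mat) == 0L)
    stop(sprintf("no usable samples in '%s' after annotation matching", expression_path),
         call. = FALSE)

  pa <- read_delim_auto(probe_annot_path, delimiter, header = TRUE)
  for (cn in c(columns$probe_id, columns$gene_symbol))
    if (!cn %in% names(pa))
      stop(sprintf("probe annotation '%s' lacks column '%s'", probe_annot_path, cn),
           call. = FALSE)
  sym <- trimws(as.character(pa[[columns$gene_symbol]]))
  ok <- nzchar(sym) & !is.na(sym)
  probe_gene <- stats::setNames(sym[ok], as.character(pa[[columns$probe_id]])[ok])
  probe_gene <- probe_gene[names(probe_gene) %in% rownames(mat)]

  bundle <- probe_bundle(donor_id, mat, sample_region, probe_gene)
  attr(bundle, "n_samples_dropped") <- n_dropped
  bundle
}

# Expression files may or may not carry a header row: peek at the first
# line and treat it as data when all non-id fields parse as numbers.
NA_header <- function(path, delimiter = NULL) {
  sep <- delimiter %||% .guess_delim(path)
  first <- readLines(path, n = 1L)
  if (!length(first)) return(FALSE)
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  if (length(fields) < 2L) return(FALSE)
  vals <- suppressWarnings(as.numeric(fields[-1L]))
  !all(!is.na(vals))
}

#' Write a bundle back to the three-file layout
#'
#' Inverse of [read_bundle()]; used for round-trip checks and by the
#' synthetic-data writer.
#'
#' @param bundle A [probe_bundle()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"tsv"`.
#' @return Named character vector of the three paths written.
#' @export
write_bundle <- function(bundle, dir, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_%s.%s", bundle$donor_id,
                                  c("expression", "samples", "probes"), format))
  expr_df <- data.frame(probe_id = rownames(bundle$expression),
                        bundle$expression, check.names = FALSE)
  utils::write.table(expr_df, paths[1L], sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(bundle$sample_region),
               region = unname(bundle$sample_region)),
    paths[2L], sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = names(bundle$probe_gene),
               gene_symbol = unname(bundle$probe_gene)),
    paths[3L], sep = sep, quote = FALSE, row.names = FALSE)
  stats::setNames(paths, c("expression", "samples", "probes"))
}

#' Read a region merge map
#'
#' A two-column delimited file (composite name, member region name) grouped
#' into a named list. Composite regions pool the samples of their members so
#' that, for example, several finely parcellated labels can be analyzed as
#' one subgenual cingulate profile. Duplicate (composite, member) pairs are
#' deduplicated; a member assigned to two different composites is an error.
#'
#' @param path File path, or `NULL`/missing file for an empty map.
#' @param delimiter Optional delimiter override.
#' @param header Logical; default `FALSE` (bare two-column file).
#' @return Named list: composite name -> character vector of member regions.
#' @export
read_region_merge_map <- function(path, delimiter = NULL, header = FALSE) {
  if (is.null(path)) return(structure(list(), class = "region_merge_map"))
  df <- read_delim_auto(path, delimiter, header = header)
  if (!nrow(df)) return(structure(list(), class = "region_merge_map"))
  if (ncol(df) < 2L)
    stop(sprintf("merge map '%s' must have two columns (composite, member)", path),
         call. = FALSE)
  composite <- trimws(as.character(df[[1L]]))
  member <- trimws(as.character(df[[2L]]))
  pairs <- unique(data.frame(composite, member, stringsAsFactors = FALSE))
  if (anyDuplicated(pairs$member)) {
    bad <- pairs$member[duplicated(pairs$member)][1L]
    stop(sprintf("region '%s' is assigned to more than one composite", bad),
         call. = FALSE)
  }
  structure(split(pairs$member, pairs$composite), class = "region_merge_map")
}

# Warn (not fail) on merge-map members absent from a bundle's vocabulary.
.check_merge_map <- function(merge_map, regions) {
  unknown <- setdiff(unlist(merge_map, use.names = FALSE), regions)
  if (length(unknown))
    warning(sprintf("merge map names %d region(s) absent from the data (e.g. '%s')",
                    length(unknown), unknown[1L]), call. = FALSE)
  invisible(unknown)
}
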