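#' Construct a named gene set
#'
#' @param name Set name.
#' @param symbols Character vector of gene symbols; duplicates are removed
#'   preserving first-occurrence order.
#' @param provenance Free-text provenance note.
#' @param p Optional named numeric vector of per-gene p-values in (0, 1];
#'   names must be a subset of `symbols`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, symbols, provenance = "", p = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  symbols <- as.character(symbols)
  symbols <- symbols[nzchar(symbols) & !is.na(symbols)]
  symbols <- symbols[!duplicated(symbols)]
  if (!is.null(p) && length(p)) {
    if (is.null(names(p)) || !all(names(p) %in% symbols))
      stop("names of `p` must be a subset of `symbols`", call. = FALSE)
    if (any(is.na(p) | p <= 0 | p > 1))
      stop("per-gene p-values must lie in (0, 1]", call. = FALSE)
  }
  structure(list(name = name, symbols = symbols, provenance = provenance, p = p),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols%s\n", x$name, length(x$symbols),
              if (is.null(x$p)) "" else " (with per-gene p-values)"))
  invisible(x)
}

.as_symbols <- function(x) {
  if (inherits(x, "gene_set")) x$symbols else as.character(x)
}

#' Normalize a gene symbol
#'
#' Maps antisense and intronic transcript symbols to their protein-coding
#' host gene by removing a single trailing `-AS` or `-IT` suffix (with an
#' optional integer), then upper-cases human symbols. Mouse symbols are
#' returned with their case intact, as mouse nomenclature is
#' case-sensitive. The suffix rule is applied once, not recursively.
#'
#' @param symbol Character vector of symbols.
#' @param species `"human"` (default) or `"mouse"`.
#' @return Character vector of normalized symbols.
#' @export
normalize_symbol <- function(symbol, species = c("human", "mouse")) {
  species <- match.arg(species)
  out <- sub("-(AS|IT)[0-9]*$", "", as.character(symbol))
  if (species == "human") out <- toupper(out)
  out
}

#' Bonferroni-filter a gene set by per-gene p-values
#'
#' Retains symbols whose Bonferroni-corrected p-value (raw p times the
#' assumed number of tested genes, capped at 1) stays at or below `alpha`.
#' The default `m = 20000` reflects the conventional genome-wide estimate
#' used to reduce exome-derived candidate lists to high-confidence genes.
#'
#' @param set A [gene_set()] with `p` present for all symbols.
#' @param m Assumed number of tested genes.
#' @param alpha Significance level (inclusive boundary).
#' @return A new `gene_set` named `<name>_bonferroni`.
#' @export
bonferroni_filter <- function(set, m = 20000, alpha = 0.05) {
  stopifnot(inherits(set, "gene_set"))
  if (is.null(set$p) || !all(set$symbols %in% names(set$p)))
    stop("bonferroni_filter needs a per-gene p-value for every symbol", call. = FALSE)
  p_corr <- pmin(set$p[set$symbols] * m, 1)
  keep <- set$symbols[p_corr <= alpha]
  gene_set(paste0(set$name, "_bonferroni"), keep,
           provenance = sprintf("%s; Bonferroni m=%g alpha=%g", set$provenance, m, alpha),
           p = if (length(keep)) set$p[keep] else NULL)
}

#' Match a gene set against a reference matrix vocabulary
#'
#' Partitions the set's symbols by membership in the reference gene
#' vocabulary, after [normalize_symbol()] is applied to both sides, and
#' logs the match fraction. The matched symbols are reported in the
#' reference's own vocabulary so they can be used directly for scoring.
#'
#' @param set A [gene_set()] or character vector.
#' @param reference A `gene_region_matrix` at stage `donor_averaged`.
#' @param species Passed to [normalize_symbol()].
#' @return A list of class `matched_gene_set` with elements `source`,
#'   `matched` (reference gene names) and `unmatched` (normalized set
#'   symbols absent from the reference).
#' @export
match_to_reference <- function(set, reference, species = "human") {
  .assert_stage(reference, "donor_averaged")
  symbols <- .as_symbols(set)
  norm_set <- unique(normalize_symbol(symbols, species))
  ref_genes <- grm_genes(reference)
  norm_ref <- normalize_symbol(ref_genes, species)
  lookup <- ref_genes[!duplicated(norm_ref)]
  names(lookup) <- norm_ref[!duplicated(norm_ref)]
  hit <- norm_set %in% names(lookup)
  if (!any(hit))
    stop("no set symbols match the reference; enrichment is undefined", call. = FALSE)
  matched <- unname(lookup[norm_set[hit]])
  message(sprintf("match_to_reference: %d/%d symbols matched (%.1f%%)",
                  sum(hit), length(norm_set), 100 * mean(hit)))
  structure(list(source = if (inherits(set, "gene_set")) set else gene_set("set", symbols),
                 matched = matched,
                 unmatched = norm_set[!hit]),
            class = "matched_gene_set")
}

#' @export
print.matched_gene_set <- function(x, ...) {
  cat(sprintf("<matched_gene_set> %s: %d matched, %d unmatched\n",
              x$source$name, length(x$matched), length(x$unmatched)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' symbol...`. Duplicate symbols within a line are deduplicated.
#'
#' @param path GMT file path.
#' @return List of [gene_set()] objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    out[[i]] <- gene_set(fields[1L], fields[-(1:2)], provenance = fields[2L])
  }
  out
}

#' @rdname read_gmt
#' @param sets List of `gene_set` objects to write.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$provenance)) s$provenance else "na", s$symbols),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene list from a text file
#'
#' Accepts either one symbol per line, or a two-column table
#' (symbol, p-value) when per-gene p-values are available; the layout is
#' detected from the first data row. A header row is detected when the
#' second column of the first row does not parse as a number.
#'
#' @param path File path.
#' @param name Set name; defaults to the file name without extension.
#' @param delimiter Optional delimiter for the two-column layout.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL, delimiter = NULL) {
  name <- name %||% tools::file_path_sans_ext(basename(.strip_gz(path)))
  sep <- delimiter %||% .guess_delim(path)
  first <- readLines(path, n = 1L)
  if (!length(first)) return(gene_set(name, character()))
  two_col <- length(strsplit(first, sep, fixed = TRUE)[[1L]]) >= 2L
  if (!two_col) {
    syms <- trimws(readLines(path, warn = FALSE))
    return(gene_set(name, syms[nzchar(syms)]))
  }
  hdr <- is.na(suppressWarnings(as.numeric(strsplit(first, sep, fixed = TRUE)[[1L]][2L])))
  df <- read_delim_auto(path, sep, header = hdr)
  syms <- trimws(as.character(df[[1L]]))
  p <- as.numeric(df[[2L]])
  keep <- nzchar(syms) & !is.na(syms)
  gene_set(name, syms[keep], p = stats::setNames(p[keep], syms[keep]))
}
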