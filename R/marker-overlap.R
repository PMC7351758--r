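#' Hypergeometric overlap test between two gene sets
#'
#' Both sets are intersected with the universe before testing; the reported
#' p-value is the upper tail `P(X >= k)` of the hypergeometric(N, K, n)
#' distribution at the observed overlap k (enrichment direction only).
#'
#' @param list_a Query [gene_set()] or character vector (size n after
#'   intersection with the universe).
#' @param list_b Reference set, e.g. a cell-type marker set (size K).
#' @param universe Character vector of testable symbols (size N).
#' @param list_name,marker_name Optional display names; default to the set
#'   names when `gene_set` objects are given.
#' @return List of class `overlap_result` with fields `list_name`,
#'   `marker_name`, `k_overlap`, `n_list`, `K_marker`, `N_universe`,
#'   `p_raw` and `overlapping_symbols`.
#' @export
hypergeometric_overlap <- function(list_a, list_b, universe,
                                   list_name = NULL, marker_name = NULL) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("`universe` must be non-empty", call. = FALSE)
  a <- intersect(unique(.as_symbols(list_a)), universe)
  b <- intersect(unique(.as_symbols(list_b)), universe)
  shared <- intersect(a, b)
  k <- length(shared)
  N <- length(universe)
  K <- length(b)
  n <- length(a)
  p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(
    list(list_name = list_name %||% if (inherits(list_a, "gene_set")) list_a$name else "list",
         marker_name = marker_name %||% if (inherits(list_b, "gene_set")) list_b$name else "marker",
         k_overlap = k, n_list = n, K_marker = K, N_universe = N,
         p_raw = min(max(p, 1e-300), 1),
         overlapping_symbols = sort(shared)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %s vs %s: k=%d (n=%d, K=%d, N=%d), p=%.3g\n",
              x$list_name, x$marker_name, x$k_overlap, x$n_list, x$K_marker,
              x$N_universe, x$p_raw))
  invisible(x)
}

#' Scan a gene list against a collection of marker sets
#'
#' One hypergeometric overlap test per marker set, with Benjamini-Hochberg
#' adjustment across the marker sets in the scan (correction for the number
#' of cell types tested). Cross-species comparisons should run the query
#' list through [map_homologs()] first.
#'
#' @param list_ Query [gene_set()] or character vector.
#' @param markers List of marker `gene_set` objects (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of testable symbols.
#' @return Data frame with one row per marker set: `list_name`, `marker`,
#'   `k`, `n`, `K`, `N`, `p`, `p_fdr`, `genes` (semicolon-joined overlap).
#' @export
marker_scan <- function(list_, markers, universe) {
  if (!length(markers)) stop("need at least one marker set", call. = FALSE)
  rows <- lapply(markers, function(m) {
    o <- hypergeometric_overlap(list_, m, universe)
    data.frame(list_name = o$list_name, marker = o$marker_name,
               k = o$k_overlap, n = o$n_list, K = o$K_marker, N = o$N_universe,
               p = o$p_raw, genes = paste(o$overlapping_symbols, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_fdr(res$p)
  res <- res[, c("list_name", "marker", "k", "n", "K", "N", "p", "p_fdr", "genes")]
  rownames(res) <- NULL
  res
}

#' Read a two-column mouse/human homolog table
#'
#' @param path Delimited file with columns `mouse` and `human` (or any two
#'   columns in that order when headerless).
#' @param delimiter Optional delimiter override.
#' @return Data frame with character columns `mouse` and `human`.
#' @export
read_homolog_table <- function(path, delimiter = NULL) {
  sep <- delimiter %||% .guess_delim(path)
  first <- readLines(path, n = 1L)
  hdr <- length(first) && grepl("mouse|human", tolower(first))
  df <- read_delim_auto(path, sep, header = hdr)
  if (ncol(df) < 2L)
    stop(sprintf("homolog table '%s' must have two columns (mouse, human)", path),
         call. = FALSE)
  out <- data.frame(mouse = trimws(as.character(df[[1L]])),
                    human = trimws(as.character(df[[2L]])),
                    stringsAsFactors = FALSE)
  out[nzchar(out$mouse) & nzchar(out$human), ]
}

#' Map gene symbols across species through a homolog table
#'
#' @param symbols Character vector of symbols in the `from` species.
#' @param homologs Data frame from [read_homolog_table()].
#' @param from,to `"mouse"` or `"human"`.
#' @return Character vector of mapped symbols (symbols without a homolog
#'   are dropped; duplicates removed).
#' @export
map_homologs <- function(symbols, homologs, from = c("human", "mouse"),
                         to = c("mouse", "human")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(unique(as.character(symbols)))
  hit <- match(as.character(symbols), homologs[[from]])
  unique(homologs[[to]][hit[!is.na(hit)]])
}
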