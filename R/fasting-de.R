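#' Construct a gene-by-cell expression matrix with condition and batch labels
#'
#' Holds a single-cell expression matrix (any log-like non-negative scale;
#' the downstream tests are rank-based and monotone-invariant) together
#' with per-cell condition (`fed` / `deprived`), batch and optional sex
#' labels.
#'
#' @param values Numeric non-negative matrix, genes in rows, cells in
#'   columns (both dimnames required).
#' @param condition Named character vector cell -> `"fed"`/`"deprived"`.
#' @param batch Named character vector cell -> batch id.
#' @param sex Optional named character vector cell -> sex label.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(values, condition, batch, sex = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene rownames and cell colnames", call. = FALSE)
  cells <- colnames(values)
  for (nm in c("condition", "batch")) {
    v <- get(nm)
    if (is.null(names(v)) || !all(cells %in% names(v)))
      stop(sprintf("every cell needs a `%s` label", nm), call. = FALSE)
  }
  condition <- as.character(condition[cells])
  names(condition) <- cells
  if (any(is.na(condition) | !nzchar(condition)))
    stop("condition labels must be non-empty", call. = FALSE)
  batch <- as.character(batch[cells])
  names(batch) <- cells
  if (!is.null(sex)) {
    sex <- as.character(sex[cells])
    names(sex) <- cells
  }
  structure(list(values = values, condition = condition, batch = batch, sex = sex),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells, %d batch(es), %d deprived / %d fed\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch)),
              sum(x$condition == "deprived"), sum(x$condition == "fed")))
  invisible(x)
}

#' Read a cell matrix from a dense TSV plus a cell-metadata table
#'
#' @param matrix_path Dense gene-by-cell table, genes as rows, gene ids in
#'   the first column.
#' @param metadata_path Table with columns `cell`, `condition`, `batch` and
#'   optionally `sex`.
#' @param delimiter Optional delimiter override.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(matrix_path, metadata_path, delimiter = NULL) {
  df <- read_delim_auto(matrix_path, delimiter, header = TRUE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1L]])
  md <- read_delim_auto(metadata_path, delimiter, header = TRUE)
  for (cn in c("cell", "condition", "batch"))
    if (!cn %in% names(md))
      stop(sprintf("cell metadata lacks column '%s'", cn), call. = FALSE)
  cells <- as.character(md$cell)
  cell_matrix(mat[, cells, drop = FALSE],
              condition = stats::setNames(as.character(md$condition), cells),
              batch = stats::setNames(as.character(md$batch), cells),
              sex = if ("sex" %in% names(md)) stats::setNames(as.character(md$sex), cells))
}

#' Filter genes for homology, expression and variance
#'
#' Retains genes that (1) have at least one entry in the homolog table,
#' (2) have nonzero expression in at least one cell, and (3) have nonzero
#' variance across cells. The count removed by each criterion (applied in
#' sequence) is logged.
#'
#' @param matrix_ A [cell_matrix()].
#' @param homologs Optional homolog table from [read_homolog_table()];
#'   `NULL` skips the homology criterion.
#' @param species Which homolog column the matrix's gene symbols live in.
#' @return A filtered [cell_matrix()].
#' @export
filter_genes <- function(matrix_, homologs = NULL, species = c("mouse", "human")) {
  stopifnot(inherits(matrix_, "cell_matrix"))
  species <- match.arg(species)
  x <- matrix_$values
  keep <- rep(TRUE, nrow(x))
  if (!is.null(homologs)) {
    has_hom <- rownames(x) %in% homologs[[species]]
    message(sprintf("filter_genes: %d gene(s) removed without a homolog", sum(!has_hom)))
    keep <- keep & has_hom
  }
  expressed <- rowSums(x[, , drop = FALSE] > 0) > 0L
  message(sprintf("filter_genes: %d gene(s) removed with no expression in any cell",
                  sum(keep & !expressed)))
  keep <- keep & expressed
  v <- apply(x, 1L, stats::var)
  varying <- !is.na(v) & v > 0
  message(sprintf("filter_genes: %d gene(s) removed without any variance in expression",
                  sum(keep & !varying)))
  keep <- keep & varying
  if (!any(keep)) stop("no genes survive filtering", call. = FALSE)
  cell_matrix(x[keep, , drop = FALSE], matrix_$condition, matrix_$batch, matrix_$sex)
}

#' Subset cells by batch (and optionally sex), validating the design
#'
#' Each retained batch must contain cells of both conditions, otherwise the
#' stratified test is undefined and an error names the offending batch.
#'
#' @param matrix_ A [cell_matrix()].
#' @param batches Character/numeric vector of batch ids to keep.
#' @param sex Optional sex label to keep (requires a `sex` map).
#' @param condition_labels Optional named map translating the stored
#'   condition labels to `fed`/`deprived` (e.g.
#'   `c(ad_lib = "fed", fasted = "deprived")`), applied before validation.
#' @return A subsetted [cell_matrix()].
#' @export
select_cells <- function(matrix_, batches, sex = NULL, condition_labels = NULL) {
  stopifnot(inherits(matrix_, "cell_matrix"))
  batches <- as.character(batches)
  if (!length(batches)) stop("`batches` must name at least one batch", call. = FALSE)
  missing_b <- setdiff(batches, unique(matrix_$batch))
  if (length(missing_b))
    stop(sprintf("batch '%s' not present in the data", missing_b[1L]), call. = FALSE)
  keep <- matrix_$batch %in% batches
  if (!is.null(sex)) {
    if (is.null(matrix_$sex)) stop("no sex labels available", call. = FALSE)
    keep <- keep & matrix_$sex %in% sex
  }
  cells <- colnames(matrix_$values)[keep]
  cond <- matrix_$condition[cells]
  if (!is.null(condition_labels)) {
    cond <- unname(condition_labels[cond])
    names(cond) <- cells
  }
  for (b in batches) {
    cb <- cond[matrix_$batch[cells] == b]
    if (!all(c("fed", "deprived") %in% cb))
      stop(sprintf("batch '%s' lacks cells of both conditions", b), call. = FALSE)
  }
  cell_matrix(matrix_$values[, cells, drop = FALSE], cond,
              matrix_$batch[cells],
              if (!is.null(matrix_$sex)) matrix_$sex[cells])
}

#' Per-batch one-sided Mann-Whitney differential expression
#'
#' For each gene and batch, the Mann-Whitney U statistic compares deprived
#' against fed cells; both one-sided p-values (`p_up`: deprived > fed,
#' `p_down`: deprived < fed) are the two tails of the same U, with tie
#' correction and continuity correction.
#'
#' @param matrix_ A filtered [cell_matrix()].
#' @param exact_threshold Passed to [mwu_pvalue()].
#' @return Long data frame: `gene`, `batch`, `u`, `p_up`, `p_down`.
#' @export
per_batch_de <- function(matrix_, exact_threshold = 20L) {
  stopifnot(inherits(matrix_, "cell_matrix"))
  if (!all(matrix_$condition %in% c("fed", "deprived")))
    stop("condition labels must be 'fed'/'deprived' at testing time; see `select_cells(condition_labels=)`",
         call. = FALSE)
  batches <- sort(unique(matrix_$batch))
  out <- lapply(batches, function(b) {
    cells <- names(matrix_$batch)[matrix_$batch == b]
    dep <- matrix_$condition[cells] == "deprived"
    sub <- matrix_$values[, cells, drop = FALSE]
    nd <- sum(dep)
    nf <- sum(!dep)
    stats_ <- t(apply(sub, 1L, function(v) {
      r <- rank(v, ties.method = "average")
      u <- sum(r[dep]) - nd * (nd + 1) / 2
      tc <- rle(sort(v))$lengths
      c(u,
        mwu_pvalue(u, nd, nf, tc, alternative = "greater", exact_threshold = exact_threshold),
        mwu_pvalue(u, nd, nf, tc, alternative = "less", exact_threshold = exact_threshold))
    }))
    data.frame(gene = rownames(sub), batch = b,
               u = stats_[, 1L], p_up = stats_[, 2L], p_down = stats_[, 3L],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Combine p-values with Fisher's method
#'
#' `X^2 = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2k` degrees of freedom. Values are clamped at 1e-300 before the log.
#'
#' @param p_values Numeric vector of p-values in (0, 1], length >= 1.
#' @return The combined meta p-value.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("need at least one p-value to combine", call. = FALSE)
  if (any(is.na(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  x2 <- -2 * sum(log(pmax(p_values, 1e-300)))
  stats::pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Batch-stratified differential expression with Fisher meta p-values
#'
#' Runs [per_batch_de()] on each supplied cell matrix, treating every
#' (dataset, batch) combination as an independent stratum, then combines
#' the per-stratum one-sided p-values per gene with Fisher's method --
#' separately for up- and for down-regulation after deprivation -- and
#' applies Benjamini-Hochberg correction per direction over all tested
#' genes. Genes missing from a stratum contribute only their available
#' strata (df = 2 x available k).
#'
#' @param matrices A [cell_matrix()] or list of them (one per dataset).
#' @param alpha FDR threshold used to call a direction.
#' @param exact_threshold Passed to [mwu_pvalue()].
#' @return List of class `fasting_de_result` with elements `table` (gene,
#'   n_strata, meta_p_up, meta_p_down, fdr_up, fdr_down, direction),
#'   `per_stratum` (long per-batch p-values) and `alpha`.
#' @export
fasting_de <- function(matrices, alpha = 0.05, exact_threshold = 20L) {
  if (inherits(matrices, "cell_matrix")) matrices <- list(matrices)
  if (is.null(names(matrices)))
    names(matrices) <- sprintf("dataset%d", seq_along(matrices))
  per <- lapply(names(matrices), function(nm) {
    d <- per_batch_de(matrices[[nm]], exact_threshold = exact_threshold)
    d$stratum <- paste(nm, d$batch, sep = ".")
    d
  })
  long <- do.call(rbind, per)

  genes <- sort(unique(long$gene))
  up_split <- split(long$p_up, long$gene)
  down_split <- split(long$p_down, long$gene)
  meta_up <- vapply(up_split, fisher_combine, numeric(1))[genes]
  meta_down <- vapply(down_split, fisher_combine, numeric(1))[genes]
  n_strata <- vapply(up_split, length, integer(1))[genes]

  fdr_up <- bh_fdr(meta_up)
  fdr_down <- bh_fdr(meta_down)
  direction <- rep("none", length(genes))
  sig <- fdr_up < alpha | fdr_down < alpha
  direction[sig & meta_up < meta_down] <- "up"
  direction[sig & meta_down < meta_up] <- "down"

  table_ <- data.frame(gene = genes, n_strata = n_strata,
                       meta_p_up = unname(meta_up), meta_p_down = unname(meta_down),
                       fdr_up = unname(fdr_up), fdr_down = unname(fdr_down),
                       direction = direction, stringsAsFactors = FALSE,
                       row.names = NULL)
  structure(list(table = table_, per_stratum = long, alpha = alpha),
            class = "fasting_de_result")
}

#' @export
print.fasting_de_result <- function(x, ...) {
  n_de <- sum(x$table$direction != "none")
  cat(sprintf("<fasting_de_result> %d genes over %d strata; %d DE at FDR < %g (%.1f%%)\n",
              nrow(x$table), length(unique(x$per_stratum$stratum)), n_de,
              x$alpha, 100 * n_de / nrow(x$table)))
  invisible(x)
}

#' Genome-wide and per-list differential-expression summary
#'
#' A gene is called differentially expressed when either direction's meta
#' FDR falls below `alpha`. Reports the genome-wide DE count and fraction,
#' each list's DE fraction among its genes with data, and a hypergeometric
#' enrichment p-value per list testing whether the list is
#' disproportionately enriched for DE genes against the tested-gene
#' universe.
#'
#' @param result A [fasting_de()] result.
#' @param gene_lists List of [gene_set()] objects (symbols in the tested
#'   matrix's namespace; map through [map_homologs()] beforehand if
#'   needed).
#' @param alpha FDR threshold; defaults to the one stored in `result`.
#' @return List with `genome` (n_tested, n_de, fraction) and `per_list`
#'   data frame (list, n_with_data, n_de, fraction, p_enrichment).
#' @export
de_summary <- function(result, gene_lists = list(), alpha = NULL) {
  stopifnot(inherits(result, "fasting_de_result"))
  alpha <- alpha %||% result$alpha
  tab <- result$table
  de <- tab$fdr_up < alpha | tab$fdr_down < alpha
  genome <- list(n_tested = nrow(tab), n_de = sum(de), fraction = mean(de))
  per_list <- NULL
  if (length(gene_lists)) {
    rows <- lapply(gene_lists, function(s) {
      syms <- intersect(.as_symbols(s), tab$gene)
      n_de_list <- sum(de[tab$gene %in% syms])
      p_enr <- if (length(syms)) {
        hypergeometric_overlap(syms, tab$gene[de], universe = tab$gene)$p_raw
      } else NA_real_
      data.frame(list = if (inherits(s, "gene_set")) s$name else "list",
                 n_with_data = length(syms), n_de = n_de_list,
                 fraction = if (length(syms)) n_de_list / length(syms) else NA_real_,
                 p_enrichment = p_enr, stringsAsFactors = FALSE)
    })
    per_list <- do.call(rbind, rows)
    rownames(per_list) <- NULL
  }
  list(genome = genome, per_list = per_list, alpha = alpha)
}
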