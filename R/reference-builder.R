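#' Construct a gene-by-region matrix with stage semantics
#'
#' The same container carries the reference matrix through its four
#' processing stages: raw `expression` (over samples or regions), `ranked`
#' (within-region midranks), `zscored` (per-gene z across regions) and
#' `donor_averaged` (z averaged over donors, with a per-cell donor count).
#'
#' @param values Numeric matrix with gene rownames and sample/region colnames.
#' @param stage One of `"expression"`, `"ranked"`, `"zscored"`,
#'   `"donor_averaged"`.
#' @param n_donors Optional integer matrix of contributing-donor counts
#'   (stage `donor_averaged` only), same dimensions as `values`.
#' @param flags Named list of character vectors of flagged genes
#'   (`zero_variance`, `too_few_regions`).
#' @return An object of class `gene_region_matrix`.
#' @export
gene_region_matrix <- function(values,
                               stage = c("expression", "ranked", "zscored", "donor_averaged"),
                               n_donors = NULL,
                               flags = list(zero_variance = character(),
                                            too_few_regions = character())) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and region/sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("gene rownames must be unique", call. = FALSE)
  if (!is.null(n_donors)) {
    stopifnot(identical(dim(n_donors), dim(values)))
  }
  structure(list(values = values, stage = stage, n_donors = n_donors, flags = flags),
            class = "gene_region_matrix")
}

#' @export
print.gene_region_matrix <- function(x, ...) {
  cat(sprintf("<gene_region_matrix> stage '%s': %d genes x %d columns\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname gene_region_matrix
#' @param x Object to query.
#' @export
grm_genes <- function(x) rownames(x$values)

#' @rdname gene_region_matrix
#' @export
grm_regions <- function(x) colnames(x$values)

.assert_stage <- function(x, stage) {
  if (!inherits(x, "gene_region_matrix") || !identical(x$stage, stage))
    stop(sprintf("expected a gene_region_matrix at stage '%s'", stage), call. = FALSE)
  invisible(x)
}

#' Collapse probe rows to gene rows by mean averaging
#'
#' Each gene's expression in a sample is the arithmetic mean of its mapped
#' probes' values in that sample, ignoring missing values. Probes with no
#' gene mapping are dropped.
#'
#' @param bundle A [probe_bundle()].
#' @return A `gene_region_matrix` at stage `expression` with sample columns.
#' @export
collapse_probes_to_genes <- function(bundle) {
  stopifnot(inherits(bundle, "probe_bundle"))
  if (!length(bundle$probe_gene))
    stop("no probes map to a gene symbol; cannot collapse", call. = FALSE)
  x <- bundle$expression[names(bundle$probe_gene), , drop = FALSE]
  g <- factor(unname(bundle$probe_gene), levels = sort(unique(unname(bundle$probe_gene))))
  obs <- !is.na(x)
  xs <- x
  xs[!obs] <- 0
  sums <- rowsum(xs, g)
  cnts <- rowsum(obs + 0, g)
  vals <- sums / cnts
  vals[cnts == 0] <- NA_real_
  gene_region_matrix(vals, stage = "expression")
}

#' Aggregate sample columns into one column per named region
#'
#' Samples mapping to the same-named region are mean averaged into a single
#' expression profile (region labels are identical strings after trimming,
#' so hemisphere-duplicated names pool automatically). Composite regions
#' from a merge map pool all member-region samples before averaging by
#' default, so members with more samples weigh more; set
#' `composite_method = "mean_of_means"` to average member means instead.
#'
#' @param matrix_ A `gene_region_matrix` at stage `expression` over samples.
#' @param sample_region Named character vector, sample id -> region name.
#' @param merge_map A [read_region_merge_map()] result (or plain named list).
#' @param keep_members Retain member regions as standalone columns next to
#'   their composite (default `TRUE`).
#' @param composite_method `"pooled"` (default) or `"mean_of_means"`.
#' @return A `gene_region_matrix` at stage `expression` with region columns.
#' @export
aggregate_samples_by_region <- function(matrix_, sample_region, merge_map = list(),
                                        keep_members = TRUE,
                                        composite_method = c("pooled", "mean_of_means")) {
  .assert_stage(matrix_, "expression")
  composite_method <- match.arg(composite_method)
  x <- matrix_$values
  samples <- colnames(x)
  sample_region <- vapply(sample_region, trimws, character(1))
  if (!all(samples %in% names(sample_region)))
    stop("every sample column needs a region annotation", call. = FALSE)
  reg <- sample_region[samples]
  regions <- sort(unique(unname(reg)))
  .check_merge_map(merge_map, regions)

  region_mean <- function(cols) {
    v <- rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }
  out <- vapply(regions, function(r) region_mean(which(reg == r)),
                numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), regions))

  comp_names <- names(merge_map)
  comp_cols <- NULL
  if (length(comp_names)) {
    comp_cols <- vapply(comp_names, function(cn) {
      members <- intersect(merge_map[[cn]], regions)
      if (!length(members)) return(rep(NA_real_, nrow(x)))
      if (composite_method == "pooled") {
        region_mean(which(reg %in% members))
      } else {
        v <- rowMeans(out[, members, drop = FALSE], na.rm = TRUE)
        v[is.nan(v)] <- NA_real_
        v
      }
    }, numeric(nrow(x)))
    comp_cols <- matrix(comp_cols, nrow = nrow(x),
                        dimnames = list(rownames(x), comp_names))
  }
  if (!keep_members)
    out <- out[, setdiff(regions, unlist(merge_map, use.names = FALSE)), drop = FALSE]
  if (!is.null(comp_cols)) out <- cbind(out, comp_cols)
  rownames(out) <- rownames(x)
  out <- out[, colSums(!is.na(out)) > 0L, drop = FALSE]
  gene_region_matrix(out, stage = "expression")
}

#' Convert each region column to within-region midranks
#'
#' Lowest expression receives rank 1; ties receive the average of the tied
#' positions (the midrank convention of the Mann-Whitney U test used
#' downstream). Missing entries stay missing and reduce the column's n.
#'
#' @param matrix_ A `gene_region_matrix` at stage `expression` over regions.
#' @return A `gene_region_matrix` at stage `ranked`.
#' @export
rank_within_region <- function(matrix_) {
  .assert_stage(matrix_, "expression")
  x <- matrix_$values
  out <- x
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    if (sum(ok) < 2L)
      stop(sprintf("region '%s' has fewer than 2 non-missing values; cannot rank",
                   colnames(x)[j]), call. = FALSE)
    out[ok, j] <- rank(x[ok, j], ties.method = "average")
  }
  gene_region_matrix(out, stage = "ranked")
}

#' Z-score each gene's ranks across regions
#'
#' Each gene row is transformed to `(r - mean(r)) / sd(r)` over its
#' non-missing regions, with the sample (n-1) standard deviation. Rows with
#' zero variance become all-zero and are flagged `zero_variance` (kept
#' neutral rather than dropped, so the gene vocabulary stays stable for set
#' matching); genes observed in fewer than two regions become missing and
#' are flagged `too_few_regions`.
#'
#' @param matrix_ A `gene_region_matrix` at stage `ranked`.
#' @return A `gene_region_matrix` at stage `zscored`.
#' @export
zscore_across_regions <- function(matrix_) {
  .assert_stage(matrix_, "ranked")
  x <- matrix_$values
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  xc <- x - m
  ss <- rowSums(xc^2, na.rm = TRUE)
  sd_ <- sqrt(ss / pmax(n - 1, 1))
  out <- xc / sd_

  zero_var <- n >= 2L & sd_ == 0
  out[zero_var, ] <- ifelse(is.na(x[zero_var, , drop = FALSE]), NA_real_, 0)
  too_few <- n < 2L
  out[too_few, ] <- NA_real_
  gene_region_matrix(out, stage = "zscored",
                     flags = list(zero_variance = rownames(x)[zero_var],
                                  too_few_regions = rownames(x)[too_few]))
}

#' Average per-donor z-score matrices into a single reference matrix
#'
#' Gene and region vocabularies may differ across donors; each output cell
#' is the mean z over the donors in which it is present, and the per-cell
#' donor count is recorded. Genes or regions present in no donor are absent
#' from the output.
#'
#' @param matrices List of `gene_region_matrix` objects at stage `zscored`.
#' @return A `gene_region_matrix` at stage `donor_averaged`.
#' @export
average_donors <- function(matrices) {
  if (!length(matrices)) stop("need at least one donor matrix", call. = FALSE)
  lapply(matrices, .assert_stage, stage = "zscored")
  genes <- sort(unique(unlist(lapply(matrices, grm_genes))))
  regions <- sort(unique(unlist(lapply(matrices, grm_regions))))
  sums <- matrix(0, length(genes), length(regions), dimnames = list(genes, regions))
  cnts <- matrix(0L, length(genes), length(regions), dimnames = list(genes, regions))
  for (m in matrices) {
    v <- m$values
    obs <- !is.na(v)
    v[!obs] <- 0
    gi <- match(rownames(v), genes)
    ri <- match(colnames(v), regions)
    sums[gi, ri] <- sums[gi, ri] + v
    cnts[gi, ri] <- cnts[gi, ri] + obs
  }
  vals <- sums / cnts
  vals[cnts == 0L] <- NA_real_
  keep_g <- rowSums(cnts) > 0L
  keep_r <- colSums(cnts) > 0L
  gene_region_matrix(vals[keep_g, keep_r, drop = FALSE],
                     stage = "donor_averaged",
                     n_donors = cnts[keep_g, keep_r, drop = FALSE])
}

#' Build the reference matrix from per-donor bundles
#'
#' Runs the full per-donor chain -- probe collapsing, region aggregation
#' (with optional composite regions), within-region ranking, cross-region
#' z-scoring -- and averages the per-donor z matrices into the single
#' gene-by-region reference used by all enrichment tests.
#'
#' @param bundles List of [probe_bundle()] objects (one per donor).
#' @param merge_map Optional region merge map.
#' @param ... Passed to [aggregate_samples_by_region()].
#' @return A `gene_region_matrix` at stage `donor_averaged`.
#' @export
build_reference <- function(bundles, merge_map = list(), ...) {
  per_donor <- lapply(bundles, function(b) {
    g <- collapse_probes_to_genes(b)
    r <- aggregate_samples_by_region(g, b$sample_region, merge_map, ...)
    zscore_across_regions(rank_within_region(r))
  })
  average_donors(per_donor)
}

#' Serialize / deserialize a reference matrix as TSV
#'
#' The matrix is written with a `gene` first column and region-named
#' columns; for stage `donor_averaged` a sidecar `<path>.ndonors.tsv` holds
#' the per-cell donor counts.
#'
#' @param x A `gene_region_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(x, path) {
  stopifnot(inherits(x, "gene_region_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  .write_tsv(df, path)
  if (!is.null(x$n_donors)) {
    nd <- data.frame(gene = rownames(x$n_donors), x$n_donors, check.names = FALSE)
    .write_tsv(nd, paste0(path, ".ndonors.tsv"))
  }
  invisible(path)
}

#' @rdname write_reference
#' @param stage Stage to stamp on the read matrix (default `donor_averaged`).
#' @export
read_reference <- function(path, stage = "donor_averaged") {
  df <- read_delim_auto(path, delimiter = "\t", header = TRUE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1L]])
  nd <- NULL
  side <- paste0(path, ".ndonors.tsv")
  if (identical(stage, "donor_averaged") && file.exists(side)) {
    nd_df <- read_delim_auto(side, delimiter = "\t", header = TRUE)
    nd <- as.matrix(nd_df[, -1L, drop = FALSE])
    storage.mode(nd) <- "integer"
    rownames(nd) <- as.character(nd_df[[1L]])
  }
  gene_region_matrix(mat, stage = stage, n_donors = nd)
}
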