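#' Specification for a synthetic multi-donor atlas
#'
#' The generator emulates the structure the ingest and reference-building
#' stages consume: per donor, a probe-by-sample matrix of normalized
#' log-intensity-like values with region-structured samples, plus the two
#' annotation maps. A designated gene set is shifted upward only in the
#' planted region, providing ground truth for enrichment recovery; noise
#' is additive Gaussian on the log-like scale, matching what the pipeline
#' actually ingests (the real inputs are already normalized intensities).
#'
#' @param n_genes,n_regions,n_donors,n_samples_per_region Dimensions.
#' @param probes_per_gene Number of probe rows per gene (>= 1).
#' @param planted_set_size Number of genes carrying the planted shift.
#' @param planted_region Region receiving the shift (default: the first
#'   generated region).
#' @param effect Planted shift in units of the within-region noise SD.
#' @param noise_sd Within-region sample noise SD (> 0).
#' @param missing_region_rate Probability that a (donor, region) block is
#'   omitted, emulating incomplete donor coverage.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `atlas_sim_spec`.
#' @export
atlas_sim_spec <- function(n_genes = 5000, n_regions = 40, n_donors = 3,
                           n_samples_per_region = 3, probes_per_gene = 2,
                           planted_set_size = 200, planted_region = NULL,
                           effect = 0, noise_sd = 1, missing_region_rate = 0,
                           seed = 1) {
  regions <- sprintf("R%03d", seq_len(n_regions))
  planted_region <- planted_region %||% regions[1L]
  stopifnot(n_genes >= 2, n_regions >= 2, n_donors >= 1,
            n_samples_per_region >= 1, probes_per_gene >= 1,
            planted_set_size >= 0, planted_set_size < n_genes,
            noise_sd > 0, missing_region_rate >= 0, missing_region_rate < 1)
  if (!planted_region %in% regions)
    stop("`planted_region` must be among the generated regions", call. = FALSE)
  structure(list(n_genes = n_genes, n_regions = n_regions, n_donors = n_donors,
                 n_samples_per_region = n_samples_per_region,
                 probes_per_gene = probes_per_gene,
                 planted_set_size = planted_set_size,
                 planted_region = planted_region, effect = effect,
                 noise_sd = noise_sd, missing_region_rate = missing_region_rate,
                 seed = as.integer(seed)),
            class = "atlas_sim_spec")
}

#' Simulate a multi-donor probe-level atlas with a planted enriched region
#'
#' Baseline gene means are drawn once and shared across donors; each sample
#' value is gene mean + region intercept + Gaussian noise, with the planted
#' gene set receiving an additional `effect * noise_sd` only in the planted
#' region. Each gene expands to `probes_per_gene` probe rows with small
#' fixed probe offsets. A fraction `missing_region_rate` of (donor, region)
#' blocks is omitted.
#'
#' @param spec An [atlas_sim_spec()].
#' @return List with `bundles` (list of [probe_bundle()], one per donor)
#'   and `truth` (planted genes, planted region, effect).
#' @export
simulate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_sim_spec"))
  seeds <- .substream_seeds(spec$seed, spec$n_donors + 1L)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  regions <- sprintf("R%03d", seq_len(spec$n_regions))
  probe_ids <- paste0(rep(genes, each = spec$probes_per_gene),
                      "_p", seq_len(spec$probes_per_gene))
  probe_gene <- stats::setNames(rep(genes, each = spec$probes_per_gene), probe_ids)

  set.seed(seeds[1L])
  mu <- stats::rnorm(spec$n_genes, mean = 8, sd = 1)
  region_int <- stats::rnorm(spec$n_regions, mean = 0, sd = 0.25)
  probe_off <- stats::rnorm(length(probe_ids), mean = 0, sd = 0.1)
  planted <- if (spec$planted_set_size) sample(genes, spec$planted_set_size) else character()
  shift <- (genes %in% planted) * spec$effect * spec$noise_sd

  bundles <- vector("list", spec$n_donors)
  for (d in seq_len(spec$n_donors)) {
    set.seed(seeds[d + 1L])
    present <- stats::runif(spec$n_regions) >= spec$missing_region_rate
    if (sum(present) < 2L) present[seq_len(2L)] <- TRUE
    keep_regions <- which(present)
    nspr <- spec$n_samples_per_region
    n_samp <- length(keep_regions) * nspr
    gmat <- matrix(NA_real_, spec$n_genes, n_samp)
    sample_ids <- character(n_samp)
    sample_region <- character(n_samp)
    col <- 0L
    for (ri in keep_regions) {
      base <- mu + region_int[ri] + if (regions[ri] == spec$planted_region) shift else 0
      for (s in seq_len(nspr)) {
        col <- col + 1L
        gmat[, col] <- base + stats::rnorm(spec$n_genes, 0, spec$noise_sd)
        sample_ids[col] <- sprintf("D%d_%s_s%d", d, regions[ri], s)
        sample_region[col] <- regions[ri]
      }
    }
    pmat <- gmat[rep(seq_len(spec$n_genes), each = spec$probes_per_gene), , drop = FALSE] +
      probe_off
    dimnames(pmat) <- list(probe_ids, sample_ids)
    bundles[[d]] <- probe_bundle(sprintf("D%d", d), pmat,
                                 stats::setNames(sample_region, sample_ids),
                                 probe_gene)
  }
  list(bundles = bundles,
       truth = list(planted_genes = sort(planted),
                    planted_region = spec$planted_region,
                    effect = spec$effect, seed = spec$seed))
}

#' Specification for a synthetic batched two-condition single-cell matrix
#'
#' Zero-inflated continuous values on a log-like scale (the downstream
#' tests are rank-based, so the exact marginal family is immaterial);
#' batch-specific intercepts; planted directional shifts in the deprived
#' condition.
#'
#' @param n_genes,n_batches,cells_per_arm_per_batch Dimensions.
#' @param planted_up,planted_down Numbers of genes shifted up / down in the
#'   deprived condition.
#' @param log_effect Planted shift on the log scale.
#' @param dropout_rate Zero-inflation probability in `[0, 1)`.
#' @param dispersion Cell-level noise SD (> 0).
#' @param seed Integer seed.
#' @return An object of class `sc_sim_spec`.
#' @export
sc_sim_spec <- function(n_genes = 5000, n_batches = 3,
                        cells_per_arm_per_batch = 150,
                        planted_up = 50, planted_down = 50,
                        log_effect = 1.0, dropout_rate = 0.3,
                        dispersion = 1.0, seed = 1) {
  stopifnot(n_genes >= 2, n_batches >= 1, cells_per_arm_per_batch >= 2,
            planted_up >= 0, planted_down >= 0,
            planted_up + planted_down < n_genes,
            dropout_rate >= 0, dropout_rate < 1, dispersion > 0)
  structure(list(n_genes = n_genes, n_batches = n_batches,
                 cells_per_arm_per_batch = cells_per_arm_per_batch,
                 planted_up = planted_up, planted_down = planted_down,
                 log_effect = log_effect, dropout_rate = dropout_rate,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "sc_sim_spec")
}

#' Simulate a batched two-condition single-cell matrix with planted effects
#'
#' @param spec An [sc_sim_spec()].
#' @return List with `matrix` (a [cell_matrix()]) and `truth` (data frame
#'   of planted genes and their directions).
#' @export
simulate_sc <- function(spec) {
  stopifnot(inherits(spec, "sc_sim_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  mu <- stats::rlnorm(spec$n_genes, meanlog = 0.8, sdlog = 0.4)
  planted <- sample(genes, spec$planted_up + spec$planted_down)
  up <- planted[seq_len(spec$planted_up)]
  down <- setdiff(planted, up)
  delta <- numeric(spec$n_genes)
  delta[genes %in% up] <- spec$log_effect
  delta[genes %in% down] <- -spec$log_effect
  batch_int <- stats::rnorm(spec$n_batches, 0, 0.3)

  n_arm <- spec$cells_per_arm_per_batch
  n_cells <- 2L * n_arm * spec$n_batches
  vals <- matrix(0, spec$n_genes, n_cells)
  cond <- character(n_cells)
  batch <- character(n_cells)
  ids <- character(n_cells)
  col <- 0L
  for (b in seq_len(spec$n_batches)) {
    for (cc in c("fed", "deprived")) {
      mean_vec <- mu + batch_int[b] + if (cc == "deprived") delta else 0
      for (i in seq_len(n_arm)) {
        col <- col + 1L
        v <- mean_vec + stats::rnorm(spec$n_genes, 0, spec$dispersion)
        v <- pmax(v, 0)
        if (spec$dropout_rate > 0)
          v[stats::runif(spec$n_genes) < spec$dropout_rate] <- 0
        vals[, col] <- v
        cond[col] <- cc
        batch[col] <- sprintf("b%d", b)
        ids[col] <- sprintf("b%d_%s_c%d", b, cc, i)
      }
    }
  }
  dimnames(vals) <- list(genes, ids)
  truth <- data.frame(gene = c(up, down),
                      direction = c(rep("up", length(up)), rep("down", length(down))),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene), ]
  rownames(truth) <- NULL
  list(matrix = cell_matrix(vals, stats::setNames(cond, ids), stats::setNames(batch, ids)),
       truth = truth)
}

#' Simulate gene lists with an exactly planted pairwise overlap
#'
#' Lists are drawn from a shared symbol universe; the first two lists share
#' exactly `planted_overlap` symbols (their remaining symbols are disjoint),
#' and any further lists are drawn freely from the universe.
#'
#' @param universe_size Size of the symbol universe.
#' @param list_sizes Integer vector of list sizes (>= 2 lists when an
#'   overlap is planted).
#' @param planted_overlap Exact overlap between the first two lists.
#' @param seed Integer seed.
#' @return List with `universe`, `sets` (list of [gene_set()]) and `truth`
#'   (shared symbols and overlap count).
#' @export
simulate_gene_lists <- function(universe_size, list_sizes, planted_overlap = 0,
                                seed = 1) {
  stopifnot(universe_size >= 1, length(list_sizes) >= 1, all(list_sizes >= 1),
            all(list_sizes <= universe_size), planted_overlap >= 0)
  if (length(list_sizes) >= 2L) {
    if (planted_overlap > min(list_sizes[1:2]))
      stop("`planted_overlap` cannot exceed the smaller of the first two lists",
           call. = FALSE)
    if (sum(list_sizes[1:2]) - planted_overlap > universe_size)
      stop("universe too small for the requested overlap structure", call. = FALSE)
  } else if (planted_overlap > 0) {
    stop("need at least two lists to plant an overlap", call. = FALSE)
  }
  set.seed(as.integer(seed))
  universe <- sprintf("U%05d", seq_len(universe_size))
  sets <- vector("list", length(list_sizes))
  if (length(list_sizes) >= 2L) {
    shared <- sample(universe, planted_overlap)
    pool <- setdiff(universe, shared)
    extra1 <- sample(pool, list_sizes[1L] - planted_overlap)
    extra2 <- sample(setdiff(pool, extra1), list_sizes[2L] - planted_overlap)
    sets[[1L]] <- gene_set("list1", c(shared, extra1), provenance = "synthetic")
    sets[[2L]] <- gene_set("list2", c(shared, extra2), provenance = "synthetic")
    rest <- seq_along(list_sizes)[-(1:2)]
  } else {
    shared <- character()
    rest <- seq_along(list_sizes)
  }
  for (i in rest)
    sets[[i]] <- gene_set(sprintf("list%d", i), sample(universe, list_sizes[i]),
                          provenance = "synthetic")
  list(universe = universe, sets = sets,
       truth = list(shared = sort(shared), k = length(shared)))
}
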