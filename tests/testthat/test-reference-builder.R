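make_bundle <- function(expr, sample_region, probe_gene, donor = "D1") {
  probe_bundle(donor, expr, sample_region, probe_gene)
}

test_that("probe collapsing takes the per-sample mean over mapped probes", {
  expr <- matrix(c(2, 4, 7,   # G: two probes {2, 4} in s1
                   1, 5, 9),
                 nrow = 3, byrow = FALSE,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  expr["p1", ] <- c(2, 1); expr["p2", ] <- c(4, 5); expr["p3", ] <- c(7, 9)
  b <- make_bundle(expr, c(s1 = "r1", s2 = "r2"),
                   c(p1 = "G", p2 = "G", p3 = "H"))
  g <- collapse_probes_to_genes(b)
  expect_equal(g$stage, "expression")
  expect_equal(g$values["G", "s1"], 3.0)       # mean of {2, 4}
  expect_equal(g$values["H", ], expr["p3", ])  # single probe passes through

  # missing values excluded from the mean: {1, NA, 5} -> 3
  expr2 <- matrix(c(1, NA, 5, 2, 2, 2), nrow = 3,
                  dimnames = list(c("q1", "q2", "q3"), c("s1", "s2")))
  b2 <- make_bundle(expr2, c(s1 = "r1", s2 = "r2"),
                    c(q1 = "G", q2 = "G", q3 = "G"))
  g2 <- collapse_probes_to_genes(b2)
  expect_equal(g2$values["G", "s1"], mean(c(1, 5)))

  # no mapped probes at all is an error
  b3 <- make_bundle(expr, c(s1 = "r1", s2 = "r2"), character())
  expect_error(collapse_probes_to_genes(b3), "no probes map")
})

test_that("region aggregation pools same-named samples and composites", {
  vals <- matrix(c(1, 3, 2, 4, 6, 8), nrow = 1,
                 dimnames = list("G", paste0("s", 1:6)))
  g <- gene_region_matrix(vals, stage = "expression")
  sr <- c(s1 = "R", s2 = "R", s3 = "R1", s4 = "R2", s5 = "R2", s6 = "Q")

  agg <- aggregate_samples_by_region(g, sr)
  expect_equal(agg$values["G", "R"], 2.0)      # mean of {1, 3}

  # composite pools member samples before averaging: mean(2, 4, 6) = 4
  mm <- list(C = c("R1", "R2"))
  agg2 <- aggregate_samples_by_region(g, sr, mm)
  expect_equal(agg2$values["G", "C"], 4.0)
  expect_true(all(c("R1", "R2") %in% colnames(agg2$values)))  # members retained

  # mean-of-means alternative: mean(2, mean(4, 6)) = 3.5
  agg3 <- aggregate_samples_by_region(g, sr, mm, composite_method = "mean_of_means")
  expect_equal(agg3$values["G", "C"], 3.5)

  # hemisphere-duplicated names are identical strings, hence pooled
  sr_hemi <- c(s1 = "amygdala", s2 = "amygdala", s3 = "R1", s4 = "R2",
               s5 = "R2", s6 = "Q")
  agg4 <- aggregate_samples_by_region(g, sr_hemi)
  expect_equal(sum(colnames(agg4$values) == "amygdala"), 1L)
  expect_equal(agg4$values["G", "amygdala"], 2.0)
})

test_that("within-region ranking uses ascending midranks and errors on tiny columns", {
  vals <- matrix(c(0.1, 0.9, 0.5, NA,
                   0.1, 0.5, 0.5, 0.9), ncol = 2,
                 dimnames = list(paste0("g", 1:4), c("A", "B")))
  r <- rank_within_region(gene_region_matrix(vals, stage = "expression"))
  expect_equal(r$stage, "ranked")
  expect_equal(unname(r$values[1:3, "A"]), c(1, 3, 2))
  expect_true(is.na(r$values[4, "A"]))
  expect_equal(unname(r$values[, "B"]), c(1, 2.5, 2.5, 4))  # midranks for ties

  # tie-free columns are a permutation of 1..n (sort-based oracle)
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(50)
    m <- matrix(c(v, rnorm(50)), ncol = 2,
                dimnames = list(sprintf("g%02d", 1:50), c("A", "B")))
    rr <- rank_within_region(gene_region_matrix(m, stage = "expression"))
    expect_equal(unname(sort(rr$values[, "A"])), as.numeric(1:50))
    expect_equal(order(v), order(rr$values[, "A"]))
  }

  bad <- matrix(c(1, NA, NA, 2, 3, 4), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("tiny", "ok")))
  expect_error(rank_within_region(gene_region_matrix(bad, stage = "expression")),
               "tiny")
})

test_that("cross-region z-scoring centers, scales and flags degenerate rows", {
  vals <- matrix(c(1, 2, 3,
                   5, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  z <- zscore_across_regions(gene_region_matrix(vals, stage = "ranked"))
  expect_equal(z$stage, "zscored")
  expect_equal(unname(z$values["g1", ]), c(-1, 0, 1))  # sd with n-1 denominator
  expect_equal(unname(z$values["g2", ]), c(0, 0, 0))
  expect_equal(z$flags$zero_variance, "g2")

  # a gene observed in < 2 regions becomes missing and flagged
  vals2 <- matrix(c(1, NA, NA, 2, 3, 4), nrow = 2, byrow = TRUE,
                  dimnames = list(c("lone", "ok"), c("A", "B", "C")))
  z2 <- zscore_across_regions(gene_region_matrix(vals2, stage = "ranked"))
  expect_true(all(is.na(z2$values["lone", ])))
  expect_equal(z2$flags$too_few_regions, "lone")

  # random rows: mean 0 and sd 1 to 1e-9 (direct recomputation oracle)
  set.seed(7)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("R%02d", 1:10)))
  zz <- zscore_across_regions(gene_region_matrix(m, stage = "ranked"))
  expect_true(all(abs(rowMeans(zz$values)) < 1e-9))
  expect_true(all(abs(apply(zz$values, 1, sd) - 1) < 1e-9))
})

test_that("donor averaging handles partial coverage and the single-donor identity", {
  z1 <- gene_region_matrix(matrix(c(0.5, 1), 1, 2, dimnames = list("g", c("A", "B"))),
                           stage = "zscored")
  z2 <- gene_region_matrix(matrix(1.5, 1, 1, dimnames = list("g", "A")),
                           stage = "zscored")
  avg <- average_donors(list(z1, z2))
  expect_equal(avg$stage, "donor_averaged")
  expect_equal(avg$values["g", "A"], 1.0)       # mean of 0.5 and 1.5
  expect_equal(avg$n_donors["g", "A"], 2L)
  expect_equal(avg$values["g", "B"], 1.0)       # present in only one donor
  expect_equal(avg$n_donors["g", "B"], 1L)

  solo <- average_donors(list(z1))
  expect_equal(solo$values, z1$values)
  expect_true(all(solo$n_donors == 1L))

  expect_error(average_donors(list()), "at least one")
})

test_that("the full per-donor chain is deterministic and recovers a planted region", {
  spec <- atlas_sim_spec(n_genes = 500, n_regions = 10, n_donors = 3,
                         planted_set_size = 50, effect = 1, seed = 42)
  sim1 <- simulate_atlas(spec)
  sim2 <- simulate_atlas(spec)
  ref1 <- build_reference(sim1$bundles)
  ref2 <- build_reference(sim2$bundles)
  expect_identical(ref1$values, ref2$values)    # bit-identical

  # planted genes' donor-averaged z peaks in the planted region
  planted_z <- colMeans(ref1$values[sim1$truth$planted_genes, ])
  expect_equal(names(which.max(planted_z)), sim1$truth$planted_region)
  expect_true(all(planted_z[sim1$truth$planted_region] >
                  planted_z[setdiff(names(planted_z), sim1$truth$planted_region)]))
})

test_that("reference matrices round-trip through their TSV serialization", {
  spec <- atlas_sim_spec(n_genes = 60, n_regions = 5, n_donors = 2,
                         planted_set_size = 5, seed = 3)
  ref <- build_reference(simulate_atlas(spec)$bundles)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ref.tsv")
  write_reference(ref, path)
  ref2 <- read_reference(path)
  expect_equal(ref2$values, ref$values, tolerance = 1e-12)
  expect_equal(ref2$n_donors, ref$n_donors)
})
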