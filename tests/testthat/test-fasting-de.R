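toy_cells <- function(values, cond, batch = rep("b1", length(cond))) {
  ids <- sprintf("c%02d", seq_along(cond))
  colnames(values) <- ids
  cell_matrix(values, setNames(cond, ids), setNames(batch, ids))
}

test_that("gene filtering applies homology, expression and variance rules in order", {
  set.seed(2)
  vals <- matrix(abs(rnorm(10 * 6)), 10, 6,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  vals["g01", ] <- 0          # all-zero
  vals["g02", ] <- 0
  vals["g03", ] <- 2          # constant nonzero -> variance filter
  cm <- toy_cells(vals, rep(c("fed", "deprived"), 3))
  hom <- data.frame(mouse = sprintf("g%02d", 4:10), human = sprintf("G%02d", 4:10))

  # 3 genes lack homologs (g01..g03), of the rest none are all-zero/constant
  msgs <- capture_messages(out <- filter_genes(cm, hom))
  expect_equal(nrow(out$values), 7L)
  expect_match(msgs[1], "3 gene\\(s\\) removed without a homolog")

  # without the homolog table: 2 removed as all-zero, 1 as zero-variance
  msgs2 <- capture_messages(out2 <- filter_genes(cm))
  expect_equal(nrow(out2$values), 7L)
  expect_match(msgs2[1], "2 gene\\(s\\) removed with no expression")
  expect_match(msgs2[2], "1 gene\\(s\\) removed without any variance")

  all_bad <- toy_cells(matrix(0, 2, 4, dimnames = list(c("a", "b"), NULL)),
                       rep(c("fed", "deprived"), 2))
  expect_error(suppressMessages(filter_genes(all_bad)), "no genes survive")
})

test_that("cell selection validates that every batch keeps both conditions", {
  set.seed(3)
  vals <- matrix(abs(rnorm(5 * 9)), 5, 9,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
  cond <- c("fed", "deprived", "fed", "deprived", "fed", "fed", "fed", "fed", "deprived")
  batch <- c("1", "1", "2", "2", "3", "3", "3", "3", "3")
  cm <- toy_cells(vals, cond, batch)

  sel <- select_cells(cm, c("1", "2"))
  expect_equal(ncol(sel$values), 4L)
  expect_setequal(unique(sel$batch), c("1", "2"))

  # a batch with only fed cells is rejected by name
  cm_bad <- toy_cells(vals, c("fed", "fed", cond[-(1:2)]), batch)
  expect_error(select_cells(cm_bad, c("1", "2")), "batch '1'")
  expect_error(select_cells(cm, character()), "at least one")
  expect_error(select_cells(cm, "9"), "batch '9'")

  # foreign condition labels are translated before validation
  cm_lbl <- toy_cells(vals, c("ad_lib", "fasted")[1 + (cond == "deprived")], batch)
  sel2 <- select_cells(cm_lbl, c("1", "2"),
                       condition_labels = c(ad_lib = "fed", fasted = "deprived"))
  expect_setequal(unique(sel2$condition), c("fed", "deprived"))
})

test_that("per-batch tests give exact one-sided tails that swap under relabeling", {
  vals <- matrix(c(0, 1, 2, 3, 4, 5), 1, dimnames = list("g", NULL))
  cm <- toy_cells(vals, c("fed", "fed", "fed", "deprived", "deprived", "deprived"))
  de <- per_batch_de(cm)
  expect_equal(de$u, 9)                      # maximal U
  expect_equal(de$p_up, 1 / 20)              # 1 / C(6,3)
  expect_equal(de$p_down, 1.0)

  # swapping the condition labels swaps the two tails
  cm_sw <- toy_cells(vals, c("deprived", "deprived", "deprived", "fed", "fed", "fed"))
  de_sw <- per_batch_de(cm_sw)
  expect_equal(de_sw$p_up, de$p_down)
  expect_equal(de_sw$p_down, de$p_up)

  # literally identical arm values: both tails at the null center
  set.seed(9)
  arm <- rnorm(25)
  cm2 <- toy_cells(matrix(rep(arm, 2), 1, dimnames = list("g", NULL)),
                   rep(c("fed", "deprived"), each = 25))
  de2 <- per_batch_de(cm2)
  expect_gt(de2$p_up, 0.4)
  expect_gt(de2$p_down, 0.4)
})

test_that("approximate one-sided p-values track exact enumeration for small arms", {
  set.seed(13)
  for (i in 1:15) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    orc <- oracle_mwu(x, y)
    p_app <- mwu_pvalue(orc$u, n1, n2, alternative = "greater", exact_threshold = 0L)
    expect_lt(abs(p_app - orc$p_greater), 0.02)
  }
})

test_that("Fisher's method combines one-sided evidence with 2k degrees of freedom", {
  expect_equal(fisher_combine(c(0.1, 0.2, 0.3)),
               oracle_fisher(c(0.1, 0.2, 0.3)), tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.1, 0.2, 0.3)), 0.1152163, tolerance = 1e-6)
  expect_equal(fisher_combine(1.0), 1.0)
  # k = 1 identity: the meta p equals the single p
  for (a in c(0.01, 0.3, 0.77)) expect_equal(fisher_combine(a), a, tolerance = 1e-12)
  expect_error(fisher_combine(numeric()), "at least one")
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("meta analysis recovers planted directional effects across batches", {
  sc <- simulate_sc(sc_sim_spec(n_genes = 1200, n_batches = 3,
                                cells_per_arm_per_batch = 100,
                                planted_up = 25, planted_down = 25,
                                log_effect = 1.0, seed = 31))
  de <- fasting_de(sc$matrix)
  tab <- de$table
  called <- tab$direction[match(sc$truth$gene, tab$gene)]
  expect_gt(mean(called == sc$truth$direction), 0.85)
  # recovered planted-up genes never carry the opposite sign
  up_called <- tab$gene[tab$direction == "up"]
  expect_false(any(up_called %in% sc$truth$gene[sc$truth$direction == "down"]))
  null_genes <- setdiff(tab$gene, sc$truth$gene)
  expect_lt(mean(tab$direction[tab$gene %in% null_genes] != "none"), 0.07)
  # strata bookkeeping
  expect_true(all(tab$n_strata == 3L))
  expect_equal(nrow(de$per_stratum), 3L * nrow(tab))
})

test_that("genes missing from a stratum combine over their available strata", {
  set.seed(41)
  mk <- function(genes, n_per_arm, batch) {
    vals <- matrix(abs(rnorm(length(genes) * 2 * n_per_arm)), length(genes),
                   dimnames = list(genes, NULL))
    toy_cells(vals, rep(c("fed", "deprived"), each = n_per_arm),
              rep(batch, 2 * n_per_arm))
  }
  d1 <- mk(c("gA", "gB"), 10, "b1")
  d2 <- mk(c("gA"), 10, "b1")
  res <- fasting_de(list(one = d1, two = d2))
  expect_equal(res$table$n_strata[res$table$gene == "gA"], 2L)
  expect_equal(res$table$n_strata[res$table$gene == "gB"], 1L)
})

test_that("the DE summary reports genome-wide and per-list fractions", {
  sc <- simulate_sc(sc_sim_spec(n_genes = 800, n_batches = 3,
                                cells_per_arm_per_batch = 50,
                                planted_up = 20, planted_down = 20,
                                log_effect = 1.2, seed = 55))
  de <- fasting_de(sc$matrix)
  planted_list <- gene_set("planted", sc$truth$gene)
  set.seed(56)
  random_list <- gene_set("random", sample(de$table$gene, 100))
  s <- de_summary(de, list(planted_list, random_list))
  expect_equal(s$genome$n_tested, 800L)
  expect_equal(s$genome$fraction, s$genome$n_de / s$genome$n_tested)
  # the planted list is disproportionately enriched, a random one is not
  expect_lt(s$per_list$p_enrichment[1], 1e-6)
  expect_gt(s$per_list$p_enrichment[2], 0.01)
  expect_gt(s$per_list$fraction[1], s$genome$fraction)

  # nothing passes on a tiny null: fractions all zero
  null_sc <- simulate_sc(sc_sim_spec(n_genes = 300, n_batches = 2,
                                     cells_per_arm_per_batch = 20,
                                     planted_up = 0, planted_down = 0,
                                     log_effect = 0, seed = 57))
  null_de <- fasting_de(null_sc$matrix)
  s0 <- de_summary(null_de, list(gene_set("l", rownames(null_sc$matrix$values)[1:30])))
  expect_equal(s0$genome$n_de, 0L)
  expect_equal(s0$per_list$n_de, 0L)
})
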