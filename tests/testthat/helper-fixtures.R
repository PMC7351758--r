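# In-code fixtures: tiny atlas bundles and reference matrices built at test
# time; no files are stored in the repository.

# Four probes (three genes), three samples, three regions; written as CSV
# files in a fresh temporary directory.
write_toy_bundle_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                   drop_sample_annot = character(),
                                   duplicate_probe = FALSE) {
  expr <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    S1 = c(1.0, 2.0, 3.0, 4.0),
    S2 = c(1.5, 2.5, 3.5, 4.5),
    S3 = c(0.5, 1.5, 2.5, 3.5)
  )
  if (duplicate_probe) expr$probe_id[2L] <- "p1"
  samples <- data.frame(sample_id = c("S1", "S2", "S3"),
                        region = c("cortex", "thalamus", "pons"))
  samples <- samples[!samples$sample_id %in% drop_sample_annot, ]
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       gene_symbol = c("GENEA", "GENEA", "GENEB"))
  paths <- file.path(dir, c("expr.csv", "samples.csv", "probes.csv"))
  write.csv(expr, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(samples, paths[2], row.names = FALSE, quote = FALSE)
  write.csv(probes, paths[3], row.names = FALSE, quote = FALSE)
  list(expression = paths[1], samples = paths[2], probes = paths[3])
}

# A donor-averaged reference straight from a value matrix.
reference_from_matrix <- function(values) {
  gene_region_matrix(values, stage = "donor_averaged",
                     n_donors = matrix(1L, nrow(values), ncol(values),
                                       dimnames = dimnames(values)))
}

# Random named score vector over a synthetic gene vocabulary.
random_scores <- function(n, ties = FALSE) {
  v <- if (ties) sample(seq_len(max(2L, n %/% 3L)), n, replace = TRUE) / 2
       else stats::rnorm(n)
  stats::setNames(v, sprintf("g%04d", seq_len(n)))
}
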