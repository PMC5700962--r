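test_that("config validation names the offending field", {
  expect_error(synth_config(n_genes = 0), "n_genes")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(dosage_coupled_fraction = 1.5),
               "dosage_coupled_fraction")
  expect_error(synth_config(module_size_range = c(10, 5)), "module_size_range")
  expect_error(synth_config(n_genes = 30, n_modules = 2,
                            module_size_range = c(20, 20)), "n_genes")
})

test_that("zero-noise single-modulator module takes exactly two leaf values", {
  b <- generate_bundle(synth_config(n_genes = 30L, n_samples_resistant = 10L,
                                    n_samples_sensitive = 10L, n_modules = 1L,
                                    module_size_range = c(8L, 8L),
                                    n_modulators = 1L,
                                    n_passenger_long_genes = 0L,
                                    noise_sd = 0, effect_size = 2, seed = 3))
  members <- names(b$truth$module_membership)[b$truth$module_membership == "M1"]
  vals <- sort(unique(as.vector(b$expression[members, ])))
  expect_equal(vals, c(0, 2))
  status <- b$truth$modulator_status[1, ]
  for (g in members)
    expect_equal(unname(b$expression[g, ]), unname(2 * status))
})

test_that("identical seed gives an identical bundle; different seed differs", {
  b1 <- small_bundle(seed = 11)
  b2 <- small_bundle(seed = 11)
  b3 <- small_bundle(seed = 12)
  expect_identical(b1, b2)
  expect_false(identical(b1$expression, b3$expression))
})

test_that("planted passenger mutation frequencies match length x rate", {
  b <- generate_bundle(synth_config(seed = 5))
  m <- ncol(b$somatic)
  rate <- b$config$background_mutation_rate_per_kb
  for (g in b$truth$passenger_ids) {
    p <- min(0.9, b$lengths[[g]] / 1000 * rate)
    obs <- mean(b$somatic[g, ])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / m) + 1e-12)
  }
})

test_that("marginal modulator mutation counts match group rates across seeds", {
  ## aggregate Bernoulli counts over many independent bundles and compare to
  ## the generating rate with a 99% binomial interval
  n_seeds <- 100
  tot <- 0; n_tot <- 0
  for (s in seq_len(n_seeds)) {
    b <- generate_bundle(synth_config(n_genes = 20L, n_samples_resistant = 5L,
                                      n_samples_sensitive = 5L, n_modules = 1L,
                                      module_size_range = c(5L, 5L),
                                      n_modulators = 2L,
                                      n_passenger_long_genes = 2L, seed = s))
    st <- b$truth$modulator_status[, b$labels == "resistant", drop = FALSE]
    tot <- tot + sum(st); n_tot <- n_tot + length(st)
  }
  p <- 0.5  # resistant-group modulator rate
  ci <- qnorm(0.995) * sqrt(p * (1 - p) / n_tot)
  expect_lt(abs(tot / n_tot - p), ci)
})

test_that("ground truth is internally consistent", {
  b <- small_bundle(seed = 2)
  tr <- b$truth
  expect_length(intersect(tr$modulator_ids, tr$passenger_ids), 0)
  for (spec in tr$program_specs)
    expect_true(all(spec$modulators %in% tr$modulator_ids))
  expect_setequal(names(tr$dosage_class), tr$modulator_ids)
})

test_that("written bundle round-trips through the pipeline readers", {
  b <- small_bundle(seed = 4)
  dir <- withr::local_tempdir()
  manifest <- write_bundle(b, dir)
  expect_true(all(file.exists(manifest)))

  expect_equal(read_expression_tsv(manifest[["expression"]]), b$expression)
  expect_identical(read_labels_tsv(manifest[["labels"]]), b$labels)
  expect_equal(read_lengths_tsv(manifest[["lengths"]]), b$lengths)

  maf <- read_maf(manifest[["maf"]])
  expect_true(all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                    "Variant_Classification") %in% names(maf)))
  som <- maf_to_matrix(maf, rownames(b$somatic), colnames(b$somatic))
  expect_equal(som, b$somatic, ignore_attr = TRUE)
})

test_that("segment mapping reconstructs the generator's CN states", {
  b <- small_bundle(seed = 6)
  dir <- withr::local_tempdir()
  manifest <- write_bundle(b, dir)
  seg <- read_seg(manifest[["seg"]])
  bed <- read_bed(manifest[["bed"]])
  log2m <- map_segments_to_genes(seg, bed)
  expect_equal(log2m[rownames(b$cnv_log2), colnames(b$cnv_log2)],
               b$cnv_log2, tolerance = 1e-6)
  states <- call_cnv_states(log2m[rownames(b$cnv_log2), colnames(b$cnv_log2)])
  expect_equal(states, b$truth$cn_state, ignore_attr = TRUE)
})

test_that("read_bundle reassembles the full input set", {
  b <- small_bundle(seed = 8)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  rb <- read_bundle(dir)
  expect_equal(rb$expression, b$expression)
  expect_equal(rb$somatic, b$somatic, ignore_attr = TRUE)
  expect_equal(rb$cnv_log2, b$cnv_log2, tolerance = 1e-6)
  expect_setequal(rb$truth$modulator_ids, b$truth$modulator_ids)
})
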