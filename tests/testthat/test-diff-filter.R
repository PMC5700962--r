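test_that("emd_statistic handles identical and point-mass inputs", {
  expect_equal(emd_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  ## unit-width bins with the masses one bin apart: EMD = 1 bin unit
  expect_equal(emd_statistic(rep(0, 5), rep(1, 5),
                             breaks = seq(-0.5, 1.5, by = 1)), 1)
  expect_error(emd_statistic(numeric(0), 1), "non-empty")
})

test_that("emd_statistic matches the CDF-difference oracle and is a metric", {
  set.seed(42)
  breaks <- seq(-4, 4, length.out = 21)
  for (i in 1:20) {
    a <- rnorm(20); b <- rnorm(20, mean = runif(1, -1, 1))
    expect_equal(emd_statistic(a, b, breaks = breaks),
                 emd_cdf_oracle(a, b, breaks), tolerance = 1e-12)
    ## symmetry
    expect_equal(emd_statistic(a, b, breaks = breaks),
                 emd_statistic(b, a, breaks = breaks))
  }
  ## identity and triangle inequality on a shared binning
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15); c <- rnorm(15, 0.5)
    dab <- emd_statistic(a, b, breaks = breaks)
    dbc <- emd_statistic(b, c, breaks = breaks)
    dac <- emd_statistic(a, c, breaks = breaks)
    expect_gte(dab, 0)
    expect_lte(dac, dab + dbc + 1e-12)
    expect_equal(emd_statistic(a, a, breaks = breaks), 0)
  }
})

test_that("emd_qvalues: constant genes score zero, seeds reproduce", {
  set.seed(1)
  X <- rbind(flat = rep(1, 40),
             signal = c(rnorm(20, 0), rnorm(20, 3)),
             noise = rnorm(40))
  colnames(X) <- paste0("s", 1:40)
  labels <- setNames(rep(c("resistant", "sensitive"), each = 20), colnames(X))
  r1 <- emd_qvalues(X, labels, n_perm = 200, seed = 9)
  r2 <- emd_qvalues(X, labels, n_perm = 200, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$emd[r1$gene == "flat"], 0)
  expect_equal(r1$q_value[r1$gene == "flat"], 1)
  expect_lt(r1$q_value[r1$gene == "signal"], 0.1)
  ## BH q-values are monotone in p-value rank
  o <- order(r1$p_value)
  expect_true(all(diff(r1$q_value[o]) >= -1e-12))
  expect_error(emd_qvalues(X, labels, n_perm = 10), "n_perm")
  bad <- setNames(rep("resistant", 40), colnames(X))
  expect_error(emd_qvalues(X, bad, n_perm = 200), "classes")
})

test_that("segment-to-gene mapping follows the maximal-overlap rule", {
  genes <- data.frame(chrom = "chr1", start = c(100, 1000), end = c(200, 2000),
                      gene = c("gA", "gB"))
  seg <- data.frame(sample = "s1", chrom = "chr1",
                    start = c(50, 1001, 1701), end = c(300, 1700, 2600),
                    num_mark = 10, seg_mean = c(0.4, -0.5, 0.9))
  m <- map_segments_to_genes(seg, genes)
  expect_equal(m["gA", "s1"], 0.4)      # fully inside one segment
  expect_equal(m["gB", "s1"], -0.5)     # 70% overlap beats 30%
  ## gene with no overlapping segment defaults to normal
  genes2 <- rbind(genes, data.frame(chrom = "chr2", start = 0, end = 100,
                                    gene = "gC"))
  m2 <- map_segments_to_genes(seg, genes2)
  expect_equal(m2["gC", "s1"], 0)
})

test_that("CNV state calls use strict thresholds", {
  x <- matrix(c(0.31, -0.31, 0.3, -0.3, 0, 0.29), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  st <- call_cnv_states(x, 0.3)
  expect_identical(as.vector(st), c(1L, -1L, 0L, 0L, 0L, 0L))
  expect_identical(call_cnv_states(matrix(0, 2, 2)),
                   matrix(0L, 2, 2))
  expect_error(call_cnv_states(x, 0), "threshold")
})

test_that("CNV and mutation frequency filters are strict and per-group", {
  labels <- setNames(rep(c("resistant", "sensitive"), each = 10),
                     paste0("s", 1:20))
  st <- matrix(0L, 3, 20, dimnames = list(c("big", "flat", "edge"),
                                          names(labels)))
  st["big", 1:5] <- 1L            # 50% amp resistant vs 10% sensitive
  st["big", 11] <- 1L
  st["flat", c(1:3, 11:13)] <- 1L # 30% both groups
  st["edge", 1:2] <- 1L           # exactly 20% difference
  expect_identical(cnv_frequency_filter(st, labels, 0.2), "big")

  calls <- matrix(0L, 2, 20, dimnames = list(c("hit", "rare"), names(labels)))
  calls["hit", 1:3] <- 1L         # 30% in resistant
  calls["rare", c(1, 11)] <- 1L   # 10% each -- above 2%? yes
  expect_setequal(mutation_frequency_filter(calls, labels, 0.02),
                  c("hit", "rare"))
  ## exactly at threshold is dropped
  labels2 <- setNames(rep(c("resistant", "sensitive"), each = 50),
                      paste0("t", 1:100))
  calls2 <- matrix(0L, 1, 100, dimnames = list("edge", names(labels2)))
  calls2["edge", c(1, 51)] <- 1L  # exactly 2% in each group
  expect_length(mutation_frequency_filter(calls2, labels2, 0.02), 0)
})

test_that("filters are invariant to gene and sample order", {
  b <- small_bundle(seed = 13)
  st <- call_cnv_states(b$cnv_log2)
  gp <- sample(nrow(st)); sp <- sample(ncol(st))
  expect_setequal(cnv_frequency_filter(st, b$labels),
                  cnv_frequency_filter(st[gp, sp], b$labels))
  expect_setequal(mutation_frequency_filter(b$somatic, b$labels),
                  mutation_frequency_filter(b$somatic[gp, sp], b$labels))
})
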