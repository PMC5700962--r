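test_that("similarity is the absolute Pearson correlation", {
  set.seed(31)
  x <- rnorm(20)
  X <- rbind(a = x, b = 2 * x + 1, c = -x, d = rnorm(20))
  colnames(X) <- paste0("s", 1:20)
  S <- similarity(X)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], 1)
  expect_equal(S["a", "d"], abs(cor(x, X["d", ])))
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, 4))
  Xz <- rbind(X, e = rep(3, 20))
  expect_error(similarity(Xz), "e")
})

test_that("adjacency is the elementwise soft-threshold power", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(unclass(adjacency(S, 1)), S, ignore_attr = TRUE)
  expect_equal(adjacency(S, 6)[1, 2], 0.015625)
  expect_equal(adjacency(S, 6)[1, 1], 1)
  expect_error(adjacency(S, 0.5), "beta")
})

test_that("soft-threshold selection falls back on degenerate input", {
  S <- diag(30) + 0.01
  expect_warning(beta <- pick_soft_threshold(S), "default")
  expect_equal(as.numeric(beta), 6)
  expect_equal(suppressWarnings(as.numeric(pick_soft_threshold(S, candidates = 6))), 6)
})

test_that("soft-threshold selection is stable on modular data", {
  b <- small_bundle(seed = 19)
  S <- similarity(b$expression)
  b1 <- pick_soft_threshold(S)
  b2 <- pick_soft_threshold(S)
  expect_identical(as.numeric(b1), as.numeric(b2))
  expect_true(as.numeric(b1) %in% 1:20)
})

test_that("topological overlap matches hand and brute-force evaluation", {
  ## fully connected triangle: omega_12 = (1 + 1) / (min(2, 2) + 1 - 1) = 1
  A3 <- matrix(1, 3, 3)
  W3 <- tom(A3)
  expect_equal(W3[1, 2], 1)

  ## no off-diagonal adjacency: no overlap
  W0 <- tom(diag(4))
  expect_equal(unname(W0[upper.tri(W0)]), rep(0, 6))

  set.seed(7)
  for (i in 1:10) {
    A <- matrix(runif(100), 10, 10)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    expect_equal(tom(A), tom_bruteforce(A), tolerance = 1e-12)
  }
})

test_that("tom output stays within [0, 1] on random adjacencies", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
    W <- tom(A)
    expect_true(all(W >= -1e-12 & W <= 1 + 1e-12))
    expect_true(isSymmetric(W))
  }
})

test_that("module detection labels blocks by decreasing size in color order", {
  set.seed(41)
  base1 <- rnorm(30); base2 <- rnorm(30)
  X <- rbind(matrix(rep(base1, 30), 30, byrow = TRUE) + rnorm(900, 0, 0.01),
             matrix(rep(base2, 20), 20, byrow = TRUE) + rnorm(600, 0, 0.01))
  rownames(X) <- paste0("g", 1:50); colnames(X) <- paste0("s", 1:30)
  W <- tom(adjacency(similarity(X), 6))
  ma <- detect_modules(W, min_module_size = 10)
  expect_equal(sum(ma$colors == "turquoise"), 30)
  expect_equal(sum(ma$colors == "blue"), 20)
  expect_setequal(names(ma$colors)[ma$colors == "turquoise"],
                  paste0("g", 1:30))
})

test_that("independent genes end up unassigned (grey)", {
  set.seed(43)
  X <- matrix(rnorm(60 * 30), 60, 30,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:30)))
  W <- tom(adjacency(similarity(X), 6))
  ma <- detect_modules(W, min_module_size = 20)
  expect_true(mean(ma$colors == "grey") > 0.9)
})

test_that("module detection is invariant to gene permutation up to labels", {
  b <- small_bundle(seed = 23)
  W <- tom(adjacency(similarity(b$expression), 6))
  ma1 <- detect_modules(W, min_module_size = 8)
  set.seed(1); p <- sample(nrow(W))
  ma2 <- detect_modules(W[p, p], min_module_size = 8)
  expect_equal(ari(ma1$colors, ma2$colors[names(ma1$colors)]), 1)
})

test_that("eigengene is the leading PC with positive orientation", {
  set.seed(47)
  prof <- rnorm(25)
  X <- matrix(rep(prof, 6), 6, byrow = TRUE) * runif(6, 0.5, 2) + 1
  rownames(X) <- paste0("g", 1:6); colnames(X) <- paste0("s", 1:25)
  E <- eigengene(X)
  expect_equal(sum(E^2), 1)
  expect_gt(abs(cor(E, prof)), 0.999)
  expect_gt(mean(apply(X, 1, cor, E)), 0)
  ## flipping all genes flips the orientation back
  E2 <- eigengene(-X)
  expect_gt(mean(apply(-X, 1, cor, E2)), 0)

  ## PCA optimality: E explains at least as much module variance as any
  ## single standardized member profile
  b <- small_bundle(seed = 3)
  members <- names(b$truth$module_membership)[b$truth$module_membership == "M1"]
  Xm <- b$expression[members, ]
  Z <- t(scale(t(Xm)))
  Em <- eigengene(Xm)
  var_of <- function(v) sum((Z %*% v / sqrt(sum(v^2)))^2)
  ve <- var_of(Em)
  for (i in seq_len(nrow(Z))) expect_gte(ve + 1e-8, var_of(Z[i, ]))

  expect_error(eigengene(Xm[1, , drop = FALSE]), ">= 2")
})

test_that("module membership is plain correlation with the eigengene", {
  set.seed(51)
  E <- rnorm(20)
  expect_equal(module_membership(E, E), 1)
  expect_equal(module_membership(-E, E), -1)
  x <- rnorm(20)
  expect_equal(module_membership(x, E), cor(x, E))
  expect_error(module_membership(rep(1, 20), E), "zero-variance")
})

test_that("gene significance is the absolute trait correlation", {
  labels <- setNames(rep(c("resistant", "sensitive"), each = 15),
                     paste0("s", 1:30))
  trait <- as.numeric(labels == "resistant")
  set.seed(53)
  X <- rbind(perfect = trait, anti = -trait, null = rnorm(30))
  colnames(X) <- names(labels)
  gs <- gene_significance(X, labels)
  expect_equal(unname(gs["perfect"]), 1)
  expect_equal(unname(gs["anti"]), 1)
  expect_lt(unname(gs["null"]), 0.5)
  expect_true(all(gs >= 0 & gs <= 1))
})
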