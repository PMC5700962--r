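# helper: build a tiny planted module-network problem
planted_problem <- function(n_samples = 40, noise = 0, seed = 1,
                            effect = 2) {
  set.seed(seed)
  status <- rbind(mA = rbinom(n_samples, 1, 0.5),
                  mB = rbinom(n_samples, 1, 0.5),
                  mC = rbinom(n_samples, 1, 0.5))
  colnames(status) <- paste0("s", seq_len(n_samples))
  mu1 <- effect * status["mA", ]
  mu2 <- effect * (2 * status["mB", ] + status["mC", ])
  X <- rbind(
    do.call(rbind, lapply(1:6, function(i) mu1 + rnorm(n_samples, 0, noise))),
    do.call(rbind, lapply(1:6, function(i) mu2 + rnorm(n_samples, 0, noise))))
  rownames(X) <- c(paste0("p", 1:6), paste0("q", 1:6))
  colnames(X) <- colnames(status)
  init <- setNames(rep(c("M1", "M2"), each = 6), rownames(X))
  list(X = X, status = status, init = init)
}

test_that("leaf marginal: empty, single-value, and order invariance", {
  pr <- normal_gamma_prior()
  expect_equal(leaf_log_marginal(numeric(0), pr), 0)
  ## one observation: the prior-predictive Student-t density
  for (v in c(-2.5, 0, 0.7, 4)) {
    expect_equal(leaf_log_marginal(v, pr), student_t_log_predictive(v, pr),
                 tolerance = 1e-10)
  }
  pr2 <- normal_gamma_prior(mu0 = 1, kappa0 = 2, alpha0 = 3, beta0 = 0.5)
  expect_equal(leaf_log_marginal(1.3, pr2), student_t_log_predictive(1.3, pr2),
               tolerance = 1e-10)
  set.seed(77)
  v <- rnorm(25)
  expect_equal(leaf_log_marginal(v, pr), leaf_log_marginal(sample(v), pr))
  expect_error(leaf_log_marginal(c(1, NA), pr), "finite")
  expect_error(normal_gamma_prior(kappa0 = 0), "kappa0")
})

test_that("score from pooled sufficient statistics matches raw recomputation", {
  set.seed(79)
  pr <- normal_gamma_prior()
  for (i in 1:20) {
    v <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    k <- sample(2:(length(v) - 1), 1)
    a <- v[1:k]; b <- v[-(1:k)]
    ## pool the two blocks' sufficient statistics
    na <- length(a); nb <- length(b)
    mu <- (na * mean(a) + nb * mean(b)) / (na + nb)
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2) +
      na * (mean(a) - mu)^2 + nb * (mean(b) - mu)^2
    expect_equal(drivermod:::lml_stats(na + nb, mu, ss, pr),
                 leaf_log_marginal(v, pr), tolerance = 1e-8)
  }
})

test_that("model scoring accounts for data terms and the node penalty", {
  pb <- planted_problem(noise = 0.3, seed = 5)
  pr <- normal_gamma_prior()

  ## no-split model: score is the sum of whole-profile marginals
  leaf_prog <- structure(list(
    tree = list(type = "leaf", samples = seq_len(ncol(pb$X)), n = ncol(pb$X)),
    modulators = character(0), n_nodes = 0L,
    leaf_samples = list(seq_len(ncol(pb$X)))), class = "regulatory_program")
  model <- list(assignment = pb$init,
                programs = list(M1 = leaf_prog, M2 = leaf_prog), prior = pr)
  s0 <- score_model(model, pb$X, penalty = 3)
  direct <- sum(vapply(rownames(pb$X),
                       function(g) leaf_log_marginal(pb$X[g, ], pr), 0))
  expect_equal(s0, direct, tolerance = 1e-10)

  ## a decision node routing every sample one way adds exactly the penalty
  idx <- seq_len(ncol(pb$X))
  vacuous_split <- structure(list(
    tree = list(type = "split", modulator = "mA",
                no = list(type = "leaf", samples = idx, n = length(idx)),
                yes = list(type = "leaf", samples = integer(0), n = 0L)),
    modulators = "mA", n_nodes = 1L,
    leaf_samples = list(idx, integer(0))), class = "regulatory_program")
  model2 <- model
  model2$programs$M1 <- vacuous_split
  expect_equal(score_model(model2, pb$X, penalty = 3), s0 - 3)

  ## small-instance oracle: recompute the full score from scratch
  prog1 <- learn_tree(pb$X[1:6, ], pb$status, pr, penalty = 3)
  model3 <- list(assignment = pb$init,
                 programs = list(M1 = prog1, M2 = leaf_prog), prior = pr)
  manual <- 0
  for (g in names(pb$init)) {
    prog <- model3$programs[[pb$init[[g]]]]
    for (leaf in prog$leaf_samples)
      manual <- manual + leaf_log_marginal(pb$X[g, leaf], pr)
  }
  manual <- manual - 3 * prog1$n_nodes
  expect_equal(score_model(model3, pb$X, penalty = 3), manual,
               tolerance = 1e-10)
})

test_that("tree learning recovers planted splits and respects the penalty", {
  pb <- planted_problem(noise = 0, seed = 7)
  pr <- normal_gamma_prior()

  prog <- learn_tree(pb$X[1:6, ], pb$status, pr, penalty = 2)
  expect_equal(prog$tree$modulator, "mA")  # root tests the planted modulator
  expect_equal(prog$modulators, "mA")      # and nothing else at zero noise

  prog2 <- learn_tree(pb$X[7:12, ], pb$status, pr, penalty = 2)
  expect_setequal(prog2$modulators, c("mB", "mC"))

  ## constant expression: a single leaf
  Xc <- matrix(1, 3, ncol(pb$X),
               dimnames = list(paste0("c", 1:3), colnames(pb$X)))
  progc <- learn_tree(Xc, pb$status, pr, penalty = 2)
  expect_equal(progc$n_nodes, 0L)
  expect_length(progc$leaf_samples, 1)

  ## overwhelming penalty forbids any split
  prog3 <- learn_tree(pb$X[1:6, ], pb$status, pr, penalty = 1e9)
  expect_equal(prog3$n_nodes, 0L)
})

test_that("gene reassignment moves genes to their generating program", {
  pb <- planted_problem(noise = 0.3, seed = 11)
  pr <- normal_gamma_prior()
  progs <- list(M1 = learn_tree(pb$X[1:6, ], pb$status, pr, 2),
                M2 = learn_tree(pb$X[7:12, ], pb$status, pr, 2))
  ## start from a deliberately wrong assignment
  wrong <- setNames(rep(c("M2", "M1"), each = 6), rownames(pb$X))
  model <- list(assignment = wrong, programs = progs,
                prior = pr, penalty = 2)
  re <- reassign_genes(model, pb$X)
  expect_equal(unname(re[paste0("p", 1:6)]), rep("M1", 6))
  expect_equal(unname(re[paste0("q", 1:6)]), rep("M2", 6))
  ## the E-step never decreases the total score
  s_before <- score_model(model, pb$X, 2)
  model$assignment <- re
  expect_gte(score_model(model, pb$X, 2), s_before - 1e-9)

  single <- list(assignment = setNames(rep("M1", 12), rownames(pb$X)),
                 programs = progs["M1"], prior = pr)
  expect_identical(reassign_genes(single, pb$X), single$assignment)
})

test_that("EM fit recovers planted modulators and converges monotonically", {
  pb <- planted_problem(noise = 0.4, seed = 13)
  fit <- module_network(pb$X, pb$init, pb$status, max_iter = 10)
  expect_s3_class(fit, "module_network")
  expect_true(all(diff(fit$trace$score) >= -1e-8))
  mods <- extract_modulators(fit)
  expect_setequal(names(mods), c("mA", "mB", "mC"))
  ## converged: one more EM pass changes the score by less than tol
  tr <- fit$trace$score
  expect_lt(abs(tr[length(tr)] - tr[length(tr) - 2]), 1e-4 + 1e-9)
  expect_output(print(fit), "module_network")
  expect_output(summary(fit), "modules")
})

test_that("zero-noise planted data is recovered exactly", {
  pb <- planted_problem(noise = 0, seed = 17)
  fit <- module_network(pb$X, pb$init, pb$status, max_iter = 10)
  mods <- extract_modulators(fit)
  expect_setequal(names(mods), c("mA", "mB", "mC"))
  expect_equal(ari(fit$assignment, pb$init[names(fit$assignment)]), 1)
})

test_that("extract_modulators reports multi-module spans once per gene", {
  pb <- planted_problem(noise = 0)
  pr <- normal_gamma_prior()
  leaf_prog <- learn_tree(matrix(1, 2, ncol(pb$X),
                                 dimnames = list(c("z1", "z2"),
                                                 colnames(pb$X))),
                          pb$status, pr, 2)
  model <- list(programs = list(A = leaf_prog), assignment = c(z1 = "A"),
                prior = pr)
  expect_length(extract_modulators(model), 0)

  shared <- learn_tree(pb$X[1:6, ], pb$status, pr, 2)
  model2 <- list(programs = list(A = shared, B = shared, C = shared),
                 assignment = c(z1 = "A"), prior = pr)
  mods <- extract_modulators(model2)
  expect_length(mods, 1)
  expect_setequal(mods[["mA"]], c("A", "B", "C"))
})

test_that("prediction routes planted genes to their module", {
  pb <- planted_problem(noise = 0.3, seed = 19)
  fit <- module_network(pb$X, pb$init, pb$status, max_iter = 10)
  pred <- predict(fit, pb$X[c("p1", "q3"), ])
  expect_equal(unname(pred["p1"]), unname(fit$assignment[["p2"]]))
  expect_equal(unname(pred["q3"]), unname(fit$assignment[["q4"]]))
})
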