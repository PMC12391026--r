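hand_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("newick reading validates structure and branch lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_newick(path)
  expect_equal(sort(tree$tip.label), c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tree)[1:3]
  expect_equal(depths, rep(2, 3))

  writeLines("((A:1,B:1:1,C:2);", path)
  expect_error(read_newick(path), "unclosed")
  writeLines("((A,B),C);", path)
  expect_error(read_newick(path), "branch lengths")
})

test_that("trees round-trip through newick text", {
  sim <- simulate_tree_bm(25, seed = 31)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(sim$tree, path, digits = 15)
  back <- read_newick(path)
  expect_equal(phylo_covariance(back, sim$tree$tip.label),
               phylo_covariance(sim$tree), tolerance = 1e-12)
})

test_that("duplicate species measurements are averaged", {
  out <- resolve_duplicate_tips(
    tibble::tibble(species = c("Hakea", "Hakea"), psm = c(0.2, 0.4)))
  expect_equal(out$psm, 0.3)
  out <- resolve_duplicate_tips(tibble::tibble(species = "sp", psm = 0.7))
  expect_equal(out$psm, 0.7)
  out <- resolve_duplicate_tips(
    tibble::tibble(species = rep("sp", 3), psm = c(1, 2, 3)))
  expect_equal(out$psm, 2)
  expect_error(resolve_duplicate_tips(
    tibble::tibble(species = "sp", psm = NA_real_)), "missing")
})

test_that("the phylogenetic covariance is shared path length", {
  cv <- phylo_covariance(hand_tree(), c("A", "B", "C"))
  expect_equal(unname(diag(cv)), c(2, 2, 2))
  expect_equal(cv["A", "B"], 1)
  expect_equal(cv["A", "C"], 0)
  expect_identical(cv, t(cv))

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(phylo_covariance(star)), diag(4))

  expect_error(phylo_covariance(hand_tree(), c("A", "Z")), "Z")

  # PSD across random trees
  for (i in 1:10) {
    sim <- simulate_tree_bm(20, seed = 400 + i)
    ev <- eigen(phylo_covariance(sim$tree), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("the lambda profile likelihood is valid and matches an oracle", {
  sim <- simulate_tree_bm(40, sigma2 = 1, lambda_true = 1, seed = 77)
  lam <- pagels_lambda(sim$tree, sim$values)
  # optimizer validity: profile at the optimum beats both bounds
  expect_gte(lam$loglik, lam$loglik0 - 1e-8)
  expect_gte(lam$lambda_hat, 0)
  expect_lte(lam$lambda_hat, 1)

  # independent maximum-likelihood oracle
  ph <- phytools::phylosig(sim$tree, sim$values, method = "lambda",
                           test = TRUE)
  expect_equal(lam$lambda_hat, min(1, ph$lambda), tolerance = 0.02)
  expect_equal(lam$loglik0, ph$logL0, tolerance = 1e-4)

  # at lambda = 0 on an ultrametric tree the model is iid normal around the mean
  y <- unname(sim$values)
  n <- length(y)
  sd_ml <- sqrt(mean((y - mean(y))^2) )
  depth <- phylo_covariance(sim$tree)[1, 1]
  iid_ll <- sum(dnorm(y, mean(y), sd_ml, log = TRUE))
  # lambda = 0 covariance is depth * I, but sigma2 is profiled, so equal
  expect_equal(lam$loglik0, iid_ll, tolerance = 1e-8)
})

test_that("Blomberg's K matches its oracle and is shift/scale invariant", {
  sim <- simulate_tree_bm(40, sigma2 = 2, lambda_true = 1, seed = 123)
  k <- blombergs_k(sim$tree, sim$values, n_permutations = 99, seed = 8)
  expect_equal(k$k_hat,
               unclass(phytools::phylosig(sim$tree, sim$values, method = "K")),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(k$k_hat, picante::Kcalc(sim$values[sim$tree$tip.label],
                                       sim$tree),
               tolerance = 1e-8, ignore_attr = TRUE)

  shifted <- blombergs_k(sim$tree, sim$values + 100, n_permutations = 99,
                         seed = 8)
  scaled <- blombergs_k(sim$tree, sim$values * -3.7, n_permutations = 99,
                        seed = 8)
  expect_equal(shifted$k_hat, k$k_hat, tolerance = 1e-10)
  expect_equal(scaled$k_hat, k$k_hat, tolerance = 1e-10)
  # identical seeds give bit-identical permutation p-values
  expect_identical(shifted$k_p, k$k_p)

  expect_gte(k$k_p, 1 / (99 + 1))
  expect_lte(k$k_p, 1)
  expect_error(blombergs_k(sim$tree, sim$values * 0, n_permutations = 9,
                           seed = 1), "zero variance")
})

test_that("signal is recovered under Brownian motion and lost on permutation", {
  lam_bm <- numeric(12)
  lam_perm <- numeric(12)
  for (i in 1:12) {
    sim <- simulate_tree_bm(60, sigma2 = 1, lambda_true = 1, seed = 9000 + i)
    lam_bm[i] <- pagels_lambda(sim$tree, sim$values)$lambda_hat
    shuffled <- withr::with_seed(500 + i,
                                 setNames(sample(sim$values),
                                          names(sim$values)))
    lam_perm[i] <- pagels_lambda(sim$tree, shuffled)$lambda_hat
  }
  expect_gte(mean(lam_bm), 0.8)
  expect_lte(median(lam_perm), 0.25)
})

test_that("the tidy wrapper averages duplicates and reports one row", {
  sim <- simulate_tree_bm(30, seed = 61)
  psm_tab <- tibble::tibble(
    species = c(names(sim$values), names(sim$values)[1]),
    psm = c(abs(sim$values), abs(sim$values[1]) + 0.2)
  )
  row <- phylo_signal(psm_tab, sim$tree, n_permutations = 99, seed = 13)
  expect_equal(nrow(row), 1)
  expect_equal(row$n_tips, 30)
  expect_true(row$lambda_hat >= 0 && row$lambda_hat <= 1)
  expect_true(row$k_p >= 0.01 && row$k_p <= 1)
})
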