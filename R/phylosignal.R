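# Phylogenetic signal in the sensitivity metric: Pagel's lambda by profile
# maximum likelihood with a likelihood-ratio p-value, Blomberg's K with a
# tip-permutation p-value, plus tree input and duplicate-measurement handling.

#' Read a phylogeny from a newick file
#'
#' Parses a newick tree (polytomies preserved) and checks that branch lengths
#' are present, since the phylogenetic covariance is built from them.
#' Unbalanced parentheses are reported with their character offset.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0) {
      abort(sprintf("malformed newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0) {
    abort(sprintf("malformed newick: %d unclosed '(' at end of text", depth))
  }
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tree)) abort(sprintf("could not parse newick file %s", path))
  if (is.null(tree$edge.length)) {
    abort(sprintf("%s has no branch lengths; they are required", path))
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  tree
}

#' Average repeated measurements per species
#'
#' Species measured at more than one site get the arithmetic mean of their
#' sensitivity values before any tree-based analysis; single measurements pass
#' through unchanged.
#'
#' @param data Data frame with a `species` column and a value column.
#' @param value_col Name of the value column (default `"psm"`).
#' @return Tibble with one row per species and the averaged value column.
#' @examples
#' resolve_duplicate_tips(
#'   tibble::tibble(species = c("Hakea", "Hakea"), psm = c(0.2, 0.4)))
#' @export
resolve_duplicate_tips <- function(data, value_col = "psm") {
  data <- as_tibble(data)
  if (!all(c("species", value_col) %in% names(data))) {
    abort(sprintf("data must have columns species and %s", value_col))
  }
  if (any(is.na(data[[value_col]]))) {
    abort(sprintf("missing %s value for species: %s", value_col,
                  paste(unique(data$species[is.na(data[[value_col]])]),
                        collapse = ", ")))
  }
  out <- data |>
    group_by(.data$species) |>
    summarise(.value = mean(.data[[value_col]]), .groups = "drop")
  names(out)[names(out) == ".value"] <- value_col
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared root-to-most-recent-common-ancestor path length
#' of tips i and j; the diagonal is each tip's root-to-tip depth. The tree is
#' pruned to the requested species and the matrix returned in their order.
#'
#' @param tree An `ape::phylo` tree.
#' @param species Optional character vector of tip labels; defaults to all
#'   tips in the tree's order. Species absent from the tree are an error.
#' @return Symmetric positive semi-definite matrix with species dimnames.
#' @export
phylo_covariance <- function(tree, species = NULL) {
  species <- species %||% tree$tip.label
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp) > 0) {
    abort(sprintf("species absent from the tree: %s",
                  paste(missing_sp, collapse = ", ")))
  }
  if (length(species) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, species)
  }
  vv <- ape::vcv(tree)
  vv <- vv[species, species, drop = FALSE]
  (vv + t(vv)) / 2
}

# match a named value vector to tree tips; values may also be unnamed and in
# tip order
match_tip_values <- function(tree, values) {
  if (is.null(names(values))) {
    if (length(values) != length(tree$tip.label)) {
      abort("unnamed values must have one entry per tip")
    }
    names(values) <- tree$tip.label
  }
  missing_sp <- setdiff(names(values), tree$tip.label)
  if (length(missing_sp) > 0) {
    abort(sprintf("species absent from the tree: %s",
                  paste(missing_sp, collapse = ", ")))
  }
  values
}

# Gaussian log-likelihood of tip values under covariance V, with the mean and
# scale profiled out by GLS (ML scale, n denominator)
gls_profile_loglik <- function(y, v) {
  n <- length(y)
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch)) {
    abort("singular phylogenetic covariance; consider jittering zero branch lengths")
  }
  logdet <- 2 * sum(log(diag(ch)))
  one <- rep(1, n)
  vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  vi_1 <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(vi_y) / sum(vi_1)
  r <- y - mu
  q <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
  sigma2 <- q / n
  list(
    loglik = -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n),
    mu = mu, sigma2 = sigma2
  )
}

lambda_cov <- function(c_mat, lambda) {
  v <- c_mat * lambda
  diag(v) <- diag(c_mat)
  v
}

#' Pagel's lambda for a continuous trait
#'
#' Profile maximum likelihood of the lambda transform: off-diagonal entries of
#' the phylogenetic covariance are scaled by lambda while the diagonal is kept
#' fixed; the phylogenetic mean and scale are profiled out in closed form by
#' generalized least squares. Lambda is searched on `bounds` (default 0 to 1,
#' with both endpoints checked) by bounded scalar optimization to tolerance
#' 1e-6. The p-value is the upper chi-square(1) tail of the likelihood ratio
#' against lambda = 0 (no signal: star-like covariance).
#'
#' @param tree An `ape::phylo` tree.
#' @param values Named numeric vector of tip values (at least 4).
#' @param bounds Search interval for lambda (default `c(0, 1)`).
#' @return A list: `lambda_hat`, `loglik` (at the optimum), `loglik0` (at
#'   lambda = 0), `lambda_p`, `n_tips`.
#' @export
pagels_lambda <- function(tree, values, bounds = c(0, 1)) {
  values <- match_tip_values(tree, values)
  if (length(values) < 4) abort("at least 4 tips are required")
  c_mat <- phylo_covariance(tree, names(values))
  ll <- function(lam) gls_profile_loglik(unname(values),
                                         lambda_cov(c_mat, lam))$loglik
  opt <- optimize(ll, interval = bounds, maximum = TRUE, tol = 1e-6)
  cand_lambda <- c(opt$maximum, bounds)
  cand_ll <- c(opt$objective, ll(bounds[1]), ll(bounds[2]))
  best <- which.max(cand_ll)
  ll0 <- if (bounds[1] == 0) cand_ll[2] else ll(0)
  lr <- max(0, 2 * (cand_ll[best] - ll0))
  list(
    lambda_hat = cand_lambda[best],
    loglik = cand_ll[best],
    loglik0 = ll0,
    lambda_p = pchisq(lr, df = 1, lower.tail = FALSE),
    n_tips = length(values)
  )
}

# K statistic for one value vector given C, its inverse column sums etc.
k_statistic <- function(y, cinv, trace_c, n, expected_ratio) {
  a <- sum(cinv %*% y) / sum(cinv)
  r <- y - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% cinv %*% r) / (n - 1)
  (mse0 / mse) / expected_ratio
}

#' Blomberg's K with a tip-permutation test
#'
#' K compares the observed ratio of the tip-value mean squared deviation
#' (about the phylogenetically corrected mean) to the GLS mean squared error
#' under the tree's covariance, against the ratio expected under Brownian
#' motion, `(trace(C) - n / sum(C^-1)) / (n - 1)`. K near 1 indicates
#' Brownian-like signal, near 0 no signal. The p-value permutes tip values
#' uniformly at random: `p = (1 + #{K_perm >= K_obs}) / (n_permutations + 1)`,
#' one-tailed for signal stronger than random, reproducible for a fixed seed.
#'
#' @param tree An `ape::phylo` tree.
#' @param values Named numeric vector of tip values (at least 4, not all
#'   equal).
#' @param n_permutations Number of random tip permutations (default 999).
#' @param seed Integer seed for the permutations; required.
#' @return A list: `k_hat`, `k_p`, `n_tips`, `n_permutations`, `seed`.
#' @export
blombergs_k <- function(tree, values, n_permutations = 999L, seed) {
  if (missing(seed)) abort("a seed is required for the permutation test")
  values <- match_tip_values(tree, values)
  n <- length(values)
  if (n < 4) abort("at least 4 tips are required")
  y <- unname(values)
  if (sd(y) == 0) abort("tip values have zero variance; K is undefined")
  c_mat <- phylo_covariance(tree, names(values))
  cinv <- solve(c_mat)
  expected_ratio <- (sum(diag(c_mat)) - n / sum(cinv)) / (n - 1)
  k_obs <- k_statistic(y, cinv, sum(diag(c_mat)), n, expected_ratio)
  k_perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(i) {
      k_statistic(sample(y), cinv, sum(diag(c_mat)), n, expected_ratio)
    }, numeric(1))
  })
  list(
    k_hat = k_obs,
    k_p = (1 + sum(k_perm >= k_obs)) / (n_permutations + 1),
    n_tips = n,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  )
}

#' Phylogenetic signal in the sensitivity metric
#'
#' Convenience wrapper running [resolve_duplicate_tips()], [pagels_lambda()]
#' and [blombergs_k()] on a sensitivity table and a tree, returning one tidy
#' row.
#'
#' @param psm_results Tibble with `species` and a value column (default
#'   `psm`), e.g. from [compute_psm_table()]; repeated species are averaged.
#' @param tree An `ape::phylo` tree containing all species as tips.
#' @param value_col Name of the value column (default `"psm"`).
#' @param n_permutations Permutations for the K test (default 999).
#' @param seed Integer seed; required.
#' @return One-row tibble: `lambda_hat`, `lambda_p`, `k_hat`, `k_p`,
#'   `n_tips`, `n_permutations`, `seed`.
#' @export
phylo_signal <- function(psm_results, tree, value_col = "psm",
                         n_permutations = 999L, seed) {
  if (missing(seed)) abort("a seed is required for the permutation test")
  resolved <- resolve_duplicate_tips(psm_results, value_col = value_col)
  resolved <- filter(resolved, is.finite(.data[[value_col]]))
  values <- setNames(resolved[[value_col]], resolved$species)
  lam <- pagels_lambda(tree, values)
  k <- blombergs_k(tree, values, n_permutations = n_permutations, seed = seed)
  tibble(
    lambda_hat = lam$lambda_hat,
    lambda_p = lam$lambda_p,
    k_hat = k$k_hat,
    k_p = k$k_p,
    n_tips = lam$n_tips,
    n_permutations = k$n_permutations,
    seed = as.integer(seed)
  )
}
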