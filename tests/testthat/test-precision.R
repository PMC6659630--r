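# exact identity sample second-moment matrix at p = 2
identity_gram_data <- function() {
  x <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  colnames(x) <- c("a", "b")
  stopifnot(all(crossprod(x) / 4 == diag(2)))
  x
}

test_that("p = 2 with identity Gram recovers the identity precision", {
  est <- estimate_precision(identity_gram_data())
  expect_equal(unname(est$omega), diag(2))
  expect_equal(est$partial_corr[1, 2], 0)
  expect_equal(est$pvalue[1, 2], 1)
})

test_that("z-scores, Fisher information and p-values are mutually consistent", {
  set.seed(4)
  om <- graph_to_precision(generate_base_graph("random", 12))
  x <- sample_gaussian(om, 80)
  for (mode in c("pairwise", "nodewise")) {
    est <- estimate_precision(x, mode = mode)
    off <- upper.tri(est$z)
    d1 <- est$pair_diag
    # F = 1 / (omega_ii omega_jj + omega_ij^2) with per-pair diagonals
    expect_equal(est$fisher_info[off],
                 (1 / (d1 * t(d1) + est$omega^2))[off], tolerance = 1e-12)
    expect_equal(est$z[off],
                 (sqrt(est$n * est$fisher_info) * est$omega)[off],
                 tolerance = 1e-10)
    expect_equal(est$pvalue[off], 2 * pnorm(-abs(est$z[off])),
                 tolerance = 1e-12)
    # stored matrices satisfy the structural invariants
    expect_true(isSymmetric(unname(est$omega)))
    expect_true(all(diag(est$omega) > 0))
    expect_true(all(est$pvalue[off] > 0 & est$pvalue[off] <= 1))
    expect_equal(est$partial_corr, partial_correlations(est$omega))
  }
})

test_that("the legacy variance form is available behind its flag", {
  set.seed(5)
  x <- sample_gaussian(graph_to_precision(generate_base_graph("random", 8)), 60)
  est <- estimate_precision(x)
  leg <- estimate_precision(x, printed_variance = TRUE)
  expect_equal(est$omega, leg$omega)          # the estimate itself is shared
  expect_false(isTRUE(all.equal(est$z, leg$z)))
  expect_true(isSymmetric(unname(leg$z)))
})

test_that("pairwise and nodewise modes agree within the documented gap", {
  gaps <- sapply(1:3, function(seed) {
    pair <- simulate_pair(graph_scenario("random", 15, 200, 0.25,
                                         seed = 31 * seed))
    ep <- estimate_precision(pair$data1, mode = "pairwise")
    en <- estimate_precision(pair$data1, mode = "nodewise")
    mean(abs((ep$omega - en$omega)[upper.tri(ep$omega)]))
  })
  expect_lt(mean(gaps), 0.25)
})

test_that("permuting columns conjugates the estimate", {
  set.seed(6)
  x <- sample_gaussian(graph_to_precision(generate_base_graph("random", 10)), 60)
  colnames(x) <- paste0("g", 1:10)
  perm <- sample(10)
  for (mode in c("pairwise", "nodewise")) {
    e <- estimate_precision(x, mode = mode)
    ep <- estimate_precision(x[, perm], mode = mode)
    expect_equal(unname(ep$omega), unname(e$omega[perm, perm]),
                 tolerance = 1e-7)
    expect_equal(ep$gene_names, e$gene_names[perm])
  }
})

test_that("the single-edge type-I error is near nominal under the null", {
  set.seed(6)
  seeds <- sample.int(2^31 - 2, 500)
  om <- diag(20) * 0.3
  hits <- 0
  for (r in 1:500) {
    set.seed(seeds[r])
    x <- sample_gaussian(om, 200)
    hits <- hits + (estimate_precision(x, mode = "nodewise")$pvalue[1, 2] < 0.05)
  }
  expect_gte(hits / 500, 0.03)
  expect_lte(hits / 500, 0.07)
})

test_that("partial correlations match the elementwise formula", {
  expect_equal(partial_correlations(diag(c(2, 3, 4)))[upper.tri(diag(3))],
               rep(0, 3))
  expect_equal(partial_correlations(matrix(c(1, -0.5, -0.5, 1), 2))[1, 2], 0.5)
  set.seed(7)
  a <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
  expect_equal(unname(partial_correlations(a)), oracle_pcor(a),
               tolerance = 1e-12)
  bad <- diag(3); bad[1, 1] <- 0
  expect_error(partial_correlations(bad), "positive diagonal")
})

test_that("partial-correlation p-values follow the asymptotic normal form", {
  expect_equal(partial_corr_pvalues(0, 50), 1)
  expect_equal(partial_corr_pvalues(0.5, 64),
               2 * pnorm(-8 * 0.5 / (1 - 0.25)), tolerance = 1e-12)
  expect_equal(partial_corr_pvalues(0.5, 64), 9.66e-8, tolerance = 1e-3)
  g <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(partial_corr_pvalues(g, 40), partial_corr_pvalues(-g + 2 * diag(2), 40))
  expect_warning(p1 <- partial_corr_pvalues(matrix(c(1, 1, 1, 1), 2), 10),
                 "saturated")
  expect_equal(p1[1, 2], 0)
})

test_that("invalid and degenerate inputs follow their contracts", {
  expect_error(estimate_precision(matrix(rnorm(9), 3, 3)), "at least 4")
  xx <- matrix(rnorm(40), 10, 4); xx[2, 2] <- NA
  expect_error(estimate_precision(xx), "finite")

  # duplicated columns make residual Grams singular: flagged, not an error
  set.seed(8)
  x <- sample_gaussian(graph_to_precision(generate_base_graph("random", 6)), 50)
  y <- cbind(x[, 1:3], x[, 3])
  colnames(y) <- paste0("g", 1:4)
  expect_warning(est <- estimate_precision(y), "singular")
  expect_true(est$nonestimable[3, 4])
  expect_equal(est$pvalue[3, 4], 1)
  expect_true(all(diag(est$omega) > 0))
})
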