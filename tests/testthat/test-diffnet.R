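test_that("W statistics follow their two-sample formula", {
  p <- 3
  om <- diag(p); om[1, 2] <- om[2, 1] <- 0.5
  dp <- matrix(1, p, p); diag(dp) <- 0
  est1 <- make_est(om, dp, 100)
  est2 <- make_est(diag(p), dp, 100)

  W <- w_statistics(est1, est2)
  # hand-built pair: 0.5 / sqrt(1.25/100 + 1/100) = 10/3
  expect_equal(W[1, 2], 0.5 / sqrt(0.0225), tolerance = 1e-12)
  expect_equal(W[1, 2], 10 / 3, tolerance = 1e-12)
  expect_equal(unname(diag(W)), rep(0, p))

  # null numerator and antisymmetry under group swap
  expect_true(all(w_statistics(est1, est1) == 0))
  expect_equal(w_statistics(est2, est1), -W)

  est3 <- make_est(diag(p), dp, 100, genes = c("x", "y", "z"))
  expect_error(w_statistics(est1, est3), "gene names")
})

test_that("the FDR threshold matches a dense-grid oracle", {
  # 45 fixed |W| values at p = 10, alpha = 0.2 (infimum falls between
  # observed statistics, which the grid oracle detects)
  set.seed(10)
  W <- matrix(0, 10, 10)
  W[upper.tri(W)] <- rnorm(45, sd = 1.5)
  W <- W + t(W)
  expect_lt(abs(fdr_threshold(W, 0.2) - oracle_grid_threshold(W, 0.2)),
            2 * 2 * sqrt(log(10)) / 1e5)

  for (seed in 11:13) {
    set.seed(seed)
    V <- matrix(0, 12, 12)
    V[upper.tri(V)] <- rnorm(66, sd = 2)
    V <- V + t(V)
    for (alpha in c(0.05, 0.3)) {
      expect_lt(abs(fdr_threshold(V, alpha) -
                    oracle_grid_threshold(V, alpha)),
                2 * 2 * sqrt(log(12)) / 1e5)
    }
  }
})

test_that("FDR threshold boundary cases behave as stated", {
  set.seed(14)
  W <- matrix(0, 10, 10)
  W[upper.tri(W)] <- rnorm(45)
  W <- W + t(W)
  expect_equal(fdr_threshold(W, 1), 0)   # criterion holds already at t = 0

  Z <- matrix(0, 50, 50)                 # no signal: threshold at the cap
  expect_equal(fdr_threshold(Z, 0.05), 2 * sqrt(log(50)))
  expect_equal(nrow(differential_network(Z, fdr_threshold(Z, 0.05))), 0)

  expect_error(fdr_threshold(Z, 0), "alpha")
  expect_error(fdr_threshold(Z, 1.5), "alpha")
})

test_that("differential-network extraction matches a brute-force filter", {
  set.seed(15)
  W <- matrix(0, 12, 12)
  W[upper.tri(W)] <- rnorm(66)
  W <- W + t(W)
  genes <- paste0("g", 1:12)
  dimnames(W) <- list(genes, genes)

  t_med <- median(abs(W[upper.tri(W)]))
  edges <- differential_network(W, t_med)
  up <- which(upper.tri(W), arr.ind = TRUE)
  keep <- abs(W[up]) >= t_med
  expect_equal(nrow(edges), sum(keep))
  expect_setequal(paste(edges$gene_i, edges$gene_j),
                  paste(genes[up[keep, 1]], genes[up[keep, 2]]))
  expect_true(all(diff(abs(edges$W)) <= 1e-12))        # sorted descending
  expect_equal(edges$pvalue, 2 * pnorm(-abs(edges$W)))

  expect_equal(nrow(differential_network(W, max(abs(W)) + 1)), 0)
  expect_equal(nrow(differential_network(W, 0)), 66)
})

test_that("clusters match a breadth-first-search oracle", {
  expect_equal(network_clusters(data.frame(a = character(0),
                                           b = character(0))), list())

  # a path of 10 edges over 11 nodes is one component of 11 nodes
  path <- data.frame(a = paste0("n", 1:10), b = paste0("n", 2:11))
  cl <- network_clusters(path, min_size = 10)
  expect_length(cl, 1)
  expect_setequal(cl[[1]], paste0("n", 1:11))

  set.seed(16)
  idx <- matrix(sample(100, 160, replace = TRUE), ncol = 2)
  idx <- idx[idx[, 1] != idx[, 2], ]
  edges <- data.frame(a = paste0("v", idx[, 1]), b = paste0("v", idx[, 2]))
  got <- network_clusters(edges, min_size = 1)
  want <- oracle_components(edges)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
  # size filter
  sizes <- lengths(oracle_components(edges))
  expect_length(network_clusters(edges, min_size = 5), sum(sizes >= 5))
})

test_that("rejections are monotone in the FDR level", {
  for (seed in 17:21) {
    set.seed(seed)
    W <- matrix(0, 20, 20)
    W[upper.tri(W)] <- rnorm(190, sd = 1.8)
    W <- W + t(W)
    t05 <- fdr_threshold(W, 0.05)
    t10 <- fdr_threshold(W, 0.10)
    expect_gte(t05, t10)
    e05 <- differential_network(W, t05)
    e10 <- differential_network(W, t10)
    expect_true(all(paste(e05$gene_i, e05$gene_j) %in%
                    paste(e10$gene_i, e10$gene_j)))
  }
})

test_that("the fitted model object is coherent end to end", {
  pair <- simulate_pair(graph_scenario("random", 20, 40, 0.5, seed = 22))
  fit <- diffnet(pair$data1, pair$data2, alpha = 0.1, min_cluster = 3)

  expect_s3_class(fit, "diffnet")
  expect_equal(fit$delta, fit$est1$omega - fit$est2$omega)
  expect_equal(coef(fit), fit$delta)
  expect_true(isSymmetric(unname(fit$adjacency)))
  expect_false(any(diag(fit$adjacency)))
  expect_equal(unname(fit$adjacency),
               unname(abs(fit$W) >= fit$t_hat & row(fit$W) != col(fit$W)))
  expect_gte(fit$t_hat, 0)
  expect_lte(fit$t_hat, 2 * sqrt(log(20)))
  expect_equal(nrow(fit$edges), sum(fit$adjacency) / 2)
  expect_named(fit$edges,
               c("gene_i", "gene_j", "omega1", "p1", "pcor1", "pcor_p1",
                 "omega2", "p2", "pcor2", "pcor_p2", "W", "pvalue"))

  expect_output(print(fit), "Differential network")
  expect_output(summary(fit), "Top differential edges")
  pdf(NULL)
  expect_no_error(plot(fit))
  dev.off()

  # swapping the conditions negates the statistics exactly
  fit2 <- diffnet(pair$data2, pair$data1, alpha = 0.1, mode = "nodewise")
  fit1 <- diffnet(pair$data1, pair$data2, alpha = 0.1, mode = "nodewise")
  expect_equal(fit2$W, -fit1$W)
})

test_that("power does not decrease with sample size", {
  # same pair of precision matrices, data drawn at n = 50 and n = 200
  set.seed(23)
  adj <- generate_base_graph("random", 50)
  om <- graph_to_precision(adj)
  pert <- heterogeneity_perturb(om, 0.25)
  truth <- pert$omega1 != pert$omega2
  power_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      x <- sample_gaussian(pert$omega1, n)
      y <- sample_gaussian(pert$omega2, n)
      e1 <- estimate_precision(x, mode = "nodewise")
      e2 <- estimate_precision(y, mode = "nodewise")
      W <- w_statistics(e1, e2)
      th <- fdr_threshold(W, 0.1)
      up <- upper.tri(W)
      sum(abs(W[up]) >= th & truth[up]) / sum(truth[up])
    }, 0))
  }
  seeds <- sample.int(2^31 - 2, 10)
  expect_gte(power_at(200, seeds), power_at(50, seeds))
})
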