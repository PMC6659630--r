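#' Generate a base graph structure
#'
#' Draws the common undirected graph underlying both simulated conditions.
#' Three structures are supported:
#' \describe{
#'   \item{hub}{nodes are partitioned evenly into `ceiling(p / 20)` groups
#'     and every node in a group is attached to that group's hub (a union of
#'     stars); deterministic.}
#'   \item{scale_free}{Barabasi-Albert preferential attachment adding one
#'     edge per new node, i.e. a random tree with p - 1 edges.}
#'   \item{random}{each pair is an edge independently with probability
#'     3 / p.}
#' }
#' Randomness (for `scale_free` and `random`) comes from R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param structure One of `"hub"`, `"scale_free"`, `"random"`.
#' @param p Number of vertices (>= 3).
#' @param edge_prob Edge probability for the random structure (default
#'   `3 / p`).
#' @param hub_group_size Approximate nodes per hub group (default 20).
#' @return A p x p logical adjacency matrix (symmetric, no self loops).
#' @examples
#' sum(generate_base_graph("hub", 20)) / 2   # one star: 19 edges
#' @export
generate_base_graph <- function(structure = c("hub", "scale_free", "random"),
                                p, edge_prob = 3 / p, hub_group_size = 20L) {
  structure <- match.arg(structure)
  if (!is.numeric(p) || length(p) != 1L || p < 3) stop("'p' must be >= 3")
  p <- as.integer(p)
  adj <- matrix(FALSE, p, p)
  if (structure == "hub") {
    g <- ceiling(p / hub_group_size)
    sizes <- rep(p %/% g, g)
    extra <- p %% g
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (k in seq_len(g)) {
      hub <- starts[k]
      members <- seq(starts[k] + 1L, stops[k])
      adj[hub, members] <- TRUE
      adj[members, hub] <- TRUE
    }
  } else if (structure == "random") {
    up <- which(upper.tri(adj))
    sel <- up[runif(length(up)) < edge_prob]
    adj[sel] <- TRUE
    adj <- adj | t(adj)
  } else {
    g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    adj[el] <- TRUE
    adj <- adj | t(adj)
  }
  adj
}

#' Convert an adjacency matrix to a positive-definite precision matrix
#'
#' Places `v_offdiag` on every edge and sets a constant diagonal
#' \eqn{|\lambda_{\min}(v A)| + 0.1 + u} (the shift-to-SPD recipe of the
#' standard graphical-model generators), so the result is strictly positive
#' definite with smallest eigenvalue at least `0.1 + u_diag`. A plain
#' `1 + u_diag` diagonal is available via `diag_method = "unit"` (positive
#' definiteness is then not guaranteed for dense graphs).
#'
#' @param adjacency Symmetric logical (or 0/1) matrix with empty diagonal.
#' @param v_offdiag Value placed on the off-diagonal edge entries.
#' @param u_diag Diagonal boost added on top of the SPD shift.
#' @param diag_method `"shift"` (default) or `"unit"`.
#' @return A symmetric positive-definite matrix.
#' @examples
#' graph_to_precision(matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
#' @export
graph_to_precision <- function(adjacency, v_offdiag = 0.5, u_diag = 0.2,
                               diag_method = c("shift", "unit")) {
  diag_method <- match.arg(diag_method)
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency * 1)))
    stop("'adjacency' must be symmetric")
  if (any(diag(adjacency) != 0)) stop("'adjacency' must have empty diagonal")
  if (v_offdiag <= 0 || u_diag <= 0)
    stop("'v_offdiag' and 'u_diag' must be positive")
  omega <- v_offdiag * (adjacency * 1)
  d <- if (diag_method == "shift") {
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    abs(min(ev)) + 0.1 + u_diag
  } else {
    1 + u_diag
  }
  diag(omega) <- d
  omega
}

#' Inject heterogeneity into a pair of precision matrices
#'
#' Starting from a common matrix \eqn{\Omega_1 = \Omega_2 = \Omega}, flips
#' `round(gamma * M)` of the zero entries of each matrix (chosen
#' independently per matrix, without replacement, symmetry maintained) to a
#' uniform draw with magnitude in `value_range` and random sign, where M is
#' the number of edges (strictly-upper-triangular nonzeros) of
#' \eqn{\Omega}. `gamma` is thus the ratio of injected group-specific edges
#' to common edges. If either perturbed matrix has smallest eigenvalue at or
#' below 0.05 it is re-conditioned by adding a common multiple of the
#' identity to both matrices, which preserves the support of the difference.
#'
#' @param omega Symmetric positive-definite matrix.
#' @param gamma Heterogeneity ratio (>= 0).
#' @param value_range Magnitude range of the injected entries.
#' @return A list with `omega1`, `omega2`, `diff_support` (2-column matrix
#'   of pairs i < j where the matrices differ), the per-matrix perturbation
#'   index sets `perturbed1`, `perturbed2`, the number of index `collisions`
#'   between them, and the applied diagonal `shift` (0 if none).
#' @export
heterogeneity_perturb <- function(omega, gamma, value_range = c(0.2, 0.8)) {
  omega <- as.matrix(omega)
  if (gamma < 0) stop("'gamma' must be >= 0")
  p <- ncol(omega)
  up <- upper.tri(omega)
  M <- sum(omega[up] != 0)
  k <- round(gamma * M)
  zeros <- which(up & omega == 0)
  if (length(zeros) < k)
    stop("invalid scenario: ", k, " perturbations requested but only ",
         length(zeros), " zero entries available")

  flip <- function(base, cells) {
    if (length(cells) == 0L) return(base)
    vals <- runif(length(cells), value_range[1L], value_range[2L]) *
      sample(c(-1, 1), length(cells), replace = TRUE)
    base[cells] <- vals
    ij <- arrayInd(cells, dim(base))
    base[ij[, c(2L, 1L), drop = FALSE]] <- vals
    base
  }
  pick1 <- if (k > 0) sample(zeros, k) else integer(0)
  pick2 <- if (k > 0) sample(zeros, k) else integer(0)
  omega1 <- flip(omega, pick1)
  omega2 <- flip(omega, pick2)

  e1 <- min(eigen(omega1, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- min(eigen(omega2, symmetric = TRUE, only.values = TRUE)$values)
  shift <- 0
  if (min(e1, e2) <= 0.05) {
    shift <- abs(min(e1, e2)) + 0.05
    omega1 <- omega1 + shift * diag(p)
    omega2 <- omega2 + shift * diag(p)
  }

  diff_cells <- which(up & omega1 != omega2)
  list(omega1 = omega1, omega2 = omega2,
       diff_support = arrayInd(diff_cells, dim(omega)),
       perturbed1 = sort(pick1), perturbed2 = sort(pick2),
       collisions = length(intersect(pick1, pick2)),
       shift = shift)
}

#' Sample Gaussian data from a precision matrix
#'
#' Draws n i.i.d. mean-zero multivariate normal rows with covariance
#' \eqn{\Omega^{-1}}, via the Cholesky factor of the covariance. Uses R's
#' RNG: the same seed produces an identical matrix.
#'
#' @param omega Symmetric positive-definite precision matrix.
#' @param n Number of rows (>= 2).
#' @return An n x p numeric matrix (column names taken from `omega`).
#' @export
sample_gaussian <- function(omega, n) {
  omega <- as.matrix(omega)
  if (!is.numeric(n) || length(n) != 1L || n < 2) stop("'n' must be >= 2")
  p <- ncol(omega)
  ch <- tryCatch(chol(omega),
                 error = function(e) stop("'omega' must be symmetric ",
                                          "positive definite", call. = FALSE))
  sigma <- chol2inv(ch)
  r <- chol(sigma)
  x <- matrix(rnorm(as.integer(n) * p), as.integer(n), p) %*% r
  colnames(x) <- colnames(omega)
  x
}

#' Define a simulation scenario
#'
#' Bundles the parameters of one simulated two-condition study: the common
#' graph structure, its size, the per-group sample size, and the
#' heterogeneity level controlling how many group-specific edges are
#' injected.
#'
#' @param structure `"hub"`, `"scale_free"` or `"random"`.
#' @param p Number of vertices (>= 3).
#' @param n Per-group sample size.
#' @param gamma Heterogeneity ratio (>= 0): group-specific edges per common
#'   edge.
#' @param v_offdiag Common-edge value in the precision matrix.
#' @param u_diag Diagonal boost.
#' @param value_range Magnitude range of injected group-specific entries.
#' @param seed Optional RNG seed applied by [simulate_pair()].
#' @param replications Bookkeeping field for harnesses.
#' @return An object of class `"graph_scenario"`.
#' @examples
#' graph_scenario("random", p = 100, n = 50, gamma = 0.25)
#' @export
graph_scenario <- function(structure = c("hub", "scale_free", "random"),
                           p, n, gamma, v_offdiag = 0.5, u_diag = 0.2,
                           value_range = c(0.2, 0.8), seed = NULL,
                           replications = 1L) {
  structure <- match.arg(structure)
  if (p < 3) stop("'p' must be >= 3")
  if (gamma < 0) stop("'gamma' must be >= 0")
  if (v_offdiag <= 0 || u_diag <= 0)
    stop("'v_offdiag' and 'u_diag' must be positive")
  if (replications < 1) stop("'replications' must be >= 1")
  out <- list(structure = structure, p = as.integer(p), n = as.integer(n),
              gamma = gamma, v_offdiag = v_offdiag, u_diag = u_diag,
              value_range = value_range, seed = seed,
              replications = as.integer(replications))
  class(out) <- "graph_scenario"
  out
}

#' @export
print.graph_scenario <- function(x, ...) {
  cat("Simulation scenario: ", x$structure, " graph, p = ", x$p,
      ", n = ", x$n, " per group, gamma = ", x$gamma, "\n", sep = "")
  invisible(x)
}

#' Simulate a paired two-condition dataset
#'
#' Runs the four-step simulation design for a scenario: (1) draw the common
#' graph and its precision matrix, (2, 3) inject `round(gamma * M)`
#' group-specific edges into each of the two copies, (4) sample the two
#' Gaussian data matrices from the inverse precision matrices.
#'
#' @param scenario A [graph_scenario()].
#' @return An object of class `"simulated_pair"`: a list with `omega1`,
#'   `omega2`, `common_support` and `diff_support` (2-column index
#'   matrices, i < j), data matrices `data1`, `data2` (n x p, genes
#'   `g1..gp`), and the scenario.
#' @examples
#' pair <- simulate_pair(graph_scenario("hub", 20, 30, 0.5, seed = 1))
#' dim(pair$data1)
#' nrow(pair$diff_support)
#' @export
simulate_pair <- function(scenario) {
  if (!inherits(scenario, "graph_scenario"))
    stop("'scenario' must be a graph_scenario")
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  adj <- generate_base_graph(scenario$structure, scenario$p)
  omega <- graph_to_precision(adj, scenario$v_offdiag, scenario$u_diag)
  pert <- heterogeneity_perturb(omega, scenario$gamma, scenario$value_range)
  genes <- paste0("g", seq_len(scenario$p))
  dimnames(pert$omega1) <- dimnames(pert$omega2) <- list(genes, genes)
  data1 <- sample_gaussian(pert$omega1, scenario$n)
  data2 <- sample_gaussian(pert$omega2, scenario$n)
  up_cells <- which(upper.tri(adj) & adj)
  out <- list(omega1 = pert$omega1, omega2 = pert$omega2,
              common_support = arrayInd(up_cells, dim(adj)),
              diff_support = pert$diff_support,
              perturbed1 = pert$perturbed1, perturbed2 = pert$perturbed2,
              collisions = pert$collisions, shift = pert$shift,
              data1 = data1, data2 = data2, scenario = scenario)
  class(out) <- "simulated_pair"
  out
}

#' @export
print.simulated_pair <- function(x, ...) {
  print(x$scenario)
  cat("  common edges: ", nrow(x$common_support),
      ";  differential entries: ", nrow(x$diff_support), "\n", sep = "")
  invisible(x)
}
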