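# Independent reference implementations used to cross-check the package.

# scaled-lasso objective L(beta, sigma)
sl_objective <- function(x, y, beta, sigma, lambda0) {
  n <- length(y)
  sum((y - x %*% beta)^2) / (2 * n * sigma) + sigma / 2 +
    lambda0 * sum(abs(beta))
}

# profiling out sigma = ||y - X b|| / sqrt(n) gives the square-root-lasso
# form; minimized by chained Nelder-Mead restarts from two fixed starts
oracle_sl_min <- function(x, y, lambda0) {
  n <- length(y)
  profile <- function(b) sqrt(sum((y - x %*% b)^2) / n) +
    lambda0 * sum(abs(b))
  best <- Inf
  for (start in list(rep(0, ncol(x)), qr.solve(x, y))) {
    cur <- start
    for (i in 1:6) {
      o <- optim(cur, profile, method = "Nelder-Mead",
                 control = list(maxit = 2e4, reltol = 1e-15))
      cur <- o$par
    }
    best <- min(best, profile(cur))
  }
  best
}

# dense-grid search for the FDR threshold
oracle_grid_threshold <- function(W, alpha, npts = 1e5) {
  p <- ncol(W)
  m <- p * (p - 1) / 2
  L <- 2 * sqrt(log(p))
  aw <- abs(W[upper.tri(W)])
  ts <- seq(0, L, length.out = npts)
  for (t in ts) {
    if (2 * (1 - pnorm(t)) * m / max(sum(aw >= t), 1) <= alpha) return(t)
  }
  L
}

# O(n^2) pairwise-concordance AUC
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# breadth-first-search connected components over an edge data frame
oracle_components <- function(edges) {
  nodes <- unique(c(as.character(edges[[1]]), as.character(edges[[2]])))
  nbr <- lapply(setNames(nodes, nodes), function(x) character(0))
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges[r, 1]); b <- as.character(edges[r, 2])
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- character(0)
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in nbr[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# elementwise partial correlations
oracle_pcor <- function(omega) {
  p <- ncol(omega)
  out <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j)
      out[i, j] <- -omega[i, j] / sqrt(omega[i, i] * omega[j, j])
  }
  out
}

# design with centered columns of unit root-mean-square
make_std_design <- function(n, k) {
  x <- matrix(rnorm(n * k), n, k)
  xc <- sweep(x, 2, colMeans(x))
  sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
}

# chain (tridiagonal) adjacency
chain_adj <- function(p) {
  adj <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}

# minimal precision_estimate for formula-level tests of w_statistics
make_est <- function(omega, dpair, n, genes = paste0("g", seq_len(ncol(omega)))) {
  structure(list(omega = omega, pair_diag = dpair, n = n,
                 gene_names = genes,
                 nonestimable = matrix(FALSE, ncol(omega), ncol(omega))),
            class = "precision_estimate")
}
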