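#' Two-sample test statistics for precision-matrix entries
#'
#' For every pair (i, j), tests \eqn{H_{0,ij}: \omega_{ij,1} = \omega_{ij,2}}
#' with the asymptotically standard-normal statistic
#' \deqn{W_{ij} = \frac{\hat\omega_{ij,1} - \hat\omega_{ij,2}}
#'   {\sqrt{(\hat\omega_{ii,1}\hat\omega_{jj,1} + \hat\omega_{ij,1}^2)/n_1 +
#'          (\hat\omega_{ii,2}\hat\omega_{jj,2} + \hat\omega_{ij,2}^2)/n_2}}.}
#' The denominator uses each group's per-pair diagonal estimates (pairwise
#' mode) or the global diagonal estimates (nodewise mode), matching how the
#' entries themselves were estimated.
#'
#' @param est1,est2 Objects of class `"precision_estimate"` over the same
#'   genes in the same order.
#' @return Symmetric p x p matrix of W statistics with zero diagonal.
#'   Pairs flagged non-estimable in either group carry `W = 0`.
#' @examples
#' set.seed(1)
#' om <- graph_to_precision(generate_base_graph("random", 10))
#' e1 <- estimate_precision(sample_gaussian(om, 60))
#' e2 <- estimate_precision(sample_gaussian(om, 60))
#' range(w_statistics(e1, e2))
#' @export
w_statistics <- function(est1, est2) {
  if (!inherits(est1, "precision_estimate") ||
      !inherits(est2, "precision_estimate"))
    stop("'est1' and 'est2' must be precision_estimate objects")
  if (!identical(est1$gene_names, est2$gene_names))
    stop("gene names of the two estimates do not match")
  if (est1$n < 4L || est2$n < 4L) stop("both sample sizes must be >= 4")
  v1 <- t(est1$pair_diag) * est1$pair_diag + est1$omega^2
  v2 <- t(est2$pair_diag) * est2$pair_diag + est2$omega^2
  W <- (est1$omega - est2$omega) / sqrt(v1 / est1$n + v2 / est2$n)
  diag(W) <- 0
  bad <- est1$nonestimable | est2$nonestimable
  W[bad] <- 0
  dimnames(W) <- list(est1$gene_names, est1$gene_names)
  W
}

#' FDR threshold for a matrix of test statistics
#'
#' Finds the smallest threshold t at which the estimated false discovery
#' proportion among edges with \eqn{|W_{ij}| \ge t} falls below `alpha`:
#' \deqn{\hat t = \inf\{0 \le t \le 2\sqrt{\log p} :
#'   \frac{2(1 - \Phi(t)) \cdot p(p-1)/2}{\max(R(t), 1)} \le \alpha\},}
#' where \eqn{R(t)} counts the pairs with \eqn{|W_{ij}| \ge t}. If no such t
#' exists, \eqn{\hat t = 2\sqrt{\log p}}. Thresholding the statistics
#' directly (rather than Benjamini-Hochberg on p-values) remains valid under
#' the weak dependence natural to graphical-model estimates.
#'
#' The infimum is computed exactly: within each interval between consecutive
#' observed \eqn{|W_{ij}|} values, \eqn{R(t)} is constant and the criterion
#' reduces to a closed-form normal quantile, so the overall infimum is the
#' smallest admissible point across intervals.
#'
#' @param W Symmetric finite matrix of test statistics.
#' @param alpha FDR level in (0, 1].
#' @return The threshold, a scalar in \eqn{[0, 2\sqrt{\log p}]}.
#' @examples
#' W <- matrix(0, 50, 50)
#' fdr_threshold(W, 0.05)       # no signal: upper bound 2*sqrt(log(50))
#' @export
fdr_threshold <- function(W, alpha = 0.05) {
  W <- as.matrix(W)
  if (anyNA(W) || any(!is.finite(W))) stop("'W' must be finite")
  if (!isSymmetric(unname(W), tol = 1e-8)) stop("'W' must be symmetric")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]")
  p <- ncol(W)
  m <- p * (p - 1) / 2
  L <- 2 * sqrt(log(p))
  aw <- abs(W[upper.tri(W)])

  if (2 * (1 - pnorm(0)) * m / max(sum(aw >= 0), 1L) <= alpha) return(0)

  cand <- sort(unique(c(0, aw[aw <= L])))
  K <- length(cand)
  for (k in seq_len(K)) {
    lo <- cand[k]
    if (k < K) {
      hi <- cand[k + 1L]
      Rk <- sum(aw >= hi)
    } else {
      hi <- L
      Rk <- sum(aw > lo)
    }
    if (hi <= lo) next
    q <- alpha * max(Rk, 1L) / (2 * m)
    tstar <- if (q >= 0.5) 0 else qnorm(1 - q)
    if (tstar <= hi) return(max(lo, tstar))
  }
  L
}

#' Extract the differential network above a threshold
#'
#' Lists the gene pairs whose statistic clears the rejection threshold,
#' sorted by decreasing \eqn{|W_{ij}|} (ties broken by row/column index).
#'
#' @param W Symmetric matrix of test statistics.
#' @param t_hat Nonnegative rejection threshold, typically from
#'   [fdr_threshold()].
#' @param gene_names Optional length-p labels; defaults to the dimnames of
#'   `W` or `V1..Vp`.
#' @param pvalue Optional matrix of p-values aligned with `W`; defaults to
#'   the two-sided normal tail of `W`.
#' @return A data frame with columns `gene_i`, `gene_j`, `W`, `pvalue`, one
#'   row per rejected pair (i < j).
#' @export
differential_network <- function(W, t_hat, gene_names = NULL, pvalue = NULL) {
  W <- as.matrix(W)
  if (!is.numeric(t_hat) || length(t_hat) != 1L || t_hat < 0)
    stop("'t_hat' must be a nonnegative scalar")
  p <- ncol(W)
  if (is.null(gene_names)) gene_names <- colnames(W)
  if (is.null(gene_names)) gene_names <- paste0("V", seq_len(p))
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(W))
  up <- which(upper.tri(W), arr.ind = TRUE)
  keep <- abs(W[up]) >= t_hat
  up <- up[keep, , drop = FALSE]
  w <- W[up]
  pv <- pvalue[up]
  ord <- order(-abs(w), up[, 1L], up[, 2L])
  data.frame(gene_i = gene_names[up[ord, 1L]],
             gene_j = gene_names[up[ord, 2L]],
             W = w[ord], pvalue = pv[ord],
             stringsAsFactors = FALSE)
}

#' Connected clusters of a differential network
#'
#' Maximal connected components of the rejected-edge graph with at least
#' `min_size` nodes, largest first.
#'
#' @param edges Data frame whose first two columns name the endpoints of
#'   each edge (e.g. the output of [differential_network()]).
#' @param min_size Minimum number of nodes for a component to be reported.
#' @return A list of character vectors of node names, sorted by decreasing
#'   size (ties by first node name).
#' @export
network_clusters <- function(edges, min_size = 10L) {
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(v) sort(v))
  members <- members[lengths(members) >= min_size]
  if (length(members) == 0L) return(list())
  ord <- order(-lengths(members), vapply(members, `[`, "", 1L))
  unname(members[ord])
}

#' Differential network analysis between two conditions
#'
#' Fits the full two-sample differential-network procedure: estimates each
#' condition's precision matrix entrywise by scaled-lasso regression
#' ([estimate_precision()]), forms the entrywise two-sample statistics
#' ([w_statistics()]), picks the FDR rejection threshold
#' ([fdr_threshold()]), and reports the rejected edges and their connected
#' clusters.
#'
#' @param x,y Numeric matrices, samples in rows and the same genes in
#'   columns, one per condition (e.g. tumor and normal).
#' @param alpha FDR level for edge rejection.
#' @param mode Estimation mode, `"pairwise"` (default) or `"nodewise"`;
#'   see [estimate_precision()].
#' @param lambda0 Base scaled-lasso penalty; default `sqrt(2 * log(p) / n)`
#'   per condition.
#' @param min_cluster Minimum node count for a reported cluster.
#' @param ... Further arguments passed to [estimate_precision()].
#'
#' @return An object of class `"diffnet"`: a list with the two
#'   `precision_estimate`s (`est1`, `est2`), the statistic matrix `W`, its
#'   two-sided p-values `pvalue`, the entrywise difference `delta`, the
#'   threshold `t_hat`, `alpha`, the logical rejected-edge `adjacency`, the
#'   annotated edge table `edges` (per-group precision entries, their
#'   p-values, partial correlations and their p-values, then `W` and its
#'   p-value), the `clusters` list, and sample sizes `n1`, `n2`.
#'
#' @examples
#' set.seed(7)
#' sc <- graph_scenario("random", p = 30, n = 60, gamma = 0.5)
#' pair <- simulate_pair(sc)
#' fit <- diffnet(pair$data1, pair$data2, alpha = 0.1)
#' fit
#' head(fit$edges)
#' @export
diffnet <- function(x, y, alpha = 0.05, mode = c("pairwise", "nodewise"),
                    lambda0 = NULL, min_cluster = 10L, ...) {
  mode <- match.arg(mode)
  cl <- match.call()
  est1 <- estimate_precision(x, mode = mode, lambda0 = lambda0, ...)
  est2 <- estimate_precision(y, mode = mode, lambda0 = lambda0, ...)
  W <- w_statistics(est1, est2)
  t_hat <- fdr_threshold(W, alpha)
  pvalue <- 2 * pnorm(-abs(W))
  diag(pvalue) <- 1
  genes <- est1$gene_names
  edges <- differential_network(W, t_hat, genes, pvalue)

  idx <- cbind(match(edges$gene_i, genes), match(edges$gene_j, genes))
  pcp1 <- partial_corr_pvalues(est1$partial_corr, est1$n)
  pcp2 <- partial_corr_pvalues(est2$partial_corr, est2$n)
  edges <- data.frame(
    gene_i = edges$gene_i, gene_j = edges$gene_j,
    omega1 = est1$omega[idx], p1 = est1$pvalue[idx],
    pcor1 = est1$partial_corr[idx], pcor_p1 = pcp1[idx],
    omega2 = est2$omega[idx], p2 = est2$pvalue[idx],
    pcor2 = est2$partial_corr[idx], pcor_p2 = pcp2[idx],
    W = edges$W, pvalue = edges$pvalue,
    stringsAsFactors = FALSE)

  adjacency <- abs(W) >= t_hat
  diag(adjacency) <- FALSE

  out <- list(call = cl, est1 = est1, est2 = est2, W = W, pvalue = pvalue,
              delta = est1$omega - est2$omega, alpha = alpha, t_hat = t_hat,
              adjacency = adjacency, edges = edges,
              clusters = network_clusters(edges, min_cluster),
              min_cluster = min_cluster, n1 = est1$n, n2 = est2$n,
              gene_names = genes, mode = mode)
  class(out) <- "diffnet"
  out
}

#' @export
print.diffnet <- function(x, ...) {
  p <- length(x$gene_names)
  nodes <- unique(c(x$edges$gene_i, x$edges$gene_j))
  cat("Differential network analysis (", x$mode, " mode)\n", sep = "")
  cat("  genes: ", p, ";  samples: n1 = ", x$n1, ", n2 = ", x$n2, "\n",
      sep = "")
  cat("  FDR level alpha = ", x$alpha, ";  threshold t_hat = ",
      format(x$t_hat, digits = 4), "\n", sep = "")
  cat("  rejected edges: ", nrow(x$edges), " over ", length(nodes),
      " nodes;  clusters (>= ", x$min_cluster, " nodes): ",
      length(x$clusters), "\n", sep = "")
  invisible(x)
}

#' @export
summary.diffnet <- function(object, n_top = 10L, ...) {
  print(object)
  if (nrow(object$edges) > 0L) {
    cat("\nTop differential edges:\n")
    print(head(object$edges, n_top), digits = 4, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.diffnet <- function(object, ...) object$delta

#' Plot a differential network
#'
#' Draws the rejected-edge graph; edge widths are proportional to
#' \eqn{|W_{ij}|} and node sizes to degree.
#'
#' @param x A `"diffnet"` object.
#' @param cluster_only Plot only nodes belonging to reported clusters.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.diffnet <- function(x, cluster_only = FALSE, ...) {
  edges <- x$edges
  if (cluster_only && length(x$clusters) > 0L) {
    keep <- unlist(x$clusters)
    edges <- edges[edges$gene_i %in% keep & edges$gene_j %in% keep, ,
                   drop = FALSE]
  }
  if (nrow(edges) == 0L) {
    plot.new()
    title(main = "Empty differential network")
    return(invisible(NULL))
  }
  g <- igraph::graph_from_data_frame(edges[, c("gene_i", "gene_j")],
                                     directed = FALSE)
  w <- abs(edges$W)
  igraph::E(g)$width <- 0.5 + 2.5 * w / max(w)
  deg <- igraph::degree(g)
  igraph::V(g)$size <- 4 + 8 * deg / max(deg)
  igraph::plot.igraph(g, vertex.label.cex = 0.6, ...)
  invisible(g)
}
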