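#' Entrywise precision-matrix estimation with asymptotic inference
#'
#' Estimates the precision matrix (inverse covariance) of a Gaussian
#' graphical model entry by entry through scaled-lasso regressions, and
#' attaches to every off-diagonal entry its estimated Fisher information,
#' z-score and two-sided p-value, together with the matrix of partial
#' correlations.
#'
#' For an index pair A = \{i, j\}, regressing the two columns on the
#' remaining ones and inverting the 2x2 residual Gram matrix
#' \eqn{(\frac1n \hat\epsilon_A' \hat\epsilon_A)^{-1}} yields estimates of
#' \eqn{\omega_{ii}, \omega_{ij}, \omega_{jj}}. The estimator is
#' asymptotically normal,
#' \eqn{\sqrt{n \hat F_{ij}} (\hat\omega_{ij} - \omega_{ij}) \to N(0, 1)}
#' with Fisher information
#' \eqn{\hat F_{ij} = (\hat\omega_{ii}\hat\omega_{jj} + \hat\omega_{ij}^2)^{-1}},
#' which gives the edge z-scores and p-values.
#'
#' Two modes are available. `"pairwise"` (the default, faithful to the
#' construction above) excludes the partner column from every regression;
#' the full node-wise fit warm-starts each exclusion, so the cost stays
#' close to p regressions. `"nodewise"` runs only the p regressions of each
#' column on all others and forms every pair's 2x2 Gram from those
#' residuals; this is an approximation (the partner column is not excluded)
#' that is faster for large p, with per-pair diagonals replaced by the
#' global estimates \eqn{1 / (\|\hat\epsilon_i\|^2 / n)}.
#'
#' @param x Numeric matrix, samples in rows, genes in columns (n >= 4,
#'   p >= 2). Columns are centered (and scaled) internally; estimates are
#'   returned on the original scale.
#' @param mode `"pairwise"` or `"nodewise"` (see Details).
#' @param lambda0 Base scaled-lasso penalty; default `sqrt(2 * log(p) / n)`
#'   with p the number of columns of `x`.
#' @param tol,max_iter Convergence controls passed to the scaled-lasso
#'   solver.
#' @param printed_variance Compatibility flag: use the variance form
#'   \eqn{\omega_{ii}\omega_{jj} + \omega_{jj}^2} instead of the
#'   Fisher-information form \eqn{\omega_{ii}\omega_{jj} + \omega_{ij}^2}.
#'   Default `FALSE`.
#'
#' @return An object of class `"precision_estimate"`: a list with components
#'   `omega` (symmetric p x p estimate; the diagonal is the average of the
#'   per-pair diagonal estimates in pairwise mode), `fisher_info`,
#'   `partial_corr`, `z`, `pvalue`, `n`, `gene_names`, `mode`, `lambda0`,
#'   `pair_diag` (p x p matrix whose (a, b) entry is pair \{a, b\}'s
#'   estimate of \eqn{\omega_{aa}}), and `nonestimable` (logical matrix
#'   flagging pairs whose residual Gram matrix was numerically singular;
#'   those entries carry `omega = 0` and `pvalue = 1`).
#'
#' @examples
#' set.seed(1)
#' x <- sample_gaussian(graph_to_precision(generate_base_graph("random", 10)), 80)
#' est <- estimate_precision(x)
#' est
#' est$pvalue[1:4, 1:4]
#' @seealso [diffnet()], [partial_correlations()], [w_statistics()]
#' @export
estimate_precision <- function(x, mode = c("pairwise", "nodewise"),
                               lambda0 = NULL, tol = 1e-6, max_iter = 100L,
                               printed_variance = FALSE) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be a finite numeric matrix")
  n <- nrow(x)
  p <- ncol(x)
  if (n <= 3L) stop("at least 4 samples are required (n = ", n, ")")
  if (p < 2L) stop("at least 2 variables are required")
  genes <- colnames(x)
  if (is.null(genes)) genes <- paste0("V", seq_len(p))
  if (anyDuplicated(genes)) stop("gene names must be unique")
  if (is.null(lambda0)) lambda0 <- sqrt(2 * log(p) / n)
  if (!is.numeric(lambda0) || length(lambda0) != 1L || lambda0 <= 0)
    stop("'lambda0' must be a positive scalar")

  xc <- sweep(x, 2L, colMeans(x), "-")
  s <- sqrt(colMeans(xc^2))
  if (any(s == 0))
    stop("zero-variance column(s): ", paste(genes[s == 0], collapse = ", "))

  if (p == 2L) {
    omega <- solve(crossprod(xc) / n)
    dpair <- matrix(0, 2, 2)
    dpair[1, 2] <- omega[1, 1]
    dpair[2, 1] <- omega[2, 2]
    bad <- matrix(FALSE, 2, 2)
  } else {
    xs <- sweep(xc, 2L, s, "/")
    if (mode == "pairwise") {
      fit <- cpp_ggm_pairwise(xs, lambda0, tol, as.integer(max_iter))
      omega <- fit$omega
      dpair <- fit$dpair
      bad <- fit$bad > 0
    } else {
      fit <- cpp_ggm_nodewise(xs, lambda0, tol, as.integer(max_iter))
      G <- crossprod(fit$residuals) / n
      gd <- diag(G)
      det2 <- outer(gd, gd) - G^2
      bad <- det2 <= 1e-12
      diag(bad) <- FALSE
      omega <- ifelse(bad, 0, -G / det2)
      diag(omega) <- 0
      dpair <- matrix(1 / gd, p, p)  # global diagonals, recycled along rows
      diag(dpair) <- 0
    }
    # back to the original data scale: omega_std = D Omega D with D = diag(s)
    sinv <- 1 / s
    omega <- omega * tcrossprod(sinv)
    dpair <- dpair * sinv^2  # row a carries estimates of omega_aa
    if (any(bad)) {
      omega[bad] <- 0
      nb <- sum(bad[upper.tri(bad)])
      warning(nb, " pair(s) had a numerically singular residual Gram matrix;",
              " flagged non-estimable with p-value 1")
    }
    offdiag_ok <- !bad
    diag(offdiag_ok) <- FALSE
    diag(omega) <- rowSums(dpair * offdiag_ok) / pmax(rowSums(offdiag_ok), 1L)
    # nodes with no estimable pair fall back to the marginal precision
    # (1 / sample variance), keeping the diagonal strictly positive
    orphan <- rowSums(offdiag_ok) == 0L
    if (any(orphan)) diag(omega)[orphan] <- 1 / s[orphan]^2
  }

  d1 <- dpair
  d2 <- t(dpair)
  if (printed_variance) {
    # legacy form: omega_jj^2 with j the column-larger index of each pair
    upper_d2 <- d2
    vmat <- d1 * d2 + ifelse(upper.tri(d1), upper_d2^2, t(upper_d2)^2)
  } else {
    vmat <- d1 * d2 + omega^2
  }
  diag(vmat) <- NA_real_
  fisher <- 1 / vmat
  z <- sqrt(n) * omega / sqrt(vmat)
  diag(z) <- 0
  z[bad] <- 0
  pvalue <- 2 * pnorm(-abs(z))
  diag(pvalue) <- 1
  pvalue[bad] <- 1

  pc <- partial_correlations(omega)

  dimnames(omega) <- dimnames(pc) <- dimnames(z) <-
    dimnames(pvalue) <- dimnames(fisher) <- list(genes, genes)
  out <- list(omega = omega, fisher_info = fisher, partial_corr = pc,
              z = z, pvalue = pvalue, n = n, gene_names = genes,
              mode = mode, lambda0 = lambda0, pair_diag = dpair,
              nonestimable = bad)
  class(out) <- "precision_estimate"
  out
}

#' @export
print.precision_estimate <- function(x, ...) {
  p <- length(x$gene_names)
  cat("Precision-matrix estimate (", x$mode, " mode): p = ", p,
      " genes, n = ", x$n, " samples, lambda0 = ",
      format(x$lambda0, digits = 4), "\n", sep = "")
  sig <- sum(x$pvalue[upper.tri(x$pvalue)] < 0.05)
  cat("Edges with p < 0.05 (unadjusted): ", sig, " of ", p * (p - 1) / 2,
      "\n", sep = "")
  invisible(x)
}

#' Partial correlations from a precision matrix
#'
#' Converts a precision matrix to partial correlations,
#' \eqn{\gamma_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\omega_{jj}}}, with
#' unit diagonal.
#'
#' @param omega Symmetric numeric matrix with strictly positive diagonal.
#' @return Symmetric matrix of partial correlations.
#' @examples
#' partial_correlations(matrix(c(1, -0.5, -0.5, 1), 2))
#' @export
partial_correlations <- function(omega) {
  omega <- as.matrix(omega)
  if (!isSymmetric(unname(omega), tol = 1e-8))
    stop("'omega' must be symmetric")
  d <- diag(omega)
  if (any(d <= 0)) stop("'omega' must have strictly positive diagonal")
  pc <- -omega / sqrt(outer(d, d))
  diag(pc) <- 1
  if (any(abs(pc) > 1)) {
    if (any(abs(pc) > 1 + 1e-8))
      warning("partial correlations outside [-1, 1] were clamped")
    pc <- pmin(pmax(pc, -1), 1)
  }
  pc
}

#' P-values for partial correlations
#'
#' Two-sided normal p-values for the null of zero partial correlation, using
#' the asymptotic result
#' \eqn{\sqrt{n (1 - \hat\gamma^2)^{-2}} (\hat\gamma - \gamma) \to N(0, 1)},
#' i.e. \eqn{z = \sqrt{n}\, \hat\gamma / (1 - \hat\gamma^2)}.
#'
#' @param partial_corr Matrix (or vector) of partial correlations.
#' @param n Sample size.
#' @return Object of the same shape with two-sided p-values; diagonal (if a
#'   matrix) set to 1. Entries with \eqn{|\hat\gamma| = 1} get p-value 0
#'   with a saturation warning.
#' @examples
#' partial_corr_pvalues(0.5, 64)
#' @export
partial_corr_pvalues <- function(partial_corr, n) {
  g <- partial_corr
  if (any(abs(g) > 1, na.rm = TRUE))
    stop("partial correlations must lie in [-1, 1]")
  sat <- abs(g) == 1 & (if (is.matrix(g)) row(g) != col(g) else TRUE)
  if (any(sat)) warning("|partial correlation| = 1: p-value saturated at 0")
  z <- sqrt(n) * g / (1 - g^2)
  pv <- 2 * pnorm(-abs(z))
  pv[sat] <- 0
  if (is.matrix(g)) {
    diag(pv) <- 1
    dimnames(pv) <- dimnames(g)
  }
  pv
}
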