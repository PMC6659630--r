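#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form of the AUC: the probability that a randomly
#' chosen positive outscores a randomly chosen negative, with ties counted
#' one half. When ranking edges by p-value, pass `1 - p` (or the absolute
#' statistic) so that smaller p-values score higher.
#'
#' @param scores Numeric vector of scores (larger = more positive).
#' @param truth Logical vector of the same length with at least one `TRUE`
#'   and one `FALSE`.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(3, 2, 1), c(TRUE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("lengths differ")
  if (anyNA(scores) || any(!is.finite(scores)) || anyNA(truth))
    stop("'scores' must be finite and 'truth' free of NA")
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("undefined AUC: 'truth' needs both classes")
  rk <- rank(scores)
  (sum(rk[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the simulation study
#'
#' For each scenario and replicate: simulate a paired dataset, estimate both
#' precision matrices, score recovery of each group's true edge support by
#' the AUC of the edge p-values (averaged over the two groups, or pooled),
#' then form the two-sample statistics and score recovery of the true
#' differential support by the AUC of \eqn{|W_{ij}|}. Reports per-scenario
#' mean AUCs with Monte-Carlo standard errors.
#'
#' Each replicate runs on its own deterministic RNG substream derived from
#' `seed`, so results are reproducible and independent of evaluation order.
#' A failed replicate is dropped with a message and counted in `failed`.
#'
#' @param scenarios A [graph_scenario()] or list of them. Scenarios must
#'   have `gamma > 0` (otherwise the differential truth is empty and the
#'   AUC undefined).
#' @param reps Replications per scenario.
#' @param mode Estimation mode passed to [estimate_precision()].
#' @param seed Integer master seed.
#' @param lambda0 Optional penalty override.
#' @param pool_groups Pool both groups' edges into one ROC instead of
#'   averaging two AUCs.
#' @return A data frame with one row per scenario: the scenario parameters,
#'   `auc_group`, `auc_group_se`, `auc_diff`, `auc_diff_se`, `reps_done`,
#'   `failed`.
#' @examples
#' \donttest{
#' sc <- graph_scenario("random", p = 40, n = 50, gamma = 0.25)
#' run_simulation_study(sc, reps = 3, mode = "nodewise", seed = 1)
#' }
#' @export
run_simulation_study <- function(scenarios, reps = 20L,
                                 mode = c("pairwise", "nodewise"),
                                 seed = 1L, lambda0 = NULL,
                                 pool_groups = FALSE) {
  mode <- match.arg(mode)
  if (inherits(scenarios, "graph_scenario")) scenarios <- list(scenarios)
  if (reps < 1L) stop("'reps' must be >= 1")
  for (sc in scenarios) {
    if (!inherits(sc, "graph_scenario"))
      stop("'scenarios' must be graph_scenario objects")
    if (sc$gamma <= 0)
      stop("degenerate truth: gamma = 0 leaves no differential edges, ",
           "so the differential AUC is undefined")
  }
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(scenarios) * reps),
                      nrow = reps)

  rows <- lapply(seq_along(scenarios), function(si) {
    sc <- scenarios[[si]]
    sc$seed <- NULL
    ag <- ad <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      res <- tryCatch({
        set.seed(rep_seeds[r, si])
        pair <- simulate_pair(sc)
        est1 <- estimate_precision(pair$data1, mode = mode,
                                   lambda0 = lambda0)
        est2 <- estimate_precision(pair$data2, mode = mode,
                                   lambda0 = lambda0)
        up <- upper.tri(pair$omega1)
        truth1 <- pair$omega1[up] != 0
        truth2 <- pair$omega2[up] != 0
        s1 <- 1 - est1$pvalue[up]
        s2 <- 1 - est2$pvalue[up]
        a_g <- if (pool_groups) roc_auc(c(s1, s2), c(truth1, truth2))
               else (roc_auc(s1, truth1) + roc_auc(s2, truth2)) / 2
        W <- w_statistics(est1, est2)
        truth_d <- (pair$omega1 != pair$omega2)[up]
        c(a_g, roc_auc(abs(W[up]), truth_d))
      }, error = function(e) {
        message("replicate ", r, " of scenario ", si, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) { ag[r] <- res[1L]; ad[r] <- res[2L] }
    }
    ok <- !is.na(ag)
    data.frame(structure = sc$structure, p = sc$p, n = sc$n,
               gamma = sc$gamma,
               auc_group = mean(ag[ok]),
               auc_group_se = sd(ag[ok]) / sqrt(sum(ok)),
               auc_diff = mean(ad[ok]),
               auc_diff_se = sd(ad[ok]) / sqrt(sum(ok)),
               reps_done = sum(ok), failed = sum(!ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
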