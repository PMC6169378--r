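#' Maximize a linear-mixture log-likelihood over the probability simplex
#'
#' Workhorse for all Delta estimation: given a per-locus conditional
#' probability matrix `B` (loci x states), maximizes
#' `sum_l log(B[l, ] %*% delta)` subject to `delta >= 0`, `sum(delta) = 1`,
#' optionally restricted to a subset of states (the rest pinned to 0).
#'
#' Because the objective is concave on the simplex, the multiplicative EM
#' update `delta_s <- mean_l( B_ls delta_s / sum_s' B_ls' delta_s' )`
#' converges to the global constrained maximum; convergence is verified via
#' the KKT conditions (gradient equal on the support, no ascent direction off
#' it). Multiple starts (uniform plus Dirichlet(1) draws) are retained as a
#' safeguard and the best kept.
#'
#' @param B numeric matrix, `L x S`.
#' @param active integer indices of free states (columns of `B` already
#'   subset by the caller map 1:S here).
#' @param n_starts number of starting points.
#' @param seed integer seed for the random starts.
#' @param tol KKT residual tolerance.
#' @param max_iter iteration cap per start.
#' @return list `delta` (length S), `loglik`, `converged`, `kkt`,
#'   `start_logliks` (log-likelihood at each initial point).
#' @keywords internal
fit_delta_simplex <- function(B, n_starts = 5L, seed = 1L, tol = 1e-8,
                              max_iter = 20000L) {
  L <- nrow(B); S <- ncol(B)
  loglik_at <- function(d) {
    v <- as.vector(B %*% d)
    if (any(v <= 0)) return(-Inf)
    sum(log(v))
  }
  kkt_residual <- function(d) {
    v <- as.vector(B %*% d)
    g <- colSums(B / v)               # gradient; at optimum g_s = L on support
    on <- d > 1e-9
    max(c(abs(g[on] - L), pmax(g[!on] - L, 0))) / L
  }
  run <- function(d) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      v <- as.vector(B %*% d)
      if (any(v <= 0)) {              # start inconsistent with structural zeros
        d <- rep(1 / S, S)
        v <- as.vector(B %*% d)
      }
      w <- B * (rep(1, L) %o% d) / v  # L x S responsibilities
      d_new <- colMeans(w)
      d_new[d_new < 1e-15] <- 0
      d_new <- d_new / sum(d_new)
      d <- d_new
      if (it %% 50L == 0L || it == max_iter) {
        ll <- loglik_at(d)
        if (kkt_residual(d) < tol) break
        if (ll - ll_old < 1e-14 && it > 200L) break
        ll_old <- ll
      }
    }
    d
  }
  set.seed(seed)
  starts <- c(list(rep(1 / S, S)),
              lapply(seq_len(max(n_starts - 1L, 0L)), function(.) {
                g <- stats::rgamma(S, 1)
                g / sum(g)
              }))
  start_ll <- vapply(starts, loglik_at, numeric(1))
  best <- NULL; best_ll <- -Inf
  for (d0 in starts) {
    d <- run(d0)
    ll <- loglik_at(d)
    if (ll > best_ll) { best <- d; best_ll <- ll }
  }
  kkt <- kkt_residual(best)
  best[best < 1e-9] <- 0     # components below optimizer precision are zeros
  best <- best / sum(best)
  list(delta = best, loglik = best_ll, converged = kkt < 1e-6, kkt = kkt,
       start_logliks = start_ll)
}

#' Coancestry and relatedness from IBD coefficients
#'
#' `theta = Delta1 + (Delta3 + Delta5 + Delta7)/2 + Delta8/4` and
#' `r = 2 * theta`. No clamping is applied: with nonzero inbred states
#' (Delta1..Delta6) the relatedness can exceed 1.
#'
#' @param delta numeric vector of 9 IBD-state probabilities.
#' @return named numeric vector `c(theta = , r = )`.
#' @export
delta_to_relatedness <- function(delta) {
  stopifnot(length(delta) == 9)
  theta <- delta[1] + 0.5 * (delta[3] + delta[5] + delta[7]) + 0.25 * delta[8]
  c(theta = unname(theta), r = unname(2 * theta))
}

#' Maximum-likelihood IBD coefficients for a dyad
#'
#' Estimates the nine condensed IBD-state probabilities `Delta` for a pair of
#' individuals by constrained maximum likelihood over the unit simplex, using
#' the admixture-model conditional probabilities of [ibs_condprob()]. The
#' `"three_state"` variant assumes an outbred population and restricts the
#' support to `Delta7, Delta8, Delta9` (the first six states pinned to 0).
#'
#' @param pair integer vector of length 2 (individual row indices).
#' @param panel a [genotype_panel()].
#' @param Z an `allele_prob_table` from [compute_Z()].
#' @param variant `"nine_state"` (default) or `"three_state"`.
#' @param n_starts number of optimizer starts.
#' @param seed integer seed.
#' @param tol KKT residual tolerance.
#' @return object of class `relatedness_estimate`: fields `delta` (named
#'   9-vector), `theta`, `r`, `loglik`, `variant`, `converged`, `kkt`,
#'   `n_loci_used`, `pair`.
#' @export
estimate_delta <- function(pair, panel, Z,
                           variant = c("nine_state", "three_state"),
                           n_starts = 5L, seed = 1L, tol = 1e-8) {
  variant <- match.arg(variant)
  B <- dyad_condprob_matrix(pair, panel, Z)
  states <- if (variant == "three_state") 7:9 else 1:9
  fit <- fit_delta_simplex(B[, states, drop = FALSE], n_starts = n_starts,
                           seed = seed, tol = tol)
  delta <- stats::setNames(numeric(9), paste0("D", 1:9))
  delta[states] <- fit$delta
  tr <- delta_to_relatedness(delta)
  structure(list(delta = delta, theta = tr["theta"], r = tr["r"],
                 loglik = fit$loglik, variant = variant,
                 converged = fit$converged, kkt = fit$kkt,
                 n_loci_used = nrow(B), pair = pair),
            class = "relatedness_estimate")
}

#' @export
print.relatedness_estimate <- function(x, ...) {
  cat(sprintf("relatedness_estimate (%s), pair (%d, %d), %d loci\n",
              x$variant, x$pair[1], x$pair[2], x$n_loci_used))
  cat(sprintf("  theta = %.4f, r = %.4f, loglik = %.3f (converged: %s)\n",
              x$theta, x$r, x$loglik, x$converged))
  cat("  Delta:", paste(sprintf("%.3f", x$delta), collapse = " "), "\n")
  invisible(x)
}

#' Relatedness estimates for many dyads
#'
#' Runs [estimate_delta()] over a set of pairs and collects the results into
#' a data frame. Per-pair failures are reported as flagged rows (with `NA`
#' estimates), not errors.
#'
#' @param panel a [genotype_panel()].
#' @param fit an `admixture_fit` for the panel (used to compute Z).
#' @param pairs two-column matrix of individual indices, or `NULL` for all
#'   unordered pairs.
#' @param variant `"nine_state"` or `"three_state"`.
#' @param n_starts,seed,tol passed to [estimate_delta()].
#' @return data frame with columns `id1`, `id2`, `D1..D9`, `theta`, `r`,
#'   `loglik`, `n_loci`, `converged`.
#' @export
relatedness_matrix <- function(panel, fit, pairs = NULL,
                               variant = c("nine_state", "three_state"),
                               n_starts = 5L, seed = 1L, tol = 1e-8) {
  variant <- match.arg(variant)
  Z <- compute_Z(fit)
  if (is.null(pairs)) {
    idx <- utils::combn(panel$n_ind, 2)
    pairs <- t(idx)
  }
  pairs <- as.matrix(pairs)
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    pr <- as.integer(pairs[r, 1:2])
    est <- tryCatch(
      estimate_delta(pr, panel, Z, variant = variant, n_starts = n_starts,
                     seed = seed + r, tol = tol),
      error = function(e) NULL)
    if (is.null(est)) {
      rows[[r]] <- data.frame(id1 = panel$ids[pr[1]], id2 = panel$ids[pr[2]],
                              t(stats::setNames(rep(NA_real_, 9),
                                                paste0("D", 1:9))),
                              theta = NA_real_, r = NA_real_,
                              loglik = NA_real_, n_loci = NA_integer_,
                              converged = FALSE)
    } else {
      rows[[r]] <- data.frame(id1 = panel$ids[pr[1]], id2 = panel$ids[pr[2]],
                              t(est$delta), theta = unname(est$theta),
                              r = unname(est$r), loglik = est$loglik,
                              n_loci = est$n_loci_used,
                              converged = est$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
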