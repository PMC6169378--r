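#' Admixture-model fit objects
#'
#' Container for estimated population structure under the admixture model:
#' each allele copy of individual `i` is an independent draw from
#' subpopulation `k` with probability `eta[i, k]`, and then from that
#' subpopulation's allele-frequency vector `p[[l]][k, ]` at locus `l`.
#'
#' @param K number of subpopulations.
#' @param eta `I x K` matrix of ancestry proportions, rows on the simplex.
#' @param p list of length `L` of `K x A_l` allele-frequency matrices, rows
#'   on the simplex.
#' @param loglik_trace per-iteration log-likelihoods of the EM run.
#' @param converged logical convergence flag.
#' @param degenerate logical; `TRUE` when some cluster received (numerically)
#'   no ancestry weight.
#' @return object of class `admixture_fit`.
#' @keywords internal
new_admixture_fit <- function(K, eta, p, loglik_trace, converged,
                              degenerate = FALSE) {
  structure(list(K = as.integer(K), eta = eta, p = p,
                 loglik_trace = loglik_trace, converged = converged,
                 degenerate = degenerate),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: %d individuals, %d loci, K = %d\n",
              nrow(x$eta), length(x$p), x$K))
  if (length(x$loglik_trace))
    cat(sprintf("  log-likelihood %.4f after %d EM iterations (converged: %s)\n",
                utils::tail(x$loglik_trace, 1), length(x$loglik_trace),
                x$converged))
  if (isTRUE(x$degenerate))
    cat("  note: degenerate cluster(s) with ~zero total ancestry\n")
  invisible(x)
}

#' Admixture-model log-likelihood
#'
#' Evaluates the log of the admixture-model likelihood of the observed allele
#' counts: `sum_{i,l,a} n_ila * log(sum_k eta_ik * p_kla)`. Missing genotypes
#' (all-zero count rows) contribute nothing. A mixture probability of zero
#' paired with a positive count yields `-Inf` with a warning.
#'
#' @param counts an `allele_counts` object from [to_allele_counts()].
#' @param fit an `admixture_fit` (only `eta` and `p` are used).
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(counts, fit) {
  ll <- 0
  hit_zero <- FALSE
  for (l in seq_along(counts)) {
    n <- counts[[l]]                       # I x A
    mix <- fit$eta %*% fit$p[[l]]          # I x A mixture probabilities
    if (ncol(n) < ncol(mix)) {             # fit may carry never-observed alleles
      n <- cbind(n, matrix(0L, nrow(n), ncol(mix) - ncol(n)))
    } else if (ncol(n) > ncol(mix)) {
      stop(sprintf("locus %d: counts have %d alleles but fit has %d",
                   l, ncol(n), ncol(mix)))
    }
    pos <- n > 0L
    if (any(pos & mix <= 0)) hit_zero <- TRUE
    ll <- ll + sum(n[pos] * log(mix[pos]))
  }
  if (hit_zero)
    warning("zero mixture probability with positive allele count; log-likelihood is -Inf")
  ll
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of ancestry proportions and subpopulation
#' allele frequencies by expectation-maximization. The E-step computes the
#' responsibility of each subpopulation for each observed allele copy; the
#' M-step renormalizes ancestry by each individual's total number of
#' non-missing allele copies and allele frequencies by responsibility-weighted
#' allele tallies. The run stops when the log-likelihood increases by less
#' than `tol` (default 1e-6). Multiple random starts are used and the best
#' log-likelihood kept; at `K = 1` the closed-form MLE (observed sample
#' frequencies) is returned after a single verification step.
#'
#' Cluster labels are arbitrary (label switching): any permutation of the
#' columns of `eta` with the matching rows of `p` gives the same likelihood.
#'
#' @param counts an `allele_counts` object.
#' @param K number of subpopulations (the model is fit at this fixed K).
#' @param seed integer seed for the random starts.
#' @param tol EM convergence tolerance on the log-likelihood increase.
#' @param max_iter iteration cap per start.
#' @param n_starts number of random restarts.
#' @return an `admixture_fit`.
#' @export
fit_admixture <- function(counts, K, seed = 1L, tol = 1e-6,
                          max_iter = 2000L, n_starts = 5L) {
  stopifnot(K >= 1L, length(counts) >= 1L)
  I <- attr(counts, "n_ind")
  L <- length(counts)
  # per-individual number of observed allele copies
  copies <- rowSums(vapply(counts, rowSums, numeric(I)))
  if (any(copies == 0))
    warning("individual(s) with no observed genotypes; their eta is uniform")

  glob <- lapply(counts, function(n) {
    f <- colSums(n)
    if (sum(f) == 0) rep(1 / ncol(n), ncol(n)) else f / sum(f)
  })

  if (K == 1L) {
    eta <- matrix(1, I, 1)
    p <- lapply(glob, function(f) matrix(f, 1))
    fit <- new_admixture_fit(1L, eta, p, numeric(0), TRUE)
    fit$loglik_trace <- admixture_loglik(counts, fit)
    return(fit)
  }

  floor_renorm <- function(m, eps = 1e-9) {
    m[m < eps] <- eps
    m / rowSums(m)
  }

  run_one <- function() {
    eta <- matrix(stats::rgamma(I * K, 1), I, K)
    eta <- eta / rowSums(eta)
    p <- lapply(glob, function(f) {
      m <- matrix(rep(f, each = K), K) *
        matrix(stats::rgamma(K * length(f), 20, 20), K)
      floor_renorm(m)
    })
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      eta_num <- matrix(0, I, K)
      p_new <- vector("list", L)
      ll <- 0
      for (l in seq_len(L)) {
        n <- counts[[l]]
        pl <- p[[l]]                      # K x A
        mix <- eta %*% pl                 # I x A
        pos <- n > 0L
        ll <- ll + sum(n[pos] * log(pmax(mix[pos], 1e-300)))
        # responsibilities: for each (i, a), r_k = eta_ik p_kla / mix_ia
        pk_num <- matrix(0, K, ncol(pl))
        w <- n / pmax(mix, 1e-300)        # I x A weights
        for (k in seq_len(K)) {
          contrib <- w * (eta[, k] %o% pl[k, ])  # I x A of n * resp_k
          eta_num[, k] <- eta_num[, k] + rowSums(contrib)
          pk_num[k, ] <- colSums(contrib)
        }
        p_new[[l]] <- floor_renorm(pk_num / pmax(rowSums(pk_num), 1e-300))
      }
      trace <- c(trace, ll)
      if (ll - ll_old < tol && it > 1L) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      eta <- eta_num / pmax(copies, 1)
      eta[copies == 0, ] <- 1 / K
      eta <- floor_renorm(eta)
      p <- p_new
    }
    list(eta = eta, p = p, trace = trace, converged = converged)
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    res <- run_one()
    if (is.null(best) ||
        utils::tail(res$trace, 1) > utils::tail(best$trace, 1))
      best <- res
  }
  degenerate <- any(colSums(best$eta) < 1e-6 * I)
  if (degenerate)
    warning("degenerate cluster(s): K may exceed the support of the data")
  new_admixture_fit(K, best$eta, best$p, best$trace, best$converged,
                    degenerate)
}
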