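#' Multi-allelic Weir-Cockerham theta (Fst)
#'
#' Variance-components estimator of population differentiation for
#' multi-allelic codominant data, following Weir & Cockerham (1984). Each
#' locus and allele contributes among-population (a), among-individual (b)
#' and within-individual (c) components; the multi-locus estimate is the
#' normalized ratio of sums `sum(a) / sum(a + b + c)` across all loci and
#' alleles.
#'
#' @param panel a [genotype_panel()].
#' @param labels subpopulation assignment per individual (defaults to the
#'   panel's `subpop` field).
#' @return object of class `fst_estimate`: `theta` (the multi-locus
#'   ratio-of-sums), and `components`, a data frame of per-locus summed
#'   numerators and denominators.
#' @export
weir_cockerham_theta <- function(panel, labels = panel$subpop) {
  if (is.null(labels)) stop("subpopulation labels required")
  stopifnot(length(labels) == panel$n_ind)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 labeled subpopulations")
  num <- den <- numeric(panel$n_loci)
  for (l in seq_len(panel$n_loci)) {
    ok <- !is.na(panel$X[, l, 1])
    lab <- droplevels(labels[ok])
    if (nlevels(lab) < 2L) next
    g <- panel$X[ok, l, , drop = FALSE]
    r <- nlevels(lab)
    ni <- as.vector(table(lab))                 # individuals per pop
    nbar <- mean(ni)
    nsum <- sum(ni)
    nc <- (nsum - sum(ni^2) / nsum) / (r - 1)
    for (a in seq_len(panel$n_alleles[l])) {
      cnt <- (g[, 1, 1] == a) + (g[, 1, 2] == a)   # allele-a copies per ind.
      het <- g[, 1, 1] != g[, 1, 2] & (g[, 1, 1] == a | g[, 1, 2] == a)
      p_i <- tapply(cnt, lab, sum) / (2 * ni)     # per-pop allele freq
      h_i <- tapply(het, lab, sum) / ni           # per-pop het freq for a
      pbar <- sum(ni * p_i) / nsum
      hbar <- sum(ni * h_i) / nsum
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      if (nbar <= 1) next
      av <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) *
           (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      bv <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
           ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cv <- hbar / 2
      num[l] <- num[l] + av
      den[l] <- den[l] + av + bv + cv
    }
  }
  theta <- if (sum(den) == 0) {
    warning("monomorphic panel: theta undefined (0/0)")
    NaN
  } else sum(num) / sum(den)
  structure(list(theta = theta,
                 components = data.frame(locus = seq_len(panel$n_loci),
                                         num = num, den = den)),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("Weir-Cockerham multi-locus theta = %.4f (%d loci)\n",
              x$theta, nrow(x$components)))
  invisible(x)
}

#' Theta-adjusted genotype-probability kernel (Polya urn)
#'
#' Under the equilibrium island model, subpopulation allele frequencies are
#' Dirichlet-distributed around the reference frequencies with concentration
#' `(1 - theta) / theta`; correlated draws from a subpopulation then follow a
#' Polya urn: the first copy of allele `a` has probability `p_a`, and each
#' subsequent draw has `P(next = a | m_a prior copies of a out of m)` equal
#' to `((1 - theta) p_a + m_a theta) / ((1 - theta) + m theta)`. In
#' particular `P(second = a | first = a) = theta + (1 - theta) p_a`, so the
#' joint two-draw probability is `p_a (theta + (1 - theta) p_a)`, reducing to
#' the Hardy-Weinberg `p_a^2` at `theta = 0`.
#'
#' @param allele_freqs numeric frequency vector for one locus (sums to 1).
#' @param theta differentiation parameter in `[0, 1)`.
#' @return object of class `polya_kernel` with functions `joint(alleles)`
#'   (probability of an ordered vector of draws) and
#'   `conditional(a, given)` (probability that the next draw is `a` given
#'   the alleles drawn so far).
#' @export
theta_adjusted_genotype_probs <- function(allele_freqs, theta) {
  stopifnot(theta >= 0, abs(sum(allele_freqs) - 1) < 1e-6)
  if (theta >= 1) stop("theta = 1 is degenerate (all draws identical)")
  p <- allele_freqs
  conditional <- function(a, given = integer(0)) {
    m <- length(given)
    ma <- sum(given == a)
    ((1 - theta) * p[a] + ma * theta) / ((1 - theta) + m * theta)
  }
  joint <- function(alleles) {
    pr <- 1
    for (m in seq_along(alleles))
      pr <- pr * conditional(alleles[m], alleles[seq_len(m - 1)])
    pr
  }
  structure(list(joint = joint, conditional = conditional,
                 p = p, theta = theta),
            class = "polya_kernel")
}

# conditional probabilities of an ordered genotype configuration given each
# IBD state under the urn kernel (single reference frequency vector):
# detailed realizations of the condensed state are averaged uniformly and the
# distinct IBD lineages' alleles are a joint (exchangeable) Polya draw.
urn_condprob <- function(gx, gy, kernel) {
  x1 <- gx[1]; x2 <- gx[2]; y1 <- gy[1]; y2 <- gy[2]
  jp <- kernel$joint
  out <- numeric(9)
  xhom <- x1 == x2; yhom <- y1 == y2
  if (xhom && yhom && x1 == y1) out[1] <- jp(x1)
  if (xhom && yhom) out[2] <- jp(c(x1, y1))
  if (xhom) {
    v <- 0
    if (y1 == x1) v <- v + 0.5 * jp(c(x1, y2))
    if (y2 == x1) v <- v + 0.5 * jp(c(x1, y1))
    out[3] <- v
    out[4] <- jp(c(x1, y1, y2))
  }
  if (yhom) {
    v <- 0
    if (x1 == y1) v <- v + 0.5 * jp(c(y1, x2))
    if (x2 == y1) v <- v + 0.5 * jp(c(y1, x1))
    out[5] <- v
    out[6] <- jp(c(y1, x1, x2))
  }
  v <- 0
  if (x1 == y1 && x2 == y2) v <- v + 0.5 * jp(c(x1, x2))
  if (x1 == y2 && x2 == y1) v <- v + 0.5 * jp(c(x1, x2))
  out[7] <- v
  v <- 0
  for (s in 1:2) for (t in 1:2) {
    if (gx[s] == gy[t])
      v <- v + 0.25 * jp(c(gx[s], gx[3 - s], gy[3 - t]))
  }
  out[8] <- v
  out[9] <- jp(c(x1, x2, y1, y2))
  names(out) <- paste0("D", 1:9)
  out
}

# L x 9 urn-kernel conditional matrix for a dyad
baseline_condprob_matrix <- function(pair, panel, allele_freqs, theta) {
  i <- pair[1]; j <- pair[2]
  keep <- which(!is.na(panel$X[i, , 1]) & !is.na(panel$X[j, , 1]))
  if (!length(keep)) stop("no informative loci for this dyad")
  B <- matrix(0, length(keep), 9, dimnames = list(NULL, paste0("D", 1:9)))
  for (r in seq_along(keep)) {
    l <- keep[r]
    kern <- theta_adjusted_genotype_probs(allele_freqs[[l]], theta)
    B[r, ] <- urn_condprob(panel$X[i, l, ], panel$X[j, l, ], kern)
  }
  attr(B, "loci") <- keep
  B
}

#' Fst-parametrized baseline relatedness estimators
#'
#' Relatedness estimation in the style of Anderson & Weir (2007) and Wang
#' (2011): the same dyad-likelihood machinery as [estimate_delta()], but with
#' IBS-given-IBD conditionals built from a single set of reference allele
#' frequencies correlated within subpopulations through the
#' [theta_adjusted_genotype_probs()] urn kernel, instead of per-individual
#' admixture probabilities. `"AW2007"` restricts the support to
#' `Delta7..Delta9` and additionally imposes `4 Delta7 Delta9 < Delta8^2`
#' (no-inbreeding condition); `"Wang2011"` estimates all nine states.
#'
#' @param pair integer vector of length 2.
#' @param panel a [genotype_panel()].
#' @param allele_freqs list of per-locus reference frequency vectors.
#' @param theta differentiation parameter (e.g. from
#'   [weir_cockerham_theta()]).
#' @param method `"AW2007"` or `"Wang2011"`.
#' @param n_starts,seed,tol as in [estimate_delta()].
#' @return a `relatedness_estimate` with an extra `method` field.
#' @export
estimate_baseline <- function(pair, panel, allele_freqs, theta,
                              method = c("AW2007", "Wang2011"),
                              n_starts = 5L, seed = 1L, tol = 1e-8) {
  method <- match.arg(method)
  B <- baseline_condprob_matrix(pair, panel, allele_freqs, theta)
  delta <- stats::setNames(numeric(9), paste0("D", 1:9))
  if (method == "Wang2011") {
    fit <- fit_delta_simplex(B, n_starts = n_starts, seed = seed, tol = tol)
    delta[] <- fit$delta
    loglik <- fit$loglik; converged <- fit$converged; kkt <- fit$kkt
  } else {
    B3 <- B[, 7:9, drop = FALSE]
    fit <- fit_delta_simplex(B3, n_starts = n_starts, seed = seed, tol = tol)
    d3 <- fit$delta
    loglik <- fit$loglik; converged <- fit$converged; kkt <- fit$kkt
    if (4 * d3[1] * d3[3] >= d3[2]^2 + 1e-12) {
      # constrained optimum lies on the boundary 4*d7*d9 = d8^2; with
      # d8 = s the pair (d7, d9) solves t^2 - (1-s) t + s^2/4 = 0 (s <= 1/2)
      obj <- function(d) {
        v <- as.vector(B3 %*% d)
        if (any(v <= 0)) -1e300 else sum(log(v))  # finite floor keeps optimize() quiet
      }
      branch <- function(s, upper) {
        disc <- (1 - s)^2 - s^2
        if (disc < 0) return(NULL)
        rt <- sqrt(disc)
        t1 <- ((1 - s) + if (upper) rt else -rt) / 2
        d <- c(t1, s, 1 - s - t1)
        if (any(d < -1e-12)) NULL else pmax(d, 0)
      }
      cand <- list()
      for (up in c(TRUE, FALSE)) {
        o <- stats::optimize(function(s) {
          d <- branch(s, up)
          if (is.null(d)) return(-1e300)
          obj(d)
        }, c(0, 0.5), maximum = TRUE, tol = 1e-10)
        d <- branch(o$maximum, up)
        if (!is.null(d)) cand <- c(cand, list(d))
      }
      # simplex edges d7 = 0 and d9 = 0 are feasible (4*d7*d9 = 0 <= d8^2)
      for (zero in c(1, 3)) {
        o <- stats::optimize(function(s) {
          d <- numeric(3); d[2] <- s; d[zero] <- 0
          d[c(1, 3)[c(1, 3) != zero]] <- 1 - s
          obj(d)
        }, c(0, 1), maximum = TRUE, tol = 1e-10)
        d <- numeric(3); d[2] <- o$maximum; d[zero] <- 0
        d[c(1, 3)[c(1, 3) != zero]] <- 1 - o$maximum
        cand <- c(cand, list(d))
      }
      lls <- vapply(cand, obj, numeric(1))
      d3 <- cand[[which.max(lls)]]
      d3 <- d3 / sum(d3)
      loglik <- max(lls)
      converged <- TRUE
      kkt <- NA_real_
    }
    delta[7:9] <- d3
  }
  tr <- delta_to_relatedness(delta)
  structure(list(delta = delta, theta = tr["theta"], r = tr["r"],
                 loglik = loglik, variant = if (method == "AW2007")
                   "three_state" else "nine_state",
                 method = method, converged = converged, kkt = kkt,
                 n_loci_used = nrow(B), pair = pair),
            class = "relatedness_estimate")
}

#' Randomly reassign a fraction of subpopulation labels
#'
#' Emulates 'label switching' in the sense of misassigning individuals to
#' a-priori subpopulations: `ceiling(fraction * n)` individuals, chosen
#' uniformly, each receive a uniformly chosen *different* label.
#'
#' @param labels vector of current labels (>= 2 distinct values).
#' @param fraction fraction of individuals to reassign, in `[0, 1]`.
#' @param seed integer seed.
#' @return relabeled vector of the same length and type.
#' @export
shuffle_labels <- function(labels, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  lv <- unique(labels)
  if (length(lv) < 2L) stop("need at least 2 distinct labels to shuffle")
  if (fraction == 0) return(labels)
  set.seed(seed)
  n <- length(labels)
  pick <- sample.int(n, ceiling(fraction * n))
  for (i in pick) {
    others <- lv[lv != labels[i]]
    labels[i] <- others[sample.int(length(others), 1L)]
  }
  labels
}
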