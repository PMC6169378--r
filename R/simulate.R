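#' Synthetic population models
#'
#' Describes how subpopulation allele frequencies are generated for
#' simulation: either independent Dirichlet(alpha) draws per subpopulation
#' and locus, or correlated draws around a shared ancestral frequency vector
#' targeting the equilibrium island-model differentiation
#' `Fst = 1 / (1 + 4 N m)` (Balding-Nichols construction: each
#' subpopulation's frequencies are Dirichlet with concentration
#' `p_ancestral * (1 - Fst) / Fst`).
#'
#' @param K number of subpopulations.
#' @param L number of loci.
#' @param n_alleles alleles per locus (scalar or length-`L` vector).
#' @param freq_model `"dirichlet"` or `"island_equilibrium"`.
#' @param alpha Dirichlet concentration (scalar, recycled per allele) for
#'   `"dirichlet"`, and for the ancestral vector of `"island_equilibrium"`.
#' @param N,m island-model subpopulation size and migration rate; used when
#'   `fst` is not given directly.
#' @param fst target differentiation for `"island_equilibrium"`; defaults to
#'   `1 / (1 + 4 N m)` when `N` and `m` are supplied.
#' @return object of class `population_model`.
#' @export
population_model <- function(K, L, n_alleles = 10L,
                             freq_model = c("dirichlet", "island_equilibrium"),
                             alpha = 1, N = NULL, m = NULL, fst = NULL) {
  freq_model <- match.arg(freq_model)
  if (alpha <= 0) stop("alpha must be > 0")
  n_alleles <- rep_len(as.integer(n_alleles), L)
  if (freq_model == "island_equilibrium") {
    if (is.null(fst)) {
      if (is.null(N) || is.null(m))
        stop("island_equilibrium needs either fst or both N and m")
      fst <- 1 / (1 + 4 * N * m)
    }
    stopifnot(fst > 0, fst < 1)
  }
  structure(list(K = as.integer(K), L = as.integer(L),
                 n_alleles = n_alleles, freq_model = freq_model,
                 alpha = alpha, N = N, m = m, fst = fst),
            class = "population_model")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Draw subpopulation allele frequencies from a population model
#'
#' @param model a [population_model()].
#' @param seed integer seed.
#' @return list of length `L` of `K x A_l` frequency matrices (rows sum
#'   to 1), with the model attached as attribute `model`.
#' @export
make_frequencies <- function(model, seed = 1L) {
  stopifnot(inherits(model, "population_model"))
  set.seed(seed)
  p <- vector("list", model$L)
  for (l in seq_len(model$L)) {
    A <- model$n_alleles[l]
    mat <- matrix(0, model$K, A)
    if (model$freq_model == "dirichlet") {
      for (k in seq_len(model$K))
        mat[k, ] <- rdirichlet1(rep(model$alpha, A))
    } else {
      anc <- rdirichlet1(rep(model$alpha, A))
      conc <- anc * (1 - model$fst) / model$fst
      for (k in seq_len(model$K))
        mat[k, ] <- rdirichlet1(conc)
    }
    # keep frequencies strictly positive so likelihoods stay finite
    mat <- pmax(mat, 1e-9)
    mat <- mat / rowSums(mat)
    p[[l]] <- mat
  }
  attr(p, "model") <- model
  p
}

# package-level counter for globally unique founder-allele labels
.label_env <- new.env(parent = emptyenv())
.label_env$counter <- 0L

next_labels <- function(n) {
  v <- .label_env$counter + seq_len(n)
  .label_env$counter <- .label_env$counter + n
  v
}

#' Sample an admixed individual with labeled founder alleles
#'
#' Each allele copy independently draws a source subpopulation from `eta`,
#' then an allele from that subpopulation's frequencies. Every copy receives
#' a fresh, globally unique founder label, so identity-by-descent can later
#' be read off exactly.
#'
#' @param p list of per-locus `K x A_l` frequency matrices.
#' @param eta ancestry proportion vector of length `K` (simplex).
#' @return list with `genotype` (`L x 2` allele indices), `labels`
#'   (`L x 2` founder labels) and `source` (`L x 2` subpopulation of origin).
#' @export
sample_individual <- function(p, eta) {
  K <- nrow(p[[1]])
  stopifnot(length(eta) == K, abs(sum(eta) - 1) < 1e-8)
  L <- length(p)
  g <- lab <- src <- matrix(0L, L, 2)
  for (l in seq_len(L)) {
    for (c2 in 1:2) {
      k <- sample.int(K, 1L, prob = eta)
      g[l, c2] <- sample.int(ncol(p[[l]]), 1L, prob = p[[l]][k, ])
      src[l, c2] <- k
    }
  }
  lab[] <- next_labels(2L * L)
  list(genotype = g, labels = lab, source = src)
}

# one offspring by independent Mendelian transmission per locus
mate <- function(par1, par2) {
  L <- nrow(par1$genotype)
  pick1 <- sample.int(2L, L, replace = TRUE)
  pick2 <- sample.int(2L, L, replace = TRUE)
  idx1 <- cbind(seq_len(L), pick1)
  idx2 <- cbind(seq_len(L), pick2)
  list(genotype = cbind(par1$genotype[idx1], par2$genotype[idx2]),
       labels = cbind(par1$labels[idx1], par2$labels[idx2]),
       source = cbind(par1$source[idx1], par2$source[idx2]))
}

# condensed IBD state (1..9) from the founder-label partition of the four
# allele copies (x1, x2, y1, y2)
ibd_state_from_labels <- function(lx, ly) {
  x1 <- lx[1]; x2 <- lx[2]; y1 <- ly[1]; y2 <- ly[2]
  xin <- x1 == x2; yin <- y1 == y2
  ncross <- (x1 == y1) + (x1 == y2) + (x2 == y1) + (x2 == y2)
  if (xin && yin) {
    if (x1 == y1) return(1L)
    return(2L)
  }
  if (xin && !yin) {
    if (x1 == y1 || x1 == y2) return(3L)
    return(4L)
  }
  if (!xin && yin) {
    if (y1 == x1 || y1 == x2) return(5L)
    return(6L)
  }
  if (ncross == 2L) return(7L)
  if (ncross == 1L) return(8L)
  9L
}

#' Simulate a related dyad by Mendelian gene-dropping
#'
#' Builds a pair of individuals of a given pedigree category from founders
#' sampled in a designated subpopulation (or with an admixed ancestry
#' vector), transmitting alleles independently per locus (unlinked loci; no
#' IBD-tract model). Founder labels are propagated so the true condensed IBD
#' state at every locus is known exactly. Constructions: FS two shared
#' parents; HS one shared parent; PO parent and own offspring; FC two full
#' sibs each mated to an unrelated same-subpopulation individual, one
#' offspring per cross; MZ one individual duplicated; UR two independent
#' individuals.
#'
#' @param category one of `"FS"`, `"HS"`, `"FC"`, `"PO"`, `"UR"`, `"MZ"`.
#' @param p list of per-locus `K x A_l` frequency matrices.
#' @param subpop founder subpopulation index (ancestry `e_k`), ignored when
#'   `eta` is given.
#' @param eta optional ancestry vector for the founders (admixed parents).
#' @return object of class `dyad_truth`: `category`, `gx`, `gy` (`L x 2`
#'   genotypes), `labels_x`, `labels_y`, `ibd_state` (length-`L` integer,
#'   1..9), `r_true`, `subpop`.
#' @export
make_dyad <- function(category, p, subpop = 1L, eta = NULL) {
  K <- nrow(p[[1]])
  if (is.null(eta)) {
    eta <- numeric(K); eta[subpop] <- 1
  }
  founder <- function() sample_individual(p, eta)
  pair <- switch(category,
    MZ = { a <- mate(founder(), founder()); list(a, a) },
    PO = { p1 <- founder(); p2 <- founder(); list(p1, mate(p1, p2)) },
    FS = { p1 <- founder(); p2 <- founder()
           list(mate(p1, p2), mate(p1, p2)) },
    HS = { sh <- founder()
           list(mate(sh, founder()), mate(sh, founder())) },
    FC = { g1 <- founder(); g2 <- founder()
           s1 <- mate(g1, g2); s2 <- mate(g1, g2)
           list(mate(s1, founder()), mate(s2, founder())) },
    UR = list(founder(), founder()),
    stop(sprintf("unknown dyad category '%s'", category)))
  L <- length(p)
  state <- integer(L)
  for (l in seq_len(L))
    state[l] <- ibd_state_from_labels(pair[[1]]$labels[l, ],
                                      pair[[2]]$labels[l, ])
  r_true <- c(MZ = 1, FS = 0.5, PO = 0.5, HS = 0.25, FC = 0.125,
              UR = 0)[[category]]
  structure(list(category = category, gx = pair[[1]]$genotype,
                 gy = pair[[2]]$genotype, labels_x = pair[[1]]$labels,
                 labels_y = pair[[2]]$labels, ibd_state = state,
                 r_true = r_true, subpop = subpop),
            class = "dyad_truth")
}

#' Mean squared error and bias of relatedness estimates
#'
#' `mse = mean((r_hat - r_true)^2)`; `bias = r_true - mean(r_hat)` (truth
#' minus estimate).
#'
#' @param estimates numeric vector of relatedness estimates.
#' @param r_true true relatedness for the category.
#' @return named numeric vector `c(mse = , bias = )`.
#' @export
evaluate_estimates <- function(estimates, r_true) {
  stopifnot(length(estimates) >= 1L)
  c(mse = mean((estimates - r_true)^2),
    bias = r_true - mean(estimates))
}

#' Assemble a genotype panel from simulated individuals
#'
#' @param genotypes list of `L x 2` genotype matrices.
#' @param ids optional individual labels.
#' @param subpop_labels optional subpopulation labels.
#' @return a [genotype_panel()].
#' @export
panel_from_genotypes <- function(genotypes, ids = NULL, subpop_labels = NULL) {
  I <- length(genotypes)
  L <- nrow(genotypes[[1]])
  X <- array(NA_integer_, c(I, L, 2))
  for (i in seq_len(I)) X[i, , ] <- genotypes[[i]]
  genotype_panel(X, individual_ids = ids, subpop_labels = subpop_labels)
}

#' End-to-end simulation scenario
#'
#' Simulates subpopulation frequencies, background individuals and replicate
#' dyads, fits the admixture model at the true `K`, estimates relatedness for
#' every dyad with the requested estimator variants, and summarizes per
#' category with MSE and bias. Fully reproducible from `seed`.
#'
#' @param model a [population_model()].
#' @param categories pedigree categories to simulate.
#' @param n_dyads dyads per category.
#' @param estimators subset of `c("nine_state", "three_state")`.
#' @param n_background unrelated background individuals per subpopulation
#'   (stabilizes the structure fit).
#' @param seed integer seed.
#' @param n_starts EM restarts for the structure fit.
#' @return list with `summary` (data frame: category, estimator, n, mean_r,
#'   bias, mse), `estimates` (per-dyad data frame), `panel`, `fit`.
#' @export
run_scenario <- function(model, categories = c("FS", "HS", "FC", "PO", "UR"),
                         n_dyads = 100L,
                         estimators = c("nine_state", "three_state"),
                         n_background = 20L, seed = 1L, n_starts = 3L) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  p <- make_frequencies(model, seed = seed)
  set.seed(seed + 1L)
  K <- model$K

  genos <- list(); subs <- integer(0)
  dyads <- list(); dyad_rows <- list()
  for (k in seq_len(K)) {
    ek <- numeric(K); ek[k] <- 1
    for (b in seq_len(n_background)) {
      genos[[length(genos) + 1L]] <- sample_individual(p, ek)$genotype
      subs <- c(subs, k)
    }
  }
  for (cat in categories) {
    for (d in seq_len(n_dyads)) {
      sp <- ((d - 1L) %% K) + 1L
      dy <- make_dyad(cat, p, subpop = sp)
      i1 <- length(genos) + 1L
      genos[[i1]] <- dy$gx
      genos[[i1 + 1L]] <- dy$gy
      subs <- c(subs, sp, sp)
      dyads[[length(dyads) + 1L]] <- dy
      dyad_rows[[length(dyad_rows) + 1L]] <-
        data.frame(category = cat, i1 = i1, i2 = i1 + 1L, r_true = dy$r_true)
    }
  }
  dyad_tab <- do.call(rbind, dyad_rows)
  panel <- panel_from_genotypes(genos, subpop_labels = subs)
  counts <- to_allele_counts(panel)
  fit <- fit_admixture(counts, K = K, seed = seed + 2L, n_starts = n_starts)
  Z <- compute_Z(fit)

  est_rows <- list()
  for (v in estimators) {
    for (r in seq_len(nrow(dyad_tab))) {
      e <- estimate_delta(c(dyad_tab$i1[r], dyad_tab$i2[r]), panel, Z,
                          variant = v, n_starts = 2L, seed = seed + 10L + r)
      est_rows[[length(est_rows) + 1L]] <-
        data.frame(category = dyad_tab$category[r], estimator = v,
                   i1 = dyad_tab$i1[r], i2 = dyad_tab$i2[r],
                   r_true = dyad_tab$r_true[r], r_hat = unname(e$r),
                   theta_hat = unname(e$theta))
    }
  }
  est <- do.call(rbind, est_rows)
  summ <- do.call(rbind, lapply(split(est, list(est$category, est$estimator),
                                      drop = TRUE), function(g) {
    ev <- evaluate_estimates(g$r_hat, g$r_true[1])
    data.frame(category = g$category[1], estimator = g$estimator[1],
               n = nrow(g), mean_r = mean(g$r_hat), bias = ev["bias"],
               mse = ev["mse"])
  }))
  rownames(summ) <- NULL
  list(summary = summ, estimates = est, panel = panel, fit = fit,
       dyads = dyads, frequencies = p)
}
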