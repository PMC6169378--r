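#' Per-individual allele probabilities under the admixture model
#'
#' For individual `i`, locus `l`, allele `a`, the marginal probability that a
#' random allele copy is of type `a` is `Z_i(l, a) = sum_k eta_ik * p_kla`.
#' These quantities replace population allele frequencies in the
#' IBS-given-IBD conditional probabilities.
#'
#' @param fit an `admixture_fit`.
#' @return object of class `allele_prob_table`: list of length `L` of
#'   `I x A_l` matrices, each row summing to 1.
#' @export
compute_Z <- function(fit) {
  Z <- lapply(fit$p, function(pl) fit$eta %*% pl)
  structure(Z, class = "allele_prob_table",
            n_ind = nrow(fit$eta), n_loci = length(fit$p))
}

#' Classify an ordered genotype pair into its IBS mode
#'
#' The nine identity-by-state modes partition all ordered pairs of diploid
#' genotypes by their allele-sharing pattern: S1 `(aa, aa)`, S2 `(aa, bb)`,
#' S3 `(aa, ab)`, S4 `(aa, bc)`, S5 `(ab, aa)`, S6 `(bc, aa)`, S7
#' `(ab, ab)`, S8 `(ab, ac)` and S9 `(ab, cd)`. Allele order within a
#' genotype is irrelevant; the order of the two genotypes is not (S3 vs S5,
#' S4 vs S6). Role alleles are reported in ascending allele index where the
#' mode leaves a choice; for S8 the shared allele takes role `i`.
#'
#' @param gx,gy integer vectors of length 2 (non-missing allele indices).
#' @return list with `mode` (e.g. `"S8"`), and `roles`, a named integer
#'   vector mapping role letters to allele indices.
#' @export
classify_ibs <- function(gx, gy) {
  stopifnot(length(gx) == 2L, length(gy) == 2L, !anyNA(gx), !anyNA(gy))
  x <- sort(gx); y <- sort(gy)
  xhom <- x[1] == x[2]; yhom <- y[1] == y[2]
  shared <- intersect(x, y)
  if (xhom && yhom) {
    if (x[1] == y[1]) return(list(mode = "S1", roles = c(i = x[1])))
    return(list(mode = "S2", roles = c(i = x[1], j = y[1])))
  }
  if (xhom && !yhom) {
    if (x[1] %in% y)
      return(list(mode = "S3", roles = c(i = x[1], j = setdiff(y, x[1]))))
    return(list(mode = "S4", roles = c(i = x[1], j = y[1], k = y[2])))
  }
  if (!xhom && yhom) {
    if (y[1] %in% x)
      return(list(mode = "S5", roles = c(i = y[1], j = setdiff(x, y[1]))))
    return(list(mode = "S6", roles = c(i = y[1], j = x[1], k = x[2])))
  }
  # both heterozygous
  if (length(shared) == 2L)
    return(list(mode = "S7", roles = c(i = x[1], j = x[2])))
  if (length(shared) == 1L)
    return(list(mode = "S8", roles = c(i = shared,
                                       j = setdiff(x, shared),
                                       k = setdiff(y, shared))))
  list(mode = "S9", roles = c(i = x[1], j = x[2], k = y[1], l = y[2]))
}

#' Conditional probabilities of an observed genotype pair given each IBD state
#'
#' Evaluates `P(observed ordered allele configuration | D_q)` for all nine
#' condensed IBD states, with per-individual allele probabilities `Zx`, `Zy`
#' standing in for population frequencies. The generative convention: a
#' detailed (per-gene-copy) realization of the condensed state is picked
#' uniformly; a global swap of the two individuals' Z rows is applied with
#' probability 1/2; each IBD lineage private to one individual draws its
#' allele from that individual's (possibly swapped) Z row, and a lone
#' cross-individual lineage left without a free row slot (states D1 and D8)
#' draws from the even mixture of the two rows. Structurally impossible
#' combinations return exactly 0. The returned values are invariant to allele
#' order within each genotype, and each column of the implied 9x9 table sums
#' to 1 over the full space of ordered configurations.
#'
#' @param gx,gy genotypes: integer vectors of length 2 (allele indices).
#' @param Zx,Zy numeric allele-probability vectors for the two individuals at
#'   this locus.
#' @return named numeric vector `D1..D9`.
#' @export
ibs_condprob <- function(gx, gy, Zx, Zy) {
  x1 <- gx[1]; x2 <- gx[2]; y1 <- gy[1]; y2 <- gy[2]
  mix <- function(a) 0.5 * (Zx[a] + Zy[a])
  sym2 <- function(a, b) 0.5 * (Zx[a] * Zy[b] + Zy[a] * Zx[b])
  out <- numeric(9)
  xhom <- x1 == x2; yhom <- y1 == y2

  if (xhom && yhom && x1 == y1) out[1] <- mix(x1)
  if (xhom && yhom) out[2] <- sym2(x1, y1)
  if (xhom) {
    v <- 0
    if (y1 == x1) v <- v + 0.5 * sym2(x1, y2)
    if (y2 == x1) v <- v + 0.5 * sym2(x1, y1)
    out[3] <- v
    out[4] <- 0.5 * (Zx[x1] * Zy[y1] * Zy[y2] + Zy[x1] * Zx[y1] * Zx[y2])
  }
  if (yhom) {
    v <- 0
    if (x1 == y1) v <- v + 0.5 * sym2(y1, x2)
    if (x2 == y1) v <- v + 0.5 * sym2(y1, x1)
    out[5] <- v
    out[6] <- 0.5 * (Zy[y1] * Zx[x1] * Zx[x2] + Zx[y1] * Zy[x1] * Zy[x2])
  }
  v <- 0
  if (x1 == y1 && x2 == y2) v <- v + 0.5 * sym2(x1, x2)
  if (x1 == y2 && x2 == y1) v <- v + 0.5 * sym2(x1, x2)
  out[7] <- v
  v <- 0
  for (s in 1:2) for (t in 1:2) {
    if (gx[s] == gy[t])
      v <- v + 0.25 * mix(gx[s]) * sym2(gx[3 - s], gy[3 - t])
  }
  out[8] <- v
  out[9] <- 0.5 * (Zx[x1] * Zx[x2] * Zy[y1] * Zy[y2] +
                     Zy[x1] * Zy[x2] * Zx[y1] * Zx[y2])
  names(out) <- paste0("D", 1:9)
  out
}

#' Per-locus conditional probability matrix for a dyad
#'
#' Builds the `L_used x 9` matrix whose row `l` holds
#' `P(observed configuration at locus l | D_q)` for the two individuals,
#' skipping loci with a missing genotype in either individual.
#'
#' @param pair integer vector of length 2: row indices of the two individuals.
#' @param panel a [genotype_panel()].
#' @param Z an `allele_prob_table` from [compute_Z()].
#' @return matrix with attribute `loci` (the locus indices used).
#' @export
dyad_condprob_matrix <- function(pair, panel, Z) {
  i <- pair[1]; j <- pair[2]
  keep <- which(!is.na(panel$X[i, , 1]) & !is.na(panel$X[j, , 1]))
  if (!length(keep)) stop("no informative loci for this dyad")
  B <- matrix(0, length(keep), 9, dimnames = list(NULL, paste0("D", 1:9)))
  for (r in seq_along(keep)) {
    l <- keep[r]
    B[r, ] <- ibs_condprob(panel$X[i, l, ], panel$X[j, l, ],
                           Z[[l]][i, ], Z[[l]][j, ])
  }
  attr(B, "loci") <- keep
  B
}

#' Dyad log-likelihood for a given IBD-coefficient vector
#'
#' The log-likelihood of the pair's genotypes given `Delta` is additive over
#' (unlinked) loci: `sum_l log sum_q P(S_xl | D_q) Delta_q`. Loci missing in
#' either individual are skipped.
#'
#' @param pair integer vector of length 2 (individual indices).
#' @param panel a [genotype_panel()].
#' @param Z an `allele_prob_table`.
#' @param delta numeric vector of 9 IBD-state probabilities on the simplex.
#' @return scalar log-likelihood.
#' @export
dyad_loglik <- function(pair, panel, Z, delta) {
  stopifnot(length(delta) == 9, all(delta >= -1e-12),
            abs(sum(delta) - 1) < 1e-6)
  B <- dyad_condprob_matrix(pair, panel, Z)
  sum(log(as.vector(B %*% delta)))
}

#' Simulate IBS modes given an IBD state (Monte-Carlo oracle)
#'
#' Draws ordered allele configurations for a dyad under a fixed condensed IBD
#' state by direct simulation of the generative recipe behind
#' [ibs_condprob()] (detailed realization, global row swap, per-lineage
#' draws), then tabulates IBS-mode frequencies. Serves as an independent
#' cross-check of the closed-form conditional probabilities.
#'
#' @param q IBD state index 1..9.
#' @param Zx,Zy allele-probability vectors.
#' @param n number of Monte-Carlo draws.
#' @return named numeric vector of relative IBS-mode frequencies (`S1..S9`).
#' @export
sample_ibs_given_ibd <- function(q, Zx, Zy, n = 10000L) {
  A <- length(Zx)
  stopifnot(length(Zy) == A, q %in% 1:9)
  draw <- function(p, m = n) sample.int(A, m, replace = TRUE, prob = p)
  # row used for the x slot / y slot under the global swap bit
  s <- stats::runif(n) < 0.5
  slot_draw <- function(which_x) {
    # vector of draws: from Zx where (swap xor slot) keeps x's row
    use_x <- if (which_x) !s else s
    out <- integer(n)
    out[use_x] <- draw(Zx, sum(use_x))
    out[!use_x] <- draw(Zy, sum(!use_x))
    out
  }
  mix_draw <- function() {
    b <- stats::runif(n) < 0.5
    out <- integer(n)
    out[b] <- draw(Zx, sum(b))
    out[!b] <- draw(Zy, sum(!b))
    out
  }
  if (q == 1) {
    a <- mix_draw()
    cfg <- cbind(a, a, a, a)
  } else if (q == 2) {
    a <- slot_draw(TRUE); b <- slot_draw(FALSE)
    cfg <- cbind(a, a, b, b)
  } else if (q == 3 || q == 5) {
    a <- slot_draw(q == 3); b <- slot_draw(q != 3)
    d <- stats::runif(n) < 0.5
    free1 <- ifelse(d, a, b); free2 <- ifelse(d, b, a)
    cfg <- if (q == 3) cbind(a, a, free1, free2) else cbind(free1, free2, a, a)
  } else if (q == 4 || q == 6) {
    a <- slot_draw(q == 4)
    b <- slot_draw(q != 4); c2 <- slot_draw(q != 4)
    cfg <- if (q == 4) cbind(a, a, b, c2) else cbind(b, c2, a, a)
  } else if (q == 7) {
    a <- slot_draw(TRUE); b <- slot_draw(FALSE)
    d <- stats::runif(n) < 0.5
    cfg <- cbind(a, b, ifelse(d, a, b), ifelse(d, b, a))
  } else if (q == 8) {
    a <- mix_draw()
    bx <- slot_draw(TRUE); by <- slot_draw(FALSE)
    sdet <- sample.int(2L, n, replace = TRUE)
    tdet <- sample.int(2L, n, replace = TRUE)
    x1 <- ifelse(sdet == 1L, a, bx); x2 <- ifelse(sdet == 1L, bx, a)
    y1 <- ifelse(tdet == 1L, a, by); y2 <- ifelse(tdet == 1L, by, a)
    cfg <- cbind(x1, x2, y1, y2)
  } else {
    cfg <- cbind(slot_draw(TRUE), slot_draw(TRUE),
                 slot_draw(FALSE), slot_draw(FALSE))
  }
  modes <- classify_ibs_config(cfg)
  tab <- tabulate(modes, nbins = 9) / n
  names(tab) <- paste0("S", 1:9)
  tab
}

# vectorized IBS-mode index (1..9) for an n x 4 config matrix
classify_ibs_config <- function(cfg) {
  x1 <- cfg[, 1]; x2 <- cfg[, 2]; y1 <- cfg[, 3]; y2 <- cfg[, 4]
  xhom <- x1 == x2; yhom <- y1 == y2
  nshare <- (x1 == y1) + (x1 == y2) + (x2 == y1) + (x2 == y2)
  mode <- integer(length(x1))
  mode[xhom & yhom & x1 == y1] <- 1L
  mode[xhom & yhom & x1 != y1] <- 2L
  sel <- xhom & !yhom
  mode[sel & (x1 == y1 | x1 == y2)] <- 3L
  mode[sel & !(x1 == y1 | x1 == y2)] <- 4L
  sel <- !xhom & yhom
  mode[sel & (y1 == x1 | y1 == x2)] <- 5L
  mode[sel & !(y1 == x1 | y1 == x2)] <- 6L
  sel <- !xhom & !yhom
  mode[sel & nshare == 2L] <- 7L
  mode[sel & nshare == 1L] <- 8L
  mode[sel & nshare == 0L] <- 9L
  mode
}
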