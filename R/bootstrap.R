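#' Reference coancestry values for standard pedigree categories
#'
#' Expected coancestry `theta0` (half the expected relatedness) for the
#' pedigree categories used in dyad classification: monozygotic twins (MZ),
#' full siblings (FS), parent-offspring (PO), half siblings (HS), avuncular
#' (AC), first cousins (FC), second cousins (SC) and unrelated (UR). FS and
#' PO share `theta0 = 0.25`, HS and AC share `0.125`; a Wald test on theta
#' alone cannot separate the members of those ties.
#'
#' @return named numeric vector of `theta0` values.
#' @export
category_reference_thetas <- function() {
  c(MZ = 0.5, FS = 0.25, PO = 0.25, HS = 0.125, AC = 0.125,
    FC = 0.0625, SC = 0.015625, UR = 0)
}

#' Bootstrap-over-loci standard error of the coancestry estimate
#'
#' Loci (assumed unlinked, hence independent) are resampled with replacement
#' from the dyad's informative loci; for each replicate the IBD coefficients
#' are re-maximized and the coancestry recorded. The structure fit (ancestry
#' proportions and subpopulation frequencies, hence Z) is held fixed across
#' replicates: only the loci entering the dyad likelihood are resampled. The
#' standard error is the sample standard deviation of the replicates
#' (denominator `B - 1`) and the confidence interval is the 2.5/97.5
#' percentile interval.
#'
#' @param pair integer vector of length 2.
#' @param panel a [genotype_panel()].
#' @param fit an `admixture_fit` for the panel.
#' @param variant `"nine_state"` or `"three_state"`.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param n_starts optimizer starts per replicate (1 suffices: the objective
#'   is concave).
#' @return object of class `bootstrap_result`: `theta_hat` (point estimate on
#'   the original loci), `theta_reps`, `se`, `ci_low`, `ci_high`, `B`,
#'   `n_dropped` (failed replicates).
#' @export
bootstrap_theta <- function(pair, panel, fit,
                            variant = c("nine_state", "three_state"),
                            B = 200L, seed = 1L, n_starts = 1L) {
  variant <- match.arg(variant)
  stopifnot(B >= 2L)
  Z <- compute_Z(fit)
  Bm <- dyad_condprob_matrix(pair, panel, Z)
  L <- nrow(Bm)
  if (L < 2L) stop("need at least 2 informative loci to bootstrap")
  states <- if (variant == "three_state") 7:9 else 1:9
  theta_from <- function(M) {
    f <- fit_delta_simplex(M[, states, drop = FALSE], n_starts = n_starts,
                           seed = seed)
    d <- numeric(9); d[states] <- f$delta
    delta_to_relatedness(d)["theta"]
  }
  theta_hat <- theta_from(Bm)
  # draw all resampling indices up front: the inner optimizer seeds the RNG
  # itself, which must not leak into the bootstrap stream
  set.seed(seed)
  idx_all <- matrix(sample.int(L, L * B, replace = TRUE), B, L)
  reps <- numeric(B)
  ok <- logical(B)
  for (b in seq_len(B)) {
    reps[b] <- tryCatch({
      ok[b] <- TRUE
      theta_from(Bm[idx_all[b, ], , drop = FALSE])
    }, error = function(e) {
      ok[b] <<- FALSE
      NA_real_
    })
  }
  n_drop <- sum(!ok)
  if (n_drop > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates failed", n_drop, B))
  reps <- reps[ok]
  se <- stats::sd(reps)
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(theta_hat = unname(theta_hat), theta_reps = reps, se = se,
                 ci_low = ci[1], ci_high = ci[2], B = B, n_dropped = n_drop,
                 variant = variant, pair = pair),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result (%s): theta = %.4f, SE = %.4f, 95%% CI [%.4f, %.4f] (B = %d)\n",
              x$variant, x$theta_hat, x$se, x$ci_low, x$ci_high,
              length(x$theta_reps)))
  invisible(x)
}

#' Wald-test assignment of a dyad to a pedigree category
#'
#' For each candidate category with reference coancestry `theta0`, the Wald
#' statistic `(theta_hat - theta0) / se` is compared to the standard normal
#' (two-sided). After Bonferroni correction (per-test threshold
#' `alpha / n_categories`), the dyad is assigned to the *non-rejected*
#' category with the largest p-value; categories sharing the winning
#' `theta0` (FS/PO, HS/AC) are reported jointly. If every category is
#' rejected the dyad is `"unassigned"`.
#'
#' @param theta_hat estimated coancestry.
#' @param se bootstrap standard error (> 0; `se = 0` falls back to exact
#'   matching of `theta_hat` against the `theta0` values, flagged as
#'   degenerate).
#' @param categories named vector of reference `theta0` values.
#' @param alpha familywise significance level.
#' @return object of class `category_assignment`: `table` (data frame with
#'   per-category `theta0`, `wald`, `p`, `rejected`), `assigned` (character
#'   vector, possibly several tied categories, or `"unassigned"`),
#'   `alpha`, `threshold`, `degenerate`.
#' @export
wald_assign <- function(theta_hat, se,
                        categories = category_reference_thetas(),
                        alpha = 0.05) {
  m <- length(categories)
  thr <- alpha / m
  degenerate <- FALSE
  if (se <= 0) {
    degenerate <- TRUE
    exact <- abs(theta_hat - categories) < 1e-12
    tab <- data.frame(category = names(categories), theta0 = categories,
                      wald = ifelse(exact, 0, Inf) * sign(theta_hat - categories),
                      p = ifelse(exact, 1, 0), rejected = !exact,
                      row.names = NULL)
    assigned <- if (any(exact)) names(categories)[exact] else "unassigned"
  } else {
    wald <- (theta_hat - categories) / se
    p <- 2 * stats::pnorm(-abs(wald))
    rejected <- p < thr
    tab <- data.frame(category = names(categories), theta0 = categories,
                      wald = wald, p = p, rejected = rejected,
                      row.names = NULL)
    if (all(rejected)) {
      assigned <- "unassigned"
    } else {
      best <- which.max(ifelse(rejected, -Inf, p))
      # report all surviving categories that share the winning theta0
      assigned <- names(categories)[!rejected &
                                      categories == categories[best]]
    }
  }
  structure(list(table = tab, assigned = assigned, alpha = alpha,
                 threshold = thr, theta_hat = theta_hat, se = se,
                 degenerate = degenerate),
            class = "category_assignment")
}

#' @export
print.category_assignment <- function(x, ...) {
  cat(sprintf("category_assignment: theta = %.4f (SE %.4f), per-test threshold %.5f\n",
              x$theta_hat, x$se, x$threshold))
  print(x$table, row.names = FALSE, digits = 4)
  cat("assigned:", paste(x$assigned, collapse = "/"), "\n")
  invisible(x)
}

#' Bootstrap and assign pedigree categories for a set of dyads
#'
#' Convenience wrapper: for each pair, runs [bootstrap_theta()] then
#' [wald_assign()], collecting one row per dyad.
#'
#' @param pairs two-column matrix of individual indices.
#' @param panel a [genotype_panel()].
#' @param fit an `admixture_fit`.
#' @param variant,B,seed passed to [bootstrap_theta()].
#' @param alpha familywise level for [wald_assign()].
#' @return data frame: `id1`, `id2`, `theta`, `se`, `ci_low`, `ci_high`,
#'   per-category p-values (`p_MZ`, ...), `assigned` (slash-joined ties).
#' @export
assign_categories <- function(pairs, panel, fit,
                              variant = c("nine_state", "three_state"),
                              B = 200L, seed = 1L, alpha = 0.05) {
  variant <- match.arg(variant)
  pairs <- as.matrix(pairs)
  cats <- category_reference_thetas()
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    pr <- as.integer(pairs[r, 1:2])
    bt <- bootstrap_theta(pr, panel, fit, variant = variant, B = B,
                          seed = seed + r)
    as_ <- wald_assign(bt$theta_hat, bt$se, cats, alpha = alpha)
    pv <- stats::setNames(as_$table$p, paste0("p_", as_$table$category))
    rows[[r]] <- data.frame(id1 = panel$ids[pr[1]], id2 = panel$ids[pr[2]],
                            theta = bt$theta_hat, se = bt$se,
                            ci_low = bt$ci_low, ci_high = bt$ci_high,
                            t(pv),
                            assigned = paste(as_$assigned, collapse = "/"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
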