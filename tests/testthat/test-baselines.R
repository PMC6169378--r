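test_that("Weir-Cockerham theta hits the two differentiation limits", {
  # two subpopulations fixed for alternate alleles: theta ~ 1
  L <- 20; n_per <- 20
  X <- array(NA_integer_, c(2 * n_per, L, 2))
  X[1:n_per, , ] <- 1L
  X[(n_per + 1):(2 * n_per), , ] <- 2L
  panel <- genotype_panel(X, subpop_labels = rep(1:2, each = n_per))
  expect_gt(weir_cockerham_theta(panel)$theta, 0.95)

  # one population duplicated under two labels: theta ~ 0
  set.seed(171)
  mod <- population_model(K = 1, L = 50, n_alleles = 6, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 172)
  genos <- lapply(1:200, function(i) sample_individual(p, 1)$genotype)
  panel0 <- panel_from_genotypes(genos, subpop_labels = rep(1:2, 100))
  expect_lt(abs(weir_cockerham_theta(panel0)$theta), 0.05)

  # monomorphic panel: NaN with warning
  Xm <- array(1L, c(10, 3, 2))
  pm <- genotype_panel(Xm, subpop_labels = rep(1:2, 5))
  expect_warning(thm <- weir_cockerham_theta(pm)$theta, "monomorphic")
  expect_true(is.nan(thm))
})

test_that("WC theta is invariant to allele relabeling and locus order", {
  set.seed(181)
  mod <- population_model(K = 3, L = 15, n_alleles = 4,
                          freq_model = "island_equilibrium", fst = 0.2)
  p <- make_frequencies(mod, seed = 182)
  genos <- unlist(lapply(1:3, function(k) {
    ek <- numeric(3); ek[k] <- 1
    lapply(1:25, function(i) sample_individual(p, ek)$genotype)
  }), recursive = FALSE)
  labs <- rep(1:3, each = 25)
  panel <- panel_from_genotypes(genos, subpop_labels = labs)
  th <- weir_cockerham_theta(panel)$theta

  # permute allele indices at every locus
  X2 <- panel$X
  set.seed(183)
  for (l in 1:15) {
    perm <- sample(4)
    X2[, l, ] <- perm[X2[, l, ]]
  }
  panel2 <- genotype_panel(X2, subpop_labels = labs)
  expect_equal(weir_cockerham_theta(panel2)$theta, th, tolerance = 1e-12)

  # permute locus order
  X3 <- panel$X[, 15:1, , drop = FALSE]
  panel3 <- genotype_panel(X3, subpop_labels = labs)
  expect_equal(weir_cockerham_theta(panel3)$theta, th, tolerance = 1e-12)
})

test_that("urn kernel: HWE at theta = 0, full correlation near theta = 1, normalization", {
  p <- c(0.1, 0.2, 0.3, 0.4)
  k0 <- theta_adjusted_genotype_probs(p, 0)
  expect_equal(k0$joint(c(2, 2)), p[2]^2)
  expect_equal(k0$conditional(3, c(3)), p[3])

  k9 <- theta_adjusted_genotype_probs(p, 0.999)
  expect_gt(k9$conditional(1, c(1)), 0.99)
  expect_error(theta_adjusted_genotype_probs(p, 1), "degenerate")

  kt <- theta_adjusted_genotype_probs(p, 0.3)
  # P(second = a | first = a) = theta + (1 - theta) p_a
  expect_equal(kt$conditional(1, c(1)), 0.3 + 0.7 * p[1])
  # two-draw joint probabilities sum to 1
  tot <- 0
  for (a in 1:4) for (b in 1:4) tot <- tot + kt$joint(c(a, b))
  expect_equal(tot, 1, tolerance = 1e-12)
  # four-draw joint probabilities sum to 1 (Polya-urn extension)
  tot4 <- 0
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4)
    tot4 <- tot4 + kt$joint(c(a, b, cc, d))
  expect_equal(tot4, 1, tolerance = 1e-12)
})

test_that("baseline at theta = 0 collapses to the K = 1 admixture estimator", {
  set.seed(191)
  mod <- population_model(K = 1, L = 100, n_alleles = 6, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 192)
  bg <- lapply(1:30, function(i) sample_individual(p, 1)$genotype)
  freqs <- NULL
  for (cat in c("PO", "UR")) {
    dy <- make_dyad(cat, p)
    panel <- panel_from_genotypes(c(list(dy$gx, dy$gy), bg))
    fit <- fit_admixture(to_allele_counts(panel), K = 1)
    Z <- compute_Z(fit)
    freqs <- lapply(fit$p, function(m) m[1, ])

    w <- estimate_baseline(c(1, 2), panel, freqs, theta = 0,
                           method = "Wang2011", seed = 7)
    e9 <- estimate_delta(c(1, 2), panel, Z, "nine_state", seed = 7)
    expect_lt(abs(w$r - e9$r), 1e-4)
    expect_lt(abs(w$loglik - e9$loglik), 1e-6)

    a <- estimate_baseline(c(1, 2), panel, freqs, theta = 0,
                           method = "AW2007", seed = 7)
    e3 <- estimate_delta(c(1, 2), panel, Z, "three_state", seed = 7)
    d3 <- e3$delta
    if (4 * d3[7] * d3[9] < d3[8]^2 - 1e-6) {
      # no-inbreeding constraint inactive: AW2007 must coincide exactly
      expect_lt(abs(a$r - e3$r), 1e-4)
    } else {
      # constraint binds: AW2007 is additionally restricted
      expect_lte(a$loglik, e3$loglik + 1e-8)
    }
  }
})

test_that("AW2007 optimum honors 4*D7*D9 < D8^2 even when it binds", {
  set.seed(201)
  mod <- population_model(K = 1, L = 200, n_alleles = 8, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 202)
  freqs <- lapply(p, function(m) m[1, ])
  for (cat in c("FS", "HS", "UR")) {
    dy <- make_dyad(cat, p)
    panel <- panel_from_genotypes(list(dy$gx, dy$gy))
    est <- estimate_baseline(c(1, 2), panel, freqs, theta = 0.05,
                             method = "AW2007", seed = 8)
    d <- est$delta
    expect_true(all(d[1:6] == 0))
    expect_lt(abs(sum(d) - 1), 1e-8)
    expect_lte(4 * d[7] * d[9], d[8]^2 + 1e-8)
  }
})

test_that("label shuffling follows its contract and erodes differentiation", {
  labs <- rep(1:3, each = 10)
  expect_identical(shuffle_labels(labs, 0), labs)
  full <- shuffle_labels(labs, 1, seed = 5)
  expect_true(all(full != labs))
  expect_error(shuffle_labels(rep(1, 5), 0.5), "at least 2")
  half <- shuffle_labels(labs, 0.5, seed = 6)
  expect_equal(sum(half != labs), 15)

  # a full shuffle with >= 3 labels mixes each relabeled group over the other
  # subpopulations, collapsing most of the among-group variance
  set.seed(211)
  mod <- population_model(K = 3, L = 60, n_alleles = 5,
                          freq_model = "island_equilibrium", fst = 0.2)
  p <- make_frequencies(mod, seed = 212)
  genos <- unlist(lapply(1:3, function(k) {
    ek <- numeric(3); ek[k] <- 1
    lapply(1:40, function(i) sample_individual(p, ek)$genotype)
  }), recursive = FALSE)
  labs2 <- rep(1:3, each = 40)
  panel <- panel_from_genotypes(genos, subpop_labels = labs2)
  th_true <- weir_cockerham_theta(panel)$theta
  th_shuf <- weir_cockerham_theta(panel, shuffle_labels(labs2, 1, seed = 7))$theta
  expect_gt(th_true, 0.12)
  expect_lt(th_shuf, 0.4 * th_true)
})

test_that("misspecified theta from shuffled labels inflates FS dispersion", {
  set.seed(221)
  mod <- population_model(K = 3, L = 50, n_alleles = 8,
                          freq_model = "island_equilibrium", fst = 0.2)
  p <- make_frequencies(mod, seed = 222)
  genos <- unlist(lapply(1:3, function(k) {
    ek <- numeric(3); ek[k] <- 1
    lapply(1:20, function(i) sample_individual(p, ek)$genotype)
  }), recursive = FALSE)
  labs <- rep(1:3, each = 20)
  n_dyads <- 12
  dys <- lapply(1:n_dyads, function(d) make_dyad("FS", p, subpop = (d %% 3) + 1))
  genos <- c(genos, unlist(lapply(dys, function(d) list(d$gx, d$gy)),
                           recursive = FALSE))
  labs <- c(labs, rep(sapply(1:n_dyads, function(d) (d %% 3) + 1), each = 2))
  panel <- panel_from_genotypes(genos, subpop_labels = labs)

  # pooled sample frequencies as the reference
  cnts <- to_allele_counts(panel)
  freqs <- lapply(cnts, function(n) {
    f <- colSums(n); f <- pmax(f, 0.5); f / sum(f)
  })
  th_good <- weir_cockerham_theta(panel)$theta
  th_bad <- weir_cockerham_theta(panel, shuffle_labels(labs, 1, seed = 9))$theta

  r_at <- function(theta) {
    sapply(seq_len(n_dyads), function(d) {
      pr <- c(60 + 2 * d - 1, 60 + 2 * d)
      estimate_baseline(pr, panel, freqs, theta = theta,
                        method = "Wang2011", seed = 10 + d)$r
    })
  }
  r_good <- r_at(max(th_good, 0.01))
  r_bad <- r_at(max(th_bad, 1e-4))
  dev_good <- mean(abs(r_good - 0.5))
  dev_bad <- mean(abs(r_bad - 0.5))
  expect_gt(dev_bad, dev_good - 0.02)  # degradation (allowing noise margin)
})
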