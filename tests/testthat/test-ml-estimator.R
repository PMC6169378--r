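test_that("theta/r follow the affine map from Delta, without clamping", {
  d <- numeric(9); d[8] <- 1
  expect_equal(delta_to_relatedness(d), c(theta = 0.25, r = 0.5))

  d <- numeric(9); d[7] <- 0.25; d[8] <- 0.5; d[9] <- 0.25  # full sibs
  expect_equal(delta_to_relatedness(d), c(theta = 0.25, r = 0.5))

  d <- numeric(9); d[1] <- 1   # fully inbred identical pair: r exceeds 1
  expect_equal(delta_to_relatedness(d), c(theta = 1, r = 2))

  d <- rep(1 / 9, 9)
  expect_equal(delta_to_relatedness(d)[["theta"]],
               1 / 9 + 0.5 * (3 / 9) + 0.25 / 9)
})

test_that("simplex optimizer matches an exhaustive grid oracle on 3 states", {
  set.seed(101)
  mod <- population_model(K = 1, L = 120, n_alleles = 6, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 102)
  for (cat in c("FS", "HS", "UR")) {
    dy <- make_dyad(cat, p)
    bg <- lapply(1:30, function(i) sample_individual(p, 1)$genotype)
    panel <- panel_from_genotypes(c(list(dy$gx, dy$gy), bg))
    fit <- fit_admixture(to_allele_counts(panel), K = 1)
    Z <- compute_Z(fit)
    B3 <- dyad_condprob_matrix(c(1, 2), panel, Z)[, 7:9]

    opt <- inrelate:::fit_delta_simplex(B3, n_starts = 2, seed = 5)
    grid <- grid_oracle_3state(B3, by = 0.01)
    # the optimizer is never beaten by more than a grid-resolution margin
    expect_gte(opt$loglik, grid$loglik - 1e-4)
    expect_lt(max(abs(opt$delta - grid$delta)), 0.02)
  }
})

test_that("estimates satisfy the simplex contract and KKT conditions", {
  set.seed(111)
  mod <- population_model(K = 2, L = 60, n_alleles = 6, freq_model = "dirichlet",
                          alpha = 0.5)
  p <- make_frequencies(mod, seed = 112)
  dy <- make_dyad("HS", p, subpop = 1)
  bg <- c(lapply(1:15, function(i) sample_individual(p, c(1, 0))$genotype),
          lapply(1:15, function(i) sample_individual(p, c(0, 1))$genotype))
  panel <- panel_from_genotypes(c(list(dy$gx, dy$gy), bg))
  fit <- fit_admixture(to_allele_counts(panel), K = 2, seed = 1, n_starts = 2)
  Z <- compute_Z(fit)

  for (variant in c("nine_state", "three_state")) {
    est <- estimate_delta(c(1, 2), panel, Z, variant = variant, seed = 2)
    expect_true(all(est$delta >= 0))
    expect_lt(abs(sum(est$delta) - 1), 1e-8)
    expect_lt(est$kkt, 1e-6)
    expect_equal(est$theta, delta_to_relatedness(est$delta)["theta"])
    expect_equal(unname(est$r), unname(2 * est$theta))
    if (variant == "three_state") expect_true(all(est$delta[1:6] == 0))
  }
})

test_that("a duplicated individual is recovered as (nearly) monozygotic", {
  set.seed(121)
  mod <- population_model(K = 1, L = 300, n_alleles = 8, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 122)
  ind <- make_dyad("FS", p)$gx   # any outbred individual
  bg <- lapply(1:40, function(i) sample_individual(p, 1)$genotype)
  panel <- panel_from_genotypes(c(list(ind, ind), bg))
  fit <- fit_admixture(to_allele_counts(panel), K = 1)
  est <- estimate_delta(c(1, 2), panel, compute_Z(fit), "nine_state", seed = 3)

  expect_gte(est$delta[["D7"]], 0.95)
  expect_lt(abs(est$r - 1), 0.05)
})

test_that("a simulated parent-offspring dyad recovers Delta8 and r near 0.5", {
  set.seed(131)
  mod <- population_model(K = 1, L = 500, n_alleles = 8, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 132)
  dy <- make_dyad("PO", p)
  bg <- lapply(1:50, function(i) sample_individual(p, 1)$genotype)
  panel <- panel_from_genotypes(c(list(dy$gx, dy$gy), bg))
  fit <- fit_admixture(to_allele_counts(panel), K = 1)
  est <- estimate_delta(c(1, 2), panel, compute_Z(fit), "nine_state", seed = 3)

  expect_equal(unname(which.max(est$delta)), 8)
  expect_lt(abs(est$r - 0.5), 0.05)
})

test_that("three-state log-likelihood never exceeds nine-state (nested models)", {
  set.seed(141)
  mod <- population_model(K = 1, L = 80, n_alleles = 6, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 142)
  bg <- lapply(1:25, function(i) sample_individual(p, 1)$genotype)
  for (cat in c("FS", "PO", "UR")) {
    dy <- make_dyad(cat, p)
    panel <- panel_from_genotypes(c(list(dy$gx, dy$gy), bg))
    fit <- fit_admixture(to_allele_counts(panel), K = 1)
    Z <- compute_Z(fit)
    e9 <- estimate_delta(c(1, 2), panel, Z, "nine_state", seed = 4)
    e3 <- estimate_delta(c(1, 2), panel, Z, "three_state", seed = 4)
    expect_gte(e9$loglik, e3$loglik - 1e-7)
  }
})

test_that("consistency: with many loci Delta_hat approaches the simulating Delta", {
  set.seed(151)
  mod <- population_model(K = 1, L = 2000, n_alleles = 10, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 152)
  # draw genotypes directly from a known Delta* (outbred mixture of D7/D8/D9)
  d_true <- c(rep(0, 6), 0.25, 0.5, 0.25)
  gx <- gy <- matrix(0L, 2000, 2)
  for (l in 1:2000) {
    f <- p[[l]][1, ]
    q <- sample(7:9, 1, prob = d_true[7:9])
    if (q == 7) {
      a <- sample(length(f), 1, prob = f); b <- sample(length(f), 1, prob = f)
      gx[l, ] <- c(a, b); gy[l, ] <- c(a, b)
    } else if (q == 8) {
      a <- sample(length(f), 1, prob = f)
      gx[l, ] <- c(a, sample(length(f), 1, prob = f))
      gy[l, ] <- c(a, sample(length(f), 1, prob = f))
    } else {
      gx[l, ] <- sample(length(f), 2, replace = TRUE, prob = f)
      gy[l, ] <- sample(length(f), 2, replace = TRUE, prob = f)
    }
  }
  bg <- lapply(1:100, function(i) sample_individual(p, 1)$genotype)
  panel <- panel_from_genotypes(c(list(gx, gy), bg))
  fit <- fit_admixture(to_allele_counts(panel), K = 1)
  est <- estimate_delta(c(1, 2), panel, compute_Z(fit), "nine_state", seed = 6)
  expect_lt(max(abs(est$delta - d_true)), 0.05)
})

test_that("relatedness_matrix is symmetric in pair order and matches single calls", {
  set.seed(161)
  mod <- population_model(K = 1, L = 100, n_alleles = 6, freq_model = "dirichlet")
  p <- make_frequencies(mod, seed = 162)
  dy <- make_dyad("FS", p)
  bg <- lapply(1:20, function(i) sample_individual(p, 1)$genotype)
  panel <- panel_from_genotypes(c(list(dy$gx, dy$gy), bg))
  fit <- fit_admixture(to_allele_counts(panel), K = 1)

  tab <- relatedness_matrix(panel, fit, pairs = rbind(c(1, 2), c(2, 1)),
                            seed = 9)
  expect_equal(tab$r[1], tab$r[2], tolerance = 1e-6)

  Z <- compute_Z(fit)
  single <- estimate_delta(c(1, 2), panel, Z, "nine_state",
                           n_starts = 5, seed = 9 + 1)
  expect_equal(tab$theta[1], unname(single$theta), tolerance = 1e-10)
})
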