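test_that("observed mismatch distribution matches pair enumeration", {
  same <- dna_alignment(setNames(rep("ACGT", 4), paste0("s", 1:4)))
  obs <- mismatch_observed(same)
  expect_equal(obs$freq, 1)
  expect_equal(obs$d_max, 0)
  two <- dna_alignment(c(a = "AAAA", b = "TTTA"))
  expect_equal(mismatch_observed(two)$freq, c(0, 0, 0, 1))
  # brute force over all pairs of a random toy
  aln <- random_alignment(5, 30, seed = 8)
  obs2 <- mismatch_observed(aln)
  m <- aln$mat
  dd <- c()
  for (i in 1:4) for (j in (i + 1):5) dd <- c(dd, sum(m[i, ] != m[j, ]))
  expect_equal(obs2$counts, tabulate(dd + 1, nbins = max(dd) + 1))
  expect_equal(sum(obs2$freq), 1)
})

test_that("expected mismatch collapses to equilibrium and to Poisson-like", {
  eq <- equilibrium_mismatch(3, 25)
  expect_equal(expected_mismatch(0, 3, 3, 25), eq / sum(eq))
  expect_equal(sum(expected_mismatch(7, 1, 500, 40)), 1)
  # large tau, tiny theta0, huge theta1 -> mode near tau
  f <- expected_mismatch(10, 0.01, 5000, 50)
  expect_lte(abs(which.max(f) - 1 - 10), 1)
  # matched against coalescent simulation of the same scenario
  set.seed(31)
  acc <- numeric(61)
  for (r in 1:150) {
    D <- fishpopgen:::sim_coalescent_pairdiff(25, theta0 = 0.01,
                                              theta1 = 5000, tau = 10)
    o <- mismatch_observed(D)
    f_r <- c(o$freq, numeric(61 - length(o$freq)))
    acc <- acc + f_r[1:61]
  }
  acc <- acc / 150
  fexp <- expected_mismatch(10, 0.01, 5000, 60)
  expect_lt(max(abs(acc - fexp)), 0.05)
})

test_that("fitting the model's own expectation is a fixed point", {
  f <- expected_mismatch(6, 1, 1000, 30)
  obs <- structure(list(freq = f, counts = round(f * 435), n_pairs = 435,
                        d_max = 30), class = "mismatch_distribution")
  fit <- fit_sudden_expansion(obs)
  expect_lt(fit$ssd, 1e-8)
  expect_equal(fit$tau, 6, tolerance = 0.05)
})

test_that("equilibrium-shaped input fits tau near zero", {
  eq <- equilibrium_mismatch(4, 30)
  obs <- structure(list(freq = eq / sum(eq), counts = round(eq * 100),
                        n_pairs = 100, d_max = 30),
                   class = "mismatch_distribution")
  fit <- fit_sudden_expansion(obs)
  expect_lt(fit$ssd, 1e-6)
  expect_lt(fit$tau, 0.5)
})

test_that("raggedness follows the closing-term convention", {
  expect_equal(raggedness(c(0.1, 0.2, 0.4, 0.2, 0.1)),
               0.01 + 0.04 + 0.04 + 0.01 + 0.01, tolerance = 1e-12)
  expect_equal(raggedness(c(1)), 1)  # point mass at zero differences
  # invariant to trailing zero classes
  expect_equal(raggedness(c(0.5, 0.5)), raggedness(c(0.5, 0.5, 0, 0, 0)))
})

test_that("log-space Ewens matches the exact brute-force recursion", {
  for (n in c(4, 6, 9, 12)) {
    for (theta in c(0.3, 1, 2.5, 7)) {
      expect_equal(ewens_allele_probs(n, theta), oracle_ewens(n, theta),
                   tolerance = 1e-10)
    }
  }
  # probabilities sum to 1
  expect_equal(sum(ewens_allele_probs(30, 5)), 1, tolerance = 1e-10)
})

test_that("Fu's Fs definition and degenerate handling", {
  # Fs = ln(S'/(1-S')) from the Ewens tail
  n <- 8; h <- 6; th <- 2.5
  pk <- oracle_ewens(n, th)
  sp <- sum(pk[h:n])
  res <- fus_fs(n = n, h = h, theta_pi = th)
  expect_equal(res$Fs, log(sp / (1 - sp)), tolerance = 1e-10)
  # theta = 0 -> NA
  expect_true(is.na(fus_fs(n = 5, h = 1, theta_pi = 0)$Fs))
  expect_error(fus_fs(n = 2, h = 1, theta_pi = 1), "n >= 3")
})

test_that("Fs is near zero under neutrality, strongly negative under expansion", {
  set.seed(12)
  fs_neutral <- replicate(40, {
    g <- fishpopgen:::sim_coalescent_summary(20, 3)
    if (g$theta_pi <= 0) return(NA)
    fus_fs(n = 20, h = g$h, theta_pi = g$theta_pi)$Fs
  })
  expect_lt(abs(median(fs_neutral, na.rm = TRUE)), 1.5)
  sim <- simulate_coalescent(30, 2000, theta0 = 1, theta1 = 1000, tau = 6,
                             seed = 17)
  fs_exp <- fus_fs(sim$alignment)
  expect_lt(fs_exp$Fs, -5)
})

test_that("SSD parametric bootstrap is seeded and sane", {
  set.seed(2)
  sim <- simulate_coalescent(20, 1500, theta0 = 1, theta1 = 1000, tau = 5,
                             seed = 23)
  obs <- mismatch_observed(sim$alignment)
  fit <- fit_sudden_expansion(obs)
  p1 <- ssd_pvalue(obs, fit, n = 20, B = 30, seed = 5)
  p2 <- ssd_pvalue(obs, fit, n = 20, B = 30, seed = 5)
  expect_identical(p1$P, p2$P)
  expect_gte(p1$P, 0)
  expect_lte(p1$P, 1)
})

test_that("bimodal two-clade data reject the expansion model", {
  sim <- simulate_structured(
    data.frame(population = c("a", "b"), region = c("w", "e"), n = 10),
    k = 3000, theta = 1, t_pop_split = 0.5, t_region_split = 40, seed = 29)
  obs <- mismatch_observed(sim$alignment)
  fit <- fit_sudden_expansion(obs)
  pv <- ssd_pvalue(obs, fit, n = 20, B = 60, seed = 6)
  expect_lt(pv$P, 0.1)
})

test_that("expansion dating follows the t = tau/2u chain", {
  et <- expansion_time(12.345, 1.69, 1855, 10)
  expect_equal(et$u, 2 * 1.69e-8 * 1855 * 10, tolerance = 1e-12)
  expect_equal(et$t_generations, 12.345 / (2 * et$u), tolerance = 1e-12)
  expect_equal(et$T_years, et$t_generations * 10)
  expect_equal(expansion_time(0, 1, 1000, 10)$T_ma, 0)
  expect_error(expansion_time(1, 0, 1000, 10), "positive")
  # T = tau/(4 mu k), independent of generation time
  set.seed(7)
  for (i in 1:10) {
    tau <- runif(1, 0, 20); mu <- runif(1, 0.5, 4); k <- sample(500:2000, 1)
    tg <- sample(1:30, 1)
    et <- expansion_time(tau, mu, k, tg)
    expect_equal(et$T_years, tau / (4 * (mu / 100 / 1e6) * k),
                 tolerance = 1e-9)
  }
})
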