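test_that("same seed gives byte-identical output", {
  s1 <- simulate_coalescent(12, 400, theta0 = 2, seed = 101)
  s2 <- simulate_coalescent(12, 400, theta0 = 2, seed = 101)
  expect_identical(s1$alignment$mat, s2$alignment$mat)
  b1 <- simulate_tetraploid_bands(list(A = list(L1 = c("10" = 0.5, "12" = 0.5))),
                                  5, seed = 7)
  b2 <- simulate_tetraploid_bands(list(A = list(L1 = c("10" = 0.5, "12" = 0.5))),
                                  5, seed = 7)
  expect_identical(b1, b2)
})

test_that("constant-size coalescent matches neutral expectations", {
  set.seed(71)
  n <- 10; theta <- 4
  pis <- replicate(400, {
    D <- fishpopgen:::sim_coalescent_pairdiff(n, theta)
    mean(D[upper.tri(D)])
  })
  expect_equal(mean(pis), theta, tolerance = 0.06)
  # E[S] = theta * sum 1/i via the sequence generator
  set.seed(72)
  Ss <- replicate(300, {
    sim <- simulate_coalescent(n, 5000, theta0 = theta)
    unname(attr(classify_sites(sim$alignment), "counts")["variable"])
  })
  expect_equal(mean(Ss), theta * sum(1 / (1:(n - 1))), tolerance = 0.07)
})

test_that("expansion scenario produces unimodal mismatch with mode near tau", {
  set.seed(73)
  acc <- numeric(40)
  for (r in 1:60) {
    D <- fishpopgen:::sim_coalescent_pairdiff(30, theta0 = 1, theta1 = 1000,
                                              tau = 6)
    o <- mismatch_observed(D)
    f <- c(o$freq, numeric(40))[1:40]
    acc <- acc + f
  }
  acc <- acc / 60
  expect_lte(abs(which.max(acc) - 1 - 6), 2)
  # high haplotype diversity, low nucleotide diversity signature
  sim <- simulate_coalescent(30, 2000, theta0 = 1, theta1 = 1000, tau = 6,
                             seed = 74)
  div <- nucleotide_diversity(sim$alignment)
  ht <- collapse_haplotypes(sim$alignment)
  expect_gt(haplotype_diversity(ht), 0.9)
  expect_lt(div$pi, 0.02)
})

test_that("deep region split shares no haplotypes; panmixia has low Phi", {
  sim <- simulate_structured(
    data.frame(population = c("w1", "w2", "e1"), region = c("w", "w", "e"),
               n = 8),
    k = 1500, theta = 2, t_pop_split = 1, t_region_split = 40, seed = 75)
  ht <- collapse_haplotypes(sim$alignment, sim$pop_map)
  west <- rowSums(ht$counts[, c("w1", "w2"), drop = FALSE]) > 0
  east <- ht$counts[, "e1"] > 0
  expect_equal(sum(west & east), 0)
  # panmictic control: negligible structure
  pan <- simulate_structured(
    data.frame(population = c("a", "b"), region = c("r", "r"), n = 10),
    k = 1000, theta = 3, t_pop_split = 0, t_region_split = 0, seed = 76)
  res <- amova(pairwise_differences(pan$alignment), pan$pop_map, n_perm = 0,
               two_level = FALSE)
  expect_lt(abs(unname(res$phi["phi_st"])), 0.15)
})

test_that("within-region migration homogenises populations", {
  mig <- simulate_structured(
    data.frame(population = c("a", "b"), region = c("r", "r"), n = 10),
    k = 1000, theta = 2, t_pop_split = 8, t_region_split = 8,
    migration = 10, seed = 77)
  nomig <- simulate_structured(
    data.frame(population = c("a", "b"), region = c("r", "r"), n = 10),
    k = 1000, theta = 2, t_pop_split = 8, t_region_split = 8,
    migration = 0, seed = 77)
  phi_m <- amova(pairwise_differences(mig$alignment), mig$pop_map,
                 n_perm = 0, two_level = FALSE)$phi["phi_st"]
  phi_0 <- amova(pairwise_differences(nomig$alignment), nomig$pop_map,
                 n_perm = 0, two_level = FALSE)$phi["phi_st"]
  expect_lt(unname(phi_m), unname(phi_0))
})

test_that("tetraploid band draws respect 1..4 bands and presence frequency", {
  freqs <- list(P = list(mono = c("100" = 1),
                         poly = c("90" = 0.3, "94" = 0.3, "98" = 0.4)))
  bpm <- simulate_tetraploid_bands(freqs, 50, seed = 81)
  nb <- lengths(strsplit(bpm$bands, ","))
  expect_true(all(nb >= 1 & nb <= 4))
  expect_true(all(nb[bpm$locus == "mono"] == 1))
  # presence frequency of a band ~ 1 - (1-p)^4
  big <- simulate_tetraploid_bands(
    list(P = list(L = c("10" = 0.2, "12" = 0.8))), 5000, seed = 82)
  has10 <- grepl("(^|,)10(,|$)", big$bands)
  expect_equal(mean(has10), 1 - 0.8^4, tolerance = 0.02)
})

test_that("hierarchical band generator has the requested F_CT", {
  set.seed(83)
  pops <- data.frame(population = paste0("p", 1:6),
                     region = rep(c("w", "e"), each = 3), n = 15)
  est <- replicate(15, {
    s <- simulate_band_presence(pops, n_bands = 150, f_ct = 0.2, f_sc = 0.05)
    unname(amova(binary_squared_distances(s$binary), s$pop_map,
                 n_perm = 0)$phi["phi_ct"])
  })
  expect_equal(mean(est), 0.2, tolerance = 0.05)
})
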