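test_that("binary transform is hand-checkable and lossless", {
  bpm <- make_band_toy()
  bb <- phenotypes_to_binary(bpm)
  # column count = sum of per-locus distinct band counts
  expect_equal(ncol(bb$binary),
               length(unique(c(151, 155, 159))) + length(unique(c(200, 204, 208))))
  expect_equal(unname(bb$binary["i1", c("L1:151", "L1:155", "L1:159")]),
               c(1L, 1L, 0L))
  expect_equal(unname(bb$binary["i1", c("L2:200", "L2:204", "L2:208")]),
               c(1L, 0L, 0L))
  expect_equal(unname(bb$binary["i5", "L1:159"]), 1L)
  # lossless for presence information
  back <- binary_to_phenotypes(bb)
  o1 <- bpm[order(bpm$individual, bpm$locus), c("individual", "locus", "bands")]
  o2 <- back[order(back$individual, back$locus), c("individual", "locus", "bands")]
  expect_equal(o1$bands, o2$bands)
  # validation: more than 4 bands
  bad <- bpm
  bad$bands[1] <- "1,2,3,4,5"
  expect_error(phenotypes_to_binary(bad), "i1/L1")
})

test_that("band diversity matches closed forms and brute force", {
  bpm <- make_band_toy()
  bb <- phenotypes_to_binary(bpm)
  div <- band_diversity(bb)
  # brute force per population
  for (p in c("A", "B")) {
    sub <- bb$binary[bb$pop_map$population[match(rownames(bb$binary),
                                                 bb$pop_map$id)] == p, ]
    pr <- colMeans(sub)
    H <- mean(2 * pr * (1 - pr))
    I <- mean(ifelse(pr <= 0 | pr >= 1, 0,
                     -(pr * log(pr) + (1 - pr) * log(1 - pr))))
    ppl <- 100 * mean(pr > 0 & pr < 1)
    row <- div[div$population == p, ]
    expect_equal(row$H, H, tolerance = 1e-12)
    expect_equal(row$I, I, tolerance = 1e-12)
    expect_equal(row$PPL, ppl, tolerance = 1e-12)
  }
  # p = 0.5 closed forms
  bin <- matrix(c(1, 0, 1, 0), 4, 1, dimnames = list(paste0("i", 1:4), "L:1"))
  pm <- data.frame(id = paste0("i", 1:4), population = "X", region = "all")
  d1 <- band_diversity(bin, pm)
  expect_equal(d1$H, 0.5)
  expect_equal(d1$I, log(2), tolerance = 1e-12)
  # monomorphic band contributes zero and is excluded from PPL
  bin2 <- cbind(bin, "L:2" = 1)
  d2 <- band_diversity(bin2, pm)
  expect_equal(d2$PPL, 50)
  expect_equal(d2$H, 0.25)
})

test_that("private bands are counted per population", {
  bpm <- make_band_toy()
  bb <- phenotypes_to_binary(bpm)
  div <- band_diversity(bb)
  # bands observed: A has L1:{151,155,159}, L2:{200,204}; B has
  # L1:{151,155,159}, L2:{204,208} -> A private: 200; B private: 208
  expect_equal(div$private_bands[div$population == "A"], 1)
  expect_equal(div$private_bands[div$population == "B"], 1)
})

test_that("HWE-dominant convention transforms the band frequency", {
  bin <- matrix(c(1, 1, 1, 0), 4, 1, dimnames = list(paste0("i", 1:4), "L:1"))
  pm <- data.frame(id = paste0("i", 1:4), population = "X", region = "all")
  q <- 1 - sqrt(1 - 0.75)
  dh <- band_diversity(bin, pm, hwe_dominant = TRUE)
  expect_equal(dh$H, 2 * q * (1 - q), tolerance = 1e-12)
})

test_that("Nei unbiased distance matches the hand formula", {
  set.seed(33)
  binA <- matrix(rbinom(8 * 10, 1, 0.6), 8, 10)
  binB <- matrix(rbinom(6 * 10, 1, 0.3), 6, 10)
  bin <- rbind(binA, binB)
  rownames(bin) <- sprintf("i%02d", 1:14)
  colnames(bin) <- sprintf("L:%d", 1:10)
  pm <- data.frame(id = rownames(bin),
                   population = rep(c("A", "B"), c(8, 6)), region = "all")
  got <- nei_unbiased_distance(bin, pm)
  expect_equal(got$D["A", "B"], oracle_nei_D(binA, binB), tolerance = 1e-12)
  # identical frequencies -> standard D exactly 0; the unbiased variant is
  # only 0 in expectation over sampling (the correction shrinks the
  # within-population identity)
  dup <- rbind(binA, binA)
  rownames(dup) <- sprintf("i%02d", 1:16)
  pm2 <- data.frame(id = rownames(dup),
                    population = rep(c("A", "B"), each = 8), region = "all")
  resd <- nei_unbiased_distance(dup, pm2)
  expect_equal(resd$D_standard["A", "B"], 0, tolerance = 1e-12)
  expect_lt(abs(resd$D["A", "B"]), 0.25)
  # disjoint band sets -> infinite distance, flagged
  x <- rbind(a1 = c(1L, 1L, 0L, 0L), b1 = c(0L, 0L, 1L, 1L),
             a2 = c(1L, 1L, 0L, 0L), b2 = c(0L, 0L, 1L, 1L))
  colnames(x) <- sprintf("L:%d", 1:4)
  pmx <- data.frame(id = rownames(x), population = c("A", "B", "A", "B"),
                    region = "all")
  resx <- nei_unbiased_distance(x, pmx)
  expect_true(is.infinite(resx$D["A", "B"]))
  expect_true(resx$infinite["A", "B"])
})

test_that("binary F_ST behaves at the boundaries", {
  set.seed(44)
  base <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  rownames(base) <- sprintf("i%02d", 1:20)
  colnames(base) <- sprintf("L:%d", 1:30)
  # duplicated population -> F_ST ~ 0
  pm <- data.frame(id = rownames(base),
                   population = rep(c("A", "B"), 10), region = "all")
  r0 <- binary_fst(base, pm, n_perm = 0, pairwise = FALSE)
  expect_lt(abs(unname(r0$amova$phi["phi_st"])), 0.1)
  # fully distinct band sets -> 1
  top <- cbind(matrix(1L, 10, 15), matrix(0L, 10, 15))
  bot <- cbind(matrix(0L, 10, 15), matrix(1L, 10, 15))
  sep <- rbind(top, bot)
  rownames(sep) <- sprintf("i%02d", 1:20)
  colnames(sep) <- sprintf("L:%d", 1:30)
  pm2 <- data.frame(id = rownames(sep),
                    population = rep(c("A", "B"), each = 10), region = "all")
  r1 <- binary_fst(sep, pm2, n_perm = 0, pairwise = FALSE)
  expect_equal(unname(r1$amova$phi["phi_st"]), 1)
})

test_that("PCoA recovers known configurations", {
  # collinear points: first axis carries all positive variance
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x))
  p <- pcoa(D)
  expect_equal(p$pct_variance[1], 100, tolerance = 1e-8)
  # 2-D configuration recovered up to rotation/reflection
  set.seed(51)
  X <- matrix(rnorm(12 * 2), 12, 2)
  p2 <- pcoa(as.matrix(dist(X)))
  expect_equal(ncol(p2$coordinates), 2)
  # Procrustes via cross-distance comparison: inter-point distances agree
  expect_equal(as.matrix(dist(p2$coordinates)), as.matrix(dist(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalue sum equals trace of the centered matrix
  D2 <- as.matrix(dist(X))
  n <- nrow(D2)
  J <- diag(n) - 1 / n
  B <- J %*% (-0.5 * D2^2) %*% J
  expect_equal(sum(p2$eigenvalues), sum(diag(B)), tolerance = 1e-8)
})

test_that("Evanno delta-K finds the elbow", {
  # L(K) exactly linear -> delta K = 0 everywhere interior
  ks <- 1:5
  L <- t(sapply(ks, function(k) c(-100 - 10 * k, -100.5 - 10 * k)))
  rownames(L) <- ks
  res <- evanno_delta_k(L)
  expect_equal(res$delta_K[2:4], rep(0, 3), tolerance = 1e-9)
  # pronounced elbow at K = 3
  lnp <- data.frame(
    K = rep(1:5, each = 3),
    lnP = c(-500, -501, -499, -400, -402, -401, -300, -299, -301,
            -295, -294, -296, -290, -291, -292))
  res2 <- evanno_delta_k(lnp)
  expect_equal(attr(res2, "best_K"), 3)
  # scaling all L(K) leaves the argmax unchanged
  lnp2 <- lnp; lnp2$lnP <- lnp2$lnP * 3.7
  expect_equal(attr(evanno_delta_k(lnp2), "best_K"), 3)
  # sd = 0 flagged
  lnp3 <- data.frame(K = rep(1:3, each = 2), lnP = rep(c(-10, -5, -4), each = 2))
  res3 <- evanno_delta_k(lnp3)
  expect_true(res3$sd_zero[2])
  expect_true(is.na(res3$delta_K[2]))
})
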