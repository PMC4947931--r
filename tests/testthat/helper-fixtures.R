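# Shared fixtures and independent brute-force oracles.

toy_alignment <- function() {
  # 6 sequences: AAA x3 (pop1), AAT x2 (pop1) + x1 (pop2)
  seqs <- c(a1 = "AAA", a2 = "AAA", a3 = "AAA", b1 = "AAT", b2 = "AAT",
            c1 = "AAT")
  list(aln = dna_alignment(seqs),
       pm = data.frame(id = names(seqs),
                       population = c("pop1", "pop1", "pop1", "pop1", "pop1",
                                      "pop2"),
                       region = "all", stringsAsFactors = FALSE))
}

random_alignment <- function(n, k, seed = 1, bases = c("A", "C", "G", "T")) {
  set.seed(seed)
  m <- matrix(sample(bases, n * k, replace = TRUE), n, k)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  dna_alignment(m)
}

# brute-force nucleotide diversity over explicit pair loops
oracle_pi_K <- function(aln) {
  m <- aln$mat
  n <- nrow(m)
  ks <- 0; ps <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
    d <- sum(m[i, ok] != m[j, ok])
    ks <- ks + d
    ps <- ps + d / sum(ok)
    np <- np + 1
  }
  list(K = ks / np, pi = ps / np)
}

# brute-force K2P from explicit transition/transversion counting
oracle_k2p <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  pur <- c("A", "G")
  P <- mean(a != b & ((a %in% pur) == (b %in% pur)))
  Q <- mean(a != b & ((a %in% pur) != (b %in% pur)))
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# classical nested ANOVA variance components computed from coordinates
# (not from pairwise distances): the independent oracle for AMOVA.
oracle_nested_anova <- function(X, pop, reg = NULL) {
  X <- as.matrix(X)
  N <- nrow(X)
  pops <- unique(pop)
  P <- length(pops)
  gm <- colMeans(X)
  ss_wp <- 0
  for (p in pops) {
    idx <- which(pop == p)
    pm <- colMeans(X[idx, , drop = FALSE])
    ss_wp <- ss_wp + sum(sweep(X[idx, , drop = FALSE], 2, pm)^2)
  }
  n_p <- vapply(pops, function(p) sum(pop == p), 0L)
  if (is.null(reg)) {
    ss_ap <- 0
    for (p in pops) {
      idx <- which(pop == p)
      pm <- colMeans(X[idx, , drop = FALSE])
      ss_ap <- ss_ap + length(idx) * sum((pm - gm)^2)
    }
    ms_wp <- ss_wp / (N - P)
    ms_ap <- ss_ap / (P - 1)
    n_c <- (N - sum(n_p^2) / N) / (P - 1)
    sigma_c <- ms_wp
    sigma_a <- (ms_ap - sigma_c) / n_c
    c(among = sigma_a, within = sigma_c)
  } else {
    regs <- unique(reg)
    G <- length(regs)
    reg_of_pop <- vapply(pops, function(p) reg[match(p, pop)], "")
    n_g <- vapply(regs, function(g) sum(reg == g), 0L)
    ss_ag <- 0; ss_ap <- 0
    for (g in regs) {
      idx <- which(reg == g)
      rm_ <- colMeans(X[idx, , drop = FALSE])
      ss_ag <- ss_ag + length(idx) * sum((rm_ - gm)^2)
      for (p in pops[reg_of_pop == g]) {
        pidx <- which(pop == p)
        pm <- colMeans(X[pidx, , drop = FALSE])
        ss_ap <- ss_ap + length(pidx) * sum((pm - rm_)^2)
      }
    }
    ms_wp <- ss_wp / (N - P)
    ms_ap <- ss_ap / (P - G)
    ms_ag <- ss_ag / (G - 1)
    sum_npsq_over_ng <- sum(vapply(regs, function(g) {
      inp <- pops[reg_of_pop == g]
      sum(n_p[inp]^2) / sum(n_p[inp])
    }, 0))
    n1 <- (N - sum_npsq_over_ng) / (P - G)
    n2 <- (sum_npsq_over_ng - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(n_g^2) / N) / (G - 1)
    sigma_c <- ms_wp
    sigma_b <- (ms_ap - sigma_c) / n1
    sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
    c(among_regions = sigma_a, among_pops = sigma_b, within = sigma_c)
  }
}

# exact unsigned Stirling numbers of the first kind via plain integer
# recursion (safe in doubles for n <= 12), and plain-arithmetic Ewens
oracle_ewens <- function(n, theta) {
  S <- matrix(0, n + 1, n + 1)
  S[1 + 1, 1 + 1] <- 1
  for (m in 1:(n - 1)) {
    for (k in 1:(m + 1)) {
      S[m + 2, k + 1] <- m * S[m + 1, k + 1] + S[m + 1, k]
    }
  }
  s <- S[n + 1, 1 + (1:n)]
  rising <- prod(theta + 0:(n - 1))
  s * theta^(1:n) / rising
}

# hand Nei unbiased identity/distance for two populations of binary bands
oracle_nei_D <- function(binA, binB) {
  pA <- colMeans(binA); pB <- colMeans(binB)
  nA <- nrow(binA); nB <- nrow(binB)
  jA <- mean((nA * (pA^2 + (1 - pA)^2) - 1) / (nA - 1))
  jB <- mean((nB * (pB^2 + (1 - pB)^2) - 1) / (nB - 1))
  jAB <- mean(pA * pB + (1 - pA) * (1 - pB))
  -log(jAB / sqrt(jA * jB))
}

make_band_toy <- function() {
  # 5 individuals x 2 loci, hand-designed band sets
  data.frame(
    individual = rep(c("i1", "i2", "i3", "i4", "i5"), each = 2),
    population = rep(c("A", "A", "A", "B", "B"), each = 2),
    locus = rep(c("L1", "L2"), 5),
    bands = c("151,155", "200", "151", "200,204", "155,159", "200",
              "151,155,159", "204", "159", "204,208"),
    stringsAsFactors = FALSE)
}
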