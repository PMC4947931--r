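# Hierarchical analysis of molecular variance from pairwise distances
# (Excoffier, Smouse & Quattro 1992 style), with permutation tests.

# Sum over unordered pairs within an index set of a squared-distance matrix.
.pair_sum <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx]) / 2
}

# Variance components for a one- or two-level design.
# pop, reg: character vectors aligned with rows of d2.
.amova_components <- function(d2, pop, reg = NULL) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  n_p <- vapply(pops, function(p) sum(pop == p), 0L)
  ss_total <- .pair_sum(d2, seq_len(N)) / N
  ss_wp <- sum(vapply(pops, function(p) {
    idx <- which(pop == p)
    .pair_sum(d2, idx) / length(idx)
  }, 0))
  if (is.null(reg)) {
    df_ap <- P - 1L
    df_wp <- N - P
    ms_wp <- (ss_wp) / df_wp
    ss_ap <- ss_total - ss_wp
    ms_ap <- ss_ap / df_ap
    n_c <- (N - sum(n_p^2) / N) / df_ap
    sigma_c <- ms_wp
    sigma_a <- (ms_ap - sigma_c) / n_c
    total <- sigma_a + sigma_c
    list(levels = 1L,
         df = c(among_pops = df_ap, within_pops = df_wp),
         ss = c(among_pops = ss_ap, within_pops = ss_wp),
         sigma = c(among_pops = sigma_a, within_pops = sigma_c),
         phi = c(phi_st = sigma_a / total))
  } else {
    regs <- unique(reg)
    G <- length(regs)
    df_ag <- G - 1L
    df_ap <- P - G
    df_wp <- N - P
    ss_wg <- sum(vapply(regs, function(g) {
      idx <- which(reg == g)
      .pair_sum(d2, idx) / length(idx)
    }, 0))
    ss_ag <- ss_total - ss_wg
    ss_ap <- ss_wg - ss_wp
    ms_wp <- ss_wp / df_wp
    ms_ap <- ss_ap / df_ap
    ms_ag <- ss_ag / df_ag
    # unequal-sample-size coefficients
    reg_of_pop <- vapply(pops, function(p) reg[match(p, pop)], "")
    n_g <- vapply(regs, function(g) sum(reg == g), 0L)
    sum_npsq_over_ng <- sum(vapply(regs, function(g) {
      inpops <- pops[reg_of_pop == g]
      sum(n_p[inpops]^2) / sum(n_p[inpops])
    }, 0))
    n1 <- (N - sum_npsq_over_ng) / df_ap
    n2 <- (sum_npsq_over_ng - sum(n_p^2) / N) / df_ag
    n3 <- (N - sum(n_g^2) / N) / df_ag
    sigma_c <- ms_wp
    sigma_b <- (ms_ap - sigma_c) / n1
    sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
    total <- sigma_a + sigma_b + sigma_c
    list(levels = 2L,
         df = c(among_regions = df_ag, among_pops_within = df_ap,
                within_pops = df_wp),
         ss = c(among_regions = ss_ag, among_pops_within = ss_ap,
                within_pops = ss_wp),
         sigma = c(among_regions = sigma_a, among_pops_within = sigma_b,
                   within_pops = sigma_c),
         phi = c(phi_ct = sigma_a / total,
                 phi_sc = sigma_b / (sigma_b + sigma_c),
                 phi_st = (sigma_a + sigma_b) / total))
  }
}

#' Analysis of molecular variance (AMOVA)
#'
#' Partitions molecular variance from a matrix of squared pairwise
#' inter-individual distances into nested components (among regions, among
#' populations within regions, within populations) by equating observed mean
#' squares to their expectations with unequal-sample-size coefficients.
#' For sequence data pass the pairwise difference-count matrix
#' ([pairwise_differences]); for binary band data the squared Euclidean
#' distances between 0/1 rows.
#'
#' Fixation-index significance uses the standard permutation schemes:
#' Phi_ST permutes individuals among populations over the whole sample;
#' Phi_SC permutes individuals among populations within regions; Phi_CT
#' permutes whole populations among regions (exact enumeration when the
#' arrangement space is smaller than `n_perm`).  Negative variance
#' components are retained in the index formulas but flagged.
#'
#' @param d2 symmetric matrix of squared distances, zero diagonal, with ids
#'   as dimnames.
#' @param design population map (see [as_pop_map]).  Region column with >= 2
#'   distinct values triggers the two-level design unless `two_level=FALSE`.
#' @param n_perm permutations for P-values (0 to skip testing).
#' @param seed RNG seed.
#' @param two_level force one-/two-level; default auto.
#' @return an `amova_result`: list with `table` (data frame: source, df, SS,
#'   variance component, percentage, fixation index, P), `phi`, `sigma`,
#'   `negative_components` flag, `n_perm`, `permutation` details.
#' @export
amova <- function(d2, design, n_perm = 10000, seed = 1, two_level = NULL) {
  design <- as_pop_map(design)
  ids <- rownames(d2)
  if (is.null(ids)) stop("distance matrix needs ids as dimnames")
  idx <- match(ids, design$id)
  if (anyNA(idx)) stop("ids missing from design: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  pop <- design$population[idx]
  reg <- design$region[idx]
  if (is.null(two_level)) two_level <- length(unique(reg)) >= 2
  if (!two_level) reg <- NULL
  pops <- unique(pop)
  if (length(pops) < 2) stop("AMOVA needs >= 2 populations")
  n_p <- table(pop)
  if (any(n_p == 1)) {
    warning("singleton population(s): ",
            paste(names(n_p)[n_p == 1], collapse = ", "),
            "; degrees of freedom absorb them")
  }
  obs <- .amova_components(d2, pop, reg)
  pvals <- rep(NA_real_, length(obs$phi))
  names(pvals) <- names(obs$phi)
  perm_info <- list()
  if (n_perm > 0) {
    set.seed(seed)
    N <- length(pop)
    if (is.null(reg)) {
      stat <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        stat[b] <- .amova_components(d2, sample(pop), NULL)$phi["phi_st"]
      }
      pvals["phi_st"] <- (sum(stat >= obs$phi["phi_st"]) + 1) / (n_perm + 1)
      perm_info$phi_st <- list(type = "random", n = n_perm)
    } else {
      # Phi_ST: individuals among populations, whole sample
      st <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        ord <- sample.int(N)
        st[b] <- .amova_components(d2, pop[ord], reg[ord])$phi["phi_st"]
      }
      pvals["phi_st"] <- (sum(st >= obs$phi["phi_st"]) + 1) / (n_perm + 1)
      perm_info$phi_st <- list(type = "random", n = n_perm)
      # Phi_SC: individuals among populations within regions
      sc <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        p2 <- pop
        for (g in unique(reg)) {
          w <- which(reg == g)
          p2[w] <- p2[sample(w)]
        }
        sc[b] <- .amova_components(d2, p2, reg)$phi["phi_sc"]
      }
      pvals["phi_sc"] <- (sum(sc >= obs$phi["phi_sc"]) + 1) / (n_perm + 1)
      perm_info$phi_sc <- list(type = "random", n = n_perm)
      # Phi_CT: whole populations among regions
      reg_of_pop <- vapply(pops, function(p) reg[match(p, pop)], "")
      G <- length(unique(reg))
      P <- length(pops)
      n_arr <- choose(P, sum(reg_of_pop == unique(reg_of_pop)[1]))
      if (G == 2 && n_arr <= n_perm) {
        sz <- sum(reg_of_pop == unique(reg_of_pop)[1])
        combs <- combn(P, sz)
        ct <- apply(combs, 2, function(sel) {
          rp <- rep(unique(reg_of_pop)[2], P)
          rp[sel] <- unique(reg_of_pop)[1]
          names(rp) <- pops
          .amova_components(d2, pop, rp[pop])$phi["phi_ct"]
        })
        pvals["phi_ct"] <- mean(ct >= obs$phi["phi_ct"] - 1e-12)
        perm_info$phi_ct <- list(type = "exact", n = ncol(combs))
      } else {
        ct <- numeric(n_perm)
        for (b in seq_len(n_perm)) {
          rp <- setNames(sample(reg_of_pop), pops)
          ct[b] <- .amova_components(d2, pop, rp[pop])$phi["phi_ct"]
        }
        pvals["phi_ct"] <- (sum(ct >= obs$phi["phi_ct"]) + 1) / (n_perm + 1)
        perm_info$phi_ct <- list(type = "random", n = n_perm)
      }
    }
  }
  sigma <- obs$sigma
  neg <- any(sigma < 0)
  sig_disp <- pmax(sigma, 0)
  pct <- 100 * sig_disp / sum(sig_disp)
  src <- if (obs$levels == 1L) {
    c("Among populations", "Within populations")
  } else {
    c("Between regions", "Among populations within regions",
      "Within populations")
  }
  phi_col <- if (obs$levels == 1L) {
    c("phi_st", NA)
  } else c("phi_ct", "phi_sc", "phi_st")
  tab <- data.frame(
    source = src, df = unname(obs$df), SS = unname(obs$ss),
    variance = unname(sigma), percentage = unname(pct),
    index = phi_col,
    phi = ifelse(is.na(phi_col), NA_real_, unname(obs$phi[phi_col])),
    P = ifelse(is.na(phi_col), NA_real_, unname(pvals[phi_col])),
    stringsAsFactors = FALSE)
  structure(list(table = tab, phi = obs$phi, sigma = sigma, pvals = pvals,
                 negative_components = neg, n_perm = n_perm,
                 permutation = perm_info, levels = obs$levels),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$levels, "-level design)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  if (x$negative_components) {
    cat("note: negative variance component(s) retained in indices,",
        "truncated at 0 for percentages\n")
  }
  invisible(x)
}

#' Pairwise Phi_ST between populations
#'
#' Each population pair is analysed as a one-level two-population AMOVA on
#' the corresponding submatrix of squared distances.
#'
#' @param d2 squared-distance matrix between individuals (ids as dimnames).
#' @param pop_map population map.
#' @param n_perm permutations per pair (0 to skip).
#' @param seed RNG seed.
#' @param bonferroni apply Bonferroni correction across pairs (alpha scaled
#'   by the number of pairs); adds a `significant` logical matrix.
#' @param alpha family-wise level for the Bonferroni flag.
#' @return list with matrices `phi_st`, `P`, and (if requested)
#'   `significant`.
#' @export
pairwise_phi_st <- function(d2, pop_map, n_perm = 1000, seed = 1,
                            bonferroni = TRUE, alpha = 0.05) {
  pop_map <- as_pop_map(pop_map)
  ids <- rownames(d2)
  pop <- pop_map$population[match(ids, pop_map$id)]
  lev <- unique(pop)
  P <- length(lev)
  phi <- matrix(NA_real_, P, P, dimnames = list(lev, lev))
  pv <- phi
  npair <- P * (P - 1) / 2
  pair_seed <- seed
  for (i in seq_len(P - 1)) {
    for (j in seq.int(i + 1, P)) {
      sel <- which(pop %in% c(lev[i], lev[j]))
      sub <- d2[sel, sel, drop = FALSE]
      dsub <- data.frame(id = ids[sel], population = pop[sel],
                         region = "all", stringsAsFactors = FALSE)
      pair_seed <- pair_seed + 1
      res <- amova(sub, dsub, n_perm = n_perm, seed = pair_seed,
                   two_level = FALSE)
      phi[i, j] <- phi[j, i] <- unname(res$phi["phi_st"])
      pv[i, j] <- pv[j, i] <- unname(res$pvals["phi_st"])
    }
  }
  diag(phi) <- 0
  out <- list(phi_st = phi, P = pv)
  if (bonferroni && n_perm > 0) {
    out$significant <- pv < alpha / npair
    out$alpha_adjusted <- alpha / npair
  }
  out
}

#' Export an AMOVA table as CSV
#' @param x an `amova_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_amova_csv <- function(x, path) {
  tab <- x$table
  tab$stars <- ifelse(is.na(tab$P), "",
                      ifelse(tab$P < 0.001, "***",
                             ifelse(tab$P < 0.01, "**",
                                    ifelse(tab$P < 0.05, "*", ""))))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
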