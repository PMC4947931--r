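# Coalescent and band-phenotype simulators.  Time is measured in mutational
# units throughout (tau = 2ut): a pair of lineages accumulates differences at
# rate 1 and coalesces at rate 1/theta per unit, so E[pairwise diff] = theta
# at equilibrium and E[S] = theta * sum_{i<n} 1/i.

# Simulate an n-coalescent genealogy under a piecewise-constant size:
# scaled size theta1 from the present back to tau, theta0 earlier.
# Returns edge list: parent, child, length (tau units), for nodes 1..2n-1
# (tips 1..n, root 2n-1).
sim_coalescent_tree <- function(n, theta0, theta1 = theta0, tau = Inf) {
  active <- seq_len(n)
  node_time <- numeric(2 * n - 1)
  parent <- integer(2 * n - 1)
  nxt <- n + 1L
  s <- 0
  while (length(active) > 1L) {
    j <- length(active)
    repeat {
      theta <- if (s < tau) theta1 else theta0
      if (theta <= 0) { w <- 0 } else {
        rate <- choose(j, 2) / theta
        w <- rexp(1, rate)
      }
      if (s < tau && s + w > tau) { s <- tau; next }  # rate changes at tau
      s <- s + w
      break
    }
    pair <- sample.int(j, 2L)
    a <- active[pair[1]]; b <- active[pair[2]]
    node_time[nxt] <- s
    parent[a] <- nxt; parent[b] <- nxt
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  root <- 2L * n - 1L
  child <- seq_len(2L * n - 2L)
  list(n = n, parent = parent[child], child = child,
       length = node_time[parent[child]] - node_time[child],
       node_time = node_time, root = root)
}

# Tip sets below each edge (child node) as a logical n x n_edges matrix.
.tips_below <- function(tree) {
  n <- tree$n
  n_nodes <- 2L * n - 1L
  below <- matrix(FALSE, n, n_nodes)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  # children have smaller index than parents by construction
  for (v in seq_len(n_nodes - 1L)) {
    below[, tree$parent[v]] <- below[, tree$parent[v]] | below[, v]
  }
  below
}

# Pairwise difference-count matrix under the infinite-sites model for a
# simulated genealogy; the workhorse for mismatch bootstraps.
sim_coalescent_pairdiff <- function(n, theta0, theta1 = theta0, tau = Inf) {
  tree <- sim_coalescent_tree(n, theta0, theta1, tau)
  muts <- rpois(length(tree$child), tree$length / 2)
  D <- matrix(0L, n, n)
  below <- .tips_below(tree)
  for (e in which(muts > 0L)) {
    inb <- below[, tree$child[e]]
    D[inb, !inb] <- D[inb, !inb] + muts[e]
    D[!inb, inb] <- D[!inb, inb] + muts[e]
  }
  D
}

# Summary statistics (theta_pi, haplotype count, S) of a neutral
# constant-size coalescent sample; used for Fu's Fs null distributions.
sim_coalescent_summary <- function(n, theta) {
  D <- sim_coalescent_pairdiff(n, theta)
  cls <- integer(n)
  h <- 0L
  for (i in seq_len(n)) {
    if (cls[i] == 0L) {
      h <- h + 1L
      cls[D[i, ] == 0L] <- h
    }
  }
  list(theta_pi = mean(D[upper.tri(D)]), h = h)
}

#' Simulate aligned sequences under a sudden-expansion coalescent
#'
#' Draws an n-coalescent genealogy with piecewise-constant scaled size
#' (theta1 from the present back to tau, theta0 earlier; constant size when
#' `tau = Inf` or theta0 = theta1), places Poisson mutations on branches,
#' and emits aligned sequences of length `k`.  Under `model = "infinite"`
#' each mutation hits a fresh site (error if mutations exceed k); under
#' `model = "finite"` sites are drawn uniformly with a transition:transversion
#' bias so repeat hits can occur.
#'
#' @param n sample size.
#' @param k sequence length (sites).
#' @param theta0,theta1 pre-/post-expansion scaled sizes.
#' @param tau expansion age in mutational units (Inf = constant size).
#' @param model "infinite" or "finite" sites.
#' @param ts_tv transition:transversion ratio for the finite-sites model.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param population population label for the emitted map.
#' @return list with `alignment` (a [dna_alignment]) and `pop_map`.
#' @export
simulate_coalescent <- function(n, k = 1000, theta0 = 1, theta1 = theta0,
                                tau = Inf, model = c("infinite", "finite"),
                                ts_tv = 10, seed = NULL, population = "pop1") {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  tree <- sim_coalescent_tree(n, theta0, theta1, tau)
  aln <- .mutate_tree_sequences(tree, k, model, ts_tv)
  ids <- sprintf("%s_%03d", population, seq_len(n))
  rownames(aln) <- ids
  list(alignment = dna_alignment(aln),
       pop_map = data.frame(id = ids, population = population,
                            region = "all", stringsAsFactors = FALSE))
}

# Evolve sequences down a genealogy. Returns an n x k character matrix.
.mutate_tree_sequences <- function(tree, k, model, ts_tv) {
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  n <- tree$n
  muts <- rpois(length(tree$child), tree$length / 2)
  root_seq <- sample(bases, k, replace = TRUE)
  if (model == "infinite") {
    total <- sum(muts)
    if (total > k) {
      stop("infinite-sites model needs k >= total mutations (", total, ")")
    }
    free_sites <- sample.int(k, total)
  }
  seqs <- matrix(NA_character_, n, k)
  # children of each node
  kids <- split(tree$child, tree$parent)
  used <- 0L
  assign_down <- function(node, seq_now) {
    if (node <= n) { seqs[node, ] <<- seq_now; return(invisible()) }
    for (ch in kids[[as.character(node)]]) {
      e <- ch  # edge index == child node index
      s <- seq_now
      m <- muts[e]
      if (m > 0L) {
        if (model == "infinite") {
          sites <- free_sites[(used + 1L):(used + m)]
          used <<- used + m
        } else {
          sites <- sample.int(k, m, replace = TRUE)
        }
        p_ts <- ts_tv / (ts_tv + 1)
        for (site in sites) {
          cur <- s[site]
          s[site] <- if (runif(1) < p_ts) ts_partner[[cur]] else
            sample(tv_partners[[cur]], 1L)
        }
      }
      assign_down(ch, s)
    }
    invisible()
  }
  assign_down(tree$root, root_seq)
  seqs
}

#' Simulate a two-region hierarchically structured sample
#'
#' Populations within a region descend from a common ancestral population at
#' depth `t_pop_split`; the two regions merge at depth `t_region_split`
#' (both in mutational units, `t_region_split > t_pop_split`).  Within a
#' region, lineages may migrate between populations at rate `migration` per
#' lineage per unit before `t_pop_split`.  Deep region splits with no
#' migration produce no shared haplotypes between regions.
#'
#' @param pops data frame with columns `population`, `region`, `n`
#'   (sample size per population).
#' @param k sequence length.
#' @param theta scaled size of each extant and ancestral population.
#' @param t_pop_split,t_region_split split depths (mutational units).
#' @param migration within-region migration rate per lineage.
#' @param model,ts_tv as in [simulate_coalescent].
#' @param seed RNG seed.
#' @param km_positions optional named vector of river positions (km) per
#'   population; default equal 100 km spacing in the order given.
#' @return list with `alignment`, `pop_map`, and `geo_km` (population
#'   distance matrix).
#' @export
simulate_structured <- function(pops, k = 1000, theta = 2,
                                t_pop_split = 2, t_region_split = 20,
                                migration = 0, model = "infinite",
                                ts_tv = 10, seed = NULL,
                                km_positions = NULL) {
  stopifnot(t_region_split >= t_pop_split)
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(pops)
  n_tot <- sum(pops$n)
  tip_pop <- rep(pops$population, pops$n)
  tip_reg <- rep(pops$region, pops$n)
  # structured coalescent, event-driven
  deme <- rep(seq_len(P), pops$n)      # deme of each active lineage
  active <- seq_len(n_tot)
  node_time <- numeric(2 * n_tot - 1)
  parent <- integer(2 * n_tot - 1)
  nxt <- n_tot + 1L
  s <- 0
  phase <- 1L  # 1: pops separate; 2: regions separate; 3: one pool
  reg_of_deme <- match(pops$region, unique(pops$region))
  R <- length(unique(pops$region))
  n_demes <- P + R + 1L
  repeat {
    if (length(active) == 1L) break
    # per-deme lineage counts
    cnt <- tabulate(deme[active], nbins = n_demes)
    coal_rates <- choose(cnt, 2) / theta
    mig_rate <- if (phase == 1L && migration > 0) migration * length(active) else 0
    tot <- sum(coal_rates) + mig_rate
    w <- if (tot > 0) rexp(1, tot) else Inf
    nxt_event <- s + w
    if (phase == 1L && nxt_event > t_pop_split) {
      s <- t_pop_split
      deme[active] <- P + reg_of_deme[pmin(deme[active], P)]
      # merged into one deme per region (demes P+1, P+2)
      phase <- 2L
      next
    }
    if (phase == 2L && nxt_event > t_region_split) {
      s <- t_region_split
      deme[active] <- n_demes  # one ancestral pool
      phase <- 3L
      next
    }
    s <- nxt_event
    u <- runif(1) * tot
    if (u < mig_rate) {
      # migrate a random lineage to another deme in its region
      li <- active[sample.int(length(active), 1L)]
      d <- deme[li]
      mates <- which(reg_of_deme == reg_of_deme[d])
      mates <- setdiff(mates, d)
      if (length(mates)) deme[li] <- mates[sample.int(length(mates), 1L)]
      next
    }
    u <- u - mig_rate
    d <- which(cumsum(coal_rates) >= u)[1L]
    members <- active[deme[active] == d]
    pair <- sample(members, 2L)
    node_time[nxt] <- s
    parent[pair] <- nxt
    deme[nxt] <- d
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  child <- seq_len(2L * n_tot - 2L)
  tree <- list(n = n_tot, parent = parent[child], child = child,
               length = node_time[parent[child]] - node_time[child],
               node_time = node_time, root = 2L * n_tot - 1L)
  aln <- .mutate_tree_sequences(tree, k, model, ts_tv)
  ids <- sprintf("%s_%03d", tip_pop, unlist(lapply(pops$n, seq_len)))
  rownames(aln) <- ids
  pm <- data.frame(id = ids, population = tip_pop, region = tip_reg,
                   stringsAsFactors = FALSE)
  if (is.null(km_positions)) {
    km_positions <- setNames(100 * (seq_len(P) - 1), pops$population)
  }
  geo <- abs(outer(km_positions[pops$population],
                   km_positions[pops$population], "-"))
  dimnames(geo) <- list(pops$population, pops$population)
  list(alignment = dna_alignment(aln), pop_map = pm, geo_km = geo)
}

#' Simulate tetraploid microsatellite band phenotypes
#'
#' Four alleles are drawn per individual per locus (tetrasomic inheritance)
#' from population allele frequencies; the observed phenotype is the set of
#' distinct band sizes (1 to 4 bands).
#'
#' @param pop_allele_freqs named list (per population) of named lists (per
#'   locus) of named numeric frequency vectors (names = band sizes); each
#'   vector must sum to 1.
#' @param n_per_pop individuals per population (single value or named).
#' @param seed RNG seed.
#' @return a `band_phenotypes` data frame: columns `individual`,
#'   `population`, `locus`, `bands` (comma-separated sizes).
#' @export
simulate_tetraploid_bands <- function(pop_allele_freqs, n_per_pop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- names(pop_allele_freqs)
  if (length(n_per_pop) == 1L) {
    n_per_pop <- setNames(rep(n_per_pop, length(pops)), pops)
  }
  rows <- list()
  for (p in pops) {
    loci <- pop_allele_freqs[[p]]
    for (i in seq_len(n_per_pop[[p]])) {
      ind <- sprintf("%s_%03d", p, i)
      for (loc in names(loci)) {
        fr <- loci[[loc]]
        if (abs(sum(fr) - 1) > 1e-8) {
          stop("allele frequencies must sum to 1 (", p, "/", loc, ")")
        }
        alleles <- sample(names(fr), 4L, replace = TRUE, prob = fr)
        bands <- sort(unique(as.integer(alleles)))
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, population = p, locus = loc,
          bands = paste(bands, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("band_phenotypes", "data.frame")
  out
}

#' Simulate hierarchically structured binary band data
#'
#' Balding-Nichols-style generator for dominant (presence/absence) band
#' data with a two-level hierarchy: per band, the regional presence
#' frequency is Beta-distributed around an ancestral frequency with
#' variance F_ct * p(1-p); population frequencies are Beta around their
#' region with relative variance F_sc; individuals are Bernoulli draws.
#' The generating AMOVA components then satisfy
#' sigma_a/sigma_total = F_ct and sigma_b/(sigma_b + sigma_c) ~ F_sc.
#'
#' @param pops data frame with columns `population`, `region`, `n`.
#' @param n_bands number of binary band columns.
#' @param f_ct,f_sc generating fixation indices.
#' @param p_anc ancestral presence frequencies (single value or vector of
#'   length `n_bands`); default drawn Uniform(0.2, 0.8).
#' @param seed RNG seed.
#' @return list with `binary` (individuals x bands 0/1 matrix) and
#'   `pop_map`.
#' @export
simulate_band_presence <- function(pops, n_bands = 200, f_ct = 0.09,
                                   f_sc = 0.05, p_anc = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p_anc)) p_anc <- runif(n_bands, 0.2, 0.8)
  if (length(p_anc) == 1L) p_anc <- rep(p_anc, n_bands)
  regions <- unique(pops$region)
  rbeta_fix <- function(m, p, f) {
    # Beta with mean p, variance f*p*(1-p); degenerate when f = 0
    if (f <= 0) return(rep(p, m))
    a <- p * (1 - f) / f
    b <- (1 - p) * (1 - f) / f
    rbeta(m, a, b)
  }
  p_reg <- sapply(regions, function(r) {
    vapply(p_anc, function(p) rbeta_fix(1, p, f_ct), 0)
  })  # n_bands x regions
  mats <- list()
  ids <- character(0); popv <- character(0); regv <- character(0)
  for (i in seq_len(nrow(pops))) {
    r <- match(pops$region[i], regions)
    p_pop <- vapply(p_reg[, r], function(p) rbeta_fix(1, p, f_sc), 0)
    X <- matrix(rbinom(pops$n[i] * n_bands, 1, rep(p_pop, each = pops$n[i])),
                nrow = pops$n[i])
    mats[[i]] <- X
    id_i <- sprintf("%s_%03d", pops$population[i], seq_len(pops$n[i]))
    ids <- c(ids, id_i)
    popv <- c(popv, rep(pops$population[i], pops$n[i]))
    regv <- c(regv, rep(pops$region[i], pops$n[i]))
  }
  bin <- do.call(rbind, mats)
  dimnames(bin) <- list(ids, sprintf("band%03d", seq_len(n_bands)))
  list(binary = bin,
       pop_map = data.frame(id = ids, population = popv, region = regv,
                            stringsAsFactors = FALSE))
}
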