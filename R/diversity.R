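# Sequence diversity indices, K2P distances, NJ trees with bootstrap.

#' Haplotype (gene) diversity
#'
#' Nei's estimator Hd = n/(n-1) * (1 - sum p_i^2) where p_i are haplotype
#' relative frequencies.
#'
#' @param ht a `haplotype_table`, or an integer vector of haplotype counts.
#' @return haplotype diversity in [0, 1].
#' @export
haplotype_diversity <- function(ht) {
  counts <- if (inherits(ht, "haplotype_table")) rowSums(ht$counts) else ht
  n <- sum(counts)
  if (n < 2) stop("undefined statistic: haplotype diversity needs n >= 2")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity and mean pairwise differences
#'
#' K is the mean number of pairwise nucleotide differences over all C(n,2)
#' unordered pairs; pi divides each pair's difference count by the number of
#' sites compared for that pair (pairwise deletion of gap/N positions) and
#' averages, so pi = mean per-site difference and K = mean per-pair count.
#'
#' @param aln a `dna_alignment`.
#' @param pop_map optional population map; when given, statistics are
#'   returned per population (and for the pooled sample as row "all").
#' @return data frame with columns `group`, `n`, `S`, `h`, `Hd`, `K`, `pi`.
#' @export
nucleotide_diversity <- function(aln, pop_map = NULL) {
  groups <- list(all = aln$ids)
  if (!is.null(pop_map)) {
    pop_map <- as_pop_map(pop_map)
    pops <- pop_map$population[match(aln$ids, pop_map$id)]
    groups <- c(groups, split(aln$ids, pops))
  }
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    sub <- subset_alignment(aln, ids)
    n <- length(ids)
    if (n < 2) stop("undefined statistic: n < 2 in group ", g)
    pd <- pairwise_differences(sub, effective_length = TRUE)
    ut <- upper.tri(pd$diff)
    K <- mean(pd$diff[ut])
    pi <- mean(pd$diff[ut] / pd$sites[ut])
    ss <- classify_sites(sub)
    ht <- collapse_haplotypes(sub)
    data.frame(group = g, n = n, S = unname(attr(ss, "counts")["variable"]),
               h = length(ht$sequences), Hd = haplotype_diversity(ht),
               K = K, pi = pi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kimura two-parameter distance between two sequences
#'
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q), with P and Q the proportions
#' of sites showing a transition and a transversion difference among sites
#' compared (pairwise deletion of gap/N).
#'
#' @param a,b character strings or character vectors of equal length.
#' @return list with `d`, `P`, `Q`, `sites`.
#' @export
k2p <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  ns <- length(a)
  diffs <- a != b
  ts <- sum(diffs & ((a %in% PURINES) == (b %in% PURINES)))
  tv <- sum(diffs) - ts
  P <- ts / ns; Q <- tv / ns
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop("saturation error: K2P distance undefined (1-2P-Q = ", signif(arg1, 4),
         ", 1-2Q = ", signif(arg2, 4), ")")
  }
  list(d = -0.5 * log(arg1) - 0.25 * log(arg2), P = P, Q = Q, sites = ns)
}

#' K2P distance matrix for an alignment
#'
#' @param aln a `dna_alignment`.
#' @return symmetric numeric matrix of K2P distances.
#' @export
k2p_matrix <- function(aln) {
  n <- length(aln$ids)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- k2p(aln$mat[i, ], aln$mat[j, ])$d
    }
  }
  D
}

#' Mean K2P distances within and between populations
#'
#' Within-group distance is the mean pairwise d over members; between-group
#' is the mean over cross pairs (raw dXY).  The net distance
#' dA = dXY - (dX + dY)/2 is also reported.
#'
#' @param aln a `dna_alignment`.
#' @param pop_map population map.
#' @return list with matrices `raw` (within on diagonal, raw between off) and
#'   `net` (0 diagonal, net between off).
#' @export
group_k2p <- function(aln, pop_map) {
  pop_map <- as_pop_map(pop_map)
  D <- k2p_matrix(aln)
  pops <- pop_map$population[match(aln$ids, pop_map$id)]
  lev <- unique(pops)
  P <- length(lev)
  raw <- matrix(NA_real_, P, P, dimnames = list(lev, lev))
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      ii <- which(pops == lev[i]); jj <- which(pops == lev[j])
      if (i == j) {
        raw[i, j] <- if (length(ii) > 1) mean(D[ii, ii][upper.tri(D[ii, ii])]) else NA_real_
      } else raw[i, j] <- mean(D[ii, jj, drop = FALSE])
    }
  }
  net <- raw
  for (i in seq_len(P)) for (j in seq_len(P)) {
    net[i, j] <- if (i == j) 0 else raw[i, j] - (raw[i, i] + raw[j, j]) / 2
  }
  list(raw = raw, net = net)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape's reference implementation); negative
#' branch lengths are clamped to zero and flagged.  Optionally rooted on an
#' outgroup.
#'
#' @param dist symmetric distance matrix with dimnames.
#' @param outgroup_ids optional tip labels to root on.
#' @return an `ape::phylo` tree; attribute `clamped` gives the number of
#'   negative branch lengths set to zero.
#' @export
build_nj_tree <- function(dist, outgroup_ids = NULL) {
  if (nrow(dist) < 3) stop("NJ needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(dist))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  if (!is.null(outgroup_ids)) {
    tr <- ape::root(tr, outgroup = outgroup_ids, resolve.root = TRUE)
  }
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Bootstrap support for tree bipartitions
#'
#' Resamples alignment columns with replacement B times, rebuilds the tree
#' with `tree_builder`, and reports for each internal edge of the reference
#' tree the fraction of replicates containing the same bipartition.
#'
#' @param aln a `dna_alignment`.
#' @param tree_builder function(dna_alignment) -> phylo; default K2P + NJ.
#' @param B number of replicates.
#' @param seed RNG seed.
#' @param reference_tree optional `phylo` to score; default
#'   `tree_builder(aln)`.
#' @return list with `tree` (reference) and `support` (numeric vector per
#'   internal node, fraction in [0,1]).
#' @export
bootstrap_support <- function(aln, tree_builder = NULL, B = 100, seed = 1,
                              reference_tree = NULL) {
  stopifnot(B >= 1)
  if (is.null(tree_builder)) {
    tree_builder <- function(a) build_nj_tree(k2p_matrix(a))
  }
  set.seed(seed)
  ref <- if (is.null(reference_tree)) tree_builder(aln) else reference_tree
  k <- n_sites(aln)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(k, k, replace = TRUE)
    rep_aln <- dna_alignment(aln$mat[, cols, drop = FALSE])
    boots[[b]] <- tree_builder(rep_aln)
  }
  pp <- ape::prop.part(boots)
  support <- ape::prop.clades(ref, part = pp, rooted = FALSE)
  support[is.na(support)] <- 0
  list(tree = ref, support = support / B)
}
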