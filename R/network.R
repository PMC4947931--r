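# Minimum spanning and median-joining haplotype networks (Bandelt et al.
# 1999 style), with deterministic processing order.

# Character matrix (rows = node sequences) from a vector of strings.
.seq_mat <- function(seqs) {
  do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
}

# Vectorised majority-consensus of three character vectors; three-way ties
# resolve to the lexicographically smallest state.
.median3 <- function(a, b, c) {
  med <- a
  bc <- a != b & b == c
  med[bc] <- b[bc]
  tie <- a != b & a != c & b != c
  if (any(tie)) {
    med[tie] <- pmin(pmin(a[tie], b[tie]), c[tie])
  }
  med
}

# Hamming distances from one sequence to every row of a matrix.
.dist_to_all <- function(mat, v) {
  colSums(t(mat) != v)
}

# Hamming distances between rows of a character matrix ('-'/'N' count as
# ordinary fifth/sixth states: a haplotype differing by an indel differs).
.hamming <- function(m) {
  n <- nrow(m)
  D <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  D
}

# Total MST weight by Prim's algorithm.
.mst_cost <- function(D) {
  n <- nrow(D)
  if (n <= 1) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  key <- D[1, ]
  cost <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!intree)
    v <- cand[which.min(key[cand])]
    cost <- cost + key[v]
    intree[v] <- TRUE
    key <- pmin(key, D[v, ])
  }
  cost
}

# Edge list (i < j, weight) of the minimum spanning network: edge (u,v) is
# included iff u and v are in different components of the graph restricted
# to edges of weight < d(u,v) - eps (union of all MSTs at eps = 0).
.msn_edges <- function(D, eps = 0) {
  n <- nrow(D)
  if (n < 2) return(data.frame(from = integer(0), to = integer(0),
                               weight = integer(0)))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  keep <- logical(length(w))
  for (e in seq_along(w)) {
    thr <- w[e] - eps
    # components under edges with weight < thr
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    sub <- which(w < thr)
    for (e2 in sub) {
      a <- find(pairs[e2, 1]); b <- find(pairs[e2, 2])
      if (a != b) parent[a] <- b
    }
    keep[e] <- find(pairs[e, 1]) != find(pairs[e, 2])
  }
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2], weight = w[keep])
}

#' Minimum spanning network of haplotypes
#'
#' Union of all minimum spanning trees on Hamming distances, with an
#' optional epsilon relaxation admitting connections within `eps` steps of
#' the connection threshold.
#'
#' @param ht a `haplotype_table` ([collapse_haplotypes]) or named character
#'   vector of sequences.
#' @param eps tolerance parameter (default 0).
#' @return a `haplotype_network` (see [median_joining]) without median
#'   vectors.
#' @export
minimum_spanning_network <- function(ht, eps = 0) {
  median_joining(ht, eps = eps, max_iter = 0)
}

#' Median-joining haplotype network
#'
#' Bandelt-style iteration: starting from the minimum spanning network,
#' median (majority-consensus) vectors of connected node triples are
#' proposed and the one giving the largest reduction in total spanning cost
#' is added; the process repeats to a fixed point, then unsampled median
#' vectors of degree <= 2 are pruned.  Processing order is deterministic:
#' nodes sorted by (frequency desc, label asc); per-site three-way ties in
#' median construction resolve to the lexicographically smallest state.
#'
#' @param ht a `haplotype_table` or named character vector of sequences.
#' @param eps epsilon tolerance for the underlying spanning network.
#' @param max_iter cap on median-addition rounds (0 = plain MSN).
#' @return a `haplotype_network`: list with `nodes` (data frame: label,
#'   sequence, median flag, size = total count), `counts` (node x population
#'   matrix), `edges` (data frame from/to labels + weight), `eps`.
#' @export
median_joining <- function(ht, eps = 0, max_iter = 50) {
  if (inherits(ht, "haplotype_table")) {
    seqs <- ht$sequences
    counts <- ht$counts
  } else {
    seqs <- ht
    counts <- matrix(1L, length(seqs), 1,
                     dimnames = list(names(seqs), "all"))
  }
  if (length(seqs) < 2) stop("network needs >= 2 haplotypes")
  # deterministic node order: frequency desc, then label
  ord <- order(-rowSums(counts), names(seqs))
  seqs <- seqs[ord]
  counts <- counts[ord, , drop = FALSE]
  labels <- names(seqs)
  mat <- .seq_mat(seqs)
  is_median <- rep(FALSE, nrow(mat))
  med_id <- 0L
  iter <- 0L
  D <- .hamming(mat)
  while (iter < max_iter) {
    edges <- .msn_edges(D, eps)
    cur_cost <- .mst_cost(D)
    # adjacency for triple generation
    adj <- vector("list", nrow(mat))
    for (r in seq_len(nrow(edges))) {
      adj[[edges$from[r]]] <- c(adj[[edges$from[r]]], edges$to[r])
      adj[[edges$to[r]]] <- c(adj[[edges$to[r]]], edges$from[r])
    }
    cand <- character(0)
    for (u in seq_len(nrow(mat))) {
      nb <- sort(unique(adj[[u]]))
      if (length(nb) < 2) next
      for (a in seq_len(length(nb) - 1)) for (b in seq.int(a + 1, length(nb))) {
        med <- .median3(mat[u, ], mat[nb[a], ], mat[nb[b], ])
        cand <- c(cand, paste(med, collapse = ""))
      }
    }
    cand <- setdiff(sort(unique(cand)),
                    apply(mat, 1, paste, collapse = ""))
    if (!length(cand)) break
    best <- NULL; best_cost <- cur_cost - 1e-9; best_row <- NULL
    for (cs in cand) {
      v <- strsplit(cs, "")[[1]]
      row <- .dist_to_all(mat, v)
      Dc <- rbind(cbind(D, row), c(row, 0))
      cost <- .mst_cost(Dc)
      if (cost < best_cost) { best <- cs; best_cost <- cost; best_row <- row }
    }
    if (is.null(best)) break
    mat <- rbind(mat, strsplit(best, "")[[1]])
    D <- rbind(cbind(D, best_row), c(best_row, 0))
    dimnames(D) <- NULL
    med_id <- med_id + 1L
    labels <- c(labels, sprintf("mv%02d", med_id))
    is_median <- c(is_median, TRUE)
    counts <- rbind(counts, 0L)
    rownames(counts) <- labels
    iter <- iter + 1L
  }
  # prune unsampled medians of degree <= 2 (one at a time, deterministic)
  repeat {
    edges <- .msn_edges(D, eps)
    deg <- tabulate(c(edges$from, edges$to), nbins = nrow(mat))
    drop <- which(is_median & deg <= 2)
    if (!length(drop)) break
    drop <- drop[1]
    mat <- mat[-drop, , drop = FALSE]
    D <- D[-drop, -drop, drop = FALSE]
    labels <- labels[-drop]
    is_median <- is_median[-drop]
    counts <- counts[-drop, , drop = FALSE]
  }
  nodes <- data.frame(label = labels,
                      sequence = apply(mat, 1, paste, collapse = ""),
                      median = is_median,
                      size = rowSums(counts),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, counts = counts,
                 edges = data.frame(from = labels[edges$from],
                                    to = labels[edges$to],
                                    weight = edges$weight,
                                    stringsAsFactors = FALSE),
                 eps = eps),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$median), "median vectors ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#' @param net a `haplotype_network`.
#' @return an igraph graph with node attributes `median`, `size`, per-
#'   population counts (`count_<pop>`), and edge attribute `weight`.
#' @export
network_igraph <- function(net) {
  nodes <- net$nodes
  nodes$median <- as.integer(nodes$median)  # GML has no boolean type
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = nodes)
  for (p in colnames(net$counts)) {
    g <- igraph::set_vertex_attr(g, paste0("count_", p),
                                 value = net$counts[net$nodes$label, p])
  }
  g
}

#' Export a haplotype network to GraphML, GML or edge-list CSV
#'
#' @param net a `haplotype_network`.
#' @param path output file.
#' @param format "graphml", "gml" or "csv".
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "gml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(net$edges, path, row.names = FALSE)
  } else {
    igraph::write_graph(network_igraph(net), path, format = format)
  }
  invisible(path)
}

#' Read a network exported with [export_network]
#' @param path GraphML or GML file.
#' @param format "graphml" or "gml".
#' @return an igraph graph.
#' @export
read_network <- function(path, format = c("graphml", "gml")) {
  igraph::read_graph(path, format = match.arg(format))
}
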