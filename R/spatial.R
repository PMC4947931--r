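# Isolation-by-distance: Mantel test of linearised differentiation against
# log10 geographic distance.

#' Mantel test of isolation by distance
#'
#' Correlates linearised genetic differentiation d/(1-d) (Phi_ST or F_ST)
#' with log10 geographic distance (km) over unordered population pairs, and
#' tests significance by joint row/column permutation of one matrix.
#' Entries with d = 1 are excluded with a warning (linearisation
#' undefined).  With fewer than 4 populations the permutation space is
#' enumerated exactly (with a warning that it is tiny).
#'
#' @param gen_dist symmetric matrix of pairwise Phi_ST/F_ST values.
#' @param geo_km symmetric matrix of geographic distances in km, same
#'   population order.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param linearize apply d/(1-d)?
#' @param log10_geo apply log10 to distances?
#' @param alternative "two.sided" (default) or "greater" (positive IBD).
#' @return an `ibd_result`: list with `R`, `P`, `n_perm`, `n_pops`,
#'   `alternative`, `excluded_pairs`.
#' @export
mantel_ibd <- function(gen_dist, geo_km, n_perm = 9999, seed = 1,
                       linearize = TRUE, log10_geo = TRUE,
                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  gen_dist <- as.matrix(gen_dist); geo_km <- as.matrix(geo_km)
  P <- nrow(gen_dist)
  stopifnot(nrow(geo_km) == P)
  G <- gen_dist
  excluded <- 0L
  if (linearize) {
    one <- G >= 1 & row(G) != col(G)
    if (any(one)) {
      warning(sum(one) / 2, " pair(s) with differentiation >= 1 excluded")
      excluded <- sum(one) / 2
      G[one] <- NA
    }
    G <- G / (1 - G)
  }
  X <- if (log10_geo) log10(geo_km) else geo_km
  ut <- upper.tri(G)
  r_for <- function(perm) {
    g <- G[perm, perm][ut]
    x <- X[ut]
    ok <- is.finite(g) & is.finite(x)
    cor(g[ok], x[ok])
  }
  R_obs <- r_for(seq_len(P))
  score <- function(r) if (alternative == "two.sided") abs(r) else r
  if (P < 4) {
    warning("fewer than 4 populations: permutation space is tiny, ",
            "using exact enumeration")
    perms <- .all_perms(P)
    stats <- vapply(perms, r_for, 0)
    Pval <- mean(score(stats) >= score(R_obs) - 1e-12)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    stats <- numeric(n_perm)
    for (b in seq_len(n_perm)) stats[b] <- r_for(sample.int(P))
    Pval <- (sum(score(stats) >= score(R_obs)) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(R = R_obs, P = Pval, n_perm = n_used, n_pops = P,
                 alternative = alternative, excluded_pairs = excluded,
                 seed = seed),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf("Mantel IBD: R = %.3f, P = %.3f (%d populations, %d permutations, %s)\n",
              x$R, x$P, x$n_pops, x$n_perm, x$alternative))
  invisible(x)
}

.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .all_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Great-circle distances between coordinates (helper)
#'
#' Haversine distances in km.  Provided as a convenience only: river-path
#' distances supplied by the user are the intended input for IBD along a
#' drainage.
#'
#' @param lat,lon numeric vectors of coordinates in decimal degrees.
#' @param labels optional names.
#' @return symmetric distance matrix (km).
#' @export
great_circle_km <- function(lat, lon, labels = NULL) {
  stopifnot(length(lat) == length(lon))
  rad <- pi / 180
  n <- length(lat)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dlat <- (lat[j] - lat[i]) * rad
    dlon <- (lon[j] - lon[i]) * rad
    a <- sin(dlat / 2)^2 + cos(lat[i] * rad) * cos(lat[j] * rad) *
      sin(dlon / 2)^2
    D[i, j] <- 6371 * 2 * asin(pmin(1, sqrt(a)))
  }
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  D
}
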