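# Polyploid (band-phenotype) microsatellite analysis: binary transform,
# dominant-marker diversity, Nei's unbiased distance, F_ST via AMOVA,
# principal coordinates, Evanno delta-K.

#' Read band phenotypes from delimited text
#'
#' Expected columns: `individual`, `population`, `locus`, `bands`
#' (comma-separated integer band sizes).
#'
#' @param path file path (any whitespace/tab separated text with header).
#' @return a `band_phenotypes` data frame.
#' @export
read_band_phenotypes <- function(path) {
  x <- read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("individual", "population", "locus", "bands")
  if (!all(need %in% names(x))) {
    stop("band file needs columns: ", paste(need, collapse = ", "))
  }
  class(x) <- c("band_phenotypes", "data.frame")
  x
}

#' Transform band phenotypes to a binary presence/absence matrix
#'
#' One column per observed (locus, band) combination; copy number is
#' discarded.  A locus not scored for an individual yields NA in all of
#' that locus's columns (missing, distinct from absence).
#'
#' @param bpm a `band_phenotypes` data frame (individual, population,
#'   locus, bands).
#' @param max_bands validation ceiling on bands per individual per locus
#'   (4 for a tetraploid).
#' @return a `binary_bands` object: list with `binary` (individuals x
#'   (locus:band) 0/1/NA matrix), `pop_map`, `locus_of_column`.
#' @export
phenotypes_to_binary <- function(bpm, max_bands = 4) {
  bands_list <- strsplit(bpm$bands, ",", fixed = TRUE)
  nb <- lengths(bands_list)
  bad <- which(nb > max_bands | nb < 1)
  if (length(bad)) {
    stop("validation error: ", bpm$individual[bad[1]], "/", bpm$locus[bad[1]],
         " has ", nb[bad[1]], " bands (allowed 1..", max_bands, ")")
  }
  loci <- unique(bpm$locus)
  cols <- character(0)
  locus_of_col <- character(0)
  for (loc in loci) {
    b <- sort(unique(as.integer(unlist(bands_list[bpm$locus == loc]))))
    cols <- c(cols, paste0(loc, ":", b))
    locus_of_col <- c(locus_of_col, rep(loc, length(b)))
  }
  inds <- unique(bpm$individual)
  bin <- matrix(NA_integer_, length(inds), length(cols),
                dimnames = list(inds, cols))
  for (r in seq_len(nrow(bpm))) {
    ind <- bpm$individual[r]; loc <- bpm$locus[r]
    loc_cols <- which(locus_of_col == loc)
    bin[ind, loc_cols] <- 0L
    hit <- paste0(loc, ":", as.integer(bands_list[[r]]))
    bin[ind, hit] <- 1L
  }
  pm <- unique(bpm[, c("individual", "population")])
  pm <- data.frame(id = pm$individual, population = pm$population,
                   region = "all", stringsAsFactors = FALSE)
  structure(list(binary = bin, pop_map = pm,
                 locus_of_column = setNames(locus_of_col, cols)),
            class = "binary_bands")
}

#' Reconstruct band sets from a binary matrix
#'
#' Inverse of [phenotypes_to_binary] for presence information.
#'
#' @param bb a `binary_bands` object.
#' @return a `band_phenotypes` data frame.
#' @export
binary_to_phenotypes <- function(bb) {
  rows <- list()
  loci <- unique(bb$locus_of_column)
  for (ind in rownames(bb$binary)) {
    for (loc in loci) {
      cc <- which(bb$locus_of_column == loc)
      v <- bb$binary[ind, cc]
      if (all(is.na(v))) next
      sizes <- sub(".*:", "", names(v)[which(v == 1L)])
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind,
        population = bb$pop_map$population[match(ind, bb$pop_map$id)],
        locus = loc, bands = paste(sizes, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("band_phenotypes", "data.frame")
  out
}

#' Dominant-marker diversity statistics per population
#'
#' For each binary band with presence frequency p in a population:
#' gene diversity H = 2p(1-p) and Shannon index
#' I = -(p ln p + (1-p) ln(1-p)) under the direct phenotype-frequency
#' convention (the default); with `hwe_dominant = TRUE` the band frequency
#' is first converted to an allele frequency q = 1 - sqrt(1-p) assuming
#' dominant inheritance at Hardy-Weinberg equilibrium.  Population values
#' are means over all band columns.  PPL counts bands polymorphic within
#' the population; `criterion = "95"` additionally requires the commoner
#' state's frequency to be at most 0.95.
#'
#' @param bb a `binary_bands` object, or a 0/1 matrix (then `pop_map`
#'   required).
#' @param pop_map used when `bb` is a plain matrix.
#' @param hwe_dominant use the dominant-marker HWE allele-frequency
#'   estimator.
#' @param criterion "any" (0 < p < 1) or "95".
#' @return data frame per population: `population`, `n`, `total_bands`,
#'   `private_bands`, `PPL` (percent), `H`, `I`.
#' @export
band_diversity <- function(bb, pop_map = NULL, hwe_dominant = FALSE,
                           criterion = c("any", "95")) {
  criterion <- match.arg(criterion)
  if (inherits(bb, "binary_bands")) {
    bin <- bb$binary; pop_map <- bb$pop_map
  } else bin <- bb
  pop_map <- as_pop_map(pop_map)
  pops <- pop_map$population[match(rownames(bin), pop_map$id)]
  lev <- unique(pops)
  pres <- vapply(lev, function(p) {
    colMeans(bin[pops == p, , drop = FALSE] > 0, na.rm = TRUE) > 0
  }, logical(ncol(bin)))  # bands x pops presence
  pres <- matrix(pres, ncol = length(lev),
                 dimnames = list(colnames(bin), lev))
  rows <- lapply(lev, function(pl) {
    sub <- bin[pops == pl, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty population: ", pl)
    p <- colMeans(sub, na.rm = TRUE)
    f <- if (hwe_dominant) 1 - sqrt(pmax(1 - p, 0)) else p
    H <- 2 * f * (1 - f)
    ent <- function(q) ifelse(q <= 0 | q >= 1, 0,
                              -(q * log(q) + (1 - q) * log(1 - q)))
    I <- ent(f)
    poly <- p > 0 & p < 1
    if (criterion == "95") poly <- poly & pmax(p, 1 - p) <= 0.95
    others <- pres[, setdiff(lev, pl), drop = FALSE]
    private <- sum(pres[, pl] & rowSums(others) == 0)
    data.frame(population = pl, n = nrow(sub),
               total_bands = sum(p > 0, na.rm = TRUE),
               private_bands = private,
               PPL = 100 * mean(poly, na.rm = TRUE),
               H = mean(H, na.rm = TRUE), I = mean(I, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nei's unbiased genetic distance from binary band frequencies
#'
#' Band presence frequencies are treated as allele frequencies of biallelic
#' loci (presence/absence).  With per-locus identities
#' j_XY = sum_i x_i y_i, the unbiased within-population identity applies
#' Nei's (1978) sample-size correction (n j_X - 1)/(n - 1) with n the
#' number of individuals scored.  D = -ln( J_XY / sqrt(J_X J_Y) ) with
#' identities averaged over loci.  Populations with n = 1 fall back to the
#' biased identity with a warning; non-overlapping band sets give
#' infinite D, returned as Inf and flagged.
#'
#' @param bb a `binary_bands` object or 0/1 matrix.
#' @param pop_map used when `bb` is a plain matrix.
#' @return list with `D` (unbiased distance matrix), `D_standard` (Nei's
#'   standard distance, no sample-size correction) and `infinite` (logical
#'   flag matrix).
#' @export
nei_unbiased_distance <- function(bb, pop_map = NULL) {
  if (inherits(bb, "binary_bands")) {
    bin <- bb$binary; pop_map <- bb$pop_map
  } else bin <- bb
  pop_map <- as_pop_map(pop_map)
  pops <- pop_map$population[match(rownames(bin), pop_map$id)]
  lev <- unique(pops)
  P <- length(lev)
  freq <- sapply(lev, function(pl) {
    colMeans(bin[pops == pl, , drop = FALSE], na.rm = TRUE)
  })
  nn <- vapply(lev, function(pl) sum(pops == pl), 0L)
  # per-pop unbiased mean identity over loci (allele freqs p and 1-p)
  jx <- vapply(seq_len(P), function(i) {
    p <- freq[, i]
    j <- p^2 + (1 - p)^2
    if (nn[i] > 1) {
      mean((nn[i] * j - 1) / (nn[i] - 1))
    } else {
      warning("population ", lev[i], " has n = 1; unbiased correction ",
              "undefined, using biased identity")
      mean(j)
    }
  }, 0)
  jx_std <- vapply(seq_len(P), function(i) {
    mean(freq[, i]^2 + (1 - freq[, i])^2)
  }, 0)
  D <- matrix(0, P, P, dimnames = list(lev, lev))
  Ds <- D
  for (i in seq_len(P - 1)) for (j in seq.int(i + 1, P)) {
    jxy <- mean(freq[, i] * freq[, j] + (1 - freq[, i]) * (1 - freq[, j]))
    val <- jxy / sqrt(jx[i] * jx[j])
    val_s <- jxy / sqrt(jx_std[i] * jx_std[j])
    D[i, j] <- D[j, i] <- if (val <= 0) Inf else -log(val)
    Ds[i, j] <- Ds[j, i] <- if (val_s <= 0) Inf else -log(val_s)
  }
  list(D = D, D_standard = Ds,
       infinite = !is.finite(D) & row(D) != col(D))
}

#' Squared Euclidean distances between binary rows
#'
#' Missing scores are excluded pairwise, with the count rescaled to the
#' full column count.
#'
#' @param bin 0/1 (possibly NA) matrix.
#' @return symmetric squared-distance matrix.
#' @export
binary_squared_distances <- function(bin) {
  n <- nrow(bin)
  D <- matrix(0, n, n, dimnames = list(rownames(bin), rownames(bin)))
  if (!anyNA(bin)) {
    cp <- tcrossprod(bin)
    s <- diag(cp)
    D <- outer(s, s, "+") - 2 * cp
    dimnames(D) <- list(rownames(bin), rownames(bin))
    return(D)
  }
  m <- ncol(bin)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ok <- !is.na(bin[i, ]) & !is.na(bin[j, ])
    d <- sum((bin[i, ok] - bin[j, ok])^2) * m / sum(ok)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' F_ST analysis of binary band data
#'
#' Delegates to [amova] on squared Euclidean distances between binary
#' rows; returns the hierarchical AMOVA and the pairwise F_ST matrix.
#'
#' @param bb a `binary_bands` object or 0/1 matrix.
#' @param pop_map population map (with regions for the two-level design).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param pairwise also compute the pairwise F_ST matrix?
#' @return list with `amova` (an `amova_result`) and optionally `pairwise`.
#' @export
binary_fst <- function(bb, pop_map = NULL, n_perm = 1000, seed = 1,
                       pairwise = TRUE) {
  if (inherits(bb, "binary_bands")) {
    bin <- bb$binary
    if (is.null(pop_map)) pop_map <- bb$pop_map
  } else bin <- bb
  pop_map <- as_pop_map(pop_map)
  d2 <- binary_squared_distances(bin)
  out <- list(amova = amova(d2, pop_map, n_perm = n_perm, seed = seed))
  if (pairwise) {
    out$pairwise <- pairwise_phi_st(d2, pop_map, n_perm = n_perm, seed = seed)
  }
  out
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition.
#' Coordinates are returned for axes with positive eigenvalues, ordered by
#' eigenvalue; negative eigenvalues are reported.
#'
#' @param distances symmetric distance matrix (not squared).
#' @return list with `coordinates`, `eigenvalues`, `pct_variance` (percent
#'   of the positive-eigenvalue total per retained axis).
#' @export
pcoa <- function(distances) {
  D <- as.matrix(distances)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > sqrt(.Machine$double.eps) * max(abs(e$values)))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  list(coordinates = coords, eigenvalues = e$values,
       pct_variance = 100 * e$values[pos] / sum(e$values[pos]))
}

#' Evanno delta-K from clustering log-likelihoods
#'
#' Given replicate lnP(D) values per K, computes per interior K the mean
#' absolute second difference across replicates divided by the standard
#' deviation of lnP(D) at K:
#' delta K = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| / sd_r(L_r(K)).
#'
#' @param lnp data frame with columns `K` and `lnP` (one row per
#'   replicate), or a matrix with K values as rows (rownames = K) and
#'   replicates as columns.
#' @return data frame per K: `K`, `mean_lnP`, `sd_lnP`, `delta_K` (NA at
#'   the boundary or when sd = 0, flagged via `sd_zero`), plus attribute
#'   `best_K` (argmax of delta_K).
#' @export
evanno_delta_k <- function(lnp) {
  if (is.data.frame(lnp)) {
    ks <- sort(unique(lnp$K))
    reps <- split(lnp$lnP, lnp$K)
    nr <- unique(lengths(reps))
    if (length(nr) > 1) stop("unequal replicate counts across K")
    L <- do.call(rbind, reps[as.character(ks)])
  } else {
    L <- as.matrix(lnp)
    ks <- as.numeric(rownames(L))
  }
  if (length(ks) < 3) stop("delta-K needs >= 3 consecutive K values")
  if (ncol(L) < 2) stop("delta-K needs >= 2 replicates per K")
  mlnp <- rowMeans(L)
  sdev <- apply(L, 1, sd)
  dk <- rep(NA_real_, length(ks))
  sd_zero <- rep(FALSE, length(ks))
  for (i in seq.int(2, length(ks) - 1)) {
    sec <- abs(L[i + 1, ] - 2 * L[i, ] + L[i - 1, ])
    if (sdev[i] == 0) { sd_zero[i] <- TRUE; next }
    dk[i] <- mean(sec) / sdev[i]
  }
  out <- data.frame(K = ks, mean_lnP = mlnp, sd_lnP = sdev, delta_K = dk,
                    sd_zero = sd_zero, row.names = NULL)
  attr(out, "best_K") <- if (all(is.na(dk))) NA else ks[which.max(dk)]
  out
}
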