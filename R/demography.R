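# Mismatch distributions, sudden-expansion (Rogers-Harpending) model,
# neutrality tests (Fu's Fs via the Ewens sampling formula) and
# expansion-time dating.

#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over all C(n,2) unordered pairs,
#' normalised to sum to 1.
#'
#' @param x a `dna_alignment`, or a symmetric integer matrix of pairwise
#'   difference counts.
#' @return a `mismatch_distribution`: list with `freq` (relative class
#'   frequencies for 0..d_max differences), `counts`, `n_pairs`, `d_max`.
#' @export
mismatch_observed <- function(x) {
  D <- if (inherits(x, "dna_alignment")) pairwise_differences(x) else x
  if (nrow(D) < 2) stop("mismatch distribution needs n >= 2")
  d <- D[upper.tri(D)]
  d_max <- max(d)
  counts <- tabulate(d + 1L, nbins = d_max + 1L)
  structure(list(freq = counts / sum(counts), counts = counts,
                 n_pairs = length(d), d_max = d_max),
            class = "mismatch_distribution")
}

#' Equilibrium mismatch distribution
#'
#' Geometric form F_j(theta) = theta^j / (1+theta)^(j+1): the stationary
#' distribution of pairwise differences for a constant-size population.
#'
#' @param theta scaled population size (mean pairwise differences).
#' @param d_max largest difference class.
#' @return numeric vector of length d_max+1 (not renormalised).
#' @export
equilibrium_mismatch <- function(theta, d_max) {
  j <- 0:d_max
  if (theta == 0) return(c(1, rep(0, d_max)))
  exp(j * log(theta) - (j + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' Rogers-Harpending model: a population at equilibrium size theta0 grew
#' instantaneously to theta1 at tau units of mutational time (tau = 2ut)
#' before the present.  Pairs coalescing since the expansion follow the
#' theta1 equilibrium; older pairs carry a Poisson(tau) increment over the
#' theta0 equilibrium:
#' F_i = Fhat_i(theta1) +
#'       exp(-tau/theta1) * sum_j Pois(tau)_j (Fhat_{i-j}(theta0) -
#'                                             Fhat_{i-j}(theta1)).
#' The vector is truncated at `d_max` and renormalised.
#'
#' @param tau expansion age in mutational time units (>= 0).
#' @param theta0,theta1 pre-/post-expansion scaled sizes (>= 0).
#' @param d_max largest difference class.
#' @return numeric vector of length d_max+1 summing to 1.
#' @export
expected_mismatch <- function(tau, theta0, theta1, d_max) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 >= 0, d_max >= 0)
  f1 <- equilibrium_mismatch(theta1, d_max)
  if (tau == 0) {
    f <- equilibrium_mismatch(theta0, d_max)
    return(f / sum(f))
  }
  surv <- if (theta1 > 0) exp(-tau / theta1) else 0
  f <- f1
  if (surv > 0) {
    x <- equilibrium_mismatch(theta0, d_max) - f1
    pois <- stats::dpois(0:d_max, tau)
    m <- d_max + 1L
    conv <- stats::convolve(pois, rev(x), type = "open")[seq_len(m)]
    f <- f1 + surv * conv
  }
  f[f < 0] <- 0
  f / sum(f)
}

#' Sum of squared deviations between two mismatch distributions
#' @param obs_freq,exp_freq numeric vectors (padded to common length).
#' @return SSD.
#' @export
mismatch_ssd <- function(obs_freq, exp_freq) {
  m <- max(length(obs_freq), length(exp_freq))
  o <- c(obs_freq, rep(0, m - length(obs_freq)))
  e <- c(exp_freq, rep(0, m - length(exp_freq)))
  sum((o - e)^2)
}

#' Fit the sudden-expansion model to an observed mismatch distribution
#'
#' Least-squares fit of (tau, theta0, theta1) minimising
#' SSD = sum_i (f_obs_i - f_exp_i)^2, by a coarse deterministic grid search
#' followed by a Nelder-Mead polish with box penalties
#' (tau in [0, 2 d_max], theta >= 0, theta1 capped at 1e5).
#'
#' @param obs a `mismatch_distribution` (see [mismatch_observed]).
#' @return an `expansion_fit`: list with `tau`, `theta0`, `theta1`,
#'   `expected` (fitted distribution over 0..d_max), `ssd`,
#'   `raggedness`, `boundary` flag (degenerate tau = 0 fit).
#' @export
fit_sudden_expansion <- function(obs) {
  stopifnot(inherits(obs, "mismatch_distribution"))
  d_max <- obs$d_max
  f_obs <- obs$freq
  if (d_max == 0) {
    return(structure(list(tau = 0, theta0 = 0, theta1 = 0,
                          expected = 1, ssd = 0,
                          raggedness = raggedness(obs), boundary = TRUE),
                     class = "expansion_fit"))
  }
  tau_hi <- 2 * d_max
  m <- d_max + 1L
  jj <- 0:d_max
  geom <- function(th) {
    if (th <= 0) c(1, numeric(d_max)) else exp(jj * log(th) - (jj + 1) * log1p(th))
  }
  obj <- function(p) {
    tau <- p[1]; th0 <- p[2]; th1 <- p[3]
    if (tau < 0 || tau > tau_hi || th0 < 0 || th1 < 0 || th1 > 1e5) {
      return(1e6)
    }
    f1 <- geom(th1)
    if (tau == 0) {
      f <- geom(th0)
    } else {
      surv <- if (th1 > 0) exp(-tau / th1) else 0
      f <- f1
      if (surv > 0) {
        x <- geom(th0) - f1
        pois <- stats::dpois(jj, tau)
        if (m > 64) {
          conv <- stats::convolve(pois, rev(x), type = "open")[seq_len(m)]
        } else {
          conv <- numeric(m)
          for (i in seq_len(m)) conv[i] <- sum(pois[seq_len(i)] * x[i:1])
        }
        f <- f1 + surv * conv
      }
    }
    f[f < 0] <- 0
    f <- f / sum(f)
    sum((f_obs - f)^2)
  }
  # moment-seeded coarse grid, then Nelder-Mead polish
  mbar <- sum(jj * f_obs)
  grid <- expand.grid(tau = unique(pmin(c(0, mbar * c(0.5, 0.75, 1, 1.25, 1.5),
                                          d_max), tau_hi)),
                      theta0 = c(0, max(mbar / 4, 0.5)),
                      theta1 = c(10, 100, 1000, 1e4))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  fit <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-9))
  p <- fit$par
  p[1] <- min(max(p[1], 0), tau_hi)
  p[2] <- max(p[2], 0)
  p[3] <- min(max(p[3], 0), 1e5)
  structure(list(tau = p[1], theta0 = p[2], theta1 = p[3],
                 expected = expected_mismatch(p[1], p[2], p[3], d_max),
                 ssd = obj(p), raggedness = raggedness(obs),
                 boundary = p[1] < 1e-8),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("sudden-expansion fit: tau=%.3f theta0=%.3f theta1=%.3g SSD=%.5f r=%.4f\n",
              x$tau, x$theta0, x$theta1, x$ssd, x$raggedness))
  invisible(x)
}

#' Harpending's raggedness index
#'
#' r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2 over the relative class frequencies
#' x_0..x_d of the observed mismatch distribution, with the closing
#' convention x_{d+1} = 0 (so a distribution ending abruptly is penalised).
#' Trailing zero classes beyond d+1 do not change r.
#'
#' @param obs a `mismatch_distribution` or a numeric frequency vector.
#' @return raggedness index r >= 0.
#' @export
raggedness <- function(obs) {
  x <- if (inherits(obs, "mismatch_distribution")) obs$freq else obs
  x <- c(x, 0)
  sum(diff(x)^2)
}

#' Parametric-bootstrap P-value for the expansion-model SSD
#'
#' Simulates `B` coalescent samples of the same size under the fitted
#' sudden-expansion history, re-fits the model to each, and reports
#' P = fraction of replicates with SSD_sim >= SSD_obs.
#'
#' @param obs observed `mismatch_distribution`.
#' @param fit an `expansion_fit` for `obs`.
#' @param n sample size (sequences) behind `obs`.
#' @param B bootstrap replicates (>= 100 recommended).
#' @param seed RNG seed.
#' @return list with `P`, `ssd_obs`, `ssd_sim`, and the raggedness analogue
#'   `P_r` computed from the same replicates.
#' @export
ssd_pvalue <- function(obs, fit, n, B = 1000, seed = 1) {
  stopifnot(B >= 1)
  set.seed(seed)
  ssd_sim <- numeric(B)
  r_sim <- numeric(B)
  # cap the simulated class range: replicates under a poorly fitting model
  # (e.g. huge theta) can otherwise produce enormous histograms
  cap <- max(2L * obs$d_max, 50L)
  for (b in seq_len(B)) {
    g <- sim_coalescent_pairdiff(n, theta0 = fit$theta0, theta1 = fit$theta1,
                                 tau = fit$tau)
    ob <- mismatch_observed(g)
    if (ob$d_max > cap) {
      cnt <- ob$counts
      cnt2 <- cnt[seq_len(cap + 1L)]
      cnt2[cap + 1L] <- cnt2[cap + 1L] + sum(cnt[-seq_len(cap + 1L)])
      ob <- structure(list(freq = cnt2 / sum(cnt2), counts = cnt2,
                           n_pairs = ob$n_pairs, d_max = cap),
                      class = "mismatch_distribution")
    }
    fb <- fit_sudden_expansion(ob)
    ssd_sim[b] <- fb$ssd
    r_sim[b] <- fb$raggedness
  }
  list(P = mean(ssd_sim >= fit$ssd), P_r = mean(r_sim >= fit$raggedness),
       ssd_obs = fit$ssd, ssd_sim = ssd_sim)
}

# log of unsigned Stirling numbers of the first kind |s(n, k)|, k = 1..n,
# by the recursion |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| in log space.
log_stirling1 <- function(n) {
  L <- -Inf
  Lrow <- c(0)                      # n = 1: |s(1,1)| = 1
  if (n == 1) return(Lrow)
  for (m in seq_len(n - 1)) {       # build row m+1 from row m
    prev <- c(Lrow, -Inf)           # k = 1..m+1 (k = m+1 absent in row m)
    shift <- c(-Inf, Lrow)          # |s(m, k-1)|
    a <- log(m) + prev
    Lrow <- pmax(a, shift) + log1p(exp(-abs(a - shift)))
    Lrow[is.nan(Lrow)] <- -Inf
  }
  Lrow
}

#' Ewens sampling-formula distribution of the number of alleles
#'
#' Pr(K = k | theta, n) = |s(n,k)| theta^k / (theta (theta+1) ...
#' (theta+n-1)), computed in log space with unsigned Stirling numbers of the
#' first kind.
#'
#' @param n sample size.
#' @param theta scaled mutation rate (> 0).
#' @return numeric vector of probabilities for k = 1..n.
#' @export
ewens_allele_probs <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  k <- seq_len(n)
  logp <- log_stirling1(n) + k * log(theta) -
    sum(log(theta + 0:(n - 1)))
  exp(logp)
}

#' Fu's Fs neutrality statistic
#'
#' With theta estimated from mean pairwise differences, S' is the
#' probability under the Ewens sampling formula of observing at least as
#' many alleles (haplotypes) as seen; Fs = ln(S'/(1 - S')).  Strongly
#' negative Fs indicates an excess of rare haplotypes, as after a
#' demographic expansion.  The P-value is the fraction of neutral
#' constant-size coalescent simulations (at the observed theta and n)
#' with Fs_sim <= Fs_obs; by the usual convention Fs is judged significant
#' at the 5% level when P < 0.02.
#'
#' @param x a `dna_alignment`, or NULL if `n`, `h`, `theta_pi` are given.
#' @param n,h,theta_pi sample size, haplotype count and mean pairwise
#'   differences (used when `x` is NULL).
#' @param B neutral simulations for the P-value (0 to skip).
#' @param seed RNG seed.
#' @return a `neutrality_result`: list with `Fs`, `S_prime`, `P`, `theta_pi`,
#'   `n`, `h`.
#' @export
fus_fs <- function(x = NULL, n = NULL, h = NULL, theta_pi = NULL,
                   B = 0, seed = 1) {
  if (!is.null(x)) {
    D <- pairwise_differences(x)
    n <- nrow(D)
    theta_pi <- mean(D[upper.tri(D)])
    h <- length(collapse_haplotypes(x)$sequences)
  }
  if (n < 3) stop("Fu's Fs needs n >= 3")
  if (is.na(theta_pi) || theta_pi <= 0) {
    return(structure(list(Fs = NA_real_, S_prime = NA_real_, P = NA_real_,
                          theta_pi = theta_pi, n = n, h = h),
                     class = "neutrality_result"))
  }
  pk <- ewens_allele_probs(n, theta_pi)
  S_prime <- sum(pk[h:n])
  S_prime <- min(max(S_prime, .Machine$double.xmin), 1 - 1e-15)
  Fs <- log(S_prime) - log1p(-S_prime)
  P <- NA_real_
  if (B > 0) {
    set.seed(seed)
    fs_sim <- numeric(B)
    for (b in seq_len(B)) {
      g <- sim_coalescent_summary(n, theta = theta_pi)
      if (g$theta_pi <= 0) { fs_sim[b] <- Inf; next }
      pk_s <- ewens_allele_probs(n, g$theta_pi)
      sp <- min(max(sum(pk_s[g$h:n]), .Machine$double.xmin), 1 - 1e-15)
      fs_sim[b] <- log(sp) - log1p(-sp)
    }
    P <- mean(fs_sim <= Fs)
  }
  structure(list(Fs = Fs, S_prime = S_prime, P = P, theta_pi = theta_pi,
                 n = n, h = h),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("Fu's Fs = %.4f (S' = %.4g, n = %d, h = %d, theta_pi = %.3f)",
              x$Fs, x$S_prime, x$n, x$h, x$theta_pi))
  if (!is.na(x$P)) cat(sprintf(", P = %.4f", x$P))
  cat("\n")
  invisible(x)
}

#' Expansion-time dating from tau
#'
#' Converts the mismatch mode tau into calendar time: u = 2 mu k T_gen is
#' the per-sequence neutral mutation rate per generation (mu per site per
#' year), t = tau/(2u) generations since expansion, and T = t * T_gen years.
#' Algebraically T = tau/(4 mu k), independent of generation time.
#'
#' @param tau expansion age in mutational units (>= 0).
#' @param mu substitution rate in percent per site per million years (e.g.
#'   1.69 for 1.69%/site/Myr).
#' @param k sequence length in sites.
#' @param t_gen generation time in years.
#' @return an `expansion_timing`: list with `u` (per sequence per
#'   generation), `t_generations`, `T_years`, `T_ma` (millions of years).
#' @export
expansion_time <- function(tau, mu, k, t_gen) {
  if (tau < 0) stop("tau must be >= 0")
  if (mu <= 0 || k <= 0 || t_gen <= 0) {
    stop("mu, k and t_gen must be positive")
  }
  mu_per_year <- mu / 100 / 1e6
  u <- 2 * mu_per_year * k * t_gen
  t <- if (u > 0) tau / (2 * u) else 0
  T_years <- t * t_gen
  structure(list(tau = tau, mu_pct_per_myr = mu, k = k, t_gen = t_gen,
                 u = u, t_generations = t, T_years = T_years,
                 T_ma = T_years / 1e6),
            class = "expansion_timing")
}

#' @export
print.expansion_timing <- function(x, ...) {
  cat(sprintf("expansion timing: tau=%.3f -> t=%.0f generations, T=%.3f Ma\n",
              x$tau, x$t_generations, x$T_ma))
  invisible(x)
}
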