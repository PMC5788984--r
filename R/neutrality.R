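#' Tajima's (1989) constants
#' @param n Sample size (n >= 2).
#' @return Named list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Vectorized neutral constant-size coalescent: returns per-replicate
# segregating sites S and mean pairwise differences kbar for M samples of
# size n at scaled mutation rate theta (per locus). Time in units of Ne
# generations (haploid); mutation rate theta/2 per lineage per unit time.
sim_neutral_sk <- function(n, theta, M, seed = NULL) {
  with_seed_(seed, {
    counts <- matrix(1L, nrow = M, ncol = n)
    S <- numeric(M)
    kb <- numeric(M)
    denom <- choose(n, 2)
    for (k in n:2) {
      t_k <- stats::rexp(M, rate = k * (k - 1) / 2)
      lam <- rep(t_k * theta / 2, times = k)
      mut <- matrix(stats::rpois(M * k, lam), nrow = M, ncol = k)
      csz <- counts[, 1:k, drop = FALSE]
      S <- S + rowSums(mut)
      kb <- kb + rowSums(mut * csz * (n - csz)) / denom
      i1 <- sample.int(k, M, replace = TRUE)
      i2 <- sample.int(k - 1, M, replace = TRUE)
      i2 <- i2 + (i2 >= i1)
      counts[cbind(seq_len(M), i1)] <- counts[cbind(seq_len(M), i1)] +
        counts[cbind(seq_len(M), i2)]
      counts[cbind(seq_len(M), i2)] <- counts[, k]
    }
    tibble(S = S, kbar = kb)
  })
}

# Single neutral replicate returning (S, kbar, K): simulates the genealogy,
# drops Poisson mutations on branches, and counts haplotype classes by
# contracting mutation-free edges.
sim_neutral_skk1 <- function(n, theta) {
  n_nodes <- 2 * n - 1
  parent <- integer(n_nodes)
  t_node <- numeric(n_nodes)
  leaves <- c(rep(1L, n), integer(n - 1))
  active <- 1:n
  t <- 0
  nxt <- n
  for (k in n:2) {
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    nxt <- nxt + 1
    parent[active[pair]] <- nxt
    t_node[nxt] <- t
    leaves[nxt] <- sum(leaves[active[pair]])
    active <- c(active[-pair], nxt)
  }
  v <- 1:(n_nodes - 1)
  blen <- t_node[parent[v]] - t_node[v]
  mut <- stats::rpois(n_nodes - 1, theta / 2 * blen)
  # contract mutation-free edges: assign classes root-downwards so each
  # parent's class is final before its children are visited
  cls <- seq_len(n_nodes)
  for (x in v[order(t_node[v], decreasing = TRUE)]) {
    if (mut[x] == 0) cls[x] <- cls[parent[x]]
  }
  list(S = sum(mut), kbar = sum(mut * leaves[v] * (n - leaves[v])) / choose(n, 2),
       K = length(unique(cls[1:n])))
}

# M replicates of (S, kbar, K).
sim_neutral_skk <- function(n, theta, M, seed = NULL) {
  with_seed_(seed, {
    res <- purrr::map_dfr(seq_len(M), function(i) {
      r <- sim_neutral_skk1(n, theta)
      tibble(S = r$S, kbar = r$kbar, K = r$K)
    })
    res
  })
}

#' Tajima's D with coalescent p-value
#'
#' `D = (kbar - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard Tajima
#' (1989) constants. The p-value is obtained by simulating `n_reps` neutral
#' constant-size coalescent samples of size n at `theta_hat = S/a1`
#' (Watterson) and taking the two-tailed simulated probability
#' `2 * min(Pr(D* <= D), Pr(D* >= D))`.
#'
#' @param S Number of segregating sites (>= 1 for a defined D).
#' @param kbar Mean pairwise differences.
#' @param n Sample size (>= 4).
#' @param n_reps Coalescent replicates for the p-value (default 10000); set
#'   to 0 to skip the p-value.
#' @param seed Seed for the null simulations.
#' @return Tibble with D, p_D (NA when skipped) and an `undefined` flag
#'   (TRUE when S = 0).
#' @export
tajimas_d <- function(S, kbar, n, n_reps = 10000, seed = NULL) {
  if (n < 4) abort("Tajima's D needs n >= 4.")
  if (S == 0) {
    return(tibble(D = NA_real_, p_D = NA_real_, undefined = TRUE))
  }
  cons <- tajima_constants(n)
  D <- (kbar - S / cons$a1) / sqrt(cons$e1 * S + cons$e2 * S * (S - 1))
  p <- NA_real_
  if (n_reps > 0) {
    theta_hat <- S / cons$a1
    null <- sim_neutral_sk(n, theta_hat, n_reps, seed = seed)
    ok <- null$S > 0
    Dn <- (null$kbar[ok] - null$S[ok] / cons$a1) /
      sqrt(cons$e1 * null$S[ok] + cons$e2 * null$S[ok] * (null$S[ok] - 1))
    p <- min(1, 2 * min(mean(Dn <= D), mean(Dn >= D)))
  }
  tibble(D = D, p_D = p, undefined = FALSE)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n),
# computed by the stable log-space recurrence; memoized per session.
.stirling_cache <- new.env(parent = emptyenv())
log_stirling1_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  ls <- 0  # row 1: |s(1,1)| = 1
  if (n > 1) {
    for (m in 2:n) {
      prev <- c(-Inf, ls, -Inf)  # pad k=0 and k=m
      ls <- vapply(seq_len(m), function(k) {
        a <- prev[k]                  # |s(m-1, k-1)|
        b <- log(m - 1) + prev[k + 1] # (m-1) |s(m-1, k)|
        logsumexp(c(a, b))
      }, numeric(1))
    }
  }
  .stirling_cache[[key]] <- ls
  ls
}

#' Ewens tail probability Pr(K >= k_obs)
#'
#' Probability of observing at least `k_obs` distinct haplotypes in a sample
#' of n under the Ewens sampling distribution at scaled mutation rate theta:
#' `Pr(K = k) = |s(n,k)| theta^k / (theta (theta+1) ... (theta+n-1))`.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (> 0).
#' @param k_obs Observed haplotype count (1..n).
#' @return Probability in `[0, 1]`.
#' @export
ewens_k_tail <- function(n, theta, k_obs) {
  if (theta <= 0) abort("theta must be positive.")
  if (k_obs < 1 || k_obs > n) abort("k_obs must be in 1..n.")
  ls <- log_stirling1_row(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  lp <- lp - logsumexp(lp)  # guard rounding; sums to 1 analytically
  sum(exp(lp[k_obs:n]))
}

#' Fu's Fs with coalescent p-value
#'
#' `S' = Pr(K >= k_obs | theta = kbar)` under the Ewens sampling
#' distribution; `Fs = ln(S'/(1 - S'))`. Strongly negative values indicate an
#' excess of rare haplotypes, as produced by demographic expansion. The
#' p-value simulates `n_reps` neutral coalescent samples at `theta = kbar`,
#' computes each replicate's Fs (from its own K and kbar) and reports the
#' one-tailed probability `Pr(Fs* <= Fs)` (significance conventionally
#' assessed at alpha = 0.02).
#'
#' @param n Sample size (>= 3).
#' @param kbar Observed mean pairwise differences (> 0 for a defined Fs).
#' @param k_obs Observed number of haplotypes (>= 1).
#' @param n_reps Coalescent replicates for the p-value; 0 skips it.
#' @param seed Seed for the null simulations.
#' @return Tibble with Fs, p_Fs and an `undefined` flag (k_obs = 1 gives
#'   S' = 1, Fs = +Inf; kbar = 0 is undefined).
#' @export
fus_fs <- function(n, kbar, k_obs, n_reps = 1000, seed = NULL) {
  if (n < 3) abort("Fu's Fs needs n >= 3.")
  if (k_obs < 1) abort("k_obs must be >= 1.")
  if (kbar <= 0) {
    return(tibble(Fs = NA_real_, p_Fs = NA_real_, undefined = TRUE))
  }
  if (k_obs == 1) {
    return(tibble(Fs = Inf, p_Fs = NA_real_, undefined = TRUE))
  }
  sp <- ewens_k_tail(n, kbar, k_obs)
  # S' near 0 (more haplotypes than neutrality predicts) gives strongly
  # negative Fs; log1p keeps precision when S' is close to 1
  Fs <- log(sp) - log1p(-sp)
  p <- NA_real_
  if (n_reps > 0) {
    null <- sim_neutral_skk(n, kbar, n_reps, seed = seed)
    fs_rep <- vapply(seq_len(n_reps), function(i) {
      if (null$kbar[i] <= 0 || null$K[i] <= 1) return(Inf)
      s2 <- ewens_k_tail(n, null$kbar[i], null$K[i])
      log(s2) - log1p(-s2)
    }, numeric(1))
    p <- mean(fs_rep <= Fs)
  }
  tibble(Fs = Fs, p_Fs = p, undefined = FALSE)
}

#' Neutrality tests for a group alignment
#'
#' Convenience wrapper computing S, mean pairwise differences, Tajima's D and
#' Fu's Fs with their simulated p-values for one group.
#'
#' @param a Group [mt_alignment()] (n >= 4).
#' @param n_reps Null-coalescent replicates per test.
#' @param seed Master seed (spawns one stream per test).
#' @return One-row tibble: n, S, kbar, k (haplotypes), D, p_D, Fs, p_Fs.
#' @export
neutrality_tests <- function(a, n_reps = 1000, seed = NULL) {
  n <- nrow(a)
  mask <- usable_sites(a)
  S <- segregating_sites(a, sites = mask)
  d <- pairwise_diff_matrix(a)
  kbar <- sum(d[upper.tri(d)]) / choose(n, 2)
  k_obs <- nrow(collapse_haplotypes(a))
  seeds <- spawn_seeds(seed, 2)
  td <- tajimas_d(S, kbar, n, n_reps = n_reps, seed = seeds[1])
  fs <- fus_fs(n, kbar, k_obs, n_reps = n_reps, seed = seeds[2])
  tibble(n = n, S = S, kbar = kbar, k = k_obs,
         D = td$D, p_D = td$p_D, Fs = fs$Fs, p_Fs = fs$p_Fs)
}
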