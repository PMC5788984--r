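# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: plain loops over pairs and sites.

random_toy_alignment <- function(n, L, p_missing = 0.1) {
  chars <- c("A", "C", "G", "T", "N", "-")
  probs <- c(rep((1 - p_missing) / 4, 4), p_missing / 2, p_missing / 2)
  m <- matrix(sample(chars, n * L, replace = TRUE, prob = probs), nrow = n)
  mt_alignment(m, sprintf("t%02d", seq_len(n)))
}

# columns where every record is a plain base
oracle_complete_sites <- function(m) {
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    keep[j] <- all(m[, j] %in% c("A", "C", "G", "T"))
  }
  which(keep)
}

oracle_pairwise_diffs <- function(m, sites = seq_len(ncol(m))) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cnt <- 0L
    for (s in sites) {
      bi <- m[i, s]; bj <- m[j, s]
      if (bi %in% c("A", "C", "G", "T") && bj %in% c("A", "C", "G", "T") && bi != bj) {
        cnt <- cnt + 1L
      }
    }
    d[i, j] <- d[j, i] <- cnt
  }
  d
}

oracle_diversity <- function(m, groups = NULL) {
  sites <- oracle_complete_sites(m)
  n <- nrow(m)
  S <- 0L
  for (s in sites) if (length(unique(m[, s])) > 1) S <- S + 1L
  d <- oracle_pairwise_diffs(m, sites)
  pi <- sum(d[upper.tri(d)]) / (n * (n - 1) / 2) / length(sites)
  key <- apply(m[, sites, drop = FALSE], 1, paste, collapse = "")
  freqs <- as.vector(table(key))
  Hd <- n / (n - 1) * (1 - sum((freqs / n)^2))
  h <- length(freqs)
  hP <- NULL
  if (!is.null(groups)) {
    hP <- sapply(unique(groups), function(g) {
      sum(sapply(unique(key), function(k) {
        any(key == k & groups == g) && !any(key == k & groups != g)
      }))
    })
    names(hP) <- unique(groups)
  }
  list(S = S, pi = pi, Hd = Hd, h = h, h_P = hP, sites = sites)
}

# Exhaustive union of all minimum spanning trees of a weighted complete graph
# given as a distance matrix: enumerate all spanning trees, keep the minima.
oracle_mst_union <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  combos <- utils::combn(ne, n - 1)
  best <- Inf
  union_edges <- matrix(numeric(0), ncol = 2)
  for (c_i in seq_len(ncol(combos))) {
    sel <- combos[, c_i]
    # spanning tree test: n-1 edges connecting all n vertices
    comp <- seq_len(n)
    for (e in sel) {
      a <- comp[pairs[e, 1]]; b <- comp[pairs[e, 2]]
      if (a != b) comp[comp == b] <- a
    }
    if (length(unique(comp)) != 1) next
    w <- sum(d[pairs[sel, , drop = FALSE]])
    if (w < best - 1e-9) {
      best <- w
      union_edges <- pairs[sel, , drop = FALSE]
    } else if (abs(w - best) < 1e-9) {
      union_edges <- rbind(union_edges, pairs[sel, , drop = FALSE])
    }
  }
  unique(as.data.frame(union_edges))
}

# Tajima's D from first principles (textbook constants, coded independently)
oracle_tajimas_d <- function(S, kbar, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Ewens haplotype-count pmf via explicit expansion of the rising factorial
# theta (theta+1) ... (theta+n-1): exact in double arithmetic for small n.
oracle_ewens_pmf <- function(n, theta) {
  co <- 1
  for (i in 0:(n - 1)) co <- c(0, co) + c(co * i, 0)  # multiply by (theta + i)
  k <- seq_len(n)
  co[k + 1] * theta^k / prod(theta + 0:(n - 1))
}
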