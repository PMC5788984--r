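#' Number of segregating sites
#'
#' Counts usable columns carrying at least two distinct bases among the
#' sequences. By default the complete-deletion mask of `a` itself is used;
#' pass `sites` to impose an external mask (e.g. the global mask of a larger
#' alignment when profiling subsets).
#'
#' @param a An [mt_alignment()] with n >= 2.
#' @param sites Optional integer vector of 1-based columns to consider.
#' @return Integer count.
#' @export
segregating_sites <- function(a, sites = NULL) {
  if (nrow(a) < 2) abort("Segregating sites need at least 2 sequences.")
  if (is.null(sites)) sites <- usable_sites(a)
  m <- unclass(a)[, sites, drop = FALSE]
  sum(apply(m, 2, function(col) {
    col <- col[col %in% .DNA_STRICT]
    length(unique(col)) > 1
  }))
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences over all n(n-1)/2 sequence pairs,
#' divided by the number of compared sites.
#'
#' @inheritParams segregating_sites
#' @return Per-site nucleotide diversity (numeric).
#' @export
nucleotide_diversity <- function(a, sites = NULL) {
  n <- nrow(a)
  if (n < 2) abort("Nucleotide diversity needs at least 2 sequences.")
  if (is.null(sites)) sites <- usable_sites(a)
  sub <- mt_alignment(unclass(a)[, sites, drop = FALSE], rownames(a))
  d <- pairwise_diff_matrix(sub, policy = "pairwise_deletion")
  sum(d[upper.tri(d)]) / choose(n, 2) / length(sites)
}

#' Haplotype (gene) diversity
#'
#' `Hd = n/(n-1) * (1 - sum((f_i/n)^2))` — the probability that two randomly
#' drawn sequences carry different haplotypes, with small-sample correction.
#'
#' @param freqs Haplotype frequencies (positive integers).
#' @param n Sample size; defaults to `sum(freqs)`.
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(freqs, n = sum(freqs)) {
  if (n < 2) abort("Haplotype diversity needs n >= 2.")
  if (sum(freqs) != n) abort("Frequencies must sum to n.")
  n / (n - 1) * (1 - sum((freqs / n)^2))
}

#' Number of private haplotypes of a group
#'
#' A haplotype is private to a group when it occurs there and in no other
#' group of the same partition.
#'
#' @param ht Haplotype table from [collapse_haplotypes()].
#' @param group Group name (one of the frequency columns).
#' @return Integer count.
#' @export
private_haplotypes <- function(ht, group) {
  groups <- attr(ht, "groups")
  if (!group %in% groups) {
    abort(paste0("Unknown group '", group, "'; available: ", paste(groups, collapse = ", ")))
  }
  fr <- as.matrix(as_tibble(ht)[, groups, drop = FALSE])
  others <- setdiff(groups, group)
  sum(fr[, group] > 0 & rowSums(fr[, others, drop = FALSE]) == 0)
}

#' Diversity indices per group
#'
#' Computes, for each group of the partition, the sample size n, segregating
#' sites S, haplotype count h, private haplotype count h_P, haplotype
#' diversity Hd and per-site nucleotide diversity pi. All values are stored
#' at full precision; see [format_diversity_table()] for report rounding.
#' A single complete-deletion site mask computed on the full alignment is
#' applied to every group so that group values are commensurable.
#'
#' @param a An [mt_alignment()].
#' @param s Sample table.
#' @param partition Column of `s` defining the groups (default `"group"`).
#' @return A tibble with one row per group; groups with n < 2 carry NA for
#'   the indices that require two sequences.
#' @export
diversity_profile <- function(a, s, partition = "group") {
  if (!partition %in% names(s)) abort(paste0("No column '", partition, "' in sample table."))
  s <- s[s$sample_id %in% rownames(a), , drop = FALSE]
  mask <- usable_sites(a[s$sample_id, , drop = FALSE])
  ht <- collapse_haplotypes(a, s, group_col = partition)
  groups <- attr(ht, "groups")
  purrr::map_dfr(groups, function(g) {
    ids <- s$sample_id[s[[partition]] == g]
    sub <- a[ids, , drop = FALSE]
    n <- length(ids)
    hp <- private_haplotypes(ht, g)
    h <- sum(as_tibble(ht)[[g]] > 0)
    if (n < 2) {
      return(tibble(group = g, n = n, S = NA_integer_, h = h, h_P = hp,
                    Hd = NA_real_, pi = NA_real_))
    }
    tibble(
      group = g, n = n,
      S = segregating_sites(sub, sites = mask),
      h = h, h_P = hp,
      Hd = haplotype_diversity(as_tibble(ht)[[g]][as_tibble(ht)[[g]] > 0], n),
      pi = nucleotide_diversity(sub, sites = mask)
    )
  })
}

#' Round a diversity table for reporting
#'
#' Mirrors the usual report convention: Hd to 3 decimals, pi reported
#' multiplied by 1000 with 2 decimals (column `pi_e3`).
#'
#' @param prof Result of [diversity_profile()] or [rarefy()].
#' @return Tibble with rounded `Hd` and `pi_e3` columns.
#' @export
format_diversity_table <- function(prof) {
  dplyr::mutate(
    prof,
    Hd = round(.data$Hd, 3),
    pi_e3 = round(.data$pi * 1000, 2),
    pi = NULL
  )
}

#' Rarefied diversity indices for one group
#'
#' Draws `reps` random subsamples of `target_n` individuals without
#' replacement from the group, recomputes the diversity indices on each draw
#' and returns their arithmetic means. Draws are independent across reps and
#' fully reproducible: the master `seed` spawns one sub-seed per rep.
#' Private haplotypes of a subsample are counted against the *full* data of
#' the other groups. The global complete-deletion site mask of the input
#' alignment is reused for every subsample so rarefied and total indices are
#' commensurable.
#'
#' @param a An [mt_alignment()].
#' @param s Sample table.
#' @param group Group to rarefy.
#' @param target_n Subsample size; defaults to the smallest group size in the
#'   partition. Must not exceed the group's n.
#' @param reps Number of subsamples (default 5).
#' @param seed Master seed.
#' @param partition Column of `s` defining groups.
#' @return One-row tibble of mean indices with attribute `reps` holding the
#'   per-rep tibble.
#' @export
rarefy <- function(a, s, group, target_n = NULL, reps = 5, seed = NULL,
                   partition = "group") {
  s <- s[s$sample_id %in% rownames(a), , drop = FALSE]
  sizes <- table(s[[partition]])
  if (!group %in% names(sizes)) abort(paste0("Unknown group '", group, "'."))
  if (is.null(target_n)) target_n <- min(sizes)
  n_g <- sizes[[group]]
  if (target_n > n_g) abort("target_n exceeds the group's sample size.")
  if (reps < 1) abort("reps must be >= 1.")
  mask <- usable_sites(a[s$sample_id, , drop = FALSE])
  ids <- s$sample_id[s[[partition]] == group]
  other <- s[s[[partition]] != group, , drop = FALSE]
  seeds <- spawn_seeds(seed, reps)
  per_rep <- purrr::map_dfr(seq_len(reps), function(r) {
    draw <- with_seed_(seeds[r], sample(ids, target_n))
    sub_s <- dplyr::bind_rows(s[s$sample_id %in% draw, , drop = FALSE], other)
    sub_a <- a[sub_s$sample_id, , drop = FALSE]
    ht <- collapse_haplotypes(sub_a, sub_s, group_col = partition)
    fr <- as_tibble(ht)[[group]]
    tibble(
      rep = r,
      n = target_n,
      S = segregating_sites(a[draw, , drop = FALSE], sites = mask),
      h = sum(fr > 0),
      h_P = private_haplotypes(ht, group),
      Hd = haplotype_diversity(fr[fr > 0], target_n),
      pi = nucleotide_diversity(a[draw, , drop = FALSE], sites = mask)
    )
  })
  out <- dplyr::summarise(
    per_rep,
    group = group, n = target_n,
    S = mean(.data$S), h = mean(.data$h), h_P = mean(.data$h_P),
    Hd = mean(.data$Hd), pi = mean(.data$pi)
  )
  out <- out[, c("group", "n", "S", "h", "h_P", "Hd", "pi")]
  attr(out, "reps") <- per_rep
  out
}
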