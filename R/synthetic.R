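#' Star-like expansion fixture
#'
#' One central haplotype at high frequency surrounded by `n_tip_haplotypes`
#' singleton tips, each one mutation step away at a distinct site — the
#' signature of a recent demographic expansion (unimodal mismatch
#' distribution, negative Tajima's D and Fu's Fs).
#'
#' @param n Total sample size.
#' @param L Sequence length (default 866).
#' @param n_tip_haplotypes Number of tip haplotypes (< n).
#' @param seed Seed.
#' @param lineage,group Labels for the sample table.
#' @return List with `alignment`, `samples`, and `truth` (central sequence
#'   index, tip sites).
#' @export
make_star_expansion <- function(n = 50, L = 866, n_tip_haplotypes = 11,
                                seed = NULL, lineage = "blue", group = "North") {
  if (n_tip_haplotypes >= n) abort("n_tip_haplotypes must be < n.")
  if (L < n_tip_haplotypes) abort("L too small for the requested tips.")
  with_seed_(seed, {
    centre <- sample(.DNA_STRICT, L, replace = TRUE)
    sites <- sample.int(L, n_tip_haplotypes)
    m <- matrix(centre, nrow = n, ncol = L, byrow = TRUE)
    for (i in seq_len(n_tip_haplotypes)) {
      cur <- centre[sites[i]]
      m[i + 1, sites[i]] <- sample(setdiff(.DNA_STRICT, cur), 1)
    }
    ids <- sprintf("%s_%03d", lineage, seq_len(n))
    aln <- mt_alignment(m, ids)
    samples <- tibble(sample_id = ids, lineage = lineage,
                      group = group, subgroup = ".")
    list(alignment = aln, samples = samples,
         truth = list(kind = "star_expansion", central = ids[1],
                      tip_sites = sites, n_tip_haplotypes = n_tip_haplotypes))
  })
}

#' Two-refuge disjunct fixture
#'
#' Two haplotype clusters assigned to groups North and South whose exclusive
#' cores differ by `inter_cluster_steps` mutation steps, with exactly
#' `n_shared` haplotypes present in both groups. The northern cluster is
#' star-like (skewed frequencies); the southern one has near-equifrequent
#' haplotypes, so southern haplotype diversity exceeds northern.
#'
#' @param nN,nS Sample sizes of the northern/southern groups.
#' @param inter_cluster_steps Steps between the exclusive cluster cores
#'   (>= 2).
#' @param n_shared Number of shared haplotypes (default 1).
#' @param n_tips_north,n_tips_south Tip haplotypes per cluster.
#' @param L Sequence length.
#' @param seed Seed.
#' @param lineage Lineage label.
#' @return List with `alignment`, `samples`, `truth` (core sequences, shared
#'   haplotype ids, planned step distance).
#' @export
make_two_refuge <- function(nN = 40, nS = 24, inter_cluster_steps = 4,
                            n_shared = 1, n_tips_north = 5, n_tips_south = 5,
                            L = 866, seed = NULL, lineage = "yellow") {
  if (inter_cluster_steps < 2) abort("inter_cluster_steps must be >= 2.")
  need_sites <- inter_cluster_steps + n_tips_north + n_tips_south + n_shared
  if (L < need_sites) abort("L too small for the requested structure.")
  n_hapN <- 1 + n_tips_north + n_shared
  n_hapS <- 1 + n_tips_south + n_shared
  if (nN < n_hapN || nS < n_hapS) abort("Group sizes too small for the haplotypes.")
  with_seed_(seed, {
    coreN <- sample(.DNA_STRICT, L, replace = TRUE)
    sites <- sample.int(L, need_sites)
    flip <- function(seqv, at) {
      for (s in at) seqv[s] <- sample(setdiff(.DNA_STRICT, seqv[s]), 1)
      seqv
    }
    core_sites <- sites[seq_len(inter_cluster_steps)]
    tipN_sites <- sites[inter_cluster_steps + seq_len(n_tips_north)]
    tipS_sites <- sites[inter_cluster_steps + n_tips_north + seq_len(n_tips_south)]
    shared_sites <- sites[inter_cluster_steps + n_tips_north + n_tips_south +
                            seq_len(n_shared)]
    coreS <- flip(coreN, core_sites)
    hapsN <- c(list(coreN), lapply(tipN_sites, function(s) flip(coreN, s)))
    hapsS <- c(list(coreS), lapply(tipS_sites, function(s) flip(coreS, s)))
    shared <- lapply(shared_sites, function(s) flip(coreN, s))  # northern-cluster tips
    # northern group: star-skewed; one copy of each shared haplotype
    freqN <- c(nN - n_tips_north - n_shared, rep(1, n_tips_north))
    seqsN <- c(rep(list(coreN), freqN[1]),
               hapsN[-1][rep(seq_len(n_tips_north), 1)],
               shared)
    # southern group: near-equifrequent across its own haplotypes + shared
    n_hapS_all <- length(hapsS) + n_shared
    base <- (nS - n_shared) %/% length(hapsS)
    rem <- (nS - n_shared) %% length(hapsS)
    freqS <- rep(base, length(hapsS)) + c(rep(1, rem), rep(0, length(hapsS) - rem))
    seqsS <- c(unlist(lapply(seq_along(hapsS),
                             function(i) rep(hapsS[i], freqS[i])), recursive = FALSE),
               shared)
    mN <- do.call(rbind, seqsN)
    mS <- do.call(rbind, seqsS)
    ids <- c(sprintf("N_%03d", seq_len(nrow(mN))), sprintf("S_%03d", seq_len(nrow(mS))))
    aln <- mt_alignment(rbind(mN, mS), ids)
    samples <- tibble(
      sample_id = ids, lineage = lineage,
      group = c(rep("North", nrow(mN)), rep("South", nrow(mS))),
      subgroup = "."
    )
    list(alignment = aln, samples = samples,
         truth = list(kind = "two_refuge",
                      core_north = paste(coreN, collapse = ""),
                      core_south = paste(coreS, collapse = ""),
                      inter_cluster_steps = inter_cluster_steps,
                      n_shared = n_shared,
                      shared_seqs = vapply(shared, paste, character(1), collapse = "")))
  })
}

#' Bimodal co-distributed subcluster fixture
#'
#' Two star-like subclusters whose central haplotypes differ by
#' `centre_distance` mutation steps, with members of both subclusters
#' interleaved across the North and South groups (no geographic sorting).
#' The pooled mismatch distribution is multimodal while each subcluster's is
#' unimodal.
#'
#' @param n Total sample size (split evenly between subclusters).
#' @param L Sequence length.
#' @param centre_distance Steps between the two subcluster centres (>= 1).
#' @param tips_per_cluster Singleton tip haplotypes per subcluster.
#' @param seed Seed.
#' @param lineage Lineage label.
#' @return List with `alignment`, `samples`, `truth` (centre ids, distance,
#'   subcluster membership).
#' @export
make_bimodal_pair <- function(n = 24, L = 866, centre_distance = 2,
                              tips_per_cluster = 2, seed = NULL,
                              lineage = "red") {
  if (centre_distance < 1) abort("centre_distance must be >= 1.")
  n1 <- n %/% 2
  n2 <- n - n1
  if (min(n1, n2) <= tips_per_cluster) abort("n too small for the requested tips.")
  with_seed_(seed, {
    c1 <- sample(.DNA_STRICT, L, replace = TRUE)
    sites <- sample.int(L, centre_distance + 2 * tips_per_cluster)
    flip <- function(seqv, at) {
      for (s in at) seqv[s] <- sample(setdiff(.DNA_STRICT, seqv[s]), 1)
      seqv
    }
    c2 <- flip(c1, sites[seq_len(centre_distance)])
    t1_sites <- sites[centre_distance + seq_len(tips_per_cluster)]
    t2_sites <- sites[centre_distance + tips_per_cluster + seq_len(tips_per_cluster)]
    cl1 <- c(rep(list(c1), n1 - tips_per_cluster),
             lapply(t1_sites, function(s) flip(c1, s)))
    cl2 <- c(rep(list(c2), n2 - tips_per_cluster),
             lapply(t2_sites, function(s) flip(c2, s)))
    m <- do.call(rbind, c(cl1, cl2))
    ids <- sprintf("r_%03d", seq_len(n))
    subcl <- c(rep(1L, n1), rep(2L, n2))
    aln <- mt_alignment(m, ids)
    samples <- tibble(
      sample_id = ids, lineage = lineage,
      group = rep_len(c("North", "South"), n),  # interleaved, both subclusters
      subgroup = "."
    )
    list(alignment = aln, samples = samples,
         truth = list(kind = "bimodal_pair",
                      centre1 = paste(c1, collapse = ""),
                      centre2 = paste(c2, collapse = ""),
                      centre_distance = centre_distance,
                      subcluster = stats::setNames(subcl, ids)))
  })
}

#' Pseudo-observed dataset from a known scenario
#'
#' One coalescent draw under a scenario with known parameters, with the
#' ground truth carried alongside (and written as a JSON sidecar when the
#' alignment is exported via the pipeline).
#'
#' @param kind Scenario kind.
#' @param params Named list/row with Ne1, Ne2, Ne3, Ne_anc, t1, t2, mu.
#' @param sample_sizes Per-population sample sizes.
#' @param populations Population names.
#' @param L Sequence length.
#' @param seed Seed.
#' @return List with `alignment`, `samples`, `variants`, `truth`.
#' @export
make_pseudoobs <- function(kind, params, sample_sizes = c(25, 25, 25),
                           populations = c("P1", "P2", "P3"), L = 866,
                           seed = NULL) {
  scn <- scenario(kind, populations,
                  Ne = c(params$Ne1, params$Ne2, params$Ne3),
                  Ne_anc = params$Ne_anc, t1 = params$t1,
                  t2 = if (is.null(params$t2) || is.na(params$t2)) NULL else params$t2)
  sim <- simulate_scenario(scn, mu = params$mu, n = sample_sizes, L = L, seed = seed)
  sim$truth <- list(kind = kind, params = params[!vapply(params, is.null, logical(1))],
                    sample_sizes = sample_sizes, populations = populations,
                    L = L, seed = seed)
  sim
}
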