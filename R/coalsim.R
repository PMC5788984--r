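#' Define a demographic scenario
#'
#' Three-population divergence scenarios for a single non-recombining mtDNA
#' locus with haploid effective sizes and pure splits (no migration):
#'
#' * `gradual_north_derived` (scenario 1): looking backward, population 1
#'   merges into population 2 at `t1` generations, and population 2 merges
#'   into the ancestral population (size `Ne_anc`) at `t2` — forward in time,
#'   a stepwise expansion out of population 3's refuge.
#' * `gradual_south_derived` (scenario 2): the mirror image — population 3
#'   merges into population 2 at `t1`, population 2 into the ancestor at `t2`.
#' * `sudden_trifurcation` (scenario 3): all three populations merge into the
#'   ancestral population at the single time `t1`.
#' * `constant`: a single population of size `Ne[1]`, no splits (used for
#'   neutral calibration).
#'
#' At an intermediate merge the receiving population keeps its own size; the
#' ancestral size `Ne_anc` applies after the final merge.
#'
#' @param kind Scenario kind (see above).
#' @param populations Ordered population names (length 3, or 1 for
#'   `constant`).
#' @param Ne Haploid effective sizes, one per population (> 0).
#' @param Ne_anc Ancestral haploid size (> 0).
#' @param t1 First (most recent) event time in generations (> 0).
#' @param t2 Second event time for the gradual scenarios (`t1 < t2`).
#' @return Object of class `demographic_scenario`.
#' @export
scenario <- function(kind = c("gradual_north_derived", "gradual_south_derived",
                              "sudden_trifurcation", "constant"),
                     populations, Ne, Ne_anc = NULL, t1 = NULL, t2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (length(populations) != 1 || length(Ne) != 1) {
      abort("A constant scenario has exactly one population.")
    }
  } else {
    if (length(populations) != 3 || length(Ne) != 3) {
      abort("Divergence scenarios need exactly 3 populations and sizes.")
    }
    if (is.null(Ne_anc) || Ne_anc <= 0) abort("Ne_anc must be > 0.")
    if (is.null(t1) || t1 <= 0) abort("t1 must be > 0.")
    if (kind != "sudden_trifurcation") {
      if (is.null(t2)) abort("Gradual scenarios need t2.")
      if (t1 >= t2) abort("Gradual scenarios require t1 < t2.")
    } else if (!is.null(t2)) {
      abort("sudden_trifurcation has a single event time t1.")
    }
  }
  if (any(Ne <= 0)) abort("All Ne must be > 0.")
  structure(
    list(kind = kind, populations = populations, Ne = Ne,
         Ne_anc = Ne_anc, t1 = t1, t2 = t2),
    class = "demographic_scenario"
  )
}

# Backward-time merge schedule: list of (time, from_pop, into_pop, new_Ne).
merge_events <- function(scn) {
  switch(
    scn$kind,
    constant = list(),
    gradual_north_derived = list(
      list(t = scn$t1, from = 1L, into = 2L, Ne = scn$Ne[2]),
      list(t = scn$t2, from = 2L, into = 3L, Ne = scn$Ne_anc)
    ),
    gradual_south_derived = list(
      list(t = scn$t1, from = 3L, into = 2L, Ne = scn$Ne[2]),
      list(t = scn$t2, from = 2L, into = 1L, Ne = scn$Ne_anc)
    ),
    sudden_trifurcation = list(
      list(t = scn$t1, from = 1L, into = 3L, Ne = scn$Ne_anc),
      list(t = scn$t1, from = 2L, into = 3L, Ne = scn$Ne_anc)
    )
  )
}

# Structured coalescent genealogy under a scenario. Returns parent pointers,
# node times (generations) and leaf counts; leaves are 1..sum(n).
sim_genealogy <- function(scn, n) {
  n_pops <- length(scn$populations)
  stopifnot(length(n) == n_pops)
  ntot <- sum(n)
  n_nodes <- 2 * ntot - 1
  parent <- integer(n_nodes)
  t_node <- numeric(n_nodes)
  leaves <- c(rep(1L, ntot), integer(ntot - 1))
  pop_of_leaf <- rep(seq_len(n_pops), times = n)
  active <- split(seq_len(ntot), pop_of_leaf)
  active <- lapply(as.character(seq_len(n_pops)), function(p) active[[p]] %||% integer(0))
  sizes <- as.numeric(scn$Ne)
  events <- merge_events(scn)
  ev_i <- 1
  t <- 0
  nxt <- ntot
  repeat {
    k <- lengths(active)
    if (sum(k) <= 1 && ev_i > length(events)) break
    rates <- k * (k - 1) / 2 / sizes
    total <- sum(rates)
    t_next_ev <- if (ev_i <= length(events)) events[[ev_i]]$t else Inf
    dt <- if (total > 0) stats::rexp(1, total) else Inf
    if (t + dt >= t_next_ev) {
      t <- t_next_ev
      while (ev_i <= length(events) && events[[ev_i]]$t <= t) {
        ev <- events[[ev_i]]
        active[[ev$into]] <- c(active[[ev$into]], active[[ev$from]])
        active[[ev$from]] <- integer(0)
        sizes[ev$into] <- ev$Ne
        ev_i <- ev_i + 1
      }
    } else {
      t <- t + dt
      p <- sample.int(length(rates), 1, prob = rates / total)
      pair <- sample.int(k[p], 2)
      ids <- active[[p]][pair]
      nxt <- nxt + 1
      parent[ids] <- nxt
      t_node[nxt] <- t
      leaves[nxt] <- sum(leaves[ids])
      active[[p]] <- c(active[[p]][-pair], nxt)
    }
  }
  list(parent = parent, t_node = t_node, leaves = leaves,
       pop_of_leaf = pop_of_leaf, ntot = ntot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop Jukes-Cantor mutations on a genealogy and return the leaf states at
# the mutated sites only: integer matrix (ntot x n_variant_sites) of bases
# 1..4 plus the variant site positions. rate = expected mutations per branch
# per generation x branch length; sites chosen uniformly on 1..L.
drop_mutations <- function(gen, mu_L, L) {
  ntot <- gen$ntot
  n_nodes <- 2 * ntot - 1
  v <- seq_len(n_nodes - 1)
  blen <- gen$t_node[gen$parent[v]] - gen$t_node[v]
  n_mut <- stats::rpois(n_nodes - 1, mu_L * blen)
  tot <- sum(n_mut)
  if (tot == 0) {
    return(list(states = matrix(integer(0), nrow = ntot, ncol = 0),
                sites = integer(0)))
  }
  site <- sample.int(L, tot, replace = TRUE)
  vsites <- sort(unique(site))
  scol <- match(site, vsites)
  branch <- rep(v, times = n_mut)
  ns <- length(vsites)
  # root state at variant sites
  root_state <- sample.int(4, ns, replace = TRUE)
  states <- matrix(0L, nrow = n_nodes, ncol = ns)
  states[n_nodes, ] <- root_state
  # children processed after parents: a parent node is always created after
  # its children, so decreasing node index is a safe order even with tied
  # node times (instantaneous star coalescence)
  muts_by_branch <- split(seq_len(tot), branch)
  for (x in rev(v)) {
    st <- states[gen$parent[x], ]
    mb <- muts_by_branch[[as.character(x)]]
    if (!is.null(mb)) {
      for (m in mb[sample.int(length(mb))]) {  # order within branch randomized
        cur <- st[scol[m]]
        st[scol[m]] <- sample((1:4)[-cur], 1)
      }
    }
    states[x, ] <- st
  }
  list(states = states[seq_len(ntot), , drop = FALSE], sites = vsites)
}

#' Simulate an mtDNA sample under a demographic scenario
#'
#' Samples a structured coalescent genealogy backward in time (lineages merge
#' across populations at the scenario's split times), drops Poisson mutations
#' under a finite-sites Jukes-Cantor model (rate `mu` per site per
#' generation) and returns the resulting alignment plus a sample table.
#' Fully deterministic given (`scn`, parameters, `seed`).
#'
#' @param scn A [scenario()].
#' @param mu Per-site per-generation mutation rate.
#' @param n Sample sizes, one per population.
#' @param L Sequence length in sites (default 866).
#' @param seed Seed.
#' @param lineage Lineage label written to the sample table.
#' @return List with `alignment` ([mt_alignment()]), `samples` (tibble), and
#'   `variants` (integer matrix of leaf states at the mutated sites, for fast
#'   summary statistics).
#' @export
simulate_scenario <- function(scn, mu, n, L = 866, seed = NULL, lineage = "sim") {
  stopifnot(mu >= 0, L > 0)
  with_seed_(seed, {
    gen <- sim_genealogy(scn, n)
    vm <- drop_mutations(gen, mu * L, L)
    ids <- sprintf("%s_%s_%03d", lineage,
                   scn$populations[gen$pop_of_leaf], seq_len(gen$ntot))
    samples <- tibble(
      sample_id = ids,
      lineage = lineage,
      group = scn$populations[gen$pop_of_leaf],
      subgroup = "."
    )
    aln <- variants_to_alignment(vm$states, vm$sites, L, ids)
    list(alignment = aln, samples = samples,
         variants = structure(vm$states, sites = vm$sites,
                              pop = scn$populations[gen$pop_of_leaf]))
  })
}

# Embed variant-site states into a full random-background alignment.
variants_to_alignment <- function(states, sites, L, ids) {
  background <- sample.int(4, L, replace = TRUE)
  m <- matrix(.DNA_STRICT[background], nrow = length(ids), ncol = L, byrow = TRUE)
  if (length(sites)) {
    m[, sites] <- .DNA_STRICT[states]
  }
  mt_alignment(m, ids)
}

#' Simulate a sample under the sudden-expansion demography
#'
#' Single population whose scaled size is `theta1` at present and `theta0`
#' before time `tau` (mutational units) — the generative counterpart of
#' [expected_mismatch()], used by the parametric bootstrap. Time is measured
#' in mutational units (pair accumulates differences at rate 1 per unit), so
#' the pair coalescence rate in a population of scaled size theta is
#' 1/theta; mutations fall on each lineage at rate 1/2 per unit time, placed
#' uniformly on L finite sites under Jukes-Cantor.
#'
#' @param theta0,theta1 Scaled sizes before/after the expansion (>= 0;
#'   `theta0 = 0` collapses all remaining lineages at `tau`).
#' @param tau Expansion time in mutational units (>= 0).
#' @param n Sample size.
#' @param L Sequence length.
#' @param seed Seed.
#' @return List with `alignment` and `samples` as in [simulate_scenario()].
#' @export
sim_sudden_expansion <- function(theta0, theta1, tau, n, L = 866, seed = NULL) {
  stopifnot(theta0 >= 0, theta1 >= 0, tau >= 0, n >= 2, L > 0)
  with_seed_(seed, {
    n_nodes <- 2 * n - 1
    parent <- integer(n_nodes)
    t_node <- numeric(n_nodes)
    leaves <- c(rep(1L, n), integer(n - 1))
    active <- 1:n
    t <- 0
    nxt <- n
    while (length(active) > 1) {
      k <- length(active)
      th <- if (t < tau) theta1 else theta0
      if (th == 0) {  # instantaneous coalescence of everything remaining
        dt <- 0
      } else {
        dt <- stats::rexp(1, k * (k - 1) / 2 / th)
      }
      if (t < tau && t + dt > tau) {
        t <- tau
        next
      }
      t <- t + dt
      pair <- sample.int(k, 2)
      nxt <- nxt + 1
      parent[active[pair]] <- nxt
      t_node[nxt] <- t
      leaves[nxt] <- sum(leaves[active[pair]])
      active <- c(active[-pair], nxt)
    }
    gen <- list(parent = parent, t_node = t_node, leaves = leaves,
                pop_of_leaf = rep(1L, n), ntot = n)
    vm <- drop_mutations(gen, 0.5, L)  # rate 1/2 per lineage per tau-unit
    ids <- sprintf("exp_%03d", 1:n)
    list(
      alignment = variants_to_alignment(vm$states, vm$sites, L, ids),
      samples = tibble(sample_id = ids, lineage = "sim", group = "pop", subgroup = ".")
    )
  })
}
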