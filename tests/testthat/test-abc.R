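test_that("prior draws respect bounds, ordering and uniform moments", {
  spec <- prior_spec()
  d <- sample_priors(spec, "gradual_north_derived", n = 5000, seed = 1)
  expect_true(all(d$t1 < d$t2))
  for (cc in c("Ne1", "Ne2", "Ne3", "Ne_anc")) {
    expect_true(all(d[[cc]] >= 10 & d[[cc]] <= 10000))
  }
  expect_true(all(d$mu >= 1e-8 & d$mu <= 1e-6))
  expect_equal(mean(d$Ne1), (10 + 10000) / 2, tolerance = 0.03)
  d3 <- sample_priors(spec, "sudden_trifurcation", n = 100, seed = 2)
  expect_true(all(is.na(d3$t2)))
  expect_error(prior_spec(ne = c(10, 5)), "lower < upper")
})

test_that("summary statistics match a brute-force recount on toy data", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- 12
      a <- random_toy_alignment(n, 40, p_missing = 0)
      grp <- rep(c("X", "Y", "Z"), each = 4)
      s <- tibble::tibble(sample_id = rownames(a), lineage = "l",
                          group = grp, subgroup = ".")
      st <- summary_statistics(a, s, group_order = c("X", "Y", "Z"))
      m <- unclass(a)
      d <- oracle_pairwise_diffs(m)
      for (g in c("X", "Y", "Z")) {
        ix <- which(grp == g)
        sub <- m[ix, , drop = FALSE]
        expect_equal(st[[paste0("nhap_", g)]],
                     length(unique(apply(sub, 1, paste, collapse = ""))))
        expect_equal(st[[paste0("S_", g)]],
                     sum(apply(sub, 2, function(x) length(unique(x)) > 1)))
        dg <- d[ix, ix]
        expect_equal(st[[paste0("kbar_", g)]],
                     sum(dg[upper.tri(dg)]) / choose(length(ix), 2))
        seg_g <- apply(sub, 2, function(x) length(unique(x)) > 1)
        mono_others <- sapply(seq_len(ncol(m)), function(j) {
          all(sapply(setdiff(c("X", "Y", "Z"), g), function(o) {
            length(unique(m[grp == o, j])) == 1
          }))
        })
        expect_equal(st[[paste0("priv_", g)]], sum(seg_g & mono_others))
      }
      for (pair in list(c("X", "Y"), c("X", "Z"), c("Y", "Z"))) {
        i1 <- which(grp == pair[1]); i2 <- which(grp == pair[2])
        B <- mean(d[i1, i2])
        d11 <- d[i1, i1]; d22 <- d[i2, i2]
        W <- (sum(d11[upper.tri(d11)]) + sum(d22[upper.tri(d22)])) /
          (choose(length(i1), 2) + choose(length(i2), 2))
        expect_equal(st[[paste0("B_", pair[1], "_", pair[2])]], B)
        expect_equal(st[[paste0("W_", pair[1], "_", pair[2])]], W)
        fst_want <- if (B == 0) 0 else min(max(1 - W / B, 0), 1)
        expect_equal(st[[paste0("FST_", pair[1], "_", pair[2])]], fst_want)
      }
    }
  })
})

test_that("summary statistic conventions on degenerate data", {
  a <- mt_alignment(matrix("A", 6, 20), sprintf("s%d", 1:6))
  s <- tibble::tibble(sample_id = rownames(a), lineage = "l",
                      group = rep(c("X", "Y"), each = 3), subgroup = ".")
  st <- summary_statistics(a, s)
  expect_equal(st$nhap_X, 1)
  expect_equal(st$S_X, 0)
  expect_equal(st$FST_X_Y, 0)  # B = 0 convention
  # two monomorphic groups fixed for different bases at k sites
  m <- matrix("A", 6, 20)
  m[4:6, 1:3] <- "G"
  a2 <- mt_alignment(m, sprintf("s%d", 1:6))
  st2 <- summary_statistics(a2, s)
  expect_equal(st2$FST_X_Y, 1)
  expect_equal(st2$B_X_Y, 3)
})

test_that("reference table is seeded, complete and typed", {
  ref <- build_reference_table(n_sims = 10, sample_sizes = c(4, 4, 4),
                               L = 120, seed = 5)
  expect_equal(nrow(ref), 30)
  expect_equal(as.vector(table(ref$scenario)), rep(10L, 3))
  ref2 <- build_reference_table(n_sims = 10, sample_sizes = c(4, 4, 4),
                                L = 120, seed = 5)
  expect_identical(ref, ref2)
  expect_true(all(is.na(ref$t2[ref$kind == "sudden_trifurcation"])))
  expect_false(anyNA(ref$kbar_P1))
})

test_that("model choice probabilities sum to one and standardization is affine-invariant", {
  withr::with_seed(23, {
    ref <- build_reference_table(n_sims = 150, sample_sizes = c(6, 6, 6),
                                 L = 300, seed = 8)
    p <- sample_priors(prior_spec(), "sudden_trifurcation", 1)
    po <- make_pseudoobs("sudden_trifurcation", as.list(p),
                         sample_sizes = c(6, 6, 6), L = 300, seed = 99)
    obs <- summary_statistics(po$alignment, po$samples,
                              group_order = c("P1", "P2", "P3"))
    mc <- model_choice(obs, ref, n_closest = 45)
    expect_equal(sum(mc$posterior$prob), 1, tolerance = 1e-6)
    expect_true(all(mc$posterior$lo <= mc$posterior$prob + 1e-9))
    expect_true(all(mc$posterior$hi >= mc$posterior$prob - 1e-9))
    # affine rescaling of one statistic leaves the result unchanged
    ref2 <- ref
    ref2$kbar_P1 <- ref2$kbar_P1 * 1000 + 7
    obs2 <- obs
    obs2$kbar_P1 <- obs2$kbar_P1 * 1000 + 7
    mc2 <- model_choice(obs2, ref2, n_closest = 45)
    expect_equal(mc2$posterior$prob, mc$posterior$prob, tolerance = 1e-6)
  })
})

test_that("posterior is near-uniform when all scenarios generate identically", {
  # same generating model labelled as three scenarios: expect ~1/3 each
  withr::with_seed(31, {
    scn <- scenario("sudden_trifurcation", c("P1", "P2", "P3"),
                    Ne = c(500, 500, 500), Ne_anc = 500, t1 = 500)
    rows <- purrr::map_dfr(1:240, function(i) {
      sim <- simulate_scenario(scn, mu = 5e-7, n = c(5, 5, 5), L = 300)
      st <- refugia:::summary_stats_variants(sim$variants,
                                             attr(sim$variants, "pop"),
                                             c("P1", "P2", "P3"))
      dplyr::bind_cols(tibble::tibble(scenario = ((i - 1) %% 3) + 1,
                                      kind = "same"), st)
    })
    probs <- replicate(12, {
      sim_o <- simulate_scenario(scn, mu = 5e-7, n = c(5, 5, 5), L = 300)
      obs <- refugia:::summary_stats_variants(sim_o$variants,
                                              attr(sim_o$variants, "pop"),
                                              c("P1", "P2", "P3"))
      model_choice(obs, rows, n_closest = 120)$posterior$prob
    })
    expect_lt(max(abs(rowMeans(probs) - 1 / 3)), 0.25)
  })
})

test_that("parameter estimation collapses on a homogeneous table and falls back cleanly", {
  withr::with_seed(41, {
    ref <- build_reference_table(kinds = "sudden_trifurcation", n_sims = 60,
                                 sample_sizes = c(4, 4, 4), L = 200, seed = 3)
    obs <- ref[1, grep("^(nhap|S_|kbar|priv|W_|B_|FST)", names(ref))]
    # homogeneous parameters: posterior collapses to that value
    refh <- ref
    for (cc in c("Ne1", "Ne2", "Ne3", "Ne_anc", "t1", "mu")) refh[[cc]] <- 123
    est <- suppressWarnings(estimate_parameters(refh, obs, n_closest = 20))
    expect_equal(est$median[est$parameter == "t1"], 123, tolerance = 1e-6)
    expect_equal(est$lo[est$parameter == "t1"], 123, tolerance = 1e-6)
    # CIs contain the medians in the general case
    est2 <- estimate_parameters(ref, obs, n_closest = 20)
    expect_true(all(est2$lo <= est2$median & est2$median <= est2$hi))
    expect_equal(est2$median_years[est2$parameter == "t1"],
                 10 * est2$median[est2$parameter == "t1"])
  })
})

test_that("generation-time conversion", {
  expect_equal(to_years(0), 0)
  expect_equal(to_years(770), 7700)
  expect_equal(to_years(1200), 12000)
  expect_equal(to_years(100, g = 5), 500)
})
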