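test_that("mismatch histogram counts all pairs and conserves mass", {
  a2 <- mt_alignment(c(a = "ACGT", b = "ACGT"))
  h <- mismatch_histogram(a2)
  expect_equal(as.numeric(h$counts), 1)
  expect_equal(names(h$counts), "0")

  d <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3)
  h3 <- mismatch_histogram(d)
  expect_equal(unname(h3$counts), c(0, 2, 1))
  expect_equal(sum(h3$counts), choose(3, 2))

  withr::with_seed(4, {
    a <- random_toy_alignment(9, 30)
    hh <- mismatch_histogram(a)
    expect_equal(sum(hh$counts), choose(9, 2))
  })
  expect_error(mismatch_histogram(mt_alignment(c(a = "ACGT"))), "2")
})

test_that("expected_mismatch limits: equilibrium, tau = 0, normalization", {
  for (th in c(0.5, 2, 10)) {
    f <- expected_mismatch(5, th, th, 50)
    eq <- th^(0:50) / (1 + th)^(1:51)
    expect_lt(max(abs(f - eq)), 1e-10)
  }
  f0 <- expected_mismatch(0, 1.5, 80, 40)
  eq0 <- 1.5^(0:40) / 2.5^(1:41)
  expect_lt(max(abs(f0 - eq0)), 1e-12)
  expect_true(all(f0 >= 0))
  fr <- expected_mismatch(3, 0.5, 20, 200, renormalize = TRUE)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_lte(attr(expected_mismatch(3, 0.5, 20, 200), "mass"), 1 + 1e-9)
  expect_error(expected_mismatch(Inf, 1, 1, 10), "finite")
})

test_that("expected_mismatch agrees with Monte-Carlo coalescent pair draws", {
  # distribution of pairwise differences for n = 2 under (tau, th0, th1)
  withr::with_seed(21, {
    tau <- 5; th0 <- 1; th1 <- 100
    n_pairs <- 20000
    # independent simulation of the pair coalescence time: piecewise hazard
    t_recent <- stats::rexp(n_pairs, 1 / th1)
    t_c <- ifelse(t_recent < tau, t_recent, tau + stats::rexp(n_pairs, 1 / th0))
    diffs <- stats::rpois(n_pairs, t_c)
    emp <- tabulate(diffs + 1, nbins = 26) / n_pairs
    thr <- expected_mismatch(tau, th0, th1, 25)
    expect_lt(max(abs(emp - thr)), 4 / sqrt(n_pairs))
  })
})

test_that("raggedness follows the boundary-inclusive formula", {
  expect_equal(raggedness(rep(0.2, 5)), 0.08)
  # spike is maximal among same-support histograms
  spike <- c(0, 0, 1, 0, 0)
  expect_gte(raggedness(spike), raggedness(rep(0.2, 5)))
  expect_gte(raggedness(spike), raggedness(c(0.1, 0.2, 0.4, 0.2, 0.1)))
})

test_that("expansion fit: self-consistency, equilibrium and translation", {
  f <- expected_mismatch(4, 0.5, 50, 150)
  h <- structure(list(counts = as.numeric(f), n = 1000, n_pairs = 1,
                      modality = 1), class = "mismatch_hist")
  fit <- fit_sudden_expansion(h)
  expect_equal(fit$tau, 4, tolerance = 0.01)
  expect_equal(fit$theta0, 0.5, tolerance = 0.01)
  expect_equal(fit$theta1, 50, tolerance = 0.01)

  # equilibrium-generated histogram: fitted theta0 ~ theta1
  eq <- 3^(0:60) / 4^(1:61)
  heq <- structure(list(counts = eq, n = 1000, n_pairs = 1, modality = 1),
                   class = "mismatch_hist")
  feq <- fit_sudden_expansion(heq)
  expect_lt(abs(feq$theta0 - feq$theta1) / max(feq$theta1, 1), 0.25)

  # translation: shifting a tight histogram right increases tau-hat
  taus <- sapply(c(2, 5, 9), function(k) {
    counts <- rep(0, 20); counts[k + 1] <- 80; counts[k] <- 10; counts[k + 2] <- 10
    fit_sudden_expansion(structure(list(counts = counts, n = 30,
                                        n_pairs = 100, modality = 1),
                                   class = "mismatch_hist"))$tau
  })
  expect_true(all(diff(taus) > 0))

  # degenerate: all mass at zero
  fd <- fit_sudden_expansion(structure(list(counts = c(10), n = 5, n_pairs = 10,
                                            modality = 1), class = "mismatch_hist"))
  expect_true(fd$degenerate)
  expect_equal(fd$tau, 0)
})

test_that("Tajima's D equals an independent computation and handles edges", {
  expect_true(tajimas_d(0, 0, 10, n_reps = 0)$undefined)
  cons <- tajima_constants(10)
  expect_equal(tajimas_d(5, 5 / cons$a1, 10, n_reps = 0)$D, 0)
  d <- tajimas_d(16, 3.0, 20, n_reps = 0)$D
  expect_equal(d, oracle_tajimas_d(16, 3.0, 20), tolerance = 1e-10)
  p <- tajimas_d(8, 2.1, 12, n_reps = 400, seed = 5)
  expect_gte(p$p_D, 0)
  expect_lte(p$p_D, 1)
})

test_that("Fu's Fs tail probability matches the exact Ewens expansion", {
  for (n in c(5, 9, 12)) for (th in c(0.5, 1, 5)) {
    pmf <- oracle_ewens_pmf(n, th)
    for (k in seq_len(n)) {
      expect_equal(ewens_k_tail(n, th, k), sum(pmf[k:n]), tolerance = 1e-10)
    }
  }
  expect_true(fus_fs(10, 2.0, 1, n_reps = 0)$undefined)
  expect_true(fus_fs(10, 0, 3, n_reps = 0)$undefined)
})

test_that("star-like expansion fixture yields strongly negative Fs", {
  fx <- make_star_expansion(n = 50, L = 400, n_tip_haplotypes = 12, seed = 13)
  nt <- neutrality_tests(fx$alignment, n_reps = 0)
  expect_lt(nt$Fs, -5)
  expect_lt(nt$D, 0)
})

test_that("expansion goodness-of-fit returns calibrated-looking p values", {
  sim <- sim_sudden_expansion(0.5, 30, 4, n = 30, L = 500, seed = 31)
  h <- mismatch_histogram(sim$alignment)
  fit <- fit_sudden_expansion(h)
  gof <- expansion_gof(sim$alignment, fit, n_boot = 30, seed = 32)
  expect_gte(gof$p_ssd, 0); expect_lte(gof$p_ssd, 1)
  expect_gte(gof$p_rg, 0); expect_lte(gof$p_rg, 1)
  expect_gt(gof$p_ssd, 0.01)  # data generated under the fitted model class
  expect_warning(expansion_gof(sim$alignment, fit, n_boot = 5, seed = 1), "coarse")
})
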