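test_that("scenario construction validates its parameters", {
  expect_error(scenario("gradual_north_derived", c("A", "B", "C"),
                        Ne = c(100, 100, 100), Ne_anc = 100,
                        t1 = 500, t2 = 100), "t1 < t2")
  expect_error(scenario("sudden_trifurcation", c("A", "B", "C"),
                        Ne = c(100, 100, 100), Ne_anc = 100,
                        t1 = 500, t2 = 600), "single event")
  expect_error(scenario("constant", c("A", "B"), Ne = c(10, 10)), "one population")
  expect_silent(scenario("gradual_south_derived", c("A", "B", "C"),
                         Ne = c(10, 20, 30), Ne_anc = 40, t1 = 10, t2 = 20))
})

test_that("mu = 0 gives identical sequences; seeds give identical bytes", {
  scn <- scenario("sudden_trifurcation", c("A", "B", "C"),
                  Ne = c(200, 200, 200), Ne_anc = 500, t1 = 300)
  sim <- simulate_scenario(scn, mu = 0, n = c(3, 3, 3), L = 50, seed = 1)
  expect_equal(nrow(unique(unclass(sim$alignment))), 1)

  s1 <- simulate_scenario(scn, mu = 1e-5, n = c(4, 4, 4), L = 120, seed = 77)
  s2 <- simulate_scenario(scn, mu = 1e-5, n = c(4, 4, 4), L = 120, seed = 77)
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  s3 <- simulate_scenario(scn, mu = 1e-5, n = c(4, 4, 4), L = 120, seed = 78)
  expect_false(identical(unclass(s1$alignment), unclass(s3$alignment)))
})

test_that("pair coalescence matches E[diff] = 2 Ne mu L within Monte-Carlo error", {
  scn <- scenario("constant", "P", Ne = 800)
  withr::with_seed(100, {
    dd <- replicate(1500, {
      sim <- simulate_scenario(scn, mu = 1e-6, n = 2, L = 866)
      v <- sim$variants
      if (ncol(v) == 0) 0 else sum(v[1, ] != v[2, ])
    })
  })
  expected <- 2 * 800 * 1e-6 * 866
  expect_equal(mean(dd), expected, tolerance = 0.08)
})

test_that("segregating sites match Watterson's expectation", {
  scn <- scenario("constant", "P", Ne = 700)
  a1 <- sum(1 / (1:19))
  withr::with_seed(200, {
    SS <- replicate(1200, {
      v <- simulate_scenario(scn, mu = 1e-6, n = 20, L = 866)$variants
      if (ncol(v) == 0) 0 else
        sum(apply(v, 2, function(x) length(unique(x)) > 1))
    })
  })
  expect_equal(mean(SS), a1 * 2 * 700 * 1e-6 * 866, tolerance = 0.06)
})

test_that("sudden-expansion simulator hits its model's limits", {
  # tau = 0: equilibrium at theta0
  withr::with_seed(300, {
    kb0 <- replicate(400, {
      sim <- sim_sudden_expansion(2, 50, 0, n = 2, L = 866)
      d <- pairwise_diff_matrix(sim$alignment)
      d[1, 2]
    })
  })
  expect_equal(mean(kb0), 2, tolerance = 0.15)  # E[pair diff] = theta0
  # large tau: equilibrium at theta1
  withr::with_seed(301, {
    kb1 <- replicate(400, {
      sim <- sim_sudden_expansion(0.5, 3, 60, n = 2, L = 866)
      pairwise_diff_matrix(sim$alignment)[1, 2]
    })
  })
  expect_equal(mean(kb1), 3, tolerance = 0.15)
  # peak of the mismatch distribution sits near tau after an expansion
  withr::with_seed(302, {
    peaks <- replicate(30, {
      sim <- sim_sudden_expansion(0.5, 50, 4, n = 50, L = 866)
      h <- mismatch_histogram(sim$alignment)
      as.integer(names(which.max(h$counts)))
    })
  })
  expect_equal(stats::median(peaks), 4, tolerance = 0.45)
})

test_that("exchangeability: permuting labels within a population is neutral", {
  scn <- scenario("gradual_north_derived", c("A", "B", "C"),
                  Ne = c(300, 300, 300), Ne_anc = 600, t1 = 100, t2 = 900)
  sim <- simulate_scenario(scn, mu = 5e-6, n = c(6, 6, 6), L = 300, seed = 9)
  obs <- summary_statistics(sim$alignment, sim$samples,
                            group_order = c("A", "B", "C"))
  # permute sample rows within groups: statistics must be unchanged
  s2 <- dplyr::group_by(sim$samples, .data$group)
  s2 <- dplyr::ungroup(dplyr::slice_sample(s2, prop = 1))
  obs2 <- summary_statistics(sim$alignment, s2, group_order = c("A", "B", "C"))
  expect_equal(obs, obs2)
})

test_that("trifurcation with equal sizes degenerates to a gradual scenario with t1 = t2", {
  # with t1 -> t2 the gradual scenario's intermediate epoch vanishes; mean
  # summary statistics should agree within Monte-Carlo error
  withr::with_seed(55, {
    stat_mean <- function(scn) {
      v <- replicate(250, {
        sim <- simulate_scenario(scn, mu = 2e-6, n = c(5, 5, 5), L = 500)
        st <- summary_statistics(sim$variants)
        c(st$kbar_P1, st$kbar_P3, st$B_P1_P3)
      })
      rowMeans(v)
    }
    s3 <- scenario("sudden_trifurcation", c("P1", "P2", "P3"),
                   Ne = c(400, 400, 400), Ne_anc = 400, t1 = 1000)
    s1 <- scenario("gradual_north_derived", c("P1", "P2", "P3"),
                   Ne = c(400, 400, 400), Ne_anc = 400, t1 = 999.9, t2 = 1000)
    m3 <- stat_mean(s3)
    m1 <- stat_mean(s1)
    expect_equal(m3, m1, tolerance = 0.2)
  })
})
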