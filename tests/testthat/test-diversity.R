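test_that("closed-form diversity examples", {
  a_id <- mt_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(segregating_sites(a_id), 0)
  expect_equal(nucleotide_diversity(a_id), 0)

  a3 <- mt_alignment(c(a = "ACGT", b = "ACGA", c = "ACTA"))
  expect_equal(segregating_sites(a3), 2)

  a2 <- mt_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  expect_equal(nucleotide_diversity(a2), 0.1)

  expect_equal(haplotype_diversity(c(4)), 0)
  expect_equal(haplotype_diversity(rep(1, 6)), 1)
  expect_equal(haplotype_diversity(c(2, 2)), 2 / 3, tolerance = 1e-12)
  expect_error(haplotype_diversity(c(1)), "n >= 2")
  expect_error(segregating_sites(mt_alignment(c(a = "ACGT"))), "2")
})

test_that("private haplotype counting across a partition", {
  a <- mt_alignment(c(s1 = "AAAA", s2 = "AAAT", s3 = "AAAA", s4 = "AATT"))
  s <- tibble::tibble(sample_id = rownames(a), lineage = "x",
                      group = c("N", "N", "S", "S"), subgroup = ".")
  ht <- collapse_haplotypes(a, s)
  # AAAA shared by N and S; AAAT private to N; AATT private to S
  expect_equal(private_haplotypes(ht, "N"), 1)
  expect_equal(private_haplotypes(ht, "S"), 1)
  expect_error(private_haplotypes(ht, "X"), "Unknown group")
  # single-group partition: every haplotype private
  ht1 <- collapse_haplotypes(a)
  expect_equal(private_haplotypes(ht1, "all"), nrow(ht1))
})

test_that("diversity_profile matches the brute-force oracle on random toys", {
  withr::with_seed(2024, {
    for (rep in 1:8) {
      n <- sample(4:10, 1)
      a <- random_toy_alignment(n, 30, p_missing = 0.05)
      grp <- sample(c("N", "S"), n, replace = TRUE)
      if (length(unique(grp)) < 2 || min(table(grp)) < 2) next
      s <- tibble::tibble(sample_id = rownames(a), lineage = "x",
                          group = grp, subgroup = ".")
      prof <- diversity_profile(a, s)
      m <- unclass(a)
      want_all <- oracle_diversity(m, grp)
      for (g in unique(grp)) {
        row <- prof[prof$group == g, ]
        sub <- m[grp == g, , drop = FALSE]
        # oracle uses the global mask, as the profile does
        sites <- oracle_complete_sites(m)
        S <- sum(sapply(sites, function(sj) length(unique(sub[, sj])) > 1))
        d <- oracle_pairwise_diffs(sub, sites)
        ng <- nrow(sub)
        expect_equal(row$S, S)
        expect_equal(row$pi, sum(d[upper.tri(d)]) / choose(ng, 2) / length(sites))
        expect_equal(row$h_P, unname(want_all$h_P[g]))
      }
    }
  })
})

test_that("indices are invariant under relabelling and reordering", {
  withr::with_seed(11, {
    a <- random_toy_alignment(8, 25, p_missing = 0)
    perm <- sample(nrow(a))
    a2 <- mt_alignment(unclass(a)[perm, ], rownames(a)[perm])
    expect_equal(nucleotide_diversity(a), nucleotide_diversity(a2))
    expect_equal(segregating_sites(a), segregating_sites(a2))
    f <- c(3, 2, 2, 1)
    expect_equal(haplotype_diversity(f), haplotype_diversity(rev(f)))
  })
})

test_that("rarefaction at target_n = n reproduces the full-sample indices", {
  withr::with_seed(3, {
    a <- random_toy_alignment(8, 40, p_missing = 0)
  })
  s <- tibble::tibble(sample_id = rownames(a), lineage = "x",
                      group = rep(c("N", "S"), each = 4), subgroup = ".")
  prof <- diversity_profile(a, s)
  r <- rarefy(a, s, "N", target_n = 4, reps = 3, seed = 1)
  row <- prof[prof$group == "N", ]
  expect_equal(r$S, row$S)
  expect_equal(r$pi, row$pi)
  expect_equal(r$Hd, row$Hd)
  expect_equal(r$h, row$h)
})

test_that("rarefaction is seeded, reproducible, and cannot create haplotypes", {
  withr::with_seed(8, {
    a <- random_toy_alignment(10, 40, p_missing = 0)
  })
  s <- tibble::tibble(sample_id = rownames(a), lineage = "x",
                      group = "G", subgroup = ".")
  r1 <- rarefy(a, s, "G", target_n = 5, reps = 5, seed = 99)
  r2 <- rarefy(a, s, "G", target_n = 5, reps = 5, seed = 99)
  expect_identical(attr(r1, "reps"), attr(r2, "reps"))
  h_tot <- nrow(collapse_haplotypes(a, s))
  expect_lte(r1$h, h_tot)
  expect_error(rarefy(a, s, "G", target_n = 11), "exceeds")
})

test_that("mean rarefied S and h are nondecreasing in target_n (enumeration)", {
  a <- mt_alignment(c(a = "AAAA", b = "AAAT", c = "AATT", d = "ATTT",
                      e = "AAAA", f = "TTTT"))
  ids <- rownames(a)
  exact_mean <- function(k) {
    combs <- utils::combn(6, k)
    vals <- apply(combs, 2, function(ix) {
      sub <- unclass(a)[ix, , drop = FALSE]
      c(S = sum(apply(sub, 2, function(col) length(unique(col)) > 1)),
        h = length(unique(apply(sub, 1, paste, collapse = ""))))
    })
    rowMeans(vals)
  }
  means <- sapply(2:6, exact_mean)
  expect_true(all(diff(means["S", ]) >= 0))
  expect_true(all(diff(means["h", ]) >= 0))
})
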