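test_that("AMOVA reproduces the hand-computed worked example", {
  wx <- worked_example()
  am <- amova(wx$ht, wx$d, wx$grouping, n_perm = 0)
  expect_equal(am$sigma_a, 0.59375, tolerance = 1e-8)
  expect_equal(am$sigma_b, 0.1145833333, tolerance = 1e-8)
  expect_equal(am$sigma_c, 0.2916666667, tolerance = 1e-8)
  expect_equal(am$phi_st, 0.7083333333, tolerance = 1e-8)
  expect_equal(am$phi_sc, 0.2820512821, tolerance = 1e-8)
  expect_equal(am$phi_ct, 0.59375, tolerance = 1e-8)
  expect_equal(sum(am$percent), 100, tolerance = 1e-8)
})

test_that("limiting cases: no structure and complete fixation", {
  # identical composition in both populations
  counts0 <- cbind(P1 = c(20L, 20L), P2 = c(20L, 20L))
  rownames(counts0) <- c("H1", "H2")
  ht0 <- make_ht(c("AAAA", "AATT"), counts0)
  am0 <- amova(ht0, pairwise_differences(ht0), n_perm = 200, seed = 3)
  expect_lt(abs(am0$phi_st), 0.05)
  expect_gt(am0$p_phi_st, 0.05)
  # populations fixed for distinct haplotypes
  counts1 <- cbind(P1 = c(8L, 0L), P2 = c(0L, 8L))
  rownames(counts1) <- c("H1", "H2")
  ht1 <- make_ht(c("AAAA", "AATT"), counts1)
  am1 <- amova(ht1, pairwise_differences(ht1), n_perm = 0)
  expect_equal(am1$phi_st, 1)
})

test_that("the sums of squares partition the total exactly", {
  set.seed(53)
  for (rep in 1:5) {
    ht <- random_ht(K = 5, P = 4, L = 25)
    d <- pairwise_differences(ht)
    am <- amova(ht, d, c(P1 = "X", P2 = "X", P3 = "Y", P4 = "Y"), n_perm = 0)
    # conservation: SS(among groups) + SS(among pops) + SS(within) = SS(total)
    cc <- ht$counts
    keep <- colSums(cc) > 0
    cc <- cc[, keep, drop = FALSE]
    W <- t(cc) %*% d %*% cc
    N <- sum(cc)
    expect_equal(sum(am$SS), sum(W) / (2 * N), tolerance = 1e-8)
    expect_equal(sum(am$percent), 100, tolerance = 1e-8)
  }
})

test_that("permutation p-values are uniform under a random grouping", {
  set.seed(59)
  base <- random_ht(K = 4, P = 1, L = 20)
  p_st <- replicate(100, {
    # individuals assigned to populations completely at random: the
    # exchangeability null of the permutation scheme holds exactly
    hap <- sample(4, 24, replace = TRUE)
    pop <- sample(4, 24, replace = TRUE)
    counts <- as.matrix(table(factor(hap, 1:4), factor(pop, 1:4)))
    dimnames(counts) <- list(paste0("H", 1:4), paste0("P", 1:4))
    keep <- rowSums(counts) > 0
    ht <- haplotype_table(counts[keep, , drop = FALSE],
                          sequences = base$sequences[keep, , drop = FALSE])
    amova(ht, pairwise_differences(ht), grouping = NULL, n_perm = 99)$p_phi_st
  })
  expect_gt(suppressWarnings(stats::ks.test(p_st, "punif"))$p.value, 0.01)
})

test_that("AMOVA warns when a group holds a single population", {
  wx <- worked_example()
  expect_warning(amova(wx$ht, wx$d, c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G3"),
                       n_perm = 0), "single population")
})

test_that("AMOVA permutation tests are reproducible", {
  wx <- worked_example()
  a1 <- amova(wx$ht, wx$d, wx$grouping, n_perm = 100, seed = 7)
  a2 <- amova(wx$ht, wx$d, wx$grouping, n_perm = 100, seed = 7)
  expect_identical(a1$p_phi_st, a2$p_phi_st)
  expect_identical(a1$p_phi_ct, a2$p_phi_ct)
})

test_that("SAMOVA recovers a planted two-group partition", {
  px <- planted_clusters()
  res <- samova(px$ht, px$d, K = 2, n_starts = 4, steps = 300, seed = 61)
  same <- function(a, b) {
    length(unique(paste(a, b))) == length(unique(a))  # equal up to label swap
  }
  expect_true(same(res$partition, px$truth))
  # the found optimum matches direct AMOVA on the true partition
  am_true <- amova(px$ht, px$d, px$truth, n_perm = 0)
  expect_equal(res$phi_ct, am_true$phi_ct, tolerance = 1e-10)
})

test_that("SAMOVA never scores below a user-supplied start and is reproducible", {
  px <- planted_clusters()
  arbitrary <- c(P1 = 1L, P2 = 2L, P3 = 1L, P4 = 2L, P5 = 1L, P6 = 2L)
  am_arb <- amova(px$ht, px$d, arbitrary, n_perm = 0)
  res <- samova(px$ht, px$d, K = 2, n_starts = 2, steps = 150, seed = 67,
                init_partitions = list(arbitrary))
  expect_gte(res$phi_ct, am_arb$phi_ct)
  res2 <- samova(px$ht, px$d, K = 2, n_starts = 2, steps = 150, seed = 67,
                 init_partitions = list(arbitrary))
  expect_identical(res$partition, res2$partition)
  expect_error(samova(px$ht, px$d, K = 6), "K must satisfy")
})
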