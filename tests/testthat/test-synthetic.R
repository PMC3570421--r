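four_pops <- data.frame(
  population_id = c("p1", "p2", "p3", "p4"),
  lineage = c("A", "B", "C", "D"),
  n = c(4L, 4L, 4L, 4L))

test_that("zero mutation rate yields identical sequences", {
  spec <- fixture_spec(pops = four_pops, rate = 0, L = 200L, overall_Ne = 2000)
  m <- refugia_model("e", 2000, four_pops)
  tr <- simulate_gene_tree(m, seed = 3)
  a <- simulate_sequences(tr, spec, seed = 4)
  expect_equal(collapse_haplotypes(a)$K, 1L)
})

test_that("sequence simulation is reproducible and seed-sensitive", {
  spec <- fixture_spec(pops = four_pops, L = 300L, overall_Ne = 5000)
  m <- refugia_model("e", 5000, four_pops)
  tr <- simulate_gene_tree(m, seed = 11)
  a1 <- simulate_sequences(tr, spec, seed = 5)
  a2 <- simulate_sequences(tr, spec, seed = 5)
  a3 <- simulate_sequences(tr, spec, seed = 6)
  expect_identical(a1$seq, a2$seq)
  expect_false(identical(a1$seq, a3$seq))
})

test_that("divergence on a long branch matches the HKY expectation", {
  # two tips joined at depth T generations; expected identity computed with
  # an independent matrix exponential (ape::matexpo), not the package's
  # eigendecomposition
  spec <- fixture_spec(pops = four_pops, rate = 1.086, L = 20000L, g = 4,
                       overall_Ne = 1)
  Tgen <- 150000
  tr <- ape::read.tree(text = sprintf("(a|p1:%d,b|p2:%d);", Tgen, Tgen))
  a <- simulate_sequences(tr, spec, seed = 13)
  obs_div <- mean(a$seq[1, ] != a$seq[2, ])
  pi4 <- spec$base_freq
  Q <- matrix(0, 4, 4, dimnames = list(names(pi4), names(pi4)))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ti <- paste0(sort(c(names(pi4)[i], names(pi4)[j])), collapse = "") %in% c("AG", "CT")
    Q[i, j] <- (if (ti) spec$kappa else 1) * pi4[j]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-pi4 * diag(Q))
  P <- ape::matexpo(Q * 2 * Tgen * spec$rate * 1e-8 * spec$g)
  exp_div <- 1 - sum(pi4 * diag(P))
  se <- sqrt(exp_div * (1 - exp_div) / spec$L)
  expect_lt(abs(obs_div - exp_div), 4 * se)
})

test_that("the study fixture reproduces the survey's sampling structure", {
  fx <- generate_study_fixture(seed = 101)
  a <- fx$alignment
  expect_equal(length(a$ids), 146L)
  expect_equal(a$L, 2373L)
  expect_equal(length(unique(a$pops)), 19L)
  ht <- collapse_haplotypes(a)
  expect_lte(ht$K, ht$N)
  expect_gt(ht$K, 19L)
  # four reciprocally monophyletic lineages in the generating genealogy
  pops <- shanjing_populations()
  lin <- stats::setNames(pops$lineage, pops$population_id)
  tip_lin <- lin[tip_populations(fx$tree)]
  for (l in c("A", "B", "C", "D")) {
    expect_true(ape::is.monophyletic(fx$tree, fx$tree$tip.label[tip_lin == l]),
                info = l)
  }
  # no haplotype crosses a lineage boundary
  pop_lin <- lin[colnames(ht$counts)]
  shared_across <- apply(ht$counts > 0, 1, function(hit) {
    length(unique(pop_lin[hit])) > 1
  })
  expect_false(any(shared_across))
})

test_that("different seeds give different alignments with the same design", {
  f1 <- generate_study_fixture(seed = 7)
  f2 <- generate_study_fixture(seed = 8)
  expect_false(identical(f1$alignment$seq, f2$alignment$seq))
  expect_identical(dim(f1$alignment$seq), dim(f2$alignment$seq))
  f1b <- generate_study_fixture(seed = 7)
  expect_identical(f1$alignment$seq, f1b$alignment$seq)
})

test_that("between-lineage divergence ranks with split depth at small Ne", {
  # the split-time gaps (70/50 ky out of 830) are resolvable only when both
  # the ancestral coalescent noise (2 Ne mu) and the Poisson sequence noise
  # (sqrt of the expected differences) are small next to them: small Ne and
  # a long simulated sequence
  spec <- fixture_spec(pops = four_pops, L = 60000L, overall_Ne = 1500)
  ok <- 0
  for (s in 1:5) {
    fx <- generate_study_fixture(spec = spec, seed = 200 + s)
    ht <- collapse_haplotypes(fx$alignment)
    d <- pairwise_differences(ht)
    cc <- ht$counts
    lin <- stats::setNames(four_pops$lineage, four_pops$population_id)
    mean_div <- function(l1, l2) {
      h1 <- rowSums(cc[, lin[colnames(cc)] == l1, drop = FALSE]) > 0
      h2 <- rowSums(cc[, lin[colnames(cc)] == l2, drop = FALSE]) > 0
      mean(d[h1, h2])
    }
    a_rest <- mean(c(mean_div("A", "B"), mean_div("A", "C"), mean_div("A", "D")))
    d_bc <- mean(c(mean_div("D", "B"), mean_div("D", "C")))
    b_c <- mean_div("B", "C")
    if (a_rest > d_bc && d_bc > b_c) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("expansion data sets behave at their parameter limits", {
  a0 <- generate_expansion_dataset(theta0 = 2, tau_true = 0, n = 10, L = 500,
                                   seed = 5)
  expect_equal(length(a0$ids), 10L)
  a1 <- generate_expansion_dataset(theta0 = 1, tau_true = 6, n = 10, L = 500,
                                   seed = 5)
  a2 <- generate_expansion_dataset(theta0 = 1, tau_true = 6, n = 10, L = 500,
                                   seed = 5)
  expect_identical(a1$seq, a2$seq)
  expect_error(generate_expansion_dataset(-1, 1, 5), ">= 0")
})

test_that("fixtures written to disk read back identically", {
  spec <- fixture_spec(pops = four_pops, L = 120L, overall_Ne = 3000)
  fx <- generate_study_fixture(spec = spec, seed = 31)
  dir <- tempfile()
  paths <- write_fixture(fx, dir)
  back <- read_alignment(paths$fasta, paths$meta)
  expect_equal(back$L, 120L)
  expect_setequal(back$ids, fx$alignment$ids)
  expect_identical(back$seq[fx$alignment$ids, ], fx$alignment$seq)
  tr <- ape::read.tree(paths$tree)
  expect_equal(ape::Ntip(tr), 16L)
})
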