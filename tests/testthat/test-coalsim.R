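small_pops <- data.frame(
  population_id = c("p1", "p2", "p3", "p4"),
  lineage = c("A", "B", "C", "D"),
  n = c(3L, 3L, 3L, 3L))

test_that("calendar time converts to generations", {
  expect_equal(years_to_generations(18000, 4), 4500)
  expect_equal(years_to_generations(0), 0)
  expect_equal(years_to_generations(830000, 4), 207500)
  expect_error(years_to_generations(-1), "negative")
})

test_that("refugial models encode the hypothesised split times", {
  m_a <- refugia_model("a", 8000, small_pops)
  expect_equal(sort(unique(m_a$t_on)), c(0, 4500))
  expect_true(all(m_a$t_off[m_a$n_samples > 0] == 4500))

  m_e <- refugia_model("e", 8000, small_pops, apportion = "equal")
  # within-lineage splits at 250/290/70/530 ky, joins at 710/760/830 ky
  tip_on <- m_e$t_off[m_e$n_samples > 0]
  expect_setequal(tip_on / 250, c(250000, 70000, 290000, 530000) / 4 / 250)
  ref <- m_e[grepl("^ref", m_e$branch), ]
  expect_setequal(ref$t_off, c(830000, 710000, 710000, 760000) / 4)
  # equal apportionment splits overall Ne across the four refugia
  expect_equal(unname(ref$Ne), rep(2000, 4))
  expect_equal(sum(ref$Ne), 8000)
  # ancestral branches keep the overall size
  expect_equal(m_e$Ne[m_e$branch == "root"], 8000)
  expect_error(refugia_model("z", 8000, small_pops))
})

test_that("size apportionment weights refugia by their samples", {
  pops <- small_pops
  pops$n <- c(6L, 2L, 2L, 2L)
  m <- refugia_model("e", 12000, pops, apportion = "size")
  ref <- m[grepl("^ref", m$branch), ]
  expect_equal(sum(ref$Ne), 12000)
  expect_equal(ref$Ne[ref$branch == "refA"], 12000 * 6 / 12)
})

test_that("pairwise coalescence time averages Ne generations", {
  pops1 <- data.frame(population_id = "p1", lineage = "A", n = 2L)
  m <- refugia_model("a", 500, pops1)
  set.seed(99)
  tm <- replicate(3000, {
    tr <- simulate_gene_tree(m)
    max(ape::node.depth.edgelength(tr))
  })
  expect_lt(abs(mean(tm) / 500 - 1), 0.05)
})

test_that("gene trees respect the population tree's structure", {
  pops2 <- data.frame(population_id = c("p1", "p2"), lineage = c("A", "B"),
                      n = c(1L, 1L))
  m <- refugia_model("b", 300, pops2)
  set.seed(12)
  for (i in 1:40) {
    tr <- simulate_gene_tree(m)
    # two samples split 830 ky ago: TMRCA must predate the split
    expect_gte(max(ape::node.depth.edgelength(tr)), 830000 / 4)
  }
  # trees are ultrametric, binary, with generation-scaled branch lengths
  m_e <- refugia_model("e", 8000, small_pops)
  tr <- simulate_gene_tree(m_e, seed = 5)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  expect_equal(sort(unique(tip_populations(tr))), small_pops$population_id)
})

test_that("simulation is reproducible under a fixed seed", {
  m <- refugia_model("e", 8000, small_pops)
  t1 <- simulate_gene_tree(m, seed = 77)
  t2 <- simulate_gene_tree(m, seed = 77)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  s1 <- simulate_s_distribution(m, nreps = 100, seed = 13)
  s2 <- simulate_s_distribution(m, nreps = 100, seed = 13)
  expect_identical(s1$samples, s2$samples)
})

test_that("anciently isolated groups drive S to its topological minimum", {
  m <- refugia_model("e", 4000, small_pops)
  sd_ <- simulate_s_distribution(m, nreps = 150, seed = 21)
  # four groups isolated for >> Ne generations: S concentrates at k - 1 = 3
  expect_equal(stats::median(sd_$samples), 3)
  expect_gte(mean(sd_$samples == 3), 0.9)
  expect_equal(sd_$lo95, 3)
})

test_that("panmictic S distribution matches an independent simulator", {
  # same quantity through a fully independent tree generator (ape::rcoal)
  pops2 <- data.frame(population_id = c("g1", "g2"), lineage = c("A", "B"),
                      n = c(6L, 6L))
  m <- refugia_model("a", 1e8, pops2)  # split negligible relative to Ne: panmixia
  sd_ <- simulate_s_distribution(m, nreps = 400, seed = 3)
  set.seed(4)
  states <- rep(c("g1", "g2"), each = 6)
  s_ref <- replicate(400, {
    tr <- ape::rcoal(12)
    s_statistic(tr, stats::setNames(sample(states), tr$tip.label))
  })
  se <- sqrt(stats::var(sd_$samples) / 400 + stats::var(s_ref) / 400)
  expect_lt(abs(mean(sd_$samples) - mean(s_ref)), 3 * se)
})

test_that("within-population coalescence rates follow the n-coalescent", {
  # n = 3 in one population: E[T3] = Ne/3, E[TMRCA] = Ne(1/3 + 1)
  pops1 <- data.frame(population_id = "p1", lineage = "A", n = 3L)
  m <- refugia_model("a", 400, pops1)
  set.seed(55)
  tmrca <- replicate(3000, {
    max(ape::node.depth.edgelength(simulate_gene_tree(m)))
  })
  expect_lt(abs(mean(tmrca) / (400 * 4 / 3) - 1), 0.06)
})
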