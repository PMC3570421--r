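test_that("S statistic resolves textbook cases", {
  tr1 <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  st1 <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  expect_equal(s_statistic(tr1, st1), 1L)  # reciprocal monophyly
  tr2 <- ape::read.tree(text = "((A1:1,B1:1):1,(A2:1,B2:1):1);")
  st2 <- c(A1 = "A", B1 = "B", A2 = "A", B2 = "B")
  expect_equal(s_statistic(tr2, st2), 2L)  # full lineage mixing
  expect_error(s_statistic(tr1, c(A1 = "A", A2 = "A", B1 = "B")), "named|order")
  expect_error(s_statistic(tr1, c(A1 = "A", A2 = "A", B1 = "A", B2 = "A")),
               "two distinct states")
})

test_that("Fitch S equals the exhaustive minimum and phangorn's parsimony", {
  set.seed(29)
  for (i in 1:60) {
    rs <- random_state_tree(sample(4:8, 1), sample(2:3, 1))
    s <- s_statistic(rs$tree, rs$states)
    ex <- parsimony_exhaustive(rs$tree, rs$states)
    expect_identical(s, ex$S, info = paste("tree", i))
    pd <- phangorn::phyDat(matrix(rs$states[rs$tree$tip.label], ncol = 1,
                                  dimnames = list(rs$tree$tip.label, NULL)),
                           type = "USER", levels = unique(rs$states))
    expect_equal(s, as.integer(phangorn::parsimony(rs$tree, pd)),
                 info = paste("phangorn", i))
  }
})

test_that("S is bounded below by k - 1 with equality iff states form clades", {
  set.seed(31)
  for (i in 1:30) {
    rs <- random_state_tree(8, 3)
    k <- length(unique(rs$states))
    expect_gte(s_statistic(rs$tree, rs$states), k - 1L)
  }
  # constructed clade case: equality
  tr <- ape::read.tree(text = "(((a1,a2),(b1,b2)),((c1,c2),c3));")
  st <- c(a1 = "X", a2 = "X", b1 = "Y", b2 = "Y", c1 = "Z", c2 = "Z", c3 = "Z")
  expect_equal(s_statistic(tr, st), 2L)
})

test_that("S is invariant to child rotation and state relabelling", {
  set.seed(37)
  for (i in 1:10) {
    rs <- random_state_tree(7, 3)
    s0 <- s_statistic(rs$tree, rs$states)
    expect_equal(s_statistic(ape::rotateConstr(rs$tree, rev(rs$tree$tip.label)),
                             rs$states), s0)
    relab <- stats::setNames(c("Q", "R", "S")[match(rs$states, c("A", "B", "C"))],
                             names(rs$states))
    expect_equal(s_statistic(rs$tree, relab), s0)
  }
})

test_that("refugia_test applies the 95% interval decision rule", {
  fake <- structure(list(samples = c(rep(5L, 10), rep(10L, 380), rep(16L, 10)),
                         lo95 = 5, hi95 = 16, nreps = 400, seed = 1),
                    class = "s_distribution")
  expect_true(refugia_test(25, fake)$reject)
  expect_false(refugia_test(10, fake)$reject)
  expect_false(refugia_test(5, fake)$reject)
  cal_model <- refugia_model("a", 5000, data.frame(
    population_id = c("x", "y"), lineage = c("A", "B"), n = c(5L, 5L)))
  dist <- simulate_s_distribution(cal_model, nreps = 300, seed = 42)
  # drawing S from the simulating model itself rejects rarely
  set.seed(43)
  rej <- mean(replicate(120, {
    tr <- simulate_gene_tree(cal_model)
    refugia_test(s_statistic(tr, tip_populations(tr)), dist)$reject
  }))
  expect_lte(rej, 0.12)
})

test_that("root-state sets match exhaustive most-parsimonious reconstructions", {
  set.seed(41)
  for (i in 1:25) {
    rs <- random_state_tree(sample(4:8, 1), sample(2:3, 1))
    got <- rlr_root_probabilities(list(rs$tree), rs$states)
    ex <- parsimony_exhaustive(rs$tree, rs$states)
    expect_setequal(names(got$scores), ex$root_states)
    expect_equal(sum(got$scores), 1, tolerance = 1e-9)
  }
})

test_that("root-origin probabilities handle forced and trivial cases", {
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  one <- rlr_root_probabilities(list(tr), c(t1 = "X", t2 = "X", t3 = "X"))
  expect_equal(unname(one$scores), 1)
  two <- ape::read.tree(text = "(t1:1,t2:1);")
  tie <- rlr_root_probabilities(list(two), c(t1 = "X", t2 = "Y"))
  expect_equal(unname(tie$scores[c("X", "Y")]), c(0.5, 0.5))
  expect_error(rlr_root_probabilities(
    list(tr, ape::read.tree(text = "(u1:1,u2:1);")),
    c(t1 = "X", t2 = "X", t3 = "X", u1 = "X", u2 = "X")), "tip set")
})

test_that("a constructed refugial source population wins the root score", {
  m <- source_sink_model()
  set.seed(47)
  trees <- replicate(60, simulate_gene_tree(m), simplify = FALSE)
  states <- stats::setNames(tip_populations(trees[[1]]), trees[[1]]$tip.label)
  res <- rlr_root_probabilities(trees, states)
  expect_equal(sum(res$scores), 1, tolerance = 1e-9)
  expect_equal(names(res$scores)[1], "SRC")
  expect_gt(res$scores[["SRC"]], 0.5)
})

test_that("pruning to a group keeps only its tips", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  st <- c(a1 = "G1", a2 = "G1", b1 = "G2", b2 = "G2")
  pr <- prune_to_group(tr, st, "G1")
  expect_setequal(pr$tip.label, c("a1", "a2"))
  expect_error(prune_to_group(tr, st, "G3"), "fewer than two")
})
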