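#' Convert calendar time to coalescent generations
#'
#' @param t_years Time in years before present (>= 0).
#' @param g Generation time in years (default 4, a newt-like life history).
#' @return Time in generations.
#' @export
years_to_generations <- function(t_years, g = 4) {
  if (any(t_years < 0)) stopf("negative time")
  if (g <= 0) stopf("generation time must be positive")
  t_years / g
}

# Split-time templates (years BP) for the five refugial hypotheses:
# a  single refugium, populations diverging at the end of the LGM;
# b  two refugia (southern lineage vs the rest) separated 830 ky;
# c  three refugia (A, D, B+C) with the B/C stem joining D at 760 ky;
# d  four refugia persisting to the end of the LGM;
# e  four refugia with pre-LGM intra-lineage diversification
#    (within-lineage splits at the lineage TMRCAs 250/290/70/530 ky).
refugia_times <- list(
  a = list(tips = 18000),
  b = list(tips = 18000, root = 830000),
  c = list(tips = 18000, DvsBC = 760000, root = 830000),
  d = list(tips = 18000, BvsC = 710000, DvsBC = 760000, root = 830000),
  e = list(tipA = 250000, tipB = 70000, tipC = 290000, tipD = 530000,
           BvsC = 710000, DvsBC = 760000, root = 830000)
)

#' Build a refugial population-divergence model
#'
#' Encodes one of five competing hypotheses about Pleistocene refugia as a
#' population tree with split times, per-branch effective sizes and sample
#' sizes: (a) a single refugium with all populations diverging at the end
#' of the Last Glacial Maximum (18 ky BP); (b) two refugia (the southern
#' lineage versus the rest, isolated 830 ky BP); (c) three refugia; (d)
#' four refugia persisting to the end of the LGM; (e) four refugia with
#' pre-LGM within-lineage diversification (population splits at the lineage
#' TMRCAs 250/290/70/530 ky BP, refugial joins at 710/760/830 ky BP). The
#' lineage topology is (A, (D, (B, C))); within-lineage structure below the
#' refugial split is a star polytomy.
#'
#' The overall effective size is divided among the refugial branches either
#' proportionally to the number of sampled individuals descending from each
#' (`"size"`, the default, mirroring empirical theta contributions) or
#' equally (`"equal"`); tip-population branches subdivide their refugium's
#' share by the same rule. Ancestral (internal and root) branches keep the
#' overall size.
#'
#' @param hypothesis One of `"a" .. "e"`.
#' @param overall_Ne Overall (female) effective population size.
#' @param pops Data frame with columns `population_id`, `lineage` (labels
#'   `A`--`D`) and `n` (sample size per population).
#' @param apportion `"size"` or `"equal"`.
#' @param g Generation time in years.
#' @return Object of class `population_tree_model`: a data frame of
#'   branches (`branch`, `parent`, `t_on`, `t_off` in generations, `Ne`,
#'   `n_samples`) with attributes `label`, `g`, `overall_Ne`, `pops`.
#' @export
refugia_model <- function(hypothesis = c("e", "a", "b", "c", "d"),
                          overall_Ne, pops, apportion = c("size", "equal"),
                          g = 4) {
  hypothesis <- match.arg(hypothesis)
  apportion <- match.arg(apportion)
  if (overall_Ne <= 0) stopf("overall_Ne must be positive")
  stopifnot(all(c("population_id", "lineage", "n") %in% names(pops)))
  if (hypothesis != "a" && !all(pops$lineage %in% c("A", "B", "C", "D"))) {
    stopf("hypotheses b-e need every population assigned to lineage A-D")
  }
  tm <- refugia_times[[hypothesis]]
  gen <- function(y) years_to_generations(y, g)
  N <- sum(pops$n)
  share <- function(total, sizes) {
    if (apportion == "size") total * sizes / sum(sizes) else total / length(sizes)
  }
  rows <- list()
  add <- function(branch, parent, t_on, t_off, Ne, n_samples = 0L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      branch = branch, parent = parent, t_on = t_on, t_off = t_off,
      Ne = Ne, n_samples = n_samples, stringsAsFactors = FALSE)
  }
  lin_of <- split(pops, pops$lineage)
  add_tips <- function(parent, sub, t_off, Ne_parent) {
    Ne_tips <- share(Ne_parent, sub$n)
    for (i in seq_len(nrow(sub))) {
      add(sub$population_id[i], parent, 0, t_off, Ne_tips[i], sub$n[i])
    }
  }
  if (hypothesis == "a") {
    add("root", NA, gen(tm$tips), Inf, overall_Ne)
    add_tips("root", pops, gen(tm$tips), overall_Ne)
  } else if (hypothesis == "b") {
    subA <- pops[pops$lineage == "A", ]
    subR <- pops[pops$lineage != "A", ]
    Ne_ref <- if (apportion == "size") {
      overall_Ne * c(sum(subA$n), sum(subR$n)) / N
    } else rep(overall_Ne / 2, 2)
    add("root", NA, gen(tm$root), Inf, overall_Ne)
    add("refA", "root", gen(tm$tips), gen(tm$root), Ne_ref[1L])
    add("refBCD", "root", gen(tm$tips), gen(tm$root), Ne_ref[2L])
    add_tips("refA", subA, gen(tm$tips), Ne_ref[1L])
    add_tips("refBCD", subR, gen(tm$tips), Ne_ref[2L])
  } else if (hypothesis == "c") {
    subA <- pops[pops$lineage == "A", ]
    subD <- pops[pops$lineage == "D", ]
    subBC <- pops[pops$lineage %in% c("B", "C"), ]
    Ne_ref <- if (apportion == "size") {
      overall_Ne * c(sum(subA$n), sum(subD$n), sum(subBC$n)) / N
    } else rep(overall_Ne / 3, 3)
    add("root", NA, gen(tm$root), Inf, overall_Ne)
    add("refA", "root", gen(tm$tips), gen(tm$root), Ne_ref[1L])
    add("ancDBC", "root", gen(tm$DvsBC), gen(tm$root), overall_Ne)
    add("refD", "ancDBC", gen(tm$tips), gen(tm$DvsBC), Ne_ref[2L])
    add("refBC", "ancDBC", gen(tm$tips), gen(tm$DvsBC), Ne_ref[3L])
    add_tips("refA", subA, gen(tm$tips), Ne_ref[1L])
    add_tips("refD", subD, gen(tm$tips), Ne_ref[2L])
    add_tips("refBC", subBC, gen(tm$tips), Ne_ref[3L])
  } else {
    # d and e share the four-refugium topology (A,(D,(B,C))); they differ
    # in when the member populations split from their refugium.
    sizes <- vapply(c("A", "B", "C", "D"), function(l) sum(lin_of[[l]]$n), numeric(1L))
    Ne_ref <- if (apportion == "size") overall_Ne * sizes / N else rep(overall_Ne / 4, 4)
    names(Ne_ref) <- c("A", "B", "C", "D")
    tip_split <- if (hypothesis == "d") {
      c(A = tm$tips, B = tm$tips, C = tm$tips, D = tm$tips)
    } else {
      c(A = tm$tipA, B = tm$tipB, C = tm$tipC, D = tm$tipD)
    }
    join <- c(A = tm$root, B = tm$BvsC, C = tm$BvsC, D = tm$DvsBC)
    add("root", NA, gen(tm$root), Inf, overall_Ne)
    add("ancDBC", "root", gen(tm$DvsBC), gen(tm$root), overall_Ne)
    add("ancBC", "ancDBC", gen(tm$BvsC), gen(tm$DvsBC), overall_Ne)
    parent_of <- c(A = "root", B = "ancBC", C = "ancBC", D = "ancDBC")
    for (l in c("A", "B", "C", "D")) {
      add(paste0("ref", l), parent_of[[l]], gen(tip_split[[l]]), gen(join[[l]]),
          Ne_ref[[l]])
      add_tips(paste0("ref", l), lin_of[[l]], gen(tip_split[[l]]), Ne_ref[[l]])
    }
  }
  br <- do.call(rbind, rows)
  if (any(br$t_on >= br$t_off)) stopf("degenerate branch interval in model")
  if (any(br$Ne <= 0)) stopf("non-positive Ne on a branch")
  structure(br, class = c("population_tree_model", "data.frame"),
            label = hypothesis, g = g, overall_Ne = overall_Ne, pops = pops)
}

#' @export
print.population_tree_model <- function(x, ...) {
  cat(sprintf("refugial divergence model '%s': %d branches, %d sampled individuals, overall Ne = %.0f\n",
              attr(x, "label"), nrow(x), sum(x$n_samples), attr(x, "overall_Ne")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Simulate a gene genealogy within a population-divergence model
#'
#' Continuous-time n-coalescent within each branch of the population tree:
#' while `k` lineages are present in a branch of size `Ne`, the waiting time
#' to the next coalescence is exponential with rate `k(k-1)/2 / Ne` per
#' generation (haploid/mitochondrial scaling, so E[pairwise coalescence
#' time] = `Ne` generations). Lineages surviving at a split time move into
#' the parent branch; the root branch coalesces to a single ancestor.
#'
#' @param model A `population_tree_model`.
#' @param seed Optional integer seed.
#' @return A rooted, ultrametric, binary `phylo` (ape) with branch lengths
#'   in generations and tip labels `individual|population`.
#' @export
simulate_gene_tree <- function(model, seed = NULL) {
  with_seed(seed, sim_gene_tree_impl(model))
}

sim_gene_tree_impl <- function(model) {
  ord <- order(model$t_off)
  n <- sum(model$n_samples)
  if (n < 2) stopf("need at least two sampled individuals")
  tip_label <- character(n)
  waiting <- vector("list", nrow(model))  # lineages queued to enter a branch
  names(waiting) <- model$branch
  k0 <- 0L
  for (b in seq_len(nrow(model))) {
    ns <- model$n_samples[b]
    if (ns > 0L) {
      idx <- k0 + seq_len(ns)
      pop <- model$branch[b]
      tip_label[idx] <- paste0(pop, "-", seq_len(ns), "|", pop)
      waiting[[b]] <- c(waiting[[b]], idx)
      k0 <- k0 + ns
    }
  }
  m_time <- numeric(n - 1L)
  m_left <- integer(n - 1L)
  m_right <- integer(n - 1L)
  node_time <- numeric(2L * n - 1L)
  ev <- 0L
  for (b in ord) {
    lin <- waiting[[b]]
    k <- length(lin)
    t <- model$t_on[b]
    t_off <- model$t_off[b]
    Ne <- model$Ne[b]
    while (k > 1L) {
      t_next <- t + stats::rexp(1L, k * (k - 1) / 2 / Ne)
      if (t_next >= t_off) break
      t <- t_next
      pick <- sample.int(k, 2L)
      ev <- ev + 1L
      new_id <- n + ev
      m_time[ev] <- t
      m_left[ev] <- lin[pick[1L]]
      m_right[ev] <- lin[pick[2L]]
      node_time[new_id] <- t
      lin <- c(lin[-pick], new_id)
      k <- k - 1L
    }
    if (is.finite(t_off)) {
      p <- match(model$parent[b], model$branch)
      waiting[[p]] <- c(waiting[[p]], lin)
    } else if (k != 1L) {
      stopf("root branch failed to fully coalesce")  # unreachable: t_off = Inf
    }
  }
  # renumber events oldest-first so the root is node n + 1 (ape convention)
  rk <- rank(-m_time, ties.method = "first")
  node_num <- c(seq_len(n), n + rk)
  edge <- matrix(0L, 2L * n - 2L, 2L)
  edge_len <- numeric(2L * n - 2L)
  r <- 0L
  for (e in seq_len(n - 1L)) {
    for (ch in c(m_left[e], m_right[e])) {
      r <- r + 1L
      edge[r, ] <- c(node_num[n + e], node_num[ch])
      edge_len[r] <- m_time[e] - node_time[ch]
    }
  }
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = tip_label, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "postorder")
}

#' Null distribution of the minimum-sorting-events statistic S
#'
#' Simulates `nreps` gene genealogies under a population-divergence model,
#' computes the S statistic of the grouping character on each ([
#' s_statistic()]), and records the sample together with its central 95%
#' interval (equal-tailed empirical 2.5/97.5 percentiles, midpoint
#' interpolation at discontinuities).
#'
#' @param model A `population_tree_model`.
#' @param grouping Named vector mapping population id to group label;
#'   defaults to the lineage labels carried by the model.
#' @param nreps Number of genealogies (>= 100).
#' @param seed Optional integer seed.
#' @return Object of class `s_distribution` with elements `samples`,
#'   `lo95`, `hi95`, `nreps`, `seed`.
#' @export
simulate_s_distribution <- function(model, grouping = NULL, nreps = 1000L,
                                    seed = NULL) {
  if (nreps < 100L) stopf("use at least 100 replicates")
  if (is.null(grouping)) {
    pops <- attr(model, "pops")
    grouping <- stats::setNames(as.character(pops$lineage), pops$population_id)
  }
  with_seed(seed, {
    samples <- integer(nreps)
    for (r in seq_len(nreps)) {
      tr <- sim_gene_tree_impl(model)
      samples[r] <- s_statistic(tr, grouping[tip_populations(tr)])
    }
    qs <- stats::quantile(samples, c(0.025, 0.975), type = 2, names = FALSE)
    structure(list(samples = samples, lo95 = qs[1L], hi95 = qs[2L],
                   nreps = nreps, seed = seed),
              class = "s_distribution")
  })
}

#' @export
print.s_distribution <- function(x, ...) {
  cat(sprintf("S distribution: %d simulated genealogies, 95%% interval [%g, %g]\n",
              x$nreps, x$lo95, x$hi95))
  invisible(x)
}
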