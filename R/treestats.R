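#' Population labels carried by simulated tip names
#'
#' Tip labels written by [simulate_gene_tree()] (and expected of user
#' genealogies) have the form `individual|population`; this extracts the
#' population field, in tip order.
#'
#' @param tree A `phylo`.
#' @return Character vector of population ids, one per tip.
#' @export
tip_populations <- function(tree) {
  vapply(strsplit(tree$tip.label, "|", fixed = TRUE), function(x) {
    x[[min(2L, length(x))]]
  }, character(1L))
}

# Fitch bottom-up pass for an unordered multistate character on a rooted
# binary tree; state sets as bitmasks (<= 31 states). Returns the parsimony
# length and the root state set.
fitch_pass <- function(tree, states) {
  n <- length(tree$tip.label)
  states <- resolve_states(tree, states)
  lev <- unique(states)
  if (length(lev) > 31L) stopf("more than 31 states unsupported")
  tipbit <- bitwShiftL(1L, match(states, lev) - 1L)
  if (is.null(attr(tree, "order")) || attr(tree, "order") != "postorder") {
    tree <- ape::reorder.phylo(tree, "postorder")
  }
  if (max(tabulate(tree$edge[, 1L])) > 2L) {
    stopf("Fitch S statistic requires a binary (fully resolved) tree")
  }
  sets <- integer(n + tree$Nnode)
  sets[seq_len(n)] <- tipbit
  S <- 0L
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  for (e in seq_along(parent)) {
    p <- parent[e]
    cs <- sets[child[e]]
    if (sets[p] == 0L) {
      sets[p] <- cs
    } else {
      inter <- bitwAnd(sets[p], cs)
      if (inter != 0L) {
        sets[p] <- inter
      } else {
        sets[p] <- bitwOr(sets[p], cs)
        S <- S + 1L
      }
    }
  }
  root <- n + 1L
  root_states <- lev[bitwAnd(bitwShiftR(sets[root], seq_along(lev) - 1L), 1L) == 1L]
  list(S = S, root_states = root_states)
}

resolve_states <- function(tree, states) {
  n <- length(tree$tip.label)
  if (!is.null(names(states)) && all(tree$tip.label %in% names(states))) {
    states <- states[tree$tip.label]
  } else if (length(states) != n) {
    stopf("states must be named by tip label or given in tip order")
  }
  states <- as.character(states)
  if (anyNA(states)) stopf("unlabelled tip(s) in state map")
  states
}

#' Minimum number of sorting events (S) on a genealogy
#'
#' Slatkin & Maddison's S: the Fitch parsimony length of the unordered
#' multistate group character (population, lineage, ...) on a rooted binary
#' gene tree — the minimum number of sorting events needed to explain the
#' observed subdivision. Equals `k - 1` for `k` reciprocally monophyletic
#' groups and grows with incomplete lineage sorting.
#'
#' @param tree A rooted binary `phylo`, or a path to a newick file.
#' @param states Character vector of group states, named by tip label or in
#'   tip order (see [tip_populations()] to derive populations from labels).
#' @return Integer S.
#' @export
s_statistic <- function(tree, states) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (length(unique(resolve_states(tree, states))) < 2L) {
    stopf("S needs at least two distinct states")
  }
  fitch_pass(tree, states)$S
}

#' Compare an observed S value against a simulated null distribution
#'
#' Rejects a refugial hypothesis when the observed S falls outside the
#' central 95% interval of the S values simulated under it.
#'
#' @param S_obs Observed S (integer).
#' @param dist An `s_distribution` from [simulate_s_distribution()].
#' @return List with `S_obs`, `lo95`, `hi95`, `reject` (logical) and
#'   `tail_prop`, the proportion of simulated values at least as extreme as
#'   `S_obs` in its tail direction.
#' @export
refugia_test <- function(S_obs, dist) {
  stopifnot(inherits(dist, "s_distribution"))
  reject <- S_obs < dist$lo95 || S_obs > dist$hi95
  tail_prop <- min(mean(dist$samples <= S_obs), mean(dist$samples >= S_obs))
  list(S_obs = S_obs, lo95 = dist$lo95, hi95 = dist$hi95,
       reject = reject, tail_prop = tail_prop)
}

#' Root-origin (refugia localization) probabilities over a genealogy sample
#'
#' For each genealogy, reconstructs the set of most-parsimonious root states
#' of the unordered locality character (the Fitch root state set); a unique
#' root locality scores 1, and `n` equally parsimonious localities score
#' `1/n` each. Scores are summed over genealogies and divided by the number
#' of genealogies, giving each locality's relative probability of having
#' harboured the clade's most recent common ancestor.
#'
#' @param genealogies List of rooted binary `phylo` trees (or a `multiPhylo`)
#'   sharing one tip set.
#' @param states Locality of each tip: named vector (by tip label) or a
#'   vector in tip order valid for every tree.
#' @return Object of class `rlr_result`: list with `scores` (named numeric,
#'   summing to 1) and `n_genealogies`.
#' @export
rlr_root_probabilities <- function(genealogies, states) {
  if (inherits(genealogies, "phylo")) genealogies <- list(genealogies)
  genealogies <- unclass(genealogies)
  if (length(genealogies) == 0L) stopf("no genealogies supplied")
  tips <- sort(genealogies[[1L]]$tip.label)
  score <- numeric(0)
  for (tr in genealogies) {
    if (!identical(sort(tr$tip.label), tips)) {
      stopf("genealogies must share a single tip set")
    }
    rs <- fitch_pass(tr, states)$root_states
    add <- stats::setNames(rep(1 / length(rs), length(rs)), rs)
    for (s in names(add)) score[s] <- (if (s %in% names(score)) score[s] else 0) + add[[s]]
  }
  score <- score / length(genealogies)
  structure(list(scores = sort(score, decreasing = TRUE),
                 n_genealogies = length(genealogies)),
            class = "rlr_result")
}

#' @export
print.rlr_result <- function(x, ...) {
  cat(sprintf("root-origin probabilities over %d genealogies:\n", x$n_genealogies))
  print(round(x$scores, 4))
  invisible(x)
}

#' Prune a genealogy to the tips of one group
#'
#' Convenience for clade-level refugia localization: drop all tips whose
#' state is not `group`, keeping branch lengths.
#'
#' @param tree A `phylo`.
#' @param states Tip states (named by tip label or in tip order).
#' @param group State label to keep.
#' @return The pruned `phylo`.
#' @export
prune_to_group <- function(tree, states, group) {
  states <- resolve_states(tree, states)
  keep <- tree$tip.label[states == group]
  if (length(keep) < 2L) stopf("fewer than two tips in group '%s'", group)
  ape::keep.tip(tree, keep)
}
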