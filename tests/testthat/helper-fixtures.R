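# Shared fixtures and independent oracles, built in code at test time.

# Write a small aligned FASTA + metadata pair; returns the two paths.
write_tiny_fixture <- function(seqs, pops, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fasta <- file.path(dir, "aln.fasta")
  meta <- file.path(dir, "meta.tsv")
  ids <- names(seqs)
  writeLines(as.vector(rbind(paste0(">", ids), unlist(seqs))), fasta)
  utils::write.table(
    data.frame(individual_id = ids, population_id = pops),
    meta, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, meta = meta)
}

# Haplotype table straight from explicit sequences and counts.
make_ht <- function(seq_strings, counts) {
  seqs <- do.call(rbind, strsplit(seq_strings, ""))
  rownames(seqs) <- rownames(counts) <- paste0("H", seq_along(seq_strings))
  haplotype_table(counts, sequences = seqs)
}

# Random haplotype table: K random sequences of length L, counts over P pops.
random_ht <- function(K, P, L, nmax = 6L) {
  seqs <- matrix(sample(c("A", "C", "G", "T"), K * L, replace = TRUE), K, L)
  while (anyDuplicated(apply(seqs, 1L, paste, collapse = ""))) {
    seqs <- matrix(sample(c("A", "C", "G", "T"), K * L, replace = TRUE), K, L)
  }
  rownames(seqs) <- paste0("H", seq_len(K))
  counts <- matrix(sample(0:nmax, K * P, replace = TRUE), K,
                   dimnames = list(rownames(seqs), paste0("P", seq_len(P))))
  counts[rowSums(counts) == 0L, sample(P, 1L)] <- 1L
  haplotype_table(counts, sequences = seqs)
}

# Exhaustive parsimony oracle: minimum changes over all internal-node state
# assignments of a rooted binary tree (<= ~8 tips). Also returns the set of
# root states attaining the minimum.
parsimony_exhaustive <- function(tree, states) {
  n <- length(tree$tip.label)
  states <- as.character(states[tree$tip.label])
  lev <- unique(states)
  k <- length(lev)
  tip_state <- match(states, lev)
  m <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  changes <- integer(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L] - n
    ch <- tree$edge[e, 2L]
    child_states <- if (ch <= n) rep(tip_state[ch], nrow(grid)) else grid[, ch - n]
    changes <- changes + (grid[, p] != child_states)
  }
  best <- min(changes)
  root_states <- lev[sort(unique(grid[changes == best, 1L]))]
  list(S = best, root_states = root_states)
}

# Random rooted binary tree with tips labelled by random states.
random_state_tree <- function(ntips, nstates) {
  tr <- ape::rtree(ntips)
  repeat {
    st <- sample(LETTERS[seq_len(nstates)], ntips, replace = TRUE)
    if (length(unique(st)) >= 2L) break
  }
  names(st) <- tr$tip.label
  list(tree = tr, states = st)
}

# Hand-built population-tree model: one long-lived high-Ne source population
# and satellite populations that join it at `t_join` generations, each with
# small Ne so their lineages coalesce locally. Used for root-origin recovery.
source_sink_model <- function(n_src = 10L, n_sat = 5L, sat_pops = 2L,
                              Ne_src = 50000, Ne_sat = 200, t_join = 5000) {
  rows <- data.frame(
    branch = c("root", "SRC", paste0("SAT", seq_len(sat_pops))),
    parent = c(NA, "root", rep("root", sat_pops)),
    t_on = c(t_join, 0, rep(0, sat_pops)),
    t_off = c(Inf, t_join, rep(t_join, sat_pops)),
    Ne = c(Ne_src, Ne_src, rep(Ne_sat, sat_pops)),
    n_samples = c(0L, n_src, rep(n_sat, sat_pops)),
    stringsAsFactors = FALSE)
  pops <- data.frame(population_id = rows$branch[-1L],
                     lineage = "A", n = rows$n_samples[-1L])
  structure(rows, class = c("population_tree_model", "data.frame"),
            label = "custom", g = 4, overall_Ne = Ne_src, pops = pops)
}

shanjing_lineage_map <- function() {
  pops <- shanjing_populations()
  stats::setNames(pops$lineage, pops$population_id)
}

# Worked 4-population, 2-group AMOVA example with haplotypes A=AAAA, B=AAAT,
# C=ATTT (d(A,B)=1, d(A,C)=3, d(B,C)=2); variance components computed from
# first principles (individual-level sums of squares and the unbalanced
# moment equations) by an independent oracle before the build.
worked_example <- function() {
  counts <- cbind(P1 = c(3L, 1L, 0L), P2 = c(1L, 3L, 0L),
                  P3 = c(0L, 0L, 4L), P4 = c(0L, 2L, 2L))
  rownames(counts) <- c("H1", "H2", "H3")
  ht <- make_ht(c("AAAA", "AAAT", "ATTT"), counts)
  list(ht = ht, d = pairwise_differences(ht),
       grouping = c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2"))
}

# Two clearly differentiated clusters of populations for SAMOVA recovery.
planted_clusters <- function() {
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAT", "TTTTTTTTTA", "TTTTTTTTTT")
  counts <- cbind(
    P1 = c(5L, 1L, 0L, 0L), P2 = c(4L, 2L, 0L, 0L), P3 = c(5L, 1L, 0L, 0L),
    P4 = c(0L, 0L, 5L, 1L), P5 = c(0L, 0L, 4L, 2L), P6 = c(0L, 0L, 5L, 1L))
  rownames(counts) <- paste0("H", 1:4)
  ht <- make_ht(seqs, counts)
  list(ht = ht, d = pairwise_differences(ht),
       truth = c(P1 = 1L, P2 = 1L, P3 = 1L, P4 = 2L, P5 = 2L, P6 = 2L))
}
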