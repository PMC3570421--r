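#' Sampling design of the range-wide T. shanjing mtDNA survey
#'
#' The published sampling table of the red knobby newt survey that this
#' package's synthetic generator emulates: 19 populations in 4 mitochondrial
#' lineages, 146 individuals, with the printed per-population haplotype
#' counts (58 haplotypes overall). Shipped as a plain-text table in
#' `inst/extdata/shanjing_haplotypes.tsv`.
#'
#' @return Data frame with columns `lineage`, `population_id`, `n` and
#'   `haplotypes` (a `H<id>:<count>` list, `;`-separated).
#' @export
shanjing_populations <- function() {
  path <- system.file("extdata", "shanjing_haplotypes.tsv", package = "refugia")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Haplotype count matrix of the T. shanjing survey
#'
#' Expands [shanjing_populations()] into a `haplotype_table` (counts only,
#' no sequences): 58 haplotypes x 19 populations, column sums matching the
#' published sample sizes.
#'
#' @return A `haplotype_table` without sequences.
#' @export
shanjing_haplotype_table <- function() {
  pops <- shanjing_populations()
  parsed <- lapply(strsplit(pops$haplotypes, ";", fixed = TRUE), function(x) {
    kv <- strsplit(x, ":", fixed = TRUE)
    stats::setNames(vapply(kv, function(e) as.integer(e[2L]), integer(1L)),
                    vapply(kv, `[[`, character(1L), 1L))
  })
  haps <- unique(unlist(lapply(parsed, names)))
  haps <- haps[order(as.integer(sub("^H", "", haps)))]
  counts <- matrix(0L, length(haps), nrow(pops),
                   dimnames = list(haps, pops$population_id))
  for (p in seq_len(nrow(pops))) counts[names(parsed[[p]]), p] <- parsed[[p]]
  haplotype_table(counts, lineages = pops$lineage)
}

#' Specification for the synthetic study fixture
#'
#' Bundles the conditions the generator emulates: the sampling design of
#' the survey (19 populations, 146 individuals), the four-refugia pre-LGM
#' divergence model, an HKY substitution model (kappa = 4, base frequencies
#' 0.30/0.25/0.15/0.30 A/C/G/T), the estimated mean substitution rate
#' 1.086% per site per My, 2373 aligned sites and a 4-year generation time.
#' The default overall effective size is the Watterson estimate implied by
#' the survey's 144 segregating sites in 146 sequences, converted through
#' theta = 2 Ne mu.
#'
#' @param pops Sampling design (`population_id`, `lineage`, `n`).
#' @param hypothesis Refugial model label (default `"e"`).
#' @param rate Substitution rate, percent per site per My.
#' @param L Alignment length (sites).
#' @param g Generation time (years).
#' @param kappa HKY transition/transversion rate ratio.
#' @param base_freq Stationary base frequencies (A, C, G, T).
#' @param overall_Ne Overall effective size; default derived from S = 144,
#'   n = 146.
#' @param apportion Ne apportionment rule (see [refugia_model()]).
#' @param max_retries Bound on monophyly rejection sampling.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(pops = shanjing_populations(), hypothesis = "e",
                         rate = 1.086, L = 2373L, g = 4,
                         kappa = 4, base_freq = c(A = 0.30, C = 0.25, G = 0.15, T = 0.30),
                         overall_Ne = NULL, apportion = "size",
                         max_retries = 1000L) {
  if (rate < 0 || L <= 0 || g <= 0) stopf("invalid rate, L or g")
  if (rate == 0 && is.null(overall_Ne)) {
    stopf("overall_Ne must be given explicitly when rate = 0")
  }
  if (abs(sum(base_freq) - 1) > 1e-8) stopf("base frequencies must sum to 1")
  overall_Ne <- overall_Ne %||% effective_size(watterson_theta(144L, 146L), rate, L, g)
  structure(list(pops = pops, hypothesis = hypothesis, rate = rate, L = as.integer(L),
                 g = g, kappa = kappa, base_freq = base_freq,
                 overall_Ne = overall_Ne, apportion = apportion,
                 max_retries = as.integer(max_retries)),
            class = "fixture_spec")
}

# HKY85 rate matrix scaled to one expected substitution per site per unit
# branch length, and its eigendecomposition for transition probabilities.
hky_eigen <- function(kappa, base_freq) {
  pi4 <- base_freq / sum(base_freq)
  Q <- matrix(0, 4, 4, dimnames = list(names(pi4), names(pi4)))
  transitions <- list(c("A", "G"), c("C", "T"))
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      ti <- any(vapply(transitions, function(p) all(c(i, j) %in% match(p, names(pi4))),
                       logical(1L)))
      Q[i, j] <- (if (ti) kappa else 1) * pi4[j]
    }
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-pi4 * diag(Q))
  eig <- eigen(Q)
  list(values = eig$values, vectors = eig$vectors, inv = solve(eig$vectors),
       pi = pi4)
}

hky_pmatrix <- function(eig, t) {
  P <- Re(eig$vectors %*% diag(exp(eig$values * t)) %*% eig$inv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate sequences along a gene tree under HKY
#'
#' Draws a root sequence from the stationary base frequencies and applies
#' HKY substitutions along every branch, with expected substitutions per
#' site equal to `rate/100 * 1e-6 * branch_generations * g`.
#'
#' @param tree A `phylo` with branch lengths in generations and tip labels
#'   `individual|population`.
#' @param spec A [fixture_spec()] providing `rate`, `L`, `g`, `kappa` and
#'   `base_freq`.
#' @param meta Optional metadata frame; defaults to the populations parsed
#'   from the tip labels.
#' @param seed Optional integer seed.
#' @return A `hap_alignment`.
#' @export
simulate_sequences <- function(tree, spec, meta = NULL, seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(seed, {
    eig <- hky_eigen(spec$kappa, spec$base_freq)
    n <- length(tree$tip.label)
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
    states <- matrix(0L, n + tr$Nnode, spec$L)
    root <- n + 1L
    states[root, ] <- sample.int(4L, spec$L, replace = TRUE, prob = eig$pi)
    scale <- spec$rate * 1e-2 * 1e-6 * spec$g  # subs/site per generation
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]
      ch <- tr$edge[e, 2L]
      P <- hky_pmatrix(eig, tr$edge.length[e] * scale)
      par_state <- states[p, ]
      out <- integer(spec$L)
      for (s in 1:4) {
        idx <- which(par_state == s)
        if (length(idx) > 0L) {
          out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
        }
      }
      states[ch, ] <- out
    }
    bases <- c("A", "C", "G", "T")
    mat <- matrix(bases[states[seq_len(n), , drop = FALSE]], nrow = n)
    lab <- strsplit(tr$tip.label, "|", fixed = TRUE)
    ids <- vapply(lab, `[[`, character(1L), 1L)
    pops <- vapply(lab, function(x) x[[min(2L, length(x))]], character(1L))
    if (is.null(meta)) {
      meta <- data.frame(individual_id = ids, population_id = pops,
                         stringsAsFactors = FALSE)
    }
    new_alignment(ids, meta, mat)
  })
}

#' Generate a complete synthetic study data set
#'
#' Simulates one gene genealogy under the configured refugial model,
#' evolves sequences along it under HKY, and accepts the draw only if the
#' four lineages are reciprocally monophyletic in the genealogy (bounded
#' rejection sampling), mirroring the reciprocal monophyly of the empirical
#' lineages. The realized haplotype and segregating-site numbers vary
#' around the survey's; only the sampling structure is fixed.
#'
#' @param spec A [fixture_spec()].
#' @param seed Optional integer seed.
#' @return List with `alignment` (a `hap_alignment`), `tree` (the true
#'   genealogy), `model` (the `population_tree_model`), `spec`, and
#'   `tries` (accepted on which draw).
#' @export
generate_study_fixture <- function(spec = fixture_spec(), seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  model <- refugia_model(spec$hypothesis, spec$overall_Ne, spec$pops,
                         apportion = spec$apportion, g = spec$g)
  with_seed(seed, {
    for (try in seq_len(spec$max_retries)) {
      tree <- sim_gene_tree_impl(model)
      if (lineages_monophyletic(tree, spec$pops)) {
        meta <- data.frame(
          individual_id = vapply(strsplit(tree$tip.label, "|", fixed = TRUE),
                                 `[[`, character(1L), 1L),
          population_id = tip_populations(tree),
          stringsAsFactors = FALSE)
        meta$lineage <- spec$pops$lineage[match(meta$population_id,
                                                spec$pops$population_id)]
        aln <- simulate_sequences(tree, spec, meta = meta)
        return(list(alignment = aln, tree = tree, model = model, spec = spec,
                    tries = try))
      }
    }
    stopf(paste("no monophyletic draw in %d tries;",
                "consider a larger Ne separation between refugia"),
          spec$max_retries)
  })
}

lineages_monophyletic <- function(tree, pops) {
  tip_lin <- pops$lineage[match(tip_populations(tree), pops$population_id)]
  all(vapply(unique(tip_lin), function(l) {
    tips <- tree$tip.label[tip_lin == l]
    length(tips) < 2L || ape::is.monophyletic(tree, tips)
  }, logical(1L)))
}

# Kingman genealogy under sudden expansion in mutational time units
# (tau = 2 u t): no coalescence more recently than tau, constant theta0
# beyond. Branch lengths in mutational units.
expansion_genealogy <- function(n, tau, theta0) {
  birth <- c(rep(0, n), numeric(n - 1L))
  active <- seq_len(n)
  m_time <- numeric(n - 1L)
  m_left <- integer(n - 1L)
  m_right <- integer(n - 1L)
  t <- tau
  for (ev in seq_len(n - 1L)) {
    k <- n - ev + 1L
    if (theta0 > 0) t <- t + stats::rexp(1L, k * (k - 1) / 2 / theta0)
    pick <- sample.int(k, 2L)
    m_time[ev] <- t
    m_left[ev] <- active[pick[1L]]
    m_right[ev] <- active[pick[2L]]
    birth[n + ev] <- t
    active <- c(active[-pick], n + ev)
  }
  rk <- rank(-m_time, ties.method = "first")
  node_num <- c(seq_len(n), n + rk)
  edge <- matrix(0L, 2L * n - 2L, 2L)
  len <- numeric(2L * n - 2L)
  r <- 0L
  for (ev in seq_len(n - 1L)) {
    for (ch in c(m_left[ev], m_right[ev])) {
      r <- r + 1L
      edge[r, ] <- c(node_num[n + ev], node_num[ch])
      len[r] <- m_time[ev] - birth[ch]
    }
  }
  structure(list(edge = edge, edge.length = len,
                 tip.label = paste0("ind", seq_len(n), "|P1"), Nnode = n - 1L),
            class = "phylo")
}

#' Simulate an alignment under a sudden demographic expansion
#'
#' Coalescent sample of size `n` from a population that grew instantaneously
#' at mutational time `tau_true` (\eqn{\tau = 2ut}), with pre-expansion
#' theta `theta0` and mutations dropped at per-sequence rate 1/2 per
#' mutational unit onto uniformly chosen sites. Designed for calibrating
#' the mismatch and neutrality machinery against known truth.
#'
#' @param theta0 Pre-expansion theta per sequence (>= 0).
#' @param tau_true True expansion parameter (>= 0); 0 gives a constant-size
#'   population of theta `theta0`.
#' @param n Sample size.
#' @param L Alignment length (sites).
#' @param seed Optional integer seed.
#' @return A `hap_alignment` (single population `P1`).
#' @export
generate_expansion_dataset <- function(theta0, tau_true, n, L = 2373L,
                                       seed = NULL) {
  if (tau_true < 0 || theta0 < 0) stopf("tau_true and theta0 must be >= 0")
  with_seed(seed, {
    tr <- expansion_genealogy(n, tau_true, theta0)
    tr <- ape::reorder.phylo(tr, "cladewise")
    bases <- c("A", "C", "G", "T")
    states <- matrix(0L, n + tr$Nnode, L)
    states[n + 1L, ] <- sample.int(4L, L, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]
      ch <- tr$edge[e, 2L]
      s <- states[p, ]
      m <- stats::rpois(1L, tr$edge.length[e] / 2)
      if (m > 0L) {
        sites <- sample.int(L, min(m, L), replace = FALSE)
        s[sites] <- vapply(s[sites], function(b) sample(setdiff(1:4, b), 1L),
                           integer(1L))
      }
      states[ch, ] <- s
    }
    ids <- vapply(strsplit(tr$tip.label, "|", fixed = TRUE), `[[`,
                  character(1L), 1L)
    meta <- data.frame(individual_id = ids, population_id = "P1",
                       stringsAsFactors = FALSE)
    new_alignment(ids, meta, matrix(bases[states[seq_len(n), , drop = FALSE]],
                                    nrow = n))
  })
}

#' Write a synthetic fixture to disk
#'
#' Writes the alignment as FASTA, the metadata as a tab-separated table,
#' the true genealogy as newick and the generating parameters as JSON, so a
#' fixture can be consumed through the file-based interface.
#'
#' @param fix Result of [generate_study_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "alignment.fasta"),
                meta = file.path(dir, "metadata.tsv"),
                tree = file.path(dir, "genealogy.nwk"),
                params = file.path(dir, "params.json"))
  aln <- fix$alignment
  dna <- ape::as.DNAbin(aln$seq)
  rownames(dna) <- aln$ids
  ape::write.FASTA(dna, paths$fasta)
  utils::write.table(aln$meta, paths$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ape::write.tree(fix$tree, paths$tree)
  sp <- fix$spec
  jsonlite::write_json(list(hypothesis = sp$hypothesis, rate = sp$rate,
                            L = sp$L, g = sp$g, kappa = sp$kappa,
                            base_freq = as.list(sp$base_freq),
                            overall_Ne = sp$overall_Ne, tries = fix$tries),
                       paths$params, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
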