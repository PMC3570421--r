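#' Gene (haplotype) diversity with Nei's sampling standard error
#'
#' Unbiased gene diversity \eqn{h = \frac{n}{n-1}(1 - \sum p_i^2)} and the
#' square root of Nei's (1987) sampling variance
#' \deqn{V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   (\sum p_i^2)^2\right] + \sum p_i^2 - (\sum p_i^2)^2\right\}.}
#'
#' @param counts Vector of per-haplotype counts (all >= 1) for one scope
#'   (population, lineage, or the pooled sample).
#' @return List with `h` and `se_h`.
#' @examples
#' haplotype_diversity(c(2, 2, 5, 1))  # h = 0.7333, se = 0.1199
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts[counts > 0])
  n <- sum(counts)
  if (n < 2) stopf("gene diversity undefined for n < 2 (got n = %g)", n)
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, se_h = sqrt(max(V, 0)))
}

#' Nucleotide diversity (per site)
#'
#' Mean per-site pairwise difference between sequences drawn from the scope:
#' \eqn{\pi = \frac{n}{n-1} \sum_i \sum_j p_i p_j d_{ij} / L} over haplotype
#' frequencies (the unbiased form; set `unbiased = FALSE` for the plain
#' frequency-weighted average). The standard error uses Nei's (1987)
#' total-variance approximation
#' \eqn{V(\pi) = \frac{n+1}{3(n-1)}\pi/L + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2},
#' which folds in both sampling and stochastic variance.
#'
#' @param t A `haplotype_table`.
#' @param d Pairwise-difference matrix from [pairwise_differences()].
#' @param scope Scope specifier as in [scope_counts()].
#' @param unbiased Apply the n/(n-1) correction (default `TRUE`).
#' @return List with `pi` and `se_pi`.
#' @export
nucleotide_diversity <- function(t, d, scope = "all", unbiased = TRUE) {
  stopifnot(inherits(t, "haplotype_table"))
  cc <- scope_counts(t, scope)
  n <- sum(cc)
  if (n < 2) stopf("nucleotide diversity undefined for n < 2")
  L <- t$L
  if (is.na(L)) stopf("haplotype table carries no sequence length")
  dd <- d[names(cc), names(cc), drop = FALSE]
  p <- cc / n
  pi <- as.numeric(p %*% dd %*% p) / L
  if (unbiased) pi <- pi * n / (n - 1)
  V <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, se_pi = sqrt(max(V, 0)))
}

#' Watterson's theta (per sequence)
#'
#' \eqn{\theta_W = S / a_n} with \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, the
#' segregating-sites estimator of the population mutation parameter.
#'
#' @param S_seg Number of segregating sites.
#' @param n Sample size (>= 2).
#' @return Watterson's theta per sequence.
#' @export
watterson_theta <- function(S_seg, n) {
  if (n < 2) stopf("Watterson's theta undefined for n < 2")
  if (S_seg < 0) stopf("negative segregating-site count")
  S_seg / sum(1 / seq_len(n - 1))
}

#' Convert a per-sequence theta to a (female) effective population size
#'
#' For mitochondrial inheritance \eqn{\theta = 2 N_e \mu}, so
#' \eqn{N_e = \theta / (2\mu_g)} with the per-generation, per-sequence
#' mutation rate \eqn{\mu_g = \textrm{rate} \times 10^{-2} \times 10^{-6}
#' \times L \times g} (rate in % substitutions/site/My, generation time `g`
#' in years).
#'
#' @param theta_w Theta per sequence.
#' @param rate Substitution rate in percent per site per million years
#'   (e.g. `1.086`).
#' @param L Sequence length in sites.
#' @param gen_time Generation time in years.
#' @return Effective population size (individuals).
#' @export
effective_size <- function(theta_w, rate = 1.086, L = 2373, gen_time = 4) {
  if (theta_w < 0) stopf("negative theta")
  if (rate <= 0 || L <= 0 || gen_time <= 0) {
    stopf("rate, L and gen_time must be positive")
  }
  mu_g <- rate * 1e-2 * 1e-6 * L * gen_time
  theta_w / (2 * mu_g)
}

#' Per-scope diversity table
#'
#' Computes, for every population (or lineage) and for the pooled sample,
#' the sample size, haplotype count, gene diversity and nucleotide diversity
#' — the layout of a standard mtDNA survey table.
#'
#' @param t A `haplotype_table`.
#' @param d Optional pairwise-difference matrix (needed for nucleotide
#'   diversity; skipped when the table has no sequences).
#' @param by `"population"` or `"lineage"`.
#' @return A `data.frame` with one row per scope plus a `Total` row.
#' @export
diversity_table <- function(t, d = NULL, by = c("population", "lineage")) {
  by <- match.arg(by)
  scopes <- if (by == "population") {
    as.list(colnames(t$counts))
  } else {
    if (is.null(t$lineages)) stopf("haplotype table has no lineage labels")
    as.list(unique(t$lineages))
  }
  names(scopes) <- unlist(scopes)
  scopes <- c(scopes, list(Total = "all"))
  rows <- lapply(names(scopes), function(nm) {
    cc <- scope_counts(t, scopes[[nm]])
    n <- sum(cc)
    h <- se_h <- pi <- se_pi <- NA_real_
    if (n >= 2) {
      hd <- haplotype_diversity(cc)
      h <- hd$h
      se_h <- hd$se_h
      if (!is.null(d) && !is.na(t$L)) {
        nd <- nucleotide_diversity(t, d, scopes[[nm]])
        pi <- nd$pi
        se_pi <- nd$se_pi
      }
    }
    data.frame(scope = nm, n = n, K = length(cc), h = h, se_h = se_h,
               pi = pi, se_pi = se_pi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
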