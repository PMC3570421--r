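.refugia_cache <- new.env(parent = emptyenv())

#' Tajima's D
#'
#' \eqn{D = (\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with Tajima's
#' (1989) constants computed from the sample size. `pi_seq` may be a vector
#' (the statistic is vectorized over it), which the simulation-based
#' significance test exploits.
#'
#' @param n Sample size (>= 4).
#' @param S_seg Number of segregating sites (>= 1).
#' @param pi_seq Mean pairwise differences per sequence.
#' @return Tajima's D (same length as `pi_seq`).
#' @export
tajimas_d <- function(n, S_seg, pi_seq) {
  if (n < 4) stopf("Tajima's D requires n >= 4")
  if (S_seg < 1) stopf("Tajima's D undefined with no segregating sites")
  cst <- tajima_constants(n)
  (pi_seq - S_seg / cst$a1) /
    sqrt(cst$e1 * S_seg + cst$e2 * S_seg * (S_seg - 1))
}

tajima_constants <- function(n) {
  key <- paste0("tajima_", n)
  if (!is.null(.refugia_cache[[key]])) return(.refugia_cache[[key]])
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  out <- list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
  .refugia_cache[[key]] <- out
  out
}

# log unsigned Stirling numbers of the first kind |s(n, k)|, k = 1..n,
# by the standard recurrence in log space; cached per n.
log_stirling1 <- function(n) {
  key <- paste0("stirling_", n)
  if (!is.null(.refugia_cache[[key]])) return(.refugia_cache[[key]])
  row <- 0  # n = 1: |s(1,1)| = 1
  if (n > 1L) {
    for (m in 2:n) {
      prev <- c(-Inf, row, -Inf)            # k = 0 .. m
      grown <- prev[2:(m + 1)] + log(m - 1) # (m-1) |s(m-1, k)|
      shift <- prev[1:m]                    # |s(m-1, k-1)|
      row <- pmax(shift, grown) +
        log1p(exp(pmin(shift, grown) - pmax(shift, grown)))
      row[is.nan(row)] <- -Inf
    }
  }
  .refugia_cache[[key]] <- row
  row
}

#' Fu's Fs
#'
#' Under the Ewens sampling distribution with \eqn{\theta} set to the mean
#' pairwise difference, \eqn{S' = \Pr(K \ge k_{obs})} where
#' \eqn{\Pr(K = k) = |s(n,k)| \theta^k / \theta_{(n)}} (unsigned Stirling
#' numbers of the first kind, rising factorial \eqn{\theta_{(n)}}), and
#' \eqn{F_s = \ln(S'/(1 - S'))}. All computation is in log space. Following
#' Fu (1997), an Fs value should be judged significant at p < 0.02 for a
#' nominal 0.05 level; this convention is reported in the output of
#' [neutrality_pvalues()] but never applied to the returned p-value.
#'
#' @param n Sample size (>= 2).
#' @param theta_pi Mean pairwise differences per sequence (> 0).
#' @param k_obs Observed number of haplotypes, in `[1, n]`.
#' @return Fu's Fs; `+Inf`/`-Inf` sentinel with a warning when the tail
#'   probability underflows to 0 or 1.
#' @export
fus_fs <- function(n, theta_pi, k_obs) {
  if (n < 2) stopf("Fu's Fs requires n >= 2")
  if (k_obs < 1 || k_obs > n) stopf("k_obs must lie in [1, n]")
  if (theta_pi <= 0) stopf("Fu's Fs requires theta_pi > 0")
  lp <- ewens_log_probs(n, theta_pi)
  if (k_obs == 1L) {
    warning("S' = 1 (K >= 1 is certain): Fs = +Inf", call. = FALSE)
    return(Inf)
  }
  hi <- logsumexp(lp[k_obs:n])
  lo <- logsumexp(lp[1:(k_obs - 1L)])
  if (!is.finite(hi)) {
    warning("S' underflowed to 0: Fs = -Inf", call. = FALSE)
    return(-Inf)
  }
  hi - lo
}

ewens_log_probs <- function(n, theta) {
  ls <- log_stirling1(n)
  k <- seq_len(n)
  lp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  lp - logsumexp(lp)  # renormalize away rounding in the rising factorial
}

# One constant-size coalescent replicate conditioned on S segregating sites:
# Kingman topology, S mutations dropped on branches with probability
# proportional to length (infinite sites). Returns the mean pairwise
# difference and (optionally) the number of distinct haplotypes.
sim_fixed_s <- function(n, S, need_k = FALSE) {
  n_edge <- 2L * n - 2L
  birth <- numeric(2L * n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  members <- NULL
  if (need_k) members <- c(as.list(seq_len(n)), vector("list", n - 1L))
  active <- seq_len(n)
  edge_len <- numeric(n_edge)
  edge_child <- integer(n_edge)
  t <- 0
  e <- 0L
  nxt <- n
  for (k in n:2) {
    t <- t + stats::rexp(1L, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    c1 <- active[pick[1L]]
    c2 <- active[pick[2L]]
    nxt <- nxt + 1L
    birth[nxt] <- t
    size[nxt] <- size[c1] + size[c2]
    if (need_k) members[[nxt]] <- c(members[[c1]], members[[c2]])
    edge_len[e + 1L] <- t - birth[c1]
    edge_child[e + 1L] <- c1
    edge_len[e + 2L] <- t - birth[c2]
    edge_child[e + 2L] <- c2
    e <- e + 2L
    active <- c(active[-pick], nxt)
  }
  hits <- tabulate(sample.int(n_edge, S, replace = TRUE, prob = edge_len),
                   nbins = n_edge)
  csz <- size[edge_child]
  pi_seq <- sum(hits * csz * (n - csz)) / (n * (n - 1) / 2)
  K <- NA_integer_
  if (need_k) {
    mut <- which(hits > 0L)
    if (length(mut) == 0L) {
      K <- 1L
    } else {
      M <- matrix(FALSE, n, length(mut))
      for (j in seq_along(mut)) M[members[[edge_child[mut[j]]]], j] <- TRUE
      K <- nrow(unique(M))
    }
  }
  list(pi_seq = pi_seq, K = K)
}

#' Coalescent-simulated significance for Tajima's D and Fu's Fs
#'
#' Simulates `nreps` constant-size coalescent samples conditioned on the
#' observed number of segregating sites (mutations dropped uniformly on the
#' genealogy, matching the fixed-S convention of Arlequin) and reports
#' one-tailed (low) p-values: the fraction of simulated statistics less than
#' or equal to the observed value. Significantly negative D and Fs signal
#' population expansion.
#'
#' @param n Sample size.
#' @param S_seg Observed segregating sites (conditioning value).
#' @param D_obs,Fs_obs Observed statistics (either may be `NULL` to skip).
#' @param nreps Number of simulated samples (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `p_D`, `p_Fs`, the simulated statistic vectors `D_sim`
#'   and `Fs_sim`, `nreps`, `seed`, and `fs_note` restating Fu's p < 0.02
#'   significance convention.
#' @export
neutrality_pvalues <- function(n, S_seg, D_obs = NULL, Fs_obs = NULL,
                               nreps = 1000L, seed = NULL) {
  if (nreps < 100L) stopf("use at least 100 simulation replicates")
  need_k <- !is.null(Fs_obs)
  with_seed(seed, {
    pi_sim <- numeric(nreps)
    K_sim <- integer(nreps)
    for (r in seq_len(nreps)) {
      s <- sim_fixed_s(n, S_seg, need_k = need_k)
      pi_sim[r] <- s$pi_seq
      K_sim[r] <- s$K
    }
    out <- list(p_D = NULL, p_Fs = NULL, D_sim = NULL, Fs_sim = NULL,
                nreps = nreps, seed = seed,
                fs_note = "Fu (1997): judge Fs significant at p < 0.02 for a nominal 0.05 level")
    if (!is.null(D_obs)) {
      out$D_sim <- tajimas_d(n, S_seg, pi_sim)
      out$p_D <- mean(out$D_sim <= D_obs)
    }
    if (need_k) {
      out$Fs_sim <- vapply(seq_len(nreps), function(r) {
        suppressWarnings(fus_fs(n, pi_sim[r], K_sim[r]))
      }, numeric(1L))
      out$p_Fs <- mean(out$Fs_sim <= Fs_obs)
    }
    out
  })
}

#' Neutrality tests for one scope of a haplotype table
#'
#' Convenience wrapper computing the observed Tajima's D and Fu's Fs for a
#' population, lineage, or the pooled sample, plus their simulated p-values.
#'
#' @param t A `haplotype_table` with sequences.
#' @param d Pairwise-difference matrix.
#' @param scope Scope specifier as in [scope_counts()].
#' @param nreps,seed Passed to [neutrality_pvalues()].
#' @return List with `n`, `S_seg`, `pi_seq`, `K`, `D`, `p_D`, `Fs`, `p_Fs`.
#' @export
neutrality_test <- function(t, d, scope = "all", nreps = 1000L, seed = NULL) {
  cc <- scope_counts(t, scope)
  n <- sum(cc)
  if (n < 4) stopf("neutrality tests need n >= 4 in scope")
  haps <- names(cc)
  S_seg <- count_segregating(t$sequences[haps, , drop = FALSE])
  if (S_seg < 1) stopf("no segregating sites in scope")
  dd <- d[haps, haps, drop = FALSE]
  p <- cc / n
  pi_seq <- as.numeric(p %*% dd %*% p) * n / (n - 1)
  D <- tajimas_d(n, S_seg, pi_seq)
  Fs <- suppressWarnings(fus_fs(n, pi_seq, length(cc)))
  pv <- neutrality_pvalues(n, S_seg, D_obs = D, Fs_obs = Fs,
                           nreps = nreps, seed = seed)
  list(n = n, S_seg = S_seg, pi_seq = pi_seq, K = length(cc),
       D = D, p_D = pv$p_D, Fs = Fs, p_Fs = pv$p_Fs,
       nreps = nreps, seed = seed)
}
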