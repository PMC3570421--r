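# Population-level cross sums of squared distances: W[p, q] = sum over
# ordered individual pairs (i in p, j in q) of d2[hap_i, hap_j]. All AMOVA
# sums of squares are linear functionals of W.
amova_w_matrix <- function(counts, d2) {
  t(counts) %*% d2 %*% counts
}

# Variance components for the (1-, 2- or) 3-level design from W, the
# population sample sizes and a group assignment (Excoffier et al. 1992
# moment estimators). Negative components are reported as computed.
amova_components <- function(W, n_p, gvec) {
  N <- sum(n_p)
  P <- length(n_p)
  G <- length(unique(gvec))
  gfac <- factor(gvec)
  SST <- sum(W) / (2 * N)
  SSWP <- sum(diag(W) / (2 * n_p))
  Ng <- as.numeric(rowsum(n_p, gfac))
  Wg <- rowsum(t(rowsum(W, gfac)), gfac)  # G x G block sums
  Sg_sum <- sum(diag(as.matrix(Wg)) / (2 * Ng))
  SSAG <- SST - Sg_sum
  SSAP <- Sg_sum - SSWP
  df_wp <- N - P
  sigma_c <- SSWP / df_wp
  if (G == 1L) {
    n0 <- (N - sum(n_p^2) / N) / (P - 1)
    sigma_b <- (SSAP / (P - 1) - sigma_c) / n0
    sigma_a <- 0
    return(list(sigma_a = 0, sigma_b = sigma_b, sigma_c = sigma_c,
                phi_st = sigma_b / (sigma_b + sigma_c),
                phi_sc = NA_real_, phi_ct = NA_real_,
                SS = c(among_groups = NA, among_pops = SSAP, within_pops = SSWP),
                df = c(NA, P - 1, df_wp)))
  }
  A <- sum(as.numeric(rowsum(n_p^2, gfac)) / Ng)
  n1 <- (N - A) / (P - G)
  n2 <- (A - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(Ng^2) / N) / (G - 1)
  MSAP <- SSAP / (P - G)
  MSAG <- SSAG / (G - 1)
  sigma_b <- (MSAP - sigma_c) / n1
  sigma_a <- (MSAG - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       phi_st = (sigma_a + sigma_b) / tot,
       phi_sc = sigma_b / (sigma_b + sigma_c),
       phi_ct = sigma_a / tot,
       SS = c(among_groups = SSAG, among_pops = SSAP, within_pops = SSWP),
       df = c(G - 1, P - G, df_wp))
}

#' Analysis of molecular variance (AMOVA) with permutation tests
#'
#' Partitions molecular variance among groups of populations, among
#' populations within groups, and within populations, from squared pairwise
#' haplotype differences (Excoffier's sums-of-squares formulation), and
#' reports the Phi fixation indices \eqn{\Phi_{CT} = \sigma^2_a /
#' \sigma^2_T}, \eqn{\Phi_{SC} = \sigma^2_b / (\sigma^2_b + \sigma^2_c)},
#' \eqn{\Phi_{ST} = (\sigma^2_a + \sigma^2_b) / \sigma^2_T}. Significance
#' uses the standard permutation schemes: whole populations among groups
#' for \eqn{\Phi_{CT}}; individuals among populations within groups for
#' \eqn{\Phi_{SC}}; individuals among populations for \eqn{\Phi_{ST}}.
#' Negative variance components are reported as computed, not truncated.
#'
#' @param t A `haplotype_table`.
#' @param d Pairwise-difference matrix (used as squared distances).
#' @param grouping Named vector mapping population id to group label;
#'   `NULL` runs the 2-level (populations only) design.
#' @param n_perm Number of permutations (0 skips the tests).
#' @param seed Optional integer seed.
#' @return Object of class `amova_result`.
#' @export
amova <- function(t, d, grouping = NULL, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(t, "haplotype_table"))
  pops <- colnames(t$counts)
  n_p <- colSums(t$counts)
  keep <- n_p > 0
  pops <- pops[keep]
  n_p <- n_p[keep]
  counts <- t$counts[, keep, drop = FALSE]
  d2 <- d[rownames(counts), rownames(counts), drop = FALSE]
  two_level <- is.null(grouping)
  if (two_level) {
    gvec <- rep(1L, length(pops))
  } else {
    miss <- setdiff(pops, names(grouping))
    if (length(miss) > 0L) stopf("populations without group: %s", paste(miss, collapse = ", "))
    gvec <- as.integer(factor(grouping[pops]))
    single <- names(table(gvec))[table(gvec) == 1L]
    if (length(single) > 0L) {
      warning("group(s) with a single population: Phi_CT is unstable", call. = FALSE)
    }
  }
  W <- amova_w_matrix(counts, d2)
  obs <- amova_components(W, n_p, gvec)
  # individual-level expansion for the permutation schemes
  ind_pop <- rep(seq_along(pops), times = n_p)
  ind_hap <- unlist(lapply(seq_along(pops), function(p) {
    rep(seq_len(nrow(counts)), times = counts[, p])
  }))
  perm <- list(p_phi_st = NA_real_, p_phi_sc = NA_real_, p_phi_ct = NA_real_)
  if (n_perm > 0L) {
    perm <- with_seed(seed, {
      recompute <- function(hap_assign, gv) {
        C <- matrix(0L, nrow(counts), length(pops))
        for (p in seq_along(pops)) {
          tb <- tabulate(hap_assign[ind_pop == p], nbins = nrow(counts))
          C[, p] <- tb
        }
        amova_components(amova_w_matrix(C, d2), n_p, gv)
      }
      st <- sc <- ct <- numeric(n_perm)
      for (r in seq_len(n_perm)) {
        # Phi_ST: individuals among populations (whole data set)
        st[r] <- recompute(sample(ind_hap), gvec)$phi_st
        if (!two_level) {
          # Phi_SC: individuals among populations within their group
          hap_p <- ind_hap
          for (g in unique(gvec)) {
            sel <- ind_pop %in% which(gvec == g)
            hap_p[sel] <- sample(hap_p[sel])
          }
          sc[r] <- recompute(hap_p, gvec)$phi_sc
          # Phi_CT: whole populations among groups
          ct[r] <- amova_components(W, n_p, sample(gvec))$phi_ct
        }
      }
      pval <- function(sim, ob) (sum(sim >= ob) + 1) / (n_perm + 1)
      list(p_phi_st = pval(st, obs$phi_st),
           p_phi_sc = if (two_level) NA_real_ else pval(sc, obs$phi_sc),
           p_phi_ct = if (two_level) NA_real_ else pval(ct, obs$phi_ct))
    })
  }
  tot <- obs$sigma_a + obs$sigma_b + obs$sigma_c
  structure(c(obs, perm,
              list(percent = 100 * c(among_groups = obs$sigma_a,
                                     among_pops_within = obs$sigma_b,
                                     within_pops = obs$sigma_c) / tot,
                   n_permutations = n_perm, seed = seed,
                   grouping = if (two_level) NULL else grouping)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA variance components:\n")
  cat(sprintf("  among groups            : %8.4f (%6.2f%%)\n", x$sigma_a, x$percent[1L]))
  cat(sprintf("  among pops within groups: %8.4f (%6.2f%%)\n", x$sigma_b, x$percent[2L]))
  cat(sprintf("  within populations      : %8.4f (%6.2f%%)\n", x$sigma_c, x$percent[3L]))
  cat(sprintf("  Phi_ST = %.5f (p = %s), Phi_SC = %.5f (p = %s), Phi_CT = %.5f (p = %s)\n",
              x$phi_st, format(x$p_phi_st), x$phi_sc, format(x$p_phi_sc),
              x$phi_ct, format(x$p_phi_ct)))
  invisible(x)
}

#' Spatial analysis of molecular variance (SAMOVA)
#'
#' Searches for the partition of populations into `K` groups that maximizes
#' \eqn{\Phi_{CT}} by simulated annealing: single-population moves between
#' groups, Metropolis acceptance with a geometrically cooled temperature,
#' multiple random starts. An optional geographic contiguity constraint
#' (off by default) restricts moves to groups containing a neighbour of the
#' moved population, given a user-supplied adjacency matrix.
#'
#' @param t A `haplotype_table`.
#' @param d Pairwise-difference matrix.
#' @param K Number of groups (`2 <= K <` number of populations).
#' @param n_starts Random restarts.
#' @param steps Annealing steps per start.
#' @param t0 Initial temperature.
#' @param cooling Geometric cooling factor per step.
#' @param seed Optional integer seed.
#' @param init_partitions Optional list of group assignments (named vectors
#'   population -> group) used as additional starts; the returned best
#'   partition scores at least as high as any of these.
#' @param neighbors Optional logical/0-1 adjacency matrix over populations
#'   enforcing contiguous groups.
#' @return Object of class `samova_result`: `partition` (named vector),
#'   `phi_ct`, `trace` (best Phi_CT over steps of the best start), `K`,
#'   `seed`.
#' @export
samova <- function(t, d, K, n_starts = 10L, steps = 5000L, t0 = 0.1,
                   cooling = 0.995, seed = NULL, init_partitions = NULL,
                   neighbors = NULL) {
  stopifnot(inherits(t, "haplotype_table"))
  pops <- colnames(t$counts)
  P <- length(pops)
  if (K < 2L || K >= P) stopf("K must satisfy 2 <= K < %d populations", P)
  n_p <- colSums(t$counts)
  d2 <- d[rownames(t$counts), rownames(t$counts), drop = FALSE]
  W <- amova_w_matrix(t$counts, d2)
  eval_ct <- function(gv) {
    ct <- amova_components(W, n_p, gv)$phi_ct
    if (!is.finite(ct)) -Inf else ct
  }
  ok_move <- function(gv, p, g_new) {
    if (sum(gv == gv[p]) == 1L) return(FALSE)  # would empty a group
    if (!is.null(neighbors)) {
      nb <- which(neighbors[p, ] > 0)
      if (!any(gv[nb] == g_new)) return(FALSE)
    }
    TRUE
  }
  with_seed(seed, {
    starts <- lapply(seq_len(n_starts), function(i) {
      gv <- integer(P)
      gv[sample.int(P, K)] <- seq_len(K)        # guarantee non-empty groups
      gv[gv == 0L] <- sample.int(K, P - K, replace = TRUE)
      gv
    })
    for (ip in init_partitions %||% list()) {
      starts[[length(starts) + 1L]] <- as.integer(factor(ip[pops], levels = unique(ip[pops])))
    }
    best_gv <- NULL
    best_ct <- -Inf
    best_trace <- NULL
    for (gv in starts) {
      cur <- eval_ct(gv)
      loc_best <- cur
      loc_best_gv <- gv
      temp <- t0
      trace <- numeric(steps)
      for (s in seq_len(steps)) {
        p <- sample.int(P, 1L)
        g_new <- sample.int(K, 1L)
        if (g_new != gv[p] && ok_move(gv, p, g_new)) {
          cand <- gv
          cand[p] <- g_new
          val <- eval_ct(cand)
          if (val > cur || stats::runif(1L) < exp((val - cur) / temp)) {
            gv <- cand
            cur <- val
            if (cur > loc_best) {
              loc_best <- cur
              loc_best_gv <- gv
            }
          }
        }
        temp <- temp * cooling
        trace[s] <- loc_best
      }
      if (loc_best > best_ct) {
        best_ct <- loc_best
        best_gv <- loc_best_gv
        best_trace <- trace
      }
    }
    structure(list(partition = stats::setNames(best_gv, pops),
                   phi_ct = best_ct, trace = best_trace, K = K, seed = seed),
              class = "samova_result")
  })
}

#' @export
print.samova_result <- function(x, ...) {
  cat(sprintf("SAMOVA: best Phi_CT = %.5f with K = %d groups\n", x$phi_ct, x$K))
  for (g in seq_len(x$K)) {
    cat(sprintf("  group %d: %s\n", g,
                paste(names(x$partition)[x$partition == g], collapse = ", ")))
  }
  invisible(x)
}
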