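#' Pairwise mismatch histogram
#'
#' Counts, for every unordered pair of individuals in the scope, the number
#' of site differences between their haplotypes. The histogram covers
#' classes `0..max(observed)`.
#'
#' @param t A `haplotype_table`.
#' @param d Pairwise-difference matrix from [pairwise_differences()].
#' @param scope Scope specifier as in [scope_counts()].
#' @return Named integer vector; element `"i"` is the number of pairs at
#'   `i` differences. Sums to `n(n-1)/2`.
#' @export
mismatch_histogram <- function(t, d, scope = "all") {
  cc <- scope_counts(t, scope)
  n <- sum(cc)
  if (n < 2) stopf("mismatch histogram needs >= 2 individuals in scope")
  dd <- d[names(cc), names(cc), drop = FALSE]
  K <- length(cc)
  # pair multiplicities: within-haplotype C(c,2) at distance 0,
  # between haplotypes c_a * c_b at distance d_ab
  dmax <- max(dd)
  hist <- numeric(dmax + 1L)
  hist[1L] <- hist[1L] + sum(cc * (cc - 1) / 2)
  if (K > 1L) {
    for (a in seq_len(K - 1L)) {
      for (b in (a + 1L):K) {
        hist[dd[a, b] + 1L] <- hist[dd[a, b] + 1L] + cc[a] * cc[b]
      }
    }
  }
  hist <- as.integer(hist)
  names(hist) <- 0:dmax
  hist
}

#' Expected mismatch probabilities under the sudden-expansion model
#'
#' Rogers' (1995) simplification of the Rogers--Harpending sudden-expansion
#' model with the post-expansion size taken to infinity:
#' \deqn{F_i(\tau, \theta_0) = e^{-\tau} \sum_{j=0}^{i}
#'   \frac{\theta_0^j}{(\theta_0+1)^{j+1}} \cdot
#'   \frac{\tau^{i-j}}{(i-j)!},}
#' the convolution of the geometric equilibrium mismatch distribution
#' (parameter \eqn{\theta_0}) with Poisson(\eqn{\tau}) mutations accumulated
#' since the expansion.
#'
#' @param tau Expansion parameter (mutational time, \eqn{\tau = 2ut}).
#' @param theta0 Pre-expansion theta per sequence.
#' @param kmax Largest difference class to evaluate.
#' @return Numeric vector `F_0..F_kmax`.
#' @export
expected_mismatch <- function(tau, theta0, kmax) {
  j <- 0:kmax
  geom <- if (theta0 == 0) c(1, numeric(kmax)) else
    exp(j * log(theta0) - (j + 1) * log(theta0 + 1))
  pois <- if (tau == 0) c(1, numeric(kmax)) else
    exp(-tau + j * log(tau) - lgamma(j + 1))
  # F = geom (*) pois via FFT, truncated to classes 0..kmax
  pad <- numeric(kmax + 1L)
  f <- Re(stats::fft(stats::fft(c(geom, pad)) * stats::fft(c(pois, pad)),
                     inverse = TRUE))[seq_len(kmax + 1L)] / (2L * (kmax + 1L))
  f[f < 0] <- 0
  f
}

#' Fit the sudden-expansion model to a mismatch histogram
#'
#' Minimizes the sum of squared deviations between the observed relative
#' mismatch frequencies and [expected_mismatch()] over \eqn{(\tau,
#' \theta_0)} by multi-start bounded quasi-Newton search (at least 8 starts
#' on a log-spaced grid; SSD tolerance 1e-10). The post-expansion theta is
#' treated as infinite (Rogers' approximation); the reported `theta1` is
#' therefore `Inf`.
#'
#' @param histogram Mismatch histogram (counts by difference class,
#'   classes `0..dmax`), e.g. from [mismatch_histogram()].
#' @param n_starts Number of optimizer starts (>= 8).
#' @return List with `tau`, `theta0`, `theta1` (`Inf`), `SSD` and the
#'   observed relative frequencies `obs`.
#' @export
fit_sudden_expansion <- function(histogram, n_starts = 8L) {
  histogram <- as.numeric(histogram)
  if (sum(histogram) <= 0) stopf("empty mismatch histogram")
  obs <- histogram / sum(histogram)
  kmax <- length(obs) - 1L
  if (kmax == 0L) {
    # all pairs identical: tau -> 0 boundary, perfect fit
    return(list(tau = 0, theta0 = 0, theta1 = Inf, SSD = 0, obs = obs))
  }
  ssd <- function(par) {
    f <- expected_mismatch(par[1L], par[2L], kmax)
    sum((obs - f)^2)
  }
  mean_obs <- sum((0:kmax) * obs)
  taus <- exp(seq(log(max(mean_obs, 0.5) / 4), log(max(2 * kmax, 2)),
                  length.out = max(4L, ceiling(n_starts / 2))))
  starts <- expand.grid(tau = taus, theta0 = c(0.1, 2))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::nlminb(as.numeric(starts[s, ]), ssd,
                         lower = c(0, 1e-8), upper = c(4 * kmax + 10, 1e3),
                         control = list(abs.tol = 1e-10, rel.tol = 1e-12))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stopf("sudden-expansion fit failed to converge")
  list(tau = best$par[1L], theta0 = best$par[2L], theta1 = Inf,
       SSD = best$objective, obs = obs)
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum (x_i - x_{i-1})^2} over the relative mismatch frequencies,
#' padding with zero classes on both sides of the observed range, so a
#' distribution concentrated in a single class scores 2 and smooth unimodal
#' distributions score near 0.
#'
#' @param histogram Mismatch histogram (counts by class `0..dmax`).
#' @return Raggedness index.
#' @export
raggedness <- function(histogram) {
  histogram <- as.numeric(histogram)
  if (sum(histogram) <= 0) stopf("empty mismatch histogram")
  x <- c(0, histogram / sum(histogram), 0)
  sum(diff(x)^2)
}

# Coalescent sample of pairwise differences under the fitted sudden-
# expansion model (post-expansion size infinite): no coalescence more
# recently than tau (in mutational units 2u x generations), Kingman
# coalescent with rate C(k,2)/theta0 beyond, mutations Poisson with rate
# 1/2 per lineage per mutational unit (infinite sites).
sim_expansion_pairs <- function(n, tau, theta0) {
  birth <- c(rep(0, n), numeric(n - 1L))
  active <- seq_len(n)
  members <- c(as.list(seq_len(n)), vector("list", n - 1L))
  D <- matrix(0, n, n)
  t <- tau
  nxt <- n
  for (k in n:2) {
    if (theta0 > 0) t <- t + stats::rexp(1L, k * (k - 1) / 2 / theta0)
    pick <- sample.int(k, 2L)
    c1 <- active[pick[1L]]
    c2 <- active[pick[2L]]
    nxt <- nxt + 1L
    birth[nxt] <- t
    members[[nxt]] <- c(members[[c1]], members[[c2]])
    for (ch in c(c1, c2)) {
      m <- stats::rpois(1L, (t - birth[ch]) / 2)
      if (m > 0L) {
        below <- members[[ch]]
        D[below, -below] <- D[below, -below] + m
      }
    }
    active <- c(active[-pick], nxt)
  }
  d <- D[upper.tri(D)] + t(D)[upper.tri(D)]  # both sides of each pair's path
  tabulate(d + 1L, nbins = max(d) + 1L)
}

#' Parametric-bootstrap goodness of fit for the sudden-expansion model
#'
#' Simulates `nreps` coalescent samples of the same size under the fitted
#' expansion parameters, re-fits each with the same optimizer settings, and
#' reports the fraction of replicates whose SSD (resp. raggedness) is at
#' least the observed value — the mismatch-analysis bootstrap of Arlequin.
#'
#' @param histogram Observed mismatch histogram.
#' @param fit Fitted model from [fit_sudden_expansion()].
#' @param n Number of sequences behind the histogram (pairs =
#'   `n(n-1)/2`); recovered from the histogram total when `NULL`.
#' @param nreps Bootstrap replicates.
#' @param seed Optional integer seed.
#' @return List with `p_SSD`, `p_rag`, `SSD_obs`, `rag_obs`, `nreps`, `seed`.
#' @export
bootstrap_gof <- function(histogram, fit, n = NULL, nreps = 1000L, seed = NULL) {
  npairs <- sum(histogram)
  if (is.null(n)) n <- round((1 + sqrt(1 + 8 * npairs)) / 2)
  SSD_obs <- fit$SSD
  rag_obs <- raggedness(histogram)
  with_seed(seed, {
    ssd_star <- rag_star <- numeric(nreps)
    for (r in seq_len(nreps)) {
      h <- sim_expansion_pairs(n, fit$tau, fit$theta0)
      f <- fit_sudden_expansion(h)
      ssd_star[r] <- f$SSD
      rag_star[r] <- raggedness(h)
    }
    list(p_SSD = mean(ssd_star >= SSD_obs), p_rag = mean(rag_star >= rag_obs),
         SSD_obs = SSD_obs, rag_obs = rag_obs, nreps = nreps, seed = seed)
  })
}

#' Expansion time from the mismatch parameter tau
#'
#' \eqn{\tau = 2ut} with the per-sequence, per-year mutation rate
#' \eqn{u = \textrm{rate} \times 10^{-2} \times 10^{-6} \times L}, so
#' \eqn{t = \tau / (2u)} years. The per-year (not per-generation) rate is
#' what converts a fitted mismatch \eqn{\tau} directly to calendar time.
#'
#' @param tau Fitted expansion parameter (>= 0).
#' @param rate Substitution rate in percent per site per million years.
#' @param L Sequence length in sites.
#' @return Expansion time in years.
#' @export
expansion_time <- function(tau, rate = 1.086, L = 2373) {
  if (tau < 0) stopf("tau must be non-negative")
  if (rate <= 0 || L <= 0) stopf("rate and L must be positive")
  u <- rate * 1e-2 * 1e-6 * L
  tau / (2 * u)
}

#' Full mismatch analysis for one scope
#'
#' Histogram, sudden-expansion fit, bootstrap goodness of fit, raggedness
#' and expansion-time dating in one call (the right-hand block of a
#' standard demographic-history table).
#'
#' @inheritParams mismatch_histogram
#' @param rate,L Passed to [expansion_time()]; `L` defaults to the table's
#'   alignment length.
#' @param nreps,seed Passed to [bootstrap_gof()].
#' @return Object of class `mismatch_result`.
#' @export
mismatch_test <- function(t, d, scope = "all", rate = 1.086, L = NULL,
                          nreps = 1000L, seed = NULL) {
  h <- mismatch_histogram(t, d, scope)
  fit <- fit_sudden_expansion(h)
  n <- sum(scope_counts(t, scope))
  gof <- bootstrap_gof(h, fit, n = n, nreps = nreps, seed = seed)
  L <- L %||% t$L
  structure(list(histogram = h, tau = fit$tau, theta0 = fit$theta0,
                 theta1 = fit$theta1, SSD = fit$SSD, p_SSD = gof$p_SSD,
                 raggedness = gof$rag_obs, p_rag = gof$p_rag,
                 t_years = expansion_time(fit$tau, rate, L),
                 nreps = nreps, seed = seed),
            class = "mismatch_result")
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat(sprintf(
    "sudden-expansion fit: tau = %.3f, theta0 = %.3f, SSD = %.4f (p = %.3f), r = %.4f (p = %.3f)\n",
    x$tau, x$theta0, x$SSD, x$p_SSD, x$raggedness, x$p_rag))
  cat(sprintf("expansion time: %.0f years (%.3f Mya)\n", x$t_years, x$t_years / 1e6))
  invisible(x)
}
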