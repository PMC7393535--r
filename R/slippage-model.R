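#' Per-unit slippage outcome probabilities
#'
#' During replication of one repeat unit the polymerase either slips
#' backwards (hysteresis synthesis, deleting the unit), copies the unit
#' faithfully, or slips forwards (pre-synthesis, inserting an extra
#' unit). The three outcomes form a multinoulli distribution with
#' probabilities `p`, `1 - p - q` and `q`.
#'
#' @param x Outcome code: 0 = deletion step, 1 = faithful copy,
#'   2 = insertion step. Vectorised.
#' @param p Per-unit deletion probability.
#' @param q Per-unit insertion probability.
#' @return Probability of each outcome in `x`.
#' @examples
#' multinoulli_pmf(0:2, p = 0.2, q = 0.1)
#' @export
multinoulli_pmf <- function(x, p, q) {
  check_params(p, q)
  if (!all(x %in% c(0L, 1L, 2L)))
    stop("outcome 'x' must be 0 (deletion), 1 (normal) or 2 (insertion)")
  out <- numeric(length(x))
  out[x == 0L] <- p
  out[x == 1L] <- 1 - p - q
  out[x == 2L] <- q
  out
}

xlogy <- function(a, b) ifelse(a == 0, 0, a * log(b))

check_params <- function(p, q) {
  if (length(p) != 1L || length(q) != 1L || is.na(p) || is.na(q))
    stop("'p' and 'q' must be single non-missing numbers")
  if (p < 0 || q < 0 || p + q > 1)
    stop("invalid slippage parameters: need p >= 0, q >= 0, p + q <= 1")
  invisible(TRUE)
}

#' Probability of observing repeat length y at a site with n reference copies
#'
#' The observed tract length is the sum of n independent per-unit
#' outcomes. A read shorter than the reference (y <= n) is reached with
#' minimal steps by y faithful copies and n - y deletion slips; a longer
#' read (n < y <= 2n) by 2n - y faithful copies and y - n insertion
#' slips. Multi-pass slippage paths (reaching y in more than the minimal
#' number of steps) contribute negligible mass and are not modelled, so
#' the pmf over 0..2n sums to
#' \eqn{(1-q)^n + (1-p)^n - (1-p-q)^n}, slightly below 1.
#'
#' @param y Observed repeat length(s) in whole motif copies; vectorised.
#' @param n Reference repeat count (>= 1).
#' @param p,q Per-unit deletion / insertion probabilities.
#' @param log If `TRUE`, return log-probabilities.
#' @return Probability (or log-probability) for each `y`; 0 for y > 2n.
#' @examples
#' repeat_length_pmf(1, n = 2, p = 0.1, q = 0.1)  # 2 * 0.8 * 0.1 = 0.16
#' @export
repeat_length_pmf <- function(y, n, p, q, log = FALSE) {
  check_params(p, q)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a single integer >= 1")
  if (any(is.na(y)) || any(y < 0))
    stop("'y' must be non-negative")
  n <- as.integer(n)
  lp <- rep(-Inf, length(y))
  r <- 1 - p - q
  del <- y <= n
  ins <- y > n & y <= 2L * n
  # log-space binomial coefficients keep n ~ 50 exact enough;
  # xlogy(0, 0) = 0 so zero-count factors never poison the product
  if (any(del)) {
    yd <- y[del]
    lp[del] <- lchoose(n, n - yd) + xlogy(yd, r) + xlogy(n - yd, p)
  }
  if (any(ins)) {
    yi <- y[ins]
    lp[ins] <- lchoose(n, yi - n) + xlogy(2L * n - yi, r) + xlogy(yi - n, q)
  }
  if (log) lp else exp(lp)
}

#' Log-likelihood of an observed allele-length distribution
#'
#' Product over reads of the repeat-length pmf; returns `-Inf` when any
#' observed length has zero probability (including y > 2n).
#'
#' @param y Integer vector of observed repeat lengths, one entry per
#'   read (a length multiset).
#' @param n Reference repeat count.
#' @param p,q Slippage parameters.
#' @return The summed log-probability.
#' @export
log_likelihood <- function(y, n, p, q) {
  y <- expand_lengths(y)
  if (length(y) == 0L) stop("log-likelihood undefined for an empty distribution (m = 0)")
  tab <- table(y)
  yy <- as.integer(names(tab))
  sum(as.integer(tab) * repeat_length_pmf(yy, n, p, q, log = TRUE))
}

#' Closed-form slippage-rate estimates from an allele-length distribution
#'
#' Deletion rate: the total deleted units over reads at or below the
#' reference length, divided by n * m; insertion rate: total inserted
#' units over reads above the reference length, divided by n * m. Both
#' are clamped to \[0, 1\]. Reads with y > 2n (impossible under the
#' model but possible in noisy data) still contribute inserted units.
#'
#' @inheritParams log_likelihood
#' @return List with elements `p`, `q` and supporting read count `m`.
#' @examples
#' estimate_slippage(c(4, 5, 6), n = 5)  # p = q = 1/15
#' @export
estimate_slippage <- function(y, n) {
  y <- expand_lengths(y)
  m <- length(y)
  if (m == 0L) stop("slippage estimate undefined for an empty distribution (m = 0)")
  if (n < 1) stop("'n' must be >= 1")
  p_hat <- sum(pmax(n - y, 0)) / (n * m)
  q_hat <- sum(pmax(y - n, 0)) / (n * m)
  list(p = min(max(p_hat, 0), 1), q = min(max(q_hat, 0), 1), m = m)
}

# Accept either a plain vector of per-read lengths or a named count
# vector ("counts" representation used by the distribution tables).
expand_lengths <- function(y) {
  if (!is.null(names(y)))
    return(rep(as.integer(names(y)), times = as.integer(y)))
  as.integer(y)
}

#' Normalised pmf table over the support 0..2n
#'
#' The truncated model pmf renormalised to sum to one, used by the
#' forward simulator so draws form a proper distribution.
#'
#' @inheritParams repeat_length_pmf
#' @return Numeric vector of length 2n + 1 named by y.
#' @export
repeat_length_pmf_table <- function(n, p, q) {
  y <- 0:(2L * as.integer(n))
  pr <- repeat_length_pmf(y, n, p, q)
  s <- sum(pr)
  if (s <= 0) stop("degenerate pmf: zero total mass")
  stats::setNames(pr / s, y)
}

#' Simulate an allele-length distribution under the slippage model
#'
#' Draws `m` independent repeat lengths from the renormalised pmf over
#' 0..2n. Reproducible for a fixed `seed`.
#'
#' @param n Reference repeat count.
#' @param p,q Slippage parameters.
#' @param m Number of reads to draw (>= 1).
#' @param seed Optional integer seed (local to this call).
#' @return Integer vector of m simulated repeat lengths.
#' @export
simulate_allele_distribution <- function(n, p, q, m, seed = NULL) {
  if (m < 1) stop("'m' must be >= 1")
  tab <- repeat_length_pmf_table(n, p, q)
  with_seed(seed, sample(0:(2L * as.integer(n)), size = m, replace = TRUE, prob = tab))
}

#' Kolmogorov-Smirnov model-fitness test for one site
#'
#' Compares the observed allele-length distribution with `m_sim` lengths
#' simulated at the given parameters, via the two-sample KS statistic on
#' the empirical CDFs (asymptotic p-value; with heavily tied integer
#' data the test is conservative). A site is "fitted" when the test does
#' not reject at `alpha`.
#'
#' @param y Observed repeat lengths (vector or named counts).
#' @param n Reference repeat count.
#' @param p,q Parameters to test (typically the site's own estimates).
#' @param m_sim Simulated sample size; default matches the observed m
#'   for symmetric test power.
#' @param seed Optional seed for the simulation draw.
#' @param alpha Test level (default 0.05).
#' @return List with `statistic`, `p_value` and logical `fitted`.
#' @export
ks_fitness <- function(y, n, p, q, m_sim = NULL, seed = NULL, alpha = 0.05) {
  y <- expand_lengths(y)
  if (length(y) == 0L) stop("fitness test undefined for an empty distribution")
  if (is.null(m_sim)) m_sim <- length(y)
  sim <- simulate_allele_distribution(n, p, q, m_sim, seed = seed)
  if (length(unique(c(y, sim))) == 1L)
    return(list(statistic = 0, p_value = 1, fitted = TRUE))
  kt <- suppressWarnings(stats::ks.test(y, sim, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       fitted = kt$p.value >= alpha)
}

#' Slippage estimates for every site of a distribution table
#'
#' @param dists Distribution table from [extract_all()] or the fixture
#'   generator: one row per site with a `lengths` list-column (per-read
#'   repeat lengths) or a `dist` string column of "y:count" pairs, plus
#'   site identity columns including `n`.
#' @return Data frame with the site identity columns plus `p`, `q`, `m`
#'   (p and q are `NA` where m = 0).
#' @export
estimate_all <- function(dists) {
  lens <- dist_lengths(dists)
  n <- dists$n
  p <- q <- rep(NA_real_, nrow(dists))
  m <- vapply(lens, length, integer(1))
  for (i in which(m > 0L)) {
    e <- estimate_slippage(lens[[i]], n[i])
    p[i] <- e$p; q[i] <- e$q
  }
  out <- dists[, intersect(c("site_id", "chrom", "start", "motif", "n"),
                           names(dists)), drop = FALSE]
  out$p <- p; out$q <- q; out$m <- m
  attr(out, "site_hash") <- attr(dists, "site_hash")
  rownames(out) <- NULL
  out
}

# per-row list of per-read repeat lengths, whichever encoding is present
dist_lengths <- function(dists) {
  if (!is.null(dists$lengths)) return(dists$lengths)
  if (!is.null(dists$dist)) return(lapply(dists$dist, parse_dist_string))
  stop("distribution table needs a 'lengths' or 'dist' column")
}

# evaluate the log-likelihood surface on a (p, q) lattice and return the
# arg-max; the grid oracle used to check that the closed-form estimates
# sit at (or next to) the likelihood peak
grid_loglik_argmax <- function(y, n, p_grid, q_grid) {
  best <- c(p = NA_real_, q = NA_real_); best_ll <- -Inf
  for (p in p_grid) for (q in q_grid) {
    if (p + q > 1) next
    ll <- log_likelihood(y, n, p, q)
    if (ll > best_ll) { best_ll <- ll; best <- c(p = p, q = q) }
  }
  list(par = best, loglik = best_ll)
}

# run expr under a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
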