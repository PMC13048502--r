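# Emergent-coexistence (EC) metrics: excluding pairs, EC detection, analytic
# regime boundaries, and the min/max excluding-fraction bounds.
#
# A pair (i, j) is "excluding" when at least one of the two rescaled
# coefficients is stronger than self-regulation (A*_ij < -1 or A*_ji < -1):
# such a pair cannot coexist in isolation.  A stable community of S* >= 3
# species that harbours at least one excluding pair is an EC state.

#' Is a species pair exclusionary?
#'
#' True iff `a_ij < -1` or `a_ji < -1` (strict: coefficients exactly at -1
#' are not exclusionary; under continuous sampling the boundary has measure
#' zero).  Vectorized over both arguments.
#'
#' @param a_ij,a_ji the two directed interaction coefficients of the pair.
#' @return logical.
#' @export
is_excluding_pair <- function(a_ij, a_ji) {
  if (any(!is.finite(a_ij)) || any(!is.finite(a_ji)))
    glv_error("coefficients must be finite", "glv_input_error")
  a_ij < -1 | a_ji < -1
}

# number of unordered pairs with at least one exclusionary coefficient
count_excluding_pairs <- function(A_star) {
  if (nrow(A_star) < 2) return(0L)
  m <- pmin(A_star, t(A_star))
  sum(m[upper.tri(m)] < -1)
}

#' Emergent-coexistence report for a community
#'
#' Counts the excluding pairs of a verified (feasible + stable) community,
#' the excluding fraction over all `S*(S*-1)/2` pairs, and the EC flag,
#' which by definition requires coexistence of at least three species in
#' addition to at least one excluding pair.
#'
#' @param community a `glv_community` with `feasible` and `stable` flags set.
#' @param require_verified error unless the community is flagged feasible
#'   and stable (default `TRUE`).
#' @return object of class `glv_ec_report`: list with `S_star`,
#'   `n_excluding_pairs`, `fraction_excluding`, `is_ec`.
#' @export
ec_report <- function(community, require_verified = TRUE) {
  if (!inherits(community, "glv_community"))
    glv_error("`community` must be a glv_community", "glv_input_error")
  if (require_verified &&
      !(isTRUE(community$feasible) && isTRUE(community$stable)))
    glv_error("community has not been verified feasible and stable",
              "glv_state_error")
  S_star <- length(community$pool_indices)
  n_excl <- count_excluding_pairs(community$A_star)
  n_pairs <- S_star * (S_star - 1) / 2
  if (S_star == 2 && n_excl > 0)
    warning("two-species stable state with an exclusionary pair: inconsistent",
            call. = FALSE)
  structure(list(
    S_star = S_star,
    n_excluding_pairs = n_excl,
    fraction_excluding = if (n_pairs > 0) n_excl / n_pairs else NA_real_,
    is_ec = S_star >= 3 && n_excl >= 1
  ), class = "glv_ec_report")
}

#' @export
print.glv_ec_report <- function(x, ...) {
  cat(sprintf("EC report: S* = %d, excluding pairs = %d (fraction %.3f), EC = %s\n",
              x$S_star, x$n_excluding_pairs, x$fraction_excluding, x$is_ec))
  invisible(x)
}

# probability that a single Gaussian coefficient is exclusionary
p_exclusionary <- function(mu, sigma) {
  t <- (1 + mu) / sigma
  p <- stats::pnorm(-t)
  if (sigma == 0) p <- as.numeric(mu < -1) + 0.5 * (mu == -1)
  p
}

#' Analytic boundaries of the EC regime in the (mu, sigma) plane
#'
#' Two necessary conditions delimit where EC can occur in a pool of `S`
#' species with Gaussian interactions.  `sigma1c(mu)` is the smallest sigma
#' at which at least one of the `S(S-1)` pool coefficients is expected to be
#' exclusionary, from
#' `P = 1 - (1 - Phi(-(1+mu)/sigma))^(S(S-1))` crossing `crossing_level`.
#' `sigma2c(mu)` is the largest sigma at which at least one mutually
#' non-exclusionary pair remains (both coefficients > -1) to sustain an
#' excluded species: `1 - (1 - q)^(S(S-1)/2)` with
#' `q = Phi((1+mu)/sigma)^2`.  Both are located by bisection; a boundary
#' with no crossing on `(0, sigma_max]` is reported as `NA` (absent).
#'
#' @param S pool size (>= 3).
#' @param mu_grid numeric vector of mean interaction strengths.
#' @param crossing_level probability level defining the "sharp transition"
#'   (default 0.5).
#' @param sigma_max upper end of the bisection interval.
#' @return data.frame with columns `mu`, `sigma1c`, `sigma2c`.
#' @export
regime_boundaries <- function(S, mu_grid, crossing_level = 0.5,
                              sigma_max = 2) {
  if (S < 3) glv_error("`S` must be >= 3", "glv_config_error")
  if (crossing_level <= 0 || crossing_level >= 1)
    glv_error("`crossing_level` must lie in (0, 1)", "glv_config_error")
  if (any(!is.finite(mu_grid)))
    glv_error("`mu_grid` must be finite", "glv_input_error")
  n_dir <- S * (S - 1)
  n_pair <- n_dir / 2
  p_excl <- function(mu, sigma) 1 - (1 - p_exclusionary(mu, sigma))^n_dir
  p_coex <- function(mu, sigma)
    1 - (1 - (1 - p_exclusionary(mu, sigma))^2)^n_pair

  bisect <- function(f, lo, hi, level, iter = 80) {
    # locate the level crossing of a monotone f on [lo, hi]; the direction
    # of monotonicity is detected from the endpoints (the coexisting-pair
    # probability rises with sigma below mu = -1 and falls above it).
    # No crossing inside the interval -> boundary absent (NA).
    flo <- f(lo); fhi <- f(hi)
    if ((flo >= level) == (fhi >= level)) return(NA_real_)
    increasing_in_level <- fhi >= level
    for (it in seq_len(iter)) {
      mid <- (lo + hi) / 2
      ok <- f(mid) >= level
      if (ok == increasing_in_level) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }

  eps <- 1e-8
  s1 <- s2 <- numeric(length(mu_grid))
  for (i in seq_along(mu_grid)) {
    mu <- mu_grid[i]
    s1[i] <- if (p_excl(mu, eps) >= crossing_level) 0
             else bisect(function(s) p_excl(mu, s), eps, sigma_max,
                         level = crossing_level)
    s2[i] <- bisect(function(s) p_coex(mu, s), eps, sigma_max,
                    level = crossing_level)
    if (!is.na(s1[i]) && s1[i] <= 2 * eps) s1[i] <- 0
  }
  data.frame(mu = mu_grid, sigma1c = s1, sigma2c = s2)
}

#' Minimum excluding-pair fraction of an EC community
#'
#' One excluding pair over all `S*(S*-1)/2` pairs: the generic lower bound
#' attained by every EC state.
#'
#' @param S_star community size (>= 3; EC is undefined below 3 species).
#' @return `2 / (S_star * (S_star - 1))`.
#' @export
min_excluding_fraction <- function(S_star) {
  if (any(S_star < 3))
    glv_error("EC requires at least three coexisting species",
              "glv_domain_error")
  2 / (S_star * (S_star - 1))
}

#' Estimate the maximum stable diversity for pool statistics (mu, sigma)
#'
#' Moderate-size estimate of the largest community that pool statistics
#' `(mu, sigma)` can keep feasible and stable.  The default (`"clique"`)
#' notes that stable states in the multistability regime track the maximal
#' cliques of the pairwise-coexistence network: a pair coexists in isolation
#' with probability `p = Phi((1+mu)/sigma)^2`, so the coexistence network is
#' Erdős–Rényi and its maximum clique is approximately
#' `2 * log(S_pool) / log(1/p)`, capped at the pool size.  The `"may"`
#' variant inverts the random-matrix bulk criterion
#' `sqrt(S*/2) sigma < 1 + mu` instead; it collapses for `mu <= -1` and is
#' kept only for comparison.  The estimate is continuous; round it when an
#' integer community size is needed.  This function is the single swap point
#' for refined maximum-diversity formulas.
#'
#' @param mu,sigma pool interaction statistics (vectorized over `mu` and
#'   `sigma` jointly).
#' @param S_pool pool size (cap and network size; default 80).
#' @param method `"clique"` (default) or `"may"`.
#' @return numeric estimate(s) of the maximum stable diversity, in
#'   `[1, S_pool]`.
#' @export
max_stable_diversity <- function(mu, sigma, S_pool = 80,
                                 method = c("clique", "may")) {
  method <- match.arg(method)
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (method == "clique") {
      p <- (1 - p_exclusionary(mu[i], sigma[i]))^2
      out[i] <- if (p >= 1) S_pool
                else if (p <= 0) 1
                else min(S_pool, max(1, 2 * log(S_pool) / log(1 / p)))
    } else {
      t <- if (sigma[i] > 0) (1 + mu[i]) / sigma[i]
           else sign(1 + mu[i]) * Inf
      out[i] <- min(S_pool, max(1, 2 * t^2))
      if (!is.finite(t) && t > 0) out[i] <- S_pool
      if (t <= 0) out[i] <- 1
    }
  }
  out
}

#' Upper bound on diversity and excluding-pair fraction for (mu, sigma)
#'
#' Combines (i) the maximum stable diversity estimate
#' ([max_stable_diversity()]) and (ii) the pool fraction of exclusionary
#' pairs `f_max = 1 - Phi((1+mu)/sigma)^2` (probability that at least one of
#' the two directed coefficients of a pair is below -1).  The bound assumes
#' surviving communities are statistically no more competitive than the
#' pool; stable states more competitive than the pool are rare but possible,
#' so the bound is a heuristic envelope, not a theorem.  Sweeping a
#' `(mu, sigma)` grid traces the decaying maximum-fraction envelope against
#' community size.
#'
#' @param mu,sigma pool interaction statistics.
#' @param S_pool pool size (default 80).
#' @param method forwarded to [max_stable_diversity()].
#' @return list with `S_star_max` (continuous estimate) and `fraction_max`.
#' @export
max_excluding_fraction_bound <- function(mu, sigma, S_pool = 80,
                                         method = "clique") {
  if (any(sigma < 0)) glv_error("`sigma` must be >= 0", "glv_config_error")
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  f <- 1 - (1 - vapply(seq_len(n), function(i)
    p_exclusionary(mu[i], sigma[i]), 0))^2
  list(S_star_max = max_stable_diversity(mu, sigma, S_pool, method),
       fraction_max = f)
}

#' Closed-form maximum excluding-fraction envelope
#'
#' Eliminating the pairwise-coexistence probability between the clique
#' estimate of [max_stable_diversity()] and the pool pair fraction gives the
#' envelope directly as a function of community size:
#' `f(S*) = 1 - S_pool^(-2 / S*)`.
#'
#' @param S_star community size(s).
#' @param S_pool pool size (default 80).
#' @return the maximum excluding-pair fraction at each `S_star`.
#' @export
excluding_fraction_envelope <- function(S_star, S_pool = 80) {
  1 - S_pool^(-2 / S_star)
}
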