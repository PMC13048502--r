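# Algebraic equilibria, feasibility, linear stability, and direct sampling of
# stable communities from a pool.
#
# At an interior equilibrium of the rescaled GLV model, relative yields solve
# (I - A*) x* = 1.  A candidate community is feasible when every component of
# x* is strictly positive, and linearly stable when every eigenvalue of the
# Jacobian J (J[i,j] = r_i x*_i A*[i,j] for i != j, J[i,i] = -r_i x*_i) has
# negative real part.  Equilibria do not depend on growth rates r; r only
# scales the Jacobian rows and the transient.

#' Solve the interior equilibrium of a community
#'
#' Returns the relative-yield vector `x*` solving `(I - A*) x* = 1` (vector
#' of ones).  No positivity is required at this stage; feasibility is a
#' separate test ([is_feasible()]).
#'
#' @param A_star square interaction submatrix with zero diagonal.
#' @return numeric equilibrium vector.
#' @export
solve_equilibrium <- function(A_star) {
  check_square_matrix(A_star, "A_star")
  n <- nrow(A_star)
  M <- diag(n) - A_star
  if (rcond(M) < 1e-14)
    glv_error("(I - A*) is numerically singular: degenerate equilibrium",
              "glv_singular_error")
  drop(solve(M, rep(1, n)))
}

#' Test feasibility of a community
#'
#' A community is feasible when all equilibrium abundances are strictly
#' positive.
#'
#' @param A_star square interaction submatrix with zero diagonal.
#' @return list with elements `feasible` (flag) and `x_star` (the
#'   equilibrium vector).
#' @export
is_feasible <- function(A_star) {
  x <- solve_equilibrium(A_star)
  list(feasible = all(x > 0), x_star = x)
}

#' Community Jacobian at equilibrium
#'
#' `J[i,j] = r_i x*_i A*[i,j]` for `i != j` and `J[i,i] = -r_i x*_i`, the
#' linearization of the rescaled GLV equations at the interior equilibrium.
#' (The alternative sign convention with negated off-diagonals is available
#' via `negate_offdiag = TRUE`; it is not the derivative of the model and is
#' provided for comparison only.)
#'
#' @param A_star square interaction submatrix with zero diagonal.
#' @param x_star equilibrium abundances (> 0).
#' @param r_star growth rates (recycled; default 1).
#' @param negate_offdiag use the negated off-diagonal variant.
#' @return the Jacobian matrix.
#' @export
glv_jacobian <- function(A_star, x_star, r_star = 1, negate_offdiag = FALSE) {
  check_square_matrix(A_star, "A_star")
  n <- nrow(A_star)
  if (length(x_star) != n)
    glv_error("`x_star` length must match `A_star`", "glv_input_error")
  if (any(x_star <= 0))
    glv_error("`x_star` must be strictly positive", "glv_input_error")
  r_star <- rep_len(r_star, n)
  off <- if (negate_offdiag) -A_star else A_star
  J <- (r_star * x_star) * off
  diag(J) <- -r_star * x_star
  J
}

#' Linear stability report for a Jacobian
#'
#' Computes the full spectrum, the stability flag (all real parts below
#' `-tol`; a spectral abscissa within `tol` of zero is marginal and counts
#' as unstable), the monic characteristic-polynomial coefficients
#' `C_1 ... C_n` (convention `lambda^n + C1 lambda^(n-1) + ... + Cn`,
#' assembled from the eigenvalues for numerical robustness), the second
#' Routh-Hurwitz quantity `Lambda2 = C1*C2 - C3` (defined for n >= 3), and,
#' when the community interaction statistics are supplied, the random-matrix
#' instability threshold [may_threshold()] together with a flag marking
#' communities that are stable although the threshold predicts instability.
#'
#' @param J square Jacobian matrix.
#' @param mu_star,sigma_star optional measured mean/sd of the community's
#'   off-diagonal interactions, used for the May-threshold diagnostic.
#' @param tol stability tolerance on the spectral abscissa (default 1e-9).
#' @param may_literal forward to [may_threshold()].
#' @return object of class `glv_stability`: list with `eigenvalues`,
#'   `stable`, `marginal`, `char_coeffs`, `lambda2`, `may_mu_c`,
#'   `violates_may`.
#' @export
is_linearly_stable <- function(J, mu_star = NULL, sigma_star = NULL,
                               tol = 1e-9, may_literal = FALSE) {
  check_square_matrix(J, "J")
  n <- nrow(J)
  ev <- eigen(J, only.values = TRUE)$values
  mx <- max(Re(ev))
  stable <- mx < -tol
  marginal <- abs(mx) <= tol
  # char poly from roots: prod (lambda - ev_k), descending powers
  p <- 1
  for (lam in ev) p <- c(p, 0) - lam * c(0, p)
  coeffs <- Re(p)[-1]
  lambda2 <- if (n >= 3) coeffs[1] * coeffs[2] - coeffs[3] else NA_real_
  may_mu_c <- violates_may <- NA
  if (!is.null(sigma_star) && n >= 2) {
    may_mu_c <- may_threshold(n, sigma_star, literal = may_literal)
    if (!is.null(mu_star)) violates_may <- stable && mu_star < may_mu_c
  }
  structure(list(eigenvalues = ev, stable = stable, marginal = marginal,
                 char_coeffs = coeffs, lambda2 = lambda2,
                 may_mu_c = may_mu_c, violates_may = violates_may,
                 tol = tol),
            class = "glv_stability")
}

#' @export
print.glv_stability <- function(x, ...) {
  cat(sprintf("GLV stability report: %s (max Re(lambda) = %.3g), Lambda2 = %.3g\n",
              if (x$stable) "stable" else if (x$marginal) "marginal" else
                "unstable",
              max(Re(x$eigenvalues)), x$lambda2))
  invisible(x)
}

#' Random-matrix instability threshold on mean interaction strength
#'
#' For a community of `S_star` species with interaction heterogeneity
#' `sigma_star`, classical random-matrix arguments expect instability once
#' the eigenvalue bulk of `A*` crosses self-regulation, i.e. when the mean
#' interaction strength falls below
#' `mu_c = sqrt(S_star / 2) * sigma_star - 1` (equivalently, stability
#' expects `1 + mu* > sqrt(S*/2) sigma*`).  Both readings coincide at
#' `sigma_star = 0` where `mu_c = -1`.  Moderately sized communities with
#' strong competition routinely remain stable below this threshold; the
#' threshold is a diagnostic, not a constraint.
#'
#' @param S_star community size (>= 2).
#' @param sigma_star off-diagonal standard deviation (>= 0).
#' @param literal use the literal product form `(S_star / 2) * sigma_star - 1`
#'   instead of the square-root scaling.
#' @return the threshold `mu_c`.
#' @export
may_threshold <- function(S_star, sigma_star, literal = FALSE) {
  if (S_star < 2) glv_error("`S_star` must be >= 2", "glv_config_error")
  if (sigma_star < 0) glv_error("`sigma_star` must be >= 0",
                                "glv_config_error")
  if (literal) (S_star / 2) * sigma_star - 1
  else sqrt(S_star / 2) * sigma_star - 1
}

# Internal constructor for community states shared by the dynamics and
# subset-sampling paths.  mu_star / sigma_star are always recomputed from
# A_star, never cached from elsewhere.
community_state <- function(pool_indices, A_star, x_star, r_star,
                            origin = c("dynamics", "sampled"),
                            feasible = NA, stable = NA,
                            stability = NULL) {
  origin <- match.arg(origin)
  od <- offdiag(A_star)
  structure(list(
    pool_indices = as.integer(pool_indices),
    x_star = x_star,
    A_star = A_star,
    r_star = rep_len(r_star, nrow(A_star)),
    feasible = feasible,
    stable = stable,
    mu_star = if (length(od)) mean(od) else NA_real_,
    sigma_star = if (length(od) > 1) stats::sd(od) else NA_real_,
    origin = origin,
    stability = stability
  ), class = "glv_community")
}

#' @export
print.glv_community <- function(x, ...) {
  cat(sprintf(
    "GLV community (%s): S* = %d, mu* = %.3f, sigma* = %.3f, feasible = %s, stable = %s\n",
    x$origin, length(x$pool_indices), x$mu_star, x$sigma_star,
    x$feasible, x$stable))
  invisible(x)
}

# Verify a candidate species subset of a pool: solve, check feasibility and
# stability, and return a community state or NULL.
verify_subset <- function(pool, idx, origin = "sampled") {
  A_star <- pool$A[idx, idx, drop = FALSE]
  n <- length(idx)
  M <- diag(n) - A_star
  if (rcond(M) < 1e-14) return(NULL)
  x <- drop(solve(M, rep(1, n)))
  if (!all(x > 0)) return(NULL)
  r_star <- pool$r[idx]
  rep <- is_linearly_stable(glv_jacobian(A_star, x, r_star))
  if (!rep$stable) return(NULL)
  community_state(idx, A_star, x, r_star, origin = origin,
                  feasible = TRUE, stable = TRUE, stability = rep)
}

#' Sample feasible and linearly stable communities from a pool
#'
#' Uniformly samples species subsets of the requested sizes (without
#' replacement within a draw, with replacement across draws) and retains
#' those that are feasible and linearly stable.  This is the algebraic
#' shortcut to stable states that avoids integrating the full dynamics.
#'
#' @param pool a `glv_pool` from [sample_matrix()].
#' @param sizes integer vector of community sizes `S*` to sample.
#' @param n_samples number of random subsets drawn per size.
#' @param seed RNG seed (`NULL` continues the current stream).
#' @param dedup drop duplicate subsets (default `FALSE`: naive uniform
#'   sampling keeps duplicates).
#' @return list of `glv_community` objects with `origin = "sampled"`.
#' @export
sample_stable_subsets <- function(pool, sizes, n_samples, seed = NULL,
                                  dedup = FALSE) {
  S <- nrow(pool$A)
  if (any(sizes < 1 | sizes > S))
    glv_error("every requested size must lie in [1, S]", "glv_config_error")
  if (n_samples < 0)
    glv_error("`n_samples` must be >= 0", "glv_config_error")
  with_seed(seed, {
    out <- vector("list", 0L)
    seen <- new.env(parent = emptyenv())
    for (k in sizes) {
      for (i in seq_len(n_samples)) {
        idx <- sort(sample.int(S, k))
        if (dedup) {
          key <- paste(idx, collapse = ",")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
        }
        cm <- verify_subset(pool, idx)
        if (!is.null(cm)) out[[length(out) + 1L]] <- cm
      }
    }
    out
  })
}

#' Enumerate all feasible + stable subsets of a small pool
#'
#' Brute-force oracle over all `2^S - 1` non-empty subsets; intended for
#' pools with `S <= 12`.
#'
#' @param pool a `glv_pool`.
#' @param min_size,max_size size limits on enumerated subsets.
#' @return list of `glv_community` objects.
#' @export
enumerate_stable_subsets <- function(pool, min_size = 1,
                                     max_size = nrow(pool$A)) {
  S <- nrow(pool$A)
  if (S > 12)
    glv_error("exhaustive enumeration is limited to S <= 12",
              "glv_config_error")
  out <- vector("list", 0L)
  for (k in seq(max(1, min_size), min(S, max_size))) {
    combs <- utils::combn(S, k)
    for (j in seq_len(ncol(combs))) {
      cm <- verify_subset(pool, combs[, j])
      if (!is.null(cm)) out[[length(out) + 1L]] <- cm
    }
  }
  out
}
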