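# Indirect-effect metrics: net effects, Neumann expansion, collectivity phi,
# condition number kappa, their random-matrix estimates, and the two
# prediction experiments (measurement error; assembly from pairs).
#
# The net effect of species j on the equilibrium abundance of species i is
# element (i, j) of (I - A*)^-1, the sum of all chains of direct effects.
# The Neumann series I + A* + A*^2 + ... converges to that inverse exactly
# when the spectral radius phi of A* is below 1; phi >= 1 marks the
# "collective" regime where pairwise knowledge stops predicting community
# outcomes.

#' Net-effect matrix
#'
#' Returns `(I - A*)^-1`; element `(i, j)` is the net (direct plus all
#' indirect) effect of species `j` on the equilibrium abundance of species
#' `i`.  Even in fully competitive communities, chains through an even
#' number of species make some net effects positive.
#'
#' @param A_star square interaction matrix with zero diagonal.
#' @return square matrix.
#' @export
net_effects <- function(A_star) {
  check_square_matrix(A_star, "A_star")
  n <- nrow(A_star)
  M <- diag(n) - A_star
  if (rcond(M) < 1e-14)
    glv_error("(I - A*) is numerically singular", "glv_singular_error")
  solve(M)
}

#' Partial sum of the Neumann series
#'
#' `sum_{k=0..order} (A*)^k`, the truncation of
#' `(I - A*)^-1 = I + A* + (A*)^2 + ...`.  Row sums of the partial sum give
#' the corresponding truncated expansion of the equilibrium abundances
#' `x* = (I - A*)^-1 1`.
#'
#' @param A_star square interaction matrix with zero diagonal.
#' @param order truncation order (>= 0).
#' @return square matrix (the partial sum); attribute `"x_partial"` carries
#'   the row-sum abundance expansion.
#' @export
neumann_partial_sum <- function(A_star, order) {
  check_square_matrix(A_star, "A_star")
  if (order < 0) glv_error("`order` must be >= 0", "glv_input_error")
  n <- nrow(A_star)
  acc <- diag(n)
  pw <- diag(n)
  for (k in seq_len(order)) {
    pw <- pw %*% A_star
    acc <- acc + pw
  }
  attr(acc, "x_partial") <- rowSums(acc)
  acc
}

#' Collectivity: spectral radius of the interaction matrix
#'
#' The modulus of the largest-modulus eigenvalue of `A*` (zero-diagonal
#' convention).  `phi < 1` is the convergence condition of the Neumann
#' expansion of net effects.
#'
#' @param A_star square interaction matrix.
#' @return the spectral radius `phi`.
#' @export
collectivity_phi <- function(A_star) {
  check_square_matrix(A_star, "A_star")
  if (nrow(A_star) == 0) return(0)
  max(Mod(eigen(A_star, only.values = TRUE)$values))
}

#' Random-matrix estimate of collectivity
#'
#' For a fully connected random matrix with off-diagonal mean `mu_star` and
#' sd `sigma_star`, the spectral radius is governed by the larger of the
#' mean outlier `(S*-1)|mu*|` and the fluctuation bulk
#' `sqrt(S*-1) * sigma_star` (circular-law scaling).  The linear-in-S
#' fluctuation variant `(S*-1) * sigma_star` is available behind
#' `literal = TRUE` for comparison with the non-square-root convention.
#'
#' @param S_star community size (>= 2).
#' @param mu_star,sigma_star off-diagonal mean and sd.
#' @param literal use `(S_star - 1) * sigma_star` for the fluctuation term.
#' @return the estimate `phi_hat`.
#' @export
phi_estimate <- function(S_star, mu_star, sigma_star, literal = FALSE) {
  if (any(S_star < 2)) glv_error("`S_star` must be >= 2", "glv_config_error")
  fluct <- if (literal) (S_star - 1) * sigma_star
           else sqrt(S_star - 1) * sigma_star
  pmax((S_star - 1) * abs(mu_star), fluct)
}

#' Collectivity envelope over a (mu, sigma) grid
#'
#' Extremizes the random-matrix estimate [phi_estimate()] over the grid
#' points whose maximum stable diversity ([max_stable_diversity()]) reaches
#' `S_star`, producing the min/max collectivity attainable at each
#' community size.
#'
#' @param S_star community size.
#' @param mu_grid,sigma_grid numeric grids of pool statistics.
#' @param S_pool pool size for the attainability screen.
#' @param literal forwarded to [phi_estimate()].
#' @return named numeric vector `c(phi_min, phi_max)`.
#' @export
phi_bounds <- function(S_star, mu_grid, sigma_grid, S_pool = 80,
                       literal = FALSE) {
  if (S_star < 2) glv_error("`S_star` must be >= 2", "glv_config_error")
  grid <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  ok <- max_stable_diversity(grid$mu, grid$sigma, S_pool) >= S_star
  if (!any(ok)) return(c(phi_min = NA_real_, phi_max = NA_real_))
  est <- phi_estimate(S_star, grid$mu[ok], grid$sigma[ok], literal = literal)
  c(phi_min = min(est), phi_max = max(est))
}

#' Condition number of the community matrix
#'
#' Ratio of largest to smallest singular value.  The default target is
#' `(I - A*)`, the operator inverted to obtain equilibrium abundances, so
#' `kappa` measures how measurement errors in `A*` are amplified in
#' predicted abundances; `kappa = 1` (empty matrix) is the best case.  The
#' raw interaction matrix is selectable via `target = "A"`.
#'
#' @param A_star square interaction matrix with zero diagonal.
#' @param target `"I_minus_A"` (default) or `"A"`.
#' @return the condition number (`Inf` when the smallest singular value is
#'   zero; reported, not thrown).
#' @export
condition_number <- function(A_star, target = c("I_minus_A", "A")) {
  check_square_matrix(A_star, "A_star")
  target <- match.arg(target)
  M <- if (target == "I_minus_A") diag(nrow(A_star)) - A_star else A_star
  if (all(M == 0))
    glv_error("target matrix is zero", "glv_input_error")
  s <- svd(M, nu = 0, nv = 0)$d
  if (min(s) == 0) return(Inf)
  max(s) / min(s)
}

#' Lower bound on the condition number of EC communities
#'
#' The smallest condition number attainable by communities of size `S_star`
#' whose statistics are compatible with EC (an excluding pair is attainable:
#' pool fraction of exclusionary pairs at least one pair's worth).  The
#' default Monte-Carlo method samples random interaction matrices at the
#' EC-compatible grid points, keeps those that contain an exclusionary
#' element and are feasible and stable, and returns the empirical minimum
#' of `kappa(I - A*)`; the `"rmt"` method uses mean-outlier / bulk-edge
#' singular-value estimates instead.  Either way this function is a
#' calibratable envelope, isolated so a refined closed form can replace it.
#'
#' @param S_star community size (>= 3).
#' @param mu_grid,sigma_grid grids of pool statistics to scan.
#' @param method `"mc"` (default) or `"rmt"`.
#' @param n_mc matrices sampled per grid point for the Monte-Carlo method.
#' @param seed RNG seed.
#' @return the lower-bound estimate of kappa at `S_star`.
#' @export
kappa_min_bound <- function(S_star, mu_grid = seq(-1.4, -0.2, by = 0.2),
                            sigma_grid = seq(0.1, 0.9, by = 0.2),
                            method = c("mc", "rmt"), n_mc = 200,
                            seed = NULL) {
  if (S_star < 3) glv_error("`S_star` must be >= 3", "glv_config_error")
  method <- match.arg(method)
  grid <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  f_pair <- 1 - (1 - vapply(seq_len(nrow(grid)), function(i)
    p_exclusionary(grid$mu[i], grid$sigma[i]), 0))^2
  compatible <- f_pair >= min_excluding_fraction(S_star)
  if (!any(compatible)) return(NA_real_)
  grid <- grid[compatible, , drop = FALSE]
  if (method == "rmt") {
    # singular values of I - A*: mean outlier 1 + (S*-1)|mu|, bulk edges
    # 1 + mu -/+ sqrt(S*-1) sigma; min kappa over compatible statistics.
    sM <- pmax(1 + (S_star - 1) * abs(grid$mu),
               abs(1 + grid$mu) + sqrt(S_star - 1) * grid$sigma)
    sm <- pmax(1e-12, 1 + grid$mu - sqrt(S_star - 1) * grid$sigma)
    return(min(pmax(1, sM / sm)))
  }
  with_seed(seed, {
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      for (m in seq_len(n_mc)) {
        A <- matrix(stats::rnorm(S_star^2, grid$mu[g], grid$sigma[g]),
                    S_star, S_star)
        diag(A) <- 0
        if (count_excluding_pairs(A) < 1) next
        cm <- verify_subset(list(A = A, r = rep(1, S_star)),
                            seq_len(S_star))
        if (is.null(cm)) next
        best <- min(best, condition_number(A))
      }
    }
    if (is.finite(best)) best else NA_real_
  })
}

#' Correlation between direct and net effects
#'
#' Pearson correlation over the paired off-diagonal elements of `A*`
#' (direct effects) and `(I - A*)^-1` (net effects), its two-sided p-value
#' (standard t transform), and the fraction of off-diagonal net effects
#' that are positive.  At low collectivity net effects track direct effects
#' almost perfectly; as phi crosses 1 the two decouple.
#'
#' @param A_star square interaction matrix, at least 3 species.
#' @return list with `pearson_r`, `p_value`, `frac_positive_net` (`NA`
#'   correlation with a warning when either side has zero variance).
#' @export
direct_net_correlation <- function(A_star) {
  check_square_matrix(A_star, "A_star")
  if (nrow(A_star) < 3)
    glv_error("`A_star` must have at least 3 species", "glv_config_error")
  N <- net_effects(A_star)
  x <- offdiag(A_star)
  y <- offdiag(N)
  frac_pos <- mean(y > 0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(pearson_r = NA_real_, p_value = NA_real_,
                frac_positive_net = frac_pos))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       frac_positive_net = frac_pos)
}

#' Collectivity report for a community
#'
#' Bundles the indirect-effect metrics of one community: collectivity
#' `phi`, condition numbers of both targets, the direct-vs-net correlation
#' and positive-net-effect fraction, and the Neumann convergence flag
#' (`phi < 1`).
#'
#' @param community a `glv_community` (or a bare interaction matrix).
#' @return object of class `glv_collectivity_report`.
#' @export
collectivity_report <- function(community) {
  A <- if (inherits(community, "glv_community")) community$A_star
       else community
  check_square_matrix(A, "A_star")
  phi <- collectivity_phi(A)
  corr <- if (nrow(A) >= 3) direct_net_correlation(A)
          else list(pearson_r = NA_real_, p_value = NA_real_,
                    frac_positive_net = mean(offdiag(net_effects(A)) > 0))
  structure(list(
    phi = phi,
    kappa = condition_number(A, "I_minus_A"),
    kappa_A = if (all(A == 0)) NA_real_ else condition_number(A, "A"),
    pearson_direct_net = corr$pearson_r,
    p_value = corr$p_value,
    frac_positive_net = corr$frac_positive_net,
    neumann_converges = phi < 1
  ), class = "glv_collectivity_report")
}

#' @export
print.glv_collectivity_report <- function(x, ...) {
  cat(sprintf(
    "Collectivity report: phi = %.3f (Neumann %s), kappa(I-A*) = %.3f, r(direct, net) = %.3f\n",
    x$phi, if (x$neumann_converges) "converges" else "diverges",
    x$kappa, x$pearson_direct_net))
  invisible(x)
}

# perturb the off-diagonal coefficients of A with measurement noise
perturb_matrix <- function(A, rel_error, noise = "multiplicative") {
  off <- row(A) != col(A)
  n <- sum(off)
  if (noise == "multiplicative") {
    A[off] <- A[off] * (1 + rel_error * stats::rnorm(n))
  } else {
    A[off] <- A[off] + rel_error * stats::rnorm(n)
  }
  A
}

#' Measurement-error coexistence-prediction experiment
#'
#' How reliably does an imperfectly measured interaction matrix predict
#' multispecies coexistence?  Communities with condition number
#' `kappa(I - A*)` within a tolerance band of `kappa_target` are selected;
#' each replicate perturbs every off-diagonal coefficient with multiplicative
#' Gaussian noise of relative sd `rel_error` (zero entries stay zero), then
#' asks whether the perturbed matrix still predicts coexistence of the full
#' set (feasibility + linear stability).  Since the unperturbed communities
#' coexist by construction, the success fraction is the fraction of
#' replicates whose prediction matches that truth.
#'
#' @param communities list of verified `glv_community` objects (the
#'   selection pool).
#' @param kappa_target centre of the condition-number band.
#' @param rel_error relative measurement error (>= 0; default 0.1).
#' @param n_reps stochastic replicates (>= 1); replicates cycle over the
#'   selected communities.
#' @param band half-width of the kappa band as a fraction of
#'   `kappa_target` (default 0.2).
#' @param noise `"multiplicative"` (default) or `"additive"` (absolute sd
#'   `rel_error`).
#' @param seed RNG seed.
#' @return list with `success_fraction`, `n_reps`, `n_communities`,
#'   `kappa_band`.
#' @export
prediction_error_experiment <- function(communities, kappa_target,
                                        rel_error = 0.1, n_reps = 500,
                                        band = 0.2,
                                        noise = c("multiplicative",
                                                  "additive"),
                                        seed = NULL) {
  noise <- match.arg(noise)
  if (rel_error < 0) glv_error("`rel_error` must be >= 0",
                               "glv_config_error")
  if (n_reps < 1) glv_error("`n_reps` must be >= 1", "glv_config_error")
  kap <- vapply(communities, function(cm) condition_number(cm$A_star), 0)
  lo <- kappa_target * (1 - band)
  hi <- kappa_target * (1 + band)
  sel <- which(kap >= lo & kap <= hi)
  if (!length(sel))
    glv_error(sprintf("no community with kappa in [%.2f, %.2f]", lo, hi),
              "glv_state_error")
  with_seed(seed, {
    succ <- logical(n_reps)
    for (i in seq_len(n_reps)) {
      cm <- communities[[sel[(i - 1L) %% length(sel) + 1L]]]
      Ap <- perturb_matrix(cm$A_star, rel_error, noise)
      ok <- FALSE
      feas <- tryCatch(is_feasible(Ap),
                       glv_singular_error = function(e) NULL)
      if (!is.null(feas) && feas$feasible) {
        ok <- is_linearly_stable(
          glv_jacobian(Ap, feas$x_star, cm$r_star))$stable
      }
      succ[i] <- ok
    }
    list(success_fraction = mean(succ), n_reps = n_reps,
         n_communities = length(sel), kappa_band = c(lo, hi))
  })
}

#' Assembly-from-pairwise-coexistence experiment
#'
#' Tests the reductionist assembly rule: draw species sets whose every pair
#' coexists in isolation (no exclusionary coefficient between any two
#' members) and ask whether the full set is feasible and linearly stable.
#' Success rates are tabulated against the set's collectivity `phi`; the
#' rule degrades as phi grows.
#'
#' @param pool a `glv_pool`.
#' @param set_size community size to assemble (>= 3, <= pool size).
#' @param n_trials random sets drawn (sets with an excluding pair are
#'   counted as ineligible, not as failures).
#' @param seed RNG seed.
#' @param phi_breaks bin edges for the phi table.
#' @return list with `table` (data.frame `phi_bin, n_trials, success_rate`),
#'   `n_eligible`, and the per-set `phi` and `success` vectors.
#' @export
assembly_from_pairs_experiment <- function(pool, set_size, n_trials,
                                           seed = NULL,
                                           phi_breaks = c(0, 0.5, 1, 1.5,
                                                          Inf)) {
  S <- nrow(pool$A)
  if (set_size < 3) glv_error("`set_size` must be >= 3", "glv_config_error")
  if (set_size > S)
    glv_error("`set_size` exceeds the pool size", "glv_config_error")
  with_seed(seed, {
    phi <- numeric(0)
    succ <- logical(0)
    for (i in seq_len(n_trials)) {
      idx <- sample.int(S, set_size)
      A_star <- pool$A[idx, idx, drop = FALSE]
      if (count_excluding_pairs(A_star) > 0) next  # ineligible set
      phi <- c(phi, collectivity_phi(A_star))
      succ <- c(succ, !is.null(verify_subset(pool, idx)))
    }
    if (!length(phi)) {
      tab <- data.frame(phi_bin = character(0), n_trials = integer(0),
                        success_rate = numeric(0))
    } else {
      bin <- cut(phi, phi_breaks, include.lowest = TRUE)
      tab <- data.frame(
        phi_bin = levels(bin),
        n_trials = as.integer(table(bin)),
        success_rate = as.numeric(tapply(succ, bin, mean))
      )
    }
    list(table = tab, n_eligible = length(phi), phi = phi, success = succ)
  })
}
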