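# GLV trajectory integration and extraction of surviving communities.
#
# The integration protocol mirrors the standard ensemble experiment: start
# from random initial relative yields, integrate for a long transient t1,
# then a further stationarity window t2, hard-zeroing any species whose
# relative yield falls below the extinction threshold.  A state is
# stationary when no surviving abundance moved appreciably across the
# window; unbounded growth (the mutualistic outgrowth regime) is flagged as
# diverged.

glv_rhs <- function(t, x, parms) {
  x <- pmax(x, 0)
  x[parms$dead] <- 0
  dx <- parms$r * x * (1 - x + drop(parms$A %*% x))
  dx[parms$dead] <- 0
  # freeze unbounded growth at the divergence cap: keeps the solver on
  # finite-time-blowup trajectories well-behaved until the checkpoint,
  # where the capped state is classified as diverged
  over <- x >= parms$cap & dx > 0
  dx[over] <- 0
  list(dx)
}

#' Integrate GLV dynamics with extinction threshold
#'
#' Integrates `dx_i/dt = r_i x_i (1 - x_i + sum_j A_ij x_j)` with an
#' adaptive-step solver.  The time axis is split into checkpoints; at each
#' checkpoint any species below `extinction_threshold` is hard-zeroed for
#' the remainder of the run (its abundance and dynamics are removed).  After
#' `t1`, the system is integrated a further `t2` and declared stationary
#' when the maximum relative change of every surviving abundance over the
#' window is below `stationarity_tol`.  Any abundance exceeding
#' `divergence_cap` (or a solver blow-up at large state norm) yields status
#' `"diverged"`.
#'
#' @param pool a `glv_pool` from [sample_matrix()], or any list with
#'   elements `A` (zero-diagonal matrix) and `r`.
#' @param x0 non-negative initial relative yields (length S).
#' @param t1 transient duration (model-time units).
#' @param t2 stationarity window (model-time units).
#' @param extinction_threshold relative-yield extinction cutoff
#'   (0 < threshold < 1).
#' @param divergence_cap abundance above which the run is diverged (> 1).
#' @param stationarity_tol maximum tolerated relative change over the
#'   stationarity window.
#' @param checkpoint_dt spacing of extinction checkpoints.
#' @return object of class `glv_trajectory`: list with `times`, `abundances`
#'   (rows = stored time points), `status` in
#'   `{"stationary", "non_stationary", "diverged"}`, `final`, `x_t1`, and
#'   the protocol parameters.
#' @export
integrate_glv <- function(pool, x0, t1 = 3000, t2 = 100,
                          extinction_threshold = 1e-4,
                          divergence_cap = 1e6,
                          stationarity_tol = 1e-3,
                          checkpoint_dt = 50) {
  A <- pool$A
  check_square_matrix(A)
  S <- nrow(A)
  r <- rep_len(if (is.null(pool$r)) 1 else pool$r, S)
  if (length(x0) != S)
    glv_error("`x0` length must match the pool size", "glv_input_error")
  if (any(x0 < 0))
    glv_error("initial abundances must be non-negative", "glv_input_error")
  if (t1 <= 0 || t2 <= 0)
    glv_error("`t1` and `t2` must be positive", "glv_input_error")
  if (extinction_threshold <= 0 || extinction_threshold >= 1 ||
      divergence_cap <= 1)
    glv_error("require 0 < extinction_threshold < 1 < divergence_cap",
              "glv_input_error")

  parms <- new.env(parent = emptyenv())
  parms$A <- A
  parms$r <- r
  parms$dead <- x0 < extinction_threshold
  parms$cap <- divergence_cap

  state <- x0
  state[parms$dead] <- 0
  times <- 0
  traj <- matrix(state, nrow = 1)
  status <- NA_character_
  x_t1 <- NULL

  checkpoints <- function(from, to) {
    n <- max(1L, ceiling((to - from) / checkpoint_dt))
    seq(from, to, length.out = n + 1L)
  }

  advance <- function(tp) {
    # returns FALSE when integration must stop (divergence / failure)
    for (j in seq_len(length(tp) - 1L)) {
      out <- NULL
      # capture.output: the solver prints step-size diagnostics straight to
      # the console on finite-time blowup; those runs are classified below
      utils::capture.output(out <- tryCatch(
        suppressWarnings(deSolve::ode(
          y = state, times = c(tp[j], tp[j + 1L]), func = glv_rhs,
          parms = parms, method = "lsoda", rtol = 1e-8, atol = 1e-10
        )),
        error = function(e) NULL), type = "output")
      bad <- is.null(out) || nrow(out) < 2L ||
        any(!is.finite(out[nrow(out), -1L]))
      if (!bad) {
        y <- pmax(out[nrow(out), -1L], 0)
        if (any(y >= divergence_cap)) bad <- TRUE
      }
      if (bad) {
        big <- if (is.null(out)) max(state) else
          suppressWarnings(max(out[nrow(out), -1L], state, na.rm = TRUE))
        if (!is.finite(big) || big > sqrt(divergence_cap)) {
          status <<- "diverged"
          return(FALSE)
        }
        glv_error(sprintf(
          "integrator failure at t ~ %.1f (state norm %.3g)",
          tp[j + 1L], sqrt(sum(state^2))), "glv_numerical_error")
      }
      parms$dead <- parms$dead | y < extinction_threshold
      y[parms$dead] <- 0
      state <<- y
      times <<- c(times, tp[j + 1L])
      traj <<- rbind(traj, state)
    }
    TRUE
  }

  if (advance(checkpoints(0, t1))) {
    x_t1 <- state
    if (advance(checkpoints(t1, t1 + t2))) {
      delta <- abs(state - x_t1) / pmax(x_t1, extinction_threshold)
      status <- if (max(delta) < stationarity_tol) "stationary"
                else "non_stationary"
    }
  }

  structure(list(
    times = times, abundances = unname(traj), status = status,
    final = unname(state), x_t1 = unname(x_t1),
    t1 = t1, t2 = t2,
    extinction_threshold = extinction_threshold,
    divergence_cap = divergence_cap,
    stationarity_tol = stationarity_tol
  ), class = "glv_trajectory")
}

#' @export
print.glv_trajectory <- function(x, ...) {
  cat(sprintf("GLV trajectory: S = %d, status = %s, %d survivors at t = %g\n",
              ncol(x$abundances), x$status,
              sum(x$final > x$extinction_threshold), max(x$times)))
  invisible(x)
}

#' Extract the surviving community from a stationary trajectory
#'
#' Survivors are the species above the extinction threshold at the final
#' time.  The returned community carries the dynamical equilibrium
#' abundances, and its feasibility/stability flags are verified post hoc
#' with the algebraic machinery ([is_feasible()], [is_linearly_stable()]).
#'
#' @param trajectory a stationary `glv_trajectory`.
#' @param pool the `glv_pool` the trajectory was integrated from.
#' @return a `glv_community` with `origin = "dynamics"`.
#' @export
surviving_community <- function(trajectory, pool) {
  if (!inherits(trajectory, "glv_trajectory") ||
      !identical(trajectory$status, "stationary"))
    glv_error("`trajectory` must be a stationary glv_trajectory",
              "glv_state_error")
  surv <- which(trajectory$final > trajectory$extinction_threshold)
  if (!length(surv))
    glv_error("no surviving species", "glv_state_error")
  A_star <- pool$A[surv, surv, drop = FALSE]
  r_star <- rep_len(if (is.null(pool$r)) 1 else pool$r, nrow(pool$A))[surv]
  feas <- tryCatch(is_feasible(A_star), glv_singular_error = function(e) NULL)
  stable <- FALSE
  stab <- NULL
  if (!is.null(feas) && feas$feasible) {
    stab <- is_linearly_stable(glv_jacobian(A_star, feas$x_star, r_star))
    stable <- stab$stable
  }
  community_state(surv, A_star, trajectory$final[surv], r_star,
                  origin = "dynamics",
                  feasible = if (is.null(feas)) FALSE else feas$feasible,
                  stable = stable, stability = stab)
}

#' Run replicate GLV systems and tally outcomes
#'
#' For each replicate, draws a fresh interaction matrix from `spec` and
#' fresh initial conditions `x0 ~ Uniform[0, 1]^S`, integrates the dynamics
#' and classifies the outcome.  The tally counts stationary states with at
#' least three coexisting species, emergent-coexistence (EC) states among
#' them (at least one excluding pair), diverged runs, and non-stationary
#' runs.  Deterministic given `seed` (each replicate uses a counter-derived
#' sub-seed, so replicates are independent and reorderable).
#'
#' @param spec an [ensemble_spec()].
#' @param n_systems number of replicate systems (>= 1).
#' @param seed master RNG seed.
#' @param keep_communities return the surviving communities as well as the
#'   tally.
#' @inheritParams integrate_glv
#' @return list with `tally` (one-row data.frame: `mu, sigma, n_systems,
#'   n_stationary_3plus, n_ec, n_diverged, n_nonstationary, seed`) and,
#'   when `keep_communities`, the list of `glv_community` objects.
#' @export
run_replicates <- function(spec, n_systems, seed = NULL,
                           t1 = 3000, t2 = 100,
                           extinction_threshold = 1e-4,
                           divergence_cap = 1e6,
                           stationarity_tol = 1e-3,
                           checkpoint_dt = 50,
                           keep_communities = TRUE) {
  if (!inherits(spec, "glv_ensemble_spec"))
    glv_error("`spec` must be created by ensemble_spec()", "glv_config_error")
  if (n_systems < 1)
    glv_error("`n_systems` must be >= 1", "glv_config_error")
  n_3plus <- n_ec <- n_div <- n_nonstat <- 0L
  communities <- vector("list", 0L)
  for (k in seq_len(n_systems)) {
    res <- with_seed(spawn_seed(seed, k), {
      pool <- sample_matrix(spec, seed = NULL)
      x0 <- stats::runif(spec$S)
      traj <- integrate_glv(pool, x0, t1 = t1, t2 = t2,
                            extinction_threshold = extinction_threshold,
                            divergence_cap = divergence_cap,
                            stationarity_tol = stationarity_tol,
                            checkpoint_dt = checkpoint_dt)
      list(pool = pool, traj = traj)
    })
    st <- res$traj$status
    if (identical(st, "diverged")) {
      n_div <- n_div + 1L
    } else if (!identical(st, "stationary")) {
      n_nonstat <- n_nonstat + 1L
    } else {
      cm <- tryCatch(surviving_community(res$traj, res$pool),
                     glv_state_error = function(e) NULL)
      if (is.null(cm)) { n_nonstat <- n_nonstat + 1L; next }
      S_star <- length(cm$pool_indices)
      if (S_star >= 3) {
        n_3plus <- n_3plus + 1L
        if (count_excluding_pairs(cm$A_star) >= 1L) n_ec <- n_ec + 1L
      }
      if (keep_communities) communities[[length(communities) + 1L]] <- cm
    }
  }
  tally <- data.frame(
    mu = spec$mu, sigma = spec$sigma, n_systems = as.integer(n_systems),
    n_stationary_3plus = n_3plus, n_ec = n_ec,
    n_diverged = n_div, n_nonstationary = n_nonstat,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  out <- list(tally = tally)
  if (keep_communities) out$communities <- communities
  out
}
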