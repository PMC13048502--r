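# Experiment drivers: the (mu, sigma) phase diagram, community scans
# (excluding fraction / collectivity / intransitivity), and the single-matrix
# analysis entry point.  Each driver returns a plain data.frame and can
# optionally write CSV output.

write_csv_if <- function(df, output_dir, name) {
  if (is.null(output_dir)) return(invisible(NULL))
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  invisible(NULL)
}

#' Phase diagram of emergent coexistence over the (mu, sigma) grid
#'
#' For every grid cell, runs [run_replicates()] (fresh matrix and initial
#' conditions per system) and tallies the fraction of EC states among
#' stationary states with at least three coexisting species.  Each cell uses
#' a counter-derived sub-seed, so cells are independent and reorderable.
#'
#' @param mu_values,sigma_values grid axes (defaults span the usual
#'   parameter ranges `mu` in (-2, 0.5), `sigma` in (0, 1)).
#' @param S pool size (default 80).
#' @param n_systems replicate systems per cell (default 100).
#' @param seed master RNG seed.
#' @param output_dir optional directory for `phase_diagram.csv` and
#'   `boundaries.csv`.
#' @param boundaries also compute [regime_boundaries()] over `mu_values`
#'   (attached as attribute `"boundaries"`).
#' @inheritParams integrate_glv
#' @return data.frame with one row per cell: `mu, sigma, n_systems,
#'   n_stationary_3plus, n_ec, ec_fraction, n_diverged, n_nonstationary,
#'   seed` (`ec_fraction` is `NA` when no 3-plus state was seen).
#' @export
run_phase_diagram <- function(mu_values = seq(-2, 0.5, length.out = 26),
                              sigma_values = seq(0.05, 1, length.out = 20),
                              S = 80, n_systems = 100, seed = NULL,
                              t1 = 3000, t2 = 100,
                              extinction_threshold = 1e-4,
                              divergence_cap = 1e6,
                              stationarity_tol = 1e-3,
                              output_dir = NULL, boundaries = TRUE) {
  if (is.null(output_dir) == FALSE) {
    # fail before any compute if the path is unusable
    ok <- dir.exists(output_dir) ||
      tryCatch({ dir.create(output_dir, recursive = TRUE); TRUE },
               warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok) glv_error("cannot create `output_dir`", "glv_io_error")
  }
  cells <- expand.grid(mu = mu_values, sigma = sigma_values)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    spec <- ensemble_spec(S = S, mu = cells$mu[i], sigma = cells$sigma[i])
    rr <- run_replicates(spec, n_systems, seed = spawn_seed(seed, i),
                         t1 = t1, t2 = t2,
                         extinction_threshold = extinction_threshold,
                         divergence_cap = divergence_cap,
                         stationarity_tol = stationarity_tol,
                         keep_communities = FALSE)
    tl <- rr$tally
    tl$ec_fraction <- if (tl$n_stationary_3plus > 0)
      tl$n_ec / tl$n_stationary_3plus else NA_real_
    rows[[i]] <- tl
  }
  out <- do.call(rbind, rows)
  out <- out[, c("mu", "sigma", "n_systems", "n_stationary_3plus", "n_ec",
                 "ec_fraction", "n_diverged", "n_nonstationary", "seed")]
  if (boundaries) {
    bd <- regime_boundaries(S, sort(unique(mu_values)))
    attr(out, "boundaries") <- bd
    write_csv_if(bd, output_dir, "boundaries.csv")
  }
  write_csv_if(out, output_dir, "phase_diagram.csv")
  out
}

#' Community table: one row of metrics per stable community
#'
#' @param communities list of `glv_community` objects.
#' @return data.frame with columns `S_star, mu_star, sigma_star, is_ec,
#'   fraction_excluding, phi, kappa, kappa_A, lambda2, frac_positive_net,
#'   pearson_direct_net, origin, subset`.
#' @export
community_table <- function(communities) {
  rows <- lapply(communities, function(cm) {
    ec <- ec_report(cm, require_verified = FALSE)
    co <- collectivity_report(cm)
    lam2 <- if (!is.null(cm$stability)) cm$stability$lambda2 else NA_real_
    data.frame(
      S_star = ec$S_star, mu_star = cm$mu_star, sigma_star = cm$sigma_star,
      is_ec = ec$is_ec, fraction_excluding = ec$fraction_excluding,
      phi = co$phi, kappa = co$kappa, kappa_A = co$kappa_A,
      lambda2 = lam2, frac_positive_net = co$frac_positive_net,
      pearson_direct_net = co$pearson_direct_net,
      origin = cm$origin,
      subset = paste(cm$pool_indices, collapse = ";")
    )
  })
  do.call(rbind, rows)
}

#' Sample stable communities across a (mu, sigma) grid
#'
#' Workhorse behind the scan drivers: for each grid cell draws `n_pools`
#' fresh pools and samples stable subsets of the requested sizes.
#'
#' @param mu_values,sigma_values grid axes.
#' @param S pool size.
#' @param sizes community sizes to sample.
#' @param n_pools pools per cell.
#' @param n_samples subset draws per pool and size.
#' @param structure ensemble structure tag.
#' @param seed master RNG seed.
#' @return list of `glv_community` objects; each carries attribute-free
#'   provenance through its pool statistics.
#' @export
sample_communities_grid <- function(mu_values, sigma_values, S = 80,
                                    sizes = 3:10, n_pools = 2,
                                    n_samples = 2000,
                                    structure = "random", seed = NULL) {
  cells <- expand.grid(mu = mu_values, sigma = sigma_values)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    spec <- ensemble_spec(S = S, mu = cells$mu[i], sigma = cells$sigma[i],
                          structure = structure)
    for (p in seq_len(n_pools)) {
      pool <- sample_matrix(spec, seed = spawn_seed(seed, i * 1009L + p))
      cms <- sample_stable_subsets(pool, sizes, n_samples,
                                   seed = spawn_seed(seed,
                                                     2000003L + i * 1013L + p))
      out <- c(out, cms)
    }
  }
  out
}

#' Run a community scan
#'
#' Samples stable communities over the grid and applies the requested
#' metrics module.  `kind = "fraction"` and `"collectivity"` return the
#' [community_table()] (the fraction scan attaches the analytic min/max
#' excluding-fraction bounds as attribute `"bounds"`; the collectivity scan
#' attaches [phi_bounds()] per size); `kind = "intransitivity"` delegates to
#' [intransitivity_scan()].
#'
#' @param kind `"fraction"`, `"collectivity"` or `"intransitivity"`.
#' @param mu_values,sigma_values grid axes.
#' @param S pool size.
#' @param sizes community sizes.
#' @param n_pools,n_samples sampling budget per cell (see
#'   [sample_communities_grid()]).
#' @param seed master RNG seed.
#' @param output_dir optional CSV output directory.
#' @param ... forwarded to [intransitivity_scan()] when
#'   `kind = "intransitivity"`.
#' @return data.frame (see Details).
#' @export
run_scan <- function(kind = c("fraction", "collectivity", "intransitivity"),
                     mu_values = seq(-1.6, -0.4, by = 0.3),
                     sigma_values = seq(0.2, 0.8, by = 0.3),
                     S = 80, sizes = 3:10, n_pools = 2, n_samples = 2000,
                     seed = NULL, output_dir = NULL, ...) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e)
                     glv_error("unknown scan kind", "glv_config_error"))
  if (kind == "intransitivity") {
    tab <- intransitivity_scan(sizes = sizes, seed = seed, ...)
    write_csv_if(tab, output_dir, "intransitivity_scan.csv")
    return(tab)
  }
  cms <- sample_communities_grid(mu_values, sigma_values, S = S,
                                 sizes = sizes, n_pools = n_pools,
                                 n_samples = n_samples, seed = seed)
  if (!length(cms)) {
    warning("no stable community accepted at the requested sizes",
            call. = FALSE)
    return(data.frame())
  }
  tab <- community_table(cms)
  if (kind == "fraction") {
    grid <- expand.grid(mu = mu_values, sigma = sigma_values)
    bnd <- max_excluding_fraction_bound(grid$mu, grid$sigma, S_pool = S)
    attr(tab, "bounds") <- data.frame(
      mu = grid$mu, sigma = grid$sigma,
      S_star_max = bnd$S_star_max, fraction_max = bnd$fraction_max)
    write_csv_if(tab, output_dir, "fraction_scan.csv")
  } else {
    pb <- t(vapply(sort(unique(tab$S_star)), function(k)
      if (k >= 2) phi_bounds(k, mu_values, sigma_values, S_pool = S)
      else c(phi_min = NA_real_, phi_max = NA_real_),
      c(phi_min = 0, phi_max = 0)))
    attr(tab, "phi_bounds") <- data.frame(S_star = sort(unique(tab$S_star)),
                                          pb)
    write_csv_if(tab, output_dir, "collectivity_scan.csv")
  }
  tab
}

#' Analyze a user-supplied interaction matrix
#'
#' Treats a square, zero-diagonal matrix (CSV path or matrix) as the
#' interaction matrix `A*` of a candidate community, verifies feasibility
#' and linear stability, and emits the full per-community report bundle:
#' emergent coexistence, collectivity, and intransitivity.
#'
#' @param x path to a matrix CSV (see [read_interaction_matrix()]) or a
#'   square numeric matrix.
#' @param r optional growth-rate vector (defaults to 1; equilibria are
#'   r-independent, the Jacobian scale is not).
#' @param direction_rule forwarded to [exclusion_digraph()].
#' @param json_path optional path; when given, the report is also written
#'   as JSON.
#' @return list with `S_star`, `feasible`, `stable`, `x_star`,
#'   `ec`, `collectivity`, `intransitivity`, `stability`.
#' @export
analyze_matrix <- function(x, r = NULL,
                           direction_rule = "stronger_effect",
                           json_path = NULL) {
  A <- if (is.character(x)) read_interaction_matrix(x) else x
  if (!is.matrix(A) || !is.numeric(A) || nrow(A) != ncol(A))
    glv_error(sprintf("input is %s x %s, not a square numeric matrix",
                      nrow(A), ncol(A)), "glv_format_error")
  if (any(diag(A) != 0))
    glv_error("diagonal must be exactly zero", "glv_format_error")
  n <- nrow(A)
  r <- rep_len(if (is.null(r)) 1 else r, n)
  feas <- tryCatch(is_feasible(A), glv_singular_error = function(e) NULL)
  feasible <- !is.null(feas) && feas$feasible
  stab <- NULL
  stable <- FALSE
  if (feasible) {
    od <- offdiag(A)
    stab <- is_linearly_stable(glv_jacobian(A, feas$x_star, r),
                               mu_star = mean(od),
                               sigma_star = stats::sd(od))
    stable <- stab$stable
  }
  cm <- community_state(seq_len(n), A,
                        if (feasible) feas$x_star else rep(NA_real_, n),
                        r, origin = "sampled",
                        feasible = feasible, stable = stable,
                        stability = stab)
  report <- list(
    S_star = n,
    feasible = feasible,
    stable = stable,
    x_star = if (feasible) feas$x_star else NULL,
    ec = unclass(ec_report(cm, require_verified = FALSE)),
    collectivity = unclass(collectivity_report(A)),
    intransitivity = unclass(intransitivity_report(A, direction_rule)),
    stability = if (!is.null(stab)) list(
      eigenvalues_re = Re(stab$eigenvalues),
      eigenvalues_im = Im(stab$eigenvalues),
      char_coeffs = stab$char_coeffs,
      lambda2 = stab$lambda2,
      may_mu_c = stab$may_mu_c,
      violates_may = stab$violates_may) else NULL
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE,
                         force = TRUE)
  }
  report
}
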