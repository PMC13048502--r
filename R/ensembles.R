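# Interaction-matrix ensembles: the statistical structure the analysis assumes.
#
# All ensembles produce a dimensionless interaction matrix A with a zero
# diagonal: self-regulation is the explicit -x_i term of the rescaled GLV
# equations and is never stored in A.  Off-diagonal entry A[i, j] is the
# effect of (column) species j on (row) species i, measured relative to
# self-regulation.

#' Specify a random or structured interaction-matrix ensemble
#'
#' An ensemble specification fully parameterizes how a species pool is drawn:
#' pool size `S`, the Gaussian statistics of interactions (mean `mu`,
#' standard deviation `sigma`, both relative to self-regulation), network
#' connectivity, the structural family, and the auxiliary distributions used
#' by the structured variants.
#'
#' Structural families:
#' \describe{
#'   \item{`random`}{i.i.d. Gaussian off-diagonals, Erdős–Rényi connectivity
#'     mask at probability `connectivity`.}
#'   \item{`symmetric`}{`A[i,j] == A[j,i]` exactly (paired mask).}
#'   \item{`antisymmetric`}{centered pairs with correlation `rho` (default
#'     -1): `A[i,j] - mu = rho * (A[j,i] - mu)` plus independent residual for
#'     `rho > -1`.}
#'   \item{`triangular`}{upper triangle (`i < j`) Gaussian, lower triangle
#'     exactly zero: a nested hierarchy in who impacts whom.}
#'   \item{`k_correlated`}{raw interactions `a[i,j] ~ N(mu, sigma)` rescaled
#'     by heterogeneous carrying capacities, `A[i,j] = a[i,j] * K[j] / K[i]`,
#'     inducing row/column hierarchy from `K`.}
#'   \item{`crossfeeding`}{single-resource competition with cross-feeding:
#'     `A[i,j] = C[i,j] - 2*gamma[j] / (gamma[i] + gamma[j]) - alpha[i,j]`,
#'     with consumption traits `gamma` sorted in decreasing order so species
#'     order equals the competitive hierarchy.}
#' }
#'
#' The second argument of every Gaussian is a standard deviation, never a
#' variance (so `alpha ~ N(0.1, sd = 0.01)`).
#'
#' @param S integer pool size (>= 2).
#' @param mu mean off-diagonal interaction strength (dimensionless).
#' @param sigma off-diagonal standard deviation (>= 0).
#' @param connectivity probability in `[0, 1]` that a directed link is
#'   realized.
#' @param structure one of `"random"`, `"symmetric"`, `"antisymmetric"`,
#'   `"triangular"`, `"k_correlated"`, `"crossfeeding"`.
#' @param sigma_r growth-rate standard deviation around mean 1 (>= 0).
#' @param k_low,k_high carrying-capacity uniform bounds (`k_low > 0`).
#' @param gamma_low,gamma_high resource-consumption trait bounds
#'   (`gamma_low > 0`).
#' @param alpha_mean,alpha_sd weak-competition Gaussian parameters.
#' @param c_low,c_high cross-feeding uniform bounds.
#' @param rho pair correlation for the antisymmetric family, in `[-1, 1]`.
#' @param paired_mask logical: realize connectivity per unordered pair (both
#'   directions together) instead of per directed entry.  The default is the
#'   directed mask; symmetric and antisymmetric families always use a paired
#'   mask so the imposed pair structure survives masking.
#' @param seed default RNG seed used by [sample_matrix()].
#' @return an object of class `glv_ensemble_spec`.
#' @seealso [sample_matrix()]
#' @export
ensemble_spec <- function(S = 80, mu = -0.5, sigma = 0.25, connectivity = 1,
                          structure = c("random", "symmetric", "antisymmetric",
                                        "triangular", "k_correlated",
                                        "crossfeeding"),
                          sigma_r = 0, k_low = 0.5, k_high = 1.5,
                          gamma_low = 0.3, gamma_high = 0.7,
                          alpha_mean = 0.1, alpha_sd = 0.01,
                          c_low = 0, c_high = 1,
                          rho = -1, paired_mask = FALSE, seed = NULL) {
  structure <- tryCatch(match.arg(structure),
                        error = function(e)
                          glv_error("unknown ensemble structure tag",
                                    "glv_config_error"))
  if (length(S) != 1L || S < 2 || S != round(S))
    glv_error("`S` must be a single integer >= 2", "glv_config_error")
  if (sigma < 0) glv_error("`sigma` must be >= 0", "glv_config_error")
  if (connectivity < 0 || connectivity > 1)
    glv_error("`connectivity` must lie in [0, 1]", "glv_config_error")
  if (sigma_r < 0) glv_error("`sigma_r` must be >= 0", "glv_config_error")
  if (k_low <= 0) glv_error("`k_low` must be > 0", "glv_config_error")
  if (gamma_low <= 0) glv_error("`gamma_low` must be > 0", "glv_config_error")
  if (alpha_sd < 0) glv_error("`alpha_sd` must be >= 0", "glv_config_error")
  if (k_low > k_high || gamma_low > gamma_high || c_low > c_high)
    glv_error("all bounds must satisfy low <= high", "glv_config_error")
  if (rho < -1 || rho > 1)
    glv_error("`rho` must lie in [-1, 1]", "glv_config_error")
  structure(
    list(S = as.integer(S), mu = mu, sigma = sigma,
         connectivity = connectivity, structure = structure,
         sigma_r = sigma_r, k_low = k_low, k_high = k_high,
         gamma_low = gamma_low, gamma_high = gamma_high,
         alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         c_low = c_low, c_high = c_high,
         rho = rho, paired_mask = isTRUE(paired_mask), seed = seed),
    class = "glv_ensemble_spec"
  )
}

#' @export
print.glv_ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "GLV ensemble spec: S = %d, structure = %s, mu = %g, sigma = %g, C = %g\n",
    x$S, x$structure, x$mu, x$sigma, x$connectivity))
  invisible(x)
}

connectivity_mask <- function(S, C, paired) {
  if (C >= 1) {
    m <- matrix(TRUE, S, S)
  } else if (!paired) {
    m <- matrix(stats::runif(S * S) < C, S, S)
  } else {
    m <- matrix(FALSE, S, S)
    up <- upper.tri(m)
    m[up] <- stats::runif(sum(up)) < C
    m <- m | t(m)
  }
  diag(m) <- FALSE
  m
}

#' Draw an interaction matrix (and growth rates) from an ensemble
#'
#' Samples a species pool: the interaction matrix `A` (zero diagonal), the
#' intrinsic growth rates `r` (mean 1, sd `sigma_r`, strictly positive by
#' rejection resampling) and carrying capacities `K` (uniform; all 1 except
#' for the `k_correlated` family, where `K` induces the matrix structure).
#' Deterministic given `seed`.
#'
#' @param spec an [ensemble_spec()].
#' @param seed RNG seed; defaults to the seed stored in `spec`, `NULL`
#'   continues the current RNG stream.
#' @return an object of class `glv_pool`: a list with elements `A`
#'   (S x S matrix), `r`, `K`, `spec`, `seed_used`.
#' @examples
#' pool <- sample_matrix(ensemble_spec(S = 10, mu = -0.5, sigma = 0.2,
#'                                     seed = 1))
#' range(diag(pool$A))  # exactly zero
#' @export
sample_matrix <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "glv_ensemble_spec"))
    glv_error("`spec` must be created by ensemble_spec()", "glv_config_error")
  with_seed(seed, {
    S <- spec$S
    mu <- spec$mu
    sg <- spec$sigma
    K <- rep(1, S)
    A <- switch(spec$structure,
      random = {
        M <- matrix(stats::rnorm(S * S, mu, sg), S, S)
        M * connectivity_mask(S, spec$connectivity, spec$paired_mask)
      },
      symmetric = {
        M <- matrix(0, S, S)
        up <- upper.tri(M)
        M[up] <- stats::rnorm(sum(up), mu, sg)
        (M + t(M)) * connectivity_mask(S, spec$connectivity, TRUE)
      },
      antisymmetric = {
        M <- matrix(0, S, S)
        up <- upper.tri(M)
        n <- sum(up)
        u <- stats::rnorm(n, 0, sg)
        l <- spec$rho * u + sqrt(max(0, 1 - spec$rho^2)) *
          stats::rnorm(n, 0, sg)
        M[up] <- mu + u
        L <- matrix(0, S, S)
        L[up] <- mu + l
        (M + t(L)) * connectivity_mask(S, spec$connectivity, TRUE)
      },
      triangular = {
        M <- matrix(0, S, S)
        up <- upper.tri(M)
        M[up] <- stats::rnorm(sum(up), mu, sg)
        M * connectivity_mask(S, spec$connectivity, spec$paired_mask)
      },
      k_correlated = {
        a <- matrix(stats::rnorm(S * S, mu, sg), S, S)
        a <- a * connectivity_mask(S, spec$connectivity, spec$paired_mask)
        K <- stats::runif(S, spec$k_low, spec$k_high)
        a * outer(1 / K, K)
      },
      crossfeeding = {
        gam <- sort(stats::runif(S, spec$gamma_low, spec$gamma_high),
                    decreasing = TRUE)
        alpha <- matrix(stats::rnorm(S * S, spec$alpha_mean, spec$alpha_sd),
                        S, S)
        Cf <- matrix(stats::runif(S * S, spec$c_low, spec$c_high), S, S)
        Cf - 2 * matrix(gam, S, S, byrow = TRUE) / outer(gam, gam, `+`) - alpha
      }
    )
    diag(A) <- 0
    if (any(!is.finite(A)))
      glv_error("non-finite value sampled for the interaction matrix",
                "glv_generation_error")
    r <- sample_growth_rates(S, spec$sigma_r, seed = NULL)
    structure(list(A = A, r = r, K = K, spec = spec,
                   seed_used = if (is.null(seed)) NA_integer_
                               else as.integer(seed)),
              class = "glv_pool")
  })
}

#' @export
print.glv_pool <- function(x, ...) {
  od <- offdiag(x$A)
  cat(sprintf(
    "GLV species pool: S = %d (%s), off-diagonal mean %.3f, sd %.3f\n",
    nrow(x$A), x$spec$structure, mean(od), stats::sd(od)))
  invisible(x)
}

#' Sample intrinsic growth rates
#'
#' Draws `S` growth rates from a Gaussian with mean 1 and standard deviation
#' `sigma_r`.  Non-positive draws are resampled (rejection) so rates stay
#' strictly positive; this slightly truncates the distribution, negligibly so
#' for the `sigma_r` values used here.
#'
#' @param S number of species.
#' @param sigma_r standard deviation (>= 0).
#' @param seed RNG seed (`NULL` continues the current stream).
#' @return numeric vector of length `S`, all entries > 0.
#' @export
sample_growth_rates <- function(S, sigma_r, seed = NULL) {
  if (sigma_r < 0) glv_error("`sigma_r` must be >= 0", "glv_config_error")
  with_seed(seed, {
    r <- stats::rnorm(S, 1, sigma_r)
    while (any(r <= 0)) r[r <= 0] <- stats::rnorm(sum(r <= 0), 1, sigma_r)
    r
  })
}

#' Sample carrying capacities
#'
#' Uniform carrying capacities on `[k_low, k_high]`, the heterogeneity that
#' induces hierarchical structure in the `k_correlated` ensemble.
#'
#' @param S number of species.
#' @param k_low,k_high uniform bounds, `0 < k_low <= k_high`.
#' @param seed RNG seed (`NULL` continues the current stream).
#' @return numeric vector of length `S` in `[k_low, k_high]`.
#' @export
sample_carrying_capacities <- function(S, k_low = 0.5, k_high = 1.5,
                                       seed = NULL) {
  if (k_low <= 0) glv_error("`k_low` must be > 0", "glv_config_error")
  if (k_low > k_high)
    glv_error("`k_low` must be <= `k_high`", "glv_config_error")
  with_seed(seed, stats::runif(S, k_low, k_high))
}

#' Write an interaction matrix to CSV
#'
#' Plain comma-separated text with 17 significant digits, so that
#' write/read round-trips are bit-exact for doubles.  An optional single
#' header row carries species labels.
#'
#' @param A square interaction matrix with zero diagonal.
#' @param path output file path.
#' @param labels optional character vector of species labels (default: the
#'   column names of `A`, if any).
#' @export
write_interaction_matrix <- function(A, path, labels = colnames(A)) {
  check_square_matrix(A)
  rows <- apply(A, 1, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = ","))
  if (!is.null(labels)) rows <- c(paste(labels, collapse = ","), rows)
  writeLines(rows, path)
  invisible(path)
}

#' Read an interaction matrix from CSV
#'
#' Accepts a square, comma-separated numeric matrix with an optional single
#' header row of species labels.  The diagonal must be exactly zero:
#' self-regulation belongs to the model equations, never to the matrix.
#'
#' @param path file path.
#' @return square numeric matrix (with dimnames when a header was present).
#' @export
read_interaction_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    glv_error("empty matrix file", "glv_format_error")
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  labels <- NULL
  if (has_header) {
    labels <- trimws(first)
    lines <- lines[-1]
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncol <- length(cells[[1]])
  if (any(lengths(cells) != ncol))
    glv_error("ragged rows: not a rectangular matrix", "glv_format_error")
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))[1]
    glv_error(sprintf("non-numeric cell at row %d, column %d",
                      (bad - 1) %/% ncol + 1, (bad - 1) %% ncol + 1),
              "glv_format_error")
  }
  A <- matrix(vals, ncol = ncol, byrow = TRUE)
  if (nrow(A) != ncol(A))
    glv_error(sprintf("matrix is %d x %d, not square", nrow(A), ncol(A)),
              "glv_format_error")
  if (any(diag(A) != 0)) {
    bad <- which(diag(A) != 0)[1]
    glv_error(sprintf("nonzero diagonal at position %d (%g); diagonal must be exactly 0",
                      bad, diag(A)[bad]),
              "glv_format_error")
  }
  if (!is.null(labels)) dimnames(A) <- list(labels, labels)
  A
}
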