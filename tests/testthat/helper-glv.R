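# Shared fixtures, built in code.

# uniform competitive pool: every off-diagonal equal to `a`
uniform_pool <- function(S, a, r = 1) {
  A <- matrix(a, S, S)
  diag(A) <- 0
  list(A = A, r = rep_len(r, S))
}

# rock-paper-scissors community: 1 excludes 2, 2 excludes 3, 3 excludes 1
# (A[i, j] is the effect of j on i, so A[2, 1] < -1 means 1 excludes 2)
rps_matrix <- function(strong = -1.5, weak = -0.2) {
  A <- matrix(weak, 3, 3)
  A[2, 1] <- strong
  A[3, 2] <- strong
  A[1, 3] <- strong
  diag(A) <- 0
  A
}

# transitive tournament on S species: species 1 beats everyone, etc.;
# winner -> loser edges arise from A[loser, winner] < -1
hierarchy_matrix <- function(S, strong = -1.5, weak = -0.2) {
  A <- matrix(weak, S, S)
  for (i in seq_len(S - 1)) for (j in seq(i + 1, S)) A[j, i] <- strong
  diag(A) <- 0
  A
}

# wrap a bare matrix as a verified community (errors if not feasible+stable)
community_from_matrix <- function(A, r = 1) {
  feas <- is_feasible(A)
  stopifnot(feas$feasible)
  stab <- is_linearly_stable(glv_jacobian(A, feas$x_star, r))
  stopifnot(stab$stable)
  ecglv:::community_state(seq_len(nrow(A)), A, feas$x_star,
                          rep_len(r, nrow(A)), origin = "sampled",
                          feasible = TRUE, stable = TRUE, stability = stab)
}

offdiag <- function(M) M[row(M) != col(M)]

# seeded uniform initial conditions without disturbing the global stream
with_seed_runif <- function(n, seed) ecglv:::with_seed(seed, stats::runif(n))
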