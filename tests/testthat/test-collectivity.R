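# Net effects, Neumann series, phi, kappa, and the prediction experiments.

test_that("net effects match closed-form inverses", {
  expect_equal(net_effects(matrix(0, 4, 4)), diag(4))
  a <- -0.4
  A <- matrix(c(0, a, a, 0), 2, 2)
  N <- net_effects(A)
  expect_equal(N, matrix(c(1, a, a, 1), 2, 2) / (1 - a^2),
               tolerance = 1e-12)
  expect_error(net_effects(matrix(c(0, 1, 1, 0), 2, 2)),
               class = "glv_singular_error")
})

test_that("Neumann partial sums converge exactly when phi < 1", {
  expect_equal(neumann_partial_sum(matrix(-0.5, 3, 3) + diag(0.5, 3), 0),
               diag(3), ignore_attr = TRUE)
  # convergent case
  pool <- sample_matrix(ensemble_spec(S = 6, mu = -0.05, sigma = 0.1),
                        seed = 3)
  stopifnot(collectivity_phi(pool$A) < 0.9)
  ps <- neumann_partial_sum(pool$A, 40)
  expect_lt(max(abs(ps - net_effects(pool$A))), 1e-6)
  expect_equal(attr(ps, "x_partial"), rowSums(ps))
  # divergent case: partial sums blow up when phi > 1
  Ad <- matrix(-0.5, 5, 5) + diag(0.5, 5)   # phi = 2
  stopifnot(collectivity_phi(Ad) > 1.1)
  n20 <- max(abs(neumann_partial_sum(Ad, 20)))
  n40 <- max(abs(neumann_partial_sum(Ad, 40)))
  expect_gt(n40, 1e3 * n20)
})

test_that("Neumann convergence contract holds across random matrices", {
  # rescale random matrices to phi = 0.9 and 1.1 and check both sides
  for (s in 1:5) {
    A <- sample_matrix(ensemble_spec(S = 8, mu = -0.3, sigma = 0.3),
                       seed = 50 + s)$A
    A9 <- A * (0.9 / collectivity_phi(A))
    expect_lt(max(abs(neumann_partial_sum(A9, 200) - net_effects(A9))),
              1e-6)
    A11 <- A * (1.1 / collectivity_phi(A))
    expect_gt(max(abs(neumann_partial_sum(A11, 200) - net_effects(A11))),
              1)
  }
})

test_that("collectivity matches spectral closed forms", {
  expect_identical(collectivity_phi(matrix(0, 3, 3)), 0)
  a <- -0.7
  expect_equal(collectivity_phi(matrix(c(0, a, a, 0), 2, 2)), abs(a))
  # uniform matrix: dominant eigenvalue (S-1)|a|
  expect_equal(collectivity_phi(uniform_pool(10, -0.5)$A), 4.5)
})

test_that("random-matrix phi estimate anchors to the uniform case", {
  expect_equal(phi_estimate(10, -0.5, 0), 4.5)
  expect_equal(phi_estimate(10, -0.5, 0),
               collectivity_phi(uniform_pool(10, -0.5)$A))
  # fluctuation-dominated regime: sqrt scaling against measured phi
  phis <- ests <- numeric(6)
  for (s in 1:6) {
    S <- 40
    A <- sample_matrix(ensemble_spec(S = S, mu = 0, sigma = 0.3),
                       seed = 60 + s)$A
    phis[s] <- collectivity_phi(A)
    ests[s] <- phi_estimate(S, 0, 0.3)
  }
  expect_lt(abs(mean(phis) / mean(ests) - 1), 0.15)
  # literal variant scales linearly in S
  expect_equal(phi_estimate(10, 0, 0.3, literal = TRUE), 2.7)
})

test_that("phi envelope extremizes the estimate over attainable cells", {
  b <- phi_bounds(5, seq(-1.5, -0.3, by = 0.1), seq(0.1, 0.9, by = 0.1))
  expect_lt(b["phi_min"], b["phi_max"])
  expect_gt(b["phi_min"], 0)
})

test_that("condition number matches singular-value closed forms", {
  expect_equal(condition_number(matrix(0, 3, 3)), 1)
  A <- matrix(c(0, -0.5, -0.5, 0), 2, 2)
  expect_equal(condition_number(A), 3)          # |1 -/+ a| ratio
  expect_equal(condition_number(A, target = "A"), 1)
  # unitary invariance: permutations leave kappa unchanged
  pool <- sample_matrix(ensemble_spec(S = 6, mu = -0.8, sigma = 0.4),
                        seed = 8)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(condition_number(pool$A),
               condition_number(pool$A[perm, perm]), tolerance = 1e-10)
  expect_error(condition_number(matrix(0, 2, 2), target = "A"),
               class = "glv_input_error")
})

test_that("kappa lower bound grows with diversity", {
  k3 <- kappa_min_bound(3, n_mc = 150, seed = 1)
  k8 <- kappa_min_bound(8, n_mc = 150, seed = 1)
  expect_gt(k8, k3)
  expect_gte(k3, 1)
  expect_error(kappa_min_bound(2), class = "glv_config_error")
  # rmt variant is deterministic and ordered too
  expect_gt(kappa_min_bound(8, method = "rmt"),
            kappa_min_bound(3, method = "rmt"))
})

test_that("direct and net effects correlate tightly at low collectivity", {
  A <- sample_matrix(ensemble_spec(S = 8, mu = -0.02, sigma = 0.02),
                     seed = 4)$A
  stopifnot(collectivity_phi(A) < 0.3)
  dn <- direct_net_correlation(A)
  expect_gt(dn$pearson_r, 0.9)
  expect_lt(dn$p_value, 1e-6)
  expect_error(direct_net_correlation(matrix(c(0, -1, -1, 0), 2, 2)),
               class = "glv_config_error")
  expect_warning(direct_net_correlation(matrix(0, 3, 3)), "zero variance")
})

test_that("direct-net correlation degrades as phi crosses one", {
  lo <- hi <- c()
  for (s in 1:12) {
    A <- sample_matrix(ensemble_spec(S = 8, mu = -0.4, sigma = 0.25),
                       seed = 70 + s)$A
    Alo <- A * (0.4 / collectivity_phi(A))
    Ahi <- A * (1.6 / collectivity_phi(A))
    lo <- c(lo, abs(direct_net_correlation(Alo)$pearson_r))
    hi <- c(hi, abs(direct_net_correlation(Ahi)$pearson_r))
  }
  expect_gt(mean(lo), mean(hi))
})

test_that("fully competitive communities can exert positive net effects", {
  found <- FALSE
  for (s in 1:20) {
    pool <- sample_matrix(ensemble_spec(S = 40, mu = -0.6, sigma = 0.35),
                          seed = 80 + s)
    cms <- sample_stable_subsets(pool, 5, 300, seed = 90 + s)
    for (cm in cms) {
      if (all(offdiag(cm$A_star) < 0)) {
        if (any(offdiag(net_effects(cm$A_star)) > 0)) found <- TRUE
      }
      if (found) break
    }
    if (found) break
  }
  expect_true(found)
})

test_that("collectivity report bundles consistent fields", {
  rep <- collectivity_report(community_from_matrix(rps_matrix()))
  expect_s3_class(rep, "glv_collectivity_report")
  expect_identical(rep$neumann_converges, rep$phi < 1)
  expect_gte(rep$kappa, 1)
  expect_true(rep$frac_positive_net >= 0 && rep$frac_positive_net <= 1)
})

test_that("prediction experiment is exact without noise and fails cleanly", {
  pool <- sample_matrix(ensemble_spec(S = 40, mu = -0.9, sigma = 0.45),
                        seed = 7)
  cms <- sample_stable_subsets(pool, 3:5, 800, seed = 8)
  kap <- vapply(cms, function(cm) condition_number(cm$A_star), 0)
  kt <- unname(stats::quantile(kap, 0.5))
  pe0 <- prediction_error_experiment(cms, kt, rel_error = 0, n_reps = 50,
                                     seed = 9)
  expect_identical(pe0$success_fraction, 1)
  expect_error(prediction_error_experiment(cms, 1e6, n_reps = 10),
               class = "glv_state_error")
  expect_error(prediction_error_experiment(cms, kt, rel_error = -1),
               class = "glv_config_error")
})

test_that("prediction success decreases with the condition number", {
  pool <- sample_matrix(ensemble_spec(S = 60, mu = -1, sigma = 0.5),
                        seed = 17)
  cms <- sample_stable_subsets(pool, 3:6, 3000, seed = 18)
  kap <- vapply(cms, function(cm) condition_number(cm$A_star), 0)
  lo <- prediction_error_experiment(cms, 3, rel_error = 0.1,
                                    n_reps = 400, seed = 19)
  hi <- prediction_error_experiment(cms, 25, rel_error = 0.1,
                                    n_reps = 400, seed = 19)
  expect_gt(lo$success_fraction, hi$success_fraction)
})

test_that("well-conditioned communities shrug off 10% measurement error", {
  # near-empty interaction matrices: kappa ~ 1, perturbation cannot flip
  cms <- lapply(1:10, function(s) {
    A <- sample_matrix(ensemble_spec(S = 5, mu = -0.02, sigma = 0.01),
                       seed = 200 + s)$A
    community_from_matrix(A)
  })
  pe <- prediction_error_experiment(cms, 1.1, rel_error = 0.1, band = 0.3,
                                    n_reps = 200, seed = 20)
  expect_gt(pe$success_fraction, 0.98)
})

test_that("assembly from pairwise coexistence follows collectivity", {
  # weak competition: every pairwise-coexisting set truly assembles
  pool <- uniform_pool(12, -0.1)
  out <- assembly_from_pairs_experiment(pool, 4, 100, seed = 21)
  expect_identical(out$n_eligible, 100L)
  expect_true(all(out$success))
  expect_error(assembly_from_pairs_experiment(pool, 13, 10),
               class = "glv_config_error")
  expect_error(assembly_from_pairs_experiment(pool, 2, 10),
               class = "glv_config_error")
})

test_that("assembly success is higher at low phi than at high phi", {
  pool <- sample_matrix(ensemble_spec(S = 60, mu = -0.3, sigma = 0.45),
                        seed = 23)
  out <- assembly_from_pairs_experiment(pool, 5, 3000, seed = 24)
  lo <- out$success[out$phi < 0.8]
  hi <- out$success[out$phi > 1.2]
  expect_gt(length(lo), 50)
  expect_gt(length(hi), 50)
  expect_gt(mean(lo), mean(hi))
})

test_that("phi and kappa do not depend on growth rates", {
  cm <- community_from_matrix(rps_matrix(), r = 1)
  cm2 <- community_from_matrix(rps_matrix(), r = c(0.5, 1.5, 2))
  expect_identical(collectivity_report(cm)$phi, collectivity_report(cm2)$phi)
  expect_identical(collectivity_report(cm)$kappa,
                   collectivity_report(cm2)$kappa)
})
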