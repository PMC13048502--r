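# Interaction-matrix ensembles: moments, structure, determinism, I/O.

test_that("zero-variance random ensemble is exactly uniform", {
  pool <- sample_matrix(ensemble_spec(S = 12, mu = -0.7, sigma = 0,
                                      connectivity = 1), seed = 1)
  expect_identical(diag(pool$A), rep(0, 12))
  expect_true(all(offdiag(pool$A) == -0.7))
  expect_identical(pool$r, rep(1, 12))
})

test_that("degenerate cross-feeding ensemble forces B_ij = -1", {
  # C_ij = 0 and alpha = 0 leave only -2 gamma_j / (gamma_i + gamma_j),
  # which equals -1 when all gammas coincide
  spec <- ensemble_spec(S = 8, structure = "crossfeeding",
                        gamma_low = 0.5, gamma_high = 0.5,
                        alpha_mean = 0, alpha_sd = 0, c_low = 0, c_high = 0)
  pool <- sample_matrix(spec, seed = 3)
  expect_equal(offdiag(pool$A), rep(-1, 8 * 7))
})

test_that("random ensemble matches its target moments", {
  pool <- sample_matrix(ensemble_spec(S = 80, mu = -0.5, sigma = 0.25),
                        seed = 42)
  od <- offdiag(pool$A)
  n <- length(od)
  expect_identical(n, 80L * 79L)
  expect_lt(abs(mean(od) - (-0.5)), 3 * 0.25 / sqrt(n))
  expect_lt(abs(sd(od) - 0.25), 3 * 0.25 / sqrt(2 * n))
})

test_that("sampling is deterministic given spec and seed", {
  spec <- ensemble_spec(S = 20, mu = -1, sigma = 0.5, connectivity = 0.7,
                        sigma_r = 0.1)
  p1 <- sample_matrix(spec, seed = 11)
  p2 <- sample_matrix(spec, seed = 11)
  expect_identical(p1$A, p2$A)
  expect_identical(p1$r, p2$r)
  p3 <- sample_matrix(spec, seed = 12)
  expect_false(identical(p1$A, p3$A))
})

test_that("structured families satisfy their defining symmetries", {
  sym <- sample_matrix(ensemble_spec(S = 15, mu = -0.8, sigma = 0.4,
                                     structure = "symmetric"), seed = 5)
  expect_identical(sym$A, t(sym$A))

  anti <- sample_matrix(ensemble_spec(S = 15, mu = -0.8, sigma = 0.4,
                                      structure = "antisymmetric"), seed = 5)
  cent <- anti$A - (-0.8)
  diag(cent) <- 0
  expect_equal(cent, -t(cent), tolerance = 1e-12)

  tri <- sample_matrix(ensemble_spec(S = 15, mu = -0.8, sigma = 0.4,
                                     structure = "triangular"), seed = 5)
  expect_identical(sum(tri$A[lower.tri(tri$A)]), 0)
  expect_gt(sum(tri$A[upper.tri(tri$A)] != 0), 0)
})

test_that("masked symmetric ensembles keep pairwise link structure", {
  sym <- sample_matrix(ensemble_spec(S = 30, mu = -1, sigma = 0.3,
                                     structure = "symmetric",
                                     connectivity = 0.4), seed = 8)
  expect_identical(sym$A, t(sym$A))
  realized <- mean(offdiag(sym$A) != 0)
  expect_lt(abs(realized - 0.4), 3 * sqrt(0.4 * 0.6 / (30 * 29 / 2)))
})

test_that("directed connectivity mask hits the requested link density", {
  pool <- sample_matrix(ensemble_spec(S = 60, mu = -1, sigma = 0.2,
                                      connectivity = 0.5), seed = 2)
  realized <- mean(offdiag(pool$A) != 0)
  expect_lt(abs(realized - 0.5), 3 * sqrt(0.25 / (60 * 59)))
})

test_that("cross-feeding hierarchy favours the better consumer", {
  # with alpha and C held constant, B_ij - B_ji = 2 (g_i - g_j)/(g_i + g_j),
  # non-negative for i < j since gammas are sorted in decreasing order
  spec <- ensemble_spec(S = 12, structure = "crossfeeding",
                        alpha_sd = 0, c_low = 0.5, c_high = 0.5)
  pool <- sample_matrix(spec, seed = 7)
  A <- pool$A
  for (i in 1:11) for (j in (i + 1):12) expect_gte(A[i, j], A[j, i])
})

test_that("carrying-capacity correlation induces row/column hierarchy", {
  rcors <- ccors <- numeric(5)
  for (s in 1:5) {
    spec <- ensemble_spec(S = 30, mu = -1, sigma = 0.3,
                          structure = "k_correlated")
    pool <- sample_matrix(spec, seed = 100 + s)
    absA <- abs(pool$A)
    diag(absA) <- NA
    rm <- log(rowMeans(absA, na.rm = TRUE))
    cm <- log(colMeans(absA, na.rm = TRUE))
    rcors[s] <- cor(rm, -log(pool$K), method = "spearman")
    ccors[s] <- cor(cm, log(pool$K), method = "spearman")
  }
  expect_gt(mean(rcors), 0)
  expect_gt(mean(ccors), 0)
})

test_that("growth-rate sampling honours mean, positivity and preconditions", {
  expect_identical(sample_growth_rates(5, 0), rep(1, 5))
  r <- sample_growth_rates(1000, 0.1, seed = 9)
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) - 1), 3 * 0.1 / sqrt(1000))
  expect_error(sample_growth_rates(5, -0.1), class = "glv_config_error")
})

test_that("carrying-capacity sampling honours bounds and preconditions", {
  expect_identical(sample_carrying_capacities(4, 1, 1), rep(1, 4))
  K <- sample_carrying_capacities(1000, 0.5, 1.5, seed = 10)
  expect_true(all(K >= 0.5 & K <= 1.5))
  expect_lt(abs(mean(K) - 1), 3 * (1 / sqrt(12)) / sqrt(1000))
  expect_error(sample_carrying_capacities(4, 2, 1), class = "glv_config_error")
  expect_error(sample_carrying_capacities(4, 0, 1), class = "glv_config_error")
})

test_that("spec validation rejects malformed ensembles", {
  expect_error(ensemble_spec(S = 1), class = "glv_config_error")
  expect_error(ensemble_spec(sigma = -0.1), class = "glv_config_error")
  expect_error(ensemble_spec(connectivity = 1.2), class = "glv_config_error")
  expect_error(ensemble_spec(structure = "smallworld"),
               class = "glv_config_error")
  expect_error(ensemble_spec(gamma_low = 0.9, gamma_high = 0.3),
               class = "glv_config_error")
})

test_that("matrix CSV round-trips bit-exactly, with and without labels", {
  pool <- sample_matrix(ensemble_spec(S = 7, mu = -0.9, sigma = 0.33),
                        seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interaction_matrix(pool$A, path)
  expect_identical(read_interaction_matrix(path), pool$A)

  lab <- paste0("sp", 1:7)
  write_interaction_matrix(pool$A, path, labels = lab)
  back <- read_interaction_matrix(path)
  expect_identical(unname(back), pool$A)
  expect_identical(rownames(back), lab)
})

test_that("matrix CSV reader rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,-0.5", "-0.5,0", "1,2"), path)
  expect_error(read_interaction_matrix(path), class = "glv_format_error")
  writeLines(c("0,-0.5", "-0.5,0.01"), path)
  expect_error(read_interaction_matrix(path), class = "glv_format_error")
  writeLines(c("0,a", "-0.5,0"), path)
  expect_error(read_interaction_matrix(path), class = "glv_format_error")
})
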