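test_that("K=1 fit equals the closed-form independence model", {
  m <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  fit <- fit_plsa(m, 1, fit_config(seed = 1, n_restarts = 2))
  expect_lt(abs(fit$loglik - 4 * log(1 / 4)), 1e-8)
  expect_equal(unname(fit$pi_z[, 1]), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(unname(fit$pv_z[, 1]), c(0.5, 0.5), tolerance = 1e-8)

  # independence closed form on an asymmetric matrix
  m2 <- random_binary_matrix(6, 5, seed = 8)
  fit2 <- fit_plsa(m2, 1, fit_config(seed = 3, n_restarts = 1))
  R <- sum(m2)
  expect_equal(unname(fit2$pi_z[, 1]), unname(rowSums(m2) / R),
               tolerance = 1e-8)
  expect_equal(unname(fit2$pv_z[, 1]), unname(colSums(m2) / R),
               tolerance = 1e-8)
})

test_that("log-likelihood handles empty and degenerate inputs", {
  model <- uniform_model(2, 2, 1)
  zero <- matrix(0, 2, 2)
  expect_identical(log_likelihood(model, zero), 0)
  m <- matrix(1, 2, 2)
  expect_equal(log_likelihood(model, m), 4 * log(1 / 4), tolerance = 1e-12)
  # broken floor: an observed cell with zero modeled probability
  broken <- uniform_model(2, 2, 1)
  broken$pi_z[1, 1] <- 0
  broken$pi_z[2, 1] <- 1
  expect_error(log_likelihood(broken, m), "zero modeled probability")
  expect_error(log_likelihood(model, matrix(1, 3, 3)), "dimensions")
})

test_that("the block-exact model is an EM fixed point and the fit attains
           the saturated bound", {
  m <- block_matrix()
  exact <- block_exact_model()
  stepped <- em_step(exact, m)
  expect_lt(max(abs(stepped$pz - exact$pz)), 1e-11)
  expect_lt(max(abs(stepped$pi_z - exact$pi_z)), 1e-11)
  expect_lt(max(abs(stepped$pv_z - exact$pv_z)), 1e-11)

  fit <- fit_plsa(m, 2, fit_config(seed = 5, n_restarts = 5))
  expect_lt(abs(fit$loglik - 5 * log(1 / 5)), 1e-4)
})

test_that("one EM step never decreases the log-likelihood", {
  for (s in 1:10) {
    m <- random_binary_matrix(6, 5, seed = s)
    model <- suppressWarnings(
      fit_plsa(m, 2, fit_config(seed = s, n_restarts = 1, max_iter = 3))
    )
    before <- log_likelihood(model, m)
    after <- log_likelihood(em_step(model, m), m)
    expect_gte(after, before - 1e-10)
  }
})

test_that("exactly uniform initialization stays collapsed to the K=1 fit", {
  m <- block_matrix()
  u <- uniform_model(3, 3, 2)
  stepped <- em_step(u, m)
  # symmetric start: the two cluster columns remain identical
  expect_lt(max(abs(stepped$pi_z[, 1] - stepped$pi_z[, 2])), 1e-12)
  expect_lt(max(abs(stepped$pv_z[, 1] - stepped$pv_z[, 2])), 1e-12)
  # and the likelihood equals the independence (K=1) value
  k1 <- fit_plsa(m, 1, fit_config(seed = 1, n_restarts = 1))
  for (i in 1:50) stepped <- em_step(stepped, m)
  expect_equal(stepped$loglik, k1$loglik, tolerance = 1e-8)
})

test_that("multi-restart EM matches a direct-optimization oracle on small
           instances", {
  for (s in c(2, 6)) {
    m <- random_binary_matrix(4, 4, seed = s)
    fit <- fit_plsa(m, 2, fit_config(seed = 11, n_restarts = 10))
    oracle <- brute_force_plsa_loglik(m, 2, n_starts = 30, seed = 50 + s)
    expect_lt(abs(fit$loglik - oracle), 1e-4)
  }
})

test_that("log-likelihood trace is monotone and bounded by the saturated
           model over many random matrices", {
  for (s in 1:50) {
    I <- sample(3:7, 1)
    V <- sample(3:7, 1)
    m <- random_binary_matrix(I, V, seed = 100 + s)
    fit <- suppressWarnings(
      fit_plsa(m, 2, fit_config(seed = s, n_restarts = 1, max_iter = 60))
    )
    expect_true(all(diff(fit$trace) >= -1e-10), info = paste("seed", s))
    R <- sum(m)
    saturated <- sum(m[m > 0] * log(m[m > 0] / R))
    expect_lte(fit$loglik, saturated + 1e-9)
  }
})

test_that("optimal log-likelihood is invariant to row/column permutations
           and to cluster relabeling", {
  m <- block_matrix()
  cfg <- fit_config(seed = 2, n_restarts = 5)
  base <- fit_plsa(m, 2, cfg)
  pr <- c(3, 1, 2); pc <- c(2, 3, 1)
  perm <- fit_plsa(m[pr, pc], 2, cfg)
  expect_equal(base$loglik, perm$loglik, tolerance = 1e-6)

  relabeled <- base
  relabeled$pz <- base$pz[2:1]
  relabeled$pi_z <- base$pi_z[, 2:1]
  relabeled$pv_z <- base$pv_z[, 2:1]
  expect_equal(log_likelihood(relabeled, m), log_likelihood(base, m),
               tolerance = 1e-12)
})

test_that("best-of-restarts log-likelihood is non-decreasing in K", {
  m <- block_matrix()
  lls <- vapply(1:3, function(K) {
    fit_plsa(m, K, fit_config(seed = 4, n_restarts = 10))$loglik
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("fitted models survive a JSON round trip byte-exactly", {
  m <- random_binary_matrix(5, 4, seed = 3)
  fit <- suppressWarnings(fit_plsa(m, 2, fit_config(seed = 9,
                                                    n_restarts = 2)))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_model_json(fit, f1)
  back <- read_model_json(f1)
  expect_equal(back$pz, fit$pz, tolerance = 1e-12)
  expect_equal(unname(back$pi_z), unname(fit$pi_z), tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_identical(back$K, fit$K)
  expect_identical(back$row_ids, fit$row_ids)
  # serialization itself is deterministic: re-writing gives identical bytes
  write_model_json(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("impossible cluster counts are rejected", {
  m <- random_binary_matrix(3, 5, seed = 4)
  expect_error(fit_plsa(m, 4), "exceeds")
  expect_error(fit_plsa(m, 0), ">= 1")
  expect_error(fit_plsa(matrix(0, 2, 2), 1), "empty")
})
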