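# A small uniform spec for degenerate-case tests.
make_uniform_spec <- function(k_true = 1L, n_male = 10L, n_female = 10L,
                              seed = 1L) {
  cb <- default_codebook()
  theta <- lapply(seq_len(k_true), function(k) {
    lapply(cb$levels, function(lv) {
      p <- rep(1 / length(lv), length(lv))
      names(p) <- lv
      p
    })
  })
  mixing <- rep(1 / k_true, k_true)
  generator_spec(n_male, n_female, k_true,
                 mixing = list(male = mixing, female = mixing),
                 level_probs = list(male = theta, female = theta),
                 seed = seed, codebook = cb)
}

test_that("generation is byte-identical for identical spec and seed", {
  spec <- table1_preset(seed = 31)
  spec$n_male <- 150L; spec$n_female <- 150L
  a <- generate_roster(spec)
  b <- generate_roster(spec)
  expect_identical(a$roster, b$roster)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  spec2 <- table1_preset(seed = 32)
  spec2$n_male <- 150L; spec2$n_female <- 150L
  expect_false(identical(generate_roster(spec2)$roster, a$roster))
})

test_that("per-sex streams are independently reproducible", {
  spec <- table1_preset(seed = 5)
  spec$n_male <- 80L; spec$n_female <- 60L
  both <- generate_roster(spec)
  spec_m <- spec; spec_m$n_female <- 0L
  male_only <- generate_roster(spec_m)
  expect_identical(male_only$roster,
                   both$roster[both$roster$sex == "male", ])
})

test_that("a single-segment mixture yields all-ones ground truth", {
  spec <- make_uniform_spec(k_true = 1L)
  out <- generate_roster(spec)
  expect_true(all(out$truth$true_segment == 1L))
  expect_identical(nrow(out$roster), 20L)
})

test_that("invalid specs are rejected naming the offending field", {
  cb <- default_codebook()
  spec <- make_uniform_spec(k_true = 2L)
  bad_mix <- spec$mixing; bad_mix$male <- c(0.7, 0.4)
  expect_error(
    generator_spec(10, 10, 2, bad_mix, spec$level_probs, codebook = cb),
    "mixing\\$male"
  )
  bad_theta <- spec$level_probs
  bad_theta$female[[2]]$working <- c(yes = 0.5, no = 0.6)
  expect_error(
    generator_spec(10, 10, 2, spec$mixing, bad_theta, codebook = cb),
    "level_probs\\$female.*working"
  )
  expect_error(
    generator_spec(10, 10, 0, spec$mixing, spec$level_probs, codebook = cb),
    "k_true"
  )
})

test_that("the calibrated preset reproduces the published marginals
           exactly in expectation", {
  spec <- table1_preset()
  expect_identical(spec$n_male, 1483L)
  expect_identical(spec$n_female, 1682L)
  expect_identical(spec$k_true, 5L)
  for (sex in c("male", "female")) {
    target <- table1_marginals_for_test(sex)
    pi_s <- spec$mixing[[sex]]
    for (v in spec$codebook$variables) {
      mix <- Reduce(`+`, Map(function(p, th) p * th[[v]],
                             pi_s, spec$level_probs[[sex]]))
      expect_lt(max(abs(mix - target[[v]])), 0.005)
      # and in fact exact to numerical precision by construction
      expect_lt(max(abs(mix - target[[v]])), 1e-12)
    }
    for (k in seq_len(5L)) {
      for (v in spec$codebook$variables) {
        th <- spec$level_probs[[sex]][[k]][[v]]
        expect_true(all(th >= 0) && abs(sum(th) - 1) < 1e-12)
      }
    }
  }
})

test_that("preset segments are well separated: three 0.8-levels jointly
           distinguishing each segment", {
  spec <- table1_preset()
  for (sex in c("male", "female")) {
    theta <- spec$level_probs[[sex]]
    K <- spec$k_true
    flat <- lapply(theta, function(th) unlist(th))
    for (k in seq_len(K)) {
      high <- which(flat[[k]] >= 0.8)
      expect_gte(length(high), 3L)
      others <- setdiff(seq_len(K), k)
      # a greedy check: for every other segment, some high level of k
      # falls below 0.5 there
      separated <- vapply(others, function(j) {
        any(flat[[j]][high] < 0.5)
      }, logical(1))
      expect_true(all(separated),
                  info = paste(sex, "segment", k))
    }
  }
})

test_that("empirical frequencies converge to the mixture marginals", {
  spec <- table1_preset(seed = 77)
  spec$n_male <- 20000L; spec$n_female <- 0L
  out <- generate_roster(spec)
  target <- table1_marginals_for_test("male")
  for (v in c("age_group", "working", "pension_band", "living_alone")) {
    emp <- prop.table(table(factor(out$roster[[v]],
                                   levels = names(target[[v]]))))
    expect_lt(max(abs(as.numeric(emp) - target[[v]])), 0.01)
  }
})

test_that("a single preset draw lands near the published 'living alone'
           share of men", {
  spec <- table1_preset(seed = 2024)
  gen <- generate_roster(spec)
  males <- gen$roster[gen$roster$sex == "male", ]
  share <- 100 * mean(males$living_alone == "yes")
  expect_lt(abs(share - 73.0), 3.0)
})

test_that("the log-likelihood is invariant to individual order", {
  spec <- table1_preset(seed = 3)
  spec$n_male <- 40L; spec$n_female <- 0L
  roster <- generate_roster(spec)$roster
  m <- encode_roster(roster)
  fit <- suppressWarnings(fit_plsa(m, 2, fit_config(seed = 6,
                                                    n_restarts = 5)))
  set.seed(1)
  perm <- sample(nrow(m))
  permuted_fit <- fit
  permuted_fit$pi_z <- fit$pi_z[perm, , drop = FALSE]
  expect_equal(log_likelihood(permuted_fit, m[perm, ]),
               log_likelihood(fit, m), tolerance = 1e-10)
})
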