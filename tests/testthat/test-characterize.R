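test_that("affiliation is the posterior cluster distribution", {
  m <- structure(
    list(K = 2L, pz = c(0.5, 0.5),
         pi_z = cbind(c(0.5, 0.5), c(0.5, 0.5)),
         pv_z = cbind(c(0.3, 0.7), c(0.2, 0.8)),
         row_ids = c("a", "b"), column_labels = c("x", "y"), seed = 0L),
    class = "plsa_model"
  )
  af <- affiliation(m)
  expect_equal(unname(af$var_affil["x", ]), c(0.6, 0.4), tolerance = 1e-12)
  expect_equal(unname(rowSums(af$var_affil)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(rowSums(af$ind_affil)), c(1, 1), tolerance = 1e-12)

  # unequal priors dominate equal likelihoods
  m$pz <- c(0.8, 0.2)
  expect_equal(unname(affiliation(m)$ind_affil["a", ]), c(0.8, 0.2),
               tolerance = 1e-12)

  # K = 1: everything belongs to the single cluster
  m1 <- uniform_model(3, 3, 1)
  expect_true(all(affiliation(m1)$var_affil == 1))

  # zero-mass entity gets uniform affiliation with a warning
  m$pv_z <- cbind(c(0, 1), c(0, 1))
  expect_warning(af0 <- affiliation(m), "zero total mass")
  expect_equal(unname(af0$var_affil["x", ]), c(0.5, 0.5))
})

test_that("profiles respect the inclusive 0.55 threshold and are
           anti-monotone in tau", {
  af <- structure(
    list(
      var_affil = matrix(
        c(0.55, 0.45,
          0.549, 0.451,
          0.5, 0.5,
          0.9, 0.1),
        ncol = 2, byrow = TRUE,
        dimnames = list(c("v1:at", "v2:just_below", "v3:tie", "v4:high"),
                        NULL)
      ),
      ind_affil = matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE,
                         dimnames = list(c("i1", "i2"), NULL))
    ),
    class = "affiliation_table"
  )
  prof <- suppressWarnings(characterize(af, tau = 0.55))
  levels1 <- prof[[1]]$levels
  expect_true("at" %in% levels1$level)        # exactly at tau: included
  expect_false("just_below" %in% levels1$level)
  expect_identical(levels1$level[1], "high")  # sorted by affiliation
  expect_identical(prof[[1]]$n_members, 1L)
  expect_identical(prof[[2]]$n_members, 1L)

  # at tau = 0.5 a 50/50 level appears in both profiles (the rationale for
  # preferring 0.55)
  prof50 <- characterize(af, tau = 0.5)
  expect_true("tie" %in% prof50[[1]]$levels$level)
  expect_true("tie" %in% prof50[[2]]$levels$level)

  # raising tau never adds a level to any profile
  taus <- c(0.3, 0.5, 0.55, 0.7, 0.9)
  sizes <- sapply(taus, function(t) {
    p <- suppressWarnings(characterize(af, t))
    vapply(p, function(x) nrow(x$levels), integer(1))
  })
  expect_true(all(apply(sizes, 1, function(s) all(diff(s) <= 0))))

  # clusters may legitimately end up empty, with a warning
  expect_warning(characterize(af, tau = 0.95), "no variable-level")
  expect_error(characterize(af, tau = 0), "tau")
})

test_that("descriptive percentages reproduce printed rounding", {
  # printed examples: counts over the stratum size, half away from zero
  spec <- table1_preset()
  roster <- generate_roster(spec)$roster
  d <- descriptive_table(roster)
  expect_true(all(abs(stats::aggregate(
    pct ~ sex + variable, data = d, FUN = sum)$pct - 100) <= 0.2))

  # direct rounding checks through a crafted roster: 7/800 = 0.875 -> 0.9
  cb <- default_codebook()
  n <- 800L
  crafted <- data.frame(id = sprintf("C%03d", 1:n), sex = "male",
                        stringsAsFactors = FALSE)
  for (v in cb$variables) crafted[[v]] <- cb$levels[[v]][1]
  crafted$working <- c(rep("yes", 7L), rep("no", n - 7L))
  dc <- descriptive_table(crafted)
  expect_identical(dc$pct[dc$sex == "male" & dc$variable == "working" &
                            dc$level == "yes"], 0.9)
  expect_identical(dc$pct[dc$sex == "male" & dc$variable == "working" &
                            dc$level == "no"], 99.1)
  # zero counts give 0.0, empty stratum gives NA
  expect_identical(unique(dc$pct[dc$sex == "male" &
                                   dc$variable == "nationality" &
                                   dc$level == "foreign"]), 0)
  expect_true(all(is.na(dc$pct[dc$sex == "female"])))
})

test_that("median banding uses positive amounts and sends ties below", {
  b1 <- median_band(c(10, 20, 30, 40))
  expect_identical(as.character(b1),
                   c("below_median", "below_median",
                     "above_median", "above_median"))
  expect_identical(attr(b1, "median"), 25)

  b2 <- median_band(c(0, 0, 0))
  expect_true(all(b2 == "none"))
  expect_true(is.na(attr(b2, "median")))

  b3 <- median_band(c(10, 20, 30))
  expect_identical(as.character(b3),
                   c("below_median", "below_median", "above_median"))
  expect_error(median_band(c(-1, 5)), ">= 0")
})

test_that("cluster matching recovers a label swap exactly", {
  spec <- table1_preset(seed = 9)
  theta <- spec$level_probs$male
  K <- 5L
  pv <- sapply(seq_len(K), function(k) unlist(theta[[k]]) / 13)
  pv <- sweep(pv, 2, colSums(pv), "/")
  swap <- c(2L, 1L, 3L, 5L, 4L)
  model <- structure(
    list(K = K, pz = rep(0.2, K), pi_z = matrix(0.1, 10, K),
         pv_z = pv[, swap], row_ids = paste0("i", 1:10),
         column_labels = unlist(lapply(
           spec$codebook$variables,
           function(v) paste(v, spec$codebook$levels[[v]], sep = ":")))),
    class = "plsa_model"
  )
  mc <- match_clusters(model, spec, "male", source = "emission")
  expect_identical(mc$permutation[swap], 1:5)
  expect_lt(mc$recovery_error, 1e-12)

  ident <- model; ident$pv_z <- pv
  mc2 <- match_clusters(ident, spec, "male", source = "emission")
  expect_identical(mc2$permutation, 1:5)
  expect_lt(mc2$recovery_error, 1e-12)

  small <- model; small$K <- 4L
  expect_error(match_clusters(small, spec, "male"), "k_true")
})

test_that("hard-assignment cluster sizes partition the stratum", {
  spec <- table1_preset(seed = 13)
  spec$n_male <- 200L; spec$n_female <- 0L
  m <- encode_roster(generate_roster(spec)$roster)
  fit <- suppressWarnings(fit_plsa(m, 3, fit_config(seed = 2,
                                                    n_restarts = 3)))
  af <- affiliation(fit)
  prof <- suppressWarnings(characterize(af))
  expect_identical(sum(vapply(prof, `[[`, integer(1), "n_members")), 200L)
})
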