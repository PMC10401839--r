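# Small fixtures built in code, shared across test files.

# 3x3 block co-occurrence matrix whose empirical cell distribution is
# exactly representable at K = 2: five observed cells, each at mass 1/5,
# so the saturated bound sum n log(n/R) = 5 * log(1/5) is attainable.
block_matrix <- function() {
  m <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  dimnames(m) <- list(paste0("i", 1:3), paste0("v", 1:3))
  m
}

# Parameters that reproduce the block matrix exactly (a fixed point of EM).
block_exact_model <- function() {
  pz <- c(0.8, 0.2)
  pi_z <- cbind(c(0.5, 0.5, 0), c(0, 0, 1))
  pv_z <- cbind(c(0.5, 0.5, 0), c(0, 0, 1))
  structure(
    list(K = 2L, pz = pz, pi_z = pi_z, pv_z = pv_z, loglik = 5 * log(0.2),
         n_iter = 0L, seed = 0L, converged = TRUE,
         row_ids = paste0("i", 1:3), column_labels = paste0("v", 1:3)),
    class = "plsa_model"
  )
}

# Uniform-parameter model of arbitrary size (used for symmetry tests).
uniform_model <- function(I, V, K) {
  structure(
    list(K = as.integer(K), pz = rep(1 / K, K),
         pi_z = matrix(1 / I, I, K), pv_z = matrix(1 / V, V, K),
         loglik = 0, n_iter = 0L, seed = 0L, converged = FALSE,
         row_ids = paste0("i", seq_len(I)),
         column_labels = paste0("v", seq_len(V))),
    class = "plsa_model"
  )
}

# Random binary matrix with no all-zero row or column.
random_binary_matrix <- function(I, V, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(I * V, 1, p), I, V)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("i", seq_len(I)), paste0("v", seq_len(V)))
  m
}

# A tiny hand-written roster covering several variables and both sexes.
tiny_roster <- function() {
  cb <- default_codebook()
  set.seed(42)
  n <- 12L
  out <- data.frame(
    id = sprintf("T%02d", seq_len(n)),
    sex = rep(c("male", "female"), each = 6),
    stringsAsFactors = FALSE
  )
  for (v in cb$variables) {
    out[[v]] <- sample(cb$levels[[v]], n, replace = TRUE)
  }
  out
}

# Direct likelihood maximization by general-purpose optimization over a
# softmax parameterization, multi-start. Serves as an independent oracle
# for small instances: it shares no code path with the EM implementation.
brute_force_plsa_loglik <- function(m, K, n_starts = 30, seed = 99) {
  cells <- which(m != 0, arr.ind = TRUE)
  w <- m[m != 0]
  I <- nrow(m); V <- ncol(m)
  n_par <- K + I * K + V * K
  obj <- function(par) {
    pz <- exp(par[seq_len(K)])
    pz <- pz / sum(pz)
    pi_z <- matrix(exp(par[K + seq_len(I * K)]), I, K)
    pi_z <- sweep(pi_z, 2, colSums(pi_z), "/")
    pv_z <- matrix(exp(par[K + I * K + seq_len(V * K)]), V, K)
    pv_z <- sweep(pv_z, 2, colSums(pv_z), "/")
    p <- (pi_z[cells[, 1], , drop = FALSE] *
            pv_z[cells[, 2], , drop = FALSE]) %*% pz
    -sum(w * log(pmax(p, 1e-300)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    fit <- stats::optim(stats::rnorm(n_par), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (fit$value < best) best <- fit$value
  }
  -best
}

# Published per-sex marginal probabilities (internal helper re-exported
# for test assertions).
table1_marginals_for_test <- function(sex) {
  segmint:::table1_marginals(sex)
}
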