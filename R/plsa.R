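#' EM fitting configuration
#'
#' Controls for the multi-restart EM fit of the PLSA model: five random
#' restarts by default (each restart re-initializes the parameters from a
#' new seeded draw), relative log-likelihood convergence tolerance, an
#' iteration cap, and a small probability floor applied after each M-step
#' to keep the log-likelihood finite on sparse data.
#'
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood change below which a chain is declared
#'   converged.
#' @param n_restarts Number of independent random initializations.
#' @param seed Root seed; restart `r` initializes from seed `seed + r`.
#' @param floor Probability floor applied after each M-step, then
#'   renormalized.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(max_iter = 500L, tol = 1e-8, n_restarts = 5L,
                       seed = 1L, floor = 1e-12) {
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (n_restarts < 1L) stop("n_restarts must be >= 1", call. = FALSE)
  structure(
    list(max_iter = as.integer(max_iter), tol = tol,
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         floor = floor),
    class = "fit_config"
  )
}

# Nonzero cells of a co-occurrence matrix as 0-based index triplets.
matrix_cells <- function(m) {
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("co-occurrence counts must be nonnegative",
                       call. = FALSE)
  nz <- which(m != 0)
  list(
    ii = as.integer((nz - 1L) %% nrow(m)),
    vv = as.integer((nz - 1L) %/% nrow(m)),
    w = m[nz],
    I = nrow(m), V = ncol(m), R = sum(m)
  )
}

new_plsa_model <- function(K, pz, pi_z, pv_z, loglik, n_iter, seed,
                           converged, row_ids = NULL, column_labels = NULL,
                           trace = NULL) {
  tol <- 1e-10
  stopifnot(
    abs(sum(pz) - 1) < tol,
    all(abs(colSums(pi_z) - 1) < tol),
    all(abs(colSums(pv_z) - 1) < tol),
    is.finite(loglik)
  )
  structure(
    list(K = as.integer(K), pz = pz, pi_z = pi_z, pv_z = pv_z,
         loglik = loglik, n_iter = as.integer(n_iter),
         seed = as.integer(seed), converged = converged,
         row_ids = row_ids, column_labels = column_labels,
         trace = trace),
    class = "plsa_model"
  )
}

#' @export
print.plsa_model <- function(x, ...) {
  cat("PLSA model: K =", x$K, "clusters,",
      nrow(x$pi_z), "individuals x", nrow(x$pv_z), "variable-levels\n")
  cat("  log-likelihood:", format(x$loglik, digits = 10),
      " iterations:", x$n_iter,
      " converged:", x$converged, " init seed:", x$seed, "\n")
  cat("  P(z):", paste(signif(x$pz, 4), collapse = " "), "\n")
  invisible(x)
}

#' PLSA log-likelihood of a co-occurrence matrix
#'
#' Computes `sum_{i,v} n(i,v) * log sum_z P(z) P(i|z) P(v|z)` over the
#' observed (nonzero) cells; zero cells contribute nothing.
#'
#' @param model A `plsa_model`.
#' @param m A nonnegative co-occurrence matrix with dimensions matching the
#'   model.
#' @return The log-likelihood (natural log).
#' @export
log_likelihood <- function(model, m) {
  if (nrow(model$pi_z) != nrow(m) || nrow(model$pv_z) != ncol(m)) {
    stop("model dimensions do not match the matrix", call. = FALSE)
  }
  cells <- matrix_cells(m)
  if (cells$R == 0) return(0)
  p <- as.vector(
    (model$pi_z[cells$ii + 1L, , drop = FALSE] *
       model$pv_z[cells$vv + 1L, , drop = FALSE]) %*% model$pz
  )
  if (any(p <= 0)) {
    stop("an observed cell has zero modeled probability ",
         "(probability floor is broken)", call. = FALSE)
  }
  sum(cells$w * log(p))
}

#' Single EM update of a PLSA model
#'
#' Applies one E-step (posterior responsibilities `P(z|i,v)` proportional to
#' `P(z)P(i|z)P(v|z)` over observed cells) and one M-step (re-estimation of
#' `P(v|z)`, `P(i|z)`, `P(z)` from responsibility-weighted counts),
#' returning a new normalized model. The configured probability floor is
#' applied after the M-step.
#'
#' @param model A `plsa_model`.
#' @param m The co-occurrence matrix the model is being fitted to.
#' @param floor Probability floor (see [fit_config()]).
#' @return An updated `plsa_model`; its `loglik` is evaluated at the updated
#'   parameters.
#' @export
em_step <- function(model, m, floor = 1e-12) {
  if (nrow(model$pi_z) != nrow(m) || nrow(model$pv_z) != ncol(m)) {
    stop("model dimensions do not match the matrix", call. = FALSE)
  }
  cells <- matrix_cells(m)
  res <- plsa_em_cpp(cells$ii, cells$vv, cells$w, cells$I, cells$V, model$K,
                     model$pz, model$pi_z, model$pv_z,
                     max_iter = 1L, tol = 0, floor_p = floor)
  out <- new_plsa_model(
    K = model$K, pz = res$pz, pi_z = res$pi_z, pv_z = res$pv_z,
    loglik = res$trace[length(res$trace)], n_iter = 1L, seed = model$seed,
    converged = FALSE, row_ids = model$row_ids,
    column_labels = model$column_labels
  )
  out
}

# Random initialization for one restart: P(i|z), P(v|z) columns drawn from
# a symmetric Dirichlet(0.5), P(z) uniform. Random draws break the symmetry
# that traps exactly uniform starts at the K-collapsed stationary point; the
# Jeffreys-style concentration 0.5 gives sharper starts than a flat
# Dirichlet, which on simplexes of roster size concentrates so close to the
# barycenter that a substantial share of chains collapse into degenerate
# local optima with near-empty clusters.
init_params <- function(I, V, K, seed) {
  set.seed(seed)
  pi_z <- matrix(stats::rgamma(I * K, shape = 0.5) + 1e-300, I, K)
  pi_z <- sweep(pi_z, 2L, colSums(pi_z), "/")
  pv_z <- matrix(stats::rgamma(V * K, shape = 0.5) + 1e-300, V, K)
  pv_z <- sweep(pv_z, 2L, colSums(pv_z), "/")
  list(pz = rep(1 / K, K), pi_z = pi_z, pv_z = pv_z)
}

#' Fit a PLSA model by multi-restart EM
#'
#' Fits the soft-clustering model `P(i,v) = sum_z P(z) P(i|z) P(v|z)` to a
#' binary individual-by-variable-level co-occurrence matrix. Each restart
#' runs EM from an independent seeded random initialization until the
#' relative log-likelihood change falls below `config$tol` or `config$max_iter`
#' is reached; the chain with the highest final log-likelihood wins and its
#' init seed and iteration count are recorded on the model.
#'
#' @param m Co-occurrence matrix (rows: individuals; columns:
#'   variable-levels), e.g. from [encode_roster()].
#' @param K Number of clusters (`K >= 1`; at most `min(nrow(m), ncol(m))`).
#' @param config A [fit_config()].
#' @return A `plsa_model`. If no restart converged within `max_iter`, the
#'   best model is returned with `converged = FALSE` and a warning.
#' @examples
#' m <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
#' fit <- fit_plsa(m, K = 2, config = fit_config(seed = 1))
#' fit$loglik  # close to 5 * log(1/5)
#' @export
fit_plsa <- function(m, K, config = fit_config()) {
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > nrow(m) || K > ncol(m)) {
    stop("K exceeds the number of individuals or variable-levels",
         call. = FALSE)
  }
  if (nrow(m) == 0L || sum(m) == 0) stop("matrix is empty", call. = FALSE)
  cells <- matrix_cells(m)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    seed_r <- config$seed + r
    init <- init_params(cells$I, cells$V, K, seed_r)
    res <- plsa_em_cpp(cells$ii, cells$vv, cells$w, cells$I, cells$V, K,
                       init$pz, init$pi_z, init$pv_z,
                       max_iter = config$max_iter, tol = config$tol,
                       floor_p = config$floor)
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$seed <- seed_r
    }
  }
  if (!best$converged) {
    warning("EM did not converge within ", config$max_iter,
            " iterations (best restart seed ", best$seed, ")",
            call. = FALSE)
  }
  new_plsa_model(
    K = K, pz = best$pz, pi_z = best$pi_z, pv_z = best$pv_z,
    loglik = best$loglik, n_iter = best$n_iter, seed = best$seed,
    converged = best$converged, row_ids = rownames(m),
    column_labels = colnames(m), trace = best$trace
  )
}

#' Serialize and restore fitted PLSA models as JSON
#'
#' @param model A `plsa_model`.
#' @param path JSON file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the restored `plsa_model`.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    k = model$K, pz = model$pz,
    pi_z = unname(model$pi_z), pv_z = unname(model$pv_z),
    loglik = model$loglik, n_iter = model$n_iter, seed = model$seed,
    converged = model$converged,
    row_ids = model$row_ids, column_labels = model$column_labels
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_plsa_model(
    K = p$k, pz = p$pz, pi_z = as.matrix(p$pi_z), pv_z = as.matrix(p$pv_z),
    loglik = p$loglik, n_iter = p$n_iter, seed = p$seed,
    converged = p$converged, row_ids = p$row_ids,
    column_labels = p$column_labels
  )
}
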