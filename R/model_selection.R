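#' Free-parameter count of a PLSA model
#'
#' Under the full symmetric parameterization the model has `(K-1)` free
#' mixing weights, `K*(I-1)` individual-membership parameters and
#' `K*(V-1)` level-emission parameters.
#'
#' Because the membership block grows with the number of individuals, these
#' are "incidental" parameters in the classical sense: information criteria
#' computed with the full count penalize every additional cluster by
#' roughly `(I + V) * log(R)`, which at roster-sized data dwarfs any
#' achievable likelihood gain. The aspect-style count (`"emission"`)
#' excludes the membership block and counts `(K-1) + K*(V-1)`; see
#' [selection_policy()] for how the two are used.
#'
#' @param K Number of clusters.
#' @param I Number of individuals.
#' @param V Number of variable-levels.
#' @param parameterization `"full"` (default) or `"emission"`.
#' @return The free-parameter count.
#' @examples
#' count_parameters(3, 10, 5)  # 41
#' @export
count_parameters <- function(K, I, V,
                             parameterization = c("full", "emission")) {
  parameterization <- match.arg(parameterization)
  stopifnot(K >= 1, I >= 1, V >= 1)
  if (parameterization == "full") {
    (K - 1) + K * (I - 1) + K * (V - 1)
  } else {
    (K - 1) + K * (V - 1)
  }
}

#' Model-number selection policy
#'
#' Makes explicit how the working number of clusters is chosen from a sweep
#' table: which criterion is minimized, the smallest admissible cluster size
#' (by hard assignment), and the tolerance within which ties are resolved
#' toward smaller K. Interpretability of the candidate models remains a
#' human step: [select_k()] returns the ranked table alongside the chosen K
#' so profiles of competing K can be inspected.
#'
#' @param criterion `"bic"` or `"aic"`.
#' @param min_cluster_n_floor Smallest admissible hard-assigned cluster
#'   size; rows whose smallest cluster falls below it are excluded. Values
#'   in (0, 1) are read as a fraction of the stratum size (default 0.08:
#'   a working segment must cover at least 8% of the stratum — smaller
#'   fragments are symptomatic of noise-driven over-segmentation rather
#'   than actionable subpopulations).
#' @param tie_tolerance Nonnegative; criterion values this close to the
#'   admissible minimum count as ties, resolved toward the smallest K.
#' @param tie_type `"relative"` (tolerance as a fraction of the minimum
#'   criterion value, default) or `"absolute"`.
#' @param parameterization Free-parameter count convention used when the
#'   criterion is computed; see [count_parameters()].
#' @return A list of class `selection_policy`.
#' @export
selection_policy <- function(criterion = c("bic", "aic"),
                             min_cluster_n_floor = 0.08,
                             tie_tolerance = 0.002,
                             tie_type = c("relative", "absolute"),
                             parameterization = c("emission", "full")) {
  criterion <- match.arg(criterion)
  parameterization <- match.arg(parameterization)
  tie_type <- match.arg(tie_type)
  if (tie_tolerance < 0) stop("tie_tolerance must be >= 0", call. = FALSE)
  if (min_cluster_n_floor < 0) {
    stop("min_cluster_n_floor must be >= 0", call. = FALSE)
  }
  structure(
    list(criterion = criterion,
         min_cluster_n_floor = min_cluster_n_floor,
         tie_tolerance = tie_tolerance,
         tie_type = tie_type,
         parameterization = parameterization),
    class = "selection_policy"
  )
}

#' Sweep the number of clusters and score each fit
#'
#' Fits PLSA for every `K` in `k_min:k_max` (each the best of
#' `config$n_restarts` seeded EM chains) and tabulates the log-likelihood,
#' free-parameter counts, AIC and BIC under both parameter-count
#' conventions, and the smallest cluster by mass (`min P(z)`) and by
#' hard-assigned member count.
#'
#' `aic = -2*loglik + 2*d` and `bic = -2*loglik + d*log(R)`, where by
#' default `R` is the total co-occurrence count (individuals times the 13
#' variables); `bic_n = "individuals"` uses the roster size instead.
#'
#' @param m Co-occurrence matrix.
#' @param k_min,k_max Sweep range (defaults 2 and 10).
#' @param config A [fit_config()]; restart seeds derive from `config$seed`
#'   and `K` so every fit is reproducible in isolation.
#' @param bic_n Sample-size convention for the BIC penalty.
#' @param keep_models Keep the fitted models (attribute `"models"`).
#' @return A `data.frame` of class `model_selection_table` with one row per
#'   K: `k`, `loglik`, `n_params`, `aic`, `bic`, `n_params_emission`,
#'   `aic_emission`, `bic_emission`, `min_cluster_mass`, `min_cluster_n`,
#'   `seed_best`, `n_iter`, `converged`.
#' @export
sweep_k <- function(m, k_min = 2L, k_max = 10L, config = fit_config(),
                    bic_n = c("tokens", "individuals"),
                    keep_models = TRUE) {
  bic_n <- match.arg(bic_n)
  I <- nrow(m); V <- ncol(m)
  if (!(k_min >= 1L && k_min <= k_max && k_max <= min(I, V))) {
    stop("need 1 <= k_min <= k_max <= min(individuals, levels)",
         call. = FALSE)
  }
  R <- if (bic_n == "tokens") sum(m) else I
  ks <- seq.int(k_min, k_max)
  models <- vector("list", length(ks))
  rows <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    K <- ks[j]
    cfg_k <- config
    cfg_k$seed <- config$seed + 1000L * K
    fit <- tryCatch(
      fit_plsa(m, K, cfg_k),
      error = function(e) stop("K = ", K, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    models[[j]] <- fit
    sizes <- tabulate(hard_assign(affiliation(fit)), nbins = K)
    d_full <- count_parameters(K, I, V, "full")
    d_emis <- count_parameters(K, I, V, "emission")
    rows[[j]] <- data.frame(
      k = K, n_individuals = I, loglik = fit$loglik,
      n_params = d_full,
      aic = -2 * fit$loglik + 2 * d_full,
      bic = -2 * fit$loglik + d_full * log(R),
      n_params_emission = d_emis,
      aic_emission = -2 * fit$loglik + 2 * d_emis,
      bic_emission = -2 * fit$loglik + d_emis * log(R),
      min_cluster_mass = min(fit$pz),
      min_cluster_n = min(sizes),
      seed_best = fit$seed, n_iter = fit$n_iter,
      converged = fit$converged
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "R") <- R
  if (keep_models) attr(out, "models") <- models
  class(out) <- c("model_selection_table", "data.frame")
  out
}

#' Choose the working number of clusters from a sweep table
#'
#' Among rows whose smallest hard-assigned cluster passes the policy floor,
#' picks the K minimizing the policy criterion; criterion values within
#' `tie_tolerance` of the minimum are resolved toward the smallest K. The
#' full ranked table is attached so the interpretability of competing
#' candidates can be judged by a human.
#'
#' @param table A `model_selection_table` from [sweep_k()].
#' @param policy A [selection_policy()].
#' @return The chosen K (integer) with attribute `"ranked"` (the admissible
#'   rows ordered by the criterion).
#' @export
select_k <- function(table, policy = selection_policy()) {
  if (nrow(table) == 0L) stop("selection table is empty", call. = FALSE)
  col <- paste0(
    policy$criterion,
    if (policy$parameterization == "emission") "_emission" else ""
  )
  floor_n <- policy$min_cluster_n_floor
  if (floor_n > 0 && floor_n < 1) {
    floor_n <- ceiling(floor_n * table$n_individuals)
  }
  ok <- table$min_cluster_n >= floor_n
  if (!any(ok)) {
    stop("no candidate K has a smallest cluster of at least ",
         paste(unique(floor_n), collapse = "/"),
         " members; lower min_cluster_n_floor", call. = FALSE)
  }
  cand <- table[ok, , drop = FALSE]
  crit <- cand[[col]]
  slack <- if (policy$tie_type == "relative") {
    policy$tie_tolerance * abs(min(crit))
  } else {
    policy$tie_tolerance
  }
  tied <- crit <= min(crit) + slack
  k <- min(cand$k[tied])
  ranked <- cand[order(crit, cand$k), , drop = FALSE]
  attr(ranked, "models") <- NULL
  structure(as.integer(k), ranked = ranked)
}
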