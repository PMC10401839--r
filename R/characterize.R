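#' Affiliation probabilities of variable-levels and individuals
#'
#' The affiliation of a variable-level with a cluster is the posterior
#' cluster distribution given the level, `A(z|v) = P(v|z)P(z) / sum_k
#' P(v|z_k)P(z_k)`; individuals analogously via `P(i|z)`. Affiliations sum
#' to 1 across clusters for every entity, which is what makes the 0.55
#' profile threshold meaningful: mass not in one cluster necessarily
#' belongs to the others.
#'
#' @param model A `plsa_model`.
#' @return A list of class `affiliation_table` with `var_affil`
#'   (levels x clusters) and `ind_affil` (individuals x clusters); every row
#'   sums to 1.
#' @export
affiliation <- function(model) {
  posterior <- function(cond) {
    joint <- sweep(cond, 2L, model$pz, "*")
    tot <- rowSums(joint)
    zero <- tot <= 0
    if (any(zero)) {
      warning(sum(zero), " entit(ies) with zero total mass; ",
              "assigned uniform affiliation", call. = FALSE)
      joint[zero, ] <- 1 / model$K
      tot[zero] <- 1
    }
    joint / tot
  }
  var_affil <- posterior(model$pv_z)
  ind_affil <- posterior(model$pi_z)
  rownames(var_affil) <- model$column_labels
  rownames(ind_affil) <- model$row_ids
  structure(list(var_affil = var_affil, ind_affil = ind_affil),
            class = "affiliation_table")
}

# Hard assignment of individuals: argmax affiliation (first max on ties).
hard_assign <- function(affil) {
  max.col(affil$ind_affil, ties.method = "first")
}

#' Extract cluster profiles at an affiliation threshold
#'
#' For each cluster, lists the variable-levels whose affiliation probability
#' is at or above `tau` (default 0.55 — chosen above 0.50 so a profiled
#' level cannot belong to another cluster with equal probability), sorted by
#' affiliation descending, together with the cluster's hard-assigned member
#' count.
#'
#' @param affil An `affiliation_table` from [affiliation()].
#' @param tau Inclusion threshold in (0, 1]; a level with affiliation
#'   exactly `tau` is included.
#' @return A list of class `cluster_profiles`; one element per cluster with
#'   `cluster`, `n_members`, and a data.frame `levels` (`variable`, `level`,
#'   `affiliation`). Clusters with no level at or above `tau` are emitted
#'   empty with a warning.
#' @export
characterize <- function(affil, tau = 0.55) {
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]", call. = FALSE)
  K <- ncol(affil$var_affil)
  members <- tabulate(hard_assign(affil), nbins = K)
  labels <- rownames(affil$var_affil)
  profiles <- lapply(seq_len(K), function(k) {
    a <- affil$var_affil[, k]
    keep <- which(a >= tau)
    keep <- keep[order(a[keep], decreasing = TRUE)]
    lv <- labels[keep]
    parts <- strsplit(lv, ":", fixed = TRUE)
    list(
      cluster = k,
      n_members = members[k],
      levels = data.frame(
        variable = vapply(parts, `[`, character(1), 1L),
        level = vapply(parts, `[`, character(1), 2L),
        affiliation = unname(a[keep]),
        stringsAsFactors = FALSE
      )
    )
  })
  empty <- which(vapply(profiles, function(p) nrow(p$levels) == 0L,
                        logical(1)))
  if (length(empty) > 0L) {
    warning("cluster(s) ", paste(empty, collapse = ", "),
            " have no variable-level with affiliation >= ", tau,
            call. = FALSE)
  }
  structure(profiles, class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  for (p in x) {
    cat("Cluster ", p$cluster, " (n = ", p$n_members, "):\n", sep = "")
    if (nrow(p$levels) == 0L) {
      cat("  <no level above threshold>\n")
    } else {
      for (j in seq_len(nrow(p$levels))) {
        cat(sprintf("  %-22s %-24s %.3f\n", p$levels$variable[j],
                    p$levels$level[j], p$levels$affiliation[j]))
      }
    }
  }
  invisible(x)
}

#' Write cluster profiles as JSON
#'
#' @param profiles A `cluster_profiles` object.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_profiles_json <- function(profiles, path) {
  payload <- lapply(profiles, function(p) {
    list(cluster = p$cluster, n_members = p$n_members,
         levels = p$levels)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

# Percentage rounding used in the descriptive table: half away from zero,
# one decimal.
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Descriptive summary of a roster, stratified by sex
#'
#' Per-sex counts and percentages for every variable level, in codebook
#' order; percentages are `100 * count / N_sex` rounded half away from zero
#' to one decimal, matching the published table's style.
#'
#' @param roster A roster `data.frame`.
#' @param codebook A `pa_codebook`.
#' @return A `data.frame` with columns `sex`, `variable`, `level`, `n`,
#'   `pct`. In an empty stratum counts are zero and `pct` is `NA`.
#' @export
descriptive_table <- function(roster, codebook = default_codebook()) {
  validate_roster(roster, codebook)
  out <- list()
  for (sex in c("male", "female")) {
    sub <- roster[roster$sex == sex, , drop = FALSE]
    N <- nrow(sub)
    for (v in codebook$variables) {
      lev <- codebook$levels[[v]]
      counts <- table(factor(sub[[v]], levels = lev))
      out[[length(out) + 1L]] <- data.frame(
        sex = sex, variable = v, level = lev,
        n = as.integer(counts),
        pct = if (N > 0) round_half_up(100 * as.integer(counts) / N) else
          NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Band monthly amounts by the within-stratum median
#'
#' Reproduces the three-band coding of working income and pension: an
#' individual with a zero amount is banded `none`; the median is computed
#' over the strictly positive amounts only; amounts above the median are
#' `above_median`, amounts at or below it `below_median` (ties go below,
#' which reproduces the published near-even above/below counts).
#'
#' @param amounts Nonnegative numeric vector of monthly amounts (yen),
#'   typically one stratum (sex) at a time.
#' @return A character vector of bands (`above_median`, `below_median`,
#'   `none`) with the positive-amount median attached as attribute
#'   `"median"`.
#' @examples
#' median_band(c(10, 20, 30, 0))  # median 20; 20 goes below
#' @export
median_band <- function(amounts) {
  if (any(amounts < 0)) stop("amounts must be >= 0", call. = FALSE)
  pos <- amounts > 0
  med <- if (any(pos)) stats::median(amounts[pos]) else NA_real_
  band <- rep("none", length(amounts))
  band[pos & amounts > med] <- "above_median"
  band[pos & amounts <= med] <- "below_median"
  attr(band, "median") <- med
  band
}

#' Match fitted clusters to the generator's ground-truth segments
#'
#' Mixture likelihoods are invariant to permutations of the cluster labels,
#' so fitted clusters must be aligned with the generating segments before
#' parameters can be compared. For each candidate permutation this computes
#' the mean total-variation (TV) distance between each cluster's estimated
#' per-variable level distributions and the generator's, and returns the
#' permutation minimizing that mean together with the minimized value (the
#' recovery error). The search is exhaustive (K factorial), which is
#' intended for K up to 8.
#'
#' The cluster-level distributions are estimated as membership-weighted
#' empirical frequencies: each individual's one-hot rows weighted by their
#' posterior cluster affiliation `A(z|i)`. The raw emission matrix `P(v|z)`
#' is deliberately not compared against the generator directly: PLSA
#' attributes each co-occurrence token separately, so maximum likelihood
#' drives `P(v|z)` toward deterministic level bundles even when the
#' members' observed frequencies match the generating distributions (a
#' mixed individual is explained through mixed membership rather than a
#' mixed emission row). Setting `source = "emission"` restores the direct
#' `P(v|z)` comparison.
#'
#' @param model A fitted `plsa_model` for one sex stratum.
#' @param spec The `generator_spec` that produced the data.
#' @param sex `"male"` or `"female"`: which stratum's ground truth to
#'   compare against.
#' @param m The co-occurrence matrix the model was fitted to (required for
#'   the default `"members"` source).
#' @param source `"members"` (membership-weighted empirical frequencies,
#'   default) or `"emission"` (renormalized `P(v|z)` blocks).
#' @return A list with `permutation` (index `p` such that fitted cluster
#'   `k` corresponds to true segment `p[k]`), `recovery_error` (mean TV
#'   distance over clusters and variables), and `tv_by_cluster`.
#' @export
match_clusters <- function(model, spec, sex = c("male", "female"),
                           m = NULL, source = c("members", "emission")) {
  sex <- match.arg(sex)
  source <- match.arg(source)
  if (model$K != spec$k_true) {
    stop("model K (", model$K, ") does not match the ground truth k_true (",
         spec$k_true, ")", call. = FALSE)
  }
  if (model$K > 8L) {
    stop("exhaustive permutation search supports K <= 8", call. = FALSE)
  }
  cb <- spec$codebook
  theta <- spec$level_probs[[sex]]
  if (source == "members") {
    if (is.null(m)) {
      stop("the co-occurrence matrix 'm' is required for source = 'members'",
           call. = FALSE)
    }
    W <- affiliation(model)$ind_affil       # individuals x K
    raw <- t(crossprod(m, W))               # K x V weighted level counts
  } else {
    raw <- t(model$pv_z)
  }
  # per-variable level distributions, one (levels x K) matrix per variable
  fitted_theta <- list()
  offset <- 0L
  for (v in cb$variables) {
    L <- length(cb$levels[[v]])
    block <- t(raw[, offset + seq_len(L), drop = FALSE])
    fitted_theta[[v]] <- sweep(block, 2L, colSums(block), "/")
    offset <- offset + L
  }
  K <- model$K
  # TV distance between fitted cluster k and true segment j, averaged
  # over variables
  tv <- matrix(0, K, K)
  for (k in seq_len(K)) {
    for (j in seq_len(K)) {
      d <- vapply(cb$variables, function(v) {
        0.5 * sum(abs(fitted_theta[[v]][, k] - theta[[j]][[v]]))
      }, numeric(1))
      tv[k, j] <- mean(d)
    }
  }
  perms <- permutations(K)
  costs <- apply(perms, 1L, function(p) mean(tv[cbind(seq_len(K), p)]))
  best <- which.min(costs)
  list(
    permutation = perms[best, ],
    recovery_error = costs[best],
    tv_by_cluster = tv[cbind(seq_len(K), perms[best, ])]
  )
}

# All permutations of 1..n (n! x n matrix), recursively.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Export an affiliation table in long format
#'
#' @param affil An `affiliation_table`.
#' @param path CSV path; columns `entity_type,entity,cluster,affiliation`.
#' @return `path`, invisibly.
#' @export
write_affiliation_csv <- function(affil, path) {
  long <- function(mat, type) {
    data.frame(
      entity_type = type,
      entity = rep(rownames(mat), times = ncol(mat)),
      cluster = rep(seq_len(ncol(mat)), each = nrow(mat)),
      affiliation = as.vector(mat),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(long(affil$var_affil, "variable_level"),
               long(affil$ind_affil, "individual"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
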