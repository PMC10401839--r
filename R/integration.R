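#' Classify mixed-methods concordance for one cluster
#'
#' Applies the joint-display rule to caseworker recall responses for a
#' cluster: if every interviewee could think of older recipients matching
#' the cluster the verdict is `concordance`; if none could, `discordance`;
#' any mixture is `partial_concordance`.
#'
#' @param responses Nonempty logical vector, one element per interviewee
#'   (`TRUE` = could recall a matching recipient).
#' @return `"concordance"`, `"partial_concordance"` or `"discordance"`.
#' @examples
#' classify_concordance(c(TRUE, TRUE, TRUE, TRUE))    # concordance
#' classify_concordance(c(FALSE, FALSE, FALSE, FALSE)) # discordance
#' @export
classify_concordance <- function(responses) {
  if (length(responses) == 0L) {
    stop("responses must be nonempty", call. = FALSE)
  }
  if (anyNA(responses) || !is.logical(responses)) {
    stop("responses must be TRUE/FALSE", call. = FALSE)
  }
  if (all(responses)) return("concordance")
  if (!any(responses)) return("discordance")
  "partial_concordance"
}

#' Read interview responses
#'
#' The analyst fills in this CSV after reading the cluster profiles; the
#' qualitative phase itself (interviews, transcription, coding) is outside
#' the package.
#'
#' @param path CSV with columns `cluster_id,interviewee_id,could_recall`
#'   (`true`/`false`).
#' @return A `data.frame` with one row per (cluster, interviewee).
#' @export
read_responses <- function(path) {
  r <- utils::read.csv(path, colClasses = "character")
  need <- c("cluster_id", "interviewee_id", "could_recall")
  if (!all(need %in% names(r))) {
    stop("responses CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(r[c("cluster_id", "interviewee_id")])) {
    stop("duplicate (cluster, interviewee) response", call. = FALSE)
  }
  val <- tolower(r$could_recall)
  if (!all(val %in% c("true", "false"))) {
    stop("could_recall must be 'true' or 'false'", call. = FALSE)
  }
  r$cluster_id <- as.integer(r$cluster_id)
  r$could_recall <- val == "true"
  r
}

#' Build the mixed-methods joint display
#'
#' Aligns each cluster's quantitative profile with the qualitative recall
#' responses and classifies the fit as concordance, partial concordance or
#' discordance. One row per cluster.
#'
#' @param profiles A `cluster_profiles` object for one sex stratum.
#' @param responses A responses `data.frame` (see [read_responses()])
#'   covering every cluster in `profiles`.
#' @param sex Stratum label recorded in the display.
#' @return A `data.frame` with columns `sex`, `cluster_id`,
#'   `profile_summary`, `n_yes`, `n_respondents`, `verdict`.
#' @export
joint_display <- function(profiles, responses, sex = NA_character_) {
  rows <- lapply(profiles, function(p) {
    resp <- responses$could_recall[responses$cluster_id == p$cluster]
    if (length(resp) == 0L) {
      stop("no responses for cluster ", p$cluster, call. = FALSE)
    }
    summary <- if (nrow(p$levels) == 0L) "" else
      paste(paste0(p$levels$variable, "=", p$levels$level), collapse = "; ")
    data.frame(
      sex = sex, cluster_id = p$cluster, profile_summary = summary,
      n_yes = sum(resp), n_respondents = length(resp),
      verdict = classify_concordance(resp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full per-sex segmentation pipeline
#'
#' Orchestrates the whole quantitative analysis: stratify the roster by
#' sex, then per stratum encode, sweep the number of clusters, select K,
#' keep the selected model, compute affiliations, extract cluster profiles
#' at `tau`, and tabulate descriptives. All module outputs plus a run
#' manifest (seeds, config, per-stage timings) are written under `out_dir`.
#'
#' @param roster A roster `data.frame`, or `NULL` to generate one from
#'   `spec`.
#' @param spec Optional `generator_spec` used when `roster` is `NULL`; its
#'   ground truth is saved alongside the roster.
#' @param out_dir Output directory (created if needed).
#' @param k_min,k_max Sweep range.
#' @param config A [fit_config()]; the root seed drives every restart.
#' @param policy A [selection_policy()].
#' @param tau Affiliation threshold for the profiles.
#' @param codebook A `pa_codebook`.
#' @return Invisibly, a list with per-sex elements (`selection`,
#'   `selected_k`, `model`, `affiliation`, `profiles`) plus `descriptives`
#'   and the `manifest`.
#' @export
run_pipeline <- function(roster = NULL, spec = NULL, out_dir,
                         k_min = 2L, k_max = 10L,
                         config = fit_config(), policy = selection_policy(),
                         tau = 0.55, codebook = default_codebook()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, sexlab, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage ", name, " [", sexlab, "]: ",
                        conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage ", name, " [", sexlab, "]: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[paste(sexlab, name, sep = ".")]] <<-
      round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }

  if (is.null(roster)) {
    if (is.null(spec)) stop("either roster or spec is required",
                            call. = FALSE)
    gen <- stage("simulate", "all", generate_roster(spec))
    roster <- gen$roster
    write_roster(roster, file.path(out_dir, "roster.csv"), codebook)
    write_truth(gen$truth, file.path(out_dir, "truth.csv"))
  }
  validate_roster(roster, codebook)

  descr <- stage("descriptives", "all",
                 descriptive_table(roster, codebook))
  utils::write.csv(descr, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE, quote = FALSE)

  strata <- stratify_by_sex(roster)
  out <- list(descriptives = descr)
  for (sex in c("male", "female")) {
    sub <- strata[[sex]]
    if (nrow(sub) == 0L) {
      message("stratum '", sex, "' is empty; skipped")
      next
    }
    m <- stage("encode", sex, encode_roster(sub, codebook))
    k_hi <- min(k_max, nrow(m) - 1L, ncol(m) - 1L)
    tab <- stage("sweep", sex,
                 suppressWarnings(sweep_k(m, k_min, k_hi, config)))
    utils::write.csv(
      as.data.frame(tab)[, setdiff(names(tab), "models")],
      file.path(out_dir, paste0("sweep_", sex, ".csv")),
      row.names = FALSE, quote = FALSE
    )
    k_sel <- stage("select", sex, select_k(tab, policy))
    model <- attr(tab, "models")[[match(k_sel, tab$k)]]
    write_model_json(model, file.path(out_dir,
                                      paste0("model_", sex, ".json")))
    affil <- stage("affiliation", sex, affiliation(model))
    write_affiliation_csv(affil, file.path(out_dir,
                                           paste0("affiliation_", sex,
                                                  ".csv")))
    prof <- stage("characterize", sex,
                  suppressWarnings(characterize(affil, tau)))
    write_profiles_json(prof, file.path(out_dir,
                                        paste0("profiles_", sex, ".json")))
    out[[sex]] <- list(selection = as.data.frame(tab), selected_k = k_sel,
                       model = model, affiliation = affil, profiles = prof)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("segmint")),
    seed = config$seed,
    config = unclass(config),
    policy = unclass(policy),
    tau = tau,
    k_range = c(k_min, k_max),
    n = nrow(roster),
    selected_k = list(male = out$male$selected_k,
                      female = out$female$selected_k),
    winning_restart_seeds = list(male = out$male$model$seed,
                                 female = out$female$model$seed),
    timings_s = timings,
    timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(c(out, list(manifest = manifest)))
}
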