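#' Categorical codebook for the recipient roster
#'
#' The codebook fixes the 13 categorical variables describing an older
#' public-assistance recipient and, for each variable, the ordered set of
#' level codes with display labels. The default codebook mirrors the
#' descriptive table of the study population: 13 variables with 40 levels in
#' total (age group, nationality, living alone, disability/disease,
#' hospitalization history, long-term care status, working, previous use of
#' public assistance, reason for starting public assistance, facility
#' admission history, house type, working-income band, pension band).
#'
#' @param path Path to a codebook JSON file of the form
#'   `{variable: {levels: [{code, label}, ...]}, ...}`. The default reads the
#'   codebook shipped with the package.
#' @return An object of class `pa_codebook`: a list with elements
#'   `variables` (ordered character vector), `levels` (named list of level
#'   code vectors) and `labels` (named list of display-label vectors).
#' @examples
#' cb <- default_codebook()
#' cb$variables
#' cb$levels$ltc_status
#' @export
read_codebook <- function(path) {
  raw <- jsonlite::read_json(path)
  if (length(raw) == 0L) {
    stop("codebook is empty", call. = FALSE)
  }
  vars <- names(raw)
  levels <- lapply(raw, function(v) {
    vapply(v$levels, function(l) l$code, character(1))
  })
  labels <- lapply(raw, function(v) {
    vapply(v$levels, function(l) l$label, character(1))
  })
  for (v in vars) {
    if (anyDuplicated(levels[[v]])) {
      stop("duplicate level codes in variable '", v, "'", call. = FALSE)
    }
  }
  structure(
    list(variables = vars, levels = levels, labels = labels),
    class = "pa_codebook"
  )
}

#' @rdname read_codebook
#' @export
default_codebook <- function() {
  read_codebook(system.file("extdata", "codebook_table1.json",
                            package = "segmint", mustWork = TRUE))
}

#' @export
print.pa_codebook <- function(x, ...) {
  cat("Recipient codebook:", length(x$variables), "variables,",
      sum(lengths(x$levels)), "levels\n")
  for (v in x$variables) {
    cat("  ", v, ": ", paste(x$levels[[v]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Column labels of the one-hot matrix, in codebook order.
column_labels <- function(codebook) {
  unlist(lapply(codebook$variables, function(v) {
    paste(v, codebook$levels[[v]], sep = ":")
  }), use.names = FALSE)
}

validate_roster <- function(roster, codebook) {
  required <- c("id", "sex", codebook$variables)
  missing <- setdiff(required, names(roster))
  if (length(missing) > 0L) {
    stop("roster is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(roster$id)) {
    stop("roster ids are not unique", call. = FALSE)
  }
  bad_sex <- setdiff(unique(roster$sex), c("male", "female"))
  if (length(bad_sex) > 0L) {
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(roster[required])) {
    stop("roster contains missing values", call. = FALSE)
  }
  for (v in codebook$variables) {
    bad <- !(roster[[v]] %in% codebook$levels[[v]])
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "row id '%s': unknown level '%s' for variable '%s'",
        roster$id[i], roster[[v]][i], v
      ), call. = FALSE)
    }
  }
  invisible(roster)
}

#' One-hot co-occurrence encoding of a roster
#'
#' Expands each categorical variable of the roster into indicator columns,
#' producing the binary individual-by-variable-level co-occurrence matrix
#' n(i, v) that PLSA consumes. Each row holds exactly one 1 per variable, so
#' with the default codebook every row sums to 13.
#'
#' @param roster A roster `data.frame` with columns `id`, `sex` and one level
#'   code per codebook variable.
#' @param codebook A `pa_codebook`; defaults to [default_codebook()].
#' @return An integer 0/1 matrix with `rownames` set to roster ids and
#'   `colnames` of the form `"variable:level"`, columns in codebook order.
#' @examples
#' spec <- table1_preset()
#' spec$n_male <- 20; spec$n_female <- 0
#' r <- generate_roster(spec)
#' m <- encode_roster(r$roster)
#' rowSums(m)  # all 13
#' @export
encode_roster <- function(roster, codebook = default_codebook()) {
  validate_roster(roster, codebook)
  n <- nrow(roster)
  blocks <- lapply(codebook$variables, function(v) {
    lev <- codebook$levels[[v]]
    idx <- match(roster[[v]], lev)
    block <- matrix(0L, nrow = n, ncol = length(lev))
    block[cbind(seq_len(n), idx)] <- 1L
    block
  })
  m <- do.call(cbind, blocks)
  dimnames(m) <- list(roster$id, column_labels(codebook))
  m
}

#' Reconstruct a roster from a one-hot co-occurrence matrix
#'
#' Inverse of [encode_roster()] up to the `sex` column, which is not part of
#' the encoded matrix (sex is a stratifier, never a model variable).
#'
#' @param m A 0/1 matrix as produced by [encode_roster()].
#' @param codebook A `pa_codebook`.
#' @param sex Optional character vector of sexes to reattach.
#' @return A roster `data.frame`.
#' @export
decode_matrix <- function(m, codebook = default_codebook(), sex = NULL) {
  labs <- column_labels(codebook)
  if (!identical(colnames(m), labs)) {
    stop("matrix columns do not match the codebook", call. = FALSE)
  }
  out <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(sex)) out$sex <- sex
  offset <- 0L
  for (v in codebook$variables) {
    lev <- codebook$levels[[v]]
    block <- m[, offset + seq_along(lev), drop = FALSE]
    if (any(rowSums(block) != 1L)) {
      stop("matrix block for '", v, "' is not one-hot", call. = FALSE)
    }
    out[[v]] <- lev[max.col(block)]
    offset <- offset + length(lev)
  }
  out
}

#' Split a roster into male and female strata
#'
#' The segmentation is fitted separately per sex; this partitions the roster
#' preserving the original row order within each stratum.
#'
#' @param roster A roster `data.frame` with a `sex` column.
#' @return A named list with elements `male` and `female`.
#' @export
stratify_by_sex <- function(roster) {
  bad <- setdiff(unique(roster$sex), c("male", "female"))
  if (length(bad) > 0L) {
    stop("invalid sex value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  list(
    male = roster[roster$sex == "male", , drop = FALSE],
    female = roster[roster$sex == "female", , drop = FALSE]
  )
}

#' Read and write roster CSV files
#'
#' The roster CSV carries one row per individual with the header
#' `id,sex,<13 variable columns>`; values are level codes from the codebook.
#'
#' @param path CSV file path.
#' @param roster A roster `data.frame`.
#' @param codebook A `pa_codebook` used for validation.
#' @return `read_roster` returns a validated roster `data.frame`;
#'   `write_roster` returns `path` invisibly.
#' @export
read_roster <- function(path, codebook = default_codebook()) {
  roster <- utils::read.csv(path, colClasses = "character")
  validate_roster(roster, codebook)
  roster
}

#' @rdname read_roster
#' @export
write_roster <- function(roster, path, codebook = default_codebook()) {
  validate_roster(roster, codebook)
  utils::write.csv(roster[c("id", "sex", codebook$variables)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a co-occurrence matrix in MatrixMarket format
#'
#' Writes the sparse coordinate form of the 0/1 matrix plus a sidecar CSV of
#' row ids and column labels, for interoperability with other tools.
#'
#' @param m A 0/1 matrix from [encode_roster()].
#' @param path Output `.mtx` path; the sidecar is written next to it with
#'   suffix `.labels.csv`.
#' @return `path`, invisibly.
#' @export
write_matrix_mtx <- function(m, path) {
  nz <- which(m != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 2L], nz[, 1L]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz)), con)
  writeLines(sprintf("%d %d 1", nz[, 1L], nz[, 2L]), con)
  sidecar <- sub("\\.mtx$", "", path)
  sidecar <- paste0(sidecar, ".labels.csv")
  ids <- data.frame(
    kind = c(rep("row", nrow(m)), rep("col", ncol(m))),
    index = c(seq_len(nrow(m)), seq_len(ncol(m))),
    label = c(rownames(m), colnames(m)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(ids, sidecar, row.names = FALSE, quote = FALSE)
  invisible(path)
}
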