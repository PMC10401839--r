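#' Published per-sex level counts of the study population
#'
#' Returns the printed descriptive table of the study population of older
#' public-assistance recipients (1,483 men and 1,682 women from two suburban
#' municipalities): one row per variable level with the male and female
#' counts. These counts are the calibration target of [table1_preset()] and
#' the input for reproducing the printed percentages.
#'
#' @return A `data.frame` with columns `variable`, `level`, `male`, `female`.
#' @examples
#' tab <- table1_reference()
#' sum(tab$male[tab$variable == "age_group"])    # 1483
#' sum(tab$female[tab$variable == "age_group"])  # 1682
#' @export
table1_reference <- function() {
  rows <- list(
    c("age_group", "65_74", 905, 734),
    c("age_group", "75_84", 513, 698),
    c("age_group", "85_over", 65, 250),
    c("nationality", "japanese", 1462, 1650),
    c("nationality", "foreign", 21, 32),
    c("living_alone", "yes", 1082, 1186),
    c("living_alone", "no", 401, 496),
    c("disability_disease", "physical_disability", 140, 130),
    c("disability_disease", "mental_disability", 65, 55),
    c("disability_disease", "intellectual_disability", 2, 4),
    c("disability_disease", "psychiatric_disorder", 39, 87),
    c("disability_disease", "other_physical_disease", 325, 333),
    c("disability_disease", "alcohol_dependency", 12, 2),
    c("disability_disease", "none", 900, 1071),
    c("hospitalization", "yes", 77, 100),
    c("hospitalization", "no", 1406, 1582),
    c("ltc_status", "support_need", 74, 120),
    c("ltc_status", "ltc_need", 255, 385),
    c("ltc_status", "none", 1154, 1177),
    c("working", "yes", 138, 121),
    c("working", "no", 1345, 1561),
    c("previous_pa", "yes", 214, 240),
    c("previous_pa", "no", 1269, 1442),
    c("reason_start", "decreased_income", 762, 859),
    c("reason_start", "disease", 383, 368),
    c("reason_start", "unemployment", 131, 128),
    c("reason_start", "divorce_bereavement", 43, 61),
    c("reason_start", "other", 164, 266),
    c("facility_admission", "yes", 62, 97),
    c("facility_admission", "no", 1421, 1585),
    c("house_type", "rental", 988, 912),
    c("house_type", "public", 353, 561),
    c("house_type", "own", 2, 5),
    c("house_type", "other", 140, 204),
    c("income_band", "above_median", 34, 30),
    c("income_band", "below_median", 35, 31),
    c("income_band", "none", 1414, 1621),
    c("pension_band", "above_median", 239, 416),
    c("pension_band", "below_median", 241, 417),
    c("pension_band", "none", 1003, 849)
  )
  out <- data.frame(
    variable = vapply(rows, `[`, character(1), 1L),
    level = vapply(rows, `[`, character(1), 2L),
    male = as.integer(vapply(rows, `[`, character(1), 3L)),
    female = as.integer(vapply(rows, `[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
  out
}

# Per-sex marginal level probabilities implied by the reference counts,
# as a named list variable -> named probability vector.
table1_marginals <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  tab <- table1_reference()
  n <- if (sex == "male") 1483L else 1682L
  split_tab <- split(tab, factor(tab$variable, levels = unique(tab$variable)))
  lapply(split_tab, function(d) {
    p <- d[[sex]] / n
    names(p) <- d$level
    p
  })
}
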