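#' Define a primary-suspect cohort
#'
#' A cohort is the set of deduplicated reports that list at least one of a
#' given set of normalized ingredients as the primary suspect (PS) drug.
#' A single spec may name one drug or pool a whole class.
#'
#' @param label display label for the cohort.
#' @param drugs character vector of normalized ingredient names (non-empty).
#' @param pooled logical; `TRUE` marks a class-level (multi-drug) cohort.
#' @return an object of class `cohort_spec`.
#' @examples
#' il1 <- cohort_spec("IL-1 inhibitors",
#'                    c("anakinra", "canakinumab", "rilonacept"))
#' @export
cohort_spec <- function(label, drugs, pooled = length(drugs) > 1) {
  drugs <- tolower(trimws(as.character(drugs)))
  stopifnot(length(drugs) >= 1, all(nzchar(drugs)))
  structure(list(label = label, drugs = unique(drugs), pooled = pooled),
            class = "cohort_spec")
}

# primaryids of reports with >= 1 PS drug row matching the spec
cohort_ids <- function(cases, spec) {
  d <- cases$drugs
  hit <- !is.na(d$role_cod) & d$role_cod == "PS" &
    !is.na(d$drug) & d$drug %in% spec$drugs
  unique(d$primaryid[hit])
}

#' Select the reports of a primary-suspect cohort
#'
#' Keeps reports with at least one drug record whose role code is `PS`
#' and whose normalized name belongs to the spec; a report counts once
#' even when several of its PS rows match (relevant for pooled class
#' cohorts).
#'
#' @param cases deduplicated `faers_cases`.
#' @param spec a [cohort_spec()].
#' @return the matching `faers_cases` subset (a warning, not an error, if
#'   empty).
#' @export
select_cohort <- function(cases, spec) {
  stopifnot(inherits(cases, "faers_cases"), inherits(spec, "cohort_spec"))
  ids <- cohort_ids(cases, spec)
  if (!length(ids)) {
    warning("cohort '", spec$label, "' selected no reports", call. = FALSE)
  }
  filter_cases(cases, ids)
}

#' Band an age in years into the study's three age groups
#'
#' Bands are `<18` (child), `18-65` (middle age, both boundary ages
#' included) and `>65` (elder); non-integer ages band by value.
#'
#' @param age_years numeric vector of ages in years.
#' @return factor with levels `<18`, `18-65`, `>65` (`NA` for missing).
#' @export
age_band <- function(age_years) {
  lab <- ifelse(age_years < 18, "<18", ifelse(age_years <= 65, "18-65", ">65"))
  factor(lab, levels = c("<18", "18-65", ">65"))
}

#' Baseline characteristics table
#'
#' Per-cohort counts and percentages (one decimal, denominator = cohort
#' size) for sex, age band and reporter occupation, in the layout of a
#' clinical characteristics table: one row per (characteristic, level),
#' including an explicit Missing level per characteristic, so that counts
#' always sum to the cohort size.
#'
#' @param cohorts a named list of `faers_cases` objects (one per cohort);
#'   a single `faers_cases` is accepted and treated as one cohort.
#' @return tibble with columns `cohort`, `characteristic`, `level`, `n`,
#'   `pct`.
#' @export
baseline_table <- function(cohorts) {
  if (inherits(cohorts, "faers_cases")) cohorts <- list(cohort = cohorts)
  stopifnot(length(cohorts) >= 1)
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort_", seq_along(cohorts))
  one <- function(cs, label) {
    demo <- cs$demo
    N <- nrow(demo)
    lvl_count <- function(x, levels) {
      f <- factor(x, levels = levels)
      cnt <- c(table(f), Missing = sum(is.na(f)))
      tibble(level = names(cnt), n = as.integer(cnt))
    }
    blocks <- list(
      Gender = lvl_count(ifelse(demo$sex == "F", "Female", "Male"),
                         c("Female", "Male")),
      Age = lvl_count(age_band(demo$age_years), levels(age_band(numeric()))),
      `Reporter occupation` = lvl_count(demo$occp_cod,
                                        c("CN", "HP", "LW", "MD", "OT", "PH", "RN"))
    )
    out <- bind_rows(blocks, .id = "characteristic")
    out$cohort <- label
    out$pct <- if (N > 0) round(100 * out$n / N, 1) else NA_real_
    out[, c("cohort", "characteristic", "level", "n", "pct")]
  }
  bind_rows(Map(one, cohorts, names(cohorts)))
}

#' Annual report counts
#'
#' Number of reports per receipt year (`FDA_DT`), zero-filled over the
#' study window 2004-2024 (extended to cover any years observed outside
#' it).  Reports with a missing receipt date are excluded and counted in
#' the `n_missing_date` attribute.
#'
#' @param cohort a `faers_cases` object.
#' @param years integer vector of years to always include.
#' @return tibble with columns `year`, `n`; attribute `n_missing_date`.
#' @export
annual_counts <- function(cohort, years = 2004:2024) {
  stopifnot(inherits(cohort, "faers_cases"))
  yr <- as.integer(format(cohort$demo$fda_dt, "%Y"))
  n_missing <- sum(is.na(yr))
  yr <- yr[!is.na(yr)]
  all_years <- sort(union(years, yr))
  cnt <- table(factor(yr, levels = all_years))
  out <- tibble(year = as.integer(names(cnt)), n = as.integer(cnt))
  attr(out, "n_missing_date") <- n_missing
  out
}
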