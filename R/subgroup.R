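#' Define a demographic or reporter-type stratum
#'
#' Strata supported: `age_band` (`<18`, `18-65`, `>65`), `sex` (`F`, `M`)
#' and `reporter_group` (`CN` vs `HP/MD`).  By default the healthcare-
#' professional group folds in all professional occupation codes
#' (`HP`, `MD`, `OT`, `PH`, `RN`); `hp_strict = TRUE` restricts it to
#' `HP` and `MD` only.  Lawyers (`LW`) and reports with a missing
#' occupation belong to neither reporter group, and reports with a
#' missing stratum variable are excluded from the stratum rather than
#' imputed.
#'
#' @param variable one of `"age_band"`, `"sex"`, `"reporter_group"`.
#' @param value a level of that variable (see above).
#' @param hp_strict logical; restrict `HP/MD` to codes HP and MD.
#' @return an object of class `stratum_spec`.
#' @examples
#' stratum_spec("sex", "F")
#' stratum_spec("reporter_group", "HP/MD", hp_strict = TRUE)
#' @export
stratum_spec <- function(variable = c("age_band", "sex", "reporter_group"),
                         value, hp_strict = FALSE) {
  variable <- match.arg(variable)
  valid <- switch(variable,
    age_band = c("<18", "18-65", ">65"),
    sex = c("F", "M"),
    reporter_group = c("CN", "HP/MD")
  )
  if (!value %in% valid) {
    stop(sprintf("'%s' is not a level of %s (expected: %s)",
                 value, variable, paste(valid, collapse = ", ")), call. = FALSE)
  }
  structure(list(variable = variable, value = value, hp_strict = hp_strict),
            class = "stratum_spec")
}

stratum_label <- function(stratum) {
  paste0(stratum$variable, "=", stratum$value)
}

# primaryids of reports belonging to the stratum (missing values excluded)
stratum_ids <- function(cases, stratum) {
  demo <- cases$demo
  keep <- switch(stratum$variable,
    age_band = !is.na(demo$age_years) &
      as.character(age_band(demo$age_years)) == stratum$value,
    sex = !is.na(demo$sex) & demo$sex == stratum$value,
    reporter_group = {
      codes <- if (stratum$value == "CN") {
        "CN"
      } else if (stratum$hp_strict) {
        c("HP", "MD")
      } else {
        c("HP", "MD", "OT", "PH", "RN")
      }
      !is.na(demo$occp_cod) & demo$occp_cod %in% codes
    }
  )
  demo$primaryid[keep]
}

#' Stratified disproportionality scan
#'
#' Restricts both the target cohort and the comparator to the reports of
#' one stratum (within-stratum disproportionality - a cross-stratum
#' comparator would confound the stratification) and runs the standard
#' four-algorithm scan.
#'
#' @param cases deduplicated `faers_cases` (full database).
#' @param spec a [cohort_spec()].
#' @param level `"pt"` or `"soc"`.
#' @param stratum a [stratum_spec()].
#' @param vocab vocabulary, required at SOC level.
#' @param ... thresholds passed to [run_signal_scan()].
#' @return ranked signal tibble as from [run_signal_scan()]; empty (with
#'   a warning) when the stratum contains no reports.
#' @export
stratify_and_scan <- function(cases, spec, level = c("pt", "soc"), stratum,
                              vocab = NULL, ...) {
  stopifnot(inherits(stratum, "stratum_spec"))
  level <- match.arg(level)
  ids <- stratum_ids(cases, stratum)
  if (!length(ids)) {
    warning("stratum ", stratum_label(stratum), " contains no reports",
            call. = FALSE)
    return(run_signal_scan(build_contingency(filter_cases(cases, numeric()),
                                             spec, level = level, vocab = vocab)))
  }
  tables <- build_contingency(cases, spec, level = level, vocab = vocab,
                              stratum = stratum)
  run_signal_scan(tables, ...)
}
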