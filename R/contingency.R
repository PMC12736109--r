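#' Build 2x2 contingency tables for a cohort
#'
#' For every event term reported at least once in the target cohort, the
#' classical pharmacovigilance 2x2 table is built against all other
#' deduplicated reports:
#'
#' * `a` - target-cohort reports with the term,
#' * `b` - target-cohort reports without it,
#' * `c` - comparator reports with the term,
#' * `d` - comparator reports without it.
#'
#' The default counting unit is the case: a report contributes at most 1
#' to `a` (or `c`) per term even when the term is listed repeatedly
#' (`counting = "pair"` switches to raw drug-event-pair rows for
#' sensitivity checks).  At SOC level each PT is mapped through the
#' vocabulary; PTs absent from it are collected under an `"Unmapped"` SOC
#' with a warning.  When a stratum is given, both the target and the
#' comparator are restricted to reports inside the stratum; reports where
#' the stratum variable is missing are excluded.
#'
#' @param cases deduplicated `faers_cases` (the full database, not the
#'   cohort subset).
#' @param spec a [cohort_spec()] defining the target.
#' @param level `"pt"` or `"soc"`.
#' @param vocab a `faers_vocabulary`; required when `level = "soc"`.
#' @param stratum optional [stratum_spec()] restricting the analysis.
#' @param exclude_drugs optional ingredient names whose PS reports are
#'   dropped from the comparator (e.g. the other members of a drug class).
#' @param counting `"case"` (default) or `"pair"`.
#' @return tibble with columns `term`, `level`, `a`, `b`, `c`, `d`,
#'   `cohort`, `stratum`.
#' @export
build_contingency <- function(cases, spec, level = c("pt", "soc"), vocab = NULL,
                              stratum = NULL, exclude_drugs = character(),
                              counting = c("case", "pair")) {
  stopifnot(inherits(cases, "faers_cases"), inherits(spec, "cohort_spec"))
  level <- match.arg(level)
  counting <- match.arg(counting)
  if (level == "soc" && is.null(vocab)) {
    stop("a vocabulary is required for SOC-level tables", call. = FALSE)
  }

  all_ids <- cases$demo$primaryid
  tgt <- cohort_ids(cases, spec)
  allowed <- all_ids
  if (!is.null(stratum)) allowed <- stratum_ids(cases, stratum)
  tgt <- intersect(tgt, allowed)
  comp <- setdiff(allowed, tgt)
  if (length(exclude_drugs)) {
    excl_spec <- cohort_spec("excluded", exclude_drugs)
    comp <- setdiff(comp, cohort_ids(cases, excl_spec))
  }

  ev <- cases$events
  if (level == "soc") {
    soc <- unname(vocab$pt_to_soc[ev$pt])
    if (anyNA(soc)) {
      warning(sprintf("%d event row(s) with PT absent from the vocabulary mapped to 'Unmapped'",
                      sum(is.na(soc))), call. = FALSE)
      soc[is.na(soc)] <- "Unmapped"
    }
    ev$term <- soc
  } else {
    ev$term <- ev$pt
  }

  if (counting == "case") {
    ev <- distinct(ev, primaryid, term)
    n_tgt <- length(tgt)
    n_comp <- length(comp)
  } else {
    n_tgt <- sum(ev$primaryid %in% tgt)
    n_comp <- sum(ev$primaryid %in% comp)
  }

  ev_tgt <- ev[ev$primaryid %in% tgt, , drop = FALSE]
  ev_comp <- ev[ev$primaryid %in% comp, , drop = FALSE]
  terms <- sort(unique(ev_tgt$term))
  a <- as.integer(table(factor(ev_tgt$term, levels = terms)))
  cc <- as.integer(table(factor(ev_comp$term, levels = terms)))
  tibble(
    term = terms, level = level,
    a = a, b = n_tgt - a, c = cc, d = n_comp - cc,
    cohort = spec$label,
    stratum = if (is.null(stratum)) NA_character_ else stratum_label(stratum)
  )
}
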