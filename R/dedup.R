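#' Remove duplicate reports by case identifier
#'
#' FAERS stores every version of a report under the same `CASEID` with a
#' distinct `PRIMARYID`; the regulator's guidance is to analyse one row
#' per case.  `deduplicate()` keeps, for each `CASEID`, the report with
#' the most recent `FDA_DT`, breaking date ties by the higher
#' `PRIMARYID`.  A missing `FDA_DT` sorts before any real date, so a
#' dated version always wins over an undated one (the count of such rows
#' is flagged in the audit).
#'
#' The operation is idempotent and independent of input row order; output
#' reports are ordered by ascending `caseid`.
#'
#' @param cases a `faers_cases` object from [assemble_cases()].
#' @return the deduplicated `faers_cases`, with an audit list attached
#'   (see [dedup_audit()]): `n_input`, `n_kept`, `n_removed`,
#'   `n_missing_fda_dt`.
#' @examples
#' sim <- simulate_faers(synthetic_config(seed = 1, n_cases = 200,
#'                                        duplicate_rate = 0.2))
#' cs <- assemble_cases(sim$quarter, sim$vocab)
#' dd <- deduplicate(cs)
#' dedup_audit(dd)$n_removed
#' @export
deduplicate <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  demo <- cases$demo
  dt_key <- as.numeric(demo$fda_dt)
  dt_key[is.na(dt_key)] <- -Inf
  ord <- order(demo$caseid, -dt_key, -demo$primaryid)
  keep_rows <- ord[!duplicated(demo$caseid[ord])]
  keep_ids <- demo$primaryid[sort(keep_rows)]
  out <- filter_cases(cases, keep_ids)
  # deterministic output order: ascending caseid
  out$demo <- out$demo[order(out$demo$caseid), , drop = FALSE]
  audit <- list(n_input = nrow(demo),
                n_kept = length(keep_ids),
                n_removed = nrow(demo) - length(keep_ids),
                n_missing_fda_dt = sum(is.na(demo$fda_dt)))
  attr(out, "dedup_audit") <- audit
  out
}

#' @rdname deduplicate
#' @export
dedup_audit <- function(cases) attr(cases, "dedup_audit")
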