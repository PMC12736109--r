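#' Run the full signal-detection study
#'
#' Orchestrates the whole pipeline on one FAERS-style dataset: load,
#' assemble, deduplicate, select the class and per-drug cohorts, write
#' the baseline-characteristics and annual-count tables, run PT- and
#' SOC-level disproportionality scans (class and per drug), reporter-,
#' sex- and age-stratified subgroup scans, and the time-to-onset analysis
#' (interval bins, cumulative-incidence coordinates per drug, Gray's
#' test).  Every artifact is written as delimited text together with a
#' machine-readable JSON manifest and a row-drop audit log, so the
#' case-screening flowchart can be reconstructed from one run.
#'
#' When the THER table is absent the time-to-onset stage is skipped with
#' a warning and all other outputs are unchanged.  Given fixed inputs and
#' configuration the outputs are byte-identical across runs.
#'
#' @param config either a path to a YAML file or a list with elements:
#'   `input_dir` (directory of quarterly files), `pt_soc_path`,
#'   `synonym_path` (vocabulary tables; default `<input_dir>/pt_soc.tsv`
#'   and `synonyms.tsv`), `class_label`, `class_drugs` (character
#'   vector), and optional `options` overriding analysis knobs:
#'   `counting` ("case"/"pair"), `hp_strict`, `edges` (TTO bin edges),
#'   `n_min`, `ror_lo_min`, `prr_lo_min`, `ic025_min`, `ebgm05_min`,
#'   `exclude_class_from_comparator`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list (element `tables` names every
#'   table written).
#' @export
run_study <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$input_dir), !is.null(config$class_drugs))
  opts <- modifyList(list(counting = "case", hp_strict = FALSE,
                          edges = c(30, 60, 90, 120, 180, 360),
                          n_min = 3, ror_lo_min = 1, prr_lo_min = 1,
                          ic025_min = 0, ebgm05_min = 0,
                          exclude_class_from_comparator = FALSE),
                     config$options %||% list())
  class_label <- config$class_label %||% "drug class"
  class_drugs <- config$class_drugs
  pt_soc <- config$pt_soc_path %||% file.path(config$input_dir, "pt_soc.tsv")
  syn <- config$synonym_path %||% file.path(config$input_dir, "synonyms.tsv")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  vocab <- load_vocabulary(pt_soc, if (file.exists(syn)) syn else NULL)
  quarter <- load_quarter(quarter_paths(config$input_dir))
  cases <- assemble_cases(quarter, vocab)
  rep0 <- load_report(cases)
  say("loaded %d reports (%d drug rows, %d event rows, %d therapy rows)",
      rep0$n_reports, rep0$n_drug_rows, rep0$n_event_rows, rep0$n_therapy_rows)

  cases <- deduplicate(cases)
  aud <- dedup_audit(cases)
  say("deduplication removed %d of %d report versions (%d unique cases)",
      aud$n_removed, aud$n_input, aud$n_kept)

  specs <- c(list(cohort_spec(class_label, class_drugs, pooled = TRUE)),
             lapply(class_drugs, function(d) cohort_spec(d, d)))
  names(specs) <- vapply(specs, `[[`, "", "label")
  cohorts <- lapply(specs, function(s) select_cohort(cases, s))
  for (nm in names(cohorts)) {
    say("cohort '%s': %d reports", nm, nrow(cohorts[[nm]]$demo))
  }

  tables <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    tables[[name]] <<- basename(path)
  }

  emit(baseline_table(cohorts), "baseline")
  ann <- bind_rows(lapply(names(cohorts), function(nm) {
    out <- annual_counts(cohorts[[nm]])
    out$cohort <- nm
    out
  }))
  emit(ann[, c("cohort", "year", "n")], "annual_counts")

  scan_args <- opts[c("n_min", "ror_lo_min", "prr_lo_min", "ic025_min", "ebgm05_min")]
  scan_one <- function(spec, level, stratum = NULL) {
    excl <- if (opts$exclude_class_from_comparator && !spec$pooled) {
      setdiff(class_drugs, spec$drugs)
    } else character(0)
    tab <- build_contingency(cases, spec, level = level, vocab = vocab,
                             stratum = stratum, exclude_drugs = excl,
                             counting = opts$counting)
    do.call(run_signal_scan, c(list(tab), scan_args))
  }
  for (level in c("pt", "soc")) {
    scans <- bind_rows(lapply(specs, scan_one, level = level))
    emit(scans, paste0("signals_", level))
    say("%s-level scan: %d joint-positive terms across %d cohorts",
        toupper(level), sum(scans$joint_pos), length(specs))
  }

  strata <- list(stratum_spec("sex", "F"), stratum_spec("sex", "M"),
                 stratum_spec("age_band", "<18"), stratum_spec("age_band", "18-65"),
                 stratum_spec("age_band", ">65"),
                 stratum_spec("reporter_group", "CN", hp_strict = opts$hp_strict),
                 stratum_spec("reporter_group", "HP/MD", hp_strict = opts$hp_strict))
  sub <- bind_rows(lapply(strata, function(st) {
    scan_one(specs[[1]], "pt", stratum = st)
  }))
  emit(sub, "signals_subgroup")

  if (nrow(cases$therapy)) {
    tto_list <- lapply(specs, function(s) compute_tto(cases, s))
    bins <- bind_rows(lapply(names(tto_list), function(nm) {
      out <- tto_bin_table(tto_list[[nm]]$days, edges = opts$edges)
      out$cohort <- nm
      out[, c("cohort", "bin", "n", "pct")]
    }))
    emit(bins, "tto_bins")
    per_drug <- tto_list[-1]
    obs <- bind_rows(lapply(names(per_drug), function(nm) {
      tibble(group = nm, days = per_drug[[nm]]$days)
    }))
    nonempty <- length(unique(obs$group[!is.na(obs$days)]))
    if (nonempty >= 2) {
      emit(cumulative_incidence(obs$days, obs$group), "cuminc_curves")
      gt <- grays_test(obs$days, obs$group)
      emit(tibble(statistic = gt$statistic, df = gt$df, p_value = gt$p_value),
           "grays_test")
      say("Gray's test: stat %.3f, df %d, p %.3g", gt$statistic, gt$df, gt$p_value)
    }
  } else {
    warning("THER table absent: time-to-onset stage skipped", call. = FALSE)
    say("time-to-onset stage skipped (no therapy dates)")
  }

  emit(tibble(stage = c("loaded", "deduplicated"),
              n = c(rep0$n_reports, aud$n_kept),
              removed = c(0L, aud$n_removed)), "screening_audit")

  manifest <- list(tables = tables, options = opts,
                   cohorts = lapply(specs, `[[`, "drugs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}
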