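#' Read and write FAERS-style quarterly ASCII tables
#'
#' FAERS quarterly extracts are "$"-delimited ASCII files with a single
#' header row, one file per table (DEMO, DRUG, REAC, THER, ...).
#' `load_quarter()` reads one such set of files into a `faers_quarter`
#' object; `write_quarter()` writes one back in the same dialect, so that
#' a write/load round trip preserves every field value.
#'
#' Header names are matched case-insensitively and a small alias table
#' accepts legacy-era layouts (`ISR` for `PRIMARYID`, `CASE` for `CASEID`,
#' `GNDR_COD` for `SEX`, `DSG_DRUG_SEQ` for `DRUG_SEQ`), because a
#' 2004-2024 study window spans both conventions.  Unknown columns are
#' preserved untouched.  Empty strings become `NA`.
#'
#' Rows of DRUG/REAC/THER whose `PRIMARYID` does not occur in DEMO are
#' dropped with a warning (they cannot be joined to any report).
#'
#' @param paths named character vector or list with elements `demo`,
#'   `drug`, `reac` and optionally `ther`, giving one file path each.
#' @return `load_quarter()`: an object of class `faers_quarter`, a list of
#'   tibbles `demo`, `drug`, `reac`, `ther` (all columns character, names
#'   upper-cased).  `ther` may be an empty tibble when no THER file was
#'   given.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulate_faers(synthetic_config(seed = 1, n_cases = 50), out_dir = dir)
#' q <- load_quarter(quarter_paths(dir))
#' nrow(q$demo)
#' @export
load_quarter <- function(paths) {
  paths <- as.list(paths)
  stopifnot(!is.null(paths$demo), !is.null(paths$drug), !is.null(paths$reac))
  demo <- read_faers_table(paths$demo)
  drug <- read_faers_table(paths$drug)
  reac <- read_faers_table(paths$reac)
  ther <- if (!is.null(paths$ther) && !is.na(paths$ther) && file.exists(paths$ther)) {
    read_faers_table(paths$ther)
  } else {
    tibble(PRIMARYID = character(), DRUG_SEQ = character(),
           START_DT = character(), END_DT = character())
  }

  require_columns(demo, c("PRIMARYID", "CASEID"), paths$demo)
  require_columns(drug, "PRIMARYID", paths$drug)
  require_columns(reac, c("PRIMARYID", "PT"), paths$reac)

  known <- unique(demo$PRIMARYID)
  drop_orphans <- function(tab, name) {
    orphan <- !(tab$PRIMARYID %in% known)
    if (any(orphan)) {
      warning(sprintf("%d %s row(s) with PRIMARYID absent from DEMO dropped",
                      sum(orphan), name), call. = FALSE)
      tab <- tab[!orphan, , drop = FALSE]
    }
    tab
  }
  drug <- drop_orphans(drug, "DRUG")
  reac <- drop_orphans(reac, "REAC")
  if (nrow(ther)) ther <- drop_orphans(ther, "THER")

  structure(list(demo = demo, drug = drug, reac = reac, ther = ther),
            class = "faers_quarter")
}

#' @rdname load_quarter
#' @param quarter a `faers_quarter` object.
#' @param dir output directory (created if missing); files are written as
#'   `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`.
#' @return `write_quarter()`: the named vector of paths written, invisibly.
#' @export
write_quarter <- function(quarter, dir) {
  stopifnot(inherits(quarter, "faers_quarter"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt"))
  for (nm in names(paths)) {
    tab <- as.data.frame(quarter[[nm]])
    tab[] <- lapply(tab, function(x) ifelse(is.na(x), "", as.character(x)))
    write.table(tab, paths[[nm]], sep = "$", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  invisible(paths)
}

#' @rdname load_quarter
#' @details `quarter_paths()` is a convenience that maps a directory
#'   holding `DEMO.txt`/`DRUG.txt`/`REAC.txt`/`THER.txt` to the named path
#'   vector `load_quarter()` expects.
#' @export
quarter_paths <- function(dir) {
  p <- c(demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
         reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt"))
  if (!file.exists(p[["ther"]])) p <- p[c("demo", "drug", "reac")]
  p
}

# one "$"-delimited table -> tibble of character columns, aliases resolved
read_faers_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.table(path, sep = "$", header = TRUE, quote = "",
                    colClasses = "character", comment.char = "",
                    check.names = FALSE, na.strings = NULL, fill = TRUE)
  names(tab) <- toupper(trimws(names(tab)))
  aliases <- c(ISR = "PRIMARYID", CASE = "CASEID", GNDR_COD = "SEX",
               DSG_DRUG_SEQ = "DRUG_SEQ")
  hit <- names(tab) %in% names(aliases) & !(aliases[names(tab)] %in% names(tab))
  names(tab)[hit] <- aliases[names(tab)[hit]]
  tab[] <- lapply(tab, function(x) {
    x <- trimws(x)
    x[x == ""] <- NA_character_
    x
  })
  as_tibble(tab)
}

require_columns <- function(tab, cols, path) {
  miss <- setdiff(cols, names(tab))
  if (length(miss)) {
    stop(sprintf("file %s is missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse FAERS dates
#'
#' FAERS dates are 8-digit `YYYYMMDD` strings; therapy and event dates are
#' frequently reported at month precision (`YYYYMM`).  Month-precision
#' dates are imputed to day 15 and flagged, so that time-to-onset analysis
#' does not silently lose most records.  Anything else parses to `NA`.
#'
#' @param x character vector of date strings.
#' @return a list with `date` (a `Date` vector) and `imputed` (logical,
#'   `TRUE` where the day of month was imputed).
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  # parse unique values only: quarterly files repeat dates heavily
  ux <- unique(x)
  uout <- as.Date(rep(NA_character_, length(ux)))
  d8 <- !is.na(ux) & grepl("^\\d{8}$", ux)
  d6 <- !is.na(ux) & grepl("^\\d{6}$", ux)
  uout[d8] <- as.Date(ux[d8], format = "%Y%m%d")
  uout[d6] <- as.Date(paste0(ux[d6], "15"), format = "%Y%m%d")
  uimp <- d6 & !is.na(uout)
  idx <- match(x, ux)
  list(date = uout[idx], imputed = uimp[idx])
}

#' Convert a FAERS age field to years
#'
#' FAERS reports age as a number plus a unit code (`AGE_COD`): decades
#' (`DEC`), years (`YR`), months (`MON`), weeks (`WK`), days (`DY`) or
#' hours (`HR`).  A missing or unrecognized unit is taken as years, the
#' database's dominant convention.  Non-numeric or negative ages become
#' `NA`.
#'
#' @param age character or numeric vector of age values.
#' @param age_cod character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years (`NA` where unresolvable).
#' @examples
#' normalize_age(c("5", "6", "730"), c("DEC", "MON", "DY"))
#' @export
normalize_age <- function(age, age_cod) {
  val <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  if (length(cod) == 1L) cod <- rep(cod, length(val))
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor_map[cod]
  f[is.na(cod) | cod == ""] <- 1
  f[is.na(f)] <- 1
  out <- unname(val * f)
  out[is.na(val) | val < 0] <- NA_real_
  out
}

#' Build or load the PT/SOC vocabulary and drug-synonym maps
#'
#' The pipeline is dictionary-agnostic: instead of licensed MedDRA and
#' RxNorm distributions it takes two user-supplied two-column tables, one
#' mapping each preferred term (PT) to its system organ class (SOC) and
#' one mapping raw drug-name strings to a normalized ingredient.
#'
#' Duplicate PT rows with a consistent SOC are silently collapsed;
#' conflicting duplicates are a hard error (the map must be a function).
#' The synonym map is made idempotent: every normalized ingredient maps to
#' itself, so normalizing an already-normalized name is the identity.
#'
#' @param pt_soc data frame whose first two columns are PT and SOC.
#' @param synonyms data frame whose first two columns are a raw drug-name
#'   string and the normalized ingredient it denotes.
#' @return an object of class `faers_vocabulary`: a list with `pt_to_soc`
#'   (named character vector) and `drug_synonyms` (named character vector,
#'   names upper-cased raw strings).
#' @export
make_vocabulary <- function(pt_soc, synonyms = NULL) {
  pt_soc <- as.data.frame(pt_soc)
  if (!nrow(pt_soc)) stop("empty PT-to-SOC table", call. = FALSE)
  pt <- trimws(as.character(pt_soc[[1]]))
  soc <- trimws(as.character(pt_soc[[2]]))
  dup <- duplicated(pt)
  if (any(dup)) {
    first_soc <- soc[match(pt, pt)]
    if (any(soc != first_soc)) {
      bad <- unique(pt[soc != first_soc])
      stop("conflicting SOC mappings for PT(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    pt <- pt[!dup]
    soc <- soc[!dup]
  }
  syn <- character(0)
  if (!is.null(synonyms) && nrow(as.data.frame(synonyms))) {
    synonyms <- as.data.frame(synonyms)
    raw <- toupper(trimws(as.character(synonyms[[1]])))
    ing <- tolower(trimws(as.character(synonyms[[2]])))
    keep <- !duplicated(raw)
    syn <- setNames(ing[keep], raw[keep])
  }
  # idempotence: normalized ingredients map to themselves
  self <- setdiff(toupper(unique(unname(syn))), names(syn))
  syn <- c(syn, setNames(tolower(self), self))
  structure(list(pt_to_soc = setNames(soc, pt), drug_synonyms = syn),
            class = "faers_vocabulary")
}

#' @rdname make_vocabulary
#' @param pt_soc_path,synonym_path paths to tab-delimited two-column text
#'   files with a header row.
#' @param sep field separator of the vocabulary files.
#' @export
load_vocabulary <- function(pt_soc_path, synonym_path = NULL, sep = "\t") {
  read2 <- function(path) {
    tab <- read.table(path, sep = sep, header = TRUE, quote = "",
                      colClasses = "character", comment.char = "",
                      na.strings = NULL)
    if (ncol(tab) < 2) stop("expected a two-column table in ", path, call. = FALSE)
    if (!nrow(tab)) stop("empty vocabulary file: ", path, call. = FALSE)
    tab
  }
  syn <- if (!is.null(synonym_path)) read2(synonym_path) else NULL
  make_vocabulary(read2(pt_soc_path), syn)
}

# DRUGNAME then PROD_AI through the synonym map, first match wins;
# unmatched names degrade to their own lower-cased, trimmed string.
normalize_drug <- function(drugname, prod_ai, vocab) {
  syn <- vocab$drug_synonyms
  k1 <- toupper(trimws(as.character(drugname)))
  k2 <- toupper(trimws(as.character(prod_ai)))
  hit1 <- unname(syn[k1])
  hit2 <- unname(syn[k2])
  out <- tolower(k1)
  use2 <- is.na(hit1) & !is.na(hit2)
  out[use2] <- hit2[use2]
  out[!is.na(hit1)] <- hit1[!is.na(hit1)]
  out
}

#' Assemble joined per-report records from a raw quarter
#'
#' Joins the DEMO, DRUG, REAC and THER tables into a relational
#' `faers_cases` object, one report per DEMO row: demographics are parsed
#' (sex restricted to F/M, age converted to years via [normalize_age()],
#' reporter occupation restricted to the FAERS code list), drug names are
#' normalized through the vocabulary's synonym map (DRUGNAME first, then
#' the active-ingredient field), and all dates are parsed with
#' month-precision imputation.  Malformed rows never error; they degrade
#' to missing fields, which are tallied in the attached load report
#' (`load_report()`).
#'
#' @param quarter a `faers_quarter` from [load_quarter()] or
#'   [simulate_faers()].
#' @param vocab a `faers_vocabulary` from [make_vocabulary()].
#' @return an object of class `faers_cases`: a list of tibbles
#'   `demo` (primaryid, caseid, fda_dt, event_dt, sex, age_years,
#'   occp_cod, date-imputation flags), `drugs` (primaryid, drug_seq,
#'   role_cod, drug), `events` (primaryid, pt) and `therapy` (primaryid,
#'   drug_seq, start_dt, start_imputed).
#' @export
assemble_cases <- function(quarter, vocab) {
  stopifnot(inherits(quarter, "faers_quarter"), inherits(vocab, "faers_vocabulary"))
  d <- quarter$demo
  fda <- parse_faers_date(col_or(d, "FDA_DT", rep(NA_character_, nrow(d))))
  evt <- parse_faers_date(col_or(d, "EVENT_DT", rep(NA_character_, nrow(d))))
  sex_raw <- toupper(trimws(col_or(d, "SEX", rep(NA_character_, nrow(d)))))
  sex <- ifelse(sex_raw %in% c("F", "M"), sex_raw, NA_character_)
  occ_raw <- toupper(trimws(col_or(d, "OCCP_COD", rep(NA_character_, nrow(d)))))
  occ_levels <- c("CN", "HP", "LW", "MD", "OT", "PH", "RN")
  occ <- ifelse(occ_raw %in% occ_levels, occ_raw, NA_character_)
  demo <- tibble(
    primaryid = as.numeric(d$PRIMARYID),
    caseid = as.numeric(d$CASEID),
    fda_dt = fda$date, fda_dt_imputed = fda$imputed,
    event_dt = evt$date, event_dt_imputed = evt$imputed,
    sex = sex,
    age_years = normalize_age(col_or(d, "AGE", rep(NA_character_, nrow(d))),
                              col_or(d, "AGE_COD", rep("YR", nrow(d)))),
    occp_cod = occ
  )

  dr <- quarter$drug
  role_raw <- toupper(trimws(col_or(dr, "ROLE_COD", rep(NA_character_, nrow(dr)))))
  drugs <- tibble(
    primaryid = as.numeric(dr$PRIMARYID),
    drug_seq = as.numeric(col_or(dr, "DRUG_SEQ", rep("1", nrow(dr)))),
    role_cod = ifelse(role_raw %in% c("PS", "SS", "C", "I"), role_raw, NA_character_),
    drug = normalize_drug(col_or(dr, "DRUGNAME", rep(NA_character_, nrow(dr))),
                          col_or(dr, "PROD_AI", rep(NA_character_, nrow(dr))), vocab)
  )

  re <- quarter$reac
  events <- tibble(primaryid = as.numeric(re$PRIMARYID),
                   pt = trimws(re$PT))
  n_blank_pt <- sum(is.na(events$pt) | events$pt == "")
  events <- events[!is.na(events$pt) & events$pt != "", , drop = FALSE]

  th <- quarter$ther
  if (nrow(th)) {
    st <- parse_faers_date(col_or(th, "START_DT", rep(NA_character_, nrow(th))))
    therapy <- tibble(primaryid = as.numeric(th$PRIMARYID),
                      drug_seq = as.numeric(col_or(th, "DRUG_SEQ", rep("1", nrow(th)))),
                      start_dt = st$date, start_imputed = st$imputed)
  } else {
    therapy <- tibble(primaryid = numeric(), drug_seq = numeric(),
                      start_dt = as.Date(character()), start_imputed = logical())
  }

  report <- list(
    n_reports = nrow(demo),
    n_drug_rows = nrow(drugs), n_event_rows = nrow(events),
    n_therapy_rows = nrow(therapy),
    n_blank_pt_dropped = n_blank_pt,
    n_missing = c(fda_dt = sum(is.na(demo$fda_dt)),
                  event_dt = sum(is.na(demo$event_dt)),
                  sex = sum(is.na(demo$sex)),
                  age = sum(is.na(demo$age_years)),
                  occp_cod = sum(is.na(demo$occp_cod))),
    n_date_imputed = c(fda_dt = sum(demo$fda_dt_imputed),
                       event_dt = sum(demo$event_dt_imputed),
                       start_dt = sum(therapy$start_imputed)),
    n_without_events = sum(!(demo$primaryid %in% events$primaryid))
  )
  structure(list(demo = demo, drugs = drugs, events = events, therapy = therapy),
            class = "faers_cases", load_report = report)
}

#' @rdname assemble_cases
#' @param cases a `faers_cases` object.
#' @return `load_report()`: the list of row counts, per-field missingness
#'   and imputation tallies recorded at assembly.
#' @export
load_report <- function(cases) attr(cases, "load_report")

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d reports, %d drug rows, %d event rows, %d therapy rows\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$events), nrow(x$therapy)))
  invisible(x)
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat(sprintf("<faers_quarter> DEMO %d | DRUG %d | REAC %d | THER %d rows\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$ther)))
  invisible(x)
}

# keep rows of a faers_cases whose primaryid is in `ids`
filter_cases <- function(cases, ids) {
  out <- list(
    demo = cases$demo[cases$demo$primaryid %in% ids, , drop = FALSE],
    drugs = cases$drugs[cases$drugs$primaryid %in% ids, , drop = FALSE],
    events = cases$events[cases$events$primaryid %in% ids, , drop = FALSE],
    therapy = cases$therapy[cases$therapy$primaryid %in% ids, , drop = FALSE]
  )
  structure(out, class = "faers_cases", load_report = attr(cases, "load_report"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# column accessor tolerant of absent optional columns
col_or <- function(tab, nm, default) {
  if (nm %in% names(tab)) tab[[nm]] else default
}
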