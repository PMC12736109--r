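# Small hand-built fixtures and independent oracles used across tests.

# construct a faers_quarter from partial data.frames, filling the standard
# columns with empties
mk_quarter <- function(demo = NULL, drug = NULL, reac = NULL, ther = NULL) {
  fill <- function(df, cols) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (cl in setdiff(cols, names(df))) df[[cl]] <- rep("", nrow(df))
    df[] <- lapply(df, as.character)
    tibble::as_tibble(df[, cols, drop = FALSE])
  }
  structure(list(
    demo = fill(demo, c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "SEX",
                        "AGE", "AGE_COD", "OCCP_COD")),
    drug = fill(drug, c("PRIMARYID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME", "PROD_AI")),
    reac = fill(reac, c("PRIMARYID", "PT")),
    ther = fill(ther, c("PRIMARYID", "DRUG_SEQ", "START_DT", "END_DT"))
  ), class = "faers_quarter")
}

vocab_small <- function() {
  make_vocabulary(
    data.frame(pt = c("Pyrexia", "Rash", "Headache", "Nausea"),
               soc = c("General Disorders and Administration Site Conditions",
                       "Skin and Subcutaneous Tissue Disorders",
                       "Nervous System Disorders",
                       "Gastrointestinal Disorders")),
    data.frame(raw = c("KINERET", "ILARIS", "ARCALYST"),
               ingredient = c("anakinra", "canakinumab", "rilonacept"))
  )
}

# Independent one-pass counting oracle: deduplicates, classifies and counts
# case by case with plain loops and environments; shares no code with
# build_contingency()/deduplicate().
oracle_scan_all <- function(quarter, vocab, drugs, level = "pt") {
  demo <- as.data.frame(quarter$demo)
  drug <- as.data.frame(quarter$drug)
  reac <- as.data.frame(quarter$reac)

  groups <- split(seq_len(nrow(demo)), demo$CASEID)
  keep <- integer(length(groups))
  kk <- 0L
  for (idx in groups) {
    best <- idx[1]
    for (i in idx[-1]) {
      di <- demo$FDA_DT[i]; db <- demo$FDA_DT[best]
      if (is.na(di)) di <- ""
      if (is.na(db)) db <- ""
      if (di > db || (di == db &&
            as.numeric(demo$PRIMARYID[i]) > as.numeric(demo$PRIMARYID[best]))) {
        best <- i
      }
    }
    kk <- kk + 1L
    keep[kk] <- best
  }

  syn <- vocab$drug_synonyms
  drows <- split(seq_len(nrow(drug)), drug$PRIMARYID)
  rrows <- split(seq_len(nrow(reac)), reac$PRIMARYID)
  acnt <- new.env(parent = emptyenv())
  ccnt <- new.env(parent = emptyenv())
  n_t <- 0L; n_c <- 0L
  bump <- function(env, key) {
    assign(key, (if (exists(key, envir = env)) get(key, envir = env) else 0L) + 1L,
           envir = env)
  }
  for (i in keep) {
    pid <- demo$PRIMARYID[i]
    is_t <- FALSE
    for (j in drows[[pid]]) {
      if (!is.na(drug$ROLE_COD[j]) && drug$ROLE_COD[j] == "PS") {
        nm <- unname(syn[toupper(trimws(drug$DRUGNAME[j]))])
        if (is.na(nm)) nm <- unname(syn[toupper(trimws(drug$PROD_AI[j]))])
        if (is.na(nm)) nm <- tolower(trimws(drug$DRUGNAME[j]))
        if (!is.na(nm) && nm %in% drugs) {
          is_t <- TRUE
          break
        }
      }
    }
    pts <- unique(reac$PT[rrows[[pid]]])
    pts <- pts[!is.na(pts)]
    if (level == "soc") {
      s <- unname(vocab$pt_to_soc[pts])
      s[is.na(s)] <- "Unmapped"
      pts <- unique(s)
    }
    if (is_t) n_t <- n_t + 1L else n_c <- n_c + 1L
    env <- if (is_t) acnt else ccnt
    for (tm in pts) bump(env, tm)
  }
  terms <- sort(ls(acnt))
  a <- vapply(terms, function(tm) get(tm, envir = acnt), integer(1))
  cc <- vapply(terms, function(tm) {
    if (exists(tm, envir = ccnt)) get(tm, envir = ccnt) else 0L
  }, integer(1))
  data.frame(term = terms, a = unname(a), b = n_t - unname(a),
             c = unname(cc), d = n_c - unname(cc),
             stringsAsFactors = FALSE)
}

# direct scalar re-evaluation of the four disproportionality formulas
oracle_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(
    ror = a * d / (b * c),
    ror_lo = exp(log(a * d / (b * c)) - 1.96 * se),
    ror_hi = exp(log(a * d / (b * c)) + 1.96 * se),
    prr = (a / (a + b)) / (c / (c + d)),
    prr_lo = exp(log((a / (a + b)) / (c / (c + d))) -
                   1.96 * sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))),
    prr_hi = exp(log((a / (a + b)) / (c / (c + d))) +
                   1.96 * sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))),
    chi2 = (a * d - b * c)^2 * N / ((a + b) * (c + d) * (a + c) * (b + d)),
    ic = log2(a * N / ((a + b) * (a + c))),
    ic025 = log2(a * N / ((a + b) * (a + c))) - 1.96 * se / log(2),
    ebgm = a * N / ((a + c) * (a + b)),
    ebgm05 = exp(log(a * N / ((a + c) * (a + b))) - 1.96 * se)
  )
}

# uniform 100-term event vocabulary used by the calibration suites
uniform_events <- function(n_terms = 100) {
  data.frame(pt = sprintf("PT%03d", seq_len(n_terms)),
             soc = rep(sprintf("SOC%02d", seq_len(ceiling(n_terms / 10))),
                       each = 10)[seq_len(n_terms)],
             p = rep(1 / n_terms, n_terms))
}

il1_spec <- function() {
  cohort_spec("IL-1 inhibitors", c("anakinra", "canakinumab", "rilonacept"),
              pooled = TRUE)
}
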