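#' Default preferred-term vocabulary for simulated reports
#'
#' A bundled stand-in event dictionary: ~60 preferred terms across 14
#' system organ classes, with names drawn from the adverse events most
#' frequently reported for the IL-1 inhibitor class (injection-site
#' reactions, common infections, medication-error terms, ...), so that
#' simulated report output resembles real pharmacovigilance tables.
#' Background reporting probabilities decay roughly like 1/rank and are
#' normalized to sum to one.
#'
#' @return tibble with columns `pt`, `soc`, `p` (background probability).
#' @export
default_event_vocabulary <- function() {
  gen <- "General Disorders and Administration Site Conditions"
  inf <- "Infections and Infestations"
  inj <- "Injury, Poisoning and Procedural Complications"
  v <- tibble::tribble(
    ~pt, ~soc,
    "Pyrexia", gen,
    "Condition Aggravated", gen,
    "Injection Site Pain", gen,
    "Injection Site Erythema", gen,
    "Injection Site Pruritus", gen,
    "Injection Site Reaction", gen,
    "Injection Site Swelling", gen,
    "Injection Site Rash", gen,
    "Injection Site Urticaria", gen,
    "Injection Site Bruising", gen,
    "Illness", gen,
    "Fatigue", gen,
    "Malaise", gen,
    "Chest Pain", gen,
    "Chills", gen,
    "COVID-19", inf,
    "Infection", inf,
    "Nasopharyngitis", inf,
    "Influenza", inf,
    "Pneumonia", inf,
    "Sinusitis", inf,
    "Upper Respiratory Tract Infection", inf,
    "Gastroenteritis", inf,
    "Off-Label Use", inj,
    "Product Dose Omission Issue", inj,
    "Inappropriate Schedule of Product Administration", inj,
    "Incorrect Dose Administered", inj,
    "Intentional Product Misuse", inj,
    "Contusion", inj,
    "Urticaria", "Skin and Subcutaneous Tissue Disorders",
    "Rash", "Skin and Subcutaneous Tissue Disorders",
    "Pruritus", "Skin and Subcutaneous Tissue Disorders",
    "Alopecia", "Skin and Subcutaneous Tissue Disorders",
    "Arthralgia", "Musculoskeletal and Connective Tissue Disorders",
    "Rheumatoid Arthritis", "Musculoskeletal and Connective Tissue Disorders",
    "Joint Swelling", "Musculoskeletal and Connective Tissue Disorders",
    "Pain in Extremity", "Musculoskeletal and Connective Tissue Disorders",
    "Back Pain", "Musculoskeletal and Connective Tissue Disorders",
    "Abdominal Pain", "Gastrointestinal Disorders",
    "Nausea", "Gastrointestinal Disorders",
    "Vomiting", "Gastrointestinal Disorders",
    "Diarrhoea", "Gastrointestinal Disorders",
    "Cough", "Respiratory, Thoracic and Mediastinal Disorders",
    "Oropharyngeal Pain", "Respiratory, Thoracic and Mediastinal Disorders",
    "Rhinorrhoea", "Respiratory, Thoracic and Mediastinal Disorders",
    "Dyspnoea", "Respiratory, Thoracic and Mediastinal Disorders",
    "Headache", "Nervous System Disorders",
    "Dizziness", "Nervous System Disorders",
    "Hypoaesthesia", "Nervous System Disorders",
    "Postural Orthostatic Tachycardia Syndrome", "Cardiac Disorders",
    "Pulmonary Valve Incompetence", "Cardiac Disorders",
    "Palpitations", "Cardiac Disorders",
    "Pericarditis", "Cardiac Disorders",
    "Secondary Adrenocortical Insufficiency", "Endocrine Disorders",
    "Cushingoid", "Endocrine Disorders",
    "Papilloedema", "Eye Disorders",
    "Conjunctival Hyperaemia", "Eye Disorders",
    "Insomnia", "Psychiatric Disorders",
    "Anxiety", "Psychiatric Disorders",
    "Neurosensory Deafness", "Ear and Labyrinth Disorders",
    "Renal Amyloidosis", "Renal and Urinary Disorders"
  )
  v$p <- (1 / seq_len(nrow(v)))^0.8
  v$p <- v$p / sum(v$p)
  v
}

#' Default drug-synonym table for simulated reports
#'
#' Maps the brand names of the three marketed IL-1 inhibitors to their
#' ingredients, plus identity rows; the simulator emits brand names for
#' a fraction of drug rows so the normalization path is exercised.
#'
#' @return tibble with columns `raw`, `ingredient`.
#' @export
default_drug_synonyms <- function() {
  tibble::tribble(
    ~raw, ~ingredient,
    "KINERET", "anakinra",
    "ILARIS", "canakinumab",
    "ARCALYST", "rilonacept",
    "ANAKINRA", "anakinra",
    "CANAKINUMAB", "canakinumab",
    "RILONACEPT", "rilonacept"
  )
}

#' Configuration of the synthetic spontaneous-report generator
#'
#' The defaults emulate the structure of the FAERS extract underlying an
#' IL-1 inhibitor safety study: three target drugs plus a pool of
#' comparator drugs, ~60 preferred terms across 14 SOCs, about half of
#' ages and 7% of sexes missing, a consumer-heavy reporter mix, a
#' duplicate-report rate of 19% (the ratio of removed duplicates to
#' retained cases in a full-database cleaning pass), and per-drug
#' time-to-onset laws reproducing the observed qualitative pattern -
#' anakinra onsets concentrated in the first month, canakinumab heavily
#' right-tailed (about 40% beyond a year), rilonacept mostly immediate.
#'
#' @param seed integer RNG seed; the generator is a deterministic
#'   function of the full configuration including the seed.
#' @param n_cases number of unique cases to simulate.
#' @param drugs named numeric vector of per-drug marginal probabilities
#'   (must sum to 1); each case gets exactly one primary-suspect drug.
#' @param events data frame with columns `pt`, `soc`, `p` (background
#'   event multinomial).
#' @param planted data frame with columns `drug`, `pt`, `rr`: relative
#'   risks multiplying the background probability of `pt` for cases of
#'   `drug` (vector renormalized).
#' @param duplicate_rate probability that a case emits an extra report
#'   version (same CASEID, later FDA_DT, higher PRIMARYID).
#' @param missing_age_rate,missing_sex_rate,event_dt_missing_rate
#'   marginal missingness rates.
#' @param occupation named probability vector over reporter occupation
#'   codes (a `missing` entry is allowed).
#' @param events_per_case mean of the (>= 1 truncated) Poisson number of
#'   preferred terms per case.
#' @param tto_laws named list (one entry per drug; a `.default` entry
#'   covers the rest) of lists `list(family = "lognormal"|"weibull",
#'   par1, par2)` - meanlog/sdlog or shape/scale, in days.
#' @param concomitant_rate probability of an extra non-PS drug row.
#' @param start_month_precision_rate fraction of therapy start dates
#'   written at month precision (YYYYMM).
#' @param year_range two integers: calendar window for therapy starts.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_cases = 20000L,
                             drugs = c(anakinra = 0.08, canakinumab = 0.09,
                                       rilonacept = 0.005,
                                       comparator_a = 0.165, comparator_b = 0.165,
                                       comparator_c = 0.165, comparator_d = 0.165,
                                       comparator_e = 0.165),
                             events = default_event_vocabulary(),
                             planted = data.frame(
                               drug = c("anakinra", "canakinumab", "rilonacept",
                                        "anakinra", "canakinumab"),
                               pt = c("Injection Site Erythema", "Pyrexia",
                                      "Injection Site Erythema",
                                      "Injection Site Pain", "Infection"),
                               rr = c(6, 6, 8, 4, 3)),
                             duplicate_rate = 0.19,
                             missing_age_rate = 0.497,
                             missing_sex_rate = 0.072,
                             event_dt_missing_rate = 0.3,
                             occupation = c(CN = 0.557, HP = 0.130, MD = 0.200,
                                            OT = 0.071, PH = 0.017, RN = 0.001,
                                            missing = 0.024),
                             events_per_case = 2.5,
                             tto_laws = list(
                               anakinra = list(family = "lognormal",
                                               par1 = log(45), par2 = 2.0),
                               canakinumab = list(family = "weibull",
                                                  par1 = 0.6, par2 = 450),
                               rilonacept = list(family = "lognormal",
                                                 par1 = log(20), par2 = 2.2),
                               .default = list(family = "lognormal",
                                               par1 = log(60), par2 = 1.5)),
                             concomitant_rate = 0.3,
                             start_month_precision_rate = 0.1,
                             year_range = c(2004L, 2023L)) {
  cfg <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
              drugs = drugs, events = as.data.frame(events), planted = as.data.frame(planted),
              duplicate_rate = duplicate_rate, missing_age_rate = missing_age_rate,
              missing_sex_rate = missing_sex_rate,
              event_dt_missing_rate = event_dt_missing_rate,
              occupation = occupation, events_per_case = events_per_case,
              tto_laws = tto_laws, concomitant_rate = concomitant_rate,
              start_month_precision_rate = start_month_precision_rate,
              year_range = year_range)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  if (abs(sum(cfg$drugs) - 1) > 1e-8) stop("drug marginals must sum to 1", call. = FALSE)
  if (any(cfg$drugs < 0)) stop("drug marginals must be non-negative", call. = FALSE)
  if (!all(c("pt", "soc", "p") %in% names(cfg$events))) {
    stop("events needs columns pt, soc, p", call. = FALSE)
  }
  if (any(cfg$events$p < 0)) stop("event probabilities must be non-negative", call. = FALSE)
  if (nrow(cfg$planted)) {
    if (!all(c("drug", "pt", "rr") %in% names(cfg$planted))) {
      stop("planted needs columns drug, pt, rr", call. = FALSE)
    }
    if (any(!is.finite(cfg$planted$rr)) || any(cfg$planted$rr < 0)) {
      stop("planted relative risks must be finite and >= 0", call. = FALSE)
    }
    if (!all(cfg$planted$pt %in% cfg$events$pt)) {
      stop("planted PTs must occur in the event vocabulary", call. = FALSE)
    }
    if (!all(cfg$planted$drug %in% names(cfg$drugs))) {
      stop("planted drugs must occur in the drug list", call. = FALSE)
    }
  }
  rates <- c(cfg$duplicate_rate, cfg$missing_age_rate, cfg$missing_sex_rate,
             cfg$event_dt_missing_rate, cfg$concomitant_rate,
             cfg$start_month_precision_rate)
  if (any(rates < 0 | rates > 1) || cfg$duplicate_rate >= 1) {
    stop("rates must lie in [0, 1] (duplicate_rate in [0, 1))", call. = FALSE)
  }
  if (any(cfg$occupation < 0) || abs(sum(cfg$occupation) - 1) > 1e-8) {
    stop("occupation distribution must sum to 1", call. = FALSE)
  }
  if (cfg$events_per_case <= 0) stop("events_per_case must be > 0", call. = FALSE)
  invisible(TRUE)
}

# >= 1 truncated Poisson draw, resampling zeros
rtpois <- function(n, lambda) {
  k <- rpois(n, lambda)
  while (any(k == 0)) k[k == 0] <- rpois(sum(k == 0), lambda)
  k
}

draw_tto <- function(law, n) {
  days <- switch(law$family,
    lognormal = rlnorm(n, meanlog = law$par1, sdlog = law$par2),
    weibull = rweibull(n, shape = law$par1, scale = law$par2),
    stop("unknown TTO family: ", law$family, call. = FALSE)
  )
  pmax(0, round(days))
}

#' Generate a synthetic FAERS-format dataset with known ground truth
#'
#' Simulates `n_cases` unique spontaneous reports: one primary-suspect
#' drug per case drawn from the configured marginals, a truncated-Poisson
#' number of preferred terms drawn from the background multinomial with
#' planted drug-event pairs' probabilities multiplied by their relative
#' risks (vector renormalized per drug), demographics with configured
#' missingness, a therapy start date, an onset delay from the drug's
#' time-to-onset law (event date = start + delay), and a receipt date
#' lagging the event date by 0-90 days.  With probability
#' `duplicate_rate` a case emits a second report version sharing its
#' CASEID with a later FDA_DT and a higher PRIMARYID - an exact copy
#' otherwise, the minimal structure the identifier-based deduplication
#' rule acts on.
#'
#' Identical configurations (including the seed) produce byte-identical
#' files.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory; when given, the four quarterly
#'   tables plus `pt_soc.tsv`, `synonyms.tsv` and `ground_truth.tsv` are
#'   written there.
#' @return list with `quarter` (a `faers_quarter`), `truth` (list:
#'   `cases` tibble with the per-case generative record, `planted`,
#'   `duplicates` tibble, `n_duplicates`) and `vocab` (the matching
#'   `faers_vocabulary`).
#' @export
simulate_faers <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_cases
  drug_names <- names(config$drugs)
  ev <- config$events

  drug <- sample(drug_names, n, replace = TRUE, prob = config$drugs)
  k <- rtpois(n, config$events_per_case)

  # events per case, drawn drug-by-drug so planted relative risks apply
  ev_case <- vector("list", n)
  for (dn in unique(drug)) {
    idx <- which(drug == dn)
    p <- ev$p
    pl <- config$planted[config$planted$drug == dn, , drop = FALSE]
    if (nrow(pl)) {
      j <- match(pl$pt, ev$pt)
      p[j] <- p[j] * pl$rr
    }
    p <- p / sum(p)
    tot <- sum(k[idx])
    draws <- sample(ev$pt, tot, replace = TRUE, prob = p)
    ev_case[idx] <- split(draws, rep(seq_along(idx), k[idx]))
  }

  sex <- c("F", "M")[1L + (runif(n) >= 0.622)]
  sex[runif(n) < config$missing_sex_rate] <- NA_character_
  band <- sample(c("<18", "18-65", ">65"), n, replace = TRUE,
                 prob = c(0.354, 0.489, 0.157))
  age <- sample(18:65, n, replace = TRUE)
  age[band == "<18"] <- sample(0:17, sum(band == "<18"), replace = TRUE)
  age[band == ">65"] <- sample(66:90, sum(band == ">65"), replace = TRUE)
  age[runif(n) < config$missing_age_rate] <- NA
  occ <- sample(names(config$occupation), n, replace = TRUE,
                prob = config$occupation)
  occ[occ == "missing"] <- NA

  y0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  y1 <- as.Date(sprintf("%d-12-31", config$year_range[2]))
  start <- y0 + sample.int(as.integer(y1 - y0) + 1L, n, replace = TRUE) - 1L
  tto <- numeric(n)
  for (dn in unique(drug)) {
    idx <- which(drug == dn)
    law <- config$tto_laws[[dn]] %||% config$tto_laws$.default
    if (is.null(law)) stop("no TTO law for drug ", dn, call. = FALSE)
    tto[idx] <- draw_tto(law, length(idx))
  }
  event_dt <- start + tto
  fda_dt <- event_dt + sample(0:90, n, replace = TRUE)

  caseid <- 1000000L + seq_len(n)
  primaryid <- caseid * 10 + 1

  event_missing <- runif(n) < config$event_dt_missing_rate
  month_prec <- runif(n) < config$start_month_precision_rate
  fmt <- function(d) {
    ud <- unique(d)
    format(ud, "%Y%m%d")[match(d, ud)]
  }

  # demographics table
  age_chr <- as.character(age)
  age_cod <- rep("YR", n)
  infant <- !is.na(age) & age < 2
  if (any(infant)) {
    months <- age[infant] * 12 + sample(0:11, sum(infant), replace = TRUE)
    age_chr[infant] <- as.character(months)
    age_cod[infant] <- "MON"
  }
  age_chr[is.na(age)] <- ""
  age_cod[is.na(age)] <- ""
  event_chr <- fmt(event_dt)
  event_chr[event_missing] <- ""
  sex_chr <- sex; sex_chr[is.na(sex)] <- "UNK"
  occ_chr <- occ; occ_chr[is.na(occ)] <- ""
  demo <- data.frame(
    PRIMARYID = as.character(primaryid), CASEID = as.character(caseid),
    FDA_DT = fmt(fda_dt),
    EVENT_DT = event_chr,
    SEX = sex_chr,
    AGE = age_chr, AGE_COD = age_cod,
    OCCP_COD = occ_chr,
    stringsAsFactors = FALSE
  )

  brand <- c(anakinra = "KINERET", canakinumab = "ILARIS",
             rilonacept = "ARCALYST")
  use_brand <- runif(n) < 0.3 & drug %in% names(brand)
  drugname <- toupper(drug)
  drugname[use_brand] <- brand[drug[use_brand]]
  drug_tab <- data.frame(
    PRIMARYID = as.character(primaryid), DRUG_SEQ = "1", ROLE_COD = "PS",
    DRUGNAME = drugname, PROD_AI = toupper(drug), stringsAsFactors = FALSE
  )
  conc <- which(runif(n) < config$concomitant_rate)
  if (length(conc)) {
    cdrug <- toupper(sample(drug_names, length(conc), replace = TRUE))
    drug_tab <- rbind(drug_tab, data.frame(
      PRIMARYID = as.character(primaryid[conc]), DRUG_SEQ = "2",
      ROLE_COD = sample(c("SS", "C", "I"), length(conc), replace = TRUE),
      DRUGNAME = cdrug, PROD_AI = cdrug, stringsAsFactors = FALSE
    ))
  }

  reac <- data.frame(
    PRIMARYID = rep(as.character(primaryid), lengths(ev_case)),
    PT = unlist(ev_case, use.names = FALSE), stringsAsFactors = FALSE
  )

  start_chr <- ifelse(month_prec, format(start, "%Y%m"), fmt(start))
  ther <- data.frame(
    PRIMARYID = as.character(primaryid), DRUG_SEQ = "1",
    START_DT = start_chr, END_DT = "", stringsAsFactors = FALSE
  )

  # duplicate report versions: exact copies except PRIMARYID and FDA_DT
  dup <- which(runif(n) < config$duplicate_rate)
  if (length(dup)) {
    pid2 <- as.character(caseid[dup] * 10 + 2)
    demo2 <- demo[dup, , drop = FALSE]
    demo2$PRIMARYID <- pid2
    demo2$FDA_DT <- fmt(fda_dt[dup] + sample(1:180, length(dup), replace = TRUE))
    demo <- rbind(demo, demo2)
    copy_rows <- function(tab) {
      m <- tab[tab$PRIMARYID %in% as.character(primaryid[dup]), , drop = FALSE]
      m$PRIMARYID <- pid2[match(m$PRIMARYID, as.character(primaryid[dup]))]
      rbind(tab, m)
    }
    drug_tab <- copy_rows(drug_tab)
    reac <- copy_rows(reac)
    ther <- copy_rows(ther)
  }

  ord_tab <- function(tab) {
    as_tibble(tab[order(as.numeric(tab$PRIMARYID)), , drop = FALSE])
  }
  quarter <- structure(list(demo = ord_tab(demo), drug = ord_tab(drug_tab),
                            reac = ord_tab(reac), ther = ord_tab(ther)),
                       class = "faers_quarter")

  vocab <- make_vocabulary(ev[, c("pt", "soc")],
                           rbind(as.data.frame(default_drug_synonyms()),
                                 data.frame(raw = toupper(drug_names),
                                            ingredient = drug_names)))
  truth <- list(
    cases = tibble(caseid = caseid, primaryid = primaryid, drug = drug,
                   n_events = k, sex = sex, age_years = age, occp_cod = occ,
                   start_dt = start, tto_days = tto, event_dt = event_dt,
                   fda_dt = fda_dt,
                   event_dt_missing = event_missing,
                   start_month_precision = month_prec),
    planted = as_tibble(config$planted),
    duplicates = tibble(primaryid_dup = caseid[dup] * 10 + 2,
                        primaryid_orig = primaryid[dup]),
    n_duplicates = length(dup)
  )

  if (!is.null(out_dir)) {
    write_quarter(quarter, out_dir)
    write.table(ev[, c("pt", "soc")], file.path(out_dir, "pt_soc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    syn <- rbind(as.data.frame(default_drug_synonyms()),
                 data.frame(raw = toupper(drug_names), ingredient = drug_names))
    write.table(syn, file.path(out_dir, "synonyms.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gt <- as.data.frame(truth$cases)
    gt$start_dt <- fmt(gt$start_dt); gt$event_dt <- fmt(gt$event_dt)
    gt$fda_dt <- fmt(gt$fda_dt)
    write.table(gt, file.path(out_dir, "ground_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }

  list(quarter = quarter, truth = truth, vocab = vocab)
}

#' Independent brute-force contingency recount
#'
#' A deliberately simple second implementation used as a counting oracle:
#' reads the quarterly files (or takes a `faers_quarter`), applies the
#' deduplication rule, the primary-suspect rule and the once-per-case
#' event rule by scanning report by report with plain loops, and returns
#' the 2x2 table for one (drug set, term) pair.  It shares no code with
#' [build_contingency()].
#'
#' @param x a directory containing `DEMO.txt`/`DRUG.txt`/`REAC.txt`, or a
#'   `faers_quarter` object.
#' @param drugs character vector of normalized target ingredients.
#' @param term the PT (or SOC when `level = "soc"`) to count.
#' @param level `"pt"` or `"soc"`.
#' @param vocab a `faers_vocabulary` (used for synonym normalization and,
#'   at SOC level, the PT mapping).
#' @return list with counts `a`, `b`, `c`, `d`.
#' @export
oracle_counts <- function(x, drugs, term, level = c("pt", "soc"), vocab) {
  level <- match.arg(level)
  if (is.character(x)) {
    q <- list(demo = read_faers_table(file.path(x, "DEMO.txt")),
              drug = read_faers_table(file.path(x, "DRUG.txt")),
              reac = read_faers_table(file.path(x, "REAC.txt")))
  } else {
    q <- x
  }
  demo <- as.data.frame(q$demo)
  # deduplication by explicit per-case scan
  keep <- character(0)
  for (cid in unique(demo$CASEID)) {
    rows <- demo[demo$CASEID == cid, , drop = FALSE]
    best <- 1
    for (i in seq_len(nrow(rows))[-1]) {
      di <- rows$FDA_DT[i]; db <- rows$FDA_DT[best]
      di <- if (is.na(di)) "" else di
      db <- if (is.na(db)) "" else db
      if (di > db ||
          (di == db && as.numeric(rows$PRIMARYID[i]) > as.numeric(rows$PRIMARYID[best]))) {
        best <- i
      }
    }
    keep <- c(keep, rows$PRIMARYID[best])
  }

  syn <- vocab$drug_synonyms
  norm1 <- function(nm, ai) {
    h <- syn[toupper(trimws(nm))]
    if (!is.na(h)) return(unname(h))
    h <- syn[toupper(trimws(ai))]
    if (!is.na(h)) return(unname(h))
    tolower(trimws(nm))
  }
  dtab <- as.data.frame(q$drug)
  rtab <- as.data.frame(q$reac)
  a <- 0L; b <- 0L; cc <- 0L; d <- 0L
  for (pid in keep) {
    drows <- dtab[dtab$PRIMARYID == pid, , drop = FALSE]
    is_target <- FALSE
    for (i in seq_len(nrow(drows))) {
      if (!is.na(drows$ROLE_COD[i]) && drows$ROLE_COD[i] == "PS" &&
          norm1(drows$DRUGNAME[i], drows$PROD_AI[i]) %in% drugs) {
        is_target <- TRUE
      }
    }
    pts <- unique(rtab$PT[rtab$PRIMARYID == pid])
    terms <- if (level == "soc") {
      s <- unname(vocab$pt_to_soc[pts])
      s[is.na(s)] <- "Unmapped"
      unique(s)
    } else pts
    has_term <- term %in% terms
    if (is_target && has_term) a <- a + 1L
    else if (is_target) b <- b + 1L
    else if (has_term) cc <- cc + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = cc, d = d)
}
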