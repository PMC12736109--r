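test_that("identical configurations produce byte-identical outputs", {
  cfg <- synthetic_config(seed = 71, n_cases = 400)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_faers(cfg, out_dir = d1)
  s2 <- simulate_faers(cfg, out_dir = d2)
  expect_identical(s1$quarter, s2$quarter)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  s3 <- simulate_faers(synthetic_config(seed = 72, n_cases = 400))
  expect_false(identical(s1$quarter$demo, s3$quarter$demo))
})

test_that("duplicate emission matches its own bookkeeping and can be disabled", {
  s0 <- simulate_faers(synthetic_config(seed = 73, n_cases = 500,
                                        duplicate_rate = 0))
  cs0 <- assemble_cases(s0$quarter, s0$vocab)
  expect_equal(dedup_audit(deduplicate(cs0))$n_removed, 0)
  expect_equal(s0$truth$n_duplicates, 0)

  s <- simulate_faers(synthetic_config(seed = 74, n_cases = 2000,
                                       duplicate_rate = 0.2))
  expect_equal(nrow(s$quarter$demo), 2000 + s$truth$n_duplicates)
  expect_equal(length(unique(s$quarter$demo$CASEID)), 2000)
  # every duplicate links to its original and has the later receipt date
  dups <- s$truth$duplicates
  demo <- s$quarter$demo
  i_dup <- match(as.character(dups$primaryid_dup), demo$PRIMARYID)
  i_org <- match(as.character(dups$primaryid_orig), demo$PRIMARYID)
  expect_true(all(demo$FDA_DT[i_dup] > demo$FDA_DT[i_org]))
  expect_true(all(dups$primaryid_dup > dups$primaryid_orig))
})

test_that("missingness rates converge to their configured values", {
  cfg <- synthetic_config(seed = 75, n_cases = 20000)
  s <- simulate_faers(cfg)
  tol <- 4 * sqrt(0.5 * 0.5 / 20000)  # 4 sigma
  expect_equal(mean(is.na(s$truth$cases$age_years)), cfg$missing_age_rate,
               tolerance = tol / cfg$missing_age_rate)
  expect_equal(mean(is.na(s$truth$cases$sex)), cfg$missing_sex_rate,
               tolerance = tol / cfg$missing_sex_rate)
  expect_equal(mean(s$truth$cases$event_dt_missing), cfg$event_dt_missing_rate,
               tolerance = tol / cfg$event_dt_missing_rate)
  # assembled data shows the same pattern
  cs <- assemble_cases(s$quarter, s$vocab)
  expect_equal(mean(is.na(cs$demo$sex)), cfg$missing_sex_rate, tolerance = 0.1)
})

test_that("invalid configurations fail before anything is generated", {
  expect_error(synthetic_config(drugs = c(a = 0.4, b = 0.4)), "sum to 1")
  expect_error(synthetic_config(planted = data.frame(drug = "anakinra",
                                                     pt = "No Such Term",
                                                     rr = 2)),
               "vocabulary")
  expect_error(synthetic_config(planted = data.frame(drug = "anakinra",
                                                     pt = "Pyrexia", rr = -1)),
               "relative risks")
  expect_error(synthetic_config(duplicate_rate = 1), "duplicate_rate")
  expect_error(synthetic_config(events_per_case = 0), "events_per_case")
})

test_that("a zero relative risk suppresses the pair entirely", {
  cfg <- synthetic_config(seed = 76, n_cases = 3000,
                          planted = data.frame(drug = "anakinra",
                                               pt = "Pyrexia", rr = 0))
  s <- simulate_faers(cfg)
  truth <- s$truth$cases
  reac <- s$quarter$reac
  ana <- as.character(truth$primaryid[truth$drug == "anakinra"])
  expect_false(any(reac$PT[reac$PRIMARYID %in% ana] == "Pyrexia"))
  expect_true(any(reac$PT == "Pyrexia"))  # others still report it
})

test_that("the exported per-term oracle agrees with hand counts and ignores row order", {
  dir <- withr::local_tempdir()
  q <- mk_quarter(
    demo = data.frame(PRIMARYID = as.character(1:4), CASEID = as.character(1:4),
                      FDA_DT = "20200101"),
    drug = data.frame(PRIMARYID = as.character(1:4), DRUG_SEQ = "1",
                      ROLE_COD = "PS",
                      DRUGNAME = c("KINERET", "KINERET", "Aspirin", "Aspirin")),
    reac = data.frame(PRIMARYID = as.character(1:4),
                      PT = c("Pyrexia", "Rash", "Pyrexia", "Headache"))
  )
  write_quarter(q, dir)
  v <- vocab_small()
  o <- oracle_counts(dir, "anakinra", "Pyrexia", "pt", v)
  expect_equal(unlist(o), c(a = 1, b = 1, c = 1, d = 1))
  # shuffling file rows changes nothing
  set.seed(77)
  q2 <- q
  q2$demo <- q$demo[sample(4), ]
  q2$reac <- q$reac[sample(4), ]
  o2 <- oracle_counts(q2, "anakinra", "Pyrexia", "pt", v)
  expect_equal(o2, o)
  # and it matches the pipeline on simulated data
  sim <- simulate_faers(synthetic_config(seed = 78, n_cases = 600))
  dd <- deduplicate(assemble_cases(sim$quarter, sim$vocab))
  tab <- build_contingency(dd, cohort_spec("anakinra", "anakinra"), "pt", sim$vocab)
  for (tm in head(tab$term[order(-tab$a)], 3)) {
    o3 <- oracle_counts(sim$quarter, "anakinra", tm, "pt", sim$vocab)
    row <- tab[tab$term == tm, ]
    expect_equal(unlist(o3), c(a = row$a, b = row$b, c = row$c, d = row$d))
  }
})
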