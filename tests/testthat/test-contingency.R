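hand_quarter <- function() {
  # 4 cases: 2 on anakinra (1 with Pyrexia), 2 on other drugs (1 with Pyrexia)
  mk_quarter(
    demo = data.frame(PRIMARYID = as.character(1:4), CASEID = as.character(1:4),
                      FDA_DT = "20200101"),
    drug = data.frame(PRIMARYID = as.character(1:4), DRUG_SEQ = "1",
                      ROLE_COD = "PS",
                      DRUGNAME = c("KINERET", "KINERET", "Aspirin", "Aspirin")),
    reac = data.frame(PRIMARYID = c("1", "2", "3", "4"),
                      PT = c("Pyrexia", "Rash", "Pyrexia", "Headache"))
  )
}

test_that("the 2x2 cells are direct case counts", {
  cs <- assemble_cases(hand_quarter(), vocab_small())
  tab <- build_contingency(cs, cohort_spec("anakinra", "anakinra"), "pt",
                           vocab_small())
  py <- tab[tab$term == "Pyrexia", ]
  expect_equal(unlist(py[, c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 1, 1, 1))
  # margins per term
  expect_true(all(tab$a + tab$b == 2))
  expect_true(all(tab$c + tab$d == 2))
})

test_that("a repeated PT contributes once per case (and twice under pair counting)", {
  q <- hand_quarter()
  q$reac <- dplyr::bind_rows(q$reac, tibble::tibble(PRIMARYID = "1", PT = "Pyrexia"))
  cs <- assemble_cases(q, vocab_small())
  spec <- cohort_spec("anakinra", "anakinra")
  tab <- build_contingency(cs, spec, "pt", vocab_small())
  expect_equal(tab$a[tab$term == "Pyrexia"], 1L)
  pair <- build_contingency(cs, spec, "pt", vocab_small(), counting = "pair")
  expect_equal(pair$a[pair$term == "Pyrexia"], 2L)
})

test_that("SOC-level counts are case-level unions of member PT counts", {
  sim <- simulate_faers(synthetic_config(seed = 31, n_cases = 1500))
  dd <- deduplicate(assemble_cases(sim$quarter, sim$vocab))
  spec <- il1_spec()
  pt_tab <- build_contingency(dd, spec, "pt", sim$vocab)
  soc_tab <- build_contingency(dd, spec, "soc", sim$vocab)
  pt_soc <- sim$vocab$pt_to_soc[pt_tab$term]
  for (s in unique(soc_tab$term)) {
    member_a <- pt_tab$a[!is.na(pt_soc) & pt_soc == s]
    a_soc <- soc_tab$a[soc_tab$term == s]
    expect_true(a_soc >= max(member_a))
    expect_true(a_soc <= sum(member_a))
  }
})

test_that("sex-stratified counts add up to the non-missing-sex total", {
  sim <- simulate_faers(synthetic_config(seed = 32, n_cases = 2000))
  dd <- deduplicate(assemble_cases(sim$quarter, sim$vocab))
  spec <- il1_spec()
  tf <- build_contingency(dd, spec, "pt", sim$vocab,
                          stratum = stratum_spec("sex", "F"))
  tm <- build_contingency(dd, spec, "pt", sim$vocab,
                          stratum = stratum_spec("sex", "M"))
  # unstratified recount restricted to reports with known sex
  known <- dd$demo$primaryid[!is.na(dd$demo$sex)]
  restr <- dd
  restr$demo <- restr$demo[restr$demo$primaryid %in% known, ]
  restr$drugs <- restr$drugs[restr$drugs$primaryid %in% known, ]
  restr$events <- restr$events[restr$events$primaryid %in% known, ]
  tall <- build_contingency(restr, spec, "pt", sim$vocab)
  for (tm_name in tall$term) {
    af <- tf$a[tf$term == tm_name]
    am <- tm$a[tm$term == tm_name]
    expect_equal(sum(af, am),
                 tall$a[tall$term == tm_name])
  }
})

test_that("every table matches the independent brute-force recount", {
  sim <- simulate_faers(synthetic_config(seed = 33, n_cases = 1200,
                                         duplicate_rate = 0.25))
  dd <- deduplicate(assemble_cases(sim$quarter, sim$vocab))
  for (lvl in c("pt", "soc")) {
    spec <- cohort_spec("anakinra", "anakinra")
    mine <- build_contingency(dd, spec, lvl, sim$vocab)
    mine <- mine[order(mine$term), ]
    orc <- oracle_scan_all(sim$quarter, sim$vocab, spec$drugs, level = lvl)
    expect_equal(mine$term, orc$term)
    expect_equal(mine$a, orc$a)
    expect_equal(mine$b, orc$b)
    expect_equal(mine$c, orc$c)
    expect_equal(mine$d, orc$d)
  }
})

test_that("PTs missing from the vocabulary fall into an Unmapped SOC with a warning", {
  q <- hand_quarter()
  q$reac$PT[q$reac$PT == "Headache"] <- "Mystery Syndrome"
  cs <- assemble_cases(q, vocab_small())
  expect_warning(
    tab <- build_contingency(cs, cohort_spec("other", "aspirin"), "soc",
                             vocab_small()),
    "Unmapped")
  expect_true("Unmapped" %in% tab$term)
})
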