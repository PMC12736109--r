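tto_quarter <- function() {
  mk_quarter(
    demo = data.frame(PRIMARYID = as.character(1:4), CASEID = as.character(1:4),
                      FDA_DT = "20200601",
                      EVENT_DT = c("20200131", "20200101", "202003", "20200110")),
    drug = data.frame(PRIMARYID = as.character(1:4), DRUG_SEQ = "1",
                      ROLE_COD = "PS", DRUGNAME = "KINERET"),
    reac = data.frame(PRIMARYID = as.character(1:4), PT = "Pyrexia"),
    ther = data.frame(PRIMARYID = as.character(1:4), DRUG_SEQ = "1",
                      START_DT = c("20200101", "20200301", "202001", ""))
  )
}

test_that("onset days are event minus earliest therapy start, with audited exclusions", {
  cs <- assemble_cases(tto_quarter(), vocab_small())
  tto <- compute_tto(cs, cohort_spec("anakinra", "anakinra"))
  expect_equal(tto$days[tto$primaryid == 1], 30)
  # case 2: event precedes start -> excluded as negative
  expect_false(2 %in% tto$primaryid)
  # case 3: both dates month-precision, imputed to the 15th -> 60 days, flagged
  expect_equal(tto$days[tto$primaryid == 3], 60)
  expect_true(tto$imputed[tto$primaryid == 3])
  expect_false(tto$imputed[tto$primaryid == 1])
  aud <- tto_audit(tto)
  expect_equal(aud$n_cohort, 4)
  expect_equal(aud$n_negative, 1)
  expect_equal(aud$n_missing_start, 1)
  expect_equal(aud$n_obs + aud$n_negative + aud$n_missing_start +
                 aud$n_missing_event_dt, aud$n_cohort)
})

test_that("the earliest start among a case's cohort PS rows anchors the onset", {
  q <- mk_quarter(
    demo = data.frame(PRIMARYID = "1", CASEID = "1", FDA_DT = "20200601",
                      EVENT_DT = "20200401"),
    drug = data.frame(PRIMARYID = "1", DRUG_SEQ = c("1", "2"), ROLE_COD = "PS",
                      DRUGNAME = c("KINERET", "ILARIS")),
    reac = data.frame(PRIMARYID = "1", PT = "Pyrexia"),
    ther = data.frame(PRIMARYID = "1", DRUG_SEQ = c("1", "2"),
                      START_DT = c("20200301", "20200101"))
  )
  cs <- assemble_cases(q, vocab_small())
  # class cohort: earliest PS start (Jan 1) anchors
  expect_equal(compute_tto(cs, il1_spec())$days, 91)
  # single-drug cohort: only that drug's therapy row counts
  expect_equal(compute_tto(cs, cohort_spec("anakinra", "anakinra"))$days, 31)
})

test_that("binning is closed on the right and conserves totals", {
  expect_equal(as.character(bin_tto(c(0, 30, 31, 60, 90, 120, 180, 360, 361))),
               c("0-30", "0-30", "31-60", "31-60", "61-90", "91-120",
                 "121-180", "181-360", ">360"))
  set.seed(61)
  days <- round(rlnorm(500, 4, 1.5))
  bt <- tto_bin_table(days)
  expect_equal(sum(bt$n), 500)
  expect_equal(sum(bt$pct), 100, tolerance = 1e-9)
})

test_that("cumulative incidence is the empirical CDF absent competing events", {
  ci <- cumulative_incidence(c(10, 20), c("g", "g"))
  # coordinates are step-function points; the value at an event time is the
  # post-jump maximum there
  expect_equal(max(ci$est[ci$time == 10]), 0.5)
  expect_equal(max(ci$est[ci$time == 20]), 1.0)
  set.seed(62)
  days <- round(rlnorm(200, 3, 1))
  ci2 <- cumulative_incidence(days, rep("x", 200))
  expect_true(all(diff(ci2$est) >= -1e-12))
  expect_true(all(ci2$est <= 1 + 1e-12))
})

test_that("a competing event caps the curve below one (hand-computed toy)", {
  # times 1..4, causes 1,2,1,2: CIF_1 steps to 0.25 at t=1 and 0.5 at t=3
  ci <- cumulative_incidence(1:4, rep("g", 4), fstatus = c(1, 2, 1, 2))
  c1 <- ci[ci$cause == "1", ]
  expect_equal(max(c1$est[c1$time == 1]), 0.25)
  expect_equal(max(c1$est), 0.5)
})

test_that("Gray's test degenerates correctly and needs two groups", {
  same <- grays_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                     permutations = 99)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$p_permutation, 1)
  expect_error(grays_test(1:5, rep("a", 5)), "two groups")
})

test_that("asymptotic and permutation p-values agree on well-separated groups", {
  set.seed(63)
  x <- c(round(rlnorm(150, 2.5, 1)), round(rlnorm(150, 4.0, 1)))
  g <- rep(c("early", "late"), each = 150)
  gt <- grays_test(x, g, permutations = 999)
  expect_lt(gt$p_value, 0.01)
  expect_lt(gt$p_permutation, 0.01)
  # relabeling the groups leaves the statistic unchanged
  gt2 <- grays_test(x, ifelse(g == "early", "B", "A"))
  expect_equal(gt2$statistic, gt$statistic, tolerance = 1e-9)
})
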