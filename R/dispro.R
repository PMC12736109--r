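#' Disproportionality statistics for 2x2 report tables
#'
#' Computes, for each table `(a, b, c, d)`, the four signal-detection
#' statistics used throughout spontaneous-report pharmacovigilance:
#'
#' * reporting odds ratio `ROR = ad / bc` with Woolf 95% interval
#'   `exp(ln ROR +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`;
#' * proportional reporting ratio `PRR = (a/(a+b)) / (c/(c+d))` with
#'   interval `exp(ln PRR +- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`
#'   and the (uncorrected) chi-squared statistic
#'   `(ad - bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d))`;
#' * the BCPNN information component
#'   `IC = log2( a N / ((a+b)(a+c)) )`, `N = a+b+c+d`, with the
#'   delta-method lower bound `IC025 = IC - 1.96 * SE / ln 2`,
#'   `SE = sqrt(1/a + 1/b + 1/c + 1/d)`;
#' * the (unshrunk) gamma Poisson relative reporting ratio
#'   `EBGM = a N / ((a+c)(a+b))` with
#'   `EBGM05 = exp(ln EBGM - 1.96 * SE)`.
#'
#' `IC = log2(EBGM)` holds exactly under these formulas.  When any of
#' `b`, `c`, `d` is zero (and `a > 0`) a Haldane-Anscombe 0.5 continuity
#' correction is applied to all four cells for the ROR/PRR *interval*
#' computation only; point estimates are untouched.  Tables with `a = 0`
#' yield `NA` statistics and are never flagged as signals.
#'
#' @param tables data frame with integer columns `a`, `b`, `c`, `d`
#'   (extra columns such as `term` are carried through).
#' @return the input tibble with columns `n` (= `a`), `ror`, `ror_lo`,
#'   `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chi2`, `ic`, `ic025`, `ebgm`,
#'   `ebgm05` appended.
#' @examples
#' signal_stats(data.frame(a = 3, b = 7, c = 30, d = 700))
#' @export
signal_stats <- function(tables) {
  tables <- as_tibble(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c); d <- as.numeric(tables$d)
  stopifnot(all(a >= 0), all(b >= 0), all(cc >= 0), all(d >= 0))
  N <- a + b + cc + d

  ror <- (a * d) / (b * cc)
  prr <- (a / (a + b)) / (cc / (cc + d))
  chi2 <- (a * d - b * cc)^2 * N / ((a + b) * (cc + d) * (a + cc) * (b + d))
  ic <- log2(a * N / ((a + b) * (a + cc)))
  ebgm <- a * N / ((a + cc) * (a + b))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ic025 <- ic - 1.96 * se / log(2)
  ebgm05 <- exp(log(ebgm) - 1.96 * se)

  # Haldane-Anscombe correction for frequentist intervals on zero cells
  corr <- a > 0 & (b == 0 | cc == 0 | d == 0)
  a2 <- ifelse(corr, a + 0.5, a); b2 <- ifelse(corr, b + 0.5, b)
  c2 <- ifelse(corr, cc + 0.5, cc); d2 <- ifelse(corr, d + 0.5, d)
  ror_ci_mid <- (a2 * d2) / (b2 * c2)
  se_ror <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  ror_lo <- exp(log(ror_ci_mid) - 1.96 * se_ror)
  ror_hi <- exp(log(ror_ci_mid) + 1.96 * se_ror)
  prr_ci_mid <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  se_prr <- sqrt(pmax(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2), 0))
  prr_lo <- exp(log(prr_ci_mid) - 1.96 * se_prr)
  prr_hi <- exp(log(prr_ci_mid) + 1.96 * se_prr)

  undef <- a == 0
  out <- tables
  out$n <- as.integer(a)
  out$ror <- ror; out$ror_lo <- ror_lo; out$ror_hi <- ror_hi
  out$prr <- prr; out$prr_lo <- prr_lo; out$prr_hi <- prr_hi
  out$chi2 <- chi2
  out$ic <- ic; out$ic025 <- ic025
  out$ebgm <- ebgm; out$ebgm05 <- ebgm05
  stat_cols <- c("ror", "ror_lo", "ror_hi", "prr", "prr_lo", "prr_hi",
                 "chi2", "ic", "ic025", "ebgm", "ebgm05")
  out[undef, stat_cols] <- NA_real_
  out
}

#' Apply the per-algorithm signal criteria and the joint rule
#'
#' A drug-event pair is flagged by each algorithm as:
#' ROR: lower 95% bound `> 1` and `n >= 3`;
#' PRR: lower 95% bound `> 1` and `n >= 3`;
#' BCPNN: `IC025 > 0`;
#' MGPS: `EBGM05 > 0` (threshold exposed because this bound is far more
#' permissive than the `EBGM05 >= 2` convention used elsewhere).
#' The joint verdict `joint_pos` is the conjunction of all four;
#' undefined statistics flag `FALSE` everywhere.
#'
#' @param stats output of [signal_stats()].
#' @param n_min minimum report count for the frequentist criteria.
#' @param ror_lo_min,prr_lo_min,ic025_min,ebgm05_min per-algorithm
#'   thresholds (defaults as stated above).
#' @return `stats` with logical columns `ror_pos`, `prr_pos`,
#'   `bcpnn_pos`, `mgps_pos`, `joint_pos` appended.
#' @export
evaluate_signals <- function(stats, n_min = 3, ror_lo_min = 1, prr_lo_min = 1,
                             ic025_min = 0, ebgm05_min = 0) {
  flag <- function(x) !is.na(x) & x
  stats$ror_pos <- flag(stats$ror_lo > ror_lo_min & stats$n >= n_min)
  stats$prr_pos <- flag(stats$prr_lo > prr_lo_min & stats$n >= n_min)
  stats$bcpnn_pos <- flag(stats$ic025 > ic025_min)
  stats$mgps_pos <- flag(stats$ebgm05 > ebgm05_min)
  stats$joint_pos <- stats$ror_pos & stats$prr_pos &
    stats$bcpnn_pos & stats$mgps_pos
  stats
}

#' Run a full disproportionality scan over a set of tables
#'
#' Convenience wrapper: [signal_stats()] then [evaluate_signals()], with
#' rows ordered for reporting - joint-positive terms first, ranked by
#' case frequency `n` (descending) with lexicographic term tie-break,
#' followed by the remaining terms in the same order.  The ordering is a
#' deterministic function of the table contents, so permuting the input
#' rows does not change the result.
#'
#' @param tables output of [build_contingency()].
#' @inheritParams evaluate_signals
#' @return ranked tibble of statistics and per-algorithm flags.
#' @export
run_signal_scan <- function(tables, n_min = 3, ror_lo_min = 1, prr_lo_min = 1,
                            ic025_min = 0, ebgm05_min = 0) {
  out <- evaluate_signals(signal_stats(tables), n_min = n_min,
                          ror_lo_min = ror_lo_min, prr_lo_min = prr_lo_min,
                          ic025_min = ic025_min, ebgm05_min = ebgm05_min)
  out[order(-out$joint_pos, -out$n, out$term), , drop = FALSE]
}

#' Format a scan for report output
#'
#' Rounds every statistic to two decimals and renders the interval
#' columns in the conventional table layout: `ROR (95% CI)`,
#' `PRR (chi2)`, `EBGM (EBGM05)`, `IC (IC025)`.
#'
#' @param scan output of [run_signal_scan()].
#' @param joint_only keep only joint-positive rows (default `TRUE`).
#' @return tibble of display strings.
#' @export
format_signal_table <- function(scan, joint_only = TRUE) {
  if (joint_only) scan <- scan[scan$joint_pos, , drop = FALSE]
  r2 <- function(x) as.character(round(x, 2))
  tibble(
    term = scan$term,
    n = scan$n,
    `ROR (95% CI)` = sprintf("%s (%s-%s)", r2(scan$ror), r2(scan$ror_lo), r2(scan$ror_hi)),
    `PRR (chi2)` = sprintf("%s (%s)", r2(scan$prr), r2(scan$chi2)),
    `EBGM (EBGM05)` = sprintf("%s (%s)", r2(scan$ebgm), r2(scan$ebgm05)),
    `IC (IC025)` = sprintf("%s (%s)", r2(scan$ic), r2(scan$ic025))
  )
}
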