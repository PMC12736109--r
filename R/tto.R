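#' Time to onset of a cohort's adverse events
#'
#' Days from the earliest therapy start among a report's primary-suspect
#' drug rows (restricted to the cohort's drugs) to the report's event
#' date.  One observation per case: the report's single event date is
#' used even when several preferred terms are listed, consistent with the
#' case-level counting of the contingency module.  Observations are
#' missing when either date is absent or the difference is negative;
#' every exclusion is tallied in the attached audit.  Month-precision
#' dates (imputed to day 15 at parse time) are flagged per observation.
#'
#' @param cases deduplicated `faers_cases`.
#' @param spec a [cohort_spec()].
#' @return tibble with columns `primaryid`, `days`, `imputed` (logical:
#'   either anchor date was month-imputed), one row per cohort report
#'   with a computable onset time; attribute `tto_audit` lists
#'   `n_cohort`, `n_obs`, `n_missing_event_dt`, `n_missing_start`,
#'   `n_negative`.
#' @export
compute_tto <- function(cases, spec) {
  stopifnot(inherits(cases, "faers_cases"), inherits(spec, "cohort_spec"))
  ids <- cohort_ids(cases, spec)
  d <- cases$drugs
  ps <- d[!is.na(d$role_cod) & d$role_cod == "PS" &
            !is.na(d$drug) & d$drug %in% spec$drugs, c("primaryid", "drug_seq")]
  th <- inner_join(ps, cases$therapy, by = c("primaryid", "drug_seq"))
  th <- th[!is.na(th$start_dt), , drop = FALSE]
  starts <- th |>
    group_by(primaryid) |>
    summarise(start_dt = min(start_dt),
              start_imputed = start_imputed[which.min(start_dt)][1],
              .groups = "drop")
  demo <- cases$demo[cases$demo$primaryid %in% ids,
                     c("primaryid", "event_dt", "event_dt_imputed")]
  obs <- left_join(demo, starts, by = "primaryid")
  days <- as.numeric(obs$event_dt - obs$start_dt)

  n_missing_event <- sum(is.na(obs$event_dt))
  n_missing_start <- sum(!is.na(obs$event_dt) & is.na(obs$start_dt))
  n_negative <- sum(!is.na(days) & days < 0)
  keep <- !is.na(days) & days >= 0
  out <- tibble(primaryid = obs$primaryid[keep],
                days = days[keep],
                imputed = obs$event_dt_imputed[keep] | obs$start_imputed[keep])
  attr(out, "tto_audit") <- list(
    n_cohort = length(ids), n_obs = nrow(out),
    n_missing_event_dt = n_missing_event,
    n_missing_start = n_missing_start,
    n_negative = n_negative
  )
  out
}

#' @rdname compute_tto
#' @param tto output of `compute_tto()`.
#' @export
tto_audit <- function(tto) attr(tto, "tto_audit")

#' Bin onset times into the standard reporting intervals
#'
#' Default bins are 0-30, 31-60, 61-90, 91-120, 121-180, 181-360 and
#' >360 days, closed on the right (day 30 falls in the first bin, day
#' 361 in the last).
#'
#' @param days non-negative numeric vector of onset times in days.
#' @param edges increasing vector of right bin edges (the last bin is
#'   everything beyond the final edge).
#' @return factor of interval labels.
#' @examples
#' bin_tto(c(0, 30, 31, 360, 361))
#' @export
bin_tto <- function(days, edges = c(30, 60, 90, 120, 180, 360)) {
  stopifnot(all(diff(edges) > 0), all(days >= 0, na.rm = TRUE))
  lo <- c(0, edges[-length(edges)] + 1)
  labels <- c(paste0(lo, "-", edges), paste0(">", edges[length(edges)]))
  cut(days, breaks = c(-1, edges, Inf), labels = labels, right = TRUE)
}

#' @rdname bin_tto
#' @return `tto_bin_table()`: tibble with `bin`, `n` and `pct` (percent
#'   of non-missing observations; sums to 100).
#' @export
tto_bin_table <- function(days, edges = c(30, 60, 90, 120, 180, 360)) {
  b <- bin_tto(days[!is.na(days)], edges)
  cnt <- table(b)
  tibble(bin = names(cnt), n = as.integer(cnt),
         pct = 100 * as.integer(cnt) / sum(cnt))
}

#' Cumulative incidence curves by group
#'
#' Empirical cumulative incidence per group over the pooled event grid.
#' In the default configuration every observation is an event of the
#' single type of interest (spontaneous reports carry no censoring
#' information), in which case each curve is the group's empirical CDF.
#' A competing event can be encoded through `fstatus` (0 = censored,
#' 1 = event of interest, 2+ = competing causes); estimation then follows
#' the Aalen-Johansen form via [cmprsk::cuminc()].
#'
#' @param days numeric vector of onset times.
#' @param group group label per observation (>= 1 observation per group).
#' @param fstatus integer event codes per observation; default all 1.
#' @param cencode code denoting censoring (default 0).
#' @return tibble with columns `group`, `cause`, `time`, `est` - the
#'   step-function coordinates of each curve.
#' @export
cumulative_incidence <- function(days, group, fstatus = NULL, cencode = 0) {
  stopifnot(length(days) == length(group))
  if (is.null(fstatus)) fstatus <- rep(1L, length(days))
  group <- as.character(group)
  fit <- cmprsk::cuminc(ftime = days, fstatus = fstatus, group = group,
                        cencode = cencode)
  fit <- fit[setdiff(names(fit), "Tests")]
  bind_rows(lapply(names(fit), function(nm) {
    # component names are "<group> <cause>"; group labels may contain spaces
    cause <- sub("^.* ", "", nm)
    grp <- sub(" [^ ]+$", "", nm)
    tibble(group = grp, cause = cause,
           time = fit[[nm]]$time, est = fit[[nm]]$est)
  }))
}

#' Gray's K-sample test for equality of cumulative incidence
#'
#' Compares the cumulative incidence functions of K groups with Gray's
#' (1988) test as implemented in [cmprsk::cuminc()] (`rho = 0`), which
#' for complete single-event data reduces to a weighted comparison of the
#' empirical distributions.  For small samples an optional permutation
#' p-value is available: group labels are permuted and the weight-1
#' K-sample score statistic (the same functional applied to observed and
#' permuted data) is recomputed `permutations` times; the reported
#' `p_permutation` is `(1 + #{perm >= observed}) / (permutations + 1)`.
#' The permutation route requires complete data with a single event type.
#'
#' @param days numeric vector of onset times.
#' @param group group labels (>= 2 non-empty groups required).
#' @param fstatus optional event codes (default: all events of interest).
#' @param cencode censoring code for `fstatus`.
#' @param permutations number of label permutations (0 = asymptotic only).
#' @return list with `statistic`, `df`, `p_value` (asymptotic,
#'   chi-squared with K-1 df) and `p_permutation` (`NA` unless
#'   requested).
#' @examples
#' set.seed(1)
#' grays_test(c(rexp(40, 1), rexp(40, 3)), rep(c("a", "b"), each = 40))
#' @export
grays_test <- function(days, group, fstatus = NULL, cencode = 0,
                       permutations = 0) {
  stopifnot(length(days) == length(group))
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) < 2) {
    stop("Gray's test needs at least two groups to compare", call. = FALSE)
  }
  complete <- is.null(fstatus)
  if (is.null(fstatus)) fstatus <- rep(1L, length(days))

  # degenerate case: score identically zero (e.g. identical groups)
  obs_score <- if (complete) gray_score_stat(days, group) else NA_real_
  k <- length(lev)

  stat <- tryCatch({
    fit <- cmprsk::cuminc(ftime = days, fstatus = fstatus, group = group,
                          cencode = cencode)
    unname(fit$Tests[1, "stat"])
  }, error = function(e) NA_real_)
  if (!is.na(obs_score) && obs_score == 0) stat <- 0
  p <- if (is.na(stat)) NA_real_ else pchisq(stat, df = k - 1, lower.tail = FALSE)

  p_perm <- NA_real_
  if (permutations > 0) {
    if (!complete) {
      stop("permutation p-value is only available for complete, single-event data",
           call. = FALSE)
    }
    perm <- gray_score_perm(days, group, permutations)
    p_perm <- (1 + sum(perm >= obs_score - 1e-12)) / (permutations + 1)
  }
  list(statistic = stat, df = k - 1, p_value = p, p_permutation = p_perm)
}

# Weight-1 K-sample score statistic for complete single-event data:
# at each distinct event time, observed-minus-expected events per group
# with the full not-yet-failed risk set; statistic = sum of squared
# group scores.  Used only as the permutation-resampling functional.
gray_score_stat <- function(days, group) {
  ord <- order(days)
  days <- days[ord]; group <- group[ord]
  blocks <- match(days, unique(days))
  d_b <- tabulate(blocks)
  y_b <- rev(cumsum(rev(d_b)))
  lev <- unique(group)
  u <- vapply(lev, function(g) {
    z <- as.integer(group == g)
    d1 <- as.vector(rowsum(z, blocks))
    y1 <- rev(cumsum(rev(d1)))
    sum(d1 - d_b * y1 / y_b)
  }, numeric(1))
  sum(u^2)
}

# permutation replicates of gray_score_stat, vectorized over permutations
gray_score_perm <- function(days, group, n_perm) {
  ord <- order(days)
  days <- days[ord]; group <- group[ord]
  n <- length(days)
  blocks <- match(days, unique(days))
  d_b <- tabulate(blocks)
  y_b <- rev(cumsum(rev(d_b)))
  lev <- unique(group)
  ind <- vapply(lev, function(g) as.integer(group == g), integer(n))
  rev_cumsum_cols <- function(m) {
    m <- apply(m, 2, function(x) rev(cumsum(rev(x))))
    matrix(m, nrow = length(d_b))
  }
  stat <- numeric(n_perm)
  perm_idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  for (g in seq_along(lev)) {
    z <- matrix(ind[perm_idx, g], nrow = n)
    zb <- rowsum(z, blocks)
    y1 <- rev_cumsum_cols(zb)
    u <- colSums(zb - d_b * y1 / y_b)
    stat <- stat + u^2
  }
  stat
}
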