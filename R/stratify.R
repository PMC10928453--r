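# Outcome-only risk stratification: the two-sample log-rank statistic and
# its maximisation over survival-time cut-offs, yielding the endpoint used
# for supervised classification.

#' Two-sample log-rank test
#'
#' At each distinct event time t_i with d_i events among n_i at risk, of
#' which d1_i / n1_i are in group 1: `E1_i = d_i * n1_i / n_i` and
#' `V_i = d_i * (n1_i/n_i) * (1 - n1_i/n_i) * (n_i - d_i) / (n_i - 1)`
#' (`V_i = 0` when `n_i = 1`). The statistic is
#' `(sum(d1_i - E1_i))^2 / sum(V_i)`, referred to chi-squared with 1 df.
#' Events are processed before censorings at the same time. When the total
#' variance is zero, the statistic is defined as 0 with p = 1.
#'
#' @param times Positive follow-up times (months).
#' @param events Event indicators (1 = death, 0 = censored).
#' @param groups Binary group labels (two non-empty groups; any two levels).
#' @return A list of class `logrank_result`: `statistic`, `p_value`,
#'   `observed_minus_expected` (per-group O-E, group order =
#'   `sort(unique(groups))`), `variance`.
#' @export
logrank <- function(times, events, groups) {
  if (any(times <= 0)) stop("input error: times must be > 0")
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("input error: exactly two non-empty groups required")
  g1 <- groups == lev[1]
  res <- logrank_core(times, events, g1)
  structure(list(statistic = res$statistic,
                 p_value = res$p_value,
                 observed_minus_expected = stats::setNames(c(res$o_minus_e, -res$o_minus_e),
                                                           as.character(lev)),
                 variance = res$variance),
            class = "logrank_result")
}

# Lean numerical core shared with permutation oracles and cut-off searches.
#' @keywords internal
logrank_core <- function(times, events, g1) {
  ev_times <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v_sum <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    e1 <- d * n1 / n
    v <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    o_minus_e <- o_minus_e + (d1 - e1)
    v_sum <- v_sum + v
  }
  if (v_sum > 0) {
    stat <- o_minus_e^2 / v_sum
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- 0; p <- 1
  }
  list(statistic = stat, p_value = p, o_minus_e = o_minus_e, variance = v_sum)
}

#' Stratify a cohort by maximising the log-rank statistic
#'
#' Candidate cut-offs are midpoints between consecutive distinct follow-up
#' times. For each candidate t, patients with an event at or before t form
#' the high-risk group, patients followed beyond t the low-risk group, and
#' patients censored at or before t are excluded (policy `"exclude"`) or
#' counted as low-risk (policy `"low"`). Candidates leaving either group
#' below `min_group_size` are skipped. Returns the candidate with the
#' largest log-rank statistic; ties go to the smaller cut-off.
#'
#' @param cohort Cohort data frame (see [validate_cohort()]).
#' @param min_group_size Minimal patients per group (default 3).
#' @param censored_policy `"exclude"` (default) or `"low"`.
#' @return A list of class `stratification_result`: `cutoff_months`,
#'   `statistic_at_cutoff`, `p_value_at_cutoff`, `assignments` (named vector
#'   patient -> high/low/excluded), `candidate_profile` (data frame of all
#'   admissible candidates and their statistics).
#' @export
stratify_by_outcome <- function(cohort, min_group_size = 3L,
                                censored_policy = c("exclude", "low")) {
  cohort <- validate_cohort(cohort)
  censored_policy <- match.arg(censored_policy)
  if (nrow(cohort) < 2 * min_group_size) {
    stop("stratification error: fewer than 2 * min_group_size patients")
  }
  tt <- sort(unique(cohort$time_months))
  if (length(tt) < 2) stop("stratification error: no candidate cut-offs")
  candidates <- (tt[-1] + tt[-length(tt)]) / 2

  assign_at <- function(t) {
    lab <- rep(NA_character_, nrow(cohort))
    lab[cohort$event == 1 & cohort$time_months <= t] <- "high"
    lab[cohort$time_months > t] <- "low"
    cens_early <- cohort$event == 0 & cohort$time_months <= t
    lab[cens_early] <- if (censored_policy == "low") "low" else "excluded"
    lab
  }

  prof <- data.frame(cutoff = numeric(0), statistic = numeric(0),
                     p_value = numeric(0), n_high = integer(0),
                     n_low = integer(0))
  for (t in candidates) {
    lab <- assign_at(t)
    n_high <- sum(lab == "high"); n_low <- sum(lab == "low")
    if (n_high < min_group_size || n_low < min_group_size) next
    use <- lab %in% c("high", "low")
    r <- logrank_core(cohort$time_months[use], cohort$event[use],
                      lab[use] == "high")
    prof <- rbind(prof, data.frame(cutoff = t, statistic = r$statistic,
                                   p_value = r$p_value, n_high = n_high,
                                   n_low = n_low))
  }
  if (nrow(prof) == 0) stop("stratification error: no admissible candidate cut-off")
  best <- which(prof$statistic == max(prof$statistic))[1] # ties: smaller cut-off
  lab <- assign_at(prof$cutoff[best])
  structure(list(cutoff_months = prof$cutoff[best],
                 statistic_at_cutoff = prof$statistic[best],
                 p_value_at_cutoff = prof$p_value[best],
                 assignments = stats::setNames(lab, cohort$patient_id),
                 candidate_profile = prof),
            class = "stratification_result")
}

#' Label patients against a survival cut-off
#'
#' The classification endpoint: high-risk iff death at or before the cut-off;
#' low-risk iff followed beyond the cut-off; patients censored at or before
#' the cut-off carry no label (excluded from supervised modelling) under the
#' default policy, or are labelled low-risk under policy `"low"`.
#'
#' @param cohort Cohort data frame.
#' @param cutoff_months The survival cut-off.
#' @param censored_policy `"exclude"` (default) or `"low"`.
#' @return Named character vector patient_id -> "high"/"low"/"excluded".
#' @export
label_endpoint <- function(cohort, cutoff_months,
                           censored_policy = c("exclude", "low")) {
  cohort <- validate_cohort(cohort)
  censored_policy <- match.arg(censored_policy)
  lab <- rep(NA_character_, nrow(cohort))
  lab[cohort$event == 1 & cohort$time_months <= cutoff_months] <- "high"
  lab[cohort$time_months > cutoff_months] <- "low"
  cens <- cohort$event == 0 & cohort$time_months <= cutoff_months
  lab[cens] <- if (censored_policy == "low") "low" else "excluded"
  stats::setNames(lab, cohort$patient_id)
}

#' Permutation calibration of the maximally selected log-rank statistic
#'
#' The maximum of the log-rank statistic over candidate cut-offs is
#' anti-conservative when referred to the chi-squared(1) null. This utility
#' estimates, by simulation of exchangeable null cohorts, how often the
#' maximally selected statistic exceeds a chi-squared(1) quantile, so the
#' inflation can be reported alongside stratification results.
#'
#' @param n_patients Cohort size per null replicate.
#' @param n_sim Number of null replicates.
#' @param hazard Common event hazard (events/month).
#' @param censor_max Uniform censoring bound (months).
#' @param min_group_size Passed to [stratify_by_outcome()].
#' @param alpha Nominal level compared against.
#' @param seed RNG seed.
#' @return List with `exceedance` (fraction of replicates with maximal
#'   statistic above the chi-squared quantile), `nominal` (alpha) and the
#'   simulated `statistics`.
#' @export
maxsel_calibration <- function(n_patients = 29L, n_sim = 200L, hazard = 0.05,
                               censor_max = 60, min_group_size = 3L,
                               alpha = 0.05, seed = 1L) {
  set.seed(seed)
  q <- stats::qchisq(1 - alpha, df = 1)
  stats_max <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    e_time <- stats::rexp(n_patients, hazard)
    c_time <- stats::runif(n_patients, 0, censor_max)
    cohort <- data.frame(patient_id = sprintf("N%03d", seq_len(n_patients)),
                         time_months = pmin(e_time, c_time),
                         event = as.integer(e_time <= c_time))
    stats_max[i] <- tryCatch(
      stratify_by_outcome(cohort, min_group_size)$statistic_at_cutoff,
      error = function(e) NA_real_)
  }
  ok <- !is.na(stats_max)
  list(exceedance = mean(stats_max[ok] > q), nominal = alpha,
       statistics = stats_max[ok])
}
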