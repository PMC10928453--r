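# Survival analysis: Kaplan-Meier estimation with exponential Greenwood
# confidence bands, univariate Cox proportional hazards (Breslow ties,
# Newton-Raphson), and the reverse analysis that picks the patient-score
# threshold maximising the log-rank statistic.

#' Kaplan-Meier survival estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`. Censorings at
#' an event time leave the risk set after that time's events (events
#' processed first).
#'
#' @param times Positive follow-up times (months).
#' @param events Event indicators (1 = death, 0 = censored).
#' @return A list of class `km_curve`: `event_times`, `survival`, `at_risk`,
#'   `n_events` (per distinct event time), plus `n` and the inputs.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("input error: empty input")
  if (any(times <= 0)) stop("input error: times must be > 0")
  ev_times <- sort(unique(times[events == 1]))
  at_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(ev_times, function(t) sum(times == t & events == 1),
                     numeric(1))
  survival <- cumprod(1 - n_events / at_risk)
  structure(list(event_times = ev_times, survival = survival,
                 at_risk = at_risk, n_events = n_events,
                 n = length(times), times = times, events = events),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    k <- sum(curve$event_times <= ti)
    if (k == 0) 1 else curve$survival[k]
  }, numeric(1))
}

#' Exponential Greenwood confidence band
#'
#' With cumulative variance term `c(t) = sum d_i / (n_i (n_i - d_i))` over
#' event times up to t and `v(t) = c(t) / log(S(t))^2`, the pointwise band
#' is `S(t)^exp(+/- z * sqrt(v(t)))`, which always lies in \[0, 1\]. Before
#' the first event (`S = 1`) the band is reported as `[1, 1]`; where
#' `S = 0` (or the variance term degenerates) the band is omitted (NA).
#'
#' @param curve A `km_curve`.
#' @param alpha Two-sided level (default 0.05 for 95% bands).
#' @return The curve with `ci_lower` and `ci_upper` added (per event time).
#' @export
greenwood_ci <- function(curve, alpha = 0.05) {
  stopifnot(inherits(curve, "km_curve"))
  if (!(alpha > 0 && alpha < 1)) stop("config error: alpha must lie in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  chat <- cumsum(curve$n_events / (curve$at_risk * (curve$at_risk - curve$n_events)))
  s <- curve$survival
  lower <- upper <- rep(NA_real_, length(s))
  defined <- is.finite(chat) & s > 0 & s < 1
  v <- chat[defined] / log(s[defined])^2
  lower[defined] <- s[defined]^exp(z * sqrt(v))
  upper[defined] <- s[defined]^exp(-z * sqrt(v))
  at_one <- s == 1
  lower[at_one] <- 1; upper[at_one] <- 1
  curve$ci_lower <- lower
  curve$ci_upper <- upper
  curve$alpha <- alpha
  curve
}

#' Univariate Cox proportional hazards fit
#'
#' Maximises the Breslow partial likelihood for a single covariate by
#' Newton-Raphson (convergence when the absolute score falls below 1e-8, cap
#' 100 iterations). The Wald 95% interval is `exp(beta +/- z * SE)`. A
#' monotone likelihood (perfect separation of event order by the covariate)
#' is flagged and beta capped rather than diverging.
#'
#' @param covariate Per-patient numeric covariate (e.g. prediction score).
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @param alpha Level for the Wald interval (default 0.05).
#' @param beta_cap Absolute bound on beta used to detect monotone
#'   likelihoods.
#' @return A list of class `cox_fit`: `beta`, `hazard_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`, `standard_error`, `n_events`, `n_iter`,
#'   `separation` flag.
#' @export
cox_fit <- function(covariate, times, events, alpha = 0.05, beta_cap = 15) {
  if (any(times <= 0)) stop("input error: times must be > 0")
  if (stats::sd(covariate) == 0) stop("input error: constant covariate")
  if (sum(events) < 1) stop("input error: at least one event required")
  x <- as.numeric(covariate)
  ev_times <- sort(unique(times[events == 1]))
  d <- vapply(ev_times, function(t) sum(times == t & events == 1), numeric(1))
  sx <- vapply(ev_times, function(t) sum(x[times == t & events == 1]), numeric(1))
  risk_idx <- lapply(ev_times, function(t) which(times >= t))

  score_info <- function(beta) {
    sc <- 0; info <- 0
    for (j in seq_along(ev_times)) {
      xr <- x[risk_idx[[j]]]
      w <- exp(beta * xr)
      sw <- sum(w)
      m1 <- sum(w * xr) / sw
      m2 <- sum(w * xr^2) / sw
      sc <- sc + (sx[j] - d[j] * m1)
      info <- info + d[j] * (m2 - m1^2)
    }
    c(score = sc, info = info)
  }

  beta <- 0; separation <- FALSE; iter <- 0L
  for (iter in seq_len(100L)) {
    si <- score_info(beta)
    if (abs(si["score"]) < 1e-8) break
    if (si["info"] <= 0) { separation <- TRUE; break }
    beta <- beta + si["score"] / si["info"]
    if (abs(beta) > beta_cap) {
      beta <- sign(beta) * beta_cap
      separation <- TRUE
      warning("monotone partial likelihood: beta capped, estimates unreliable")
      break
    }
  }
  si <- score_info(beta)
  se <- if (si["info"] > 0) 1 / sqrt(si["info"]) else NA_real_
  z <- stats::qnorm(1 - alpha / 2)
  wald <- if (is.na(se)) NA_real_ else beta / se
  structure(list(beta = unname(beta), hazard_ratio = exp(unname(beta)),
                 ci_lower = exp(unname(beta - z * se)),
                 ci_upper = exp(unname(beta + z * se)),
                 p_value = if (is.na(wald)) NA_real_ else
                   2 * stats::pnorm(-abs(wald)),
                 standard_error = unname(se),
                 n_events = sum(events), n_iter = iter,
                 separation = separation),
            class = "cox_fit")
}

# Breslow log partial likelihood, exposed internally for grid-search oracles.
#' @keywords internal
cox_partial_loglik <- function(beta, covariate, times, events) {
  x <- as.numeric(covariate)
  ev_times <- sort(unique(times[events == 1]))
  ll <- 0
  for (t in ev_times) {
    ev <- times == t & events == 1
    at_risk <- times >= t
    ll <- ll + beta * sum(x[ev]) - sum(ev) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

#' Reverse analysis: score threshold maximising the log-rank statistic
#'
#' Candidate thresholds are midpoints between consecutive distinct patient
#' scores; patients with scores at or above a candidate form the high-risk
#' group. The candidate with the largest log-rank statistic is returned
#' (ties to the smaller threshold) along with Kaplan-Meier curves and
#' exponential Greenwood bands for both groups.
#'
#' @param scores Named vector patient_id -> prediction score.
#' @param cohort Cohort data frame covering the scored patients.
#' @param min_group_size Minimal patients per group (default 3).
#' @param alpha Level for the KM bands.
#' @return A list of class `reverse_analysis_result`: `threshold`, `groups`
#'   (named vector high/low), `logrank` (a `logrank_result`), `km_high`,
#'   `km_low`, `candidate_profile`.
#' @export
reverse_analysis <- function(scores, cohort, min_group_size = 3L,
                             alpha = 0.05) {
  cohort <- validate_cohort(cohort)
  common <- intersect(names(scores), cohort$patient_id)
  if (length(common) < 2 * min_group_size) {
    stop("input error: fewer than 2 * min_group_size scored patients")
  }
  s <- scores[common]
  cc <- cohort[match(common, cohort$patient_id), ]
  su <- sort(unique(s))
  if (length(su) < 2) stop("degenerate-input error: all scores equal")
  candidates <- (su[-1] + su[-length(su)]) / 2

  prof <- data.frame(threshold = numeric(0), statistic = numeric(0),
                     p_value = numeric(0))
  for (thr in candidates) {
    high <- s >= thr
    if (sum(high) < min_group_size || sum(!high) < min_group_size) next
    r <- logrank_core(cc$time_months, cc$event, high)
    prof <- rbind(prof, data.frame(threshold = thr, statistic = r$statistic,
                                   p_value = r$p_value))
  }
  if (nrow(prof) == 0) {
    stop("degenerate-input error: no candidate satisfies min_group_size")
  }
  best <- which(prof$statistic == max(prof$statistic))[1]
  thr <- prof$threshold[best]
  high <- s >= thr
  lr <- logrank(cc$time_months, cc$event, ifelse(high, "high", "low"))
  km_high <- greenwood_ci(km_estimate(cc$time_months[high], cc$event[high]),
                          alpha)
  km_low <- greenwood_ci(km_estimate(cc$time_months[!high], cc$event[!high]),
                         alpha)
  structure(list(threshold = thr,
                 groups = stats::setNames(ifelse(high, "high", "low"), common),
                 logrank = lr, km_high = km_high, km_low = km_low,
                 candidate_profile = prof),
            class = "reverse_analysis_result")
}

#' Write a Kaplan-Meier curve as TSV
#'
#' Columns: time, survival, ci_lower, ci_upper, at_risk, n_events.
#'
#' @param curve A `km_curve` (ideally with bands from [greenwood_ci()]).
#' @param path Output path.
#' @export
write_km_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  df <- data.frame(time = curve$event_times, survival = curve$survival,
                   ci_lower = curve$ci_lower %||% NA,
                   ci_upper = curve$ci_upper %||% NA,
                   at_risk = curve$at_risk, n_events = curve$n_events)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
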