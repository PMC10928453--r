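# Shared fixtures, built in code at test time.

# Small, fast simulation: outcome structure identical to the defaults
# (cohort draws precede pixel draws), only the image is smaller.
small_sim <- function(seed = 1, n_patients = 8, core_size = 8, ...) {
  simulate_cohort(sim_config(n_patients = n_patients, core_size = core_size,
                             seed = seed, ...))
}

# Hand-specifiable cohort table.
make_cohort <- function(times, events, ids = sprintf("P%02d", seq_along(times))) {
  data.frame(patient_id = ids, time_months = times, event = events,
             stringsAsFactors = FALSE)
}

# Random small survival cohort for permutation-based checks.
random_cohort <- function(n, seed, hazard = 0.1, censor_max = 30) {
  set.seed(seed)
  e <- stats::rexp(n, hazard)
  c0 <- stats::runif(n, 0, censor_max)
  make_cohort(pmin(e, c0), as.integer(e <= c0))
}

# Permutation oracle for the log-rank p-value: distribution of the statistic
# under random relabelling of the group memberships.
permutation_logrank_p <- function(times, events, groups, n_perm = 10000,
                                  seed = 1) {
  obs <- logrank(times, events, groups)$statistic
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- sample(groups)
    if (logrank(times, events, g)$statistic >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# All-pairs AUROC oracle.
pairs_auroc <- function(scores, labels) {
  pos <- which(labels == 1 | labels == "high")
  neg <- setdiff(seq_along(scores), pos)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}
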