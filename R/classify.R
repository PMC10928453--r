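# Datapoint-level classification: PCA to a small number of components,
# ridge-stabilised logistic regression, median-probability patient scores,
# and patient-level bootstrap out-of-bag evaluation of AUROC, sensitivity
# and specificity.

#' Fit a principal-component model
#'
#' Components are the top-k right singular vectors of the mean-centred data
#' matrix (equivalently, leading eigenvectors of the sample covariance).
#' Loading signs are fixed so the element of largest magnitude is positive,
#' making fits deterministic.
#'
#' @param x Numeric matrix, datapoints in rows.
#' @param k Number of components (default 7).
#' @return A list of class `pca_model`: `mean_spectrum`, `components`
#'   (k x ncol loadings, orthonormal rows), `explained_variance`
#'   (non-increasing).
#' @export
pca_fit <- function(x, k = 7L) {
  x <- as.matrix(x)
  if (nrow(x) < k || ncol(x) < k) {
    stop(sprintf("input error: k = %d exceeds achievable rank %d",
                 k, min(nrow(x), ncol(x))))
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (nrow(x) > ncol(x)) { # eigendecomposition of the small covariance
    ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
    rank <- sum(ev$values > max(ev$values, 0) * 1e-12)
    if (k > rank) stop(sprintf("input error: k = %d exceeds achievable rank %d", k, rank))
    comp <- t(ev$vectors[, seq_len(k), drop = FALSE])
    varexp <- ev$values[seq_len(k)]
  } else {
    sv <- svd(xc, nu = 0, nv = min(dim(xc)))
    rank <- sum(sv$d > max(sv$d) * 1e-12)
    if (k > rank) stop(sprintf("input error: k = %d exceeds achievable rank %d", k, rank))
    comp <- t(sv$v[, seq_len(k), drop = FALSE])
    varexp <- sv$d[seq_len(k)]^2 / (nrow(x) - 1)
  }
  flip <- apply(comp, 1, function(v) sign(v[which.max(abs(v))]))
  comp <- comp * flip
  structure(list(mean_spectrum = mu, components = comp,
                 explained_variance = varexp),
            class = "pca_model")
}

#' Project data onto a principal-component model
#'
#' @param model A `pca_model`.
#' @param x Matrix with the same columns as the training data.
#' @return Score matrix (rows x k).
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  sweep(as.matrix(x), 2, model$mean_spectrum) %*% t(model$components)
}

#' Fit a ridge-penalised logistic regression
#'
#' Maximises the penalised log-likelihood
#' `sum(y*log(p) + (1-y)*log(1-p)) - ridge_penalty/2 * ||w||^2` (intercept
#' unpenalised) by Newton iteration with step halving. Convergence is
#' declared when the largest absolute component of the penalised gradient
#' falls below `1e-8`. A small default penalty keeps fits finite on
#' separable data.
#'
#' @param scores Feature matrix (e.g. component scores).
#' @param labels Binary vector (0/1 or logical); both classes required.
#' @param ridge_penalty Ridge strength (default 1e-4).
#' @param max_iter Iteration cap (default 200).
#' @return A list of class `logistic_model`: `intercept`, `weights`,
#'   `ridge_penalty`, `n_iter`, `max_gradient`.
#' @export
logistic_fit <- function(scores, labels, ridge_penalty = 1e-4,
                         max_iter = 200L) {
  x <- as.matrix(scores)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("input error: both classes must be present")
  n <- nrow(x); p <- ncol(x)
  X <- cbind(1, x)
  pen <- c(0, rep(ridge_penalty, p)) # intercept unpenalised
  beta <- numeric(p + 1)
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2
  }
  f <- obj(beta)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    prob <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - prob)) - pen * beta
    if (max(abs(grad)) < 1e-8) {
      return(structure(list(intercept = beta[1], weights = beta[-1],
                            ridge_penalty = ridge_penalty, n_iter = iter - 1L,
                            max_gradient = max(abs(grad))),
                       class = "logistic_model"))
    }
    w <- pmax(prob * (1 - prob), 1e-10)
    H <- crossprod(X, X * w) + diag(pen, p + 1)
    step <- solve(H, grad)
    # step halving on the penalised objective
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      fc <- obj(cand)
      if (is.finite(fc) && fc >= f - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    beta <- beta + lambda * step
    f <- obj(beta)
  }
  grad <- drop(crossprod(X, y - stats::plogis(drop(X %*% beta)))) - pen * beta
  if (max(abs(grad)) < 1e-8) {
    return(structure(list(intercept = beta[1], weights = beta[-1],
                          ridge_penalty = ridge_penalty, n_iter = max_iter,
                          max_gradient = max(abs(grad))),
                     class = "logistic_model"))
  }
  stop(sprintf(paste0("convergence error: penalised gradient %.3e after %d ",
                      "iterations (objective %.6g)"),
               max(abs(grad)), max_iter, f))
}

#' Predicted probabilities from a logistic model
#'
#' @param model A `logistic_model`.
#' @param scores Feature matrix.
#' @return Probabilities in (0, 1).
#' @export
predict_prob <- function(model, scores) {
  stopifnot(inherits(model, "logistic_model"))
  stats::plogis(drop(as.matrix(scores) %*% model$weights) + model$intercept)
}

#' Patient prediction scores
#'
#' The patient prediction score is the median of that patient's datapoint
#' probabilities; even counts use the midpoint of the two central values.
#'
#' @param probabilities Per-datapoint probabilities.
#' @param patient_ids Patient identifier per datapoint.
#' @return Named numeric vector, one score per patient with at least one
#'   datapoint.
#' @export
patient_scores <- function(probabilities, patient_ids) {
  if (length(probabilities) != length(patient_ids)) {
    stop("input error: one patient id per probability required")
  }
  vapply(split(probabilities, factor(patient_ids, levels = unique(patient_ids))),
         stats::median, numeric(1))
}

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney pair count: concordant pairs plus half the
#' tied pairs, over positives x negatives. Positives are the high-risk class.
#'
#' @param scores Numeric scores, larger = more likely high-risk.
#' @param labels Binary labels (1/"high" = positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  pos <- labels_to_binary(labels)
  if (!any(pos) || all(pos)) stop("undefined-metric error: one class absent")
  r <- rank(scores) # mean ranks give tied pairs half credit
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Sensitivity and specificity at a threshold
#'
#' A patient is called high-risk when its score is at or above the
#' threshold. Sensitivity is the true-positive rate among high-risk
#' patients; specificity the true-negative rate among low-risk patients.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/"high" = positive).
#' @param threshold Operating point (default 0.5).
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(scores, labels, threshold = 0.5) {
  pos <- labels_to_binary(labels)
  if (!any(pos) || all(pos)) stop("undefined-metric error: one class absent")
  call_pos <- scores >= threshold
  c(sensitivity = mean(call_pos[pos]), specificity = mean(!call_pos[!pos]))
}

#' @keywords internal
labels_to_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels)) as.character(labels) == "high"
  else as.numeric(labels) == 1
}

#' Patient-level bootstrap out-of-bag evaluation
#'
#' Each replicate resamples labelled patients with replacement; the in-bag
#' datapoints (with multiplicity) fit the PCA and the logistic model, and
#' out-of-bag patients are scored by the median of their datapoint
#' probabilities. AUROC, sensitivity and specificity are computed on the
#' out-of-bag patient scores; replicates whose in-bag or out-of-bag set
#' contains a single class are discarded and redrawn. PCA is refit inside every
#' replicate so out-of-bag estimates stay honest. A final model fit on all
#' labelled datapoints produces the patient prediction scores for every
#' patient in the dataset (including unlabelled ones).
#'
#' @param dataset A `spectral_dataset`.
#' @param labels Named vector patient_id -> "high"/"low" (or 1/0); patients
#'   labelled "excluded"/NA take no part in fitting or evaluation.
#' @param B Number of bootstrap replicates (>= 10; default 500).
#' @param seed RNG seed.
#' @param k Number of principal components (default 7).
#' @param ridge_penalty Logistic ridge strength (default 1e-4).
#' @param threshold Operating point for sensitivity/specificity.
#' @param max_redraws Cap on redraws of single-class out-of-bag sets.
#' @param keep_draws If TRUE, store each replicate's in-bag and out-of-bag
#'   patient sets (for leakage auditing) under `draws`.
#' @return A list of class `bootstrap_summary`: `per_replicate` (data frame
#'   auroc/sensitivity/specificity), `median_auroc`, `median_sensitivity`,
#'   `median_specificity`, `dispersion` (half-interquartile range per
#'   metric), `n_replicates`, `seed`, `patient_scores` (full-data model),
#'   `model` (the full-data `logistic_model`) and `pca` (full-data
#'   `pca_model`).
#' @export
bootstrap_evaluate <- function(dataset, labels, B = 500L, seed = 1L, k = 7L,
                               ridge_penalty = 1e-4, threshold = 0.5,
                               max_redraws = 50L, keep_draws = FALSE) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (B < 10) stop("config error: B must be >= 10")
  lab <- labels[!is.na(labels) & labels != "excluded"]
  pos <- labels_to_binary(lab)
  ids <- names(lab)
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("input error: at least 2 patients per class required")
  }
  pid <- dataset$meta$patient_id
  row_of <- split(seq_len(nrow(dataset$matrix)), pid)

  set.seed(seed)
  per <- matrix(NA_real_, nrow = B, ncol = 3,
                dimnames = list(NULL, c("auroc", "sensitivity", "specificity")))
  draws <- if (keep_draws) vector("list", B) else NULL
  for (b in seq_len(B)) {
    for (attempt in seq_len(max_redraws)) {
      bag <- sample(ids, length(ids), replace = TRUE)
      oob <- setdiff(ids, bag)
      if (length(unique(labels_to_binary(lab[oob]))) == 2 &&
          length(unique(labels_to_binary(lab[bag]))) == 2) break
      if (attempt == max_redraws) {
        stop("input error: could not draw a two-class out-of-bag set")
      }
    }
    in_rows <- unlist(row_of[bag], use.names = FALSE) # multiplicity kept
    if (keep_draws) {
      draws[[b]] <- list(bag = bag, oob = oob, in_rows = in_rows,
                         oob_rows = unlist(row_of[oob], use.names = FALSE))
    }
    x_in <- dataset$matrix[in_rows, , drop = FALSE]
    y_in <- rep(labels_to_binary(lab[bag]),
                vapply(row_of[bag], length, integer(1)))
    pca <- pca_fit(x_in, k = k)
    model <- logistic_fit(pca_transform(pca, x_in), y_in,
                          ridge_penalty = ridge_penalty)
    oob_rows <- unlist(row_of[oob], use.names = FALSE)
    prob <- predict_prob(model, pca_transform(pca, dataset$matrix[oob_rows, , drop = FALSE]))
    sc <- patient_scores(prob, pid[oob_rows])
    y_oob <- lab[names(sc)]
    per[b, "auroc"] <- auroc(sc, y_oob)
    per[b, c("sensitivity", "specificity")] <- sens_spec(sc, y_oob, threshold)
  }

  lab_rows <- unlist(row_of[ids], use.names = FALSE)
  pca_full <- pca_fit(dataset$matrix[lab_rows, , drop = FALSE], k = k)
  model_full <- logistic_fit(pca_transform(pca_full,
                                           dataset$matrix[lab_rows, , drop = FALSE]),
                             rep(pos, vapply(row_of[ids], length, integer(1))),
                             ridge_penalty = ridge_penalty)
  prob_all <- predict_prob(model_full, pca_transform(pca_full, dataset$matrix))
  scores_all <- patient_scores(prob_all, pid)

  per_df <- as.data.frame(per)
  half_iqr <- function(v) diff(stats::quantile(v, c(0.25, 0.75), names = FALSE)) / 2
  structure(list(per_replicate = per_df,
                 median_auroc = stats::median(per_df$auroc),
                 median_sensitivity = stats::median(per_df$sensitivity),
                 median_specificity = stats::median(per_df$specificity),
                 dispersion = vapply(per_df, half_iqr, numeric(1)),
                 n_replicates = B, seed = seed,
                 patient_scores = scores_all,
                 model = model_full, pca = pca_full,
                 draws = draws),
            class = "bootstrap_summary")
}
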