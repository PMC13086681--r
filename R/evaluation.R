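# Score evaluation machinery: discrimination (Mann-Whitney AUC with
# bootstrap confidence intervals, paired permutation comparison of two
# scores) and calibration (decile reliability bins, Brier score and Brier
# skill score against the climatology forecast).

#' Mann-Whitney AUC
#'
#' Concordance of a score against a binary outcome: the probability that a
#' random event patient scores above a random non-event patient, ties
#' counted one half (midrank formula).
#'
#' @param scores Numeric vector.
#' @param events Binary vector (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, events) {
  events <- as.integer(events != 0)
  n1 <- sum(events == 1)
  n0 <- sum(events == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[events == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with bootstrap confidence interval
#'
#' Percentile bootstrap over patients, stratified by event status so every
#' resample keeps both classes, reproducible under `seed`.
#'
#' @inheritParams auc
#' @param resamples Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `lo`, `hi`, `resamples`.
#' @export
auc_ci <- function(scores, events, resamples = 2000, seed = 1L,
                   conf = 0.95) {
  events <- as.integer(events != 0)
  point <- auc(scores, events)
  i1 <- which(events == 1)
  i0 <- which(events == 0)
  boot <- with_seed(seed, vapply(seq_len(resamples), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    auc(scores[idx], events[idx])
  }, 0))
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(auc = point, lo = qs[1], hi = qs[2], resamples = resamples)
}

#' Paired permutation comparison of two scores
#'
#' Tests the AUC difference between two scores computed on the same
#' patients. The observed statistic is `auc(A) - auc(B)`; the null is
#' generated by swapping the (A, B) score pair within each patient with
#' probability one half (a paired sign-flip permutation), and the
#' two-sided p-value is the tail proportion with add-one smoothing,
#' `(r + 1) / (B + 1)`.
#'
#' @param scores_a,scores_b Paired numeric vectors.
#' @inheritParams auc
#' @param resamples Permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed` (AUC difference), `auc_a`,
#'   `auc_b`, `resamples`.
#' @export
compare_scores <- function(scores_a, scores_b, events, resamples = 1e4,
                           seed = 1L) {
  if (length(scores_a) != length(scores_b))
    stopf("paired scores differ in length")
  events <- as.integer(events != 0)
  obs <- auc(scores_a, events) - auc(scores_b, events)
  n <- length(scores_a)
  exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(resamples)) {
      swap <- runif(n) < 0.5
      a2 <- ifelse(swap, scores_b, scores_a)
      b2 <- ifelse(swap, scores_a, scores_b)
      d <- auc(a2, events) - auc(b2, events)
      if (abs(d) >= abs(obs) - 1e-12) count <- count + 1L
    }
    count
  })
  list(p_value = (exceed + 1) / (resamples + 1), observed = obs,
       auc_a = auc(scores_a, events), auc_b = auc(scores_b, events),
       resamples = resamples)
}

#' Event probability from a fitted score
#'
#' Maps the linear score to an absolute event probability by the horizon:
#' `P = 1 - exp(-H0(horizon) * exp(score))`, with `H0` the Breslow
#' baseline cumulative hazard of the fitting cohort (stored by
#' [fit_cox()]). A patient at the training means (score 0) gets the
#' baseline probability.
#'
#' @param model A [score_model()] with a `baseline` component.
#' @param newdata `data.frame` covering the model variables.
#' @param horizon_days Horizon (default 365).
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
risk_probability <- function(model, newdata, horizon_days = 365) {
  stopifnot(inherits(model, "score_model"))
  if (is.null(model$baseline))
    stopf("model has no baseline hazard: refit with fit_cox() on a cohort")
  sc <- compute_score(model, newdata)
  bl <- model$baseline
  h0 <- if (horizon_days < min(bl$time)) 0 else
    approx(bl$time, bl$hazard, xout = horizon_days, method = "constant",
           f = 0, rule = 2)$y
  1 - exp(-h0 * exp(sc))
}

#' Calibration bins, Brier score and Brier skill score
#'
#' Groups predicted probabilities into quantile (equal-count) bins,
#' merging tied break points, and reports per-bin mean predicted
#' probability, observed event rate and count. Brier is the mean squared
#' forecast error; the skill score is `1 - Brier / Brier_ref` with the
#' reference being the constant climatology forecast at the observed
#' event rate.
#'
#' @param prob Predicted probabilities in `[0, 1]`.
#' @param events Binary outcomes, both classes present.
#' @param bins Target number of quantile bins (default 10).
#' @return List with `bins` (`data.frame`: `mean_predicted`,
#'   `observed_rate`, `count`), `brier`, `brier_ref`, `brier_skill`, `n`,
#'   `events`.
#' @export
calibration <- function(prob, events, bins = 10) {
  if (any(prob < 0 | prob > 1)) stopf("probabilities must lie in [0, 1]")
  events <- as.integer(events != 0)
  if (length(unique(events)) < 2)
    stopf("both classes must be present for the skill score")
  breaks <- unique(quantile(prob, probs = seq(0, 1, length.out = bins + 1)))
  if (length(breaks) < 3) {
    # near-constant forecasts (e.g. the climatology reference) collapse to
    # one bin; the Brier decomposition is still well defined
    warnf("probabilities collapse to a single bin")
    grp <- factor(rep("all", length(prob)))
  } else grp <- cut(prob, breaks = breaks, include.lowest = TRUE)
  tab <- data.frame(
    mean_predicted = as.numeric(tapply(prob, grp, mean)),
    observed_rate = as.numeric(tapply(events, grp, mean)),
    count = as.integer(table(grp)))
  rate <- mean(events)
  brier <- mean((prob - events)^2)
  brier_ref <- mean((rate - events)^2)
  list(bins = tab, brier = brier, brier_ref = brier_ref,
       brier_skill = 1 - brier / brier_ref, n = length(prob),
       events = sum(events))
}

#' Evaluate and compare risk scores on a cohort
#'
#' Assembles the full evaluation report for one or more score vectors
#' against a one-year event indicator: per-score AUC with bootstrap 95%
#' CI, pairwise permutation p-values, and (for score vectors that are
#' probabilities) calibration with Brier skill score.
#'
#' @param scores Named list of numeric score vectors (same patients).
#' @param events Binary outcome vector.
#' @param probabilities Optional named list of probability vectors for
#'   calibration (names may be a subset of `scores`).
#' @param resamples Resamples for both the bootstrap CI and the
#'   permutation test.
#' @param seed Integer seed.
#' @return List of class `evaluation_report`: `auc` (per score),
#'   `comparisons` (`data.frame`), `calibration` (per probability set),
#'   `n`, `events`, `seed`.
#' @export
evaluate_scores <- function(scores, events, probabilities = NULL,
                            resamples = 2000, seed = 1L) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  aucs <- lapply(seq_along(scores), function(i)
    auc_ci(scores[[i]], events, resamples, seed + i))
  names(aucs) <- names(scores)
  comparisons <- NULL
  nms <- names(scores)
  if (length(scores) >= 2) {
    cmp <- list()
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      r <- compare_scores(scores[[i]], scores[[j]], events, resamples,
                          seed + 100 + i * 37 + j)
      cmp[[length(cmp) + 1]] <- data.frame(
        score_a = nms[i], score_b = nms[j], auc_a = r$auc_a,
        auc_b = r$auc_b, p_value = r$p_value)
    }
    comparisons <- do.call(rbind, cmp)
  }
  cal <- if (!is.null(probabilities))
    lapply(probabilities, calibration, events = events)
  structure(list(auc = aucs, comparisons = comparisons, calibration = cal,
                 n = length(events), events = sum(events != 0),
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, events = %d\n", x$n, x$events))
  for (nm in names(x$auc))
    cat(sprintf("  %-12s AUC %.3f [%.3f, %.3f]\n", nm, x$auc[[nm]]$auc,
                x$auc[[nm]]$lo, x$auc[[nm]]$hi))
  if (!is.null(x$comparisons))
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("  %s vs %s: p = %.4f\n", x$comparisons$score_a[i],
                  x$comparisons$score_b[i], x$comparisons$p_value[i]))
  invisible(x)
}
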