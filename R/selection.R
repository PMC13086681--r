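# Three-step biomarker selection: (1) univariate Cox screen with a
# likelihood-ratio test at p <= 0.2; (2) pruning of candidates correlated
# above 0.85 (Spearman / tetrachoric / polychoric, by variable kind) with a
# better-p competitor; (3) exhaustive subset search by 4-fold
# cross-validated one-year AUC, then a final full-training fit.

#' Classify a variable for correlation dispatch
#'
#' @param x Numeric vector.
#' @return `"binary"` (two distinct values), `"ordinal"` (integer-valued
#'   with at most 6 distinct values), else `"continuous"`.
#' @export
variable_kind <- function(x) {
  u <- unique(x[!is.na(x)])
  if (length(u) <= 2) return("binary")
  if (all(u == round(u)) && length(u) <= 6) return("ordinal")
  "continuous"
}

#' Univariate Cox screen with likelihood-ratio test
#'
#' Fits a one-variable Cox model per candidate; the LRT statistic
#' `2 * (ll_model - ll_null)` is referred to a chi-square with 1 df.
#' Candidates with p > `alpha` (default 0.2, a deliberately permissive
#' threshold that tolerates confounded effects) are marked eliminated;
#' constant candidates are excluded with a reason.
#'
#' @param cohort `data.frame` with candidates plus time/event columns.
#' @param candidates Character vector of candidate variables.
#' @param time,event Column names.
#' @param alpha Retention threshold on the LRT p-value (boundary kept).
#' @return `data.frame` with `variable`, `kind`, `beta`, `hazard_ratio`,
#'   `lrt_statistic`, `p_value`, `retained`, `reason`.
#' @export
univariate_screen <- function(cohort, candidates, time = "followup_days",
                              event = "event", alpha = 0.2) {
  if (sum(cohort[[event]]) < 2) stopf("need at least 2 events")
  rows <- lapply(candidates, function(v) {
    if (var(cohort[[v]]) == 0)
      return(data.frame(variable = v, kind = variable_kind(cohort[[v]]),
                        beta = NA_real_, hazard_ratio = NA_real_,
                        lrt_statistic = NA_real_, p_value = NA_real_,
                        retained = FALSE, reason = "constant"))
    fit <- survival::coxph(
      survival::Surv(cohort[[time]], cohort[[event]]) ~ cohort[[v]],
      ties = "efron")
    lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
    p <- pchisq(lrt, df = 1, lower.tail = FALSE)
    data.frame(variable = v, kind = variable_kind(cohort[[v]]),
               beta = unname(coef(fit)), hazard_ratio = unname(exp(coef(fit))),
               lrt_statistic = lrt, p_value = p,
               retained = p <= alpha,
               reason = if (p <= alpha) "" else sprintf("p > %.2g", alpha))
  })
  do.call(rbind, rows)
}

# --- latent-normal correlations --------------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch, cached.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n = 64) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  ord <- order(nodes)
  .gl_cache[[key]] <- list(x = nodes[ord], w = weights[ord])
  .gl_cache[[key]]
}

# Bivariate standard-normal CDF P(X <= a, Y <= b) with correlation rho, by
# Gauss-Legendre quadrature of pnorm along the conditional distribution.
pbivnorm <- function(a, b, rho) {
  if (is.infinite(a) && a < 0) return(0)
  if (is.infinite(b) && b < 0) return(0)
  if (is.infinite(a)) return(pnorm(b))
  if (is.infinite(b)) return(pnorm(a))
  rho <- max(min(rho, 0.99999), -0.99999)
  s <- sqrt(1 - rho^2)
  lo <- -8.5
  gl <- gauss_legendre(64)
  x <- (a - lo) / 2 * gl$x + (a + lo) / 2
  val <- (a - lo) / 2 * sum(gl$w * dnorm(x) * pnorm((b - rho * x) / s))
  min(max(val, 0), 1)
}

# ML polychoric/tetrachoric correlation, two-step: thresholds from the
# marginals, then 1D likelihood maximization over rho.
latent_corr <- function(x, y, clamp = 0.999) {
  tab <- table(factor(x), factor(y))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stopf("latent correlation needs at least 2 levels per variable")
  n <- sum(tab)
  a <- qnorm(cumsum(rowSums(tab)) / n)[-nrow(tab)]
  b <- qnorm(cumsum(colSums(tab)) / n)[-ncol(tab)]
  a_full <- c(-Inf, a, Inf)
  b_full <- c(-Inf, b, Inf)
  negll <- function(rho) {
    G <- outer(seq_along(a_full), seq_along(b_full),
               Vectorize(function(i, j) pbivnorm(a_full[i], b_full[j], rho)))
    ll <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] == 0) next
      p <- G[i + 1, j + 1] - G[i, j + 1] - G[i + 1, j] + G[i, j]
      ll <- ll + tab[i, j] * log(max(p, 1e-12))
    }
    -ll
  }
  opt <- optimize(negll, interval = c(-clamp, clamp), tol = 1e-6)
  rho <- opt$minimum
  boundary <- abs(rho) > clamp - 1e-3
  if (boundary && any(tab == 0))
    warnf("empty contingency cell: latent correlation clamped to %.3f",
          sign(rho) * clamp)
  rho
}

#' Mixed-type correlation with method dispatch
#'
#' Correlation between two variables using the estimator appropriate to
#' their kinds: tetrachoric (latent bivariate-normal ML on the 2x2 table)
#' for binary x binary, polychoric (ML with marginal thresholds) when both
#' are ordinal or ordinal x binary, Spearman rank correlation whenever a
#' continuous variable is involved.
#'
#' @param x,y Numeric vectors (n >= 10 pairs).
#' @param kinds Optional character pair overriding [variable_kind()].
#' @return List with `coefficient` (in `[-1, 1]`) and `method`.
#' @export
mixed_correlation <- function(x, y, kinds = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stopf("need at least 10 paired observations")
  if (is.null(kinds)) kinds <- c(variable_kind(x), variable_kind(y))
  method <- if (all(kinds == "binary")) "tetrachoric"
  else if (!"continuous" %in% kinds) "polychoric"
  else "spearman"
  coefficient <- if (method == "spearman")
    cor(x, y, method = "spearman")
  else latent_corr(x, y)
  list(coefficient = coefficient, method = method)
}

#' Pairwise mixed-type correlation matrix
#'
#' @param cohort `data.frame`.
#' @param vars Variables to correlate.
#' @return Symmetric correlation matrix with unit diagonal; the estimator
#'   used for each pair is attached as the `"methods"` attribute.
#' @export
correlation_matrix <- function(cohort, vars) {
  k <- length(vars)
  kinds <- vapply(vars, function(v) variable_kind(cohort[[v]]), "")
  m <- diag(1, k)
  meth <- matrix("", k, k, dimnames = list(vars, vars))
  dimnames(m) <- list(vars, vars)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- mixed_correlation(cohort[[vars[i]]], cohort[[vars[j]]],
                           kinds = c(kinds[i], kinds[j]))
    m[i, j] <- m[j, i] <- r$coefficient
    meth[i, j] <- meth[j, i] <- r$method
  }
  attr(m, "methods") <- meth
  m
}

#' Prune correlated candidates
#'
#' Drops every candidate whose absolute correlation with a protected (core
#' score) variable, or with another candidate achieving a strictly better
#' univariate p-value, exceeds the threshold. Protected variables are
#' never dropped (the original score's variable set is kept intact even
#' where internally correlated, e.g. PAPs and its availability flag). Ties
#' in p-value are broken lexically (the earlier name wins).
#'
#' @param screen Output of [univariate_screen()] (retained rows are the
#'   candidates).
#' @param corr Correlation matrix over candidates and protected variables,
#'   e.g. from [correlation_matrix()].
#' @param threshold Absolute-correlation threshold (default 0.85; strictly
#'   greater drops).
#' @param protected Character vector of never-dropped variables.
#' @return List with `kept`, `dropped`, and `pairs` (a `data.frame` of the
#'   offending pairs with the drop reason).
#' @export
prune_correlated <- function(screen, corr, threshold = 0.85,
                             protected = character()) {
  cand <- screen$variable[screen$retained]
  pv <- setNames(screen$p_value, screen$variable)
  pairs <- list()
  dropped <- character()
  for (v in sort(cand)) {
    others <- setdiff(union(cand, protected), v)
    others <- intersect(others, rownames(corr))
    if (!v %in% rownames(corr)) next
    for (o in sort(others)) {
      r <- corr[v, o]
      if (is.na(r) || abs(r) <= threshold) next
      better <- if (o %in% protected) TRUE
      else if (pv[o] < pv[v]) TRUE
      else if (pv[o] == pv[v]) o < v
      else FALSE
      if (better) {
        dropped <- union(dropped, v)
        pairs[[length(pairs) + 1]] <- data.frame(
          dropped = v, kept = o, correlation = r,
          reason = if (o %in% protected) "correlated with protected variable"
          else "competitor has better univariate p")
        break
      }
    }
  }
  list(kept = setdiff(cand, dropped), dropped = dropped,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(dropped = character(), kept = character(),
                    correlation = numeric(), reason = character()))
}

# stratified fold assignment: events and non-events spread evenly
stratified_folds <- function(event, folds, seed) {
  with_seed(seed, {
    f <- integer(length(event))
    for (g in unique(event)) {
      idx <- sample(which(event == g))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
}

# fast Cox fit on a bare design matrix (same engine as fit_cox)
cox_coef_fast <- function(x, y, ties = "efron") {
  fit <- survival::coxph.fit(x, y, strata = NULL, offset = NULL,
                             init = NULL,
                             control = survival::coxph.control(iter.max = 25),
                             weights = NULL, method = ties,
                             rownames = NULL)
  fit$coefficients
}

#' Exhaustive cross-validated subset search
#'
#' Evaluates every subset of the candidate biomarkers (including the empty
#' set): for each subset the augmented score (core variables plus subset)
#' is fitted by Cox regression on each fold's training 75% and its AUC for
#' the one-year event indicator is computed on the held-out 25%; the
#' subset with the best mean AUC over the folds wins. Folds are stratified
#' by event status. Ties in mean AUC are broken toward the smaller subset,
#' then lexically. Patients censored before the horizon are excluded from
#' fold AUCs with a warning.
#'
#' @param cohort Training `data.frame`.
#' @param base_vars Core score variables always included.
#' @param candidates Candidate biomarkers (at most 20; the search is
#'   exhaustive in `2^k`).
#' @param folds Number of folds (default 4: 75% train / 25% test).
#' @param seed Integer seed for the fold assignment.
#' @param time,event Column names.
#' @param horizon_days One-year horizon for the event indicator.
#' @return List with `table` (one row per subset: variables, fold AUCs,
#'   `mean_auc`), `chosen` (character vector of chosen candidates),
#'   `folds`, `seed`.
#' @export
combination_search <- function(cohort, base_vars, candidates, folds = 4,
                               seed = 1L, time = "followup_days",
                               event = "event", horizon_days = 365) {
  k <- length(candidates)
  if (k > 20) stopf("more than 20 candidates: exhaustive search refused")
  ev <- cohort[[event]]
  tt <- cohort[[time]]
  usable <- !(ev == 0 & tt < horizon_days)
  if (any(!usable))
    warnf("%d patient(s) censored before the horizon excluded from fold AUCs",
          sum(!usable))
  fold_id <- stratified_folds(ev, folds, seed)
  y <- survival::Surv(tt, ev)
  allvars <- c(base_vars, candidates)
  X <- as.matrix(cohort[, allvars, drop = FALSE])
  one_year <- as.integer(ev == 1)

  subsets <- lapply(0:(2^k - 1), function(bits)
    candidates[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0])
  rows <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    vars <- c(base_vars, subsets[[s]])
    cols <- match(vars, allvars)
    aucs <- rep(NA_real_, folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      te <- fold_id == f & usable
      if (sum(ev[tr]) < 2 || length(unique(one_year[te])) < 2) {
        warnf("fold %d skipped (too few events)", f)
        next
      }
      beta <- cox_coef_fast(X[tr, cols, drop = FALSE], y[tr, ])
      sc <- as.numeric(X[te, cols, drop = FALSE] %*% beta)
      aucs[f] <- auc(sc, one_year[te])
    }
    if (all(is.na(aucs))) stopf("every fold was skipped: cohort too small")
    rows[[s]] <- data.frame(
      subset = paste(subsets[[s]], collapse = "+"),
      size = length(subsets[[s]]),
      t(setNames(aucs, paste0("auc_fold", seq_len(folds)))),
      mean_auc = mean(aucs, na.rm = TRUE))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$mean_auc, tab$size, tab$subset)
  chosen <- subsets[[ord[1]]]
  list(table = tab, chosen = chosen, folds = folds, seed = seed)
}

#' Full three-step biomarker selection pipeline
#'
#' Runs the univariate screen, correlation pruning and exhaustive
#' cross-validated subset search in order, then refits the chosen
#' augmented score on the whole training set (the final coefficients and
#' training means define the deployable score).
#'
#' @inheritParams combination_search
#' @param candidates Candidate biomarker columns.
#' @param alpha Univariate retention threshold (default 0.2).
#' @param corr_threshold Pruning threshold (default 0.85).
#' @return List of class `selection_report`: `screen`, `correlation`,
#'   `pruning`, `search`, `chosen`, `model` (the final [score_model()]).
#' @export
select_biomarkers <- function(cohort, base_vars, candidates, folds = 4,
                              seed = 1L, alpha = 0.2, corr_threshold = 0.85,
                              time = "followup_days", event = "event",
                              horizon_days = 365) {
  screen <- univariate_screen(cohort, candidates, time, event, alpha)
  survivors <- screen$variable[screen$retained]
  if (length(survivors)) {
    corr <- correlation_matrix(cohort, union(survivors, base_vars))
    pruning <- prune_correlated(screen, corr, corr_threshold,
                                protected = base_vars)
  } else {
    corr <- NULL
    pruning <- list(kept = character(), dropped = character(),
                    pairs = data.frame())
  }
  search <- combination_search(cohort, base_vars, pruning$kept, folds, seed,
                               time, event, horizon_days)
  model <- fit_cox(cohort, c(base_vars, search$chosen), time, event,
                   name = "augmented score")
  structure(list(screen = screen, correlation = corr, pruning = pruning,
                 search = search, chosen = search$chosen, model = model),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> screen: %d/%d retained; pruned: %d; chosen: %s\n",
              sum(x$screen$retained), nrow(x$screen),
              length(x$pruning$dropped),
              if (length(x$chosen)) paste(x$chosen, collapse = ", ")
              else "(none)"))
  invisible(x)
}
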