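test_that("the LRT screen retains signal and rejects noise sensibly", {
  co <- simulate_cohort(cohort_sim_spec(
    n = 2000, variable_specs = list(
      signal = list(kind = "binary", prevalence = 0.5),
      noise = list(kind = "continuous", mean = 0, sd = 1, min = -4, max = 4)),
    true_beta = c(signal = log(2)), seed = 41))
  scr <- univariate_screen(co, c("signal", "noise"))
  expect_true(all(scr$lrt_statistic >= 0))
  expect_true(scr$retained[scr$variable == "signal"])
  expect_lt(scr$p_value[scr$variable == "signal"], 0.01)
  expect_true(all(scr$hazard_ratio > 0, na.rm = TRUE))
  # constant candidates are excluded with a reason
  co$flat <- 1
  scr2 <- univariate_screen(co, "flat")
  expect_false(scr2$retained)
  expect_identical(scr2$reason, "constant")
})

test_that("correlation dispatch picks the estimator by variable kind", {
  set.seed(5)
  x <- rnorm(500)
  r <- mixed_correlation(x, x)
  expect_identical(r$method, "spearman")
  expect_identical(r$coefficient, 1)
  b <- as.integer(x > 0)
  o <- cut(x, c(-Inf, -1, 0, 1, Inf), labels = FALSE)
  expect_identical(mixed_correlation(b, as.integer(rev(x) > 0))$method,
                   "tetrachoric")
  expect_identical(suppressWarnings(mixed_correlation(o, o + 0L)$method),
                   "polychoric")
  expect_identical(suppressWarnings(mixed_correlation(b, o)$method),
                   "polychoric")
  expect_identical(mixed_correlation(x, b)$method, "spearman")
  expect_error(mixed_correlation(x[1:5], x[1:5]), "10")
})

test_that("latent correlations recover the generating rho", {
  set.seed(77)
  n <- 5000
  z1 <- rnorm(n)
  z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  b1 <- as.integer(z1 > qnorm(0.6))
  b2 <- as.integer(z2 > qnorm(0.35))
  rt <- mixed_correlation(b1, b2)
  expect_identical(rt$method, "tetrachoric")
  expect_lt(abs(rt$coefficient - 0.6), 0.05)
  # independent ordinals estimate near zero
  o1 <- cut(rnorm(n), c(-Inf, -0.5, 0.5, Inf), labels = FALSE)
  o2 <- cut(rnorm(n), c(-Inf, 0, 1, Inf), labels = FALSE)
  rp <- mixed_correlation(o1, o2)
  expect_identical(rp$method, "polychoric")
  expect_lt(abs(rp$coefficient), 0.05)
})

test_that("correlation pruning drops the worse-p member and protects the core", {
  screen <- data.frame(
    variable = c("raw", "bsai", "lonely"),
    p_value = c(0.01, 0.05, 0.10),
    retained = TRUE)
  corr <- diag(1, 4)
  dimnames(corr) <- list(c("raw", "bsai", "lonely", "core"),
                         c("raw", "bsai", "lonely", "core"))
  corr["raw", "bsai"] <- corr["bsai", "raw"] <- 0.95
  pr <- prune_correlated(screen, corr, protected = "core")
  expect_identical(pr$dropped, "bsai")
  expect_setequal(pr$kept, c("raw", "lonely"))
  # nothing above threshold: nothing dropped
  pr0 <- prune_correlated(screen, diag(1, 4) + 0 *
                            corr, protected = "core")
  expect_identical(pr0$dropped, character(0))
  # candidate correlated with a protected core variable is dropped even
  # with the best p-value
  corr2 <- diag(1, 4)
  dimnames(corr2) <- dimnames(corr)
  corr2["raw", "core"] <- corr2["core", "raw"] <- 0.9
  pr2 <- prune_correlated(screen, corr2, protected = "core")
  expect_identical(pr2$dropped, "raw")
  expect_identical(pr2$pairs$reason, "correlated with protected variable")
})

test_that("three mutually correlated candidates reduce to the best p", {
  screen <- data.frame(variable = c("a", "b", "c"),
                       p_value = c(0.15, 0.03, 0.08), retained = TRUE)
  corr <- matrix(0.9, 3, 3, dimnames = list(c("a", "b", "c"),
                                            c("a", "b", "c")))
  diag(corr) <- 1
  pr <- prune_correlated(screen, corr)
  expect_identical(pr$kept, "b")
  expect_setequal(pr$dropped, c("a", "c"))
})

test_that("combination search enumerates all subsets and scores them by CV AUC", {
  co <- simulate_cohort(cohort_sim_spec(
    n = 600, variable_specs = c(
      list(base1 = list(kind = "binary", prevalence = 0.5)),
      list(c1 = list(kind = "continuous", mean = 0, sd = 1, min = -4, max = 4),
           c2 = list(kind = "binary", prevalence = 0.3))),
    true_beta = c(base1 = 0.5), baseline_hazard = 0.0008, seed = 51))
  cs <- combination_search(co, "base1", c("c1", "c2"), seed = 9)
  expect_identical(nrow(cs$table), 4L)        # 2^k rows including empty
  expect_true("" %in% cs$table$subset)
  expect_true(all(cs$table$mean_auc >= 0 & cs$table$mean_auc <= 1))
  # reproducible under seed
  cs2 <- combination_search(co, "base1", c("c1", "c2"), seed = 9)
  expect_identical(cs$table, cs2$table)
  # single null candidate: the two rows differ only by noise
  cs1 <- combination_search(co, "base1", "c1", seed = 9)
  expect_identical(nrow(cs1$table), 2L)
  expect_lt(abs(diff(cs1$table$mean_auc)), 0.1)
  expect_error(combination_search(co, "base1", paste0("x", 1:21), seed = 1),
               "20")
})

test_that("the empty augmentation reproduces a direct base-only evaluation", {
  co <- binary_cohort(n = 500, beta = 0.7, seed = 61)
  co$noise <- rnorm(500)
  cs <- combination_search(co, "grp", "noise", folds = 4, seed = 5)
  empty_row <- cs$table[cs$table$subset == "", ]
  # recompute the base-only fold AUCs with the same stratified folds
  fold_id <- ecapri:::stratified_folds(co$event, 4, 5)
  y <- survival::Surv(co$followup_days, co$event)
  aucs <- vapply(1:4, function(f) {
    tr <- fold_id != f; te <- fold_id == f
    beta <- ecapri:::cox_coef_fast(as.matrix(co[tr, "grp", drop = FALSE]),
                                   y[tr, ])
    auc(as.matrix(co[te, "grp", drop = FALSE]) %*% beta, co$event[te])
  }, 0)
  expect_equal(empty_row$mean_auc, mean(aucs), tolerance = 1e-12)
})

test_that("the full pipeline enforces step ordering and refits on the whole set", {
  co <- simulate_cohort(cohort_sim_spec(
    n = 1200,
    true_beta = c(bsai_rv_volume = log(1.8) / 27.70, male = 0.5),
    seed = 71))
  rep <- select_biomarkers(co, base_vars = c("male", "age_years"),
                           candidates = c("bsai_rv_volume", "rv_volume_ml",
                                          "lung_volume_ml"),
                           seed = 71)
  survivors <- rep$screen$variable[rep$screen$retained]
  expect_true(all(rep$pruning$kept %in% survivors))
  expect_true(all(rep$chosen %in% rep$pruning$kept))
  # finalization delegates to fit_cox on the full cohort
  direct <- fit_cox(co, c("male", "age_years", rep$chosen))
  expect_identical(rep$model$beta, direct$beta)
  expect_identical(rep$model$xbar, direct$xbar)
  expect_equal(unname(rep$model$xbar),
               unname(colMeans(co[, c("male", "age_years", rep$chosen)])),
               tolerance = 1e-12)
})
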