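test_that("hold-out splits partition the cohort at the stated fraction", {
  set.seed(1)
  sp <- resample(480, sampling_scheme("holdout", 0.80))
  expect_length(sp$train, 384L)
  expect_length(sp$test, 96L)
  expect_setequal(c(sp$train, sp$test), 1:480)
  expect_length(intersect(sp$train, sp$test), 0L)
})

test_that("bootstrap training covers ~63.2% distinct rows, OOB is disjoint", {
  set.seed(2)
  fracs <- replicate(200, {
    sp <- resample(480, sampling_scheme("bootstrap"))
    expect_length(sp$train, 480L)
    expect_length(intersect(unique(sp$train), sp$test), 0L)
    expect_setequal(c(unique(sp$train), sp$test), 1:480)
    length(unique(sp$train)) / 480
  })
  expect_lt(abs(mean(fracs) - (1 - exp(-1))), 0.01)
})

test_that("scheme validation rejects degenerate fractions", {
  expect_error(sampling_scheme("holdout", 0), "strictly between")
  expect_error(sampling_scheme("holdout", 1), "strictly between")
  expect_error(resample(1, sampling_scheme("bootstrap")), "n >= 2")
})

test_that("AUC matches pair enumeration and its symmetries", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75,
               tolerance = 1e-12)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # complement under score negation (tie-free scores)
  set.seed(3)
  s <- stats::runif(50)
  l <- rep(0:1, 25)
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1, tolerance = 1e-12)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  s <- stats::runif(120)
  l <- stats::rbinom(120, 1, stats::plogis(3 * s - 1.5))
  skip_if(length(unique(l)) < 2)
  ours <- roc_auc(s, l)
  theirs <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the DeLong interval brackets the AUC and matches pROC", {
  set.seed(5)
  s <- stats::runif(200)
  l <- stats::rbinom(200, 1, stats::plogis(4 * s - 2))
  ci <- auc_confidence_interval(s, l)
  expect_lte(ci$low, ci$auc)
  expect_gte(ci$high, ci$auc)
  skip_if_not_installed("pROC")
  theirs <- as.numeric(pROC::ci.auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"),
                                    method = "delong"))
  expect_equal(c(ci$low, ci$auc, ci$high), theirs, tolerance = 1e-9)
})

test_that("perfect separation truncates the interval and flags degeneracy", {
  s <- c(0.1, 0.2, 0.8, 0.9)
  l <- c(0, 0, 1, 1)
  ci <- auc_confidence_interval(s, l)
  expect_equal(ci$auc, 1)
  expect_equal(ci$high, 1)
  expect_true(ci$degenerate)
  expect_equal(ci$low, ci$auc)
})

test_that("DeLong and bootstrap-percentile intervals agree on a 480-row set", {
  set.seed(6)
  n <- 480
  l <- stats::rbinom(n, 1, 166 / 480)
  s <- stats::rnorm(n, mean = 0.3 + 0.25 * l, sd = 0.15)
  ci <- auc_confidence_interval(s, l)
  boot <- replicate(2000, {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(l[idx])) < 2) NA_real_ else roc_auc(s[idx], l[idx])
  })
  bq <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  expect_lt(abs(ci$low - bq[1]), 0.005)
  expect_lt(abs(ci$high - bq[2]), 0.005)
})

test_that("the Youden cutoff maximizes J with ties toward the smallest", {
  y <- youden_cutoff(c(0.2, 0.3, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(y$cutoff, 0.6)
  expect_equal(y$j, 1)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)

  allt <- youden_cutoff(rep(0.5, 4), c(0, 1, 0, 1))
  expect_equal(allt$j, 0)
  expect_equal(allt$cutoff, 0.5)

  # inverted labels: a perfect classifier's scan tops out at J = 0
  inv <- youden_cutoff(c(0.2, 0.3, 0.6, 0.9), c(1, 1, 0, 0))
  expect_lte(inv$j, 0 + 1e-12)
})

test_that("roc_points trace the empirical ROC curve", {
  pts <- roc_points(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  # trapezoidal area equals the rank AUC
  area <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                 utils::tail(pts$tpr, -1)) / 2)
  expect_equal(area, 0.75, tolerance = 1e-12)
})

test_that("the validation protocol reaches min_tests and reproduces", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 120, seed = 70)
  st <- ground_truth_structure()
  v1 <- run_validation(cohort, st, "atlas5", sampling_scheme("bootstrap"),
                       min_tests = 5L, seed = 71)
  expect_true(all(v1$per_patient_test_count >= 5L))
  expect_true(all(v1$per_patient_mean_probability >= 0 &
                    v1$per_patient_mean_probability <= 1))
  expect_gte(v1$auc, 0)
  expect_lte(v1$auc, 1)
  expect_lte(v1$auc_ci_low, v1$auc)
  expect_gte(v1$auc_ci_high, v1$auc)

  v2 <- run_validation(cohort, st, "atlas5", sampling_scheme("bootstrap"),
                       min_tests = 5L, seed = 71)
  expect_identical(v1$per_patient_mean_probability,
                   v2$per_patient_mean_probability)
  expect_identical(v1$auc, v2$auc)
  expect_identical(v1$n_cycles, v2$n_cycles)
})

test_that("an empty predictor set scores every patient identically", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 80, seed = 72)
  v <- run_validation(cohort, ground_truth_structure(), character(0),
                      sampling_scheme("holdout", 0.8), min_tests = 3L,
                      seed = 73)
  # constant within every cycle; averaged scores are near-constant, and
  # each cycle's AUC is exactly 0.5 under the tie convention
  expect_true(all(abs(stats::na.omit(v$cycle_auc) - 0.5) < 1e-12))
})

test_that("validation guards degenerate inputs", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 50, seed = 74)
  st <- ground_truth_structure()
  expect_error(run_validation(cohort, st, c("sex", "relapse")), "outcome")
  one_class <- bnaf:::cohort_subset(cohort, which(cohort$relapse == "false"))
  expect_error(run_validation(one_class, st, "atlas5"), "single outcome class")
})

test_that("profile probability bands behave like resampling intervals", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 480, seed = 75)
  st <- ground_truth_structure()
  ev <- evidence(sex = "female", age = "over65", smoking = "false")

  one <- profile_probability_ci(cohort, st, ev,
                                sampling_scheme("holdout", 0.9),
                                n_cycles = 1L, seed = 76)
  expect_equal(one$low, one$mean, tolerance = 1e-12)
  expect_equal(one$high, one$mean, tolerance = 1e-12)

  many <- profile_probability_ci(cohort, st, ev,
                                 sampling_scheme("holdout", 0.9),
                                 n_cycles = 40L, seed = 76)
  expect_equal(many$mean, mean(many$cycle_probs), tolerance = 1e-12)
  expect_lte(many$low, many$mean)
  expect_gte(many$high, many$mean)
  expect_true(many$mean > 0 && many$mean < 1)
})

test_that("smaller training fractions widen the profile band on average", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 480, seed = 77)
  st <- ground_truth_structure()
  ev <- evidence(sex = "male", age = "46to65", smoking = "true")
  wider <- 0L
  for (s in 1:5) {
    w80 <- profile_probability_ci(cohort, st, ev,
                                  sampling_scheme("holdout", 0.80),
                                  n_cycles = 30L, seed = 500 + s)
    w95 <- profile_probability_ci(cohort, st, ev,
                                  sampling_scheme("holdout", 0.95),
                                  n_cycles = 30L, seed = 600 + s)
    wider <- wider + ((w80$high - w80$low) > (w95$high - w95$low))
  }
  expect_gte(wider, 4L)
})
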