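#' Define a resampling scheme
#'
#' Four schemes are supported: bootstrap (training set = n draws with
#' replacement, test set = out-of-bag rows, so on average `1 - 1/e` = 63.2%
#' of distinct observations train the model), and hold-out with fixed
#' train fractions 0.80, 0.90 or 0.95 (any fraction strictly inside (0,1)
#' is accepted).
#'
#' @param kind `"bootstrap"` or `"holdout"`.
#' @param train_fraction Training fraction for hold-out; ignored by
#'   bootstrap.
#' @return An object of class `bnaf_scheme`.
#' @export
sampling_scheme <- function(kind = c("bootstrap", "holdout"),
                            train_fraction = 0.8) {
  kind <- match.arg(kind)
  if (kind == "holdout") {
    if (!is.numeric(train_fraction) || train_fraction <= 0 ||
        train_fraction >= 1) {
      stop("holdout train_fraction must lie strictly between 0 and 1",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, train_fraction = train_fraction),
            class = "bnaf_scheme")
}

scheme_label <- function(scheme) {
  if (scheme$kind == "bootstrap") "bootstrap"
  else sprintf("holdout %d:%d", round(100 * scheme$train_fraction),
               round(100 * (1 - scheme$train_fraction)))
}

#' Draw one train/test split
#'
#' Bootstrap: `n` draws with replacement form the training multiset, the
#' never-drawn (out-of-bag) rows form the test set. Hold-out: a uniform
#' random partition with `floor(fraction * n)` training rows. Draws use
#' the current RNG state; a split with an empty test set (possible for
#' tiny `n`) is retried, and the number of retries recorded.
#'
#' @param n Cohort size (at least 2).
#' @param scheme A [sampling_scheme()].
#' @return List with `train` (indices, multiset for bootstrap), `test`
#'   (indices), and `retries`.
#' @export
resample <- function(n, scheme = sampling_scheme("bootstrap")) {
  stopifnot(n >= 2L)
  retries <- 0L
  repeat {
    if (scheme$kind == "bootstrap") {
      train <- sample.int(n, n, replace = TRUE)
      test <- setdiff(seq_len(n), train)
    } else {
      train <- sample.int(n, floor(scheme$train_fraction * n))
      test <- setdiff(seq_len(n), train)
    }
    if (length(test) > 0L && length(unique(train)) > 0L) {
      return(list(train = train, test = test, retries = retries))
    }
    retries <- retries + 1L
    if (retries > 1000L) stop("could not draw a non-empty test set",
                              call. = FALSE)
  }
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counting one half — the Mann-Whitney U statistic
#' scaled to `[0, 1]`, identical to the trapezoidal area under the ROC
#' curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or a factor whose second
#'   level is positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.character(labels)) labels <- as.integer(labels == "true")
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary", call. = FALSE)
  }
  as.integer(labels)
}

#' DeLong confidence interval for an AUC
#'
#' Normal-quantile interval around the empirical AUC with the DeLong
#' variance estimate (placement values of positives and negatives),
#' truncated to `[0, 1]`. A degenerate variance (e.g. perfect separation)
#' collapses the interval to the point estimate, flagged via the
#' `degenerate` field.
#'
#' @param scores,labels As in [roc_auc()].
#' @param level Confidence level (default 0.95).
#' @return List: `auc`, `low`, `high`, `se`, `degenerate`.
#' @export
auc_confidence_interval <- function(scores, labels, level = 0.95) {
  labels <- as_binary_labels(labels)
  x <- scores[labels == 1L]  # positives
  y <- scores[labels == 0L]  # negatives
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both classes must be present", call. = FALSE)
  auc <- roc_auc(scores, labels)
  # placement values
  vx <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
               numeric(1L))
  vy <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m,
               numeric(1L))
  s2 <- stats::var(vx) / m + stats::var(vy) / n
  degenerate <- !is.finite(s2) || s2 <= 0
  se <- if (degenerate) 0 else sqrt(s2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       low = max(0, auc - z * se),
       high = min(1, auc + z * se),
       se = se, degenerate = degenerate)
}

#' Youden-optimal classification cutoff
#'
#' Scans the observed score values as candidate thresholds under the rule
#' "positive iff score >= cutoff" and returns the cutoff maximizing the
#' Youden J statistic (sensitivity + specificity - 1); ties go to the
#' smallest cutoff.
#'
#' @param scores,labels As in [roc_auc()].
#' @return List: `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("cutoff undefined: both classes must be present", call. = FALSE)
  }
  cand <- sort(unique(scores))
  best <- NULL
  for (ct in cand) {
    sens <- sum(scores >= ct & labels == 1L) / n_pos
    spec <- sum(scores < ct & labels == 0L) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec, j = j)
    }
  }
  best
}

#' ROC curve points
#'
#' False-positive and true-positive rates at every observed threshold,
#' suitable for plotting or CSV export.
#'
#' @param scores,labels As in [roc_auc()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1L))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

# deterministic per-cycle child seed below 2^31
child_seed <- function(master_seed, cycle) {
  (as.numeric(master_seed) * 48271 + cycle * 69621) %% 2147483629
}

#' Out-of-sample validation by repeated resampling
#'
#' One protocol cycle: draw a train/test split, refit the CPTs (the
#' structure stays fixed) on the training rows, and record the predicted
#' relapse probability for every test row. Whole-cohort cycles repeat
#' until every patient has been tested at least `min_tests` times; each
#' patient's final score is the arithmetic mean of their recorded
#' probabilities, and AUC / CI / Youden cutoff are computed on those mean
#' scores against the true outcomes. Fully reproducible: each cycle's RNG
#' seed is derived from `seed`.
#'
#' @param cohort Cohort including the outcome column.
#' @param structure Fixed `bnaf_structure` over the schema.
#' @param predictors Predictor names or a [predictor_set()] name.
#' @param scheme A [sampling_scheme()].
#' @param min_tests Minimum number of test inclusions per patient
#'   (default 30).
#' @param ess Equivalent sample size for each refit.
#' @param seed Master seed (integer).
#' @param max_cycles Safety cap on protocol cycles.
#' @return An object of class `bnaf_validation`: per-patient mean
#'   probabilities and test counts, `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `youden`, `scheme`, `predictors`, `n_cycles`, `cycle_seeds`, and
#'   per-cycle AUCs.
#' @export
run_validation <- function(cohort, structure, predictors = "full7",
                           scheme = sampling_scheme("bootstrap"),
                           min_tests = 30L, ess = 1, seed = 1L,
                           max_cycles = 100000L) {
  schema <- cohort_schema(cohort)
  outcome <- schema$outcome
  predictors <- predictor_set(predictors)
  if (outcome %in% predictors) {
    stop("the predictor set must not contain the outcome", call. = FALSE)
  }
  n <- nrow(cohort)
  truth <- as_binary_labels(cohort[[outcome]])
  if (length(unique(truth)) < 2L) {
    stop("AUC undefined: the cohort contains a single outcome class",
         call. = FALSE)
  }
  sums <- numeric(n)
  counts <- integer(n)
  cycle_seeds <- numeric(0L)
  cycle_auc <- numeric(0L)
  cycle <- 0L
  while (min(counts) < min_tests) {
    cycle <- cycle + 1L
    if (cycle > max_cycles) {
      stop("max_cycles exceeded before reaching min_tests", call. = FALSE)
    }
    cs <- child_seed(seed, cycle)
    set.seed(cs)
    cycle_seeds[cycle] <- cs
    sp <- resample(n, scheme)
    fit <- fit_cpts(structure, cohort_subset(cohort, sp$train), ess = ess)
    p <- predict_cohort(fit, cohort_subset(cohort, sp$test), predictors)
    sums[sp$test] <- sums[sp$test] + p
    counts[sp$test] <- counts[sp$test] + 1L
    cycle_auc[cycle] <- if (length(unique(truth[sp$test])) == 2L) {
      roc_auc(p, truth[sp$test])
    } else NA_real_
  }
  mean_p <- sums / counts
  ci <- auc_confidence_interval(mean_p, truth)
  yj <- youden_cutoff(mean_p, truth)
  structure(list(per_patient_mean_probability = mean_p,
                 per_patient_test_count = counts,
                 auc = ci$auc, auc_ci_low = ci$low, auc_ci_high = ci$high,
                 youden = yj,
                 scheme = scheme, predictors = predictors,
                 min_tests = min_tests, ess = ess, seed = seed,
                 n_cycles = cycle, cycle_seeds = cycle_seeds,
                 cycle_auc = cycle_auc, truth = truth),
            class = "bnaf_validation")
}

#' @export
print.bnaf_validation <- function(x, ...) {
  cat(sprintf("Validation [%s], %d predictors, %d cycles\n",
              scheme_label(x$scheme), length(x$predictors), x$n_cycles))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), Youden cutoff %.3f\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$youden$cutoff))
  cat(sprintf("  per-patient tests: min %d, median %d\n",
              min(x$per_patient_test_count),
              stats::median(x$per_patient_test_count)))
  invisible(x)
}

#' Validate under all four resampling schemes
#'
#' Runs [run_validation()] under bootstrap and hold-out 80:20, 90:10 and
#' 95:5, and reports the per-scheme AUCs together with their arithmetic
#' mean — one row of the usual scheme-comparison table.
#'
#' @inheritParams run_validation
#' @return List with `runs` (named list of `bnaf_validation`) and `table`
#'   (data.frame of per-scheme AUC and CI plus the mean row).
#' @export
validate_all_schemes <- function(cohort, structure, predictors = "full7",
                                 min_tests = 30L, ess = 1, seed = 1L) {
  schemes <- list(bootstrap = sampling_scheme("bootstrap"),
                  `split_80_20` = sampling_scheme("holdout", 0.80),
                  `split_90_10` = sampling_scheme("holdout", 0.90),
                  `split_95_5` = sampling_scheme("holdout", 0.95))
  runs <- lapply(seq_along(schemes), function(i) {
    run_validation(cohort, structure, predictors, schemes[[i]],
                   min_tests = min_tests, ess = ess,
                   seed = child_seed(seed, 7919 * i))
  })
  names(runs) <- names(schemes)
  tab <- data.frame(
    scheme = c(names(schemes), "mean"),
    auc = c(vapply(runs, `[[`, numeric(1L), "auc"),
            mean(vapply(runs, `[[`, numeric(1L), "auc"))),
    ci_low = c(vapply(runs, `[[`, numeric(1L), "auc_ci_low"), NA),
    ci_high = c(vapply(runs, `[[`, numeric(1L), "auc_ci_high"), NA),
    n_cycles = c(vapply(runs, `[[`, numeric(1L), "n_cycles"), NA))
  list(runs = runs, table = tab)
}

#' Resampled probability band for one clinical profile
#'
#' Refits the CPTs on `n_cycles` resamples and queries the same fixed
#' evidence each time; reports the mean probability of the positive
#' outcome with a 2.5/97.5 percentile band — the per-profile analogue of
#' per-patient averaged validation. Cycles whose refit makes the evidence
#' impossible are skipped and counted.
#'
#' @param cohort Training cohort.
#' @param structure Fixed structure.
#' @param ev An [evidence()] object (must not assign the outcome).
#' @param scheme A [sampling_scheme()].
#' @param n_cycles Number of refits.
#' @param ess Equivalent sample size per refit.
#' @param seed Master seed.
#' @return List: `mean`, `low`, `high`, `cycle_probs`, `n_excluded`.
#' @export
profile_probability_ci <- function(cohort, structure, ev,
                                   scheme = sampling_scheme("bootstrap"),
                                   n_cycles = 100L, ess = 1, seed = 1L) {
  schema <- cohort_schema(cohort)
  outcome <- schema$outcome
  ev <- check_evidence(ev, schema, target = outcome)
  n <- nrow(cohort)
  probs <- numeric(0L)
  excluded <- 0L
  for (cycle in seq_len(n_cycles)) {
    set.seed(child_seed(seed, cycle))
    sp <- resample(n, scheme)
    fit <- fit_cpts(structure, cohort_subset(cohort, sp$train), ess = ess)
    p <- tryCatch(query(fit, outcome, ev)$distribution[["true"]],
                  error = function(e) NA_real_)
    if (is.na(p)) excluded <- excluded + 1L else probs <- c(probs, p)
  }
  if (!length(probs)) stop("every cycle excluded the evidence", call. = FALSE)
  qs <- stats::quantile(probs, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = mean(probs), low = qs[1L], high = qs[2L],
       cycle_probs = probs, n_excluded = excluded)
}
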