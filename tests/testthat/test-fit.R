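test_that("posterior-mean fitting matches the closed form on one node", {
  # 166 relapses of 480, ESS = 1: alpha = 1/2, posterior mean (166+0.5)/481
  cohort <- cohort_from_counts(c(false = 314L, true = 166L))
  st <- network_structure("x")
  fit <- fit_cpts(st, cohort, ess = 1)
  expect_equal(unname(fit$cpts$x$prob["true"]), (166 + 0.5) / 481,
               tolerance = 1e-12)
  expect_equal(sum(fit$cpts$x$prob), 1, tolerance = 1e-12)
})

test_that("the prior alone gives uniform CPTs, and dominates at huge ESS", {
  schema <- domain_schema(list(variable_spec("x", c("false", "true"))),
                          outcome = "x")
  empty <- as_cohort(data.frame(x = character(0)), schema)
  fit <- fit_cpts(network_structure("x"), empty, ess = 1)
  expect_equal(as.numeric(fit$cpts$x$prob), c(0.5, 0.5))

  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 480, seed = 1)
  empty_arcs <- network_structure(gt$structure$nodes)
  big <- fit_cpts(empty_arcs, cohort, ess = 1e9)
  for (ct in big$cpts) {
    r <- dim(as.array(ct$prob))[1]
    expect_true(max(abs(as.numeric(ct$prob) - 1 / r)) < 1e-6)
  }
})

test_that("every fitted CPT row normalizes and is strictly positive", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 200, seed = 2)
  fit <- fit_cpts(gt$structure, cohort, ess = 1)
  for (ct in fit$cpts) {
    m <- matrix(as.numeric(ct$prob), nrow = dim(as.array(ct$prob))[1])
    expect_true(all(abs(colSums(m) - 1) < 1e-9))
    expect_true(all(m > 0))
  }
})

test_that("fitting is invariant to cohort row order", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 300, seed = 4)
  set.seed(99)
  shuffled <- bnaf:::cohort_subset(cohort, sample(nrow(cohort)))
  f1 <- fit_cpts(gt$structure, cohort, ess = 1)
  f2 <- fit_cpts(gt$structure, shuffled, ess = 1)
  for (node in gt$structure$nodes) {
    expect_equal(f1$cpts[[node]]$prob, f2$cpts[[node]]$prob,
                 tolerance = 1e-12)
  }
})

test_that("the ESS -> 0 limit reproduces ML frequencies at nonzero counts", {
  cohort <- cohort_from_counts(c(a = 30L, b = 50L, c = 20L),
                               states = c("a", "b", "c"))
  fit <- fit_cpts(network_structure("x"), cohort, ess = 1e-9)
  expect_equal(unname(as.numeric(fit$cpts$x$prob)), c(0.3, 0.5, 0.2),
               tolerance = 1e-9)
  expect_error(fit_cpts(network_structure("x"), cohort, ess = 0), "positive")
  expect_error(fit_cpts(network_structure("x"), cohort, ess = -1), "positive")
})

test_that("fitted CPTs converge to the generating CPTs as n grows", {
  gt <- build_ground_truth()
  wins <- 0L
  for (s in 1:10) {
    small <- fit_cpts(gt$structure, sample_cohort(gt, 500, seed = 100 + s))
    large <- fit_cpts(gt$structure, sample_cohort(gt, 50000, seed = 200 + s))
    d_small <- bnaf:::mean_cpt_tv(gt, small)
    d_large <- bnaf:::mean_cpt_tv(gt, large)
    wins <- wins + (d_large < d_small)
  }
  expect_gte(wins, 9L)
})

test_that("log-likelihood matches closed forms and decomposes", {
  # one binary node with P(true) = 0.5 and two rows: log(0.25)
  schema <- domain_schema(list(variable_spec("x", c("false", "true"))),
                          outcome = "x")
  st <- network_structure("x")
  net <- fitted_network(st, list(
    x = cpt("x", character(0),
            array(c(0.5, 0.5), 2, list(x = c("false", "true"))))), schema)
  cohort <- as_cohort(data.frame(x = c("false", "true")), schema)
  expect_equal(loglikelihood(net, cohort), log(0.25), tolerance = 1e-12)

  # agreement with brute-force joint enumeration on a random network
  net4 <- random_network(4, seed = 17)
  schema4 <- net4$schema
  set.seed(18)
  df <- as.data.frame(lapply(schema4$variables, function(v) {
    sample(v$states, 20, replace = TRUE)
  }))
  cohort4 <- as_cohort(df, schema4)
  ll <- loglikelihood(net4, cohort4)
  brute <- sum(vapply(seq_len(20), function(i) {
    log(joint_probability(net4, as.list(lapply(cohort4[i, ], as.character))))
  }, numeric(1)))
  expect_equal(ll, brute, tolerance = 1e-9)
  expect_lte(ll, 0)
})

test_that("zero-probability cells flag a distinct -Inf", {
  schema <- domain_schema(list(variable_spec("x", c("false", "true"))),
                          outcome = "x")
  st <- network_structure("x")
  net <- fitted_network(st, list(
    x = cpt("x", character(0),
            array(c(1, 0), 2, list(x = c("false", "true"))))), schema)
  cohort <- as_cohort(data.frame(x = c("false", "true")), schema)
  ll <- loglikelihood(net, cohort)
  expect_identical(as.numeric(ll), -Inf)
  expect_identical(attr(ll, "zero_cells"), 1L)
})

test_that("fitted_network validates CPT/structure agreement", {
  schema <- binary_schema(c("A", "B"))
  st <- network_structure(c("A", "B"), arcs = rbind(c("A", "B")))
  good_a <- cpt("A", character(0),
                array(c(0.4, 0.6), 2, list(A = c("false", "true"))))
  expect_error(fitted_network(st, list(A = good_a, B = good_a), schema),
               "does not match")
})
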