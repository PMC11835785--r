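test_that("joint probability follows the product rule", {
  net <- two_node_network(pa = 0.3, pb_f = 0.2, pb_t = 0.9)
  expect_equal(joint_probability(net, c(A = "true", B = "true")), 0.27,
               tolerance = 1e-12)
  expect_equal(joint_probability(net, c(A = "false", B = "true")),
               0.7 * 0.2, tolerance = 1e-12)
  expect_error(joint_probability(net, c(A = "true")), "every node")

  # annihilation by a zero CPT entry
  net0 <- two_node_network(pa = 0, pb_f = 0.2, pb_t = 0.9)
  expect_identical(joint_probability(net0, c(A = "true", B = "true")), 0)
})

test_that("the full joint of the default schema normalizes", {
  gt <- build_ground_truth()
  p <- bnaf:::joint_vector(gt)
  expect_length(p, 20736L)
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("a two-node query reproduces Bayes rule by hand", {
  net <- two_node_network(pa = 0.3, pb_f = 0.2, pb_t = 0.9)
  # P(A=t | B=t) = 0.27 / (0.27 + 0.14)
  qr <- query(net, "A", evidence(B = "true"))
  expect_equal(unname(qr$distribution[["true"]]), 0.27 / (0.27 + 0.14),
               tolerance = 1e-12)
  expect_equal(sum(qr$distribution), 1, tolerance = 1e-12)
})

test_that("empty evidence yields the marginal; root nodes their CPT", {
  net <- two_node_network(pa = 0.3)
  qr <- query(net, "A")
  expect_equal(unname(qr$distribution), c(0.7, 0.3), tolerance = 1e-12)
})

test_that("conditioning on the full parent configuration returns the CPT row", {
  gt <- build_ground_truth()
  parents <- bnaf:::parents_of(gt$structure, "relapse")
  ev <- lapply(parents, function(p) gt$schema$variables[[p]]$states[[2]])
  names(ev) <- parents
  qr <- query(gt, "relapse", evidence(ev))
  idx <- c(list(2L), rep(list(2L), length(parents)))
  expected <- do.call(`[`, c(list(gt$cpts$relapse$prob), idx))
  expect_equal(unname(qr$distribution[["true"]]), expected, tolerance = 1e-9)
})

test_that("enumeration, variable elimination and brute force agree", {
  for (s in 1:30) {
    net <- random_network(sample(3:6, 1), seed = 1000 + s)
    nodes <- names(net$schema$variables)
    target <- sample(nodes, 1)
    n_ev <- sample(0:2, 1)
    ev_vars <- sample(setdiff(nodes, target), n_ev)
    ev <- lapply(ev_vars, function(v) {
      sample(net$schema$variables[[v]]$states, 1)
    })
    names(ev) <- ev_vars
    q_enum <- tryCatch(query(net, target, evidence(ev)),
                       error = function(e) NULL)
    if (is.null(q_enum)) next  # impossible evidence drawn
    q_ve <- query(net, target, evidence(ev), method = "ve")
    brute <- brute_force_query(net, target, ev)
    expect_lt(max(abs(q_enum$distribution - q_ve$distribution)), 1e-9)
    expect_lt(max(abs(q_enum$distribution - brute)), 1e-9)
  }
})

test_that("marginalizing a variable equals averaging over its posterior", {
  # law of total probability: dropping v from full evidence must equal
  # the v-posterior-weighted average of the full-evidence answers
  net <- random_network(5, seed = 55, arc_prob = 0.5)
  nodes <- names(net$schema$variables)
  target <- nodes[5]
  dropped <- nodes[2]
  others <- setdiff(nodes, c(target, dropped))
  set.seed(56)
  ev <- lapply(others, function(v) sample(net$schema$variables[[v]]$states, 1))
  names(ev) <- others
  partial <- query(net, target, evidence(ev))$distribution
  w <- query(net, dropped, evidence(ev))$distribution
  acc <- 0
  for (s in net$schema$variables[[dropped]]$states) {
    full_ev <- c(ev, stats::setNames(list(s), dropped))
    acc <- acc + w[[s]] * query(net, target, evidence(full_ev))$distribution
  }
  expect_equal(unname(partial), unname(acc), tolerance = 1e-9)
})

test_that("impossible evidence raises a distinct error", {
  net0 <- two_node_network(pa = 0, pb_f = 0.2, pb_t = 0.9)
  expect_error(query(net0, "B", evidence(A = "true")), "impossible evidence")
  expect_error(query(net0, "B", evidence(A = "true"), method = "ve"),
               "impossible evidence")
})

test_that("evidence validation rejects bad variables, states and targets", {
  gt <- build_ground_truth()
  expect_error(query(gt, "relapse", evidence(nonsense = "true")),
               "not in the schema")
  expect_error(query(gt, "relapse", evidence(sex = "banana")), "allowed")
  expect_error(query(gt, "relapse", evidence(relapse = "true")),
               "must not assign")
})

test_that("named predictor sets expand to the documented variables", {
  expect_setequal(predictor_set("atlas5"),
                  c("age", "sex", "smoking", "af_type", "osa"))
  expect_setequal(predictor_set("easy6"),
                  c("age", "sex", "smoking", "af_type", "osa", "bmi"))
  expect_setequal(predictor_set("full7"),
                  c("age", "sex", "smoking", "af_type", "osa",
                    "la_volume", "epicardial_fat"))
})

test_that("cohort prediction matches per-row queries and preserves order", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 40, seed = 60)
  p <- predict_cohort(gt, cohort, "easy6")
  expect_length(p, 40L)
  for (i in c(1L, 17L, 40L)) {
    ev <- lapply(predictor_set("easy6"), function(v) {
      as.character(cohort[[v]][i])
    })
    names(ev) <- predictor_set("easy6")
    expect_equal(p[i],
                 unname(query(gt, "relapse", evidence(ev))$distribution[["true"]]),
                 tolerance = 1e-9)
  }
  # identical predictor rows get identical probabilities
  dup <- bnaf:::cohort_subset(cohort, c(1L, 1L, 2L))
  pd <- predict_cohort(gt, dup, "full7")
  expect_identical(pd[1], pd[2])
})

test_that("empty predictor set gives every row the outcome marginal", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 10, seed = 61)
  p <- predict_cohort(gt, cohort, character(0))
  expect_equal(unname(p), rep(166 / 480, 10), tolerance = 1e-9)
  expect_error(predict_cohort(gt, cohort, c("sex", "relapse")), "outcome")
})

test_that("self-consistent predictions are calibrated in the mean", {
  gt <- build_ground_truth()
  cohort <- sample_cohort(gt, 20000, seed = 62)
  p <- predict_cohort(gt, cohort,
                      setdiff(names(gt$schema$variables), "relapse"))
  expect_lt(abs(mean(p) - 166 / 480), 0.01)
})
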